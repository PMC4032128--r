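# In-code fixtures shared across test files.

# a chain directly from block coordinates
mk_chain <- function(starts, ends, min_intron = 40) {
  intron_chain(cbind(start = starts, end = ends), min_intron = min_intron)
}

# three-exon toy gene: e1 [0,100), e2 [200,300), e3 [400,500)
toy_template <- cbind(c(0, 200, 400), c(100, 300, 500))
toy_inclusion <- function() mk_chain(c(0, 200, 400), c(100, 300, 500))
toy_skip_e2 <- function() mk_chain(c(0, 400), c(100, 500))

# random toy gene (<= 6 exons, <= 4 isoforms) plus a mix of full-length
# and truncated chains, for oracle-equivalence testing
random_toy_gene <- function(seed) {
  cfg <- sim_config(
    n_genes = 1, n_exons = c(3, 6), n_isoforms = c(2, 4),
    exon_length = c(60, 150), intron_length = c(80, 400),
    freq_alpha = 1, seed = seed
  )
  sim <- simulate_gene_models(cfg)
  chains <- lapply(sim$isoforms$exons, intron_chain)
  # truncated variants: clip a random margin off both ends of each isoform
  clipped <- withr::with_seed(seed + 13, {
    lapply(sim$isoforms$exons, function(ex) {
      span <- ex[nrow(ex), 2] - ex[1, 1]
      lo <- ex[1, 1] + sample.int(floor(span / 3), 1)
      hi <- ex[nrow(ex), 2] - sample.int(floor(span / 3), 1)
      m <- ex[ex[, 2] > lo & ex[, 1] < hi, , drop = FALSE]
      if (nrow(m) == 0) return(NULL)
      m[1, 1] <- max(m[1, 1], lo)
      m[nrow(m), 2] <- min(m[nrow(m), 2], hi)
      intron_chain(m)
    })
  })
  clipped <- clipped[!vapply(clipped, is.null, logical(1))]
  tmpl <- merge_intervals(do.call(rbind, c(list(sim$genes$exons[[1]]),
                                           sim$isoforms$exons)))
  list(
    chains = c(chains, clipped),
    template = tmpl,
    strand = sim$genes$strand[1],
    truth = sim$truth
  )
}

# small trait table on a random ultrametric tree
toy_trait_setup <- function(n = 24, seed = 5) {
  tree <- simulate_ultrametric_tree(n, depth = 1400, seed = seed)
  xs <- simulate_bm_traits(tree, sigma2 = 1 / 1400, lambda = 1,
                           seed = seed, label = "x")
  es <- simulate_bm_traits(tree, sigma2 = 0.25 / 1400, lambda = 1,
                           seed = seed, label = "e")
  traits <- tibble::tibble(
    species = xs$species,
    x = xs$value,
    y = 1 + 2 * xs$value + es$value
  )
  list(tree = tree, traits = traits)
}
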