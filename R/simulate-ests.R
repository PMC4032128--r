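#' Simulate an EST library for simulated gene models
#'
#' Emulates the generative process behind EST archives: per-gene
#' expression weights are log-normal, each gene's EST count is Poisson
#' with mean proportional to expression (so transcript coverage per gene
#' varies over orders of magnitude), each EST picks an isoform by
#' frequency, covers a contiguous transcript fraction (optionally
#' anchored at the 3' end, as poly-A-primed single-pass reads are), is
#' mapped back to genomic blocks through the isoform's exon structure,
#' and carries an alignment identity drawn from a noise model under which
#' a minority of ESTs fall below the 95% retention threshold.
#'
#' @param sim Output of [simulate_gene_models()].
#' @param config Optional [sim_config()] override (default `sim$config`).
#' @return A tibble shaped like [read_est_alignments()] output, plus
#'   truth columns `gene_id_true` and `isoform_id`.
#' @export
simulate_est_library <- function(sim, config = sim$config) {
  stopifnot(inherits(config, "sim_config"))
  with_stream(config$seed, "est_library", {
    genes <- sim$genes
    iso <- sim$isoforms
    n_g <- nrow(genes)
    w <- rlnorm(n_g, meanlog = 0, sdlog = config$expression_sdlog)
    depth <- config$mean_depth * w / exp(config$expression_sdlog^2 / 2)
    n_est <- rpois(n_g, depth)
    counter <- 0L
    rows <- vector("list", n_g)
    for (g in seq_len(n_g)) {
      if (n_est[g] == 0) next
      gid <- genes$gene_id[g]
      strand <- genes$strand[g]
      gi <- iso[iso$gene_id == gid, , drop = FALSE]
      pick <- sample.int(nrow(gi), n_est[g], replace = TRUE,
                         prob = gi$frequency)
      blocks <- lapply(seq_len(n_est[g]), function(k) {
        simulate_read_blocks(gi$exons[[pick[k]]], strand, config)
      })
      identity <- round(1000 * (0.8 + 0.2 * rbeta(
        n_est[g], config$identity_beta[1], config$identity_beta[2]
      ))) / 1000
      rows[[g]] <- tibble::tibble(
        est_id = sprintf("est%06d", counter + seq_len(n_est[g])),
        library_id = "lib1",
        chrom = genes$chrom[g],
        strand = strand,
        start = vapply(blocks, function(m) m[1, 1], numeric(1)),
        end = vapply(blocks, function(m) m[nrow(m), 2], numeric(1)),
        identity = identity,
        blocks = blocks,
        gene_id_true = gid,
        isoform_id = gi$isoform_id[pick]
      )
      counter <- counter + n_est[g]
    }
    dplyr::bind_rows(rows)
  })
}

# map a contiguous transcript window of one isoform to genomic blocks
simulate_read_blocks <- function(exons, strand, config) {
  lens <- exons[, 2] - exons[, 1]
  L <- sum(lens)
  if (config$full_length) {
    t_s <- 0
    t_e <- L
  } else {
    frac <- rbeta(1, config$coverage_shape[1], config$coverage_shape[2])
    l <- min(L, max(20, round(frac * L)))
    if (runif(1) < config$end_bias) {
      t_s <- L - l                       # anchored at transcript 3' end
    } else {
      t_s <- floor(runif(1, 0, L - l + 1))
    }
    t_e <- t_s + l
  }
  # transcript coordinates run 5'->3'; convert to genomic
  if (strand == "-") {
    g_s <- L - t_e
    g_e <- L - t_s
  } else {
    g_s <- t_s
    g_e <- t_e
  }
  # walk exons in genomic order accumulating transcript offsets
  offs <- cumsum(c(0, lens))
  keep <- which(offs[-length(offs)] < g_e & offs[-1] > g_s)
  m <- cbind(
    start = exons[keep, 1] + pmax(0, g_s - offs[keep]),
    end = exons[keep, 1] + pmin(lens[keep], g_e - offs[keep])
  )
  m
}

#' Simulate an ultrametric species tree
#'
#' A random pure-birth (Yule) topology rescaled so every tip is exactly
#' `depth` time units (e.g. My) from the root. Pure-birth trees spread
#' divergences evenly over the tree's history, the usual stand-in for a
#' time-calibrated species tree.
#'
#' @param n_tips Number of species.
#' @param depth Root-to-tip depth (default 1400, the span of eukaryotic
#'   divergence the comparative analyses cover).
#' @param seed Integer seed.
#' @return An `ape::phylo` tree with tips `sp01, sp02, ...`.
#' @export
simulate_ultrametric_tree <- function(n_tips, depth = 1400, seed = 1) {
  with_stream(seed, "tree", {
    tr <- ape::rphylo(n_tips, birth = 1, death = 0)
    tr$tip.label <- sprintf("sp%02d", seq_len(n_tips))
    d <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * depth / d
    tr
  })
}

#' Simulate trait values under lambda-scaled Brownian motion
#'
#' Draws one multivariate-normal trait vector with covariance
#' `sigma2 * V(lambda)`, where `V(lambda)` is the Brownian-motion matrix
#' of the tree with off-diagonals scaled by lambda (`lambda = 0`: star
#' phylogeny / independent tips; `lambda = 1`: pure Brownian motion).
#'
#' @param tree `ape::phylo` tree.
#' @param sigma2 Brownian rate (variance per unit branch length).
#' @param lambda Phylogenetic signal in `[0, 1]`.
#' @param seed Integer seed.
#' @param label Stream label so several independent traits can be drawn
#'   from one seed.
#' @return Tibble with columns `species` and `value`.
#' @export
simulate_bm_traits <- function(tree, sigma2 = 1, lambda = 1, seed = 1,
                               label = "bm_trait") {
  stopifnot(lambda >= 0, lambda <= 1, sigma2 > 0)
  V <- sigma2 * lambda_cov(bm_covariance(tree), lambda)
  R <- tryCatch(chol(V), error = function(e) {
    stop("trait covariance is not positive definite")
  })
  with_stream(seed, label, {
    z <- rnorm(nrow(V))
    tibble::tibble(
      species = rownames(V),
      value = as.numeric(t(R) %*% z)
    )
  })
}
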