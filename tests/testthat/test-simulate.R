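test_that("single-isoform genes imply no events; a cassette implies one", {
  cfg1 <- sim_config(n_genes = 10, n_isoforms = c(1, 1), seed = 3)
  sim1 <- simulate_gene_models(cfg1)
  expect_true(all(sim1$truth$true_events == 0))

  spec <- function(g) list(drop_sets = list(2L), freqs = c(0.5, 0.5))
  cfg2 <- sim_config(n_genes = 5, n_exons = c(4, 4), seed = 3)
  sim2 <- simulate_gene_models(cfg2, isoform_spec = spec)
  expect_true(all(sim2$truth$true_events == 1))
  expect_true(all(vapply(sim2$truth$event_sigs, function(s) {
    grepl("^exon_skipping", s)
  }, logical(1))))
})

test_that("simulation is deterministic in the seed", {
  cfg <- sim_config(n_genes = 15, seed = 8)
  s1 <- simulate_gene_models(cfg)
  s2 <- simulate_gene_models(cfg)
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$isoforms, s2$isoforms)
  e1 <- simulate_est_library(s1)
  e2 <- simulate_est_library(s2)
  expect_identical(e1, e2)
  s3 <- simulate_gene_models(sim_config(n_genes = 15, seed = 9))
  expect_false(identical(s1$genes, s3$genes))
})

test_that("true event sets equal the brute-force oracle on isoform chains", {
  cfg <- sim_config(n_genes = 25, n_exons = c(3, 6), seed = 12)
  sim <- simulate_gene_models(cfg)
  for (g in seq_len(nrow(sim$genes))) {
    gid <- sim$genes$gene_id[g]
    iso <- sim$isoforms[sim$isoforms$gene_id == gid, ]
    chains <- lapply(iso$exons, intron_chain)
    tmpl <- merge_intervals(do.call(rbind, c(list(sim$genes$exons[[g]]),
                                             iso$exons)))
    want <- sort(oracle_events_sample(chains, tmpl, sim$genes$strand[g]))
    expect_identical(sort(sim$truth$event_sigs[[g]]), want)
  }
})

test_that("EST totals scale linearly with depth and span orders of magnitude", {
  cfg <- sim_config(n_genes = 120, mean_depth = 3, seed = 21)
  sim <- simulate_gene_models(cfg)
  n1 <- nrow(simulate_est_library(sim))
  cfg2 <- cfg
  cfg2$mean_depth <- 300
  sim$config <- cfg2
  n2 <- nrow(simulate_est_library(sim))
  # Poisson expectation: scaling x100 within 3 sigma of the realized total
  expect_lt(abs(n2 / n1 - 100) / 100, 3 * sqrt(1 / n1 + 1 / n2) + 0.15)

  # per-gene coverage under the default depth spans >= 2 orders of magnitude
  cfg3 <- sim_config(n_genes = 200, seed = 22)
  sim3 <- simulate_gene_models(cfg3)
  ests3 <- simulate_est_library(sim3)
  per_gene <- table(ests3$gene_id_true)
  expect_gte(log10(max(per_gene) / max(1, min(per_gene))), 2)
})

test_that("full-length reads reproduce their isoform's intron chain", {
  cfg <- sim_config(n_genes = 10, full_length = TRUE, seed = 5)
  sim <- simulate_gene_models(cfg)
  ests <- simulate_est_library(sim)
  iso_chain_by_id <- setNames(
    lapply(sim$isoforms$exons, intron_chain),
    sim$isoforms$isoform_id
  )
  for (i in seq_len(nrow(ests))) {
    ch <- intron_chain(ests$blocks[[i]])
    ref <- iso_chain_by_id[[ests$isoform_id[i]]]
    expect_identical(chain_sig(ch), chain_sig(ref))
  }
})

test_that("forcing high identity lets every EST through the 95% filter", {
  cfg <- sim_config(n_genes = 20, identity_beta = c(1e6, 1), seed = 6)
  sim <- simulate_gene_models(cfg)
  ests <- simulate_est_library(sim)
  expect_equal(nrow(filter_by_identity(ests)), nrow(ests))
  # while the default noise model removes some
  cfg2 <- sim_config(n_genes = 20, seed = 6)
  sim2 <- simulate_gene_models(cfg2)
  ests2 <- simulate_est_library(sim2)
  expect_lt(nrow(filter_by_identity(ests2)), nrow(ests2))
})

test_that("BM traits have the closed-form variance and signal structure", {
  # star tree: tips are iid N(0, sigma2 * T)
  st <- ape::stree(4000, "star")
  st$edge.length <- rep(2, 4000)
  y <- simulate_bm_traits(st, sigma2 = 1.5, lambda = 1, seed = 7)
  expect_lt(abs(var(y$value) / 3 - 1), 0.07)
  # lambda = 0 kills cross-tip correlation on any tree
  tree <- simulate_ultrametric_tree(10, seed = 8)
  reps <- vapply(1:1500, function(i) {
    simulate_bm_traits(tree, 1, 0, seed = i)$value
  }, numeric(10))
  C <- stats::cor(t(reps))
  off <- C[upper.tri(C)]
  expect_lt(max(abs(off)), 4 / sqrt(1500))
  # determinism
  expect_identical(simulate_bm_traits(tree, 1, 1, seed = 3),
                   simulate_bm_traits(tree, 1, 1, seed = 3))
  expect_error(simulate_bm_traits(tree, -1, 1), "sigma2")
})

test_that("fixture writers round-trip through the readers", {
  cfg <- sim_config(n_genes = 10, seed = 14)
  sim <- simulate_gene_models(cfg)
  ests <- simulate_est_library(sim)
  dir <- withr::local_tempdir()
  tree <- simulate_ultrametric_tree(6, seed = 2)
  traits <- tibble::tibble(species = tree$tip.label, asl = rnorm(6))
  p <- write_fixtures(sim, ests, dir, tree = tree, traits = traits)
  g2 <- read_gene_annotation(p[["annotation"]])
  expect_equal(as.data.frame(sim$genes), as.data.frame(g2),
               ignore_attr = TRUE)
  t2 <- ape::read.tree(p[["tree"]])
  expect_equal(sort(t2$tip.label), sort(tree$tip.label))
  tr2 <- read_trait_table(p[["traits"]])
  expect_equal(as.data.frame(tr2), as.data.frame(traits), tolerance = 1e-9)
  cfg2 <- jsonlite::read_json(p[["config"]], simplifyVector = TRUE)
  expect_equal(cfg2$seed, cfg$seed)
  # rerunning from the recorded config reproduces the fixtures
  cfg3 <- do.call(sim_config, cfg2)
  sim3 <- simulate_gene_models(cfg3)
  expect_identical(as.data.frame(sim3$genes), as.data.frame(sim$genes))
})
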