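toy_template_list <- function() {
  list(exons = tibble::tibble(start = c(0, 200, 400),
                              end = c(100, 300, 500),
                              status = "annotated"))
}

test_that("identical chains give a zero index; eligibility is strict", {
  tm <- toy_template_list()
  chains <- replicate(50, toy_inclusion(), simplify = FALSE)
  idx <- gene_as_index(chains, tm, "g1", seed = 3)
  expect_true(idx$eligible)
  expect_equal(idx$mean_events, 0)
  expect_false(idx$is_as)
  # exactly 10 ESTs: not strictly more than the sample size -> ineligible
  idx10 <- gene_as_index(chains[1:10], tm, "g1", seed = 3)
  expect_false(idx10$eligible)
  expect_true(is.na(idx10$mean_events))
})

test_that("AS classification threshold is >= 1 on the across-sample mean", {
  expect_true(classify_as_gene(1.3))
  expect_false(classify_as_gene(0.4))
  expect_true(classify_as_gene(1.0))  # boundary inclusive
  # the alternative "min" rule uses the per-sample counts, not the mean
  expect_true(classify_as_gene(NA, sample_counts = c(1L, 2L), asp_rule = "min"))
  expect_false(classify_as_gene(NA, sample_counts = c(0L, 2L), asp_rule = "min"))
})

test_that("same seed reproduces sample counts exactly", {
  tm <- toy_template_list()
  chains <- c(replicate(14, toy_inclusion(), simplify = FALSE),
              list(toy_skip_e2()))
  i1 <- gene_as_index(chains, tm, "gene42", seed = 99)
  i2 <- gene_as_index(chains, tm, "gene42", seed = 99)
  expect_identical(i1$sample_counts[[1]], i2$sample_counts[[1]])
  i3 <- gene_as_index(chains, tm, "gene42", seed = 100)
  expect_false(identical(i1$sample_counts[[1]], i3$sample_counts[[1]]))
})

test_that("subsampled index approaches the analytic two-isoform expectation", {
  # 50/50 isoform mixture with one skipping event: a 10-EST sample shows the
  # event unless it is monomorphic, so E[count] = 1 - 2 * 0.5^10
  tm <- toy_template_list()
  chains <- withr::with_seed(7, {
    lapply(seq_len(1000), function(i) {
      if (runif(1) < 0.5) toy_inclusion() else toy_skip_e2()
    })
  })
  idx <- gene_as_index(chains, tm, "ganalytic", seed = 5)
  expect_lt(abs(idx$mean_events - (1 - 2 * 0.5^10)), 0.05)
})

test_that("index is bounded by the true distinct event count", {
  for (seed in 61:75) {
    g <- random_toy_gene(seed)
    full <- g$chains[seq_len(nrow(g$truth))]  # full-length isoform chains
    pool <- full[withr::with_seed(seed, sample.int(length(full), 40,
                                                   replace = TRUE))]
    idx <- gene_as_index(pool, list(exons = tibble::tibble(
      start = g$template[, 1], end = g$template[, 2]
    )), "gb", strand = g$strand, n_samples = 20, seed = seed)
    expect_gte(idx$mean_events, 0)
    expect_lte(idx$mean_events, g$truth$true_events[1])
  }
})

test_that("species summary computes ASP/ASL and the inclusion flag", {
  idx <- tibble::tibble(
    gene_id = c("a", "b", "c"), n_ests = 20, eligible = TRUE,
    mean_events = c(0, 1.2, 2.4), is_as = c(FALSE, TRUE, TRUE),
    sample_counts = list(integer(0), integer(0), integer(0))
  )
  s <- species_summary(idx, "spX", min_genes = 2)
  expect_equal(s$asl, 1.2)
  expect_equal(s$asp, 2 / 3)
  expect_true(s$included)
  # fewer indexed genes than the threshold -> excluded
  s2 <- species_summary(idx, "spX", min_genes = 500)
  expect_false(s2$included)
  expect_equal(s2$n_genes_indexed, 3)
  # ASP of 1 when everything is spliced
  idx$is_as <- TRUE
  expect_equal(species_summary(idx, "spX", min_genes = 1)$asp, 1)
  expect_error(species_summary(idx[0, ], "spX"), "no gene indices")
})

test_that("species ASL equals the mean of its genes' indices after aggregation", {
  cfg <- sim_config(n_genes = 12, mean_depth = 40, seed = 17)
  sim <- simulate_gene_models(cfg)
  ests <- simulate_est_library(sim)
  ests$gene_id <- ests$gene_id_true
  idx <- as_index(ests, sim$genes, n_samples = 30, seed = 2)
  s <- species_summary(idx, "sp", min_genes = 1)
  eligible <- idx[idx$eligible, ]
  expect_equal(s$asl, mean(eligible$mean_events))
  expect_equal(s$asp, mean(eligible$is_as))
})
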