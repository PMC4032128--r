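# Validation experiments packaged as functions so the test suite and the
# reproduction script exercise exactly the same designs.

#' Coverage-bias correction experiment
#'
#' The defining property of the subsampled splicing index: per-gene event
#' counts from pooling *all* ESTs grow with sequencing depth, while the
#' index — always computed from fixed-size samples — does not. The design
#' holds isoform structure fixed and varies only the pool size. Most genes
#' carry two well-expressed isoforms (minor frequency 0.40–0.50, one
#' cassette event); every fifth gene carries an additional rare isoform
#' (frequency 0.004) skipping a distant, non-adjacent exon — its own
#' single event, the regime in which the naive count is most
#' coverage-sensitive. Skipped exons are kept non-adjacent so each
#' isoform pair implies exactly one event. ESTs are full length so that
#' pool size is the only variable.
#'
#' @param n_genes Number of genes (default 500).
#' @param pool_small,pool_large The two EST pool sizes compared
#'   (default 20 and 2000).
#' @param n_samples Samples per gene for the index (default 100).
#' @param seed Integer seed.
#' @return A list: `genes` (per-gene tibble with `mean_small`,
#'   `mean_large`, `naive_small`, `naive_large`, `rare`),
#'   `frac_stable` (share of genes with |index difference| < 0.1),
#'   `frac_naive_inflated` (share of rare-isoform genes whose naive count
#'   strictly increases with pool size).
#' @export
validate_coverage_bias <- function(n_genes = 500, pool_small = 20,
                                   pool_large = 2000, n_samples = 100,
                                   seed = 1) {
  spec <- function(g) {
    if (g %% 5 == 0) {
      # common cassette pair plus one rare isoform with its own event
      f_rare <- 0.004
      f_minor <- runif(1, 0.35, 0.45)
      list(drop_sets = list(2L, 5L),
           freqs = c(1 - f_minor - f_rare, f_minor, f_rare))
    } else {
      f_minor <- runif(1, 0.40, 0.50)
      list(drop_sets = list(2L), freqs = c(1 - f_minor, f_minor))
    }
  }
  cfg <- sim_config(n_genes = n_genes, n_exons = c(6, 6),
                    full_length = TRUE, seed = seed)
  sim <- simulate_gene_models(cfg, isoform_spec = spec)

  index_for_pool <- function(g, pool_size, label) {
    gid <- sim$genes$gene_id[g]
    iso <- sim$isoforms[sim$isoforms$gene_id == gid, ]
    chains <- lapply(iso$exons, intron_chain)
    counts <- with_stream(seed, paste0("pool_", label, "_", gid), {
      drop(stats::rmultinom(1, pool_size, iso$frequency))
    })
    pool <- rep(chains, counts)
    tmpl <- list(exons = tibble::tibble(
      start = sim$genes$exons[[g]][, 1], end = sim$genes$exons[[g]][, 2]
    ))
    idx <- gene_as_index(pool, tmpl, gene_id = paste0(gid, label),
                         strand = sim$genes$strand[g],
                         n_samples = n_samples, seed = seed)
    naive <- length(events_in_sample(
      pool[!duplicated(vapply(pool, chain_sig, character(1)))],
      cbind(tmpl$exons$start, tmpl$exons$end),
      strand = sim$genes$strand[g]
    ))
    c(mean = idx$mean_events, naive = naive)
  }

  rows <- lapply(seq_len(n_genes), function(g) {
    s <- index_for_pool(g, pool_small, "S")
    l <- index_for_pool(g, pool_large, "L")
    tibble::tibble(
      gene_id = sim$genes$gene_id[g],
      rare = sim$truth$min_freq[g] < 0.01,
      true_events = sim$truth$true_events[g],
      mean_small = s[["mean"]], mean_large = l[["mean"]],
      naive_small = s[["naive"]], naive_large = l[["naive"]]
    )
  })
  genes <- dplyr::bind_rows(rows)
  list(
    genes = genes,
    frac_stable = mean(abs(genes$mean_small - genes$mean_large) < 0.1),
    frac_naive_inflated = mean(genes$naive_large[genes$rare] >
                                 genes$naive_small[genes$rare])
  )
}

#' Two-isoform analytic index check
#'
#' For a gene whose EST pool is a 50/50 mixture of two isoforms differing
#' by exactly one event, a random 10-EST sample shows the event unless it
#' is monomorphic, so the expected per-sample count is
#' `1 - 2 * 0.5^10 = 0.99805`. Returns the measured index from a large
#' simulated pool for comparison with this closed form.
#'
#' @param pool_size EST pool size (default 1000).
#' @param n_samples Samples (default 100).
#' @param seed Integer seed.
#' @return A list with `mean_events` (measured) and `expected` (analytic).
#' @export
validate_analytic_index <- function(pool_size = 1000, n_samples = 100,
                                    seed = 1) {
  spec <- function(g) list(drop_sets = list(2L), freqs = c(0.5, 0.5))
  cfg <- sim_config(n_genes = 1, n_exons = c(4, 4), full_length = TRUE,
                    seed = seed)
  sim <- simulate_gene_models(cfg, isoform_spec = spec)
  chains <- lapply(sim$isoforms$exons, intron_chain)
  counts <- with_stream(seed, "analytic_pool", {
    drop(stats::rmultinom(1, pool_size, c(0.5, 0.5)))
  })
  pool <- rep(chains, counts)
  tmpl <- list(exons = tibble::tibble(
    start = sim$genes$exons[[1]][, 1], end = sim$genes$exons[[1]][, 2]
  ))
  idx <- gene_as_index(pool, tmpl, "analytic",
                       strand = sim$genes$strand[1],
                       n_samples = n_samples, seed = seed)
  list(mean_events = idx$mean_events, expected = 1 - 2 * 0.5^10)
}

#' Lambda-recovery experiment for the PGLS estimator
#'
#' Simulates response traits under lambda-scaled Brownian motion on
#' ultrametric trees (with an independent Brownian predictor), re-estimates
#' lambda by REML through [pgls_fit()], and reports the mean absolute
#' error per generating lambda.
#'
#' @param n_tips Tree size (default 100).
#' @param n_reps Replicates per lambda (default 200, spread over several
#'   independent trees).
#' @param lambdas Generating values (default 0, 0.5, 1).
#' @param seed Integer seed.
#' @return Tibble with columns `lambda`, `mae`, `mean_estimate`, `n_reps`.
#' @export
validate_lambda_recovery <- function(n_tips = 100, n_reps = 200,
                                     lambdas = c(0, 0.5, 1), seed = 1) {
  n_trees <- 10
  reps_per_tree <- ceiling(n_reps / n_trees)
  rows <- lapply(lambdas, function(lam) {
    est <- numeric(0)
    for (t in seq_len(n_trees)) {
      tree <- simulate_ultrametric_tree(
        n_tips, depth = 1400, seed = derive_seed(seed, paste0("tree", t))
      )
      for (r in seq_len(reps_per_tree)) {
        s <- derive_seed(seed, paste0("rep", lam, "_", t, "_", r))
        y <- simulate_bm_traits(tree, 1, lam, seed = s, label = "y")
        x <- simulate_bm_traits(tree, 1, 1, seed = s, label = "x")
        traits <- tibble::tibble(species = y$species, y = y$value,
                                 x = x$value)
        est <- c(est, pgls_fit(traits, "y", "x", tree)$lambda)
        if (length(est) >= n_reps) break
      }
      if (length(est) >= n_reps) break
    }
    tibble::tibble(lambda = lam, mae = mean(abs(est - lam)),
                   mean_estimate = mean(est), n_reps = length(est))
  })
  dplyr::bind_rows(rows)
}

#' Stepwise-AIC agreement with exhaustive subset search
#'
#' Simulates strong-signal regressions (two active predictors among five
#' candidates) and reports how often forward stepwise selection finds the
#' same predictor set as exhaustive best-AIC subset search.
#'
#' @param n_sims Simulated datasets (default 200).
#' @param n_obs Observations per dataset (default 30).
#' @param seed Integer seed.
#' @return A list with `agreement` (fraction of agreeing runs) and
#'   `n_sims`.
#' @export
validate_stepwise_agreement <- function(n_sims = 200, n_obs = 30, seed = 1) {
  agree <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    d <- with_stream(seed, paste0("step", i), {
      X <- matrix(rnorm(n_obs * 5), n_obs)
      y <- 2 * X[, 1] - 1.5 * X[, 4] + rnorm(n_obs, sd = 0.5)
      d <- as.data.frame(X)
      names(d) <- paste0("x", 1:5)
      d$y <- y
      d
    })
    fit <- stepwise_aic(d, "y", paste0("x", 1:5))
    best <- exhaustive_aic_subset(d, "y", paste0("x", 1:5))
    agree[i] <- setequal(fit$selected, best)
  }
  list(agreement = mean(agree), n_sims = n_sims)
}

# exhaustive best-AIC subset (the reference the stepwise path is compared
# against; exponential in the number of candidates, so only for small sets)
exhaustive_aic_subset <- function(dat, response, candidates) {
  dat <- as.data.frame(dat)
  best <- character(0)
  best_aic <- stats::AIC(stats::lm(stats::reformulate("1", response), dat))
  for (k in seq_along(candidates)) {
    sets <- utils::combn(candidates, k, simplify = FALSE)
    for (set in sets) {
      a <- stats::AIC(stats::lm(stats::reformulate(set, response), dat))
      if (a < best_aic) {
        best_aic <- a
        best <- set
      }
    }
  }
  best
}

#' End-to-end recovery under saturating coverage
#'
#' Runs the complete pipeline — EST simulation, identity filtering, gene
#' assignment, template building, subsampled index — on a simulation with
#' full-length ESTs at saturating depth, and compares against the known
#' isoform truth. 70% of genes carry three isoforms implying two cassette
#' events; the rest are single-isoform. Recovery is reported as (a) the
#' share of genes whose all-EST event enumeration equals the true event
#' count exactly and (b) the share whose rounded subsampled index equals
#' it; species-level ASP/ASL are compared with the truth-table values
#' computed directly from the isoform sets.
#'
#' @param n_genes Number of genes (default 500).
#' @param depth Expected ESTs per gene before identity filtering
#'   (default 300; about 10% of ESTs fail the 95% identity filter,
#'   leaving every gene with well over 200).
#' @param n_samples Samples per gene (default 100).
#' @param seed Integer seed.
#' @return A list with `frac_naive_exact`, `frac_index_round_exact`,
#'   `asp_measured`, `asp_truth`, `asl_measured`, `asl_truth`, `n_genes`.
#' @export
validate_recovery <- function(n_genes = 500, depth = 300, n_samples = 100,
                              seed = 1) {
  spec <- function(g) {
    if (g %% 10 < 3) {
      list(drop_sets = list(), freqs = 1)
    } else {
      list(drop_sets = list(2L, 5L), freqs = c(0.4, 0.3, 0.3))
    }
  }
  cfg <- sim_config(n_genes = n_genes, n_exons = c(6, 6),
                    full_length = TRUE, mean_depth = depth,
                    expression_sdlog = 1e-6, seed = seed)
  sim <- simulate_gene_models(cfg, isoform_spec = spec)
  ests <- simulate_est_library(sim)
  ests <- filter_by_identity(ests, 0.95)
  ests <- assign_to_genes(ests, sim$genes)
  idx <- as_index(ests, sim$genes, n_samples = n_samples, seed = seed,
                  naive = TRUE)
  joined <- dplyr::inner_join(idx, sim$truth, by = "gene_id")
  truth_asp <- mean(sim$truth$true_events >= 1)
  truth_asl <- mean(sim$truth$true_events)
  sp <- species_summary(idx, "sim_species", min_genes = 1)
  list(
    frac_naive_exact = mean(joined$naive_events == joined$true_events),
    frac_index_round_exact = mean(round(joined$mean_events) ==
                                    joined$true_events),
    asp_measured = sp$asp, asp_truth = truth_asp,
    asl_measured = sp$asl, asl_truth = truth_asl,
    n_genes = nrow(joined)
  )
}
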