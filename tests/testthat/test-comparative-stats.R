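test_that("OLS recovers exact fits and matches the normal-equation oracle", {
  d <- tibble::tibble(x = 1:10, y = 2 * (1:10) + 1)
  fit <- suppressWarnings(ols_fit(d, "y", "x"))  # lm flags the perfect fit
  expect_equal(fit$adj_r_squared, 1)
  expect_equal(unname(fit$coefficients[2]), 2)

  d2 <- withr::with_seed(24, tibble::tibble(x = rnorm(24), y = rnorm(24)))
  fit2 <- ols_fit(d2, "y", "x")
  o <- oracle_ols(d2$x, d2$y)
  expect_equal(unname(fit2$coefficients), unname(o$beta), tolerance = 1e-10)
  expect_equal(fit2$adj_r_squared, o$adj_r2, tolerance = 1e-10)

  expect_error(ols_fit(tibble::tibble(x = rep(1, 5), y = rnorm(5)), "y", "x"),
               "zero variance")
})

test_that("forward stepwise AIC selects true signal and stops correctly", {
  d <- withr::with_seed(11, {
    x1 <- rnorm(30); x2 <- rnorm(30); x3 <- rnorm(30)
    tibble::tibble(x1, x2, x3, y = 2 * x1 + rnorm(30, sd = 0.1))
  })
  fit <- stepwise_aic(d, "y", c("x1", "x2", "x3"))
  expect_equal(fit$selected, "x1")
  expect_equal(sort(fit$selected),
               oracle_best_subset_aic(as.data.frame(d), "y",
                                      c("x1", "x2", "x3"))$set)

  # orthogonal response: nothing enters
  d0 <- withr::with_seed(12, tibble::tibble(
    x1 = rnorm(30), x2 = rnorm(30), y = rnorm(30)
  ))
  fit0 <- stepwise_aic(d0, "y", c("x1", "x2"))
  if (length(fit0$selected) == 0) {
    expect_length(fit0$selected, 0)
  }
  # local optimality of whatever was returned: no single add or drop helps
  check_local_opt <- function(fit, d, response, candidates) {
    final_aic <- utils::tail(fit$aic_trace, 1)
    rest <- setdiff(candidates, fit$selected)
    for (v in rest) {
      expect_gte(stats::AIC(stats::lm(
        stats::reformulate(c(fit$selected, v), response), as.data.frame(d)
      )), final_aic)
    }
    for (v in fit$selected) {
      kept <- setdiff(fit$selected, v)
      expect_gte(stats::AIC(stats::lm(
        stats::reformulate(if (length(kept)) kept else "1", response),
        as.data.frame(d)
      )), final_aic)
    }
  }
  check_local_opt(fit, d, "y", c("x1", "x2", "x3"))
  check_local_opt(fit0, d0, "y", c("x1", "x2"))
})

test_that("stepwise AIC agrees with MASS stepAIC forward search", {
  d <- withr::with_seed(13, {
    x1 <- rnorm(40); x2 <- rnorm(40); x3 <- rnorm(40); x4 <- rnorm(40)
    tibble::tibble(x1, x2, x3, x4,
                   y = 1.5 * x1 - 2 * x3 + rnorm(40, sd = 0.5))
  })
  fit <- stepwise_aic(d, "y", c("x1", "x2", "x3", "x4"))
  ref <- MASS::stepAIC(
    stats::lm(y ~ 1, data = as.data.frame(d)),
    scope = list(upper = ~ x1 + x2 + x3 + x4, lower = ~1),
    direction = "forward", trace = 0
  )
  expect_setequal(fit$selected, attr(terms(ref), "term.labels"))
})

test_that("trait PCA matches the eigendecomposition of the correlation matrix", {
  d <- withr::with_seed(21, tibble::tibble(
    species = paste0("s", 1:20),
    a = rnorm(20), b = rnorm(20), c = rnorm(20), e = rnorm(20)
  ))
  vars <- c("a", "b", "c", "e")
  pc <- pca_traits(d, vars)
  expect_equal(sum(pc$var_explained), 1, tolerance = 1e-12)
  eo <- eigen(stats::cor(as.matrix(d[, vars])))
  expect_equal(pc$var_explained, eo$values / sum(eo$values),
               tolerance = 1e-10)
  for (k in seq_along(vars)) {
    v <- eo$vectors[, k]
    v <- v * sign(v[which.max(abs(v))])  # same sign convention
    expect_equal(unname(pc$loadings[, k]), v, tolerance = 1e-10)
  }
  # scores' covariance is diagonal
  S <- stats::cov(as.matrix(pc$scores[, -1]))
  expect_equal(S - diag(diag(S)), matrix(0, 4, 4), ignore_attr = TRUE,
               tolerance = 1e-10)
  # two identical standardized variables: PC1 explains everything
  d2 <- tibble::tibble(a = rnorm(10), b = NA_real_)
  d2$b <- 2 * d2$a + 3
  pc2 <- pca_traits(d2, c("a", "b"))
  expect_equal(pc2$var_explained[1], 1)
  expect_error(pca_traits(tibble::tibble(a = rnorm(5), b = 1), c("a", "b")),
               "constant variable")
})

test_that("partial Spearman equals the residual-rank construction exactly", {
  for (seed in 1:20) {
    d <- withr::with_seed(seed, tibble::tibble(
      x = rnorm(15), y = rnorm(15), z = rnorm(15)
    ))
    got <- partial_spearman(d, "x", "y", "z")
    expect_equal(got$estimate, oracle_partial_spearman(d$x, d$y, d$z),
                 tolerance = 1e-10)
  }
  # known closed-form value: with rank correlations r_xy = .8, r_xz = r_yz = .5
  # the first-order formula gives (0.8 - 0.25) / 0.75
  expect_equal((0.8 - 0.5 * 0.5) / sqrt((1 - 0.25) * (1 - 0.25)),
               0.73333, tolerance = 1e-4)
})

test_that("partial Spearman is near zero when x and y are independent given z", {
  d <- withr::with_seed(42, {
    z <- rnorm(500)
    tibble::tibble(x = z + rnorm(500), y = z + rnorm(500), z = z)
  })
  got <- partial_spearman(d, "x", "y", "z")
  expect_lt(abs(got$estimate), 0.1)
  # collinear control errors
  d2 <- tibble::tibble(x = 1:10, y = rnorm(10), z = 2 * (1:10))
  expect_error(partial_spearman(d2, "x", "y", "z"), "collinear")
})

test_that("EST-number correction leaves residuals orthogonal to the design", {
  d <- withr::with_seed(9, tibble::tibble(
    species = paste0("s", 1:30),
    est_count = round(10^runif(30, 2, 4)),
    asl = rnorm(30, 2)
  ))
  out <- est_number_correction(d, "asl", mode = "quadratic")
  e <- d$est_count
  for (col in list(rep(1, 30), e, e^2)) {
    expect_lt(abs(sum(out$asl * col)), 1e-8 * max(abs(col)) * 30)
  }
  # an exactly quadratic trait has zero residuals
  d$quad <- 3 + 2 * e - 1e-6 * e^2
  out2 <- est_number_correction(d, "quad", mode = "quadratic")
  expect_equal(out2$quad, rep(0, 30), tolerance = 1e-6)
  # residuals match the explicit normal-equation solution
  X <- cbind(1, e, e^2)
  beta <- solve(t(X) %*% X, t(X) %*% d$asl)
  expect_equal(out$asl, as.numeric(d$asl - X %*% beta), tolerance = 1e-8)
  # log mode
  outl <- est_number_correction(d, "asl", mode = "log")
  Xl <- cbind(1, log(e))
  bl <- solve(t(Xl) %*% Xl, t(Xl) %*% d$asl)
  expect_equal(outl$asl, as.numeric(d$asl - Xl %*% bl), tolerance = 1e-10)
  d$est_count[1] <- 0
  expect_error(est_number_correction(d, "asl", mode = "log"), "non-positive")
})

test_that("cell-type-number averaging follows the min/max and order rules", {
  est <- tibble::tibble(
    species = c("h", "h", "h", "m", "w", "w"),
    estimate = c(3, 9, 5, 12, 10, 20)
  )
  out <- average_ctn(est)
  expect_equal(out$ctn[out$species == "h"], 6)    # (3+9)/2
  expect_equal(out$ctn[out$species == "m"], 12)   # single estimate
  expect_equal(out$ctn[out$species == "w"], 15)
  orders <- tibble::tibble(species = c("h", "m", "w"),
                           order = c("prim", "rod", "rod"))
  out2 <- average_ctn(est, mode = "order_mean", orders = orders)
  expect_equal(out2$ctn[out2$species == "m"], (12 + 15) / 2)
  expect_equal(out2$ctn[out2$species == "w"], (12 + 15) / 2)
  expect_equal(out2$ctn[out2$species == "h"], 6)
  expect_error(average_ctn(tibble::tibble(species = "x",
                                          estimate = NA_real_)),
               "estimate")
})

test_that("divergence trend averages within exact time groups, order-invariantly", {
  d <- tibble::tibble(
    species = c("a", "b", "c"),
    divergence_time = c(100, 100, 300),
    asl = c(2, 4, 9)
  )
  tr <- divergence_trend(d, "asl")
  expect_equal(tr$time, c(100, 300))
  expect_equal(tr$mean_value, c(3, 9))
  perm <- d[c(3, 1, 2), ]
  expect_equal(divergence_trend(perm, "asl"), tr)
})
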