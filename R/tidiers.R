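# broom-style tidiers for the fitted objects

#' @export
tidy.trait_ols <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, 1],
    std.error = sm[, 2],
    statistic = sm[, 3],
    p.value = sm[, 4]
  )
}

#' @export
glance.trait_ols <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    adj.r.squared = x$adj_r_squared,
    p.value = x$p_value,
    nobs = x$n
  )
}

#' @export
tidy.pgls_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    statistic = unname(x$t_value),
    p.value = 2 * stats::pt(-abs(unname(x$t_value)), df = x$n - 2)
  )
}

#' @export
glance.pgls_fit <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda,
    r.squared = x$r_squared,
    adj.r.squared = x$adj_r_squared,
    p.value = x$p_value,
    REML = x$restricted_log_likelihood,
    nobs = x$n
  )
}

#' @export
tidy.stepwise_aic <- function(x, ...) {
  tibble::tibble(
    step = seq_along(x$selected),
    term = x$selected,
    AIC = x$aic_trace[-1]
  )
}

#' @export
glance.stepwise_aic <- function(x, ...) {
  tibble::tibble(
    n.selected = length(x$selected),
    AIC = utils::tail(x$aic_trace, 1),
    nobs = x$n
  )
}

#' @export
tidy.trait_pca <- function(x, ...) {
  ld <- x$loadings
  tibble::tibble(
    variable = rep(rownames(ld), ncol(ld)),
    component = rep(colnames(ld), each = nrow(ld)),
    loading = as.numeric(ld)
  )
}

#' @export
glance.trait_pca <- function(x, ...) {
  tibble::tibble(
    var.explained.pc1 = x$var_explained[1],
    var.explained.pc2 = x$var_explained[2],
    n.components = length(x$var_explained),
    nobs = x$n
  )
}
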