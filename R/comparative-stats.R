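#' Ordinary least squares association between two trait columns
#'
#' Simple cross-species linear regression, reporting the adjusted r^2
#' (which can be negative for uninformative predictors) and the two-sided
#' slope p-value.
#'
#' @param traits Data frame with one row per species.
#' @param response,predictor Column names (strings). Rows with missing
#'   values in either are dropped (complete-case).
#' @return An object of class `trait_ols` wrapping the `lm` fit, with
#'   `tidy()` and `glance()` methods.
#' @export
ols_fit <- function(traits, response, predictor) {
  dat <- traits[stats::complete.cases(traits[, c(response, predictor)]), ]
  if (nrow(dat) < 3) stop("need at least 3 complete pairs")
  x <- as.numeric(dat[[predictor]])
  if (stats::var(x) == 0) stop("predictor '", predictor, "' has zero variance")
  fml <- stats::reformulate(predictor, response)
  fit <- stats::lm(fml, data = dat)
  sm <- summary(fit)
  structure(list(
    fit = fit,
    coefficients = stats::coef(fit),
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    p_value = unname(sm$coefficients[2, 4]),
    n = nrow(dat),
    response = response,
    predictor = predictor
  ), class = "trait_ols")
}

#' @export
print.trait_ols <- function(x, ...) {
  cat("OLS:", x$response, "~", x$predictor, "\n")
  cat(sprintf("  n = %d, adj. r^2 = %.4g, p = %.4g\n",
              x$n, x$adj_r_squared, x$p_value))
  invisible(x)
}

#' Forward stepwise regression by AIC
#'
#' Starting from the intercept-only model, repeatedly adds the candidate
#' predictor that most lowers the AIC, stopping when no addition lowers
#' it. The returned model is locally AIC-optimal: no single addition (or
#' removal of a selected term) improves it.
#'
#' @param traits Data frame, one row per species.
#' @param response Response column name.
#' @param candidates Character vector of candidate predictor columns.
#' @return Object of class `stepwise_aic`: `selected` (in selection
#'   order), `fit` (the final `lm`), `aic_trace` (AIC after each step,
#'   starting with the intercept-only model), `n`.
#' @export
stepwise_aic <- function(traits, response, candidates) {
  dat <- traits[stats::complete.cases(traits[, c(response, candidates), drop = FALSE]), ]
  dat <- as.data.frame(dat)
  selected <- character(0)
  current <- stats::lm(stats::reformulate("1", response), data = dat)
  trace <- stats::AIC(current)
  remaining <- candidates
  while (length(remaining) > 0) {
    aics <- vapply(remaining, function(v) {
      stats::AIC(stats::lm(
        stats::reformulate(c(selected, v), response), data = dat
      ))
    }, numeric(1))
    best <- which.min(aics)
    if (aics[best] >= utils::tail(trace, 1)) break
    selected <- c(selected, remaining[best])
    remaining <- remaining[-best]
    trace <- c(trace, aics[best])
    current <- stats::lm(stats::reformulate(selected, response), data = dat)
  }
  structure(list(
    selected = selected, fit = current, aic_trace = trace, n = nrow(dat),
    response = response, candidates = candidates
  ), class = "stepwise_aic")
}

#' @export
print.stepwise_aic <- function(x, ...) {
  cat("Forward stepwise AIC:", x$response, "~",
      if (length(x$selected)) paste(x$selected, collapse = " + ") else "1", "\n")
  cat(sprintf("  n = %d, final AIC = %.4g\n", x$n, utils::tail(x$aic_trace, 1)))
  invisible(x)
}

#' Principal component analysis of a trait table
#'
#' Correlation-matrix PCA (all variables standardised — the predictors of
#' organism complexity have incommensurable units). Loadings follow the
#' sign convention that each component's largest-magnitude loading is
#' positive.
#'
#' @param traits Data frame, one row per species.
#' @param variables Character vector of numeric trait columns (at least
#'   two). Constant variables are an error naming the offender.
#' @param species_col Species identifier column (default "species").
#' @return Object of class `trait_pca`: `loadings` (variables x PCs),
#'   `var_explained` (fractions summing to 1), `scores` (tibble of
#'   species scores), `n`. Has `tidy()`, `glance()` and `autoplot()`
#'   methods.
#' @export
pca_traits <- function(traits, variables, species_col = "species") {
  stopifnot(length(variables) >= 2)
  dat <- traits[stats::complete.cases(traits[, variables, drop = FALSE]), ]
  m <- as.matrix(dat[, variables, drop = FALSE])
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant variable(s): ", paste(variables[sds == 0], collapse = ", "))
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  out_scores <- tibble::as_tibble(scores)
  if (species_col %in% names(dat)) {
    out_scores <- dplyr::bind_cols(
      tibble::tibble(!!species_col := dat[[species_col]]), out_scores
    )
  }
  structure(list(
    loadings = rot,
    var_explained = pc$sdev^2 / sum(pc$sdev^2),
    scores = out_scores,
    n = nrow(dat),
    variables = variables,
    species_col = species_col
  ), class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, ...) {
  cat("Trait PCA:", length(x$variables), "variables,", x$n, "species\n")
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * utils::head(x$var_explained, 4)),
            collapse = ", "),
      if (length(x$var_explained) > 4) "..." else "", "\n")
  invisible(x)
}

#' First-order partial Spearman correlation
#'
#' Rank-transforms the three variables (average ranks for ties) and
#' computes the first-order partial correlation of `x` and `y` given
#' `control`:
#' \deqn{r_{xy.z} = (r_{xy} - r_{xz} r_{yz}) / \sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}}
#' The p-value uses the t approximation with `n - 3` degrees of freedom.
#' Used to ask whether a trait association (e.g. splicing level vs cell
#' type number) survives controlling for effective population size.
#'
#' @param traits Data frame.
#' @param x,y,control Column names (strings); complete cases only.
#' @return A one-row tibble: `estimate`, `statistic`, `p_value`, `n`.
#' @export
partial_spearman <- function(traits, x, y, control) {
  dat <- traits[stats::complete.cases(traits[, c(x, y, control)]), ]
  n <- nrow(dat)
  if (n < 5) stop("need at least 5 complete triples")
  rx <- rank(as.numeric(dat[[x]]))
  ry <- rank(as.numeric(dat[[y]]))
  rz <- rank(as.numeric(dat[[control]]))
  rxy <- stats::cor(rx, ry)
  rxz <- stats::cor(rx, rz)
  ryz <- stats::cor(ry, rz)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12) {
    stop("control variable is rank-collinear with x or y")
  }
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  tval <- r * sqrt((n - 3) / (1 - r^2))
  tibble::tibble(
    estimate = r,
    statistic = tval,
    p_value = 2 * stats::pt(-abs(tval), df = n - 3),
    n = n
  )
}

#' Ascertainment correction by EST number
#'
#' Species with more sequencing data yield higher apparent splicing
#' indices and better-annotated genomes, confounding cross-species
#' comparisons. This correction replaces each trait by the residuals of a
#' regression on EST number: a quadratic polynomial (`mode =
#' "quadratic"`, the default) or on the natural log of EST number
#' (`mode = "log"`).
#'
#' @param traits Data frame.
#' @param variables Character vector of trait columns to correct.
#' @param est_col Column holding per-species EST counts.
#' @param mode `"quadratic"` or `"log"`.
#' @return `traits` with each listed variable replaced by its residuals
#'   (rows with missing values keep NA).
#' @export
est_number_correction <- function(traits, variables, est_col = "est_count",
                                  mode = c("quadratic", "log")) {
  mode <- match.arg(mode)
  e <- as.numeric(traits[[est_col]])
  if (sum(!is.na(e)) < 4) stop("need at least 4 species with EST counts")
  if (mode == "log" && any(e[!is.na(e)] <= 0)) {
    stop("non-positive EST count under log mode")
  }
  design <- if (mode == "quadratic") {
    data.frame(e1 = e, e2 = e^2)
  } else {
    data.frame(e1 = log(e))
  }
  out <- traits
  for (v in variables) {
    d <- cbind(y = as.numeric(traits[[v]]), design)
    fit <- stats::lm(y ~ ., data = d, na.action = stats::na.exclude)
    out[[v]] <- as.numeric(stats::residuals(fit))
  }
  out
}

#' Average multiple cell-type-number estimates per species
#'
#' With several published estimates per species, the species value is the
#' mean of the minimum and maximum estimate (`mode = "minmax"`). As a
#' robustness check, `mode = "order_mean"` replaces each species value by
#' the mean of the min/max-averaged values across its taxonomic order,
#' treating within-order variation as measurement noise.
#'
#' @param estimates Data frame with columns `species` and `estimate`
#'   (one row per estimate; species may repeat).
#' @param mode `"minmax"` or `"order_mean"`.
#' @param orders Data frame with columns `species` and `order`; required
#'   for `mode = "order_mean"`.
#' @return Tibble with columns `species` and `ctn`.
#' @export
average_ctn <- function(estimates, mode = c("minmax", "order_mean"),
                        orders = NULL) {
  mode <- match.arg(mode)
  if (nrow(estimates) == 0 || anyNA(estimates$estimate)) {
    stop("every species needs at least one non-missing estimate")
  }
  minmax <- estimates |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      ctn = (min(.data$estimate) + max(.data$estimate)) / 2,
      .groups = "drop"
    )
  if (mode == "minmax") return(minmax)
  if (is.null(orders)) stop("mode 'order_mean' requires an orders table")
  joined <- dplyr::left_join(minmax, orders, by = "species")
  if (anyNA(joined$order)) {
    stop("species without order label: ",
         paste(joined$species[is.na(joined$order)], collapse = ", "))
  }
  joined |>
    dplyr::group_by(.data$order) |>
    dplyr::mutate(ctn = mean(.data$ctn)) |>
    dplyr::ungroup() |>
    dplyr::select("species", "ctn")
}

#' Mean trait value at each divergence time
#'
#' Groups species by their exact divergence time from a shared reference
#' and averages the trait within each group — the trend line of trait
#' change over evolutionary time.
#'
#' @param traits Data frame.
#' @param value Trait column name.
#' @param time Divergence-time column name (typically My).
#' @return Tibble with columns `time` and `mean_value`, ordered by time.
#' @export
divergence_trend <- function(traits, value, time = "divergence_time") {
  traits |>
    dplyr::filter(!is.na(.data[[value]]), !is.na(.data[[time]])) |>
    dplyr::group_by(time = .data[[time]]) |>
    dplyr::summarise(mean_value = mean(.data[[value]]), .groups = "drop") |>
    dplyr::arrange(time)
}
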