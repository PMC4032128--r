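#' Brownian-motion covariance matrix of a phylogeny
#'
#' Under Brownian motion on a rooted tree, the covariance between two tips
#' equals the depth (root-to-node distance) of their most recent common
#' ancestor, and each tip's variance equals its root-to-tip depth. For an
#' ultrametric tree the diagonal is constant.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param tips Optional character vector of tip labels: the matrix is
#'   restricted to (and ordered by) these tips. Unknown tips are an error.
#' @return A symmetric matrix with tip labels as dimnames.
#' @export
bm_covariance <- function(tree, tips = NULL) {
  if (!is.null(tips)) {
    unknown <- setdiff(tips, tree$tip.label)
    if (length(unknown) > 0) {
      stop("tip(s) not in tree: ", paste(unknown, collapse = ", "))
    }
  }
  n <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  diag(V) <- depths[seq_len(n)]
  # walk edges in postorder, accumulating descendant tip sets; tips split
  # across the children of a node share exactly that node's depth
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- i
  po <- ape::postorder(tree)
  for (e in po) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    prev <- desc[[parent]]
    new <- desc[[child]]
    if (length(prev) > 0) {
      V[prev, new] <- depths[parent]
      V[new, prev] <- depths[parent]
    }
    desc[[parent]] <- c(prev, new)
  }
  if (!is.null(tips)) V <- V[tips, tips, drop = FALSE]
  V
}

# check tips equidistant from root (relative tolerance)
is_ultrametric_cov <- function(V, tol = 1e-6) {
  d <- diag(V)
  (max(d) - min(d)) <= tol * max(d)
}

# lambda-scaled covariance: off-diagonals scaled, diagonal unchanged
lambda_cov <- function(V, lambda) {
  D <- diag(diag(V))
  lambda * (V - D) + D
}

# restricted log-likelihood of the GLS regression y ~ X with error
# covariance sigma2 * Vl (sigma2 profiled out)
reml_loglik <- function(y, X, Vl) {
  n <- length(y)
  p <- ncol(X)
  R <- tryCatch(chol(Vl), error = function(e) NULL)
  if (is.null(R)) return(-1e10)  # penalize non-PD covariance
  logdetV <- 2 * sum(log(diag(R)))
  Xs <- backsolve(R, X, transpose = TRUE)
  ys <- backsolve(R, y, transpose = TRUE)
  XtX <- crossprod(Xs)
  beta <- solve(XtX, crossprod(Xs, ys))
  r <- ys - Xs %*% beta
  rss <- sum(r^2)
  s2 <- rss / (n - p)
  ll <- -0.5 * ((n - p) * log(2 * pi * s2) + logdetV +
                  determinant(XtX, logarithm = TRUE)$modulus[1] + (n - p))
  if (!is.finite(ll)) return(-1e10)
  ll
}

gls_solve <- function(y, X, Vl) {
  R <- chol(Vl)
  Xs <- backsolve(R, X, transpose = TRUE)
  ys <- backsolve(R, y, transpose = TRUE)
  XtX <- crossprod(Xs)
  XtXinv <- solve(XtX)
  beta <- drop(XtXinv %*% crossprod(Xs, ys))
  r <- ys - Xs %*% beta
  rss <- sum(r^2)
  list(beta = beta, rss = rss, XtXinv = XtXinv, Xs = Xs, ys = ys)
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Fits the regression `response ~ predictor` across species with error
#' covariance proportional to a lambda-scaled Brownian-motion matrix:
#' off-diagonal entries of the phylogenetic covariance are multiplied by
#' lambda while the diagonal is left unchanged. Lambda is estimated by
#' maximising the restricted log-likelihood over `[0, 1]`; an
#' unconstrained optimum below zero is clipped to and reported as 0, and
#' optima above 1 as 1. At `lambda = 0` the model collapses to ordinary
#' least squares (for an ultrametric tree).
#'
#' @param traits Data frame with one row per species.
#' @param response,predictor Column names (strings) of the regression
#'   variables.
#' @param tree Ultrametric `ape::phylo` tree whose tip labels match
#'   `traits[[species_col]]`. A tree that is not ultrametric beyond
#'   tolerance triggers a warning.
#' @param lambda Fix lambda instead of estimating it (NULL = REML
#'   estimate).
#' @param species_col Column holding species identifiers (default
#'   `"species"`).
#' @return An object of class `pgls_fit` with elements `lambda`,
#'   `coefficients`, `se`, `p_value` (two-sided slope t-test),
#'   `r_squared`, `adj_r_squared` (the reported statistic),
#'   `restricted_log_likelihood`, `reml_at_bounds`, `n`. Has `tidy()`,
#'   `glance()` and `print()` methods.
#' @export
pgls_fit <- function(traits, response, predictor, tree, lambda = NULL,
                     species_col = "species") {
  dat <- traits[stats::complete.cases(traits[, c(species_col, response, predictor)]), ]
  sp <- as.character(dat[[species_col]])
  sp <- sp[sp %in% tree$tip.label]
  dat <- dat[match(sp, as.character(dat[[species_col]])), ]
  n <- length(sp)
  if (n < 4) stop("need at least 4 species common to tree and data")
  y <- as.numeric(dat[[response]])
  x <- as.numeric(dat[[predictor]])
  if (stats::var(x) == 0) stop("predictor '", predictor, "' has zero variance")
  X <- cbind(`(Intercept)` = 1, x)
  colnames(X)[2] <- predictor

  V <- bm_covariance(tree, sp)
  if (!is_ultrametric_cov(V)) {
    warning("tree is not ultrametric within tolerance; PGLS assumes ",
            "time-calibrated tips")
  }

  if (is.null(lambda)) {
    f <- function(l) reml_loglik(y, X, lambda_cov(V, l))
    opt <- stats::optimize(f, c(0, 1), maximum = TRUE, tol = 1e-6)
    cand <- c(0, opt$maximum, 1)
    vals <- c(f(0), opt$objective, f(1))
    lambda_hat <- cand[which.max(vals)]
  } else {
    stopifnot(lambda >= 0, lambda <= 1)
    lambda_hat <- lambda
  }

  Vl <- lambda_cov(V, lambda_hat)
  if (min(eigen(Vl, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("covariance matrix singular at lambda = ", lambda_hat)
  }
  fit <- gls_solve(y, X, Vl)
  p <- ncol(X)
  s2 <- fit$rss / (n - p)
  se <- sqrt(diag(fit$XtXinv) * s2)
  tval <- fit$beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)

  # GLS analogue of r^2 against the GLS intercept-only model
  fit0 <- gls_solve(y, cbind(rep(1, n)), Vl)
  r2 <- 1 - fit$rss / fit0$rss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p)

  structure(list(
    lambda = lambda_hat,
    coefficients = stats::setNames(fit$beta, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    t_value = stats::setNames(tval, colnames(X)),
    p_value = unname(pval[2]),
    r_squared = r2,
    adj_r_squared = adj_r2,
    restricted_log_likelihood = reml_loglik(y, X, Vl),
    reml_at_bounds = c(`0` = reml_loglik(y, X, lambda_cov(V, 0)),
                       `1` = reml_loglik(y, X, lambda_cov(V, 1))),
    sigma2 = s2,
    n = n,
    response = response,
    predictor = predictor,
    data = tibble::tibble(species = sp, x = x, y = y)
  ), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("Phylogenetic GLS (Pagel's lambda):", x$response, "~", x$predictor, "\n")
  cat(sprintf("  n = %d, lambda = %.4g, adj. r^2 = %.4g, p = %.4g\n",
              x$n, x$lambda, x$adj_r_squared, x$p_value))
  invisible(x)
}
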