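# Independent brute-force oracles used to cross-check the package's
# implementations. The event oracle works on per-base coverage vectors
# (rather than interval arithmetic) and re-derives intron runs, coverage
# and boundary tests from scratch.

oracle_iv <- function(s, e) paste0(s, "-", e)

oracle_pair_sig <- function(i1, i2) {
  a <- oracle_iv(i1[1], i1[2]); b <- oracle_iv(i2[1], i2[2])
  if (a < b) paste(a, b, sep = "/") else paste(b, a, sep = "/")
}

# all events between two chains by exhaustive base-level rule application
oracle_events_pair <- function(a, b, tmpl, strand, flank = 10) {
  lo <- max(a$start, b$start); hi <- min(a$end, b$end)
  if (hi <= lo) return(character(0))
  glo <- min(a$start, b$start) - flank - 2
  ghi <- max(a$end, b$end) + flank + 2
  pos <- glo:(ghi - 1)
  cover <- function(ch) {
    v <- pos >= ch$start & pos < ch$end
    ii <- ch$introns
    for (r in seq_len(nrow(ii))) {
      v[pos >= ii[r, 1] & pos < ii[r, 2]] <- FALSE
    }
    v
  }
  at <- function(v, s, e) v[(s - glo + 1):(e - glo)]  # bases s .. e-1
  runs_false <- function(ch, v) {
    # maximal uncovered runs inside the chain's span = its introns
    r <- rle(at(v, ch$start, ch$end))
    ends <- ch$start + cumsum(r$lengths)
    starts <- ends - r$lengths
    cbind(starts[!r$values], ends[!r$values])
  }
  ca <- cover(a); cb <- cover(b)
  ia <- runs_false(a, ca); ib <- runs_false(b, cb)
  inside <- function(m) m[m[, 1] >= lo & m[, 2] <= hi, , drop = FALSE]
  iaw <- inside(ia); ibw <- inside(ib)

  sigs <- character(0)
  skip_outer <- list(matrix(numeric(0), ncol = 2),
                     matrix(numeric(0), ncol = 2))
  sides <- list(
    list(xi = iaw, ych = b, yv = cb),
    list(xi = ibw, ych = a, yv = ca)
  )
  for (d in 1:2) {
    xi <- sides[[d]]$xi; ych <- sides[[d]]$ych; yv <- sides[[d]]$yv
    for (r in seq_len(nrow(xi))) {
      s <- xi[r, 1]; e <- xi[r, 2]
      if (s - flank >= ych$start && e + flank <= ych$end &&
          all(at(yv, s - flank, e + flank))) {
        sigs <- c(sigs, paste0("intron_retention|", oracle_iv(s, e)))
      }
      yin <- runs_false(ych, yv)
      for (t in seq_len(nrow(tmpl))) {
        ts <- tmpl[t, 1]; te <- tmpl[t, 2]
        if (ts < s || te > e) next
        if (!all(at(yv, ts, te))) next
        if (!any(yin[, 1] >= s & yin[, 2] <= ts)) next
        if (!any(yin[, 1] >= te & yin[, 2] <= e)) next
        if (s - 1 < ych$start || e + 1 > ych$end) next
        if (!all(at(yv, s - 1, s)) || !all(at(yv, e, e + 1))) next
        sigs <- c(sigs, paste0("exon_skipping|", oracle_iv(ts, te), "|",
                               oracle_iv(s, e)))
        skip_outer[[d]] <- rbind(skip_outer[[d]], c(s, e))
      }
    }
  }
  in_set <- function(set, iv) {
    nrow(set) > 0 && any(set[, 1] == iv[1] & set[, 2] == iv[2])
  }
  for (i in seq_len(nrow(iaw))) {
    for (j in seq_len(nrow(ibw))) {
      p <- iaw[i, ]; q <- ibw[j, ]
      if (p[2] <= q[1] || q[2] <= p[1]) next
      if (p[1] == q[1] && p[2] == q[2]) next
      contains_pq <- p[1] <= q[1] && p[2] >= q[2]
      contains_qp <- q[1] <= p[1] && q[2] >= p[2]
      if ((contains_pq && in_set(skip_outer[[1]], p)) ||
          (contains_qp && in_set(skip_outer[[2]], q))) next
      if (p[1] == q[1] || p[2] == q[2]) {
        varies_at_start <- p[1] != q[1]
        kind <- if (strand == "+") {
          if (varies_at_start) "alt_donor" else "alt_acceptor"
        } else {
          if (varies_at_start) "alt_acceptor" else "alt_donor"
        }
        sigs <- c(sigs, paste0(kind, "|", oracle_pair_sig(p, q)))
      } else {
        sigs <- c(sigs, paste0("complex|", oracle_pair_sig(p, q)))
      }
    }
  }
  unique(sigs)
}

oracle_events_sample <- function(chains, tmpl, strand, flank = 10) {
  n <- length(chains)
  out <- character(0)
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        out <- c(out, oracle_events_pair(chains[[i]], chains[[j]], tmpl,
                                         strand, flank))
      }
    }
  }
  unique(out)
}

# OLS by explicit normal equations
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  r <- y - X %*% beta
  n <- length(y)
  rss <- sum(r^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  list(beta = drop(beta), r2 = r2,
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 2))
}

# exhaustive best-AIC subset of candidate predictors
oracle_best_subset_aic <- function(dat, response, candidates) {
  best <- character(0)
  best_aic <- stats::AIC(stats::lm(stats::reformulate("1", response), dat))
  for (k in seq_along(candidates)) {
    for (set in utils::combn(candidates, k, simplify = FALSE)) {
      a <- stats::AIC(stats::lm(stats::reformulate(set, response), dat))
      if (a < best_aic) {
        best_aic <- a
        best <- set
      }
    }
  }
  list(set = sort(best), aic = best_aic)
}

# partial Spearman via correlation of residuals from rank-on-rank OLS
oracle_partial_spearman <- function(x, y, z) {
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  ex <- stats::residuals(stats::lm(rx ~ rz))
  ey <- stats::residuals(stats::lm(ry ~ rz))
  stats::cor(ex, ey)
}
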