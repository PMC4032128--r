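# Interval utilities. All genomic intervals in this package are 0-based
# half-open [start, end), stored as two-column numeric matrices with one
# row per interval, sorted by start.

empty_intervals <- function() {
  matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
}

as_intervals <- function(start, end) {
  stopifnot(length(start) == length(end), all(end > start | length(start) == 0))
  m <- cbind(start = as.numeric(start), end = as.numeric(end))
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

#' Merge a set of genomic intervals into their union
#'
#' Overlapping or abutting intervals are fused into maximal runs. Used for
#' collapsing overlapping annotated exons and for pooling exonic evidence
#' when building exon templates.
#'
#' @param ivs Two-column matrix of 0-based half-open intervals.
#' @return Two-column matrix of disjoint, sorted intervals.
#' @keywords internal
merge_intervals <- function(ivs) {
  if (nrow(ivs) == 0) return(empty_intervals())
  ivs <- ivs[order(ivs[, 1], ivs[, 2]), , drop = FALSE]
  out_s <- ivs[1, 1]
  out_e <- ivs[1, 2]
  k <- 1L
  if (nrow(ivs) > 1) {
    for (i in 2:nrow(ivs)) {
      if (ivs[i, 1] <= out_e[k]) {
        out_e[k] <- max(out_e[k], ivs[i, 2])
      } else {
        k <- k + 1L
        out_s[k] <- ivs[i, 1]
        out_e[k] <- ivs[i, 2]
      }
    }
  }
  cbind(start = unname(out_s), end = unname(out_e))
}

# total number of bases in `ivs` falling inside [start, end)
overlap_bases <- function(ivs, start, end) {
  if (nrow(ivs) == 0) return(0)
  sum(pmax(0, pmin(ivs[, 2], end) - pmax(ivs[, 1], start)))
}

# TRUE if [s, e) intersects any interval in ivs
intersects_any <- function(ivs, s, e) {
  nrow(ivs) > 0 && any(ivs[, 1] < e & ivs[, 2] > s)
}

# TRUE if [s, e) is contained in some single interval of ivs
contained_in_any <- function(ivs, s, e) {
  nrow(ivs) > 0 && any(ivs[, 1] <= s & ivs[, 2] >= e)
}
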