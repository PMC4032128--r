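# An intron chain is the package's minimal representation of one spliced
# alignment: list(start, end, introns) where `introns` is a two-column
# matrix of 0-based half-open gaps between retained blocks. After small
# gaps are fused, the exonic coverage of a chain is exactly its span minus
# its introns, which keeps every downstream coverage test a pure interval
# operation.

new_chain <- function(start, end, introns = empty_intervals()) {
  list(start = as.numeric(start), end = as.numeric(end),
       introns = introns)
}

# canonical string signature of a chain, used for caching pair
# classifications and for deduplicating identical chains within a sample
chain_sig <- function(chain) {
  paste(chain$start, chain$end,
        paste(t(chain$introns), collapse = ","), sep = ";")
}

#' Derive the intron chain of one spliced alignment
#'
#' Gaps between consecutive aligned blocks of at least `min_intron` bases
#' are interpreted as introns; smaller gaps are treated as alignment
#' indels and the flanking blocks fused.
#'
#' @param blocks Two-column matrix of sorted, disjoint aligned blocks.
#' @param min_intron Minimum gap length (bases) to call an intron.
#'   Default 40, a common spliced-alignment heuristic (true spliceosomal
#'   introns are essentially never shorter).
#' @return A chain: `list(start, end, introns)` with `introns` a
#'   two-column matrix.
#' @export
intron_chain <- function(blocks, min_intron = 40) {
  stopifnot(nrow(blocks) >= 1)
  if (nrow(blocks) == 1) {
    return(new_chain(blocks[1, 1], blocks[1, 2]))
  }
  gap_s <- blocks[-nrow(blocks), 2]
  gap_e <- blocks[-1, 1]
  keep <- (gap_e - gap_s) >= min_intron
  introns <- if (any(keep)) {
    cbind(start = gap_s[keep], end = gap_e[keep])
  } else {
    empty_intervals()
  }
  new_chain(blocks[1, 1], blocks[nrow(blocks), 2], introns)
}

#' Add intron chains to an alignment table
#'
#' Computes [intron_chain()] for every alignment and stores it in a
#' `chain` list-column together with its string signature (`chain_sig`),
#' used internally to cache pairwise event classifications.
#'
#' @inheritParams filter_by_identity
#' @param min_intron Passed to [intron_chain()].
#' @return `alignments` with `chain` and `chain_sig` columns added.
#' @export
add_intron_chains <- function(alignments, min_intron = 40) {
  chains <- lapply(alignments$blocks, intron_chain, min_intron = min_intron)
  alignments$chain <- chains
  alignments$chain_sig <- vapply(chains, chain_sig, character(1))
  alignments
}

# exonic coverage tests against a chain -------------------------------------

# TRUE if every base of [s, e) is exonic in `chain`
chain_covers <- function(chain, s, e) {
  s >= chain$start && e <= chain$end && !intersects_any(chain$introns, s, e)
}

# introns of `chain` fully inside [s, e)
introns_within <- function(chain, s, e) {
  iv <- chain$introns
  if (nrow(iv) == 0) return(iv)
  iv[iv[, 1] >= s & iv[, 2] <= e, , drop = FALSE]
}
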