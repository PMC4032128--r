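#' Build the exon template of one gene
#'
#' Pools annotated exons with the aligned blocks of the gene's ESTs and
#' merges them into maximal template exons. Template exons supported only
#' by unspliced (single-block) ESTs, overlapping no annotated exon and
#' lying strictly inside an annotated intron are discarded as orphans —
#' they are most plausibly nested genes, not exons of this gene. Surviving
#' exons without annotation support are flagged `novel`.
#'
#' @param gene One-row slice of the gene-model tibble (or a list with
#'   `gene_id`, `start`, `end` and `exons`).
#' @param chains List of intron chains of the gene's ESTs
#'   (see [intron_chain()]).
#' @return A list with elements
#'   \describe{
#'     \item{exons}{tibble `start`, `end`, `status` (`annotated`/`novel`)}
#'     \item{orphans}{two-column matrix of discarded orphan exons}
#'     \item{est_usable}{logical vector, one per chain: FALSE when every
#'       block of the EST falls inside discarded orphans (such ESTs are
#'       excluded from downstream sampling)}
#'   }
#' @export
build_exon_template <- function(gene, chains) {
  ann <- if (is.data.frame(gene)) gene$exons[[1]] else gene$exons
  gene_id <- if (is.data.frame(gene)) gene$gene_id[[1]] else gene$gene_id
  if (length(chains) == 0 && nrow(ann) == 0) {
    stop("gene ", gene_id, " has neither alignments nor annotated exons")
  }

  # exonic evidence intervals per chain: span minus introns
  chain_blocks <- lapply(chains, function(ch) {
    bounds <- c(ch$start, t(ch$introns), ch$end)
    m <- matrix(bounds, ncol = 2, byrow = TRUE)
    colnames(m) <- c("start", "end")
    m
  })
  spliced <- vapply(chains, function(ch) nrow(ch$introns) > 0, logical(1))

  evidence <- rbind(ann, do.call(rbind, c(list(empty_intervals()), chain_blocks)))
  template <- merge_intervals(evidence)

  # annotated introns: gaps between consecutive annotated exons
  ann_introns <- if (nrow(ann) >= 2) {
    cbind(start = ann[-nrow(ann), 2], end = ann[-1, 1])
  } else {
    empty_intervals()
  }

  n <- nrow(template)
  status <- character(n)
  orphan <- logical(n)
  for (i in seq_len(n)) {
    s <- template[i, 1]; e <- template[i, 2]
    has_ann <- intersects_any(ann, s, e)
    if (has_ann) {
      status[i] <- "annotated"
      next
    }
    status[i] <- "novel"
    # support: does any spliced EST contribute a block overlapping this exon?
    spliced_support <- any(vapply(which(spliced), function(k) {
      intersects_any(chain_blocks[[k]], s, e)
    }, logical(1)))
    inside_ann_intron <- contained_in_any(ann_introns, s, e)
    if (!spliced_support && inside_ann_intron) orphan[i] <- TRUE
  }

  orphans <- template[orphan, , drop = FALSE]
  kept <- template[!orphan, , drop = FALSE]
  kept_status <- status[!orphan]

  est_usable <- vapply(seq_along(chains), function(k) {
    bl <- chain_blocks[[k]]
    if (nrow(orphans) == 0) return(TRUE)
    !all(vapply(seq_len(nrow(bl)), function(j) {
      contained_in_any(orphans, bl[j, 1], bl[j, 2])
    }, logical(1)))
  }, logical(1))

  list(
    exons = tibble::tibble(
      start = kept[, 1], end = kept[, 2], status = kept_status
    ),
    orphans = orphans,
    est_usable = est_usable
  )
}
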