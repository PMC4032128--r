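#' Read gene models from a GFF3 annotation
#'
#' Parses `gene` and `exon` features from a GFF3 file into a tibble of gene
#' models, one row per gene. GFF3 1-based closed coordinates are converted
#' to the package-internal 0-based half-open convention on read, and
#' overlapping annotated exons of a gene are merged into their union.
#'
#' @param path Path to a GFF3 file. `gene` features must carry an `ID`
#'   attribute; `exon` features must carry a `Parent` attribute naming a
#'   gene. Exons whose `Parent` does not match any gene are skipped and
#'   counted in the `n_orphan_exon_records` attribute of the result.
#' @return A tibble with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end` (0-based half-open gene span) and `exons`, a list-column of
#'   two-column matrices of sorted, disjoint exon intervals.
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3",
#'   "chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=g1",
#'   "chr1\tsrc\texon\t1001\t1100\t.\t+\t.\tParent=g1",
#'   "chr1\tsrc\texon\t1501\t2000\t.\t+\t.\tParent=g1"), gff)
#' read_gene_annotation(gff)
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  g <- tryCatch(
    as.data.frame(rtracklayer::readGFF(path)),
    error = function(e) stop("malformed GFF3 in ", path, ": ", conditionMessage(e))
  )
  if (nrow(g) == 0) {
    out <- tibble::tibble(
      gene_id = character(), chrom = character(), strand = character(),
      start = numeric(), end = numeric(), exons = list()
    )
    attr(out, "n_orphan_exon_records") <- 0L
    return(out)
  }
  genes <- g[g$type == "gene", , drop = FALSE]
  exons <- g[g$type == "exon", , drop = FALSE]
  if (nrow(genes) == 0) {
    stop("no gene features found in ", path)
  }
  exon_parent <- vapply(
    seq_len(nrow(exons)),
    function(i) {
      p <- exons$Parent[[i]]
      if (length(p) == 0 || is.na(p[1])) NA_character_ else as.character(p[1])
    },
    character(1)
  )
  known <- exon_parent %in% genes$ID
  n_orphan <- sum(!known)
  if (n_orphan > 0) {
    warning(n_orphan, " exon record(s) with no gene parent skipped")
  }
  exons <- exons[known, , drop = FALSE]
  exon_parent <- exon_parent[known]

  rows <- lapply(seq_len(nrow(genes)), function(i) {
    gid <- as.character(genes$ID[i])
    ex <- exons[exon_parent == gid, , drop = FALSE]
    # GFF3 1-based closed -> 0-based half-open
    ivs <- if (nrow(ex) > 0) {
      merge_intervals(as_intervals(ex$start - 1, ex$end))
    } else {
      empty_intervals()
    }
    tibble::tibble(
      gene_id = gid,
      chrom = as.character(genes$seqid[i]),
      strand = as.character(genes$strand[i]),
      start = genes$start[i] - 1,
      end = as.numeric(genes$end[i]),
      exons = list(ivs)
    )
  })
  out <- dplyr::bind_rows(rows)
  validate_gene_models(out)
  attr(out, "n_orphan_exon_records") <- n_orphan
  out
}

validate_gene_models <- function(genes) {
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    if (nrow(ex) > 0) {
      stopifnot(
        all(ex[, 1] >= genes$start[i]),
        all(ex[, 2] <= genes$end[i]),
        all(diff(ex[, 1]) > 0),
        all(ex[-1, 1] >= ex[-nrow(ex), 2])
      )
    }
    stopifnot(genes$start[i] < genes$end[i])
  }
  invisible(genes)
}
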