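#' Read spliced EST-to-genome alignments
#'
#' Reads EST alignments from PSL (21-column, as emitted by spliced aligners)
#' or BED12. Both dialects yield the same tibble layout so downstream code
#' is dialect-agnostic; paired fixtures encoding the same alignments parse
#' to identical collections.
#'
#' For PSL, alignment identity is computed as
#' `matches / (matches + misMatches + qBaseInsert)`; for BED12 the score
#' column is interpreted as identity x 1000. Records whose block arithmetic
#' is inconsistent (block sizes/starts disagreeing with the stated span)
#' are rejected and counted in the `n_rejected` attribute.
#'
#' @param path Path to the alignment file.
#' @param dialect `"psl"` or `"bed12"`.
#' @return A tibble with columns `est_id`, `library_id` (NA when absent;
#'   for PSL an optional `library:` prefix of the query name, for BED12 the
#'   part of the name after the last `|`), `chrom`, `strand`, `start`,
#'   `end`, `identity` and `blocks` (list-column of sorted disjoint
#'   0-based half-open intervals).
#' @export
read_est_alignments <- function(path, dialect = c("psl", "bed12")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  out <- switch(dialect, psl = read_psl(path), bed12 = read_bed12(path))
  out
}

split_est_name <- function(name) {
  # "est7|libA" -> est_id "est7", library_id "libA"
  has_lib <- grepl("|", name, fixed = TRUE)
  lib <- ifelse(has_lib, sub("^.*\\|", "", name), NA_character_)
  est <- ifelse(has_lib, sub("\\|[^|]*$", "", name), name)
  list(est_id = est, library_id = lib)
}

read_psl <- function(path) {
  lines <- readLines(path)
  # tolerate the optional psLayout header block
  body <- grep("^[0-9]", lines)
  lines <- lines[body]
  n_rejected <- 0L
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 21) {
      stop("malformed PSL line ", i, ": expected 21 columns, got ", length(f))
    }
    matches <- as.numeric(f[1]); mism <- as.numeric(f[2])
    q_base_ins <- as.numeric(f[6])
    strand <- substr(f[9], 1, 1)
    nm <- split_est_name(f[10])
    t_name <- f[14]
    t_start <- as.numeric(f[16]); t_end <- as.numeric(f[17])
    n_blocks <- as.integer(f[18])
    sizes <- as.numeric(strsplit(f[19], ",", fixed = TRUE)[[1]])
    t_starts <- as.numeric(strsplit(f[21], ",", fixed = TRUE)[[1]])
    if (length(sizes) != n_blocks || length(t_starts) != n_blocks ||
        t_starts[1] != t_start || t_starts[n_blocks] + sizes[n_blocks] != t_end ||
        any(diff(t_starts) <= 0)) {
      n_rejected <- n_rejected + 1L
      next
    }
    rows[[i]] <- tibble::tibble(
      est_id = nm$est_id, library_id = nm$library_id,
      chrom = t_name, strand = strand,
      start = t_start, end = t_end,
      identity = matches / (matches + mism + q_base_ins),
      blocks = list(cbind(start = t_starts, end = t_starts + sizes))
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- empty_alignments()
  }
  attr(out, "n_rejected") <- n_rejected
  out
}

read_bed12 <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "bed"),
    error = function(e) stop("malformed BED12 in ", path, ": ", conditionMessage(e))
  )
  if (length(gr) == 0) {
    out <- empty_alignments()
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  bl <- rtracklayer::blocks(gr)
  nm <- split_est_name(as.character(gr$name))
  n_rejected <- 0L
  keep <- rep(TRUE, length(gr))
  blocks <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    b <- bl[[i]]
    m <- cbind(start = BiocGenerics::start(b) - 1, end = BiocGenerics::end(b))
    ok <- nrow(m) >= 1 &&
      m[1, 1] == BiocGenerics::start(gr[i]) - 1 &&
      m[nrow(m), 2] == BiocGenerics::end(gr[i]) &&
      (nrow(m) == 1 || all(diff(m[, 1]) > 0 & m[-1, 1] >= m[-nrow(m), 2]))
    if (!ok) {
      keep[i] <- FALSE
      n_rejected <- n_rejected + 1L
      next
    }
    blocks[[i]] <- m
  }
  out <- tibble::tibble(
    est_id = nm$est_id[keep],
    library_id = nm$library_id[keep],
    chrom = as.character(GenomeInfoDb::seqnames(gr))[keep],
    strand = as.character(BiocGenerics::strand(gr))[keep],
    start = as.numeric(BiocGenerics::start(gr) - 1)[keep],
    end = as.numeric(BiocGenerics::end(gr))[keep],
    identity = as.numeric(gr$score)[keep] / 1000,
    blocks = blocks[keep]
  )
  attr(out, "n_rejected") <- n_rejected
  out
}

empty_alignments <- function() {
  tibble::tibble(
    est_id = character(), library_id = character(), chrom = character(),
    strand = character(), start = numeric(), end = numeric(),
    identity = numeric(), blocks = list()
  )
}

#' Filter EST alignments by identity and library
#'
#' Retains alignments with `identity >= min_identity` whose library is not
#' excluded. Order-preserving and idempotent. The default threshold follows
#' the standard high-quality-alignment cutoff of 95% identity; library
#' exclusion supports removing e.g. cancer-derived EST libraries whose
#' aberrant transcripts would inflate splicing estimates.
#'
#' @param alignments Tibble from [read_est_alignments()].
#' @param min_identity Minimum identity fraction (inclusive). Default 0.95.
#' @param exclude_libraries Character vector of `library_id`s to drop.
#' @return The filtered tibble.
#' @export
filter_by_identity <- function(alignments, min_identity = 0.95,
                               exclude_libraries = character()) {
  keep <- alignments$identity >= min_identity &
    !(alignments$library_id %in% exclude_libraries)
  alignments[keep, , drop = FALSE]
}

#' Assign ESTs to genes by annotation coordinates
#'
#' Each alignment is assigned to the gene (same chromosome) whose span
#' contains the largest fraction of its aligned bases, provided that
#' fraction is at least `min_overlap`. Ties and sub-threshold overlaps
#' leave the EST unassigned (`gene_id` NA). Strand is deliberately not
#' required to match: EST orientation is frequently unknown, and event
#' classification later uses the gene's annotated strand.
#'
#' @param alignments Tibble from [read_est_alignments()].
#' @param genes Tibble from [read_gene_annotation()].
#' @param min_overlap Minimum fraction of aligned bases inside the winning
#'   gene span (default 0.5).
#' @return `alignments` with a `gene_id` column added (NA = unassigned);
#'   the number of unassigned ESTs is in the `n_unassigned` attribute.
#' @export
assign_to_genes <- function(alignments, genes, min_overlap = 0.5) {
  gene_id <- rep(NA_character_, nrow(alignments))
  for (i in seq_len(nrow(alignments))) {
    cand <- which(genes$chrom == alignments$chrom[i] &
                    genes$start < alignments$end[i] &
                    genes$end > alignments$start[i])
    if (length(cand) == 0) next
    bl <- alignments$blocks[[i]]
    total <- sum(bl[, 2] - bl[, 1])
    frac <- vapply(cand, function(j) {
      overlap_bases(bl, genes$start[j], genes$end[j]) / total
    }, numeric(1))
    best <- max(frac)
    if (best < min_overlap) next
    if (sum(frac == best) > 1) next  # tie -> unassigned
    gene_id[i] <- genes$gene_id[cand[which.max(frac)]]
  }
  out <- alignments
  out$gene_id <- gene_id
  attr(out, "n_unassigned") <- sum(is.na(gene_id))
  out
}
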