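#' Coverage-corrected splicing index of one gene
#'
#' The comparable alternative-splicing index: for a gene with more than
#' `sample_size` ESTs, draw `n_samples` random samples of exactly
#' `sample_size` ESTs (uniformly, without replacement), count the distinct
#' splicing events in each sample, and average. Because every gene is
#' scored from samples of identical size, the index does not inherit the
#' strong dependence of raw event counts on per-gene transcript coverage,
#' making values comparable across genes and species.
#'
#' Sampling uses an RNG stream derived from `(seed, gene_id)`, so per-gene
#' results are reproducible and independent of processing order.
#'
#' @param chains List of intron chains of the gene's usable ESTs.
#' @param template Exon template from [build_exon_template()].
#' @param gene_id Gene identifier (seeds the per-gene RNG stream).
#' @param strand Gene strand.
#' @param n_samples Number of random samples (default 100).
#' @param sample_size ESTs per sample (default 10). Genes require strictly
#'   more than `sample_size` ESTs to be eligible.
#' @param seed Global integer seed.
#' @param flank Retained-intron flank (see [classify_event_pair()]).
#' @param asp_rule `"mean"` (default): a gene is alternatively spliced iff
#'   the across-sample mean event count is at least 1. `"min"`: iff every
#'   sample contains at least one event.
#' @return One-row tibble: `gene_id`, `n_ests`, `eligible`, `mean_events`,
#'   `is_as`, and `sample_counts` (list-column with the per-sample counts).
#' @export
gene_as_index <- function(chains, template, gene_id, strand = "+",
                          n_samples = 100, sample_size = 10, seed = 1,
                          flank = 10, asp_rule = c("mean", "min")) {
  asp_rule <- match.arg(asp_rule)
  n_ests <- length(chains)
  if (n_ests <= sample_size) {
    return(tibble::tibble(
      gene_id = gene_id, n_ests = n_ests, eligible = FALSE,
      mean_events = NA_real_, is_as = NA, sample_counts = list(integer(0))
    ))
  }
  tx <- cbind(template$exons$start, template$exons$end)
  cache <- new.env(parent = emptyenv())
  counts <- with_stream(seed, gene_id, {
    vapply(seq_len(n_samples), function(s) {
      idx <- sample.int(n_ests, sample_size)
      length(events_in_sample(chains[idx], tx, strand = strand,
                              flank = flank, cache = cache))
    }, integer(1))
  })
  mean_events <- mean(counts)
  tibble::tibble(
    gene_id = gene_id, n_ests = n_ests, eligible = TRUE,
    mean_events = mean_events,
    is_as = classify_as_gene(mean_events, counts, asp_rule),
    sample_counts = list(counts)
  )
}

#' Alternative-splicing classification of a gene
#'
#' A gene is alternatively spliced if it shows at least an average of one
#' splicing event over the random samples (boundary inclusive). The
#' alternative `"min"` rule requires at least one event in every sample.
#'
#' @param mean_events Across-sample mean event count.
#' @param sample_counts Integer vector of per-sample counts (used by the
#'   `"min"` rule).
#' @param asp_rule `"mean"` or `"min"`.
#' @return Logical.
#' @export
classify_as_gene <- function(mean_events, sample_counts = NULL,
                             asp_rule = c("mean", "min")) {
  asp_rule <- match.arg(asp_rule)
  if (asp_rule == "mean") {
    mean_events >= 1.0
  } else {
    !is.null(sample_counts) && length(sample_counts) > 0 &&
      min(sample_counts) >= 1
  }
}

#' Coverage-corrected splicing indices for all genes of a dataset
#'
#' Runs the full per-gene stage: groups assigned alignments by gene,
#' derives intron chains, builds each gene's exon template (dropping
#' orphan-only ESTs), and computes the subsampled splicing index.
#'
#' @param alignments Tibble of filtered alignments with `gene_id` set
#'   (see [assign_to_genes()]).
#' @param genes Gene-model tibble from [read_gene_annotation()].
#' @param min_intron Minimum intron length for [intron_chain()].
#' @param naive If TRUE, also report `naive_events`: the event count from
#'   pooling *all* of a gene's ESTs at once — the coverage-biased quantity
#'   the subsampled index is designed to replace.
#' @inheritParams gene_as_index
#' @return Tibble with one row per gene carrying at least one assigned
#'   EST; columns as in [gene_as_index()] plus `naive_events` when
#'   requested.
#' @export
as_index <- function(alignments, genes, n_samples = 100, sample_size = 10,
                     seed = 1, min_intron = 40, flank = 10,
                     asp_rule = c("mean", "min"), naive = FALSE) {
  asp_rule <- match.arg(asp_rule)
  if (!"chain" %in% names(alignments)) {
    alignments <- add_intron_chains(alignments, min_intron = min_intron)
  }
  aln <- alignments[!is.na(alignments$gene_id), , drop = FALSE]
  out <- lapply(split(seq_len(nrow(aln)), aln$gene_id), function(idx) {
    gid <- aln$gene_id[idx[1]]
    grow <- genes[genes$gene_id == gid, , drop = FALSE]
    if (nrow(grow) == 0) return(NULL)
    chains <- aln$chain[idx]
    tmpl <- build_exon_template(grow, chains)
    chains <- chains[tmpl$est_usable]
    res <- gene_as_index(
      chains, tmpl, gene_id = gid, strand = grow$strand[1],
      n_samples = n_samples, sample_size = sample_size, seed = seed,
      flank = flank, asp_rule = asp_rule
    )
    if (naive) {
      tx <- cbind(tmpl$exons$start, tmpl$exons$end)
      res$naive_events <- length(events_in_sample(
        chains, tx, strand = grow$strand[1], flank = flank,
        cache = new.env(parent = emptyenv())
      ))
    }
    res
  })
  dplyr::bind_rows(out)
}

#' Species-level splicing summary (ASP and ASL)
#'
#' Aggregates per-gene indices into the two species-level statistics:
#' ASP, the proportion of indexed genes classified as alternatively
#' spliced, and ASL, the mean of the per-gene indices (average number of
#' splicing events per gene). Species with fewer than `min_genes` indexed
#' genes are flagged as excluded (`included = FALSE`): with too few genes
#' the indices are not comparable across species.
#'
#' @param indices Per-gene index tibble from [as_index()].
#' @param species_id Species identifier for the output row.
#' @param min_genes Minimum number of indexed (eligible) genes for the
#'   species to be included (default 500).
#' @return One-row tibble: `species_id`, `n_genes_indexed`, `asp`, `asl`,
#'   `included`.
#' @export
species_summary <- function(indices, species_id, min_genes = 500) {
  if (nrow(indices) == 0) stop("no gene indices supplied for ", species_id)
  idx <- indices[indices$eligible, , drop = FALSE]
  n <- nrow(idx)
  tibble::tibble(
    species_id = species_id,
    n_genes_indexed = n,
    asp = if (n > 0) mean(idx$is_as) else NA_real_,
    asl = if (n > 0) mean(idx$mean_events) else NA_real_,
    included = n >= min_genes
  )
}
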