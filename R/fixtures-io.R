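# Plain-text fixture emission. Writers are deliberately simple formatters;
# round-trip fidelity against the package readers is part of the test
# surface (write-then-parse reproduces the in-memory objects).

#' Write gene models as GFF3
#'
#' @param genes Gene-model tibble (see [read_gene_annotation()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes))) {
    lines <- c(lines, paste(
      genes$chrom[i], "splicedex", "gene",
      genes$start[i] + 1, genes$end[i], ".", genes$strand[i], ".",
      paste0("ID=", genes$gene_id[i]), sep = "\t"
    ))
    ex <- genes$exons[[i]]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, paste(
        genes$chrom[i], "splicedex", "exon",
        ex[j, 1] + 1, ex[j, 2], ".", genes$strand[i], ".",
        paste0("Parent=", genes$gene_id[i]), sep = "\t"
      ))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

est_name <- function(est_id, library_id) {
  ifelse(is.na(library_id), est_id, paste0(est_id, "|", library_id))
}

#' Write EST alignments as 21-column PSL
#'
#' Identity is encoded in the match columns as
#' `matches = round(identity * 1000)`, `misMatches = 1000 - matches`,
#' `qBaseInsert = 0`, so the reader's identity formula recovers the
#' stored (1/1000-quantized) value exactly.
#'
#' @param alignments Alignment tibble (see [read_est_alignments()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psl <- function(alignments, path) {
  lines <- character(nrow(alignments))
  for (i in seq_len(nrow(alignments))) {
    bl <- alignments$blocks[[i]]
    sizes <- bl[, 2] - bl[, 1]
    q_len <- sum(sizes)
    matches <- round(alignments$identity[i] * 1000)
    lines[i] <- paste(
      matches, 1000 - matches, 0, 0, 0, 0,
      nrow(bl) - 1, alignments$end[i] - alignments$start[i] - q_len,
      alignments$strand[i],
      est_name(alignments$est_id[i], alignments$library_id[i]),
      q_len, 0, q_len,
      alignments$chrom[i], alignments$end[i],
      alignments$start[i], alignments$end[i],
      nrow(bl),
      paste0(paste(sizes, collapse = ","), ","),
      paste0(paste(cumsum(c(0, sizes[-length(sizes)])), collapse = ","), ","),
      paste0(paste(bl[, 1], collapse = ","), ","),
      sep = "\t"
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write EST alignments as BED12
#'
#' The score column stores `identity * 1000`; block fields encode the
#' aligned blocks.
#'
#' @inheritParams write_psl
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(alignments, path) {
  lines <- character(nrow(alignments))
  for (i in seq_len(nrow(alignments))) {
    bl <- alignments$blocks[[i]]
    sizes <- bl[, 2] - bl[, 1]
    rel <- bl[, 1] - alignments$start[i]
    lines[i] <- paste(
      alignments$chrom[i], alignments$start[i], alignments$end[i],
      est_name(alignments$est_id[i], alignments$library_id[i]),
      round(alignments$identity[i] * 1000), alignments$strand[i],
      alignments$start[i], alignments$end[i], 0,
      nrow(bl),
      paste0(paste(sizes, collapse = ","), ","),
      paste0(paste(rel, collapse = ","), ","),
      sep = "\t"
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a complete fixture set for one simulated species
#'
#' Emits every plain-text artefact of a simulation into `dir`: gene
#' annotation (GFF3), the same EST alignments in both PSL and BED12
#' dialects, truth tables (per-gene event counts and per-EST isoform of
#' origin) as TSV, and the resolved configuration (seed included) as
#' JSON. Optionally a Newick tree and a trait table. Re-reading the
#' GFF3/PSL/BED12 with the package readers reproduces the in-memory
#' objects.
#'
#' @param sim Output of [simulate_gene_models()].
#' @param ests Output of [simulate_est_library()].
#' @param dir Output directory (created if needed).
#' @param tree Optional `ape::phylo` tree, written as `tree.nwk`.
#' @param traits Optional trait data frame, written as `traits.tsv`.
#' @return Named character vector of written paths, invisibly.
#' @export
write_fixtures <- function(sim, ests, dir, tree = NULL, traits = NULL) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create fixture directory: ", dir)
  }
  paths <- c(
    annotation = file.path(dir, "genes.gff3"),
    psl = file.path(dir, "ests.psl"),
    bed12 = file.path(dir, "ests.bed"),
    gene_truth = file.path(dir, "truth_genes.tsv"),
    est_truth = file.path(dir, "truth_ests.tsv"),
    config = file.path(dir, "sim_config.json")
  )
  write_gff3(sim$genes, paths[["annotation"]])
  write_psl(ests, paths[["psl"]])
  write_bed12(ests, paths[["bed12"]])
  readr::write_tsv(
    dplyr::select(sim$truth, -"event_sigs"), paths[["gene_truth"]]
  )
  readr::write_tsv(
    dplyr::select(ests, "est_id", "gene_id_true", "isoform_id"),
    paths[["est_truth"]]
  )
  jsonlite::write_json(
    unclass(sim$config), paths[["config"]],
    auto_unbox = TRUE, digits = NA
  )
  if (!is.null(tree)) {
    paths[["tree"]] <- file.path(dir, "tree.nwk")
    ape::write.tree(tree, paths[["tree"]])
  }
  if (!is.null(traits)) {
    paths[["traits"]] <- file.path(dir, "traits.tsv")
    readr::write_tsv(traits, paths[["traits"]])
  }
  invisible(paths)
}

#' Read a trait table from TSV
#'
#' @param path TSV file with a header; one row per species.
#' @return A tibble.
#' @export
read_trait_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
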