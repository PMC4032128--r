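#' Configuration for the synthetic EST study generator
#'
#' Collects every tunable of the simulator with defaults chosen to emulate
#' desk-scale EST-era data: multi-exon genes, a handful of isoforms per
#' gene, heavy-tailed (log-normal) expression so per-gene EST depth spans
#' orders of magnitude, partial single-pass reads with optional 3'-end
#' bias, and alignment identity noise that leaves a minority of ESTs below
#' the 95% retention threshold.
#'
#' @param n_genes Number of genes.
#' @param n_exons Integer range (min, max) of exons per gene.
#' @param exon_length,intron_length Base-pair ranges for exon and intron
#'   lengths (introns are kept comfortably above the 40 bp intron-calling
#'   threshold).
#' @param n_isoforms Integer range of isoforms per gene.
#' @param freq_alpha Dirichlet concentration for isoform frequencies
#'   (1 = uniform over the simplex; small values produce rare isoforms).
#' @param expression_sdlog Log-normal sd of per-gene expression weights
#'   (default 1.5: EST totals per gene span >= 2 orders of magnitude).
#' @param mean_depth Expected number of ESTs for a gene of average
#'   expression.
#' @param full_length If TRUE every EST covers its complete isoform;
#'   otherwise the covered transcript fraction is Beta-distributed.
#' @param coverage_shape Beta shape parameters (a, b) of the covered
#'   fraction.
#' @param end_bias Probability that a partial read is anchored at the
#'   transcript 3' end (EST technology sequences from the poly-A tail).
#' @param identity_beta Beta shape parameters (a, b); alignment identity
#'   is drawn as `0.8 + 0.2 * Beta(a, b)` and quantized to 1/1000 (the
#'   resolution of the BED12 score field).
#' @param p_retention Probability that a non-reference isoform is made by
#'   retaining an intron rather than skipping exons.
#' @param min_intron Intron-calling threshold used downstream.
#' @param gap Intergenic spacing in bases.
#' @param seed Integer seed recorded in every output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200,
                       n_exons = c(4, 10),
                       exon_length = c(80, 300),
                       intron_length = c(200, 2000),
                       n_isoforms = c(1, 4),
                       freq_alpha = 1,
                       expression_sdlog = 1.5,
                       mean_depth = 30,
                       full_length = FALSE,
                       coverage_shape = c(2, 2),
                       end_bias = 0.3,
                       identity_beta = c(8, 1),
                       p_retention = 0.3,
                       min_intron = 40,
                       gap = 5000,
                       seed = 1) {
  cfg <- as.list(environment())
  ranges <- list(n_exons = n_exons, exon_length = exon_length,
                 intron_length = intron_length, n_isoforms = n_isoforms)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || any(r <= 0) || r[1] > r[2]) {
      stop("infeasible range for ", nm)
    }
  }
  if (cfg$n_exons[1] < 2) stop("genes need at least 2 exons")
  if (cfg$intron_length[1] < cfg$min_intron) {
    stop("intron_length minimum below min_intron")
  }
  structure(cfg, class = "sim_config")
}

# sample helpers immune to R's scalar-x sample() surprise
rint <- function(lo, hi) {
  if (lo >= hi) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
}
sample_vec <- function(x, n) x[sample.int(length(x), n)]

# full-length chain of an isoform (its exon matrix) under the config's
# intron threshold
isoform_chain <- function(exons, min_intron = 40) {
  intron_chain(exons, min_intron = min_intron)
}

# truth model: distinct events among all full-length isoform chains
true_event_sigs <- function(isoform_exons, template_exons, strand,
                            min_intron = 40, flank = 10) {
  chains <- lapply(isoform_exons, isoform_chain, min_intron = min_intron)
  events_in_sample(chains, template_exons, strand = strand, flank = flank)
}

#' Simulate gene models with known isoform structure
#'
#' Lays out non-overlapping multi-exon genes on a synthetic chromosome and
#' equips each with 1 or more isoforms: a reference isoform using all
#' exons, plus derived isoforms that either skip a random set of internal
#' exons (cassette events) or retain one intron. Every isoform keeps the
#' first and last exon, so all isoforms of a gene share exons. The implied
#' true event set of each gene is computed with the package's own
#' pairwise classifier applied to the full-length isoform chains.
#'
#' @param config A [sim_config()].
#' @param isoform_spec Optional function(gene_idx) returning a list with
#'   `drop_sets` (list of integer vectors of internal exon indices to skip
#'   per extra isoform; an entry of the form `list(retain = i)` retains
#'   intron i instead) and `freqs` (frequencies for all isoforms). Used by
#'   validation designs needing exact isoform structure; NULL = random per
#'   config.
#' @return List with elements `genes` (gene-model tibble as from
#'   [read_gene_annotation()]), `isoforms` (tibble: `gene_id`,
#'   `isoform_id`, `frequency`, `exons` list-column), `truth` (tibble:
#'   `gene_id`, `n_isoforms`, `min_freq`, `true_events`, plus the event
#'   signatures as a list-column) and `config`.
#' @export
simulate_gene_models <- function(config, isoform_spec = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_stream(config$seed, "gene_models", {
    pos <- config$gap
    gene_rows <- vector("list", config$n_genes)
    iso_rows <- vector("list", config$n_genes)
    truth_rows <- vector("list", config$n_genes)
    for (g in seq_len(config$n_genes)) {
      gid <- sprintf("g%04d", g)
      n_ex <- rint(config$n_exons[1], config$n_exons[2])
      ex_len <- round(runif(n_ex, config$exon_length[1], config$exon_length[2]))
      in_len <- round(runif(n_ex - 1, config$intron_length[1],
                            config$intron_length[2]))
      starts <- pos + c(0, cumsum(ex_len[-n_ex] + in_len))
      exons <- cbind(start = starts, end = starts + ex_len)
      strand <- sample_vec(c("+", "-"), 1)
      gene_start <- exons[1, 1]
      gene_end <- exons[n_ex, 2]
      pos <- gene_end + config$gap

      # isoform structures
      if (!is.null(isoform_spec)) {
        spec <- isoform_spec(g)
        drop_sets <- spec$drop_sets
        freqs <- spec$freqs
      } else {
        k <- rint(config$n_isoforms[1], config$n_isoforms[2])
        drop_sets <- list()
        if (k > 1 && n_ex >= 3) {
          internal <- 2:(n_ex - 1)
          for (j in seq_len(k - 1)) {
            if (runif(1) < config$p_retention) {
              drop_sets[[j]] <- list(retain = rint(1L, n_ex - 1L))
            } else {
              nd <- rint(1L, min(2L, length(internal)))
              drop_sets[[j]] <- sort(sample_vec(internal, nd))
            }
          }
        }
        k_eff <- length(drop_sets) + 1
        w <- rgamma(k_eff, shape = config$freq_alpha)
        freqs <- w / sum(w)
      }

      iso_exons <- list(exons)
      for (ds in drop_sets) {
        if (is.list(ds) && !is.null(ds$retain)) {
          i <- ds$retain
          m <- exons
          m[i, 2] <- m[i + 1, 2]
          m <- m[-(i + 1), , drop = FALSE]
          iso_exons[[length(iso_exons) + 1]] <- m
        } else {
          iso_exons[[length(iso_exons) + 1]] <- exons[-ds, , drop = FALSE]
        }
      }
      # deduplicate structurally identical isoforms
      sig <- vapply(iso_exons, function(m) paste(t(m), collapse = ","),
                    character(1))
      keep <- !duplicated(sig)
      iso_exons <- iso_exons[keep]
      freqs <- freqs[keep] / sum(freqs[keep])
      k_eff <- length(iso_exons)

      template <- merge_intervals(do.call(rbind, c(list(exons), iso_exons)))
      sigs <- true_event_sigs(iso_exons, template, strand,
                              min_intron = config$min_intron)

      gene_rows[[g]] <- tibble::tibble(
        gene_id = gid, chrom = "chrS1", strand = strand,
        start = gene_start, end = gene_end, exons = list(exons)
      )
      iso_rows[[g]] <- tibble::tibble(
        gene_id = gid,
        isoform_id = sprintf("%s.i%d", gid, seq_len(k_eff)),
        frequency = freqs,
        exons = iso_exons
      )
      truth_rows[[g]] <- tibble::tibble(
        gene_id = gid, n_isoforms = k_eff, min_freq = min(freqs),
        true_events = length(sigs), event_sigs = list(sigs)
      )
    }
    list(
      genes = dplyr::bind_rows(gene_rows),
      isoforms = dplyr::bind_rows(iso_rows),
      truth = dplyr::bind_rows(truth_rows),
      config = config
    )
  })
}
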