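# Alternative splicing event detection by pairwise comparison of intron
# chains. Events are identified as canonical string signatures so that the
# same event seen in many EST pairs deduplicates to one count; the public
# classify_event_pair() parses signatures into a tidy tibble.
#
# Event taxonomy: exon_skipping, alt_donor, alt_acceptor, intron_retention,
# complex. Donor/acceptor are named relative to the gene's transcriptional
# strand (on + the donor is the intron start, on - the intron end). A rule
# precedence avoids double counting: the two sub-introns flanking a skipped
# exon are not additionally reported as alternative splice sites of the
# outer skipping intron.

sig_interval <- function(s, e) paste0(s, "-", e)

sig_pair <- function(i1, i2) {
  # canonical order of an intron pair, symmetric in the two chains
  a <- sig_interval(i1[1], i1[2]); b <- sig_interval(i2[1], i2[2])
  if (a < b) paste(a, b, sep = "/") else paste(b, a, sep = "/")
}

# Classify events between two chains, returning signature strings.
# `template_exons` is the two-column matrix of kept template exon intervals.
classify_chain_pair_sigs <- function(a, b, template_exons, strand,
                                     flank = 10) {
  shared_s <- max(a$start, b$start)
  shared_e <- min(a$end, b$end)
  if (shared_e <= shared_s) return(character(0))

  sigs <- character(0)
  # outer introns that produced a skipping event, per chain (row indices)
  skip_outer <- list(matrix(numeric(0), ncol = 2), matrix(numeric(0), ncol = 2))

  chains <- list(a, b)
  for (d in 1:2) {
    x <- chains[[d]]; y <- chains[[3 - d]]
    xi <- introns_within(x, shared_s, shared_e)
    for (r in seq_len(nrow(xi))) {
      is_ <- xi[r, 1]; ie <- xi[r, 2]

      # intron retention: y exonic across the intron with flanking coverage
      if (ie - is_ >= 1 &&
          chain_covers(y, is_ - flank, ie + flank)) {
        sigs <- c(sigs, paste0("intron_retention|", sig_interval(is_, ie)))
      }

      # exon skipping: a template exon inside this intron is an internal
      # exon of y, and both chains are exonic just outside the intron
      if (nrow(template_exons) > 0) {
        cand <- which(template_exons[, 1] >= is_ & template_exons[, 2] <= ie)
        for (tc in cand) {
          ts <- template_exons[tc, 1]; te <- template_exons[tc, 2]
          if (!chain_covers(y, ts, te)) next
          left <- introns_within(y, is_, ts)
          right <- introns_within(y, te, ie)
          if (nrow(left) == 0 || nrow(right) == 0) next
          if (!chain_covers(y, is_ - 1, is_) || !chain_covers(y, ie, ie + 1)) next
          sigs <- c(sigs, paste0(
            "exon_skipping|", sig_interval(ts, te), "|", sig_interval(is_, ie)
          ))
          skip_outer[[d]] <- rbind(skip_outer[[d]], c(is_, ie))
        }
      }
    }
  }

  # intron-pair rules over introns of a vs b inside the shared span
  ai <- introns_within(a, shared_s, shared_e)
  bi <- introns_within(b, shared_s, shared_e)
  suppressed <- function(ia, ib) {
    contains <- function(outer, inner) {
      outer[1] <= inner[1] && outer[2] >= inner[2]
    }
    in_outer <- function(outer_set, iv) {
      nrow(outer_set) > 0 &&
        any(outer_set[, 1] == iv[1] & outer_set[, 2] == iv[2])
    }
    (contains(ia, ib) && in_outer(skip_outer[[1]], ia)) ||
      (contains(ib, ia) && in_outer(skip_outer[[2]], ib))
  }
  for (i in seq_len(nrow(ai))) {
    for (j in seq_len(nrow(bi))) {
      ia <- ai[i, ]; ib <- bi[j, ]
      if (ia[2] <= ib[1] || ib[2] <= ia[1]) next  # no overlap
      same_start <- ia[1] == ib[1]
      same_end <- ia[2] == ib[2]
      if (same_start && same_end) next            # identical intron
      if (suppressed(ia, ib)) next
      if (same_start || same_end) {
        # exactly one shared boundary: the varying site names the event
        varies_at_start <- !same_start
        kind <- if (strand == "+") {
          if (varies_at_start) "alt_donor" else "alt_acceptor"
        } else {
          if (varies_at_start) "alt_acceptor" else "alt_donor"
        }
        sigs <- c(sigs, paste0(kind, "|", sig_pair(ia, ib)))
      } else {
        sigs <- c(sigs, paste0("complex|", sig_pair(ia, ib)))
      }
    }
  }
  unique(sigs)
}

parse_event_sigs <- function(sigs, gene_id = NA_character_) {
  if (length(sigs) == 0) {
    return(tibble::tibble(
      gene_id = character(), kind = character(), signature = character()
    ))
  }
  tibble::tibble(
    gene_id = gene_id,
    kind = sub("\\|.*$", "", sigs),
    signature = sigs
  )
}

#' Classify alternative splicing events between two intron chains
#'
#' Compares two spliced alignments of the same gene within their shared
#' genomic span and reports every splice difference as a typed,
#' canonicalised event. The result is symmetric in the two chains.
#'
#' @param a,b Intron chains (see [intron_chain()]).
#' @param template Exon template of the gene from [build_exon_template()],
#'   or a two-column matrix of template exon intervals.
#' @param strand Gene strand, `"+"` or `"-"`; determines donor vs acceptor
#'   naming.
#' @param flank Minimum exonic bases required on both sides of a retained
#'   intron (default 10).
#' @return A tibble with columns `gene_id`, `kind`, `signature`.
#' @export
classify_event_pair <- function(a, b, template, strand = "+", flank = 10) {
  tx <- if (is.list(template) && !is.null(template$exons)) {
    cbind(template$exons$start, template$exons$end)
  } else {
    template
  }
  parse_event_sigs(classify_chain_pair_sigs(a, b, tx, strand, flank))
}

#' Enumerate splicing events within a sample of intron chains
#'
#' Takes the union of [classify_event_pair()] over all unordered pairs of
#' chains. This per-sample enumeration is the quantity averaged over
#' repeated fixed-size random samples to obtain the coverage-corrected
#' splicing index.
#'
#' @param chains List of intron chains of one gene.
#' @inheritParams classify_event_pair
#' @param cache Optional environment memoising pair classifications by
#'   chain signature (shared across the samples of one gene).
#' @return Character vector of unique event signatures (its length is the
#'   event count of the sample).
#' @export
events_in_sample <- function(chains, template, strand = "+", flank = 10,
                             cache = NULL) {
  tx <- if (is.list(template) && !is.null(template$exons)) {
    cbind(template$exons$start, template$exons$end)
  } else {
    template
  }
  sigs <- vapply(chains, chain_sig, character(1))
  uniq <- !duplicated(sigs)
  chains <- chains[uniq]
  sigs <- sigs[uniq]
  n <- length(chains)
  if (n < 2) return(character(0))
  out <- character(0)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      key <- if (sigs[i] < sigs[j]) {
        paste(sigs[i], sigs[j], sep = "||")
      } else {
        paste(sigs[j], sigs[i], sep = "||")
      }
      ev <- if (!is.null(cache) && exists(key, envir = cache, inherits = FALSE)) {
        get(key, envir = cache)
      } else {
        v <- classify_chain_pair_sigs(chains[[i]], chains[[j]], tx,
                                      strand, flank)
        if (!is.null(cache)) assign(key, v, envir = cache)
        v
      }
      out <- c(out, ev)
    }
  }
  unique(out)
}
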