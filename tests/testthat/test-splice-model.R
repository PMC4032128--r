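test_that("small inter-block gaps fuse; qualifying gaps become introns", {
  ch <- mk_chain(c(0, 105, 400), c(100, 300, 500))
  expect_equal(unname(ch$introns), cbind(300, 400), ignore_attr = TRUE)
  expect_equal(nrow(mk_chain(0, 500)$introns), 0)
  ch2 <- mk_chain(c(0, 200), c(100, 300))
  expect_equal(unname(ch2$introns[1, ]), c(100, 200))
})

test_that("exon template reproduces annotation when ESTs tile it exactly", {
  gene <- list(gene_id = "g", start = 0, end = 500, exons = toy_template)
  chains <- list(toy_inclusion(), toy_inclusion())
  tm <- build_exon_template(gene, chains)
  expect_equal(tm$exons$start, c(0, 200, 400))
  expect_equal(tm$exons$end, c(100, 300, 500))
  expect_true(all(tm$exons$status == "annotated"))
  expect_equal(nrow(tm$orphans), 0)
  expect_true(all(tm$est_usable))
})

test_that("single-block exons inside annotated introns are discarded as orphans", {
  gene <- list(gene_id = "g", start = 0, end = 500, exons = toy_template)
  chains <- list(toy_inclusion(), mk_chain(310, 390))  # nested, unspliced
  tm <- build_exon_template(gene, chains)
  expect_equal(unname(tm$orphans[1, ]), c(310, 390))
  expect_false("novel" %in% tm$exons$status)
  expect_equal(tm$est_usable, c(TRUE, FALSE))
})

test_that("spliced support keeps a non-annotated exon as novel", {
  gene <- list(gene_id = "g", start = 0, end = 500, exons = toy_template)
  # EST splices from a new exon at [120,160) into annotated e2
  chains <- list(toy_inclusion(), mk_chain(c(120, 200), c(160, 300)))
  tm <- build_exon_template(gene, chains)
  expect_true(any(tm$exons$status == "novel" &
                    tm$exons$start == 120 & tm$exons$end == 160))
  expect_true(all(tm$est_usable))
})

test_that("gene with neither alignments nor annotated exons errors", {
  gene <- list(gene_id = "g", start = 0, end = 500, exons = empty_intervals())
  expect_error(build_exon_template(gene, list()), "neither")
})

test_that("cassette, splice-site, retention and disjoint cases classify as specified", {
  # cassette: one exon_skipping event only (flanking sub-introns suppressed)
  ev <- classify_event_pair(toy_inclusion(), toy_skip_e2(), toy_template, "+")
  expect_equal(ev$kind, "exon_skipping")

  # shared acceptor, differing donor on + strand -> alt_donor
  a <- mk_chain(c(0, 200), c(100, 500))
  b <- mk_chain(c(0, 200), c(120, 500))
  ev <- classify_event_pair(a, b, toy_template, "+")
  expect_equal(ev$kind, "alt_donor")
  # same coordinates on - strand -> alt_acceptor
  ev <- classify_event_pair(a, b, toy_template, "-")
  expect_equal(ev$kind, "alt_acceptor")

  # intron retention
  r1 <- mk_chain(c(0, 200), c(100, 500))
  r2 <- mk_chain(50, 250)
  ev <- classify_event_pair(r1, r2, toy_template, "+")
  expect_equal(ev$kind, "intron_retention")

  # disjoint spans -> empty
  d1 <- mk_chain(0, 100)
  d2 <- mk_chain(400, 500)
  expect_equal(nrow(classify_event_pair(d1, d2, toy_template, "+")), 0)
})

test_that("event detection within samples matches hand-enumerated counts", {
  # 10 identical chains: no pairwise difference
  expect_length(
    events_in_sample(replicate(10, toy_inclusion(), simplify = FALSE),
                     toy_template, "+"),
    0
  )
  # 5+5 mixture of two isoforms differing by one skipped exon: one event
  chains <- c(replicate(5, toy_inclusion(), simplify = FALSE),
              replicate(5, toy_skip_e2(), simplify = FALSE))
  expect_length(events_in_sample(chains, toy_template, "+"), 1)
  # three isoforms pairwise differing by distinct retained introns
  tmpl4 <- cbind(c(0, 200, 400, 600), c(100, 300, 500, 700))
  spliced <- function(retain) {
    ex <- tmpl4
    if (!is.null(retain)) {
      ex[retain, 2] <- ex[retain + 1, 2]
      ex <- ex[-(retain + 1), , drop = FALSE]
    }
    intron_chain(ex)
  }
  chains <- list(spliced(1), spliced(2), spliced(3))
  ev <- events_in_sample(chains, tmpl4, "+")
  expect_length(ev, 3)
  expect_true(all(grepl("^intron_retention", ev)))
})

test_that("classification is symmetric in the two chains", {
  for (seed in 1:20) {
    g <- random_toy_gene(seed)
    ch <- g$chains
    for (i in seq_along(ch)) {
      for (j in seq_along(ch)) {
        expect_setequal(
          classify_event_pair(ch[[i]], ch[[j]], g$template, g$strand)$signature,
          classify_event_pair(ch[[j]], ch[[i]], g$template, g$strand)$signature
        )
      }
    }
  }
})

test_that("adding an EST to a sample never removes events", {
  for (seed in 21:40) {
    g <- random_toy_gene(seed)
    if (length(g$chains) < 3) next
    base <- g$chains[-length(g$chains)]
    ev1 <- events_in_sample(base, g$template, g$strand)
    ev2 <- events_in_sample(g$chains, g$template, g$strand)
    expect_true(all(ev1 %in% ev2))
  }
})

test_that("mirroring coordinates and flipping strand swaps donor and acceptor only", {
  mirror_chain <- function(ch, C) {
    blocks_bounds <- c(ch$start, t(ch$introns), ch$end)
    m <- matrix(blocks_bounds, ncol = 2, byrow = TRUE)
    mirrored <- cbind(C - m[, 2], C - m[, 1])
    mirrored <- mirrored[order(mirrored[, 1]), , drop = FALSE]
    intron_chain(mirrored, min_intron = 1)
  }
  C <- 10000
  for (seed in 41:55) {
    g <- random_toy_gene(seed)
    tmpl_m <- cbind(C - g$template[, 2], C - g$template[, 1])
    tmpl_m <- tmpl_m[order(tmpl_m[, 1]), , drop = FALSE]
    flip <- function(s) if (s == "+") "-" else "+"
    ev <- events_in_sample(g$chains, g$template, g$strand)
    ev_m <- events_in_sample(lapply(g$chains, mirror_chain, C = C),
                             tmpl_m, flip(g$strand))
    kind <- sort(sub("\\|.*", "", ev))
    kind_m <- sort(sub("\\|.*", "", ev_m))
    expect_equal(kind, kind_m)
  }
})

test_that("pairwise detector agrees exactly with the base-level brute-force oracle", {
  for (seed in 101:160) {
    g <- random_toy_gene(seed)
    got <- sort(events_in_sample(g$chains, g$template, g$strand))
    want <- sort(oracle_events_sample(g$chains, g$template, g$strand))
    expect_identical(got, want)
  }
})
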