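---
title: "Coverage-corrected splicing indices: models, choices, validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-corrected splicing indices: models, choices, validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicedex)
```

## The measurement problem

Detection of alternative-splicing events from partial transcript
evidence (ESTs, or any shallow cDNA sequencing) is an occupancy
process: each additional transcript is another draw from the gene's
isoform distribution, and another chance to observe a splice difference
against the transcripts already seen. Raw per-gene event counts
therefore increase with sequencing depth without bound, and differences
between genes — or between whole species, whose archives differ by
orders of magnitude — conflate biology with effort.

`splicedex` scores every gene from the same amount of evidence. For a
gene with strictly more than `sample_size` ESTs, it draws `n_samples`
uniform random samples of exactly `sample_size` ESTs without
replacement, counts the distinct events within each sample, and reports
the across-sample mean. Defaults are 100 samples of 10 ESTs: 10 is
large enough that a sample of a gene with two well-expressed isoforms
almost always contains both (the miss probability for a 50/50 gene is
$2 \cdot 0.5^{10} \approx 0.002$), and small enough that most genes in
a typical EST study clear the eligibility bar. The eligibility rule is
strict (`> 10`, not `>= 10`): a gene with exactly 10 ESTs would have a
single possible sample and no averaging.

A gene is classified alternatively spliced when its index is at least
1.0 (boundary inclusive). The across-sample *mean* is the quantity
thresholded; a stricter variant requiring at least one event in *every*
sample is available (`asp_rule = "min"`) because the phrase "an average
of one event in each sample" admits both readings — we consider the
mean reading the natural one, with the switch provided for sensitivity
analysis. Species-level ASP is the fraction of indexed genes classified
spliced; ASL is the mean index. Species with fewer than 500 indexed
genes are flagged not comparable: ASP is a proportion whose sampling
error at a few hundred genes would rival the between-species
differences of interest.

## Event detection

Each spliced alignment is reduced to an intron chain: gaps of at least
`min_intron` bases (default 40, below the length of essentially any
spliceosomal intron) between aligned blocks are introns; smaller gaps
are treated as alignment indels and fused. A chain is then fully
described by its span and its introns, and its exonic coverage is span
minus introns.

Events are detected pairwise within the *shared genomic span* of two
chains, so a short EST is never penalised for what it does not cover:

* **exon skipping** — an intron of one chain fully contains a template
  exon that is an internal exon of the other chain (introns on both
  sides, within the outer intron), with both chains exonic immediately
  outside the outer intron. Signature: (skipped exon, outer intron).
* **alternative donor / acceptor** — two introns sharing exactly one
  boundary; the varying boundary, interpreted on the gene's annotated
  strand, names the type.
* **intron retention** — an intron of one chain covered exonically by
  the other with at least `flank` bases (default 10) of exonic
  coverage on both sides; the flank guards against terminal alignment
  slop mimicking retention.
* **complex** — overlapping intron pairs sharing no boundary.

Signatures are canonical coordinate tuples, symmetric in the two
chains, and deduplicated across all pairs of a sample, so an event
supported by many ESTs counts once. One precedence rule is imposed: the
two sub-introns flanking a skipped exon also technically share single
boundaries with the outer skipping intron, and would otherwise be
re-reported as a donor and an acceptor event; intron pairs nested
inside an outer intron that produced a skipping event in the same chain
pair are suppressed. Without this rule a single cassette difference
would count as three events.

Detection is purely pairwise within samples rather than against a
per-species reference transcript. This keeps the index self-contained
and recomputable for any 10-EST sample — the property the subsampling
correction requires — at the cost of conflating reference choice: a
sample containing only the two minor isoforms of a gene still counts
their differences.

The per-gene **exon template** pools annotated exons with all EST
blocks and merges overlapping intervals. A merged exon supported only
by unspliced ESTs, overlapping no annotated exon and lying strictly
inside an annotated intron is discarded as an orphan — the typical
signature of a nested, independently transcribed gene — and ESTs whose
every block falls in discarded orphans are excluded from sampling.
Non-annotated surviving exons are flagged novel.

## Input conventions

All coordinates are 0-based half-open internally; GFF3 is converted on
read. PSL identity is computed as
`matches / (matches + misMatches + qBaseInsert)` — the stated filter is
simply "95% identity", so the denominator is fixed here and the
threshold (`min_identity = 0.95`, inclusive) configurable. ESTs are
assigned to the gene whose span contains the largest fraction of their
aligned bases when that fraction is at least 0.5; ties are left
unassigned. Strand is not used for assignment (EST orientation is often
unknown); event typing later uses the gene's annotated strand. Library
exclusion (e.g. tumour-derived libraries whose aberrant splicing would
inflate indices) is a plain identifier list.

## Comparative statistics

The cross-species layer works on a species-by-variable trait table and
an ultrametric tree. Adjusted r² is the reported regression statistic
throughout (it can be negative for uninformative predictors, which is
informative in itself); p-values are two-sided slope t-tests; analyses
are complete-case; no multiple-testing correction is applied.

**PGLS with Pagel's λ.** The error covariance is the Brownian-motion
matrix of the tree (entries = MRCA depths) with off-diagonals scaled by
λ and the diagonal unchanged. λ is estimated by maximising the
restricted log-likelihood with `optimize()` over [0, 1] at tolerance
1e-6, with the endpoints evaluated explicitly so boundary maxima are
never missed; an unconstrained optimum below 0 is clipped to and
reported as 0. Restricted (rather than full) likelihood removes the
downward bias of the variance estimate under the two-parameter mean
model. The GLS analogue of r² compares the fit against the
GLS intercept-only model under the same covariance. At λ = 0 on an
ultrametric tree the model provably collapses to OLS, which is both a
test invariant and a useful sanity check on real data.

**Stepwise AIC** is forward-only from the intercept model, adding the
candidate that most lowers AIC and stopping when none does — the final
model is locally AIC-optimal by construction. **PCA** is on the
correlation matrix (the trait sets mix counts, lengths and
percentages), with the sign convention that each component's
largest-magnitude loading is positive. **Partial Spearman** rank-
transforms (average ranks on ties) and applies the first-order partial
correlation formula, with p from the t approximation on n − 3 degrees
of freedom; an equivalent residual-of-ranks construction is used as an
independent check in the tests. **EST-number correction** replaces a
trait by the residuals of its OLS regression on (E, E²) — or ln E —
capturing the empirical, saturating relationship between archive size
and apparent trait values. **CTN averaging** takes (min + max)/2 over
available estimates per species, with an order-level averaging variant
for robustness to unevenly studied species.

## What the simulator emulates — and what it does not

The generator produces non-overlapping multi-exon genes (defaults: 4–10
exons of 80–300 bp, introns 200–2000 bp) with 1–4 isoforms built from a
reference by skipping internal exons or retaining an intron, so every
isoform pair implies a known truth event set computed with the
package's own exhaustive pairwise classifier (and cross-checked in the
tests against an independent base-level enumerator). EST libraries
emulate the features that make coverage correction necessary:
per-gene expression weights are log-normal with σ = 1.5, giving EST
totals spanning two or more orders of magnitude; reads are single-pass
partial transcripts (Beta(2, 2) covered fraction, 30% anchored at the
3' end, as poly-A-primed ESTs are); alignment identity is
0.8 + 0.2·Beta(8, 1), leaving roughly 10% of ESTs below the 95%
retention threshold. Species trees are pure-birth (Yule) topologies
rescaled to a fixed root-to-tip depth of 1400 My; traits evolve as
λ-scaled Brownian motion.

The simulator does not model nucleotide sequence, alignment error
structure beyond a scalar identity, paralogy/multi-mapping, unannotated
genes, or isoform abundance differences across tissues. Passing the
validation suite therefore demonstrates correctness of the index and
statistics under the stated generative assumptions, not robustness to
misalignment or annotation error in real archives.

## Validation designs and their rationale

The validation experiments are fixed designs, chosen from the binomial
and hypergeometric arithmetic below before measurement, and shared
verbatim between the test suite and `scripts/acceptance.R`. Problem
sizes (500 genes, 200 λ replicates, 200 stepwise simulations, 1000
oracle genes) keep each experiment in the seconds-to-minutes range on
one CPU.

**Coverage-bias correction** (`validate_coverage_bias`): 500 six-exon
genes, full-length ESTs so pool size is the only variable; 80% of genes
have two isoforms with minor frequency U(0.40, 0.50); every fifth gene
adds a rare isoform at frequency 0.004 skipping a *non-adjacent* exon.
Non-adjacency matters: adjacent cassette differences between two
derived isoforms create composite donor/acceptor/complex signatures
whose coupled detection probabilities blur the designed one-event-per-
pair structure. The rare isoform is absent from a 20-EST pool with
probability 0.996²⁰ ≈ 0.92 — driving the naive all-EST count strictly
higher at 2000 ESTs for most rare-isoform genes — while contributing
only ≈ 1 − 0.996¹⁰ ≈ 0.04 to the subsampled index, keeping the index
pool-invariant (|Δ| < 0.1) for well over 95% of genes.

**Analytic check** (`validate_analytic_index`): a 50/50 two-isoform
gene with one event has expected per-sample count
1 − 2·(0.5)¹⁰ = 0.99805; the measured index from a 1000-EST pool must
sit within ±0.05.

**λ recovery** (`validate_lambda_recovery`): traits simulated at
λ ∈ {0, 0.5, 1} on 100-tip Yule trees, 200 replicates each, re-estimated
by REML. The boundary cases recover almost exactly; at λ = 0.5 the REML
sampling standard deviation at n = 100 is ≈ 0.13, so the aggregate mean
absolute error (≈ 0.05–0.07) is the meaningful summary. Yule rather
than coalescent topologies: coalescent trees concentrate almost all
divergences near the present, which genuinely starves λ of information
and roughly doubles the intermediate-λ error.

**End-to-end recovery** (`validate_recovery`): 500 genes at ≈ 270
post-filter full-length ESTs each; 70% have three isoforms skipping two
non-adjacent exons (two true events), 30% are single-isoform. One
subtlety is documented rather than hidden: *exact* equality of the
subsampled index with the true event count is impossible in principle,
because a 10-EST sample from even a perfectly balanced two-isoform gene
is monomorphic with probability ≈ 0.002, so the index converges to
≈ 0.998 × truth, not truth. Recovery is therefore defined as (a) exact
equality of the all-EST event enumeration with the truth set and
(b) the rounded index equalling the true count; measured ASP equals the
truth-table ASP exactly (the multi-isoform genes carry two events, so
classification never sits at the detection-probability boundary), and
ASL comes out ≈ 2–3% below truth, within the 5% band asserted.

## Numerical and degenerate-input behaviour

Interval arithmetic is exact (integer-valued doubles). The REML
objective returns a large finite penalty instead of −∞ for
non-positive-definite covariances, keeping the scalar optimisation
well-behaved on trees with near-zero branches. Per-gene sampling uses
an RNG stream derived from (global seed, gene id) via an exact 31-bit
string hash, so results are independent of gene processing order and
reproducible EST-for-EST. Degenerate inputs fail loudly: constant
predictors, unknown tree tips, genes with neither annotation nor
alignments, non-positive EST counts under the log correction,
rank-collinear partial-correlation controls. An EST pool at or below
the sample size marks the gene ineligible rather than erroring, and an
identity threshold that removes every EST yields empty, well-formed
outputs.

## Limitations

The index inherits the granularity of its inputs: events in regions no
sampled EST pair covers are invisible, and the 10-EST sample size caps
sensitivity for isoforms below ≈ 5% frequency (by design — that is the
price of comparability). Mutually exclusive exons are subsumed under
`complex` rather than typed separately. The pipeline consumes
alignments; it does not audit them, so systematic aligner artefacts
(e.g. spurious small introns) pass through, mitigated only by the
identity filter and the intron-length threshold.
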