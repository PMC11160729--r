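---
title: "Models and methods behind meioscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind meioscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meioscreen)
```

# The problem

Inducing meiosis from human pluripotent stem cells requires finding which
regulatory factors, delivered as a pooled barcoded overexpression library,
push differentiating cells into the meiotic program. The experimental
readouts are (i) bulk barcode sequencing of sorted reporter-positive versus
unsorted populations, (ii) single-cell RNA-seq with hybridization capture of
the expressed barcodes, (iii) plate-based combinatorial screens scored by
the fraction of reporter-positive cells, and (iv) immunofluorescence
timecourses of meiotic prophase stages. `meioscreen` implements the
computations on top of these readouts, plus a ground-truth synthetic-data
generator that emulates all of them so every analysis can be validated
end to end.

# The synthetic-data generator

`simulate_count_matrix()` draws UMI counts from a negative binomial with a
common dispersion, the standard count model for droplet scRNA-seq. Gene base
means are log-normal (meanlog 0, sdlog 1, i.e. a median of one UMI per
cell). Cells occupy one of four states — `pluripotent`, `oogonia_like`,
`meiotic_early`, `meiotic_late` — with configurable proportions; the
defaults (38/60/1.5/0.5%) describe a culture in which most cells are
oogonia-like and a small minority has entered meiosis. Meiotic cells raise
the log-mean of the 19 panel genes by `panel_mean_shift`; in addition each
state raises its own disjoint block of `n_state_markers` (default 30)
marker genes by the same shift, so all four states are mutually
distinguishable by a classifier — without such signatures, 4-state
annotation would be ill-posed by construction.

Two defaults deserve justification. The dispersion default is 0.1
(inverse size 10) and the default gene count is 2000. The panel score's
Gaussian null (below) is an approximation whose accuracy degrades with
(a) per-gene skewness, which grows with dispersion, and (b) the
compositional negative correlation that per-cell depth normalization
induces between genes, which shrinks roughly like 1/`n_genes`. The defaults
are chosen inside the regime where the approximation is accurate — well
measured genes, a few thousand of them — which is also the regime the
score is meant for; the permutation oracle exists precisely to check the
approximation on any given dataset.

`simulate_factor_integrations()` gives each cell Poisson(`lambda`)
integrations assigned uniformly over the library. This is implemented by
thinning: each factor's copy count is an independent
Poisson(`lambda`/`n_factors`), which is mathematically identical and yields
the closed-form coverage
`1 - (1 - q e)^F` with `q = 1 - exp(-lambda/F)` used by
`solve_capture_efficiency()`. The true distribution of copies per cell in
a pooled transposon delivery is rarely known (it varies between low-copy
and high-copy integration protocols); Poisson is our modeling choice,
stated as such. Meiotic entry is
Bernoulli with probability `plogis(baseline + sum of distinct-factor
effects)` — additive on the logit scale, matching the logit-linear model
used for the factorial analysis, with baseline `qlogis(0.01)`.

`simulate_capture()` observes each true (cell, factor) pair with the
configured efficiency and gives observed pairs a UMI count of at least 1.
`simulate_screen_wells()` generates reporter fractions as
`plogis(intercept + design %*% effects/2 + block + noise)`, so a factor's
true effect equals the difference of mean logit response between its +1 and
-1 runs. `simulate_timecourse()` produces stage counts that are exactly
zero before each stage's onset day (defaults: leptotene 6, zygotene 9,
pachytene 12) and Poisson with a linearly rising mean afterwards
(onset-day mean 5), on top of a total-cell growth curve rising ~8-fold over
the first seven days and then plateauing.

Every generator derives its RNG stream from `seed` plus a fixed
per-operation offset, so outputs are byte-identical given a config and
adding a new operation never perturbs existing draws.

What the generator does **not** emulate: doublets, ambient RNA, PCR
amplification bias, batch effects between cell lines, UMI collapsing
errors, or cell-type-specific library sizes beyond the marker shifts.
Passing tests on synthetic data therefore demonstrate the correctness and
calibration of the statistics under the stated model, not robustness to
every artifact of real data.

# Bulk barcode enrichment

`extract_barcodes()` accepts a read only when both constant flanks match
exactly at their offsets; the intervening barcode may carry at most one
substitution. Whitelists are generated (and checked at load) with pairwise
Hamming distance at least 3, which makes the radius-1 correction ball of
each barcode unambiguous; reads within distance 1 of two entries (possible
only for a degraded whitelist) are discarded as `multi_match` rather than
fractionally assigned, keeping the accounting exact.

`enrich()` adds a pseudocount (default 0.5, the Haldane–Anscombe
convention) to each count,
renormalizes to frequencies within each sample, and reports
`log2(freq_sorted / freq_unsorted)` for every (sorted, unsorted) pair.
`rank_consistent()` orders factors by the fraction of pairs with positive
enrichment, then mean enrichment, then name. This sign-consistency-first
rule is this package's operationalization of consistent enrichment across
replicate conditions; it is a documented design choice, and screens with an
in-house ranking rule can rank the per-pair table themselves.

# The meiosis gene score and its null

For a panel of k genes the score of a cell is

$$ s_i = \frac{1}{\sqrt{k}} \sum_{g \in \text{panel}} z_{ig}, $$

where \(z_{ig}\) is the across-cell z-score of depth-normalized
(counts × 10⁴ / cell total), log1p-transformed expression. This form is
chosen so that under independent null genes the score has mean 0 and
variance 1, giving "σ" its standard-normal meaning and making the
expected-count arithmetic exact: with 646,493 cells and a 4σ threshold,
`expected_exceedances(646493, 4)` gives 20.47 ≈ 20 expected cells under
random gene expression. A σ threshold could alternatively be measured
against the empirical score SD, which true meiotic cells inflate; the
empirical SD is reported alongside, and the calling threshold applies to
the theoretical unit.

Numerical conventions: zero-variance genes contribute 0 (no NaN, and a
conservative choice); cells with zero totals score via z-scores of zeros;
the per-gene SD is the sample SD. Because totals include all genes,
perturbing a non-panel gene *can* move panel scores through the
normalization — scores are exactly invariant only to total-preserving
changes of non-panel genes, and the test suite checks that form of the
invariance.

`permutation_null()` redraws random panels from the expressed genes and
reports the empirical exceedance fraction with a binomial CI. On null
synthetic data it agrees with the Gaussian survival function at 1σ–3σ
within Monte-Carlo error (problem size used: 500 cells × 2000 genes ×
200 panels, chosen to keep the whole check under a few seconds); on real
data with many lowly expressed, overdispersed genes the permutation tail
is the more trustworthy of the two, which is why both are exposed.

# Factor assignment and overrepresentation

`assign_barcodes()` assigns a factor to a cell when its captured UMI
support reaches `min_umi` (default 1, matching "at least one expressed
barcode"). Cells with no assignment are excluded from the
meiotic-vs-pre-meiotic contrast — they carry no information about factor
content. Each factor's 2×2 table is tested with the two-sided exact
conditional test (sum of hypergeometric point probabilities not exceeding
the observed one); the exact test is preferred over chi-square because
meiotic cells are rare (~1% of cells), making small expected counts
routine. Odds ratios use the Haldane 0.5 correction only when a table cell
is zero. Benjamini–Hochberg correction runs across factors (a single
contrast, no hierarchy), and ranking is by q, then odds ratio, then name.
The calibration test confirms the test's type-I error sits at the nominal
5% (slightly conservative, as exact conditional tests are) on balanced
null simulations.

# Factorial analysis

`make_design()` builds regular two-level designs. The built-in generators
are F = ABCD, G = ABDE for the 32-run quarter fraction of 7 factors and
E = ABC, F = BCD, G = ACD for the 16-run eighth fraction — both resolution
IV, so main effects are aliased only with three-factor (or higher)
interactions. When a screen's own generator choice is unknown these
defaults stand in, and they are printed with the design for
reproducibility. Other
single-generator fractions use the product of all base factors, and
remaining cases are searched exhaustively for maximal resolution with a
deterministic tie-break. Generators that alias two main effects are
rejected (`aliased_design`).

Responses are logit-transformed after clipping to
`[epsilon, 1 - epsilon]`; `epsilon` defaults to `1/(2 n_cells)` per well
when cell counts are available (half a cell's worth of probability), else
0.005. Effects are estimated by OLS of the logits on the ±1 columns plus
additive cell-line block effects (sum-coded), with the effect reported as
twice the coefficient so that it equals the +1 vs −1 group-mean difference;
p-values come from the t distribution on the residual df. Only main
effects are modeled: in a quarter fraction, two-factor interactions are
aliased with each other, so fitting them would be misleading. With exactly
as many rows as parameters the fit is returned with SE and p flagged
unavailable; with fewer rows the call errors (`insufficient_df`).

# Annotation and timecourses

Atlas-projection pipelines for comparing induced cells to a combined
fetal-ovary / adult-testis reference are typically elaborate and
stochastic. Because this package's goal is the downstream proportion and
onset machinery, label transfer is deliberately simple and deterministic: per-type centroids of
log-normalized reference expression, nearest centroid by Pearson
correlation (or cosine) over the gene intersection, ties broken by type
name, all-zero cells assigned similarity 0. Fewer than 200 shared genes
triggers a warning. This is a stand-in for full atlas integration, not a
re-implementation of any particular projection pipeline.

`proportion_table()` splits types at a strict `> 5%` overall mean
proportion — the cutoff is strict, so a type at exactly 5% lands in the
rare table. `detect_onset()` returns the first day
on which at least `min_cells` cells are seen in at least `min_replicates`
lines; it is monotone in both thresholds by construction.

# Problem sizes and budgets

The validation suite uses 20,000 cells for score calling and factor
ranking, 500 × 2000 for the permutation-vs-Gaussian check, 500 null
factorial screens, and 20 seeds for the ranking/onset recovery rates —
sizes at which every Monte-Carlo tolerance in the tests is meaningful
while the full suite stays under a minute of compute.

# Known limitations

* The default 19-gene panel anchors on five canonical staging markers
  (REC8, SYCP3, HORMAD1, TEX12, MSH4) padded with fourteen further
  canonical meiosis genes; a lab's own panel can be supplied as a file.
* The enrichment ranking rule and the overrepresentation statistic are
  this package's own documented choices; other reasonable statistics exist
  and can be run on the exported tables.
* The generator's meiotic-entry model is additive on the logit scale with
  no factor interactions or copy-number dosage; the assignment tests
  cannot detect failures specific to interacting factors.
* Nearest-centroid transfer ignores batch structure; with real
  cross-platform references a dedicated integration method should replace
  it upstream, keeping the proportion/onset machinery unchanged.
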