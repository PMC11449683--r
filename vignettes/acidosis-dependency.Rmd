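---
title: "Scoring tumor acidosis dependency: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring tumor acidosis dependency: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acidep)
```

## The question and the model

Tumor extracellular pH (pHe) is chronically acidic and spatially
heterogeneous: cells experience anything from mild (~pHe 6.8) to
severe (< pHe 6.5) acidosis and respond transcriptionally to the
degree of acidity. `acidep` formalizes a pipeline that turns that
response into a per-tumor-type *acidosis dependency score*:

1. measure which genes an acidic challenge induces or reduces,
   relative to a physiological-pH control;
2. partition those genes by which degree of acidosis drives them
   (mild only, severe only, or both);
3. ask whether the acid-responsive genes look like known
   progression signatures (contingency and rank concordance against
   external high/low classifications);
4. score each tumor type by how often its top acid-induced genes are
   unfavorable prognostic markers and its top acid-reduced genes
   favorable ones ("hits"), and type the tumor by which role
   dominates.

The chain of assumptions is deliberately simple and worth stating:
expression is treated as log-normal around a per-gene baseline;
differential expression is a *fold-change rule*, not a
moderated-variance model; prognosis enters as a categorical database
annotation (direction + significance), not as patient-level survival
data; and the mapping from a mouse acidosis experiment to human
tumors rides on gene symbols, not on measured orthology of response.

## Differential expression

**Fold change.** With replicate groups on a linear intensity scale,
the fold change of gene $g$ in condition $c$ against control $0$ is
the geometric-mean ratio

$$\mathrm{FC}(g,c) = 2^{\overline{\log_2 x}_{g,c} - \overline{\log_2 x}_{g,0}},$$

i.e. the arithmetic mean taken on the log2 scale and back-transformed.
Two-color arrays are ratio data and the volcano axes are log2 units,
so the geometric mean is the natural estimator; the arithmetic-mean
ratio is kept behind `method = "arithmetic"` for sensitivity
analysis. Linear intensities are floored at `floor_eps` (default 1.0)
before the log transform; the floor count is surfaced as a warning so
silent zero-handling cannot skew ratios unnoticed.

**Testing.** `per_gene_test()` is the two-sided pooled-variance
Student's t-test per gene ($df = n_1 + n_2 - 2$), vectorized across
genes; Welch's form is available via `var_equal = FALSE`, and a
Bonferroni column (factor = number of genes tested) via
`bonferroni = TRUE`. The default is uncorrected per-gene p-values,
matching the raw-p volcano convention. Degenerate genes — zero
variance in both groups — get $p = 1$ (equal means) or $p = 0$
(unequal), flagged in a `degenerate` column rather than producing
`NaN`. On a 10,000-gene null simulation with 4 vs 4 replicates the
test suite checks the empirical type-I error is 0.05 ± 0.01.

**Selection.** "Two-fold or more" means $\mathrm{FC} \ge \theta$ and
"two-fold or less" means $\mathrm{FC} \le 1/\theta$ — boundaries
included. Whether the original selection additionally required test
significance is not documented for this kind of contractor-processed
data; the default here is fold-change-only selection, with p-values
carried alongside for the volcano and for tie-breaking.

**Top-N ranking.** Ties in $|\log_2 \mathrm{FC}|$ are broken by
smaller p-value, then lexicographic gene symbol. The rule is
arbitrary but deterministic, which matters more: the hit score is
computed over exactly the top-$N$ (default 100) genes per role, so an
unstable sort would make the headline score irreproducible. The
pipeline ranks on one condition (`rank_condition`, defaulting to the
last, most severe test condition); ranking on the mild condition or
on a combined statistic is a caller decision, not a hidden default.

## Venn partitioning

`venn_partition()` is exact set algebra over two same-direction,
same-threshold gene sets, returning A-only / common / B-only members
and counts. Its invariants (regions disjoint, union conserved) are
fuzz-tested against naive membership classification. The generator's
default planted structure — 25/85/131 genes up at mild only / both /
severe only and 63/118/82 down — reproduces the canonical four-fold
partition shape of this study design, and the noiseless round trip
through fold-change selection recovers it exactly.

## Signature comparison

**Contingency.** The 2×2 table crosses the external signature's
high/low classes with the acid-up/down sets; genes the signature does
not classify, and classified genes that are not modulated, contribute
nothing. The test is Pearson's chi-squared without continuity
correction (df = 1), the common choice at these table sizes; Yates'
correction is switchable. Zero-margin tables return a degenerate flag
instead of erroring, since simulated null configurations legitimately
produce them. The implementation is `stats::chisq.test()` behind the
module surface; the test suite verifies it exhaustively against the
closed form $\chi^2 = N(ad-bc)^2/((a{+}b)(c{+}d)(a{+}c)(b{+}d))$ on
all tables with margins ≤ 20.

A note on the shipped published counts
(`published_contingency_tests()`): the Mets-vs-primary blocks give
$\chi^2 \approx 0.26$ and $0.10$ ($p \approx 0.61$ and $0.75$) under
the standard uncorrected test — *not* significant, although the
source table annotates every block "< 0.05". The package reports what
the standard test computes for the printed counts and does not force
agreement; how those annotations were derived (or how the high/low
classes were thresholded) is not documented in the source.

**Ortholog mapping.** A user-supplied two-column table is the
default; when none is given, the uppercase heuristic
(`Mmp9 → MMP9`) is applied as a documented fallback. It is a symbol
convention, not curated orthology — fine for benchmarking, to be
replaced with a real ortholog table for serious cross-species use.
Unmapped genes are always reported, never silently dropped.

**Rank concordance.** Spearman's $\rho$ between the external
signature's descending-expression ordering and the descending
fold-change ordering, over shared genes (≥ 3 required), with a
two-sided permutation p-value ((1 + exceedances)/(permutations + 1),
default 1,000 shuffles, seeded). $\rho = 1$ for identical orderings,
$-1$ for exact reversal, and the statistic is antisymmetric under
reversal — all asserted in tests, along with null calibration on
independent orderings.

## Hit scoring

A gene's annotation in a tumor type is a direction
(unfavorable / favorable / none), a significance flag, and an
optional effect magnitude — the Protein-Atlas-style categorical
reading of survival association. The operational definitions:

- **strict hit**: induced ∧ unfavorable ∧ significant, or
  reduced ∧ favorable ∧ significant;
- **inverted (tolerant) hit**: the *opposite* direction,
  significant, with magnitude ≤ `tol` (default 0.20).

The "reversal within 20%" rule needs a metric, and the source of this
design never defines one. The package therefore treats the magnitude
as whatever effect-distance-from-neutrality the annotation table
encodes (|HR − 1|, a survival-difference fraction, ...) and exposes
the comparison as a pluggable `predicate`; the default is the plain
`magnitude <= tol` threshold. Tolerant tallies are non-decreasing in
`tol` and collapse to the strict tallies at `tol = 0` whenever
magnitudes are positive — both property-tested.

Missing (gene, tumor) annotations count as non-hits but are tallied
separately (`n_missing`, and `missing` cells in the hit matrix) so
database coverage bias stays visible rather than deflating scores
silently. Dominance typing uses a strict majority of strict hits by
default (`dominance_margin = 0`, configurable): more induced hits →
`induced_type`, more reduced → `reduced_type`, else `balanced`.
Per-gene hit rates use the full evaluated tumor panel as the
denominator, and the stage-concordance follow-up keeps genes with
rate ≥ `hit_rate_min` (default 0.5). Stage concordance itself counts,
per gene, tumor types where the stage trend significantly matches the
gene's role (induced → higher in late stage, reduced → lower).

## The synthetic-data generator

`simulate_expression()` draws per-gene log2 baselines from
$N(\mu_b, \sigma_b^2)$ (defaults 8 and 2) and adds the planted class
effect (±`effect_log2`, default 2.0 = four-fold) plus replicate noise
$N(0, \sigma^2)$, with `noise_sd_log2 = 0.25` as the default — a
typical replicate spread for two-color array log-ratios. The design
defaults are the emulated study's: three conditions
(pH 7.4 control, 6.8, 5.9), quadruplicates, and the planted Venn
structure above. Effects are additive in log2, i.e. multiplicative
on intensities. One master seed drives derived per-component
substreams (baseline, class assignment, noise, each annotation
table), so partial re-runs are stable and whole runs are
reproducible bit-for-bit.

Note one deliberate property of the defaults: the planted effect
(log2 = 2.0) sits exactly on the four-fold selection boundary, so
*at any positive noise level* each planted gene clears θ = 4 with
probability near one half. Exact partition recovery is therefore a
noiseless identity (and is tested as such); recovery under noise is
tested at θ = 2, where the one-log2-unit margin makes misses
vanishingly rare (the group-mean difference has sd
$\sigma\sqrt{2/n}$ ≈ 0.07 at defaults).

`simulate_prognostic_annotations()` plants a per-tumor concordance
probability `q`: each present (gene, tumor) entry is concordant and
significant with probability `q`, otherwise a significant reversal
(probability `inversion_fraction`, default 0.3, with magnitude drawn
from `magnitude_law`, default uniform on [0, 0.4]) or a
non-significant `none`. `missing_rate` (default 0) drops entries
entirely. The strict hit count over $n$ list genes is then
Binomial$(n, q)$, which the tests exploit: recovery of
$q \in \{0.2, 0.5, 0.8\}$ is asserted within exact binomial 99%
intervals over 100 + 100 genes, and planted orderings must be
recovered by `rank_tumors()`. Stage annotations use the analogous
Bernoulli construction.

What the generator does *not* emulate: array spatial artifacts, dye
bias, probe cross-hybridization, correlated genes or pathway
structure, annotation errors correlated across tumor types, and any
real relationship between expression effect size and prognosis.
Passing tests therefore demonstrate that the pipeline's bookkeeping
and statistics are correct under the stated generative model — not
that the biological signal in real data behaves this way.

## Numerical choices

- **Boundary tolerance.** Fold-change thresholds are compared with a
  relative tolerance of 1e-9 (`fc >= θ(1 − 10^{-9})`), because
  ratios carried through log2 space can land one ulp below an exact
  boundary (a planted log2 effect of 2.0 must select at θ = 4). The
  tolerance is far below any biologically meaningful fold-change
  difference.
- **Flooring.** Linear values below `floor_eps = 1.0` are floored
  before log transform, with the count reported.
- **Volcano cap.** $-\log_{10} p$ is capped at 300 (about the double
  precision limit) for degenerate $p = 0$ entries.
- **Determinism.** All orderings have total tie-break chains; all
  stochastic stages take explicit seeds; pipeline summaries exclude
  timestamps so identical configs give byte-identical JSON.
- **Problem sizes.** The test suite runs desk-scale: 2,000-gene
  simulations for partition recovery, 10,000 genes for t-test
  calibration, 1,000 fuzz instances for set algebra, exhaustive
  chi-squared enumeration at margins ≤ 20, and 100 + 100-gene lists
  over three planted concordance levels. Full runs complete in well
  under a minute per stage on one CPU.

## Known limitations

- Input matrices are assumed pre-normalized; no background
  correction or within/between-array normalization is performed, and
  no vendor raw-file parsing is attempted. Whether published counts
  from such experiments are probe-level or gene-level is often
  undocumented, which limits exact external reproduction.
- The hit score inherits every bias of the annotation database it is
  fed: coverage gaps (visible via `n_missing`), tumor-type
  granularity, and the categorical flattening of survival evidence.
- Gene-symbol ortholog mapping is a stand-in for curated orthology.
- The inversion-tolerance metric is user-defined by construction;
  two annotation tables encoding different magnitude semantics are
  not comparable under the same `tol`.
- No enrichment analysis, survival-model fitting, or plot rendering:
  the outputs are tables, gene sets and JSON summaries by design.
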