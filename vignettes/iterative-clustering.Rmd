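---
title: "Finding differentially expressed genes as density outliers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding differentially expressed genes as density outliers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(declust)
```

## The model behind the method

`declust` treats differential expression between two strains as an
*outlier-detection* problem rather than a testing problem. The only
quantities the method ever clusters are four aggregates per gene, computed
on the log scale: the per-strain means (μ₁, μ₂) and the per-strain sample
standard deviations (σ₁, σ₂). The implicit model is geometric:

- genes expressed equally in both strains have μ₁ ≈ μ₂, so their points
  crowd into one dense, elongated cloud along the diagonal of the
  (μ₁, μ₂) plane;
- a gene whose mean expression is shifted between the strains leaves the
  diagonal by its log fold change and lands in a low-density region;
- a gene with equal means can still behave differently if its within-strain
  variability differs, which shows up as distance from the diagonal of the
  (σ₁, σ₂) plane instead.

DBSCAN suits this geometry because it makes no assumption about cluster
count or shape and returns *noise points* as first-class output — and the
noise points are precisely what we are after. Genes are clustered in equal
batches rather than all at once: with many thousands of equally expressed
genes, the whole-set density contrast between the cloud's fringe and a
moderately shifted gene is weak, while within a batch of a few hundred
genes the same shifted gene is clearly isolated. The pooled noise of all
batches is the call set.

Two labels distinguish provenance: −1 for mean-space noise, −2 for genes
that survived the mean stage inside a compact cluster but show
|σ₁ − σ₂| > Tstd. The std stage only ever sees genes the mean stage kept,
so no gene is called twice.

## Parameters that matter

All distance-like parameters live on the chosen log scale (default log2,
recorded in output headers).

- **r** (radius) and **Nmin** (minimum neighbors, *self included*): the
  DBSCAN density thresholds. Smaller r or larger Nmin produce more noise
  points, hence more calls; noise counts are monotone in both, which the
  test suite asserts as a property. There is no automatic selection — the
  method's own practice is hand tuning per data set, watching the number
  and placement of outliers.
- **distance metric**: Euclidean, cityblock, Chebyshev, Minkowski with any
  p > 0, or Mahalanobis. The equivalence cloud is oblong, not spherical,
  which motivates the Mahalanobis default for real data: whitening by the
  cloud's covariance stretches neighborhoods along the diagonal. Fractional
  Minkowski (p < 1) is supported since DBSCAN only needs a symmetric
  dissimilarity; its triangle-inequality failure is deliberate and tested.
- **Nb** (batch size, default 511): several hundred genes per batch is the
  regime where the method works; the last batch keeps the exact remainder
  (ceiling division — 9196 genes at Nb = 511 give 18 batches, the last of
  509 genes).
- **Tstd** (default 0.3): the σ-gap threshold of the second stage. Larger
  values select fewer genes, again monotonically. Step 5.2 can also run
  DBSCAN in (σ₁, σ₂) space (`std_stage_mode = "dbscan"`); the scalar
  threshold is the default because a single interpretable cut-off is what
  makes the stage tunable in practice.

## Design choices in ambiguous corners

Several conventions are underdetermined by the procedure itself and are
fixed here explicitly, because each one changes which genes surface:

- the DBSCAN neighborhood is a *closed* ball and *includes the point
  itself*, matching common implementations (so Nmin = 1 makes every point
  core);
- border points join the cluster of their *lowest-index* core neighbor,
  and cluster ids are renumbered by lowest member index — this makes the
  labeling a pure function of the distance matrix, independent of visit
  order, which is what enables exact oracle testing;
- genes are batched in input order by default; batch composition affects
  local density and hence results, so a seeded shuffle and a
  total-expression ordering are provided for sensitivity analysis, but the
  default is fully deterministic end to end (byte-identical call files on
  repeated runs);
- the standard deviation uses denominator n − 1; each strain must
  therefore contribute ≥ 2 samples;
- the Mahalanobis covariance is estimated per batch from the points being
  clustered (the cloud the radius must conform to is the batch's own), with
  a ridge of 1e−8 · tr(C)/2 so near-singular clouds never abort; a global
  mode exists for sensitivity analysis, and the std stage re-estimates its
  covariance from σ-space, never reusing the mean-space one;
- zero handling is removal, not offsetting: any gene with a zero count in
  any sample is dropped before the log transform. An optional pseudocount
  exists but defaults to off.

## What the synthetic generator emulates — and what it does not

`simulate_counts()` exists so every stage is testable against known truth
without any external download. It draws per-gene log2 baselines from
N(6, 1.25²), negative-binomial counts with dispersion φ = 0.1
(Var = μ + φμ²), 10 + 11 replicates, and plants three kinds of structure:
2.5% of genes with a |log2 FC| = 2 mean shift (random sign, applied to
strain 2), 1.5% with equal means but dispersion inflated 4× in one random
strain, and 5% forced to contain a zero. These defaults produce exactly
the geometry the method exploits — a diagonal cloud whose half-width is
set by the count noise at ~10 replicates, plus off-diagonal points — at a
scale (2000 genes, four 511-gene batches) where the full pipeline runs in
seconds. Accidental negative-binomial zeros are clamped to 1 so that the
planted "zeroed" class coincides exactly with what the zero filter
removes, keeping truth labels and filter behavior in lockstep.

The generator does *not* mimic real library-size variation, gene-gene
correlation, or a realistic fold-change spectrum: every planted mean shift
has the same magnitude. Passing recovery tests on this data therefore
shows that the pipeline finds isolated off-diagonal points under realistic
count noise — not that it would achieve the same sensitivity on any real
data set, where effect sizes grade continuously into the cloud.

The fixed effect size also exposes a genuine limitation of the method
worth knowing about: all planted mean-DE genes lie on two lines parallel
to the diagonal, and where the baseline density peaks, several of them can
fall within r of each other. With a small Nmin such a clique certifies
itself as a *compact cluster* and is missed — DBSCAN cannot tell an
off-diagonal cluster of truly DE genes from an equivalence cluster. The
tuned preset for this generator (`preset_synthetic()`: Euclidean, r = 0.4,
Nmin = 8, Tstd = 0.5) chooses Nmin above the size such cliques reach, so
no small group of shifted genes can self-certify; on real data the same
risk argues for inspecting the per-batch scatter plots rather than
trusting any single parameter set.

The σ-stage threshold in the preset sits where the null σ-gap noise says
it should: with ~10 replicates the sampling sd of a per-strain σ estimate
is roughly σ/√(2(n−1)) ≈ 0.16 log2 units, so null gaps |σ₁ − σ₂| scatter
with sd ≈ 0.22, and a cut at 0.5 keeps the null leakage small while the
4× dispersion inflation (gap ≈ 0.45 in expectation) is still caught for
most variance-shifted genes.

## Numerical notes

- Distance matrices are dense n × n; at batch sizes of ~500–1000 points
  this is far cheaper than any spatial index would be, and the DBSCAN scan
  is the plain O(n²) variant.
- Minkowski distances at large p approach Chebyshev with the exact
  two-sided bound max ≤ Dₚ ≤ max · 2^(1/p) in 2-D; at p = 64 the worst-case
  relative gap is 2^(1/64) − 1 ≈ 1.1%, attained when the two coordinate
  deltas are equal. The suite asserts this exact bound rather than
  pretending the limit has converged beyond it.
- Identity-covariance Mahalanobis is computed without ridge and matches
  Euclidean to 1e−9; per-batch covariance estimation requires ≥ 3 points
  and fails with a clear message on singular covariance when the ridge is
  explicitly zero.
- All clustering is deterministic; the only randomness anywhere is the
  generator's seed and the optional batch shuffle seed, both recorded.

## Validation suite sizes

The test and acceptance runs use problem sizes chosen to exercise every
code path while keeping a full run in well under a minute: random DBSCAN
instances up to 50 points against a brute-force union-find/components
reference, monotonicity sweeps over 20+ random data sets, and full
pipeline runs at 600–2000 genes. The study-scale batching arithmetic
(9196 genes) is checked exactly, as it costs nothing.

## Known limitations

- No library-size normalization or variance stabilization is applied —
  the method operates on raw log counts by design; strongly different
  sequencing depths between samples would shift the cloud off the
  diagonal and should be corrected before input.
- Calls are unranked: a gene is noise or it is not. Overlap reporting
  against statistical call lists (`compare_sets()`) is the intended way to
  contextualize a run.
- Batch composition influences results; the default input order makes
  runs reproducible but is still one arbitrary choice among many, which is
  why the shuffle mode exists for sensitivity analysis.
- Parameter selection is manual by design; the monotonicities in r, Nmin
  and Tstd are the navigation aids.
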