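---
title: "Ensemble-discord quality estimation: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble-discord quality estimation: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segqc)
```

## The model and its assumptions

`segqc` estimates segmentation quality for a cohort of cases, each
segmented by the same ensemble of `K` algorithms (or raters), without any
ground truth. The driving assumption is that **ensemble discord predicts
failure**: when a case is easy, independent algorithms produce similar
masks; when it is hard or out of distribution, they diverge, and each
member also diverges from the consensus. The method therefore:

1. fuses the candidates into a consensus mask,
2. measures each candidate's similarity to the consensus (volumetric Dice
   and Hausdorff distance, per evaluation class, class-mean reduced by
   default),
3. derives a robust threshold for each (algorithm, metric) series across
   the cohort: `median − α·MAD`,
4. flags cells strictly below their threshold (plus every `NaN`/infinite
   cell), and
5. sums flags into a per-case risk score used to rank cases for review.

Two structural assumptions follow directly. First, the method needs an
ensemble — with one candidate there is no discord to measure, and
`case_ensemble()` refuses to build. Second, discord must be *possible*: if
all members converge to the same mistakes (e.g. architecturally identical
networks trained identically), failures become invisible. The synthetic
module includes a zero-jitter regime that demonstrates exactly this blind
spot: all candidates collapse onto one mask and no alarm can fire.

The validity of the estimate is also tied to how well the chosen metrics
represent segmentation quality. Dice captures volumetric overlap and is
insensitive to spacing; Hausdorff captures worst-case boundary error in mm
and is dominated by single outlier components — which is precisely why it
complements Dice for alarm purposes (a small spurious blob far from the
lesion barely moves Dice but explodes Hausdorff).

## Thresholding: why median − α·MAD, and what α means

Mean/sd statistics are corrupted by the very outliers the method hunts, so
the location and spread are the median and the **unscaled** median
absolute deviation (no 1.4826 consistency factor — any fixed scaling would
just be absorbed into α). Metrics where lower is better are negated before
thresholding so one rule serves all metrics; thresholds are reported on
the native scale in the CSV outputs.

* At `α = 0` the threshold is the median: roughly half the cohort alarms
  per (algorithm, metric) — maximally sensitive screening.
* `α > 0` flags only stronger outliers (triage under heavy workload);
  `α < 0` pushes the threshold above the median until every cell alarms.
* Equality does not alarm: "below" is strict, so an exactly-median value
  is not an outlier.
* `NaN` and infinite cells always alarm, at any α, and are excluded from
  the median/MAD estimation — a single empty prediction must neither
  escape review nor poison the threshold for everyone else.

Thresholds are derived per (algorithm, metric[, class]) *across the
cohort*, i.e. one threshold per algorithm's metric series, so a
systematically weaker algorithm is compared against its own typical
behaviour rather than alarming on every case. A per-image "global
thresholding" variant is a conceivable alternative; it is deliberately not
implemented here.

α defaults to 0.1 (slightly less conservative than the median), is
addressable per (algorithm, class, metric) with a global fallback via
`alpha_config()`, and can be calibrated by `sweep_alpha()` /
`recommend_alpha()` using three objectives: maximal |r| against a
reference quality metric, maximal alarm-histogram entropy (the most
discriminative alarm distribution), or a rank-sum combination of both. How
such a combination "should" weigh its parts is genuinely open; the
rank-sum was chosen because it is scale-free in both arguments, and it is
config-exposed rather than hard-wired. Recommendation ties resolve toward
the smaller α — the more sensitive, conservative choice.

## Fusion

**Majority voting** is strict: a voxel is foreground only with more than
half the votes. Exact ties (even ensembles) default to background, the
conservative direction — an under-segmented fusion lowers candidate
agreement and produces *more* alarms, which is the safe failure mode for a
screening tool. Multi-label voting is per-voxel plurality over disjoint
evaluation classes; background wins any tie it is part of, and class-class
ties resolve by an explicit precedence order, so the result is
deterministic and invariant to candidate order.

**SIMPLE** starts from the majority vote and alternates performance
estimation (Dice against the current fusion), discarding of weak members,
and performance-weighted re-voting, until the retained set and fusion are
stable (cap: 25 iterations). The discard rule is
`performance < mean − f·sd` over the retained members. The factor defaults
to `f = 1`: for a sample of `n` values the largest possible deviation from
the mean is `sd·(n−1)/√n`, which is below `2·sd` for `n ≤ 5` — a factor of
2 therefore *cannot discard anything* from the 3–5 member ensembles this
tool targets, while `f = 1` removes a clear outlier (e.g. an
all-background member among four agreeing ones) in the first iteration.
With two or fewer retained members the spread estimate is degenerate and
discarding is skipped; if a discard step would empty the ensemble, the
plain majority vote of all members is returned with a warning. Inside
SIMPLE, a candidate that is empty when the fusion is also empty counts as
perfect agreement (the weighting needs a number and there is no discord);
in the *metric table* the same situation is `NaN` and alarms — different
questions, different conventions. SIMPLE on multi-label input runs per
class channel and recomposes by precedence; this is an extension with
stated semantics, not a claim of equivalence with any particular published
multi-label variant.

## Metrics: conventions for empty masks and distances

* Dice: both masks empty → `NaN`; exactly one empty → 0. `NaN` rather
  than a perfect score is an interpretive choice: an ensemble unanimously
  predicting "nothing" on a case carries no evidence that nothing is
  there, and the resulting alarm routes the case to a human.
* Hausdorff: classic 100th-percentile maximum over the two directed
  farthest-nearest-point distances between foreground voxel-center sets,
  with per-axis spacing in mm (so anisotropic grids are handled
  correctly); one empty mask → `+Inf`, both empty → `NaN`. An HD95-style
  percentile is available (`hausdorff(..., percentile = 95)`) but the
  pipeline default is the classic maximum, the variant with the simplest
  exact semantics.
* The implementation is an exact early-exit scan in C++; the test suite
  checks it for exact equality against an independent all-pairs
  brute-force oracle in R on hundreds of random anisotropic mask pairs.
* Class-mean reduction (the default) averages each (case, algorithm,
  metric) over evaluation classes with explicit propagation: any infinite
  class value dominates (`Inf`), else any `NaN` poisons (`NaN`). This
  gives one alarm opportunity per (algorithm, metric), i.e. a 10-alarm
  maximum for a 5-member, 2-metric ensemble; per-class alarming
  (`class_reduce = "none"`) triples the opportunities for 3 classes and is
  available but not the default.

## The synthetic cohort: what it emulates, and what it does not

The generator stands in for a clinical validation cohort. Its defaults are
the package's reference study conditions: **50 cases × 5 sources on 64³
grids, 1 mm isotropic**, one evaluation class. Each case gets a phantom of
1–4 ellipsoidal components (semi-axes 4–9 voxels, placed off the volume
boundary, ≥ 1 voxel apart) and a difficulty grade `λ ~ U(0,1)` shared by
all its candidates — hard images are hard for every algorithm, which is
what lets alarm counts correlate with per-case quality — plus per-source
Gaussian jitter (sd 0.1) so the ensemble still disagrees. Candidates are
corrupted with λ-scaled versions of the failure modes seen in real
ensembles: ball dilation/erosion of each component (radius up to 3 voxels
at λ = 1), component dropout (probability 0.3·λ), and Poisson-distributed
small spurious components (mean 2·λ). `λ = 0` reproduces the ground truth
exactly; `λ = 1` with full dropout exercises the empty-mask/infinite-
Hausdorff paths. Every stochastic step keys its RNG stream on
`(seed, case, source)`, so any single mask regenerates byte-identically in
isolation.

What the phantoms do **not** emulate: anatomy, intensity images,
registration error, correlated failure modes between algorithms, or
class-confusion errors (a candidate never relabels a structure). Passing
tests therefore demonstrate the *mechanics* of the pipeline — metric
correctness, threshold monotonicity, and that risk scores recover a
planted quality gradient (the suite requires Pearson r between risk score
and true fused-vs-truth Dice below −0.5 on the reference cohort) — not
clinical performance on real MR or CT data.

## Numerical and interface choices

* Grids are validated, never resampled: all members of a case must share
  shape and spacing. Masks are compared in voxel space; only spacing (not
  orientation) enters any metric, which is sufficient because all members
  of a case live on one grid.
* NIfTI label maps stored as floats are rounded when within `1e-3` of an
  integer, else rejected — silent truncation of a corrupt label map is
  worse than an error.
* Entropy is reported in nats (natural log); a one-bin histogram is
  exactly 0 and a uniform `K`-bin histogram exactly `ln K`.
* Correlations drop pairs with non-finite quality values (infinite
  Hausdorff carries no usable magnitude) and return `NA` below 3 valid
  pairs or under zero variance, rather than fabricating a number.
* Risk ranking breaks ties by case identifier, so triage lists are stable
  across reruns; every CLI run writes its effective configuration next to
  its outputs and regenerates byte-identical CSVs.
* Problem sizes in the shipped tests: the reference cohort (50 × 5, 64³)
  is built once and shared by the monotonicity and parameter-recovery
  checks; unit tests use 32³ cohorts with proportionally smaller
  components, and oracle checks use masks of at most a few dozen
  foreground voxels where all-pairs brute force is exact and cheap.

## Known limitations

* Ensembles only; single-model pipelines have no discord to measure.
* Shared blind spots: unanimity is indistinguishable from correctness.
* Cohort-relative thresholds need a cohort: with fewer than two finite
  values in a series the threshold is undefined and the package raises a
  "degenerate cohort" error instead of guessing.
* The quality estimate inherits the blind spots of Dice and Hausdorff
  (e.g. neither measures topology), and per-image thresholding, additional
  metrics, and transfer of a calibrated α across sites are out of scope.
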