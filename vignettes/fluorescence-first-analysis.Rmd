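---
title: "Fluorescence-first analysis of multiplex bead immunoassays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluorescence-first analysis of multiplex bead immunoassays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Multiplex bead immunoassays (Luminex xMAP and similar platforms) report a
median fluorescence intensity (MFI) per analyte per well. Standard practice
converts MFI to a concentration (pg/ml) through a five-parameter logistic
(5PL) standard curve and analyses concentrations. That conversion has hard
limits: fluorescence at or beyond the fitted curve's asymptotes has no
concentration image, and values outside the standards' span are at best
extrapolations. For low-abundance analytes — often the scientifically
interesting ones — much of the data is censored out of the concentration
analysis, and whole design cells can empty, making the analyte inestimable.

fluorplex implements the alternative this package is built around: run the
differential analysis directly on log2 MFI, where no record is censored, and
use the concentration mapping only where concentrations are genuinely needed.
The package provides the evidence tooling for that choice (limit-of-detection
diagnostics), the mapping itself (weighted 5PL fits with censoring
classification), the differential model (a single global linear mixed model
with Wald contrasts), a simulator that shows *why* the two scales disagree,
and a synthetic data generator that reproduces the structure of the
motivating 37-plex inflammation panel study (169 patients, 191 samples over
4 tissue types, 8 clinical conditions and 3 plates).

## The differential model

All responses (every analyte, tissue, condition) enter one linear mixed
model on the log2 scale:

```
log2(response) ~ analyte + tissue + condition
                 + analyte:tissue + analyte:condition
                 + (1 | plate:condition:tissue) + (1 | patient)
```

The *reduced* model omits `condition` and its interaction. The two crossed
random intercepts absorb, respectively, the association of tissues and
conditions with plates (14 such nonempty groups in the study design) and
patient-to-patient level shifts (including the paired plasma/serum samples
from the same patients). The three-way `analyte:tissue:condition` interaction
is deliberately excluded: the design is sparse and a saturated interaction
would overfit it.

Fitting is REML via `lme4::lmer` (the same machinery the field uses for this
model class); `fit_lmm()` wraps it and exposes the fixed effects, their
covariance, and the variance components. The package's own contribution is
the inference layer on top:

* `omnibus_factor_test()` — Wald chi-square over all level differences of a
  factor within one analyte (main effect + analyte interaction), df =
  levels − 1 (3 for the four tissues). The contrast matrix is built from
  equal-weight reference-grid rows, so the statistic is invariant to the
  factor's reference level.
* `pairwise_condition_contrasts()` — single-df Wald tests of
  reference-minus-disease adjusted-mean differences ("Normal-Mono" < 0 means
  higher in mononucleosis), Holm-adjusted over the whole emitted table.
* `adjusted_means()` — model-based level means averaging the other fixed
  factors with *equal* level weights (not observed frequencies), with
  normal-quantile 95% intervals. Equal weighting matches the usual
  interaction-means convention; the difference of two adjusted means equals
  the corresponding contrast estimate exactly, which the tests assert to
  1e-9.
* `compare_models()` — likelihood-ratio test of global vs reduced. Both
  models are refit by full ML first: REML likelihoods are not comparable
  across fixed-effect structures, so the REML fits used for contrasts cannot
  feed the LRT directly.

Confidence intervals and Wald p-values use normal/chi-square reference
distributions without small-sample df corrections (Kenward-Roger and
Satterthwaite are out of scope); with hundreds to thousands of observations
per fit the difference is negligible, and the recovery experiment below
measures the realized coverage directly.

Analytes are admitted to a concentration-scale fit only if every
(analyte, tissue, condition) design cell retains at least one non-missing
response (`filter_estimable_analytes()`, default `min_per_cell = 1`);
anything less makes the fixed-effect design rank-deficient. On complete
fluorescence data the filter never drops anything — that asymmetry is the
practical core of the fluorescence-first argument.

## Standard curves, censoring and the LOD

`fivepl()` uses the standard immunoassay parameterisation

f(x) = bottom + (top − bottom) / (1 + (x / ec50)^(−hill))^asym,

increasing in x for hill > 0, with `asym = 1` reducing to the symmetric 4PL.
`fit_5pl()` minimises weighted residual sums of squares with
Levenberg-Marquardt (`minpack.lm::nlsLM`), log-parameterising `ec50`, `hill`
and `asym` because the 5PL is ill-conditioned near extreme asymmetry, and
multi-starting over a small hill × asymmetry grid from a 4PL-style
initialisation. The default weights are 1/response², the constant-CV
weighting kit software applies; replicate-variance weighting and OLS are
available. Curves are fitted per analyte per plate: between-plate variation
of a standard curve is a plate-level property, so pooling plates would
launder it into the samples.

`inverse_5pl()` applies the closed-form inverse and classifies each
fluorescence value: `in_range` within the standards' observed span,
`extrapolated` outside the span but strictly between the asymptotes (these
still receive a concentration, as instrument software reports them), and
`oor_low` / `oor_high` at or beyond the asymptotes, where no concentration
exists. `map_dataset()` applies this to every sample well and never touches
the fluorescence column.

The fluorescence LOD is `mean(blanks) + k·sd(blanks)` with `k = 2` by
default; the vendor's exact algorithm is proprietary, so `k` is
configuration, and published LOD values can be supplied as inputs instead.
Blank fluorescence is never subtracted from sample responses: the
translation-invariance identity below makes background subtraction
irrelevant for differential analysis, and subtracting a noisy background
estimate from low-abundance responses only adds noise.

## LOD diagnostics

If fluorescence responses hit a detection floor, point scatter below the
nominal LOD should be compressed relative to scatter above it. The package
tests this the way the motivating study did:

* `balanced_neighborhood()` selects the N nearest responses on each side of
  the LOD (N = the smaller side count), so the comparison is balanced. Ties
  at the LOD count as "above"; distance ties break toward the smaller value,
  making the selection deterministic and order-invariant.
* `cv_ratio_test()` compares the two sides' CVs via the equivalent F test on
  the variances of the log2 data (two-sided, doubled smaller tail).
* `aggregate_cv_comparison()` pools a whole CV table: an unpaired
  Mann-Whitney test on the log2 CV columns and a paired t test on their
  row-wise differences. The packaged printed CV table (17 analyte × tissue
  rows) reproduces the published paired-t aggregate (t = −0.42, df = 16,
  p = 0.68) from its printed 3-decimal CVs. The printed rank-sum statistic
  W = 135 was evidently computed on unrounded CVs: on the printed values the
  statistic is 130.5, which the tests assert against an exhaustive
  pair-counting oracle rather than forcing the printed number.
* `rank_difference_profile()` logs successive differences of the unique
  sorted responses. A detection floor would drive the low-rank differences
  toward zero (log2 → −∞); instead, half-unit instrument quantisation pins
  them at 0.5, i.e. a head mean of exactly −1 — the signature
  `quantize_fluorescence()` reproduces and the acceptance script recomputes.
* `pvalue_uniformity_scan()` runs Mann-Whitney tissue-pair comparisons per
  analyte (9 low-abundance analytes × 6 tissue pairs = 54 tests in the
  study configuration). If sub-LOD responses were pure noise these p-values
  would be uniform; structure shows up as an excess of small p-values. A
  one-sample Kolmogorov-Smirnov statistic against Uniform(0,1) summarises
  the histogram. Because exact rank-sum p-values have discrete support, the
  KS comparison against a continuous uniform over-rejects somewhat at small
  group sizes; the calibration test bounds the null rejection rate rather
  than asserting exact nominal size.

## The mapping simulation

The simulator works on a normalized response curve with the EC50 at 0 on the
log2 concentration axis: `normalized_sigmoid(x) = 1/(1 + 2^(−x))`, inverse
`x = log2(p/(1−p))`. Two groups are drawn on the normalized fluorescence
response scale from a centred skew-normal (shape α ∈ {0, −5, 5}; the sampler
uses the delta representation and rescales so the population mean and sd are
exact), separated by `cohen_d · sd_fl` (d = 0.8, the conventional large
effect). `translation_scan()` then *translates one fixed draw* so the pair's
midpoint visits every response level from 0.05 to 0.95 in steps of 0.01. At
each step:

* `p_fl` is a pooled two-sample t test on the translated responses. Because
  the same draw is reused, the t statistic is exactly constant across the
  scan — the identity t(x, y) = t(x + b, y + b) that makes background level
  irrelevant on the fluorescence scale. (`redraw = TRUE` gives the
  statistical version with fresh draws per step.)
* Responses are pushed through the inverse sigmoid; values outside (0, 1)
  are unmappable and dropped (the simulation's censoring), and `p_conc` is
  the t test on the mapped concentrations, by default on the log2
  concentration scale — the scale on which the package (and the field)
  models responses. Natural pg/ml testing is available via
  `conc_scale = "natural"`.

Two calibration choices matter and are deliberate:

* `sd_fl` defaults to 0.02 normalized units. The input distributions must be
  narrow relative to the curve's unit span so that even at the 0.05 and 0.95
  scan levels only an occasional draw is unmappable. With a wider input
  (e.g. 0.05), a quarter of one group is censored at the scan ends, and the
  truncation *removes* the log-stretched tail — reversing the power loss the
  mapping otherwise causes and contradicting the behaviour the simulation
  exists to demonstrate.
* `n_per_group` defaults to 100, enough for stable p-value dynamics without
  floor effects.

With symmetric inputs, `p_conc` is smallest near the EC50 and grows toward
both ends: the inverse sigmoid's derivative is minimal at the midpoint, so
off-centre distributions are stretched (variance inflation) and skewed —
left below the EC50, right above it, with the mapped mean pulled in the
direction of the skew relative to the image of the input mean
(`distribution_summary()` reports both). Skewed inputs break the symmetry:
a left-skewed input loses power below the EC50 (its long tail lands in the
log-stretched region) and *gains* power above it, where the mapping
compresses that tail — and mirrored for right skew. Since a single fixed
draw leaves a flat valley in mid-curve, the acceptance test averages log10
p-values over ten fixed seeds before locating the smoothed minimizer.

## The synthetic data generator

`generate_dataset()` simulates the full data-generating process the analysis
assumes: per sample × analyte,

latent log2 concentration = baseline(analyte) + tissue effect + condition
effect + patient intercept + plate-group intercept + residual,

then fluorescence = 5PL(2^latent) under multiplicative lognormal noise
(constant CV 3%, matching %CV as the field's dispersion measure), quantized
to 0.5 fluorescence units. Standards are an 8-level, 4-fold dilution series
in duplicate wells per analyte and plate (4-fold borrowed from the study's
stated sample dilution; the kit's actual series is unpublished), with blank
wells drawn per analyte. The default design (`default_design()`) reproduces
the study's totals — 169 patients, 191 samples, 14 nonempty
plate:condition:tissue groups, 16 mononucleosis and 6 myeloma patients
paired across plasma and serum — with per-group patient counts that are the
package's own stand-in, since the exact published allocation is not
available. Default variance components are 0.25 (patient), 0.09
(plate-group) and 0.04 (residual) on the log2 scale, and default baselines
spread from −4.5 to 11 log2 pg/ml so that roughly nine low-abundance
analytes sit below their lowest standard, mirroring the study's
low-abundance set. `inject_low_abundance()` pushes chosen analytes' medians
a specified number of log2 units below their blank mean to exercise the
censoring and estimability-filter paths (the IL-11/IL-34/Light/MMP-3
phenomenon).

What the generator does *not* emulate: bead-count QC, well failures, plate
spatial effects, drift or carryover, and any heavier-tailed or
analyte-correlated noise real panels may show. Tests passing on this
generator demonstrate that the statistical machinery is correct under its
own assumptions, not that those assumptions exhaust real data.

### Scaled-down experiment sizes

Test and recovery experiments use reduced designs chosen as follows:

* Parameter recovery (10 analytes × 4 tissues × 4 conditions, 100 seeds)
  replicates every tissue × condition cell across 12 plates with 6 patients
  per cell-plate (192 plate groups, 1152 patients). The plate-group variance
  needs this: with each cell on a single plate, the fixed tissue/condition
  margins absorb most of the group-mean degrees of freedom and the nested
  patient means (variance 0.25/patients-per-group) contaminate the rest,
  leaving the component close to unidentifiable. With the replicated layout
  the median relative errors of all three components sit well inside 15%
  and contrast interval coverage is at its nominal level.
* Null-calibration runs (type-I error of the model comparison, F-test size,
  KS uniformity) use 60–1000 replicates depending on per-replicate cost.
* 5PL simulation checks use 30–50 seeds at the 8-level standard layout.

## Numerical choices and degenerate inputs

* 5PL fits: LM tolerance 1e-12 on the residual, up to 400 iterations, 9
  starts; the best converged candidate by weighted RSS wins; total failure
  raises an error rather than returning a bad curve.
* `fivepl(0)` is exactly `bottom` (the exponent underflows to +Inf
  deliberately); negative concentrations are a domain error.
* Zero log-variance on either side of `cv_ratio_test()` flags the row as
  degenerate instead of producing an infinite F.
* `aggregate_cv_comparison()` with identical CV columns returns t = 0,
  p = 1 by convention (the paired t is undefined on all-zero differences).
* A variance component pinned at zero produces a warning, not an error; the
  fit proceeds (lme4's boundary behaviour).
* Duplicate wells are averaged (arithmetic mean of fluorescence) into one
  observation per sample × analyte before modelling; `aggregate = FALSE`
  keeps per-well rows. Whether the original analysis averaged duplicates is
  not stated; averaging is this package's default and only affects the
  effective residual variance.
* Analyte labels keep their "(bead region)" suffix as an opaque string.

## Limitations

* Wald inference uses plug-in variance components; realized coverage is
  checked by simulation (≈ 95%) but no small-sample df correction is
  offered.
* The LOD rule is a blank-based convention, not the vendor's proprietary
  algorithm; published LOD columns should be treated as inputs.
* The concentration pipeline inherits every pathology of the 5PL fit;
  standard-recovery diagnostics are reported but never enforced as
  acceptance bands.
* The simulator's sigmoid is the normalized slope-1 curve; any strictly
  monotone re-exponentiation preserves its qualitative conclusions but the
  quantitative p-value trajectories are specific to the stated calibration.
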