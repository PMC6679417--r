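---
title: "Models, assumptions and design choices in spermorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, assumptions and design choices in spermorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spermorph)
```

`spermorph` analyses how thermal acclimation of male fish affects sperm
morphology and the theoretical hydrodynamics of the sperm head. This
vignette is the package's account of the science it implements: the
geometric and physical models, the statistical machinery, what the
synthetic-data generator does and does not emulate, and the numerical
decisions taken where the design was genuinely open.

## Head geometry

A fish sperm head under light microscopy is well approximated by a prolate
spheroid: an ellipse with polar semi-axis `r_p = L_H / 2` (half the head
length, flagellum insertion to apex) and equatorial semi-axis
`r_e = W_H / 2` (half the width, measured centre-perpendicular), rotated
about the long axis. Two derived quantities matter:

* **Ellipticity** `e = sqrt(1 − r_e²/r_p²)`, the eccentricity of the
  meridional ellipse: 0 for a sphere, approaching 1 as the head elongates.
* **Surface area** `A_H = 2π r_e² + 2π r_e r_p · asin(e)/e`.

The closed form is validated in the test suite against an independent
numerical oracle — the surface-of-revolution integral of the meridional
ellipse, parametrised to avoid the pole singularity — to a relative error
below 1e-9 for aspect ratios up to 20. When `e < 1e-9` the arcsin term
degenerates to 0/0 and the exact sphere value `4π r_e²` is returned
instead; the two branches agree to better than 1e-6 relative at the
switch, so the function is numerically continuous.

Cells whose width exceeds their length violate the prolate assumption.
They are rejected with an error rather than silently axis-swapped, because
swapping would corrupt the ellipticity; `validate_prolate()` lists the
offending rows for a strict-validation report. Derivations are defined
only for cells classified "normal" — deformed cells were never measured
under the protocol this package mirrors — and the mid-piece is not
modelled at all, since it cannot be distinguished from the head by light
microscopy in most fishes.

The two ratio predictors, `L_F/L_H` (dimensionless) and `L_F/A_H` (µm⁻¹),
are the standard morphological predictors of sperm swimming speed: they
express propulsive apparatus relative to the drag-bearing head. Exact
scaling laws (area scales as the square of an isotropic size factor, the
area ratio as its inverse, ellipticity not at all) are property-tested.

## Drag model

Sperm swim at very low Reynolds numbers, where viscous forces dominate and
Stokes' law gives the drag on a small sphere: `D = 6π µ a U`. Following
the convention for sperm heads, `a` is the equatorial half-width
`0.5 × W_H` of each individual cell (an option for an
equivalent-volume-sphere radius is deliberately not provided: the
half-width convention is the one the field's drag calculations use), and
`U` is the male's average path velocity (VAP) at the activation
temperature in question — speeds are only measured as per-male averages,
so the male-level speed is applied to each of that male's cells. The drag
record stores `U` per row, so per-cell speeds could be supplied later
without a schema change.

Viscosity enters through a reference table (`temp_C`, `mu_Pa_s`). The
default lookup mode, `bracket_mean`, returns the arithmetic mean of the
two table entries bracketing the query temperature — the rule used when
studies quote tabulated literature values at 5 °C steps for an
intermediate bath temperature — while `linear` interpolation is provided
for sensitivity analysis. Exact table hits return the entry unchanged. The
shipped table holds standard pure-water values at 5 °C steps (1.5192 mPa·s
at 5 °C, 1.3069 at 10 °C, 1.1382 at 15 °C, …), but every function accepts
a user table and all arithmetic tests use toy tables, so no shipped number
is load-bearing.

Units are converted once, explicitly: µm → m (×1e-6) for radius and speed,
N → pN (×1e12) for the result; column names carry units (`_um`, `_Pa_s`,
`_pN`) to keep unit errors visible. A round-trip property test confirms
the SI path and a pN-consistent direct evaluation agree to 1e-12 relative.

## Deformity scan

The counting protocol views microscope fields in order and counts *whole*
fields until the cumulative cell count reaches the target (default 100);
the final field is always counted in full, so totals may overshoot but a
partial field is never counted. The "approximately 100" of such protocols
is exactly this overshoot rule, so the target itself is an exact,
configurable number. Cells are classified as normal, kink (bent
flagellum), coil (knotted flagellum), short (drastically shortened
flagellum) or tailless; indiscernible aggregations are tallied separately
and never enter any denominator. Totals are invariant to how the same
cells are partitioned into fields.

## Statistical comparisons

All comparisons return a uniform `sperm_fit` contract (term, estimate,
standard error, statistic, df, p-value; contrasts where applicable;
convergence flags; sample sizes) with broom-style `tidy()`/`glance()`
methods. Significance is assessed at 0.05 throughout and no
multiple-testing correction is applied anywhere — each comparison is a
single planned test.

* **Deformity**: binomial GLM of deformed/total per male on acclimation
  group. One row per male (not pooled counts), so the group term is a
  log-odds difference across males. Complete separation is flagged in the
  result rather than fatal.
* **Morphology**: mixed model of the per-cell quantity on group with a
  per-male random intercept. The absolute sizes (`A_H`, `L_F`, `L_T`) are
  right-skewed; a penalised-quasi-likelihood GLMM with a lognormal family
  is one way to fit them, but for a lognormal response the estimand
  coincides with that of a linear mixed model on the log scale, which is
  simpler, exactly testable, and implementation-independent — so that is
  what the package fits. The two ratios, whose residuals are close to
  normal at these parameter values, are fitted on the identity scale.
* **Speed vs morphology**: per-male linear model of VAP on the mean ratio,
  with acclimation group added for `L_F/A_H` (the measure that can differ
  between groups). By default the response is identity-scale at the cold
  activation temperature and log-scale at the warm one, mirroring the
  residual diagnostics of the emulated design; the transform is
  overridable, and the log choice keeps the speed stage consistent with
  the morphology stage rather than leaving "a generalised linear model"
  unspecified.
* **Drag**: linear mixed model of per-male mean drag on
  acclimation × activation with a random intercept per male. Because male
  IDs are unique, the per-male intercept realises male-nested-in-
  acclimation exactly. Post-hoc least-squares-means contrasts compare
  activation temperatures within each acclimation group, unadjusted.

**Degrees of freedom.** Mixed-model tests and contrasts use the
Satterthwaite approximation (lmerTest/emmeans). For the balanced design of
8 + 8 males × 2 activation temperatures with a non-degenerate male
variance this yields exactly 14 denominator df for the within-group
activation contrast — the natural paired-comparison df for 16 males minus
two group means — which is the compatibility anchor for this design.
Kenward-Roger is available as an option. When the male variance is
estimated at the boundary (zero), Satterthwaite df rise towards the
residual df; such fits carry a `boundary (singular)` flag.

**Degenerate inputs.** Zero-variance responses short-circuit to a flagged
result with zero effect estimates rather than an optimiser failure;
constant predictors are likewise flagged. If the random-effect structure
is unidentifiable (zero within-male variance) the morphology stage falls
back to OLS — which equals GLS on balanced data — and says so in its
flags. Fitting is deterministic: the same input table always yields the
same result, bit for bit.

## The synthetic-data generator

The generator emulates the study structure — two acclimation groups
(cold 8 °C, warm 13 °C) × 8 males × 40 measured normal cells, a ~100-cell
deformity scan per male, and one VAP per male per activation
temperature — under a lognormal size model:

* a shared per-male size factor, normal on the log scale (SD 0.05),
  multiplies head length and flagellum length, inducing intra-male
  correlation across linear dimensions;
* cell-level head length, flagellum length and the width-to-length
  fraction are lognormal, parameterised by arithmetic mean and CV so the
  configured means are the true expectations (head 3 µm × CV 10 %,
  flagellum 32 µm × CV 8 %, width fraction 0.65 × CV 5 %);
* head width is generated as a fraction < 1 of head length, never
  independently, so every generated cell satisfies the prolate
  precondition by construction;
* deformity categories are drawn per scanned cell (kink 0.12, coil 0.08,
  short 0.05, tailless 0.05 — about 30 % deformed in total, the level
  reported for fresh trout semen);
* VAP is male-level, Gaussian per activation temperature (means 80 and
  90 µm s⁻¹ at 8 and 13 °C, SD 12), independent across temperatures;
* group effects are multiplicative: a warm-group multiplier on head
  dimensions and one on flagellum length (1 = null), plus an optional
  multiplier on VAP.

Dimension means and CVs are field-realistic choices for salmonid sperm,
made once; the published source this design emulates reports no variance
components, so they are assumptions, not calibrations. The
`warm_head_reduction` scenario (warm heads ×0.95, everything else equal)
produces the characteristic pattern in which the relative measure
`L_F/A_H` responds strongly while absolute sizes respond weakly or not at
all: because the male size factor is shared, the head-area comparison
carries twice the between-male dispersion of the ratio comparison, halving
its standardised effect.

What the generator does **not** emulate: video microscopy and CASA
tracking (speeds are drawn, not tracked), flagellar beat kinematics,
preservation artefacts, correlation of VAP across activation temperatures
within a male, and any image content for deformity classes (categories are
labels only — classification was manual microscopy). Passing tests
therefore certify the computational pipeline and its statistical
calibration under this generative model, not the biology of any real
dataset.

All randomness flows through a single integer seed via an isolated RNG
scope; identical (design, effects, seed) gives bit-identical datasets and
the global RNG state is untouched.

## Calibration and verification by simulation

The acceptance test suite verifies, at the emulated design scale:

* type-I error of every inference stage within [0.03, 0.07] at α = 0.05
  under the null generator (1000 replicates);
* ≥ 90 % confidence-interval coverage of an injected +20 % warm-group
  shift in `L_F/A_H` (500 replicates), with ground truth obtained from a
  large one-off simulation (15 000 cells per group) exploiting that a
  flagellum multiplier scales the ratio exactly;
* exact (≤ 1e-8) recovery of constructed coefficients on noise-free
  balanced inputs;
* the relative-vs-absolute morphology pattern and the within-group drag
  contrasts under the `warm_head_reduction` scenario (500 replicates);
* byte-identical reruns of the simulate → analyze → report pipeline.

Simulation sizes (1000/500 replicates, 640 cells per study, 30 000 cells
for the LLN and goodness-of-fit checks) were chosen to give binomial
standard errors comfortably inside the asserted bands while keeping the
default test run at desk scale.

## Known limitations

* Drag is computed for the head only, as a rigid sphere of the head's
  half-width: no flagellar resistive-force theory, no Reynolds-number
  computation, no shape correction for the prolate geometry.
* The speed-vs-morphology stage inherits the usual caveat that per-male
  averaging discards intra-ejaculate variation, which can mask
  length-velocity relationships.
* The deformity stage implements counting and proportions only;
  classifying deformities from images is out of scope.
* With only 8 males per group, boundary (zero-variance) random-effect
  fits occur regularly under weak male-level signal; they are flagged,
  and their contrast df legitimately exceed the balanced-design anchor
  of 14.
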