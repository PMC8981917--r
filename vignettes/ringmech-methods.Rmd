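---
title: "Methods: tensile endpoints, morphometry and statistics for tissue rings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tensile endpoints, morphometry and statistics for tissue rings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringmech)
```

## The measurement problem

Self-assembled fibroblast rings are mounted over two cylindrical
gripper pins and pulled to failure in a heated bath at a quasi-static
strain rate (0.1 % of initial length per second; 5 µm/s at the 5 mm
initial grip-to-grip distance), with load and extension sampled at
20 Hz.  Because the ring hangs over two pins, two tissue limbs carry
the load, so engineering stress divides load by **twice** the initial
cross-sectional area:

$$\varepsilon_{eng} = \Delta L / L_{gauge}, \qquad
  \sigma_{eng} = N / (2 A_0),$$

and, assuming volume conservation and uniform deformation,

$$\varepsilon_{true} = \ln(1 + \varepsilon_{eng}), \qquad
  \sigma_{true} = \sigma_{eng}\,(1 + \varepsilon_{eng}).$$

Three endpoints summarize each test: the **ultimate tensile strength**
(UTS; peak stress before the failure event), the **maximum tangent
modulus** (MTM; the construct's stiffness), and the **failure strain**.

## Trace processing

1. **Drag subtraction.** The grippers moving through the bath produce
   a drag force measured by running the protocol without a specimen;
   it is linearly interpolated at each specimen extension and removed
   from the load.  A baseline must cover at least 90 % of the
   specimen's extension range.
2. **Tension onset.** The ring is slack when the pull starts.  The
   specimen is considered in tension at the first sample whose *raw*
   (pre-subtraction) load exceeds 5 mN — the load-cell resolution —
   and the gauge length is the grip-to-grip distance at that sample.
   Strain is referenced to this onset.
3. **Stress conversion** with either the minimum or the mean of the
   per-position elliptical cross-sections (both are first-class
   conventions because rings can have non-uniform walls; the minimum
   is the default, being the section that actually fails).
4. **Tangent modulus profile.** For every sample whose following
   window of 8 % engineering strain fits inside the curve, stress is
   regressed on strain by ordinary least squares; the MTM is the
   largest slope among windows ending at or before the failure sample.
   Windows are defined in strain units, not sample counts, so the
   estimate does not depend on the sampling rate.  Exact ties resolve
   to the earliest window.  On the J-shaped curves this package
   generates, the winning window always sits in the linear region past
   the toe, which the test suite asserts.
5. **Failure detection.** The instrument terminates a test when load
   drops by more than 40 % of the running maximum; offline, the
   failure sample is re-detected with the same rule.  Failure strain
   is the strain at that sample (the termination rule is the
   operational definition of failure); strain at peak stress is also
   reported for comparison with studies that use it.

### Numerical choices in the endpoint estimators

*Relative drop rule on noisy traces.*  A literal streaming
implementation of the 40 %-drop rule misfires on noisy data in the
slack and toe regions, where the load is near zero and any fluctuation
is a large *relative* drop.  Two guards restore the intended
behaviour without affecting clean traces: the rule is only evaluated
once the running maximum exceeds 10 % of the trace's global maximum
(`min_peak_frac`), and `analyze_trace()` evaluates it on a 0.5 s
moving average of the load (`failure_smooth_s`), which shifts the
detected index by at most half that window.

*Peak readout bias.*  The raw maximum of a noisy sampled stress curve
is an upward-biased UTS estimator: near the peak many samples lie
within one noise standard deviation of it, and the expected maximum of
$m$ such samples exceeds the true peak by roughly
$\sigma\sqrt{2\ln m}$.  At 20 Hz and 5 µm/s with load noise of 1 % of
peak, this bias alone is 1.5–3 % — larger than the accuracy one
should expect of the estimate itself.  `summarize_mechanics()`
therefore accepts `peak_smooth_s`, a centred moving average applied to
the stress series *only for the peak readout*; 2.5 s (about 50
samples) reduces the noise maximum bias to ≈0.3 % at the cost of a
≤0.6 % flattening of the kink at rupture.  The default remains 0 (raw
maximum), appropriate for low-noise instruments; the parameter-recovery
tests run with 2.5 s.  No smoothing is ever applied before the tangent
fits: an 8 %-strain window already averages ≈1600 samples, and
pre-smoothing would bias the MTM.

## The synthetic-data generator

The generator exists to give every stage a known ground truth, not to
model tissue biophysics.  Its constitutive law is the simplest C¹
J-curve with an exactly known linear-region slope: a quadratic toe
$\sigma = E\varepsilon^2/(2\varepsilon_t)$ for
$\varepsilon \le \varepsilon_t$, joining the linear branch
continuously in value and slope, rupturing at
$\sigma = \mathrm{UTS}$ (so the failure strain is
$\mathrm{UTS}/E + \varepsilon_t/2$) with a single-sample load drop
that unambiguously triggers the termination rule.  Load noise is
additive i.i.d. Gaussian on load only — crosshead position is
servo-controlled in the real instrument — and drag is a smooth
saturating function of extension.  All generators are pure functions
of their parameters and seed.

Default study conditions mirror the instrument protocol: 20 Hz
sampling, 5 mm grip distance, 0.1 %/s strain rate, 40 % termination
drop.  For cohort simulations the default between-specimen CV of
modulus and strength is 10 %, load noise 5 mN and drag 2 mN, chosen as
typical of soft-tissue testing at the 0.1–5 MPa stress scale.  For
parameter-recovery sweeps, strength is drawn as `E * U(0.12, 0.2)`:
strength-to-stiffness ratios near 1/6 are what these constructs (and
ligament-like tissues generally) exhibit, and they guarantee rupture
beyond the toe so that a linear region exists for the MTM to find.

What the generator does **not** emulate: viscoelasticity, cyclic
preconditioning, crimp micromechanics, grip slippage, or non-Gaussian
load-cell artifacts.  Passing the round-trip tests therefore shows the
*analysis* is correct and calibrated under the stated noise model; it
does not validate the constitutive behaviour of real tissue.

## Ring morphometry

Thickness uniformity is quantified from top-view images.  The ring is
segmented by a global Otsu threshold followed by connected-component
labelling; components smaller than 5 % of the largest are discarded as
debris, and more than one surviving component is an error rather than
a guess.  The profile is built by casting 360 rays from the ring
centre and measuring the radial extent of the foreground crossing.

Two choices matter for accuracy:

- **Centre estimate.**  The centroid of the ring *mask* is biased
  toward the thick side of an asymmetric ring, which inflates oblique
  ray crossings (about +7 % on a half-thin/half-thick test ring).  The
  rings are cast around a circular peg, so the centroid of the
  enclosed lumen is an unbiased centre; `segment_ring()` uses it
  whenever the component encloses a hole and reports the mask centroid
  separately.
- **Sub-pixel boundaries.**  Nearest-pixel lookup quantizes each
  boundary to ±0.5 px, adding spurious variance to the profile and
  hence to its CV.  The mask is instead sampled bilinearly along each
  ray and each boundary taken as the interpolated 0.5-level crossing,
  which recovers constant-thickness rings to ≈0.1 px.

The coefficient of variation uses the sample standard deviation
(n − 1): group sizes in ring experiments are small enough (n = 24
wells) for the convention to be visible, so it is stated and tested.

## Collagen assay

Collagen is quantified by inverting an ordinary least-squares standard
curve of absorbance (525 nm) on standard mass; the 0-µg standard
defines the intercept, so there is no separate blank-subtraction step.
Readings outside the standard range are flagged rather than refused,
and negative inferred masses clamp to zero with a warning.  Per-cell
normalization divides by the *seeded* cell number (3×10⁵ per well by
default) because endpoint cell counts are not part of the assay; this
is a stated convention, overridable, not an estimate of cells at
harvest.

## Statistics battery

Group comparisons follow the two-branch design used in dose-response
tissue experiments: a gate tests model assumptions, then either
one-way ANOVA with Tukey HSD or Kruskal–Wallis with Conover–Iman
post-hoc runs, and group letters are assigned so that groups sharing a
letter are not significantly different.

- **Gate.**  Shapiro–Wilk runs on the pooled group-centred residuals
  — what the one-way model actually assumes — rather than per group;
  testing k groups separately would compound to a
  $1 - 0.95^k$ false-alarm rate under normality.  Levene's test
  (median-centred) checks homoscedasticity.  The gate is advisory and
  recorded; either branch can be forced, since in practice different
  endpoints of the same study legitimately use different branches.
- **Kruskal–Wallis** uses the tie-corrected H with a chi-square
  reference (df = k − 1).  Its type-I error calibration (0.05 ± 0.02
  at 3 groups × n = 10 over 2000 replicates) is asserted by the
  acceptance tests.
- **Conover–Iman** pairwise statistics are t ratios of mean-rank
  differences with the pooled rank variance scaled by
  $(N - 1 - H)/(N - k)$, df = N − k.  Pairwise p-values are
  unadjusted by default, matching the common default of post-hoc
  rank-test software; Holm is available by argument.  Average ranks
  are used for ties throughout.
- **Compact letters** are assigned by insert-and-absorb and satisfy
  their defining invariant exactly: groups share a letter if and only
  if their pairwise p ≥ α.  The implementation is property-tested on
  randomized p-value matrices.
- **Correlation.**  Spearman's ρ is computed as the Pearson
  correlation of average ranks on pairwise-complete observations, with
  p-values from the t approximation and Bonferroni correction with m =
  number of unique off-diagonal pairs.  ρ is invariant to strictly
  monotone transforms of either variable, which the suite asserts.

α is fixed at 0.05 by default everywhere, configurable per call.

## Whole-experiment orchestration

`run_experiment()` composes the stages over a config of per-group
trace and geometry files: specimens failing validation are excluded
and logged; specimens that never reach 5 mN or never exhibit the 40 %
drop are retained (flagged) for MTM when a full window exists but
excluded from UTS and failure-strain statistics, because the
termination rule is what defines those endpoints.  More than 50 %
exclusions aborts the run.  Reports record the package version, a
config hash and every applied default, and re-running the same config
and seed reproduces all outputs byte for byte.

## Problem sizes used in the shipped tests

The test-suite and acceptance-script simulations are sized so the
whole battery runs in well under a minute on one core while keeping
every estimate's Monte-Carlo error far from its decision threshold:
20-configuration recovery sweeps, 20-image morphometry sweeps, 2000
null replicates for test calibration, and cohorts of 2–3 groups × 4–6
rings for the pipeline power checks.  These sizes are choices of the
package's own test design, and each test states its tolerance next to
the quantity it checks.

## Known limitations

- The constitutive generator is deliberately minimal; no claim of
  biological realism attaches to it.
- The collagen model quantifies only what a linear standard curve can
  see (pepsin-acid-soluble collagen); crosslinked insoluble collagen
  is out of scope.
- Morphometry assumes a single ring with a circular lumen per image;
  touching rings or fragmented masks are errors by design.
- No viscoelastic, cyclic or stress-relaxation analysis; no
  grip-compliance or ring-curvature corrections beyond the factor 2.
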