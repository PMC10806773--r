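---
title: "Methods: from monomer conformation to aggregation propensity"
author: "idplink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from monomer conformation to aggregation propensity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idplink)
```

## The scientific question

Single-point mutations in an intrinsically disordered protein (IDP) can
change its aggregation behaviour dramatically while leaving the sequence
almost untouched. One mechanistic hypothesis is conformational: a
mutation shifts the monomer ensemble toward more expanded (or more
compact) chains, and chain expansion in turn modulates how readily the
protein nucleates amyloid fibrils or undergoes liquid-liquid phase
separation (LLPS). Testing that hypothesis requires putting numbers on
both sides:

* **conformation** -- the radius of gyration Rg from small-angle X-ray
  scattering (SAXS), the Flory exponent nu from a polymer form-factor
  fit, the second virial coefficient A2 from SEC-SAXS, and gas-phase
  collision cross sections (CCS) from drift-tube ion mobility;
* **behaviour** -- the aggregation halftime from ThT fluorescence
  kinetics and the LLPS saturation concentration Csat from endpoint
  turbidity plates;

and then regressing one against the other across mutants. This package
implements that full chain as tested, reusable code, together with a
synthetic-data generator that reproduces the statistical structure of
each instrument's output so the pipeline can be validated end to end
without beamline or plate-reader data.

## Models and procedures

### Guinier analysis with a window-scan histogram

At low q the scattering of any particle follows
`ln I(q) = ln I0 - q^2 Rg^2 / 3`. Instead of one hand-picked fitting
window, `guinier_rg()` fits **every** contiguous window of the fitting
region, from 6 points up to the full region, collects the per-window Rg
values in a frequency histogram, and reports the count-weighted mean of
the bin centers; the count-weighted sd is the uncertainty. A narrow
histogram certifies a genuinely linear Guinier region; a relative width
above 10% raises a quality flag.

Numerical conventions that matter:

* **Histogram bins.** Bin *centers* span `[min, max]` of the window
  estimates with breaks at midpoints, so the extreme estimates sit at
  centers rather than edges. With estimates `{2, 2, 2, 4}` and two bins
  the reported value is `(3*2 + 1*4)/4 = 2.5`.
* **Region choice.** For an ideal-chain-like (Debye) curve the Guinier
  law is only the leading term: windows reaching `q Rg ~ 1` carry a
  systematic underestimate (`ln D(x) = -x/3 + x^2/36 + ...`,
  `x = (q Rg)^2`). Scanning all windows of a region that extends to
  `q Rg = 1.0` on a noiseless Debye curve biases the histogram mean by
  about 2.7%; restricting the region to `q Rg <= 0.8` reduces this to
  1.7% while keeping enough signal decay that 2% intensity noise does
  not dominate the short windows (measured median error 3.2% at 2%
  noise). The default region is therefore chosen adaptively: a pilot
  fit on the lowest-q points gives a provisional Rg, and the scan
  region is every point with `q Rg_pilot <= 0.8`.
* **Validity filter.** Windows whose own `qmax * Rg` exceeds 1.3 are
  dropped (configurable, off reproduces the bare scan). The permissive
  1.3 reflects IDP practice.
* Windows with non-positive intensities or non-negative slope are
  flagged invalid and skipped, never raised as errors.

### Flory exponent from the molecular form factor

From polymer scaling, `Rg ~ N^nu`: nu near 0.5 marks an ideal
(theta-solvent) chain, near 0.588 a self-avoiding chain in good
solvent. The package extracts nu by fitting a closed-form generalized
Debye form factor for an excluded-volume chain,

```
U    = (2 nu + 1)(2 nu + 2) q^2 Rg^2 / 6
P(q) = gamma(1/(2 nu), U) / (nu U^(1/(2 nu)))
     - gamma(1/nu, U)     / (nu U^(1/nu))
```

with `gamma(a, x)` the lower incomplete gamma function. At `nu = 1/2`
this collapses analytically to the Debye function
`2 (exp(-U) + U - 1)/U^2` (the package test verifies agreement to
1e-9 across `U` in `[1e-4, 25]`; note the Debye reference itself must
be evaluated with `expm1` to avoid catastrophic cancellation at small
U). `P(0) = 1` by continuity; values below `U = 1e-10` return 1.

The fit (`fit_mff()`) is weighted nonlinear least squares over
`(I0, Rg, nu)` with multi-start initialization `nu in {0.45, 0.55,
0.65}`, bounds `nu in [0.3, 0.8]` (collapsed globule to swollen coil),
and the fit range restricted to `q <= 4 / Rg_guess` to exclude the
high-q region where local chain structure, not the global exponent,
shapes the curve. A fit is flagged unreliable when a parameter sits on
a bound or the best reduced chi-squared exceeds 3x the median over
starts; unreliable exponents should be excluded from cross-condition
regressions rather than interpreted. A closed-form factor is an
approximation to simulation-derived form factors used elsewhere in the
field; absolute nu values should be read comparatively, between similar
sequences in the same buffer, which is also how the cross-condition
layer uses them.

### SAXS reduction

Frame quality control follows a chi-squared-distance rule: each frame's
distance to the pointwise mean frame, `d_i = sum_q (I_i - Ibar)^2 /
sigma_i^2` (unweighted when no errors are present), is computed once
from all frames, and frames with `|d_i - mean(d)| > 2 sd(d)` are
eliminated in a single pass. Zero dispersion (identical frames) keeps
everything -- no dispersion, no outliers. Averaging propagates errors
as standard errors of the mean; buffer subtraction adds them in
quadrature.

For SEC-SAXS elutions, sample frames are selected where the UV trace
exceeds a configurable fraction of the baseline-to-peak rise (half-max
for averaging; 10% for the A2 concentration series, which needs a wide
concentration sweep), and the buffer block is the 10 frames immediately
preceding the first frame whose UV rises above the baseline (3x the
baseline noise, floored at 1% of the peak). Ending the buffer block at
the *signal onset* rather than at the selection threshold matters:
frames on the elution shoulder carry real protein signal, and averaging
them into the buffer corrupts the subtraction of every sample frame.
The baseline and its noise are estimated from the lowest quartile of
the per-frame UV values, which stays robust when the peak occupies a
large share of the series.

### Second virial coefficient

Concentrations come from Beer-Lambert on the inline UV trace
(`c = A280 / (epsilon * path)`, default `epsilon = 2800 M^-1 cm^-1`,
path 1 cm, molecular weight 20570 Da for the g/cm^3 mirror). Each
sample frame is buffer-subtracted and Guinier-fitted at low q for its
forward intensity, and the series obeys the single-contact virial
relation

```
K c / I(0, c) = 1/Mw + 2 A2 c
```

fitted in the operational form `c/I0 = alpha + beta c`, so
`A2 = beta / (2 alpha Mw)` with the lumped instrument constant
`K = 1/(alpha Mw)` absorbing any global intensity scale -- the A2
estimate is exactly invariant under intensity rescaling. Positive A2
means net repulsive interparticle interactions. Weighted least squares
uses per-frame I0 standard errors from the Guinier fit when intensity
errors exist; the 95% interval from first-order covariance propagation
covers the true A2 in 90% of noisy synthetic runs (200 seeds at 5%
intensity noise).

### Aggregation kinetics

ThT traces are normalized between 0 and 1 and fitted with the
three-parameter logistic

```
s(t) = F / (1 + exp(-k (t - t_half)))
```

with data-driven initialization (F from the maximum, t_half from the
first half-max crossing, k from `4/(t90 - t10)`). Convergence is
policed by bounds -- `k > 0` and t_half inside the observed window --
encoded in a flag rather than exceptions, so plate-scale batches never
abort on a non-aggregating well. Replicates are fitted independently;
the reported halftime is the mean over converged replicates with the
sample sd as error bar, and conditions with no converged replicate are
reported as "no aggregation observed". A flat (non-aggregating) trace
can be normalized against the plateau of an aggregating condition via
`reference_max`.

One caveat the tests quantify: min-max normalization uses extreme order
statistics, so at noise sd 0.05 it injects a baseline offset the
three-parameter logistic cannot absorb, biasing t_half by roughly 3%.
The parameter-recovery checks therefore fit the generated traces on
their native normalized scale; normalization is for raw instrument
counts, where the bias is part of the procedure's real behaviour.

### LLPS saturation concentration

Endpoint absorbances at 0, 4, 8 and 12 uM define a pooled baseline.
Each higher concentration is compared to the baseline with a two-sided
Welch t test, in increasing order, and the lowest concentration with
`p < 0.05` is Csat; no significance anywhere yields "none detected".
No multiple-testing correction is applied, matching the stated
decision rule. Two documented consequences: (i) with 7 tested
concentrations a null plate false-detects roughly 30% of the time --
the acceptance suite measures this against the *actual* size of the
test; (ii) Welch's test is liberal at n = 3 (its true two-sided size
at 3-vs-12 is about 0.066 by direct simulation), so the nominal 0.05
understates the per-test rate; the equal-variance Student option
(`var_equal = TRUE`) is exact under the null. Zero-variance cells are
treated as not significant with a warning, never as errors.

### Ion-mobility CCS

Step-field drift-tube data at five voltages give arrival-time
distributions whose peak centers obey `tA = t0 + L^2/(K dV)`;
regressing tA on 1/dV separates the raw mobility K (slope `L^2/K`)
from the time spent outside the drift region (intercept t0). K reduces
to standard conditions as `K0 = K (p/760)(273.15/T)` and converts to a
collision cross section via Mason-Schamp:

```
CCS = 3 z e / (16 N0) * sqrt(2 pi / (mu kB T)) / K0
```

with `mu` the reduced ion/buffer-gas mass and CODATA-2018 constants
pinned in one table (`ims_constants`), covered by a frozen
dual-implementation regression value. Peak centers default to the
intensity-weighted centroid within the FWHM window (maximum-bin mode
behind a flag); on synthetic Gaussian ATDs the two differ by less than
the reported CCS uncertainty. The CCS distribution at the lowest
voltage is reconstructed by the linear map `CCS(tA) = a (tA - t0)`
anchored so the peak center maps exactly onto the regression CCS.
First-order propagation of the stated instrument uncertainties
(0.2 cm, 1 K, 0.01 Torr) lands well below the ~2.0% combined standard
uncertainty typical once calibration terms are included, so 2.0% is
reported as a floor.

### Cross-condition statistics

Simple OLS regressions (halftime vs Rg, Csat vs Rg, nu vs Rg, ...) with
`r^2 = 1 - SSres/SStot`; conditions with undefined values (a
non-aggregating condition has no halftime; a condition without LLPS in
range has no Csat) are excluded and the exclusions recorded with
reasons. No errors-in-variables correction is applied. The elbow check
runs k-means (10 restarts per k, fixed seed) for k = 1..k_max and
selects the k maximizing the second difference of the within-cluster
sum of squares, ties toward smaller k. Because a featureless 1/k decay
still has positive curvature, a "no strong elbow" flag is raised when
the curvature at the selected k does not exceed the residual WCSS
there; over repeated single-Gaussian draws the flag fires in ~95% of
cases while three well-separated clouds are never flagged.

## The synthetic-data generator

Every generator is a pure function of its parameters and seed and
records its ground truth in an attribute (`write_truth()` writes the
sidecar). What each emulates, and what it deliberately does not:

* `debye_profile()` -- exact ideal-chain scattering with optional
  relative Gaussian noise. Real reduced SAXS data have q-dependent
  error structure from azimuthal averaging; here the noise model is
  plain Gaussian (plate readers and reduced SAXS errors are near
  Gaussian), recorded in the sigma column.
* `saw_ensemble()` -- cubic-lattice self-avoiding walks by the pivot
  algorithm: random internal pivot site, random non-identity octahedral
  symmetry applied to the shorter arm, accepted iff self-avoidance
  holds; burn-in of 10 N accepted pivots, N accepted pivots between
  samples. The sampler is validated against exact enumeration of all
  1,853,886 nine-step walks and against an independent
  rejection sampler. Lattice units convert to nm by a bead spacing of
  0.38 nm (the Calpha-Calpha distance); this affects only absolute Rg,
  never nu. No excluded-volume screening, no sequence specificity --
  these chains test polymer-scaling inference, they are not tau.
* `scattering_from_ensemble()` -- exact orientation-averaged Debye sum
  over an ensemble, `I(0) = 1`.
* `sec_saxs_series()` -- an elution whose forward intensities obey the
  virial relation exactly, with Beer-Lambert UV and flat buffer
  background. `elution_profile()` clips the Gaussian tails to exact
  zero below 2% of the peak, emulating a baseline-separated peak whose
  shoulders fall below the detection floor; without this the "buffer"
  frames would carry real signal and no zero-noise round trip could be
  exact.
* `tht_traces()`, `llps_plate()`, `ims_arrival()` -- the logistic,
  step-plus-noise plate, and Gaussian-ATD models described above, with
  iid Gaussian noise throughout.

Passing tests on these generators demonstrate parameter recovery under
the stated noise models -- they do not validate detector artefacts,
radiation damage, capillary fouling, baseline drift or inter-plate
effects, none of which are simulated.

## Problem sizes and study conditions

The validation suite runs at the scales the analyses are designed for:
kinetics on a 110 h window with 100 points and 3 replicates at noise
sd 0.05; plates spanning 0-40 uM in 4 uM steps with 3 replicates;
SEC-SAXS elutions of 80 frames with 10+ true buffer frames; SAW
ensembles of 200-500 walks for chain lengths 50-400 (burn-in and
decorrelation as above); 5 drift voltages between 400 and 800 V on a
78.1 cm tube at 3.89 Torr helium and 297 K. Monte-Carlo checks use
50-1000 seeds depending on the statistic.

## Known limitations

* The generalized Debye form factor is analytic but approximate at high
  q; nu comparisons across conditions are robust, absolute values less
  so.
* The Guinier window histogram inherits a small truncation bias from
  the Debye curvature even inside `q Rg <= 0.8` (about 1-2% on ideal
  chains); for globular particles the bias is smaller.
* The A2 analysis assumes the single-contact virial truncation and a
  concentration-independent profile shape; structure-factor effects
  beyond forward scattering are out of scope.
* The Csat ladder reports raw per-test significance by design; its
  false-detection behaviour on null plates is quantified, not
  corrected.
* Errors-in-variables attenuation is not corrected in the
  cross-condition regressions; with noisy Rg estimates the fitted
  slopes and r^2 are conservative.
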