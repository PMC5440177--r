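---
title: "Models, assumptions and numerical choices in dynpet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, assumptions and numerical choices in dynpet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dynpet)
```

`dynpet` quantifies dynamic brain PET scans of reversibly binding tracers and
summarises how reproducible the resulting binding measures are across a
test–retest cohort. This vignette explains the models behind each exported
function, the parameters that matter and their defaults, the numerical
machinery, what the synthetic phantom does and does not emulate, and the
design decisions taken where more than one reasonable implementation exists.

## Time base, decay and frame weighting

All curves live on a common clock starting at scan start, with the tracer
bolus injected 30 s in. The default acquisition is 24 frames of increasing
length (1×30, 4×15, 4×60, 2×150, 10×300, 3×600 s; 5430 s in total), and all
models are evaluated at the frame midpoints — frames are short relative to
the kinetics, so midpoint evaluation plus duration-weighted frame averaging
is accurate to well below the noise level. Decay correction multiplies frame
values by `exp(λ t_mid)` with the ¹¹C decay constant λ = 5.663·10⁻⁴ s⁻¹;
`decay_correct()` tracks the correction state and refuses to apply it twice.

Frame weights are `wᵢ = Lᵢ/Tᵢ`: frame duration over true-coincidence rate,
computed from non-decay-corrected data. The variance of a frame mean is
proportional to the count rate divided by the squared duration, so this ratio
is the standard inverse-variance surrogate when only total trues are known.
For regional fits the weights are normalised to sum to the number of frames
with a cap of 2.5; both constraints are imposed simultaneously by computing
the joint fixed point directly (cap the m largest weights, rescale the rest;
m is the smallest count for which the largest uncapped weight stays at or
below the cap). The alternating clip/rescale iteration converges to the same
point but only asymptotically when a weight sits exactly at the cap, which is
why the closed form is used. Voxelwise weights are not sum-normalised; the
smallest are floored so the dynamic range `max/min` never exceeds 1000.

## Input function

The arterial data are a continuous whole-blood detector curve over the first
15 min and discrete syringe samples (baseline and 4, 6, 8, 10, 20, 35, 50,
65, 80, 90 min) that provide whole-blood and plasma activity and, via HPLC,
the fraction of unmetabolised parent tracer. Construction follows four
steps: (1) cross-calibration of the continuous detector against the early
discrete whole-blood samples — a single multiplicative factor with the
closed-form least-squares solution Σdc/Σc²; (2) multiplication by the fitted
plasma-over-blood sigmoid; (3) spline merging with the late discrete plasma
samples on a 1-s grid; (4) multiplication by the fitted parent-fraction
sigmoid.

Both corrections use the same four-parameter sigmoid
`1 − (x₁ + x₂ t_h)/((x₃/t_h)^{x₄} + 1)` (t_h in hours), which equals 1 at
t = 0 — the parent fraction starts at unity and declines, and with negative
x₁/x₂ the same family rises above 1 for the plasma-over-blood ratio. Values
are clipped to [0, 1] (parent fraction) or to non-negative (ratio). The fit
is Nelder–Mead on the sum of squared residuals with x₃, x₄ log-transformed
and a data-driven start (asymptote from the latest sample).

Two numerical choices matter here:

* **Bridging the 15–20 min gap.** A natural cubic spline interpolating every
  noisy 1-Hz detector point can swing wildly just beyond the continuous
  window. The bridge spline is therefore anchored on three 100-s binned
  means of the continuous tail plus the late discrete samples; the binning
  error for the smooth tail is second order (≪ 1%) while the noise
  robustness gain is large.
* **Grid.** Everything downstream convolves against the input on a uniform
  1-s grid, fine enough that trapezoid convolution error is negligible
  relative to the 2% round-trip tolerance the generator tests enforce.
  Before injection the input is identically zero; negative interpolants are
  clipped to zero with a warning.

## Compartmental models (2kbv, 4kbv)

The reversible one- and two-tissue models have impulse responses that are
one or two decaying exponentials; eigenvalues and amplitudes follow from
(k₂, k₃, k₄) in the usual way, and the measured signal is
`(1 − bv)·C_tissue + bv·C_wholeblood`. Whether the tissue term should carry
the (1 − bv) factor is not universally agreed; this package adopts the
scaled convention consistently in simulation and fitting, so self-consistency
tests are exact, and the ~3% effect at bv ≈ 0.03 is documented behaviour
when comparing against conventions that omit it.

Convolution uses the exact trapezoid recursion
`y[i] = a·y[i−1] + dt/2·(x[i] + a·x[i−1])`, `a = exp(−β dt)` (evaluated in C
via `stats::filter`), not ODE stepping: it is orders of magnitude faster and
agrees with a `deSolve` reference integration to < 0.1%. β = 0 degenerates
to a running integral, which is the correct k₂ → 0 limit.

Fitting minimises the weighted residual sum of squares by Nelder–Mead with
rates log-transformed and bv logit-transformed, so the constraints hold by
construction. The conventional starting estimates (K₁ = 0.01 ml cm⁻³ min⁻¹,
k₂ = k₃ = k₄ = 0.001 min⁻¹, bv = 0.05) are tried first; because noisy
two-tissue fits can be trapped at k₄ ≈ 0 (where VT diverges), two spread
starting points are also tried and the best optimum kept, followed by
restarts from the incumbent until no improvement. A soft box on the log
scale (rates within [e⁻¹⁸, e⁶] min⁻¹) prevents simplex run-away on flat
likelihood tails; the box is far outside physiology and never binds for
well-posed fits. Non-convergence sets a flag and warns rather than failing.

## Logan graphical analysis

After subtracting a fixed vascular contribution (`fixed_bv` × whole blood,
default 0.028, with whole blood rather than plasma because bv scales a
vascular compartment), the plot of ∫TAC′/TAC′ against ∫ppIF/TAC′ over frames
with midpoint ≥ t* (default 1680 s) is fitted by ordinary least squares with
equal weights, and the slope is reported as VT without rescaling by
1/(1 − bv) — the subtraction convention used with fixed-bv Logan analyses.
Both running integrals use the same trapezoid quadrature through (0, 0) and
the frame midpoints; using a finer quadrature for the input only would break
the exact degenerate identity (TAC ∝ ppIF ⇒ slope = proportionality
constant) by the difference of the two quadratures. Points where TAC′ falls
below 1% of its own maximum are excluded as numerically unstable; at least
three usable points are required. Voxelwise maps are computed after Gaussian
pre-smoothing of each frame (2 mm FWHM, separable kernel with replicate
padding) and solve the same regression vectorised across voxels; voxels with
fewer than three valid points become NaN, and more than 50% failures aborts
with a diagnostic. The well-known noise-induced negative bias of Logan VT is
left in place (it is a property of the estimator) and is asserted
directionally in the tests.

## Spectral analysis

The TAC is modelled as a non-negative sum of input-convolved exponentials
with 100 log-spaced frequencies between 0.00063 and 0.1 s⁻¹. The slow
boundary sits slightly above the ¹¹C decay constant — components slower than
the isotope's decay are not identifiable in 90.5 min and mostly absorb
noise. Weighted NNLS is reduced to plain NNLS by row-scaling with √w and
solved by a Lawson–Hanson active-set implementation in C++ (the pure-R
solver in `pracma` is kept as the independent oracle in the test suite; the
two agree to 10⁻⁸ on random problems). VT sums αⱼ/βⱼ over all components —
no separate blood column is included, the fast boundary absorbs vascular
kinetics — and the mass on the boundary components is reported as a
diagnostic because it flags kinetics at the edge of the representable range.
Voxelwise maps use no pre-smoothing; identical voxel TACs are detected and
solved once, which makes noiseless phantoms nearly free without touching
noisy data.

## Reference-tissue models (SRTM, SRTM2)

The SRTM operational equation
`C(t) = R₁·C_r(t) + R₁(k₂′ − k₂ₐ)·C_r ⊗ e^{−k₂ₐt}` is simulated by
convolution on the fine grid. The reference TAC is linearly interpolated
through (0, 0) and the frame midpoints and then refined with per-frame
offsets so that the frame averages of the interpolant reproduce the measured
frame values exactly. Without this refinement the discretisation error
exceeds the model residual on clean data and the optimiser "fits" it with
meaningless rate constants. Regional fits use Nelder–Mead from the
conventional start (R₁ = 0.95, k₂ₐ = k₂′ = 0.001 min⁻¹) plus two spread
starts, with BP_ND = R₁k₂′/k₂ₐ − 1 reported.

A degenerate case needs a tie-break: when the target is (to numerical
precision) a pure rescaling of the reference, k₂ₐ and k₂′ are individually
unidentifiable — only their equality is determined — and BP_ND is whatever
the optimiser happens to stop at on the ridge. The fit therefore also
evaluates the pure-rescaling solution and, when it fits no worse, returns it
with k₂′ = k₂ₐ, i.e. the minimal-binding answer BP_ND = R₁ − 1 (0 for an
identical target). This is the parsimonious solution and the only one
consistent across machines.

Voxelwise SRTM2 is the standard two-pass basis-function scheme: pass 1
searches 100 log-spaced k₂ₐ candidates in [0.00063, 0.014] s⁻¹, solving the
two linear coefficients per candidate by weighted least squares; the
per-voxel reference efflux follows from k₂ = φ + R₁θ, k₂′ = k₂/R₁. Pass 2
fixes k₂′ at the unweighted global median of the pass-1 estimates inside a
tight brain mask (voxels above 40% of the 99th-percentile robust maximum of
the full-scan summation image — the mask rule is a package choice) and
re-solves each voxel with a single linear coefficient per candidate. If more
than 20% of voxels land on a θ boundary a warning is raised, since boundary
solutions signal kinetics outside the basis range.

## SUV, global radioactivity, ROI sampling

SUV images are `activity × weight / dose` on decay-corrected summation
images over frames 16–21 (30.5–60.5 min) and 22–24 (60.5–90.5 min); the
unit convention (kBq/ml × kg / MBq) is recorded in the image provenance.
The global radioactivity statistic masks voxels above one-eighth of the
whole-matrix mean and returns the masked mean. ROI sampling pools the voxels
of both hemispheric homologues (grey-matter masked where the ROI definition
says so; the brainstem is unpaired and never masked), uses the sample
(n − 1) SD, reports WS-CV = 100·SD/mean, and excludes-and-counts NaN voxels
from failed fits.

## Reliability statistics

The signed test–retest difference is the symmetric percentage
`200(test − retest)/(test + retest)`; MA-TD is the median of its absolute
value across subjects with categories low (< 10%), moderate ([10, 15)),
high ([15, 20)) and very high (≥ 20%). The ICC is the one-way random-effects
single-measures coefficient: with two sessions,
`(MS_BS − MS_WS)/(MS_BS + MS_WS)`, computed from explicit sums of squares
and verified against `aov()` to 10⁻¹² on random instances. Two definitions
are not standardised in the field and are therefore isolated behind single
functions with the adopted convention documented here: **BS-CV** is the mean
of the two per-session across-subject CVs (matching the "mean
between-subject coefficient of variation" description), and the **regional
WS-CV** used only by the outlier rule is the residual-based
`100·√(wRSS/(n − p))/mean(fitted)`. Outlier flags use value ≤ 0 or
WS-CV > 50% (regional) / > 100% (voxelwise). Region summaries take the
median and type-7 quartiles across the six comparison regions (anterior
cingulate, fusiform, hippocampus, inferior frontal, insula, occipital);
display rounding is half-away-from-zero, which is what reproduces published
tables where ties like 24.5 print as 25 and −0.465 as −0.47.

## The synthetic phantom and what it shows

The generator emulates the study conditions end to end: the 24-frame
90.5-min schedule, the continuous + discrete blood sampling scheme with a
detector gain recovered by cross-calibration, eight brain regions spanning
the binding hierarchy of an α5-targeted tracer (hippocampus VT 9.0 down to
occipital 4.0 — ratio 2.25 — with cerebellum 2.7 slightly above brainstem
2.4, both pseudo-references retaining a little specific binding), Gaussian
count-scaled voxel noise with variance `TAC/(Lᵢ·count_scale)` on
non-decay-corrected data (count_scale 0.1 gives late-frame voxel CVs around
10–15%, a realistic level that also drives the wᵢ = Lᵢ/Tᵢ weights), and a
test–retest cohort with lognormal subject multipliers (10% CV), session
multipliers (3% CV — a plausible physiological retest effect) and
per-session injected doses.

Two deliberate idealisations bound what passing tests demonstrate:

* **Fast-equilibrating kinetics.** All regions share VND = 1.5 and
  k₄ = 0.2 min⁻¹, so both tissue eigenvalues lie inside the spectral basis
  range and the Logan linear phase is reached well before t*. Real
  α5-tracer kinetics are slower; with slow eigenvalues below the basis floor,
  spectral and graphical VT are *biased low* within a 90.5-min window (a
  prototype with K₁ = 0.1, k₂ = 0.05, k₃ = 0.03, k₄ = 0.01 showed −61% for
  SA and −37% for Logan). The phantom is built to validate the estimators —
  unbiased recovery, cross-method agreement, reliability propagation — not
  to reproduce the method-dependent biases of slow tracers, which are,
  however, visible in the package if slow parameters are supplied.
* **Geometry.** The atlas is cuboids in an ellipsoidal brain on a
  32×32×16 grid of 4-mm voxels (thousands of in-brain voxels, seconds-scale
  voxelwise fits); there is no scanner point-spread function, attenuation or
  motion, so partial-volume effects are limited to the phantom's sharp
  boundaries. The grey-matter mask removes a deterministic ~14% of cortical
  ROI voxels so that masked and unmasked sampling genuinely differ.

One structural property matters for interpreting cohort results: the subject
effect is a global multiplier on all regional VT values, so it cancels
exactly in reference-tissue ratios. SRTM/SRTM2 BP_ND consequently has almost
no between-subject variance in the synthetic cohort and a low ICC despite
very low MA-TD — the same dissociation reported for pseudo-reference
variants on real data, here in exaggerated form.

Test and simulation sizes throughout (a 5-subject cohort for the end-to-end
reproducibility check, 50 subjects for the variance-components calibration,
30–100 replicates for noisy-recovery medians) were chosen as the smallest
sizes at which the checked quantities are stable, keeping the default suite
in the minutes range on a single CPU.

## Interfaces

The package is tidyverse-shaped: TACs, weights, fit summaries, ROI
statistics and reliability tables are tibbles; fitted objects have
`tidy()`/`glance()`/`augment()` methods and `autoplot()` graphics; images
are plain arrays wrapped in a light `parametric_image` class with NIfTI
readers/writers. The pipeline is driven from R: `quantify_config()` bundles
every analysis constant with its conventional default, `run_quantify()`
executes any subset of the 12 variants on one scan, `run_reliability()`
turns stacked outcomes into the reliability tables, and
`write_scan_dir()`/`write_cohort_dir()` give simulated data a standard
on-disk layout (NIfTI + blood CSV + JSON metadata and manifest). Known
limitations: no dispersion/delay correction of the continuous detector, no
motion correction or partial-volume correction, no irreversible models, no
parameter covariance estimates, and no bandpass spectral analysis for
subtype-specific binding.
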