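# dynpet

Quantification of dynamic brain PET studies and the statistics used to judge
whether a binding measure is reliable enough to take into a clinical or
research study.

`dynpet` is aimed at imaging scientists working with reversibly binding
radiotracers quantified against a metabolite-corrected arterial parent-plasma
input function (ppIF) — the setting typified by [11C]Ro15-4513, a ligand for
GABA_A receptors containing the α5 subunit, whose binding is highest in the
hippocampus and near-negligible in brainstem and cerebellum. The package
implements the full analysis chain:

1. **Input function construction** — cross-calibration of a continuous
   whole-blood detector against discrete samples, sigmoid models for the
   plasma-over-blood ratio and the parent (unmetabolised) fraction,
   `f(t) = 1 − (x₁ + x₂t)/((x₃/t)^{x₄} + 1)`, and spline merging of the
   continuous and discrete plasma segments into a ppIF on a 1-s grid.
2. **Six quantification families (12 variants)** —
   * reversible one- and two-tissue compartment models with fitted fractional
     blood volume (`2kbv`, `4kbv`; VT = K₁/k₂ and VT = K₁/k₂·(1 + k₃/k₄)),
     weighted Nelder–Mead fits;
   * Logan graphical analysis (regional and voxelwise) with fixed t* = 1680 s
     and fixed blood-volume subtraction (bv = 0.028);
   * "classic" non-regularised exponential spectral analysis by non-negative
     least squares (regional and voxelwise), 100 log-spaced basis functions in
     [0.00063, 0.1] s⁻¹, VT = Σ αⱼ/βⱼ;
   * standardised uptake values over 30.5–60.5 and 60.5–90.5 min,
     SUV = activity × weight / dose;
   * SRTM on regional TACs and two-pass basis-function SRTM2 voxelwise, using
     brainstem or cerebellum as pseudo-reference region,
     BP_ND = R₁k₂′/k₂ₐ − 1.
3. **Test–retest reliability** — symmetric percent differences
   (MA-TD = median |200·(test − retest)/(test + retest)|), between-subject
   coefficients of variation, the one-way single-measures intraclass
   correlation ICC = (MS_BS − MS_WS)/(MS_BS + MS_WS) for two sessions, region
   summaries (median, IQR) and hippocampus/occipital heterogeneity ratios.
4. **A synthetic dynamic-phantom generator** with known ground truth (frame
   schedule, blood sampling scheme, regional binding hierarchy, count-scaled
   noise, between-/within-subject variance), so the whole chain is testable
   without scanner data.

Per-frame weighting follows the count-statistics scheme wᵢ = Lᵢ/Tᵢ (frame
duration over true-coincidence rate, non-decay-corrected), normalised to
`sum = 24, max ≤ 2.5` for regional fits and to a `max/min ≤ 1000` dynamic
range voxelwise.

## Worked example

Simulate one scan, build its input function from the sampled blood data, and
quantify hippocampus (high binding) and occipital lobes (low binding) with
four variants:

```r
library(dynpet)

sched <- frame_schedule()               # 24 frames, 90.5 min, injection at 30 s
sim   <- sim_blood_samples(seed = 42)   # continuous + discrete blood sampling
ppif  <- build_ppif(sim$blood, sched)   # metabolite-corrected input function
ppif
#> <plasma_input> 5431 grid points, 0-5430 s, peak parent plasma 46.02 kBq/ml,
#>                calibration factor 1.0911

scan <- sim_phantom_dynamic(phantom_spec(), ppif, sched, seed = 42)
scan$blood <- sim$blood
scan$meta  <- scan_meta(injected_dose = 441, body_weight = 80)

cfg <- quantify_config(variants = c("4kbv", "sa_regional", "sa_voxelwise",
                                    "srtm_cerebellum"))
q <- run_quantify(scan, cfg, sched)
dplyr::filter(q, region %in% c("hippocampus", "occipital"))
#> # A tibble: 8 × 8
#>   region      variant         kind      value ws_cv    rss converged outlier
#>   <chr>       <chr>           <chr>     <dbl> <dbl>  <dbl> <lgl>     <lgl>
#> 1 hippocampus 4kbv            regional  9.27  0.400  0.259 TRUE      FALSE
#> 2 occipital   4kbv            regional  4.01  0.937  0.518 TRUE      FALSE
#> 3 hippocampus sa_regional     regional  8.74  0.409  0.285 TRUE      FALSE
#> 4 occipital   sa_regional     regional  3.92  0.972  0.528 TRUE      FALSE
#> 5 hippocampus sa_voxelwise    voxelwise 8.71  1.76  NA     TRUE      FALSE
#> 6 occipital   sa_voxelwise    voxelwise 3.95  2.43  NA     TRUE      FALSE
#> 7 hippocampus srtm_cerebellum regional  2.24  1.20   2.61  TRUE      FALSE
#> 8 occipital   srtm_cerebellum regional  0.465 1.13   0.832 TRUE      FALSE
```

The phantom's true hippocampal VT is 9.0 and occipital 4.0; the 4kbv fit
recovers both within the noise. Spectral analysis sits ~3% lower because the
measured signal carries a 4% blood-volume fraction that scales the tissue
term by (1 − bv). The SRTM BP_ND of 2.24 against cerebellum matches the VT
ratio 9.0/2.7 − 1 = 2.33. `value` is VT (ml/cm³) for plasma-input variants,
BP_ND for reference-tissue variants and SUV (g/ml) for uptake variants;
`ws_cv` is the within-ROI (voxelwise) or residual-based (regional)
coefficient of variation used by the outlier rule.

Stacking `run_quantify()` outputs over a test–retest cohort and calling
`run_reliability()` yields the per-region MA-TD/BS-CV/ICC tables, their
median (IQR) summaries across the six comparison regions, and the
heterogeneity ratios; `write_reliability_csv()` writes them in the
conventional region-by-variant layout.

The package also ships the published per-region reliability values for
[11C]Ro15-4513 (`ro15_benchmark()`); `ro15_benchmark_summaries()` recomputes
every summary row from them, e.g. a median ICC of 0.89 (IQR 0.75–0.90) for
voxelwise spectral analysis.

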