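# Shared fixtures, computed once per test run and cached.

fx_cache <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (!exists(name, envir = fx_cache)) {
    assign(name, force(expr), envir = fx_cache)
  }
  get(name, envir = fx_cache)
}

fx_schedule <- function() fx("schedule", frame_schedule())

# noiseless blood sampling and its ground-truth input
fx_clean_blood <- function() {
  fx("clean_blood", sim_blood_samples(
    seed = 3, noise_continuous = 0, noise_discrete = 0,
    noise_parent_fraction = 0
  ))
}

fx_input <- function() fx("input", fx_clean_blood()$input_true)

fx_basis <- function() fx("basis", spectral_basis(fx_input(), fx_schedule()))

# boxcar input: parent plasma == whole blood == 1 between injection and 30.5 min
fx_boxcar_input <- function() {
  fx("boxcar", {
    tg <- seq(0, 5430)
    pp <- as.numeric(tg >= 30 & tg < 1830)
    plasma_input(tg, pp, pp)
  })
}

# fast-equilibrating two-tissue benchmark: VT = 8, eigenvalues inside the
# spectral band, so graphical/spectral methods are unbiased within the scan
fx_benchmark_params <- function(bv = 0) {
  kinetic_params(0.5, 0.5, 0.7, 0.1, bv = bv)
}

fx_benchmark_tac <- function() {
  fx("benchmark_tac",
     simulate_tissue_tac(fx_benchmark_params(), fx_input(), fx_schedule()))
}

# noiseless default phantom
fx_phantom_clean <- function() {
  fx("phantom_clean", sim_phantom_dynamic(
    phantom_spec(count_scale = 0), fx_input(), fx_schedule(), seed = 2
  ))
}

tac_values <- function(tac, region = NULL) {
  if (is.null(region)) region <- unique(tac$region)[[1]]
  tac$activity[tac$region == region]
}

# uniform 4D image where every voxel carries the same TAC
uniform_dyn <- function(values, dim3 = c(6, 6, 4)) {
  array(rep(values, each = prod(dim3)), c(dim3, length(values)))
}
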