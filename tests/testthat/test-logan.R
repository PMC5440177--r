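test_that("Logan slope equals VT for noiseless reversible kinetics", {
  sched <- fx_schedule()
  input <- fx_input()
  # one-tissue tracer, VT = 5
  tac1 <- simulate_tissue_tac(kinetic_params(0.3, 0.06, bv = 0), input, sched)
  f1 <- logan_regional(tac1, input, fixed_bv = 0)
  expect_equal(f1$vt, 5, tolerance = 0.02)

  # instant-equilibrium degenerate case: TAC = c * ppIF gives slope c
  c0 <- 3.7
  pp_mid <- approx(input$time, input$parent_plasma, frame_midpoints(sched))$y
  taceq <- pet_tac(sched, c0 * pp_mid)
  feq <- logan_regional(taceq, input, fixed_bv = 0)
  expect_equal(feq$vt, c0, tolerance = 1e-3)

  # fast-equilibrating two-tissue benchmark, VT = 8, fixed bv matching the
  # generating bv (zero here; with bv > 0 the measured tissue term is scaled
  # by 1 - bv, which the slope inherits by design)
  tac4 <- simulate_tissue_tac(fx_benchmark_params(bv = 0), input, sched)
  f4 <- logan_regional(tac4, input, fixed_bv = 0)
  expect_equal(f4$vt, 8, tolerance = 0.03)
})

test_that("Logan slope is invariant to joint rescaling and stable in t*", {
  sched <- fx_schedule()
  input <- fx_input()
  tac <- simulate_tissue_tac(fx_benchmark_params(), input, sched)
  f <- logan_regional(tac, input, fixed_bv = 0)
  scaled_in <- plasma_input(input$time, 4 * input$parent_plasma,
                            4 * input$whole_blood)
  tac_s <- pet_tac(sched, 4 * tac_values(tac))
  f_s <- logan_regional(tac_s, scaled_in, fixed_bv = 0)
  expect_equal(f_s$vt, f$vt, tolerance = 1e-9)

  # the asymptote is reached: a later t* moves the slope by < 1%
  f_late <- logan_regional(tac, input, t_star = 2400, fixed_bv = 0)
  expect_lt(abs(f_late$vt - f$vt) / f$vt, 0.01)

  expect_error(logan_regional(tac, input, t_star = 6000), "within the scan")
})

test_that("voxelwise Logan reduces to the regional result on uniform data", {
  sched <- fx_schedule()
  input <- fx_input()
  tac <- simulate_tissue_tac(fx_benchmark_params(bv = 0.028), input, sched)
  dyn <- uniform_dyn(tac_values(tac))
  mask <- array(TRUE, dim(dyn)[1:3])
  map <- logan_voxelwise(dyn, input, sched, mask, voxel_mm = 4)
  freg <- logan_regional(tac, input)
  vals <- map[attr(map, "mask")]
  expect_equal(max(abs(vals - freg$vt)), 0, tolerance = 1e-6)

  # all-background mask: nothing fitted
  empty <- logan_voxelwise(dyn, input, sched,
                           array(FALSE, dim(dyn)[1:3]), voxel_mm = 4)
  expect_equal(attr(empty, "provenance")$n_fitted, 0L)
  expect_true(all(is.nan(unclass(empty))))
})

test_that("two-region noiseless phantom: voxelwise matches regional Logan", {
  ph <- fx_phantom_clean()
  sched <- fx_schedule()
  input <- fx_input()
  map <- logan_voxelwise(ph$dyn, input, sched, ph$brain_mask,
                         presmooth_fwhm_mm = 0, voxel_mm = 4)
  stats <- sample_parametric(map, ph$labels, ph$rois, gm_mask = ph$gm_mask)
  tacs <- roi_tacs(ph$dyn, sched, ph$labels, ph$rois, gm_mask = ph$gm_mask)
  for (r in c("hippocampus", "occipital")) {
    reg <- logan_regional(pet_tac(sched, tac_values(tacs, r)), input)
    expect_equal(stats$mean[stats$region == r], reg$vt, tolerance = 0.03)
  }
})

test_that("noise induces the known negative Logan bias voxelwise", {
  sched <- fx_schedule()
  input <- fx_input()
  spec <- phantom_spec()          # default count-scaled noise
  ph <- sim_phantom_dynamic(spec, input, sched, seed = 9)
  map <- logan_voxelwise(ph$dyn, input, sched, ph$brain_mask, voxel_mm = 4)
  tacs <- roi_tacs(ph$dyn, sched, ph$labels, ph$rois, gm_mask = ph$gm_mask)
  reg <- logan_regional(pet_tac(sched, tac_values(tacs, "hippocampus")), input)
  vox <- median(map[ph$labels %in%
                      ph$rois$labels[[which(ph$rois$region == "hippocampus")]] &
                      is.finite(map)])
  expect_lte(vox, reg$vt + 1e-9)
})
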