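test_that("VT follows the compartmental formulas", {
  expect_equal(vt_from_params(kinetic_params(0.1, 0.05)), 2)
  expect_equal(vt_from_params(kinetic_params(0.1, 0.05, 0.03, 0.01)), 8)
  # k3 = 0 collapses the two-tissue VT onto the one-tissue VT
  expect_equal(vt_from_params(kinetic_params(0.1, 0.05, 0, 0.01)),
               vt_from_params(kinetic_params(0.1, 0.05)))
  expect_error(vt_from_params(kinetic_params(0.1, 0)), "k2 > 0")
  expect_error(kinetic_params(-0.1, 0.05), "non-negative")
  expect_error(kinetic_params(0.1, 0.05, bv = 1), "bv")
})

test_that("forward model limits: no influx, and the integrator limit", {
  sched <- fx_schedule()
  input <- fx_input()
  # K1 = 0: the tissue term vanishes, only the vascular term remains
  tac0 <- simulate_tissue_tac(kinetic_params(0, 1, bv = 0.1), input, sched)
  wb <- approx(input$time, input$whole_blood, frame_midpoints(sched))$y
  expect_equal(tac_values(tac0), 0.1 * wb, tolerance = 0.02)
  # bv = 0, k2 -> 0: the model integrates the input, K1 * int ppIF
  k1 <- 0.3
  taci <- simulate_tissue_tac(kinetic_params(k1, 1e-12, bv = 0), input, sched)
  cum <- cumsum(input$parent_plasma) / 60   # 1-s grid, rates per minute
  expected <- k1 * approx(input$time, cum, frame_midpoints(sched))$y
  expect_equal(tac_values(taci), expected, tolerance = 0.02)
})

test_that("forward simulation matches an independent ODE solver", {
  sched <- fx_schedule()
  input <- fx_boxcar_input()
  p <- kinetic_params(0.1, 0.05, 0.03, 0.01, bv = 0)
  tac <- simulate_tissue_tac(p, input, sched)
  # deSolve integration of the two-tissue system in minutes
  cp <- function(t_min) as.numeric(t_min >= 0.5 & t_min < 30.5)
  rhs <- function(t, y, parms) {
    list(c(
      p$K1 * cp(t) - (p$k2 + p$k3) * y[1] + p$k4 * y[2],
      p$k3 * y[1] - p$k4 * y[2]
    ))
  }
  mids_min <- frame_midpoints(sched) / 60
  sol <- deSolve::ode(c(0, 0), c(0, mids_min), rhs, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-10)
  ct_mid <- rowSums(sol[-1, 2:3, drop = FALSE])
  # compare at frame midpoints away from the boxcar edges
  keep <- abs(frame_midpoints(sched) - 30) > 60 &
    abs(frame_midpoints(sched) - 1830) > 160
  expect_equal(tac_values(tac)[keep], ct_mid[keep], tolerance = 1e-3)
})

test_that("forward model is linear in the input amplitude", {
  sched <- fx_schedule()
  input <- fx_input()
  p <- fx_benchmark_params(bv = 0.04)
  tac1 <- simulate_tissue_tac(p, input, sched)
  scaled <- plasma_input(input$time, 2.5 * input$parent_plasma,
                         2.5 * input$whole_blood)
  tac2 <- simulate_tissue_tac(p, scaled, sched)
  expect_equal(tac_values(tac2), 2.5 * tac_values(tac1), tolerance = 1e-12)
})

test_that("noiseless self-consistency: fits recover the generating VT", {
  sched <- fx_schedule()
  input <- fx_input()
  tac2 <- simulate_tissue_tac(kinetic_params(0.1, 0.05, bv = 0.05),
                              input, sched)
  f2 <- fit_compartmental(tac2, input, model = "2kbv")
  expect_equal(f2$vt, 2, tolerance = 0.01)
  expect_true(f2$converged)

  tac4 <- simulate_tissue_tac(kinetic_params(0.1, 0.05, 0.03, 0.01, bv = 0.03),
                              input, sched)
  f4 <- fit_compartmental(tac4, input, model = "4kbv")
  expect_equal(f4$vt, 8, tolerance = 0.02)

  # weighted RSS at the optimum beats the starting estimates by construction
  start_pred <- simulate_tissue_tac(kinetic_params(0.01, 0.001, bv = 0.05),
                                    input, sched)
  rss_start <- sum((tac_values(tac2) - tac_values(start_pred))^2)
  expect_lt(f2$weighted_rss, rss_start)
})

test_that("4kbv nests 2kbv: fitting richer model to 1-tissue data", {
  sched <- fx_schedule()
  input <- fx_input()
  tac <- simulate_tissue_tac(kinetic_params(0.2, 0.1, bv = 0.02), input, sched)
  f <- suppressWarnings(fit_compartmental(tac, input, model = "4kbv"))
  # VT matches the 1-tissue truth; the specific compartment contributes ~0
  expect_equal(f$vt, 2, tolerance = 0.02)
  expect_lt(f$params$k3 / f$params$k4 * (f$params$K1 / f$params$k2), 0.1 * 2)
})

test_that("count-scaled noisy replicates recover VT in the median", {
  sched <- fx_schedule()
  input <- fx_input()
  act <- tac_values(simulate_tissue_tac(
    kinetic_params(0.1, 0.05, 0.03, 0.01, bv = 0.03), input, sched))
  mids <- frame_midpoints(sched)
  dec <- exp(-lambda_c11() * mids)
  # ROI-scale counts: voxel count_scale 0.1 pooled over ~150 voxels
  sd_dc <- sqrt(pmax(act * dec, 1e-3) / (sched$duration * 15)) / dec
  w <- normalize_weights(
    compute_frame_weights(sched, pmax(act * dec, 1e-3) * 15), "roi")
  set.seed(42)
  vts <- replicate(30, {
    noisy <- pet_tac(sched, pmax(act + rnorm(24, 0, sd_dc), 0))
    suppressWarnings(fit_compartmental(noisy, input, w, model = "4kbv",
                                       restarts = 1, max_iter = 2000)$vt)
  })
  expect_equal(median(vts), 8, tolerance = 0.05)
})

test_that("degenerate flat TACs are rejected", {
  sched <- fx_schedule()
  input <- fx_input()
  flat <- pet_tac(sched, rep(0, 24))
  expect_error(fit_compartmental(flat, input, model = "2kbv"), "flat TAC")
})
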