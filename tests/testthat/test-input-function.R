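test_that("sigmoid model has the right limits and identities", {
  m <- sigmoid_model(0.5, 0.1, 0.3, 2, kind = "parent_fraction")
  # value tends to 1 as t -> 0 and equals 1 at t = 0
  expect_equal(eval_sigmoid(m, 0), 1)
  expect_equal(eval_sigmoid(m, 1e-6), 1, tolerance = 1e-6)
  # x1 = x2 = 0 gives identically 1
  m0 <- sigmoid_model(0, 0, 0.3, 2)
  expect_equal(eval_sigmoid(m0, c(0, 10, 1000, 5430)), rep(1, 4))
  # large x4 and t >> x3: asymptote 1 - x1
  msharp <- sigmoid_model(0.5, 0, 1e-3, 50)
  expect_equal(eval_sigmoid(msharp, 2 * 3600), 0.5, tolerance = 1e-6)
  # parent fraction clipped to [0, 1]
  mneg <- sigmoid_model(2, 0, 0.01, 2, kind = "parent_fraction")
  expect_gte(min(eval_sigmoid(mneg, seq(0, 5430, 60))), 0)
  expect_error(eval_sigmoid(m, -5), "non-negative")
  expect_error(sigmoid_model(0, 0, -1, 2), "x3")
})

test_that("fit_sigmoid recovers noiseless curves and tracks noisy ones", {
  truth <- sigmoid_model(0.75, 0.05, 0.3, 2, kind = "parent_fraction")
  t_s <- c(0, c(4, 6, 8, 10, 20, 35, 50, 65, 80, 90) * 60)
  v <- eval_sigmoid(truth, t_s)
  fit <- fit_sigmoid(t_s, v, kind = "parent_fraction")
  expect_lt(max(abs(eval_sigmoid(fit, t_s) - v)), 1e-3)

  # constant data stay constant
  cfit <- fit_sigmoid(t_s, rep(1, length(t_s)), kind = "parent_fraction")
  expect_equal(eval_sigmoid(cfit, t_s), rep(1, length(t_s)), tolerance = 1e-6)

  # noisy data: fitted-curve RMSE no worse than twice the noise SD
  set.seed(7)
  sigma <- 0.02
  vn <- pmin(pmax(v + rnorm(length(v), 0, sigma), 0), 1)
  nfit <- fit_sigmoid(t_s, vn, kind = "parent_fraction")
  rmse <- sqrt(mean((eval_sigmoid(nfit, t_s) - eval_sigmoid(truth, t_s))^2))
  expect_lt(rmse, 2 * sigma)

  expect_error(fit_sigmoid(c(0, 60, 120), c(1, 0.9, 0.8)), "4 data points")
})

test_that("cross-calibration recovers scale factors by least squares", {
  tc <- seq(0, 900)
  curve <- 20 * exp(-tc / 400)
  cont <- tibble::tibble(time_s = tc, activity = curve)
  disc_t <- c(4, 6, 8, 10) * 60
  disc <- tibble::tibble(time_s = disc_t,
                         activity = 20 * exp(-disc_t / 400))
  expect_equal(as.numeric(cross_calibrate(cont, disc)), 1, tolerance = 1e-12)

  # continuous at half scale: factor 2 restores it
  cont_half <- tibble::tibble(time_s = tc, activity = curve / 2)
  expect_equal(as.numeric(cross_calibrate(cont_half, disc)), 2,
               tolerance = 1e-12)

  # noisy case matches the closed form sum(d*c) / sum(c^2)
  set.seed(11)
  dn <- disc$activity * (1 + rnorm(4, 0, 0.05))
  chat <- approx(tc, curve, disc_t)$y
  expect_equal(
    as.numeric(cross_calibrate(cont, tibble::tibble(time_s = disc_t,
                                                    activity = dn))),
    sum(dn * chat) / sum(chat^2), tolerance = 1e-12
  )
  expect_error(
    cross_calibrate(cont, tibble::tibble(time_s = 5000, activity = 1)),
    "inside the continuous window"
  )
})

test_that("build_ppif degenerates correctly for trivial correction models", {
  sched <- fx_schedule()
  unit <- sigmoid_model(0, 0, 0.3, 2, kind = "parent_fraction")
  unit_pob <- sigmoid_model(0, 0, 0.3, 2, kind = "plasma_over_blood")
  # blood data generated with plasma == whole blood and no metabolites
  sim <- sim_blood_samples(
    input_function_model(pob = unit_pob, parent = unit),
    sched, seed = 5, noise_continuous = 0, noise_discrete = 0,
    noise_parent_fraction = 0
  )
  # parent fraction and plasma-over-blood both 1: ppIF equals calibrated blood
  pp <- build_ppif(sim$blood, sched, pob = unit_pob, parent = unit)
  expect_equal(pp$parent_plasma, pp$whole_blood, tolerance = 1e-9)

  # halving the parent fraction halves the ppIF exactly
  half <- sigmoid_model(1, 0, 1, 1e-9, kind = "parent_fraction")
  expect_equal(max(abs(eval_sigmoid(half, seq(30, 5430)) - 0.5)), 0,
               tolerance = 1e-6)
  pp_half <- build_ppif(sim$blood, sched, pob = unit_pob, parent = half)
  expect_equal(pp_half$parent_plasma, pp$parent_plasma / 2, tolerance = 1e-6)
})

test_that("ppIF construction round-trips the synthetic generator within 2%", {
  sched <- fx_schedule()
  sim <- fx_clean_blood()
  pp <- build_ppif(sim$blood, sched)
  truth <- sim$input_true
  sel <- truth$time >= 60 & truth$time <= 5400
  rel <- abs(pp$parent_plasma[sel] - truth$parent_plasma[sel]) /
    truth$parent_plasma[sel]
  expect_lt(max(rel), 0.02)
  # calibration factor undoes the detector gain used by the generator
  expect_equal(pp$calibration_factor, 1 / 0.92, tolerance = 1e-6)
  # non-negative, zero before injection
  expect_true(all(pp$parent_plasma >= 0))
  expect_true(all(pp$parent_plasma[pp$time < 30] == 0))
})

test_that("build_ppif is homogeneous of degree 1 in blood activities", {
  sched <- fx_schedule()
  b <- fx_clean_blood()$blood
  scaled <- blood_samples(
    b$continuous_time, 3 * b$continuous_whole_blood,
    b$discrete_time, 3 * b$discrete_whole_blood, 3 * b$discrete_plasma,
    b$parent_fraction_time, b$parent_fraction
  )
  pp1 <- build_ppif(b, sched)
  pp3 <- build_ppif(scaled, sched)
  sel <- pp1$parent_plasma > 1e-6
  expect_equal(pp3$parent_plasma[sel], 3 * pp1$parent_plasma[sel],
               tolerance = 1e-6)
})

test_that("blood and ppIF tables survive a CSV round trip", {
  withr::with_tempdir({
    b <- fx_clean_blood()$blood
    write_blood_csv(b, "blood.csv")
    b2 <- read_blood_csv("blood.csv")
    expect_equal(b2$continuous_whole_blood, b$continuous_whole_blood,
                 tolerance = 1e-9)
    expect_equal(b2$discrete_plasma, b$discrete_plasma, tolerance = 1e-9)
    expect_equal(b2$parent_fraction, b$parent_fraction, tolerance = 1e-9)

    pp <- fx_input()
    write_ppif_csv(pp, "ppif.csv")
    df <- utils::read.csv("ppif.csv")
    expect_equal(df$parent_plasma_kBq_per_ml, pp$parent_plasma,
                 tolerance = 1e-9)
  })
})
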