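test_that("default frame schedule matches the acquisition protocol", {
  sched <- fx_schedule()
  expect_equal(nrow(sched), 24L)
  expect_equal(max(sched$t_end), 5430)           # 90.5 min
  expect_equal(sched$t_start[-1], sched$t_end[-24])  # contiguous
  expect_true(all(sched$duration > 0))
  # cumulative sums of the printed durations place frame 6 at [90, 150) s
  expect_equal(unname(sched$t_start[6]), 90)
  expect_equal(unname(sched$t_end[6]), 150)
  # SUV windows: frames 16-21 span 30.5-60.5 min, frames 22-24 span 60.5-90.5
  expect_equal(sched$t_start[16] / 60, 30.5)
  expect_equal(sched$t_end[21] / 60, 60.5)
  expect_equal(sched$t_end[24] / 60, 90.5)
})

test_that("frame_schedule validates and handles single-frame layouts", {
  one <- frame_schedule(tibble::tibble(count = 1L, duration_s = 10))
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$t_start, one$t_end), c(0, 10))
  expect_error(frame_schedule(tibble::tibble(count = 1L, duration_s = 0)),
               "positive")
  expect_error(frame_schedule(tibble::tibble(count = integer(),
                                             duration_s = numeric())),
               "non-empty")
})

test_that("decay correction scales by exp(lambda t_mid) and round-trips", {
  sched <- fx_schedule()
  lambda <- attr(sched, "decay_constant")
  # half-life midpoint gives factor 2
  t_half <- log(2) / lambda
  expect_equal(exp(lambda * t_half), 2)
  expect_equal(t_half, 1224, tolerance = 1e-3)

  # constant true activity measured with decay is restored exactly
  mids <- frame_midpoints(sched)
  measured <- pet_tac(sched, 5 * exp(-lambda * mids), decay_corrected = FALSE)
  corrected <- decay_correct(measured, "apply")
  expect_equal(tac_values(corrected), rep(5, 24), tolerance = 1e-12)

  # round trip is the identity
  back <- decay_correct(corrected, "remove")
  expect_equal(tac_values(back), tac_values(measured), tolerance = 1e-12)

  # zero decay constant leaves values untouched
  s0 <- frame_schedule(decay_constant = 1e-300)
  tac0 <- pet_tac(s0, 1:24, decay_corrected = FALSE)
  expect_equal(tac_values(decay_correct(tac0, "apply")),
               as.numeric(1:24), tolerance = 1e-12)

  expect_error(decay_correct(corrected, "apply"), "already")
  expect_error(decay_correct(measured, "remove"), "not decay-corrected")
})

test_that("sum_frames is a duration-weighted mean that preserves constants", {
  sched <- fx_schedule()
  vals <- seq(2, 48, by = 2)
  dyn <- uniform_dyn(vals)
  one <- sum_frames(dyn, sched, c(7, 7))
  expect_equal(one[2, 3, 1], vals[7])
  # uniform value c is conserved over any range
  dync <- uniform_dyn(rep(3.5, 24))
  expect_equal(max(abs(sum_frames(dync, sched, c(1, 24)) - 3.5)), 0)
  # hand-computed duration weighting over frames 1-2
  expect_equal(sum_frames(dyn, sched, c(1, 2))[1, 1, 1],
               (vals[1] * 30 + vals[2] * 15) / 45)
  expect_error(sum_frames(dyn, sched, c(5, 2)), "range")
  expect_error(sum_frames(dyn, sched, c(0, 2)), "range")
})

test_that("frame weights follow w = L/T and respect both normalisations", {
  sched2 <- frame_schedule(tibble::tibble(count = 2L, duration_s = c(30, 60)))
  w <- compute_frame_weights(
    frame_schedule(tibble::tibble(count = c(1L, 1L), duration_s = c(30, 60))),
    c(10, 10)
  )
  expect_equal(w$weight, c(3, 6))
  # homogeneity: doubling T halves w
  w2 <- compute_frame_weights(
    frame_schedule(tibble::tibble(count = c(1L, 1L), duration_s = c(30, 60))),
    c(20, 20)
  )
  expect_equal(w2$weight, w$weight / 2)

  sched <- fx_schedule()
  # equal durations and rates give equal weights
  weq <- compute_frame_weights(
    frame_schedule(tibble::tibble(count = 24L, duration_s = 300)),
    rep(7, 24)
  )
  roi <- normalize_weights(weq, "roi")
  expect_equal(roi$weight, rep(1, 24), tolerance = 1e-12)

  # dominated raw weight is clipped at 2.5 and sum stays 24
  wdom <- compute_frame_weights(sched, c(0.1, rep(1, 23)))
  roi2 <- normalize_weights(wdom, "roi")
  expect_lte(max(roi2$weight), 2.5 + 1e-9)
  expect_equal(sum(roi2$weight), 24, tolerance = 1e-9)

  # voxel mode caps the dynamic range at exactly 1000
  wv <- compute_frame_weights(
    frame_schedule(tibble::tibble(count = c(1L, 1L), duration_s = c(2000, 1))),
    c(1, 1)
  )
  vox <- normalize_weights(wv, "voxel")
  expect_equal(max(vox$weight) / min(vox$weight), 1000)

  expect_error(compute_frame_weights(sched, rep(0, 24)), "positive")
})

test_that("ROI weight constraints hold for random positive inputs", {
  sched <- fx_schedule()
  set.seed(101)
  for (i in 1:50) {
    raw <- compute_frame_weights(sched, stats::rlnorm(24, 0, runif(1, 0.1, 3)))
    roi <- normalize_weights(raw, "roi")
    expect_equal(sum(roi$weight), 24, tolerance = 1e-9)
    expect_lte(max(roi$weight), 2.5 + 1e-9)
    vox <- normalize_weights(raw, "voxel")
    expect_lte(max(vox$weight) / min(vox$weight), 1000 + 1e-9)
    expect_true(all(vox$weight > 0))
  }
})

test_that("TAC tables survive a CSV round trip with their metadata", {
  sched <- fx_schedule()
  tac <- pet_tac(sched, cbind(a = 1:24 / 2, b = sqrt(1:24)),
                 region = c("a", "b"), decay_corrected = FALSE)
  withr::with_tempdir({
    write_tac_csv(tac, "tac.csv")
    back <- read_tac_csv("tac.csv")
    expect_equal(back$activity, tac$activity, tolerance = 1e-12)
    expect_equal(unique(back$region), c("a", "b"))
    expect_false(attr(back, "decay_corrected"))
    expect_equal(attr(back, "schedule")$duration, sched$duration)
  })
})
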