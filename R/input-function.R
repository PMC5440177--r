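# Construction of the metabolite-corrected arterial parent-plasma input
# function (ppIF) from continuous and discrete blood sampling.

#' Arterial blood sampling data
#'
#' Container for one scan's blood data: the continuously withdrawn
#' whole-blood detector curve (first ~15 min), discrete whole-blood and
#' plasma samples (centrifuged syringe samples), and the measured parent
#' fraction (HPLC) at the discrete sample times.
#'
#' @param continuous_time,continuous_whole_blood Continuous detector curve:
#'   times (s) and whole-blood activity (kBq/ml).
#' @param discrete_time Times (s) of the discrete samples.
#' @param discrete_whole_blood,discrete_plasma Whole-blood and plasma
#'   activity (kBq/ml) of the discrete samples.
#' @param parent_fraction_time,parent_fraction Times (s) and measured parent
#'   fraction in \[0, 1\].
#' @return A `blood_samples` object.
#' @export
blood_samples <- function(continuous_time, continuous_whole_blood,
                          discrete_time, discrete_whole_blood,
                          discrete_plasma,
                          parent_fraction_time, parent_fraction) {
  series_ok <- function(t, nm) {
    if (is.unsorted(t, strictly = TRUE)) {
      abort(sprintf("`%s` times must be strictly increasing.", nm))
    }
  }
  series_ok(continuous_time, "continuous")
  series_ok(discrete_time, "discrete")
  series_ok(parent_fraction_time, "parent_fraction")
  structure(
    list(
      continuous_time = continuous_time,
      continuous_whole_blood = continuous_whole_blood,
      discrete_time = discrete_time,
      discrete_whole_blood = discrete_whole_blood,
      discrete_plasma = discrete_plasma,
      parent_fraction_time = parent_fraction_time,
      parent_fraction = parent_fraction
    ),
    class = "blood_samples"
  )
}

#' @export
print.blood_samples <- function(x, ...) {
  cat(sprintf(
    "<blood_samples> continuous: %d points (%.0f-%.0f s); discrete: %d samples; parent fraction: %d samples\n",
    length(x$continuous_time), min(x$continuous_time), max(x$continuous_time),
    length(x$discrete_time), length(x$parent_fraction_time)
  ))
  invisible(x)
}

#' Cross-calibrate the continuous detector against discrete samples
#'
#' The continuous whole-blood detector has its own efficiency; a single
#' multiplicative factor is estimated by least squares between the discrete
#' whole-blood samples falling inside the continuous window (nominally the
#' 4, 6, 8 and 10 min samples) and the time-interpolated continuous curve.
#' The closed form is `sum(d * c) / sum(c^2)` for discrete values `d` and
#' interpolated continuous values `c`.
#'
#' @param continuous Data frame with columns `time_s`, `activity`.
#' @param discrete Data frame with columns `time_s`, `activity`.
#' @param injection_time Samples at or before this time are ignored.
#' @return The scalar calibration factor, with attribute `n_samples`.
#' @export
cross_calibrate <- function(continuous, discrete, injection_time = 30) {
  use <- discrete$time_s > injection_time &
    discrete$time_s >= min(continuous$time_s) &
    discrete$time_s <= max(continuous$time_s)
  if (!any(use)) abort("No discrete samples fall inside the continuous window.")
  chat <- approx(continuous$time_s, continuous$activity,
                 discrete$time_s[use])$y
  d <- discrete$activity[use]
  if (sum(chat^2) == 0) abort("Continuous curve is zero at all calibration times.")
  factor <- sum(d * chat) / sum(chat^2)
  attr(factor, "n_samples") <- sum(use)
  factor
}

#' Assemble a plasma input function from curves
#'
#' Constructor for users who already have a metabolite-corrected parent
#' plasma curve (and its companion whole-blood curve) on a fine time grid,
#' e.g. read from a ppIF CSV. [build_ppif()] is the full construction from
#' raw blood samples.
#'
#' @param time Time grid in seconds, uniform with spacing <= 1 s.
#' @param parent_plasma Parent plasma activity (kBq/ml) on `time`.
#' @param whole_blood Whole-blood activity (kBq/ml) on `time`; defaults to
#'   `parent_plasma` (adequate only when no vascular term is used).
#' @param calibration_factor Continuous-detector calibration factor, for
#'   provenance.
#' @return A `plasma_input` object.
#' @export
plasma_input <- function(time, parent_plasma, whole_blood = parent_plasma,
                         calibration_factor = 1) {
  if (length(time) < 2 || max(diff(time)) > 1 + 1e-9) {
    abort("`time` must be a fine grid with spacing <= 1 s.")
  }
  if (any(parent_plasma < 0) || any(whole_blood < 0)) {
    abort("Input curves must be non-negative.")
  }
  new_plasma_input(time, parent_plasma, whole_blood,
                   calibration_factor = calibration_factor)
}

new_plasma_input <- function(time, parent_plasma, whole_blood,
                             calibration_factor = 1, models = NULL) {
  structure(
    list(
      time = time,
      parent_plasma = parent_plasma,
      whole_blood = whole_blood,
      calibration_factor = calibration_factor,
      models = models
    ),
    class = "plasma_input"
  )
}

assert_input <- function(input) {
  if (!inherits(input, "plasma_input")) {
    abort("Expected a `plasma_input` object (see `build_ppif()`).")
  }
  invisible(input)
}

#' @export
print.plasma_input <- function(x, ...) {
  cat(sprintf(
    "<plasma_input> %d grid points, 0-%.0f s, peak parent plasma %.2f kBq/ml, calibration factor %.4f\n",
    length(x$time), max(x$time), max(x$parent_plasma), x$calibration_factor
  ))
  invisible(x)
}

#' @export
as_tibble.plasma_input <- function(x, ...) {
  tibble(
    time_s = x$time,
    parent_plasma_kBq_per_ml = x$parent_plasma,
    whole_blood_kBq_per_ml = x$whole_blood
  )
}

#' Build the parent-plasma input function from blood samples
#'
#' Follows the standard four-step construction: (1) cross-calibration of the
#' continuous whole-blood detector against the early discrete samples;
#' (2) multiplication of the calibrated continuous curve by the fitted
#' plasma-over-blood sigmoid to obtain continuous plasma activity;
#' (3) merging with the late discrete plasma samples by natural cubic spline
#' on a 1-s grid; (4) multiplication by the fitted parent-fraction sigmoid.
#' The whole-blood curve is retained on the same grid (continuous segment
#' plus a spline through the discrete whole-blood samples) for vascular
#' terms in the tissue models.
#'
#' @param blood A [blood_samples()] object.
#' @param schedule The acquisition [frame_schedule()]; fixes the grid extent
#'   and the injection time before which the input is zero.
#' @param pob,parent Optional pre-fitted [sigmoid_model()]s for the
#'   plasma-over-blood ratio and the parent fraction; fitted from `blood`
#'   when `NULL`.
#' @param dt Grid spacing in seconds (must be <= 1 for convolution accuracy).
#' @return A `plasma_input` object with fields `time`, `parent_plasma`,
#'   `whole_blood`, `calibration_factor` and `models`.
#' @export
build_ppif <- function(blood, schedule, pob = NULL, parent = NULL, dt = 1) {
  if (!inherits(blood, "blood_samples")) {
    abort("`blood` must be a `blood_samples` object.")
  }
  assert_schedule(schedule)
  if (dt > 1) abort("`dt` must be <= 1 s for convolution accuracy.")
  tinj <- attr(schedule, "injection_time")
  tg <- fine_grid(schedule, dt)

  cal <- cross_calibrate(
    tibble(time_s = blood$continuous_time,
           activity = blood$continuous_whole_blood),
    tibble(time_s = blood$discrete_time,
           activity = blood$discrete_whole_blood),
    injection_time = tinj
  )
  cont_t <- blood$continuous_time
  cont_wb <- blood$continuous_whole_blood * as.numeric(cal)

  if (is.null(pob)) {
    post <- blood$discrete_time > tinj & is.finite(blood$discrete_plasma) &
      blood$discrete_whole_blood > 0
    pob <- fit_sigmoid(blood$discrete_time[post],
                       blood$discrete_plasma[post] /
                         blood$discrete_whole_blood[post],
                       kind = "plasma_over_blood")
  }
  if (is.null(parent)) {
    parent <- fit_sigmoid(blood$parent_fraction_time, blood$parent_fraction,
                          kind = "parent_fraction")
  }

  cont_plasma <- cont_wb * eval_sigmoid(pob, cont_t)

  late <- blood$discrete_time > max(cont_t)
  if (!any(late)) {
    abort("No discrete plasma samples beyond the continuous window; cannot cover the scan.")
  }
  if (min(blood$discrete_time[late]) - max(cont_t) > 900) {
    warn("Gap of more than 15 min between continuous and discrete plasma segments.")
  }
  # bridge the 15-20 min gap with a natural spline anchored on noise-robust
  # binned means of the continuous tail (interpolating through every noisy
  # 1-Hz detector sample would let the spline swing wildly beyond 15 min)
  t_tail <- max(cont_t)
  bins <- list(c(t_tail - 300, t_tail - 200), c(t_tail - 200, t_tail - 100),
               c(t_tail - 100, t_tail))
  anchor <- function(values) {
    vapply(bins, function(b) {
      sel <- cont_t >= b[1] & cont_t <= b[2]
      c(mean(cont_t[sel]), mean(values[sel]))
    }, numeric(2))
  }
  bridge <- function(values, late_t, late_v, xout) {
    a <- anchor(values)
    spline(c(a[1, ], late_t), c(a[2, ], late_v), xout = xout,
           method = "natural")$y
  }
  early <- tg <= t_tail
  plasma <- numeric(length(tg))
  plasma[early] <- approx(cont_t, cont_plasma, tg[early], rule = 2)$y
  plasma[!early] <- bridge(cont_plasma, blood$discrete_time[late],
                           blood$discrete_plasma[late], tg[!early])
  wb <- numeric(length(tg))
  wb[early] <- approx(cont_t, cont_wb, tg[early], rule = 2)$y
  wb[!early] <- bridge(cont_wb, blood$discrete_time[late],
                       blood$discrete_whole_blood[late], tg[!early])

  if (any(plasma < 0) || any(wb < 0)) {
    warn("Negative interpolated blood values clipped to zero.")
  }
  plasma <- pmax(plasma, 0)
  wb <- pmax(wb, 0)
  ppif <- plasma * eval_sigmoid(parent, tg)
  ppif[tg < tinj] <- 0
  wb[tg < tinj] <- 0

  new_plasma_input(tg, ppif, wb,
                   calibration_factor = as.numeric(cal),
                   models = list(plasma_over_blood = pob, parent = parent))
}

#' Read or write blood sampling tables
#'
#' The CSV layout has one row per measurement: `time_s`, `source`
#' (`continuous` or `discrete`), `whole_blood_kBq_per_ml`,
#' `plasma_kBq_per_ml` (blank where unmeasured) and `parent_fraction`
#' (blank where unmeasured).
#'
#' @param blood A [blood_samples()] object.
#' @param path File path.
#' @return `read_blood_csv()` returns a [blood_samples()] object;
#'   `write_blood_csv()` returns `path` invisibly.
#' @export
write_blood_csv <- function(blood, path) {
  cont <- tibble(
    time_s = blood$continuous_time,
    source = "continuous",
    whole_blood_kBq_per_ml = blood$continuous_whole_blood,
    plasma_kBq_per_ml = NA_real_,
    parent_fraction = NA_real_
  )
  disc <- tibble(
    time_s = blood$discrete_time,
    source = "discrete",
    whole_blood_kBq_per_ml = blood$discrete_whole_blood,
    plasma_kBq_per_ml = blood$discrete_plasma,
    parent_fraction = blood$parent_fraction[
      match(blood$discrete_time, blood$parent_fraction_time)]
  )
  utils::write.csv(rbind(cont, disc), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_blood_csv
#' @export
read_blood_csv <- function(path) {
  df <- utils::read.csv(path)
  cont <- df[df$source == "continuous", ]
  disc <- df[df$source == "discrete", ]
  pf <- disc[is.finite(disc$parent_fraction), ]
  blood_samples(
    continuous_time = cont$time_s,
    continuous_whole_blood = cont$whole_blood_kBq_per_ml,
    discrete_time = disc$time_s,
    discrete_whole_blood = disc$whole_blood_kBq_per_ml,
    discrete_plasma = disc$plasma_kBq_per_ml,
    parent_fraction_time = pf$time_s,
    parent_fraction = pf$parent_fraction
  )
}

#' Write a parent-plasma input function to CSV
#'
#' @param input A `plasma_input` object.
#' @param path File path.
#' @export
write_ppif_csv <- function(input, path) {
  assert_input(input)
  utils::write.csv(as_tibble(input), path, row.names = FALSE)
  invisible(path)
}
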