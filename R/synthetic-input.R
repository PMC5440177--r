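# Synthetic arterial input functions and blood-sampling tables.

#' Ground-truth input-function model for the synthetic study
#'
#' The plasma curve is a Feng-type bolus model (linear rise times a fast
#' exponential, plus two slower clearance exponentials), zero before the
#' injection time. The plasma-over-blood ratio and parent fraction are
#' four-parameter sigmoids; whole blood is plasma divided by the
#' plasma-over-blood ratio, and the parent-plasma input is plasma times the
#' parent fraction.
#'
#' @param peak_amp Amplitude of the bolus term (kBq/ml per min).
#' @param clearance Named list of the Feng parameters `a2`, `a3` (kBq/ml)
#'   and `l1`, `l2`, `l3` (min^-1).
#' @param pob,parent [sigmoid_model()]s for the two blood corrections.
#' @param injection_time Seconds from scan start.
#' @return An `if_model` list with fields `plasma(t_s)`, `whole_blood(t_s)`,
#'   `ppif(t_s)` (functions of seconds) plus the component models.
#' @export
input_function_model <- function(peak_amp = 300,
                                 clearance = list(a2 = 15, a3 = 12,
                                                  l1 = 4, l2 = 0.25, l3 = 0.012),
                                 pob = sigmoid_model(-0.35, -0.05, 0.25, 2,
                                                     "plasma_over_blood"),
                                 parent = sigmoid_model(0.75, 0.05, 0.3, 2,
                                                        "parent_fraction"),
                                 injection_time = 30) {
  plasma <- function(t_s) {
    tm <- pmax(t_s - injection_time, 0) / 60
    p <- (peak_amp * tm - clearance$a2 - clearance$a3) * exp(-clearance$l1 * tm) +
      clearance$a2 * exp(-clearance$l2 * tm) +
      clearance$a3 * exp(-clearance$l3 * tm)
    p[t_s < injection_time] <- 0
    pmax(p, 0)
  }
  whole_blood <- function(t_s) plasma(t_s) / pmax(eval_sigmoid(pob, t_s), 1e-6)
  ppif <- function(t_s) plasma(t_s) * eval_sigmoid(parent, t_s)
  structure(
    list(plasma = plasma, whole_blood = whole_blood, ppif = ppif,
         pob = pob, parent = parent, injection_time = injection_time),
    class = "if_model"
  )
}

#' True plasma input on the fine grid
#'
#' Evaluates an [input_function_model()] as a `plasma_input` object, i.e.
#' the noiseless ground truth that [build_ppif()] should recover from the
#' sampled blood data.
#'
#' @param model An `if_model`.
#' @param schedule A [frame_schedule()].
#' @param dt Grid spacing (s).
#' @return A `plasma_input`.
#' @export
true_plasma_input <- function(model, schedule, dt = 1) {
  tg <- fine_grid(schedule, dt)
  new_plasma_input(tg, model$ppif(tg), model$whole_blood(tg),
                   calibration_factor = 1,
                   models = list(plasma_over_blood = model$pob,
                                 parent = model$parent))
}

#' Simulate one scan's blood sampling data
#'
#' Emulates the clinical sampling scheme: a continuous whole-blood detector
#' over the first 15 min (1 Hz, with its own gain, recovered later by
#' cross-calibration) and discrete syringe samples at baseline and 4, 6, 8,
#' 10, 20, 35, 50, 65, 80 and 90 min, from which plasma activity and parent
#' fraction are measured. Gaussian measurement noise is multiplicative for
#' activities and additive for the parent fraction.
#'
#' @param model An [input_function_model()].
#' @param schedule A [frame_schedule()].
#' @param seed Integer seed; the same seed reproduces the data bit for bit.
#' @param detector_gain Gain of the continuous detector relative to the well
#'   counter (cross-calibration recovers `1/detector_gain`).
#' @param noise_continuous,noise_discrete Relative SD of the activity
#'   measurements.
#' @param noise_parent_fraction Absolute SD of the parent-fraction
#'   measurements.
#' @return A list: `blood` ([blood_samples()]), `truth` (the `if_model`),
#'   `input_true` (the noiseless `plasma_input`).
#' @export
sim_blood_samples <- function(model = input_function_model(),
                              schedule = frame_schedule(),
                              seed = 1L,
                              detector_gain = 0.92,
                              noise_continuous = 0.01,
                              noise_discrete = 0.02,
                              noise_parent_fraction = 0.01) {
  if (noise_continuous < 0 || noise_discrete < 0 || noise_parent_fraction < 0) {
    abort("Noise levels must be non-negative.")
  }
  set.seed(seed)
  cont_t <- seq(0, 900, by = 1)
  disc_t <- c(0, c(4, 6, 8, 10, 20, 35, 50, 65, 80, 90) * 60)

  wb_cont <- model$whole_blood(cont_t) * detector_gain
  wb_cont <- wb_cont * (1 + stats::rnorm(length(wb_cont), 0, noise_continuous))
  wb_disc <- model$whole_blood(disc_t) *
    (1 + stats::rnorm(length(disc_t), 0, noise_discrete))
  pl_disc <- model$plasma(disc_t) *
    (1 + stats::rnorm(length(disc_t), 0, noise_discrete))
  pf <- eval_sigmoid(model$parent, disc_t) +
    stats::rnorm(length(disc_t), 0, noise_parent_fraction)
  pf <- pmin(pmax(pf, 0), 1)

  blood <- blood_samples(
    continuous_time = cont_t,
    continuous_whole_blood = pmax(wb_cont, 0),
    discrete_time = disc_t,
    discrete_whole_blood = pmax(wb_disc, 0),
    discrete_plasma = pmax(pl_disc, 0),
    parent_fraction_time = disc_t,
    parent_fraction = pf
  )
  list(blood = blood, truth = model,
       input_true = true_plasma_input(model, schedule))
}
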