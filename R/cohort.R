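# Paired test-retest cohorts with known ground truth.

#' Generate a paired test-retest cohort
#'
#' Each subject gets a lognormal VT multiplier with coefficient of variation
#' `spec$bs_cv_true` (%), and each session an independent lognormal
#' multiplier with CV `spec$ws_cv_true` (%); both multipliers have unit
#' mean, so the cohort-average kinetics match the phantom spec. Every scan
#' gets its own voxel-noise realisation, its own blood-sampling noise, and a
#' session-specific injected dose, so the input-function construction is
#' exercised per scan.
#'
#' @param n_subjects Number of subjects (>= 2; the reference study used 5).
#' @param spec A [phantom_spec()].
#' @param schedule A [frame_schedule()].
#' @param if_model An [input_function_model()] shared by the cohort.
#' @param seed Integer seed for the whole cohort.
#' @param images Generate the dynamic phantom images (default). With
#'   `FALSE` only the blood data, metadata and ground-truth values are
#'   produced -- enough to study the cohort variance structure at large n
#'   without the imaging cost.
#' @return A list with `scans` (one element per subject x session holding
#'   the [sim_phantom_dynamic()] output plus `subject`, `session`, `blood`,
#'   `meta`) and `truth` (tibble of the per-scan true VT multipliers and
#'   per-region true values).
#' @export
sim_cohort <- function(n_subjects = 5, spec = phantom_spec(),
                       schedule = frame_schedule(),
                       if_model = input_function_model(),
                       seed = 1L, images = TRUE) {
  if (n_subjects < 2) abort("A test-retest cohort needs at least 2 subjects.")
  set.seed(seed)
  cv_to_sdlog <- function(cv) sqrt(log(1 + (cv / 100)^2))
  sd_bs <- cv_to_sdlog(spec$bs_cv_true)
  sd_ws <- cv_to_sdlog(spec$ws_cv_true)
  subj_mult <- stats::rlnorm(n_subjects, -sd_bs^2 / 2, sd_bs)
  sess_mult <- matrix(stats::rlnorm(2 * n_subjects, -sd_ws^2 / 2, sd_ws),
                      nrow = n_subjects)
  doses <- matrix(stats::rnorm(2 * n_subjects, 441, 6), nrow = n_subjects)
  weights_kg <- stats::rnorm(n_subjects, 80, 8)
  scan_seeds <- sample.int(2^30, 2 * n_subjects * 2)

  scans <- list()
  truth_rows <- list()
  idx <- 0L
  for (s in seq_len(n_subjects)) {
    for (k in 1:2) {
      idx <- idx + 1L
      session <- c("test", "retest")[k]
      vt_scale <- subj_mult[s] * sess_mult[s, k]
      amp_scale <- doses[s, k] / 441
      scan_model <- input_function_model(
        peak_amp = 300 * amp_scale,
        clearance = list(a2 = 15 * amp_scale, a3 = 12 * amp_scale,
                         l1 = 4, l2 = 0.25, l3 = 0.012),
        pob = if_model$pob, parent = if_model$parent,
        injection_time = if_model$injection_time
      )
      bl <- sim_blood_samples(scan_model, schedule,
                              seed = scan_seeds[2 * idx - 1])
      ph <- if (images) {
        sim_phantom_dynamic(spec, bl$input_true, schedule,
                            vt_scale = vt_scale,
                            seed = scan_seeds[2 * idx])
      } else {
        vt_scaled <- spec$regions$vt_true * vt_scale
        list(truth = dplyr::mutate(
          spec$regions, vt_true = vt_scaled,
          bp_vs_brainstem = vt_scaled /
            vt_scaled[spec$regions$region == "brainstem"] - 1,
          bp_vs_cerebellum = vt_scaled /
            vt_scaled[spec$regions$region == "cerebellum"] - 1
        ))
      }
      ph$subject <- sprintf("s%02d", s)
      ph$session <- session
      ph$blood <- bl$blood
      ph$input_true <- bl$input_true
      ph$meta <- scan_meta(doses[s, k], weights_kg[s],
                           subject_id = ph$subject, session = session)
      scans[[idx]] <- ph
      truth_rows[[idx]] <- tibble(
        subject = ph$subject, session = session, vt_scale = vt_scale,
        region = ph$truth$region, vt_true = ph$truth$vt_true,
        bp_vs_brainstem = ph$truth$bp_vs_brainstem,
        bp_vs_cerebellum = ph$truth$bp_vs_cerebellum
      )
    }
  }
  list(scans = scans, truth = dplyr::bind_rows(truth_rows))
}
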