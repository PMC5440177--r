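# SUV images, the global-radioactivity statistic, and ROI sampling of
# parametric images.

#' Scan metadata
#'
#' @param injected_dose Injected activity in MBq (> 0).
#' @param body_weight Body weight in kg (> 0).
#' @param subject_id,session Identifiers (session is `"test"` or `"retest"`).
#' @return A `scan_meta` object.
#' @export
scan_meta <- function(injected_dose, body_weight,
                      subject_id = "s01", session = "test") {
  check_number(injected_dose, "injected_dose", lower = 0, strict_lower = TRUE)
  check_number(body_weight, "body_weight", lower = 0, strict_lower = TRUE)
  structure(
    list(injected_dose = injected_dose, body_weight = body_weight,
         subject_id = subject_id, session = session),
    class = "scan_meta"
  )
}

#' Standardised uptake value image
#'
#' `SUV = activity * body_weight / injected_dose` per voxel, with activity in
#' kBq/ml, weight in kg and dose in MBq (so SUV is in g/ml under the usual
#' 1 ml ~ 1 g tissue convention). The input is a decay-corrected summation
#' image, typically over frames 16-21 (30.5-60.5 min) or 22-24
#' (60.5-90.5 min); see [sum_frames()].
#'
#' @param summed 3D decay-corrected summation image, kBq/ml.
#' @param meta A [scan_meta()] with dose and weight.
#' @return A `parametric_image` of SUV.
#' @export
compute_suv <- function(summed, meta) {
  if (!inherits(meta, "scan_meta")) abort("`meta` must be a `scan_meta`.")
  suv <- summed * meta$body_weight / meta$injected_dose
  parametric_image(suv, array(TRUE, dim(summed)), outcome = "SUV",
                   units = "kBq/ml * kg / MBq",
                   injected_dose = meta$injected_dose,
                   body_weight = meta$body_weight)
}

#' Global radioactivity concentration
#'
#' Mean voxel value within the implicit mask of all voxels exceeding
#' one-eighth of the whole-matrix mean.
#'
#' @param summed 3D decay-corrected summation image, kBq/ml.
#' @return The masked mean, with attribute `n_voxels`.
#' @export
global_radioactivity <- function(summed) {
  if (length(summed) == 0) abort("Empty image.")
  thr <- mean(summed) / 8
  mask <- summed > thr
  if (!any(mask)) abort("Global mask is empty (all-zero image?).")
  out <- mean(summed[mask])
  attr(out, "n_voxels") <- sum(mask)
  out
}

#' Sample a parametric image over regions of interest
#'
#' Pools voxels of both hemispheric homologues of each region (grey-matter
#' masked where the ROI definition says so) and reports the mean, sample SD,
#' within-subject coefficient of variation (WS-CV = 100 * SD / mean) and
#' voxel counts. `NaN` voxels (failed fits) are excluded and counted.
#'
#' @param map A [parametric_image()] (or plain 3D array).
#' @param labels Integer 3D label image on the same grid.
#' @param roi_spec A data frame with columns `region` (name), `labels` (list
#'   column of integer label ids, both homologues) and `gm_masked`
#'   (logical); see [phantom_rois()] for the phantom's table.
#' @param gm_mask Optional logical 3D grey-matter mask; required when any
#'   ROI has `gm_masked = TRUE`.
#' @return A tibble: `region`, `mean`, `sd`, `ws_cv`, `n_voxels`, `n_missing`.
#' @export
sample_parametric <- function(map, labels, roi_spec, gm_mask = NULL) {
  vals <- as.numeric(unclass(map))
  lab <- as.integer(labels)
  if (length(vals) != length(lab)) {
    abort("`map` and `labels` must be on the same grid.")
  }
  if (any(roi_spec$gm_masked) && is.null(gm_mask)) {
    abort("`gm_mask` is required for grey-matter-masked ROIs.")
  }
  purrr::pmap_dfr(roi_spec, function(region, labels, gm_masked, ...) {
    sel <- lab %in% labels
    if (gm_masked) sel <- sel & as.logical(gm_mask)
    if (!any(sel)) abort(sprintf("ROI '%s' is empty after masking.", region))
    v <- vals[sel]
    miss <- !is.finite(v)
    v <- v[!miss]
    if (length(v) == 0) {
      return(tibble(region = region, mean = NaN, sd = NaN, ws_cv = NaN,
                    n_voxels = 0L, n_missing = sum(miss)))
    }
    m <- mean(v)
    s <- if (length(v) > 1) stats::sd(v) else 0
    tibble(
      region = region, mean = m, sd = s,
      ws_cv = if (m != 0) 100 * s / abs(m) else NaN,
      n_voxels = length(v), n_missing = sum(miss)
    )
  })
}

#' Regional time-activity curves from a dynamic image
#'
#' Builds the mean TAC over the pooled (grey-matter masked where specified)
#' voxels of each ROI.
#'
#' @param dyn 4D dynamic image.
#' @param schedule A [frame_schedule()].
#' @inheritParams sample_parametric
#' @param decay_corrected Whether `dyn` is decay-corrected.
#' @return A multi-region [pet_tac()].
#' @export
roi_tacs <- function(dyn, schedule, labels, roi_spec, gm_mask = NULL,
                     decay_corrected = TRUE) {
  assert_schedule(schedule)
  lab <- as.integer(labels)
  if (any(roi_spec$gm_masked) && is.null(gm_mask)) {
    abort("`gm_mask` is required for grey-matter-masked ROIs.")
  }
  curves <- purrr::pmap(roi_spec, function(region, labels, gm_masked, ...) {
    sel <- lab %in% labels
    if (gm_masked) sel <- sel & as.logical(gm_mask)
    if (!any(sel)) abort(sprintf("ROI '%s' is empty after masking.", region))
    roi_mean_tac(dyn, which(sel))
  })
  names(curves) <- roi_spec$region
  pet_tac(schedule, curves, decay_corrected = decay_corrected)
}
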