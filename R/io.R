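# On-disk representation of scans and cohorts: NIfTI images, blood CSV,
# JSON metadata and a manifest that indexes a whole cohort.

#' Write a scan to a directory
#'
#' Stores the dynamic image, label image and masks as NIfTI, the blood
#' samples as CSV, and the remaining scalars (metadata, frame schedule,
#' true-coincidence rates, ROI table) as JSON.
#'
#' @param scan A scan list as produced by [sim_phantom_dynamic()] /
#'   [sim_cohort()] (fields `dyn`, `labels`, `gm_mask`, `brain_mask`,
#'   `trues_rate`, `rois`; optionally `blood`, `meta`).
#' @param dir Output directory (created if needed).
#' @param schedule The acquisition [frame_schedule()].
#' @param voxel_mm Voxel size recorded in the NIfTI headers.
#' @return `dir`, invisibly.
#' @export
write_scan_dir <- function(scan, dir, schedule = frame_schedule(),
                           voxel_mm = 4) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(arr, name) {
    nii <- RNifti::asNifti(arr * 1, pixdim = rep_len(voxel_mm, 3),
                           datatype = "float")
    RNifti::writeNifti(nii, file.path(dir, name))
  }
  wr(scan$dyn, "dynamic.nii.gz")
  wr(array(as.numeric(scan$labels), dim(scan$labels)), "labels.nii.gz")
  wr(array(as.numeric(scan$gm_mask), dim(scan$gm_mask)), "gm_mask.nii.gz")
  wr(array(as.numeric(scan$brain_mask), dim(scan$brain_mask)),
     "brain_mask.nii.gz")
  if (!is.null(scan$blood)) write_blood_csv(scan$blood, file.path(dir, "blood.csv"))
  meta <- list(
    subject = scan$subject %||% NA,
    session = scan$session %||% NA,
    injected_dose_MBq = if (!is.null(scan$meta)) scan$meta$injected_dose else NA,
    body_weight_kg = if (!is.null(scan$meta)) scan$meta$body_weight else NA,
    trues_rate = scan$trues_rate,
    voxel_mm = voxel_mm,
    frame_spec = list(injection_time_s = attr(schedule, "injection_time"),
                      decay_constant_per_s = attr(schedule, "decay_constant"),
                      duration_s = schedule$duration),
    rois = lapply(seq_len(nrow(scan$rois)), function(i) {
      list(region = scan$rois$region[i],
           labels = scan$rois$labels[[i]],
           gm_masked = scan$rois$gm_masked[i])
    })
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a scan directory back
#'
#' @param dir A directory written by [write_scan_dir()].
#' @return A list with the scan fields and its `schedule`.
#' @export
read_scan_dir <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  durs <- unlist(meta$frame_spec$duration_s)
  schedule <- frame_schedule(
    tibble(count = rep(1L, length(durs)), duration_s = durs),
    injection_time = meta$frame_spec$injection_time_s,
    decay_constant = meta$frame_spec$decay_constant_per_s
  )
  rois <- tibble(
    region = vapply(meta$rois, function(r) r$region, character(1)),
    labels = lapply(meta$rois, function(r) as.integer(unlist(r$labels))),
    gm_masked = vapply(meta$rois, function(r) isTRUE(r$gm_masked), logical(1))
  )
  blood_path <- file.path(dir, "blood.csv")
  lab_arr <- read_nifti_array(file.path(dir, "labels.nii.gz"))
  scan <- list(
    dyn = read_nifti_array(file.path(dir, "dynamic.nii.gz")),
    labels = array(as.integer(round(lab_arr)), dim(lab_arr)),
    gm_mask = read_nifti_array(file.path(dir, "gm_mask.nii.gz")) > 0.5,
    brain_mask = read_nifti_array(file.path(dir, "brain_mask.nii.gz")) > 0.5,
    trues_rate = unlist(meta$trues_rate),
    rois = rois,
    subject = meta$subject,
    session = meta$session,
    schedule = schedule
  )
  if (file.exists(blood_path)) scan$blood <- read_blood_csv(blood_path)
  if (!is.na(meta$injected_dose_MBq %||% NA)) {
    scan$meta <- scan_meta(meta$injected_dose_MBq, meta$body_weight_kg,
                           subject_id = meta$subject %||% "s01",
                           session = meta$session %||% "test")
  }
  scan
}

#' Write a simulated cohort with a manifest
#'
#' One subdirectory per scan (`<subject>_<session>`) in [write_scan_dir()]
#' layout, the ground-truth table as CSV, and a `manifest.json` indexing all
#' scans.
#'
#' @param cohort Output of [sim_cohort()].
#' @param dir Output directory.
#' @inheritParams write_scan_dir
#' @return `dir`, invisibly.
#' @export
write_cohort_dir <- function(cohort, dir, schedule = frame_schedule(),
                             voxel_mm = 4) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  entries <- lapply(cohort$scans, function(sc) {
    sub <- paste(sc$subject, sc$session, sep = "_")
    write_scan_dir(sc, file.path(dir, sub), schedule, voxel_mm)
    list(subject = sc$subject, session = sc$session, path = sub)
  })
  utils::write.csv(cohort$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(format_version = 1L, n_scans = length(entries), scans = entries,
         ground_truth = "ground_truth.csv"),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
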