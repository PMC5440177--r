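# End-to-end pipeline: quantify one scan with any subset of the 12
# variants, then summarise a paired cohort into reliability tables.

#' Pipeline configuration with the standard analysis settings
#'
#' Collects every tunable constant of the 12 variants. Defaults are the
#' conventional settings for slow-kinetics 11C tracers: Logan `t* = 1680 s`
#' with fixed blood volume 0.028 and 2 mm FWHM pre-smoothing (voxelwise
#' only); spectral analysis with 100 log-spaced components in
#' \[0.00063, 0.1\] s^-1; SRTM2 with 100 components in \[0.00063, 0.014\]
#' s^-1; SUV windows over frames 16-21 and 22-24.
#'
#' @param variants Character subset of [variant_names()].
#' @param t_star,fixed_bv,presmooth_fwhm_mm Logan settings.
#' @param sa_n_basis,sa_beta_min,sa_beta_max Spectral-analysis basis.
#' @param srtm2_n_basis,srtm2_beta_min,srtm2_beta_max SRTM2 basis.
#' @param suv_windows Named list of inclusive frame ranges.
#' @param voxel_mm Voxel size used for smoothing kernels.
#' @return A `quantify_config` list.
#' @export
quantify_config <- function(variants = variant_names(),
                            t_star = 1680, fixed_bv = 0.028,
                            presmooth_fwhm_mm = 2,
                            sa_n_basis = 100, sa_beta_min = 0.00063,
                            sa_beta_max = 0.1,
                            srtm2_n_basis = 100, srtm2_beta_min = 0.00063,
                            srtm2_beta_max = 0.014,
                            suv_windows = list(suv_30_60 = c(16L, 21L),
                                               suv_60_90 = c(22L, 24L)),
                            voxel_mm = 4) {
  unknown <- setdiff(variants, variant_names())
  if (length(unknown) > 0) {
    abort(paste0("Unknown variant(s): ", paste(unknown, collapse = ", "), "."))
  }
  structure(
    list(variants = variants, t_star = t_star, fixed_bv = fixed_bv,
         presmooth_fwhm_mm = presmooth_fwhm_mm,
         sa_n_basis = sa_n_basis, sa_beta_min = sa_beta_min,
         sa_beta_max = sa_beta_max,
         srtm2_n_basis = srtm2_n_basis, srtm2_beta_min = srtm2_beta_min,
         srtm2_beta_max = srtm2_beta_max,
         suv_windows = suv_windows, voxel_mm = voxel_mm),
    class = "quantify_config"
  )
}

needs_arterial_input <- function(variants) {
  intersect(variants, c("2kbv", "4kbv", "logan_regional", "logan_voxelwise",
                        "sa_regional", "sa_voxelwise"))
}

variant_kind <- function(variant) {
  ifelse(variant %in% c("2kbv", "4kbv", "logan_regional", "sa_regional",
                        "srtm_brainstem", "srtm_cerebellum"),
         "regional", "voxelwise")
}

#' Quantify one dynamic scan with the requested variants
#'
#' Runs any subset of the 12 quantification variants on a scan (a dynamic
#' image with its ROI labels, grey-matter mask and ancillary data, as
#' produced by [sim_phantom_dynamic()]/[sim_cohort()] or assembled from
#' files) and samples every outcome over the ROIs.
#'
#' @param scan A list with elements `dyn` (4D decay-corrected image),
#'   `labels`, `gm_mask`, `rois` (see [phantom_rois()]); optionally
#'   `brain_mask`, `trues_rate`, `blood` ([blood_samples()]) and `meta`
#'   ([scan_meta()], required for SUV variants).
#' @param config A [quantify_config()].
#' @param schedule A [frame_schedule()].
#' @param input Optional pre-built `plasma_input`; built from `scan$blood`
#'   when needed and `NULL`.
#' @param keep_maps Keep the voxelwise parametric images in the result's
#'   `maps` attribute.
#' @return A tibble with one row per region x variant: `region`, `variant`,
#'   `kind`, `value` (VT, BPND or SUV), `ws_cv`, `rss`, `converged`,
#'   `outlier`.
#' @export
run_quantify <- function(scan, config = quantify_config(),
                         schedule = frame_schedule(), input = NULL,
                         keep_maps = FALSE) {
  if (!is.list(scan) || is.null(scan$dyn) || is.null(scan$labels) ||
      is.null(scan$rois)) {
    abort("`scan` must contain at least `dyn`, `labels` and `rois`.")
  }
  variants <- config$variants
  need_if <- needs_arterial_input(variants)
  if (length(need_if) > 0 && is.null(input)) {
    if (is.null(scan$blood)) {
      abort(paste0("Variant(s) ", paste(need_if, collapse = ", "),
                   " require an arterial input; supply `scan$blood` or `input`."))
    }
    input <- build_ppif(scan$blood, schedule)
  }
  if (any(grepl("^suv", variants)) && is.null(scan$meta)) {
    abort("SUV variants require `scan$meta` (injected dose and body weight).")
  }

  rois <- scan$rois[scan$rois$region != "rest_of_brain", ]
  gm <- scan$gm_mask
  mask <- scan$brain_mask %||% array(scan$labels > 0, dim(scan$labels))
  w_roi <- w_vox <- NULL
  if (!is.null(scan$trues_rate)) {
    raw <- compute_frame_weights(schedule, scan$trues_rate)
    w_roi <- normalize_weights(raw, "roi")
    w_vox <- normalize_weights(raw, "voxel")
  }

  regional_needed <- any(variant_kind(variants) == "regional")
  tacs <- if (regional_needed || any(grepl("^srtm", variants))) {
    roi_tacs(scan$dyn, schedule, scan$labels, rois, gm_mask = gm)
  }
  maps <- list()
  rows <- list()
  add_regional <- function(variant, region, fit) {
    rows[[length(rows) + 1]] <<- tibble(
      region = region, variant = variant, kind = "regional",
      value = fit$vt, ws_cv = fit_residual_cv(fit),
      rss = fit$weighted_rss, converged = fit$converged
    )
  }
  add_map <- function(variant, map) {
    if (keep_maps) maps[[variant]] <<- map
    stats <- sample_parametric(map, scan$labels, rois, gm_mask = gm)
    rows[[length(rows) + 1]] <<- tibble(
      region = stats$region, variant = variant, kind = "voxelwise",
      value = stats$mean, ws_cv = stats$ws_cv, rss = NA_real_,
      converged = TRUE
    )
  }
  one_tac <- function(region) {
    pet_tac(schedule, tac_activity(tacs, region), region = region)
  }

  for (v in intersect(variants, c("2kbv", "4kbv"))) {
    for (r in rois$region) {
      add_regional(v, r, fit_compartmental(one_tac(r), input, w_roi, model = v))
    }
  }
  if ("logan_regional" %in% variants) {
    for (r in rois$region) {
      add_regional("logan_regional", r,
                   logan_regional(one_tac(r), input,
                                  t_star = config$t_star,
                                  fixed_bv = config$fixed_bv))
    }
  }
  if ("sa_regional" %in% variants || "sa_voxelwise" %in% variants) {
    basis <- spectral_basis(input, schedule, n = config$sa_n_basis,
                            beta_min = config$sa_beta_min,
                            beta_max = config$sa_beta_max)
  }
  if ("sa_regional" %in% variants) {
    for (r in rois$region) {
      sp <- sa_fit(one_tac(r), basis, w_roi)
      rows[[length(rows) + 1]] <- tibble(
        region = r, variant = "sa_regional", kind = "regional",
        value = sp$vt,
        ws_cv = 100 * sqrt(max(sp$weighted_rss, 0) /
                             max(length(sp$observed) - sum(sp$spectrum$alpha > 0), 1)) /
          mean(sp$fitted),
        rss = sp$weighted_rss, converged = TRUE
      )
    }
  }
  for (ref in c("brainstem", "cerebellum")) {
    v <- paste0("srtm_", ref)
    if (v %in% variants) {
      ref_tac <- one_tac(ref)
      for (r in setdiff(rois$region, ref)) {
        add_regional(v, r, fit_srtm(one_tac(r), ref_tac, w_roi))
      }
    }
  }

  if ("logan_voxelwise" %in% variants) {
    add_map("logan_voxelwise",
            logan_voxelwise(scan$dyn, input, schedule, mask,
                            t_star = config$t_star,
                            fixed_bv = config$fixed_bv,
                            presmooth_fwhm_mm = config$presmooth_fwhm_mm,
                            voxel_mm = config$voxel_mm))
  }
  if ("sa_voxelwise" %in% variants) {
    add_map("sa_voxelwise", sa_voxelwise(scan$dyn, basis, w_vox, mask))
  }
  for (ref in c("brainstem", "cerebellum")) {
    v <- paste0("srtm2_", ref)
    if (v %in% variants) {
      map <- fit_srtm2_voxelwise(
        scan$dyn, one_tac(ref), mask, w_vox,
        n_basis = config$srtm2_n_basis,
        beta_min = config$srtm2_beta_min,
        beta_max = config$srtm2_beta_max
      )
      add_map(v, map)
    }
  }
  for (wname in intersect(variants, names(config$suv_windows))) {
    summed <- sum_frames(scan$dyn, schedule, config$suv_windows[[wname]])
    add_map(wname, compute_suv(summed, scan$meta))
  }

  out <- dplyr::bind_rows(rows)
  out$outlier <- ifelse(
    out$kind == "regional",
    flag_outliers(out$value, out$ws_cv, "regional"),
    flag_outliers(out$value, out$ws_cv, "voxelwise")
  )
  out <- dplyr::arrange(out, match(.data$variant, variant_names()),
                        .data$region)
  if (keep_maps) attr(out, "maps") <- maps
  out
}

#' Reliability tables from paired outcome tables
#'
#' Computes, for every variant x region present in both sessions, the MA-TD
#' (with category), BS-CV and one-way single-measures ICC, then the
#' median/IQR summary across the six comparison regions and the
#' hippocampus/occipital heterogeneity ratio per variant.
#'
#' @param outcomes A tibble with columns `subject`, `session` (`"test"` /
#'   `"retest"`), `variant`, `region`, `value` -- typically stacked
#'   [run_quantify()] outputs.
#' @return A list of tibbles: `per_region`, `summary`, `heterogeneity`.
#' @export
run_reliability <- function(outcomes) {
  need <- c("subject", "session", "variant", "region", "value")
  if (!all(need %in% names(outcomes))) {
    abort(paste0("`outcomes` must have columns ",
                 paste(need, collapse = ", "), "."))
  }
  wide <- tidyr::pivot_wider(
    outcomes[need], names_from = "session", values_from = "value"
  )
  if (!all(c("test", "retest") %in% names(wide))) {
    abort("Both a 'test' and a 'retest' session are required.")
  }
  unpaired <- wide[!stats::complete.cases(wide[c("test", "retest")]), ]
  if (nrow(unpaired) > 0) {
    abort(sprintf("%d unpaired subject/region/variant combinations.",
                  nrow(unpaired)))
  }
  # near-zero outcomes (e.g. BPND of a pseudo-reference region against the
  # other reference) can make a session mean non-positive; such metrics are
  # undefined and reported as NA rather than aborting the whole table
  quietly_na <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  per_region <- wide |>
    dplyr::group_by(.data$variant, .data$region) |>
    dplyr::summarise(
      n = dplyr::n(),
      ma_td = quietly_na(ma_td(.data$test, .data$retest)$ma_td),
      bs_cv = if (dplyr::n() >= 2) {
        quietly_na(bs_cv(.data$test, .data$retest))
      } else NA_real_,
      icc = if (dplyr::n() >= 2) {
        quietly_na(icc_oneway(.data$test, .data$retest)$icc)
      } else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(ma_td_category = as.character(td_category(.data$ma_td)),
                  .after = "ma_td")
  if (any(per_region$n < 2)) {
    warn("Single-subject data: BS-CV and ICC are undefined and set to NA.")
  }

  summary_rows <- list()
  for (v in unique(per_region$variant)) {
    sub <- per_region[per_region$variant == v, ]
    if (!all(comparison_regions() %in% sub$region)) next
    for (metric in c("ma_td", "bs_cv", "icc")) {
      vals <- setNames(sub[[metric]], sub$region)
      if (any(!is.finite(vals[comparison_regions()]))) next
      digits <- if (metric == "icc") 2 else 0
      s <- summarize_by_region(vals, digits = digits)
      summary_rows[[length(summary_rows) + 1]] <-
        dplyr::bind_cols(tibble(variant = v, metric = metric), s)
    }
  }

  het <- outcomes |>
    dplyr::filter(.data$region %in% c("hippocampus", "occipital")) |>
    dplyr::group_by(.data$variant, .data$region) |>
    dplyr::summarise(value = median(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "region", values_from = "value")
  het_tbl <- purrr::pmap_dfr(het, function(variant, hippocampus, occipital) {
    dplyr::bind_cols(tibble(variant = variant),
                     heterogeneity_ratio(hippocampus, occipital))
  })

  list(per_region = per_region,
       summary = dplyr::bind_rows(summary_rows),
       heterogeneity = het_tbl)
}

#' Write reliability tables as CSV files
#'
#' One file per metric (`ma_td.csv`, `bs_cv.csv`, `icc.csv`), each with one
#' row per region plus `median` and `iqr` summary rows and one column per
#' variant, mirroring the conventional reporting layout.
#'
#' @param rel Output of [run_reliability()].
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_reliability_csv <- function(rel, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (metric in c("ma_td", "bs_cv", "icc")) {
    digits <- if (metric == "icc") 2 else 0
    wide <- tidyr::pivot_wider(
      rel$per_region[c("variant", "region", metric)],
      names_from = "variant", values_from = dplyr::all_of(metric)
    )
    summ <- rel$summary[rel$summary$metric == metric, ]
    if (nrow(summ) > 0) {
      med_row <- tibble(region = "median")
      iqr_row <- tibble(region = "iqr")
      for (v in setdiff(names(wide), "region")) {
        srow <- summ[summ$variant == v, ]
        med_row[[v]] <- if (nrow(srow) == 1) {
          format(srow$median_display)
        } else NA_character_
        iqr_row[[v]] <- if (nrow(srow) == 1) {
          sprintf("%s-%s", format(srow$q25_display), format(srow$q75_display))
        } else NA_character_
      }
      wide <- dplyr::mutate(wide, dplyr::across(-"region",
                                                \(x) format(round_half_up(x, digits))))
      wide <- dplyr::bind_rows(wide, med_row, iqr_row)
    }
    utils::write.csv(wide, file.path(dir, paste0(metric, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(rel$heterogeneity, file.path(dir, "heterogeneity.csv"),
                   row.names = FALSE)
  invisible(dir)
}
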