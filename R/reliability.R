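# Test-retest reliability statistics: symmetric percentage differences,
# between-subject CV, one-way single-measures ICC, region summaries,
# heterogeneity ratio and outlier flags.

#' Signed symmetric test-retest difference (%)
#'
#' `200 * (test - retest) / (test + retest)`: antisymmetric in its arguments
#' and bounded in (-200, 200) for positive values.
#'
#' @param test,retest Outcome values (same units).
#' @return Percentage difference(s).
#' @export
signed_td <- function(test, retest) {
  s <- test + retest
  if (any(s == 0)) abort("`test + retest` must be non-zero.")
  200 * (test - retest) / s
}

td_category <- function(ma_td) {
  cut(ma_td, c(-Inf, 10, 15, 20, Inf),
      labels = c("low", "moderate", "high", "very high"), right = FALSE)
}

#' Median absolute test-retest difference (MA-TD)
#'
#' Median over subjects of `|signed_td|`, with the conventional qualitative
#' category: < 10% low, 10-15% moderate, 15-20% high, >= 20% very high
#' (left-closed intervals, so exactly 10% is "moderate").
#'
#' @param test,retest Paired outcome values, one element per subject.
#' @return A one-row tibble: `ma_td` (%), `category`, `n`.
#' @export
ma_td <- function(test, retest) {
  if (length(test) != length(retest) || length(test) < 1) {
    abort("`test` and `retest` must be non-empty and paired.")
  }
  v <- median(abs(signed_td(test, retest)))
  tibble(ma_td = v, category = as.character(td_category(v)), n = length(test))
}

#' Between-subject coefficient of variation (%)
#'
#' For each session the CV across subjects (100 * sample SD / mean); the
#' reported BS-CV is the mean of the two session CVs.
#'
#' @param test,retest Paired outcome values, one element per subject (>= 2).
#' @return BS-CV in percent.
#' @export
bs_cv <- function(test, retest) {
  if (length(test) < 2 || length(test) != length(retest)) {
    abort("BS-CV needs paired values from at least 2 subjects.")
  }
  cv1 <- 100 * stats::sd(test) / mean(test)
  cv2 <- 100 * stats::sd(retest) / mean(retest)
  if (mean(test) <= 0 || mean(retest) <= 0) {
    abort("Session means must be positive for a coefficient of variation.")
  }
  (cv1 + cv2) / 2
}

#' One-way single-measures intraclass correlation coefficient
#'
#' One-way random-effects ANOVA decomposition with subjects as the grouping
#' factor and the two sessions as replicates:
#' `ICC = (MS_BS - MS_WS) / (MS_BS + df_WS * MS_WS)` with `df_WS = k - 1 = 1`
#' replicate degree of freedom per subject, i.e. the single-measures ICC(1,1).
#'
#' @param test,retest Paired outcome values, one element per subject (>= 2).
#' @return A one-row tibble: `icc`, `ms_bs`, `ms_ws`, `df_bs`, `df_ws`, `n`.
#' @export
icc_oneway <- function(test, retest) {
  n <- length(test)
  if (n < 2 || length(retest) != n) {
    abort("ICC needs paired values from at least 2 subjects.")
  }
  k <- 2
  x <- cbind(test, retest)
  subj_mean <- rowMeans(x)
  grand <- mean(x)
  ss_bs <- k * sum((subj_mean - grand)^2)
  ss_ws <- sum((x - subj_mean)^2)
  if (ss_bs + ss_ws == 0) abort("Zero total variance; ICC undefined.")
  ms_bs <- ss_bs / (n - 1)
  ms_ws <- ss_ws / (n * (k - 1))
  icc <- (ms_bs - ms_ws) / (ms_bs + (k - 1) * ms_ws)
  tibble(icc = icc, ms_bs = ms_bs, ms_ws = ms_ws,
         df_bs = n - 1, df_ws = n * (k - 1), n = n)
}

#' Regions used for between-variant comparison
#'
#' The six bilateral non-reference grey-matter ROIs over which the summary
#' rows of the reliability tables are computed.
#'
#' @return Character vector of region names.
#' @export
comparison_regions <- function() {
  c("acg", "fusiform", "hippocampus", "inferior_frontal", "insula",
    "occipital")
}

#' Median and interquartile range across the six comparison regions
#'
#' @param values Named numeric vector or data frame (`region`, `value`)
#'   holding one metric value for each of the six comparison regions.
#' @param digits Display rounding (half away from zero) for the `display`
#'   columns; use 0 for percentages and 2 for ICCs. `NULL` suppresses them.
#' @return A one-row tibble: `median`, `q25`, `q75` (type-7 quantiles) and,
#'   if `digits` is given, their display-rounded counterparts.
#' @export
summarize_by_region <- function(values, digits = NULL) {
  if (is.data.frame(values)) {
    values <- setNames(values$value, values$region)
  }
  missing <- setdiff(comparison_regions(), names(values))
  if (length(missing) > 0) {
    abort(paste0("Missing regions: ", paste(missing, collapse = ", "), "."))
  }
  v <- unname(values[comparison_regions()])
  q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  out <- tibble(median = q[2], q25 = q[1], q75 = q[3])
  if (!is.null(digits)) {
    out$median_display <- round_half_up(q[2], digits)
    out$q25_display <- round_half_up(q[1], digits)
    out$q75_display <- round_half_up(q[3], digits)
  }
  out
}

#' Regional heterogeneity ratio
#'
#' Ratio of binding in the highest-binding region (hippocampus) to the
#' lowest-binding non-reference region (occipital lobes), with categories
#' 1.5 <= x < 1.8 moderate, 1.8 <= x < 2.0 high, x >= 2.0 very high.
#'
#' @param high_region_value,low_region_value Binding values (low > 0).
#' @return A one-row tibble: `ratio`, `category`.
#' @export
heterogeneity_ratio <- function(high_region_value, low_region_value) {
  if (low_region_value <= 0) abort("Denominator region value must be positive.")
  r <- high_region_value / low_region_value
  cat <- as.character(cut(r, c(-Inf, 1.5, 1.8, 2.0, Inf),
                          labels = c("low", "moderate", "high", "very high"),
                          right = FALSE))
  tibble(ratio = r, category = cat)
}

#' Flag implausible regional or voxelwise outcomes
#'
#' Regional variants are flagged when the outcome is <= 0 or the fit's
#' WS-CV exceeds 50%; voxelwise variants when the ROI-mean outcome is <= 0
#' or the within-ROI WS-CV exceeds 100%.
#'
#' @param value Outcome value (VT, BPND or SUV; regional value or ROI mean).
#' @param ws_cv Within-subject coefficient of variation (%), `NA` if unknown.
#' @param variant_kind `"regional"` or `"voxelwise"`.
#' @return Logical flag (vectorised).
#' @export
flag_outliers <- function(value, ws_cv, variant_kind = c("regional", "voxelwise")) {
  variant_kind <- match.arg(variant_kind)
  lim <- if (variant_kind == "regional") 50 else 100
  (value <= 0) | (!is.na(ws_cv) & ws_cv > lim)
}
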