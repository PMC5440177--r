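# Published test-retest benchmark for [11C]Ro15-4513.
#
# Per-region reliability values reported for the GABA-A alpha5 tracer
# [11C]Ro15-4513 in five healthy males scanned twice: the median absolute
# test-retest difference (MA-TD, %), the between-subject coefficient of
# variation (BS-CV, %) and the one-way single-measures ICC, for all 12
# quantification variants, plus the hippocampus/occipital heterogeneity
# ratio per variant. Summary rows (median, IQR) are *not* stored; they are
# recomputed from these values by summarize_by_region().

#' The 12 quantification variant names
#'
#' @return Character vector in the conventional reporting order.
#' @export
variant_names <- function() {
  c("2kbv", "4kbv", "logan_regional", "logan_voxelwise",
    "sa_regional", "sa_voxelwise", "suv_30_60", "suv_60_90",
    "srtm_brainstem", "srtm2_brainstem", "srtm_cerebellum", "srtm2_cerebellum")
}

#' Published test-retest benchmark values for [11C]Ro15-4513
#'
#' Per-region MA-TD, BS-CV and ICC for the six comparison regions and all 12
#' variants, as reported for the five-subject test-retest study of this
#' tracer, together with the hippocampus/occipital binding ratio per
#' variant. Used to validate the summary statistics against an independent
#' published table, and as a worked example for [summarize_by_region()].
#'
#' @return A list with `values` (long tibble: `metric`, `region`, `variant`,
#'   `value`) and `heterogeneity` (tibble: `variant`, `ratio`).
#' @export
ro15_benchmark <- function() {
  regions <- comparison_regions()
  v <- variant_names()
  row_tbl <- function(metric, region, x) {
    tibble(metric = metric, region = region, variant = v, value = x)
  }
  matd <- rbind(
    row_tbl("ma_td", "acg",              c(28, 7, 18, 19, 10, 4, 11, 21, 5, 6, 2, 1)),
    row_tbl("ma_td", "fusiform",         c(28, 14, 19, 20, 14, 10, 10, 15, 8, 6, 5, 4)),
    row_tbl("ma_td", "hippocampus",      c(22, 3, 13, 9, 6, 2, 6, 16, 3, 2, 3, 2)),
    row_tbl("ma_td", "inferior_frontal", c(17, 5, 8, 9, 7, 5, 11, 14, 5, 5, 5, 4)),
    row_tbl("ma_td", "insula",           c(27, 8, 16, 17, 14, 1, 12, 20, 7, 6, 3, 2)),
    row_tbl("ma_td", "occipital",        c(21, 8, 17, 15, 15, 8, 13, 17, 4, 1, 5, 3))
  )
  bscv <- rbind(
    row_tbl("bs_cv", "acg",              c(15, 9, 12, 12, 10, 10, 16, 20, 5, 5, 8, 8)),
    row_tbl("bs_cv", "fusiform",         c(15, 26, 12, 12, 14, 14, 14, 19, 5, 6, 7, 8)),
    row_tbl("bs_cv", "hippocampus",      c(15, 9, 10, 11, 12, 11, 13, 18, 8, 9, 8, 11)),
    row_tbl("bs_cv", "inferior_frontal", c(12, 20, 10, 10, 15, 12, 18, 22, 8, 8, 9, 10)),
    row_tbl("bs_cv", "insula",           c(14, 11, 10, 10, 10, 10, 14, 18, 6, 6, 7, 8)),
    row_tbl("bs_cv", "occipital",        c(11, 18, 9, 10, 14, 10, 19, 21, 7, 7, 9, 9))
  )
  icc <- rbind(
    row_tbl("icc", "acg",              c(-0.24, 0.64, 0.08, 0.00, 0.32, 0.91, 0.59, 0.62, -0.33, -0.18, 0.59, 0.66)),
    row_tbl("icc", "fusiform",         c(-0.38, 0.45, -0.08, -0.12, 0.60, 0.71, 0.67, 0.65, 0.22, 0.27, 0.68, 0.64)),
    row_tbl("icc", "hippocampus",      c(-0.52, 0.89, -0.07, -0.10, 0.35, 0.89, 0.72, 0.72, 0.77, 0.85, 0.95, 0.93)),
    row_tbl("icc", "inferior_frontal", c(-0.41, -0.01, -0.01, -0.02, 0.40, 0.88, 0.76, 0.75, 0.63, 0.66, 0.87, 0.87)),
    row_tbl("icc", "insula",           c(-0.55, 0.51, -0.21, -0.22, -0.73, 0.90, 0.60, 0.63, 0.22, 0.34, 0.74, 0.84)),
    row_tbl("icc", "occipital",        c(-0.65, 0.36, -0.30, -0.30, -0.18, 0.59, 0.72, 0.68, 0.46, 0.50, 0.63, 0.81))
  )
  het <- tibble(
    variant = v,
    ratio = c(1.7, 1.9, 1.8, 1.8, 1.8, 2.2, 1.9, 2.5, 2.1, 1.9, 3.2, 2.8)
  )
  stopifnot(all(matd$region %in% regions))
  list(values = rbind(matd, bscv, icc), heterogeneity = het)
}

#' Summaries of the published benchmark
#'
#' Recomputes the median and IQR across the six comparison regions for every
#' metric and variant of [ro15_benchmark()], display-rounded to the
#' conventional precision (integer % for MA-TD and BS-CV, two decimals for
#' ICC).
#'
#' @return A tibble: `metric`, `variant`, `median`, `q25`, `q75`,
#'   `median_display`, `q25_display`, `q75_display`.
#' @export
ro15_benchmark_summaries <- function() {
  bench <- ro15_benchmark()$values
  combos <- unique(bench[c("metric", "variant")])
  purrr::pmap_dfr(combos, function(metric, variant) {
    rows <- bench[bench$metric == metric & bench$variant == variant, ]
    digits <- if (metric == "icc") 2 else 0
    s <- summarize_by_region(setNames(rows$value, rows$region), digits = digits)
    tibble(metric = metric, variant = variant) |> cbind(s) |> as_tibble()
  })
}
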