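# Frame weighting from true-coincidence rates.

#' Raw frame weights from true-coincidence rates
#'
#' Computes the per-frame weight `w_i = L_i / T_i` where `L_i` is the frame
#' duration (s) and `T_i` the true-coincidence rate (counts/s) of the frame,
#' both taken from non-decay-corrected data. Longer frames carry more counts
#' (more weight); high count rates imply relatively smaller variance per
#' second and hence less weight per unit duration.
#'
#' @param schedule A [frame_schedule()].
#' @param trues_rate Positive numeric vector, counts/s per frame.
#' @return A `frame_weights` tibble with columns `frame`, `duration`,
#'   `trues_rate`, `weight`, and a `mode` attribute (`"raw"` until
#'   normalised).
#' @export
compute_frame_weights <- function(schedule, trues_rate) {
  assert_schedule(schedule)
  if (length(trues_rate) != n_frames(schedule)) {
    abort("`trues_rate` must have one value per frame.")
  }
  if (any(!is.finite(trues_rate)) || any(trues_rate <= 0)) {
    abort("`trues_rate` must be positive and finite for every frame.")
  }
  out <- tibble(
    frame = schedule$frame,
    duration = schedule$duration,
    trues_rate = trues_rate,
    weight = schedule$duration / trues_rate
  )
  structure(out, mode = "raw", class = c("frame_weights", class(out)))
}

#' Normalise frame weights for regional or voxelwise fitting
#'
#' Regional (`mode = "roi"`) weights are scaled to sum to the number of
#' frames, clipped at 2.5, and rescaled; clipping and rescaling are iterated
#' to a joint fixed point so both constraints hold simultaneously. Voxelwise
#' (`mode = "voxel"`) weights are not sum-normalised, but the smallest
#' weights are floored so that `max(weight)/min(weight) <= 1000`.
#'
#' @param w A `frame_weights` tibble from [compute_frame_weights()].
#' @param mode `"roi"` or `"voxel"`.
#' @return The weights tibble with `weight` replaced and `mode` set.
#' @export
normalize_weights <- function(w, mode = c("roi", "voxel")) {
  mode <- match.arg(mode)
  if (!inherits(w, "frame_weights")) {
    abort("`w` must come from `compute_frame_weights()`.")
  }
  x <- w$weight
  if (all(x == 0)) abort("All-zero weights cannot be normalised.")
  n <- length(x)
  if (mode == "roi") {
    # joint fixed point of {scale to sum n, cap at 2.5}, computed directly:
    # cap the m largest weights and rescale the rest to sum n - 2.5 m, with
    # m the smallest count for which the largest uncapped weight stays <= 2.5
    # (water-filling; always feasible because 2.5 n > n)
    ord <- order(x, decreasing = TRUE)
    xs <- x[ord]
    for (m in 0:(n - 1L)) {
      r <- (n - 2.5 * m) / sum(xs[(m + 1L):n])
      if (r * xs[m + 1L] <= 2.5 + 1e-12) break
    }
    xs <- c(rep(2.5, m), r * xs[(m + 1L):n])
    x[ord] <- xs
  } else {
    floor_w <- max(x) / 1000
    x <- pmax(x, floor_w)
  }
  out <- w
  out$weight <- x
  attr(out, "mode") <- mode
  out
}

weights_vector <- function(w, schedule, mode = "roi") {
  if (is.null(w)) return(rep(1, n_frames(schedule)))
  if (inherits(w, "frame_weights")) {
    if (identical(attr(w, "mode"), "raw")) w <- normalize_weights(w, mode)
    return(w$weight)
  }
  if (is.numeric(w) && length(w) == n_frames(schedule)) return(w)
  abort("`weights` must be NULL, a numeric vector, or a `frame_weights` table.")
}
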