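# Logan graphical analysis with arterial input, regional and voxelwise.

# running integral of frame-valued curves from time 0, evaluated at the
# frame midpoints: trapezoid through (0, 0) and the (midpoint, value) knots
frame_integral_matrix <- function(schedule) {
  mids <- frame_midpoints(schedule)
  knots <- c(0, mids)
  n <- length(mids)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    # integral up to mids[i]: sum of trapezoids between successive knots
    for (j in seq_len(i)) {
      h <- knots[j + 1] - knots[j]
      if (j > 1) M[i, j - 1] <- M[i, j - 1] + h / 2
      M[i, j] <- M[i, j] + h / 2
    }
  }
  M
}

#' Logan graphical analysis of a regional TAC
#'
#' After a fixed vascular contribution `fixed_bv * wholeblood` is subtracted
#' from the TAC, the Logan plot of `int TAC' / TAC'` against
#' `int ppIF / TAC'` becomes linear for reversible tracers once `t >= t_star`;
#' its slope estimates VT. The regression uses equal weights over the frames
#' with midpoint at or beyond `t_star`. Points where the vascular-corrected
#' TAC falls below 1% of its own maximum are excluded as numerically
#' unstable; at least 3 points must remain.
#'
#' @param tac A single-region [pet_tac()].
#' @param input A `plasma_input`.
#' @param t_star Start of the linear segment, seconds (default 1680 s = 28 min).
#' @param fixed_bv Fixed fractional blood volume subtracted before analysis
#'   (default 0.028).
#' @return A `kinfit` object (`model = "logan"`) whose `vt` is the slope;
#'   `points` holds the plot coordinates with their inclusion flags.
#' @export
logan_regional <- function(tac, input, t_star = 1680, fixed_bv = 0.028) {
  assert_tac(tac)
  assert_input(input)
  schedule <- tac_schedule(tac)
  check_number(fixed_bv, "fixed_bv", lower = 0, upper = 1 - 1e-9)
  if (t_star >= max(schedule$t_end)) abort("`t_star` must lie within the scan.")
  mids <- frame_midpoints(schedule)
  obs <- tac_activity(tac)
  wb_mid <- approx(input$time, input$whole_blood, mids, rule = 2)$y
  tacp <- obs - fixed_bv * wb_mid

  M <- frame_integral_matrix(schedule)
  int_tac <- as.vector(M %*% tacp)
  # same quadrature for the input integral, so TAC = c * ppIF gives slope c
  pp_mid <- approx(input$time, input$parent_plasma, mids, rule = 2)$y
  int_pp <- as.vector(M %*% pp_mid)

  late <- mids >= t_star
  if (sum(late) < 3) abort("Fewer than 3 frames with midpoint at or beyond `t_star`.")
  ok <- late & tacp > 0.01 * max(tacp)
  if (sum(ok) < 3) abort("Fewer than 3 usable Logan points after exclusions.")
  x <- int_pp[ok] / tacp[ok]
  y <- int_tac[ok] / tacp[ok]
  if (stats::sd(x) == 0) abort("Singular Logan regression (constant abscissa).")
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  fitted_y <- intercept + slope * x
  structure(
    list(
      params = list(slope = slope, intercept = intercept,
                    t_star = t_star, fixed_bv = fixed_bv),
      model = "logan",
      outcome = "VT",
      vt = slope,
      weighted_rss = sum((y - fitted_y)^2),
      n_iter = 0L,
      converged = TRUE,
      weights = as.numeric(ok),
      observed = obs,
      fitted = obs,
      schedule = schedule,
      points = tibble(t_mid = mids, x = int_pp / tacp, y = int_tac / tacp,
                      used = ok)
    ),
    class = "kinfit"
  )
}

# separable Gaussian smoothing; fwhm in mm, voxel_mm a length-3 voxel size
gaussian_smooth_3d <- function(vol, fwhm_mm, voxel_mm) {
  if (fwhm_mm <= 0) return(vol)
  voxel_mm <- rep_len(voxel_mm, 3)
  out <- vol
  for (axis in 1:3) {
    sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm[axis]
    r <- max(1L, ceiling(3 * sigma))
    k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
    k <- k / sum(k)
    out <- convolve_along(out, k, axis)
  }
  out
}

convolve_along <- function(vol, kernel, axis) {
  d <- dim(vol)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  v <- aperm(vol, perm)
  dv <- dim(v)
  m <- matrix(v, nrow = dv[1])
  r <- (length(kernel) - 1L) / 2L
  # replicate-pad ends so the kernel integrates to 1 at the borders
  padded <- rbind(
    m[rep(1L, r), , drop = FALSE], m, m[rep(nrow(m), r), , drop = FALSE]
  )
  sm <- apply(padded, 2, function(col) {
    as.numeric(stats::filter(col, kernel, sides = 2))
  })
  sm <- sm[(r + 1L):(r + nrow(m)), , drop = FALSE]
  aperm(array(sm, dv), order(perm))
}

#' Voxelwise Logan graphical analysis
#'
#' Each frame is pre-smoothed with an isotropic Gaussian filter
#' (default 2.0 mm FWHM), then the Logan regression of [logan_regional()] is
#' solved independently for every in-mask voxel (vectorised across voxels).
#' Voxels with fewer than 3 usable late points get `NaN`.
#'
#' @param dyn 4D dynamic image (x, y, z, frame), decay-corrected kBq/ml.
#' @param input A `plasma_input`.
#' @param schedule A [frame_schedule()].
#' @param mask Logical 3D array of voxels to fit.
#' @param t_star,fixed_bv As in [logan_regional()].
#' @param presmooth_fwhm_mm Gaussian pre-smoothing FWHM in mm (0 disables).
#' @param voxel_mm Voxel size in mm (scalar or length 3).
#' @return A `parametric_image` (see [parametric_image()]) of VT.
#' @export
logan_voxelwise <- function(dyn, input, schedule, mask,
                            t_star = 1680, fixed_bv = 0.028,
                            presmooth_fwhm_mm = 2, voxel_mm = 4) {
  assert_input(input)
  assert_schedule(schedule)
  if (!identical(dim(dyn)[1:3], dim(mask))) {
    abort("`mask` must match the spatial dimensions of `dyn`.")
  }
  mask <- array(as.logical(mask), dim(mask))
  nf <- dim(dyn)[4]
  sm <- dyn
  if (presmooth_fwhm_mm > 0) {
    for (f in seq_len(nf)) {
      sm[, , , f] <- gaussian_smooth_3d(dyn[, , , f], presmooth_fwhm_mm, voxel_mm)
    }
  }
  vox <- which(mask)
  out <- array(NaN, dim(mask))
  if (length(vox) == 0) {
    return(parametric_image(out, mask, outcome = "VT",
                            n_fitted = 0L, n_failed = 0L))
  }
  V <- matrix(sm, nrow = prod(dim(mask)), ncol = nf)[vox, , drop = FALSE]
  mids <- frame_midpoints(schedule)
  wb_mid <- approx(input$time, input$whole_blood, mids, rule = 2)$y
  tacp <- sweep(V, 2, fixed_bv * wb_mid)        # voxels x frames
  M <- frame_integral_matrix(schedule)
  int_tac <- tacp %*% t(M)
  pp_mid <- approx(input$time, input$parent_plasma, mids, rule = 2)$y
  int_pp <- as.vector(M %*% pp_mid)
  late <- mids >= t_star
  if (sum(late) < 3) abort("Fewer than 3 frames with midpoint at or beyond `t_star`.")

  thresh <- 0.01 * apply(tacp, 1, max)
  U <- sweep(tacp, 1, thresh, `>`) & matrix(late, nrow(tacp), nf, byrow = TRUE)
  X <- sweep(1 / tacp, 2, int_pp, `*`)          # x_ij per voxel
  Y <- int_tac / tacp
  X[!U] <- 0
  Y[!U] <- 0
  n <- rowSums(U)
  sx <- rowSums(X); sy <- rowSums(Y)
  sxx <- rowSums(X^2); sxy <- rowSums(X * Y)
  denom <- n * sxx - sx^2
  slope <- (n * sxy - sx * sy) / denom
  slope[n < 3 | abs(denom) < .Machine$double.eps] <- NaN
  out[vox] <- slope
  n_failed <- sum(!is.finite(slope))
  if (n_failed > 0.5 * length(vox)) {
    abort(sprintf("Voxelwise Logan failed for %d of %d voxels (> 50%%).",
                  n_failed, length(vox)))
  }
  parametric_image(out, mask, outcome = "VT",
                   n_fitted = length(vox) - n_failed, n_failed = n_failed)
}
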