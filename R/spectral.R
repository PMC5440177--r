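# "Classic" non-regularised exponential spectral analysis (SA) by NNLS.

#' Build the spectral basis for a given input function
#'
#' The basis frequencies are log-spaced,
#' `beta_j = beta_min * (beta_max / beta_min)^((j-1)/(n-1))`, and each basis
#' column is the frame-averaged convolution of the parent-plasma input with
#' `exp(-beta_j * t)`. Defaults follow the usual practice for slow-kinetics
#' 11C tracers: 100 components between 0.00063 s^-1 (slightly above the 11C
#' decay constant, chosen to suppress noise components) and the fast
#' boundary 0.1 s^-1.
#'
#' @param input A `plasma_input`.
#' @param schedule A [frame_schedule()].
#' @param n Number of basis components (>= 2).
#' @param beta_min,beta_max Frequency boundaries in s^-1.
#' @return A `spectral_basis` object with fields `betas` (s^-1) and `design`
#'   (frames x n matrix).
#' @export
spectral_basis <- function(input, schedule, n = 100,
                           beta_min = 0.00063, beta_max = 0.1) {
  assert_input(input)
  assert_schedule(schedule)
  if (n < 2) abort("`n` must be at least 2.")
  check_number(beta_min, "beta_min", lower = 0, strict_lower = TRUE)
  check_number(beta_max, "beta_max", lower = beta_min, strict_lower = TRUE)
  betas <- beta_min * (beta_max / beta_min)^((seq_len(n) - 1) / (n - 1))
  tg <- fine_grid(schedule, min(1, diff(input$time[1:2])))
  pp <- input_on_grid(input, tg)$parent_plasma
  dt <- tg[2] - tg[1]
  op <- frame_avg_op(schedule, tg)
  design <- vapply(
    betas,
    function(b) as.vector(op %*% exp_conv(pp, b, dt)),
    numeric(n_frames(schedule))
  )
  structure(
    list(betas = betas, design = design, schedule = schedule),
    class = "spectral_basis"
  )
}

#' @export
print.spectral_basis <- function(x, ...) {
  cat(sprintf(
    "<spectral_basis> %d components, beta in [%g, %g] s^-1, %d frames\n",
    length(x$betas), min(x$betas), max(x$betas), nrow(x$design)
  ))
  invisible(x)
}

#' Spectral analysis of a regional TAC
#'
#' Solves the non-negative least squares problem
#' `min || sqrt(w) (TAC - design %*% alpha) ||^2, alpha >= 0` and reports
#' `VT = sum(alpha_j / beta_j)` over all components. Mass on the boundary
#' components is reported as a diagnostic, since it signals kinetics at the
#' edge of the representable range.
#'
#' @param tac A single-region [pet_tac()].
#' @param basis A [spectral_basis()].
#' @param weights Frame weights (`NULL` for equal); see [fit_compartmental()].
#' @return A `pet_spectrum` object with fields `spectrum` (tibble of `beta`,
#'   `alpha`), `vt`, `weighted_rss`, `boundary_mass`.
#' @export
sa_fit <- function(tac, basis, weights = NULL) {
  assert_tac(tac)
  if (!inherits(basis, "spectral_basis")) {
    abort("`basis` must come from `spectral_basis()`.")
  }
  obs <- tac_activity(tac)
  schedule <- tac_schedule(tac)
  if (length(obs) != nrow(basis$design)) {
    abort("TAC and basis use different frame schedules.")
  }
  w <- weights_vector(weights, schedule, mode = "roi")
  sw <- sqrt(w)
  alpha <- nnls_solve(basis$design * sw, obs * sw)
  fitted <- as.vector(basis$design %*% alpha)
  vt <- sum(alpha / basis$betas)
  nb <- length(basis$betas)
  boundary <- (alpha[1] / basis$betas[1] + alpha[nb] / basis$betas[nb])
  structure(
    list(
      spectrum = tibble(beta = basis$betas, alpha = alpha),
      vt = vt,
      weighted_rss = sum(w * (obs - fitted)^2),
      boundary_mass = if (vt > 0) boundary / vt else 0,
      observed = obs,
      fitted = fitted,
      schedule = schedule
    ),
    class = "pet_spectrum"
  )
}

#' @export
print.pet_spectrum <- function(x, ...) {
  cat(sprintf(
    "<pet_spectrum> VT = %.4g, %d non-zero components, weighted RSS = %.4g\n",
    x$vt, sum(x$spectrum$alpha > 0), x$weighted_rss
  ))
  invisible(x)
}

#' Voxelwise spectral analysis
#'
#' Runs [sa_fit()] for every in-mask voxel (no pre-smoothing). Identical
#' voxel TACs are solved once and shared, which makes noiseless phantoms
#' cheap without affecting noisy data.
#'
#' @param dyn 4D dynamic image, decay-corrected kBq/ml.
#' @param basis A [spectral_basis()].
#' @param weights Per-frame voxel weights (`NULL` for equal); bounded per the
#'   voxel-mode rules of [normalize_weights()].
#' @param mask Logical 3D array.
#' @return A `parametric_image` of VT with an `rss` image in its provenance.
#' @export
sa_voxelwise <- function(dyn, basis, weights = NULL, mask = NULL) {
  if (!inherits(basis, "spectral_basis")) {
    abort("`basis` must come from `spectral_basis()`.")
  }
  schedule <- basis$schedule
  if (is.null(mask)) mask <- array(TRUE, dim(dyn)[1:3])
  mask <- array(as.logical(mask), dim(mask))
  w <- weights_vector(weights, schedule, mode = "voxel")
  sw <- sqrt(w)
  vox <- which(mask)
  out <- array(NaN, dim(mask))
  rss_img <- array(NaN, dim(mask))
  if (length(vox) == 0) {
    return(parametric_image(out, mask, outcome = "VT",
                            n_fitted = 0L, n_failed = 0L))
  }
  V <- matrix(dyn, nrow = prod(dim(mask)), ncol = dim(dyn)[4])[vox, , drop = FALSE]
  B <- t(V) * sw                               # frames x voxels, row-scaled
  key <- apply(B, 2, function(col) paste(col, collapse = "\r"))
  uniq <- !duplicated(key)
  sol <- nnls_solve_many(basis$design * sw, B[, uniq, drop = FALSE])
  map <- match(key, key[uniq])
  vt_u <- colSums(sol$coef / basis$betas)
  out[vox] <- vt_u[map]
  rss_img[vox] <- sol$rss[map]
  parametric_image(out, mask, outcome = "VT",
                   n_fitted = sum(is.finite(out[vox])),
                   n_failed = sum(!is.finite(out[vox])),
                   rss = rss_img)
}
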