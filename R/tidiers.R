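# broom-style tidy()/glance()/augment() methods for fitted objects.

#' Tidy a kinetic fit
#'
#' @param x A `kinfit` from [fit_compartmental()], [logan_regional()] or
#'   [fit_srtm()].
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`.
#' @export
tidy.kinfit <- function(x, ...) {
  p <- x$params
  if (inherits(p, "kinetic_params")) {
    terms <- c("K1", "k2", "k3", "k4", "bv")
    est <- c(p$K1, p$k2, p$k3, p$k4, p$bv)
    keep <- !is.na(est)
    tibble(term = terms[keep], estimate = est[keep])
  } else if (inherits(p, "srtm_params")) {
    tibble(term = c("r1", "k2a", "k2ref"),
           estimate = c(p$r1, p$k2a, p$k2ref))
  } else {
    tibble(term = names(p), estimate = unlist(p, use.names = FALSE))
  }
}

#' One-row summary of a kinetic fit
#'
#' @inheritParams tidy.kinfit
#' @return A one-row tibble: `model`, `outcome`, `value`, `weighted_rss`,
#'   `n_iter`, `converged`.
#' @export
glance.kinfit <- function(x, ...) {
  tibble(model = x$model, outcome = x$outcome, value = x$vt,
         weighted_rss = x$weighted_rss, n_iter = x$n_iter,
         converged = x$converged)
}

#' Observed and fitted frame values of a kinetic fit
#'
#' @inheritParams tidy.kinfit
#' @return A tibble: `t_mid` (s), `observed`, `fitted`, `weight`, `residual`.
#' @export
augment.kinfit <- function(x, ...) {
  tibble(
    t_mid = frame_midpoints(x$schedule),
    observed = x$observed,
    fitted = x$fitted,
    weight = x$weights,
    residual = x$observed - x$fitted
  )
}

#' Tidy a spectral-analysis result
#'
#' @param x A `pet_spectrum` from [sa_fit()].
#' @param ... Unused.
#' @return The spectrum tibble: `beta` (s^-1), `alpha`.
#' @export
tidy.pet_spectrum <- function(x, ...) x$spectrum

#' One-row summary of a spectral-analysis result
#'
#' @inheritParams tidy.pet_spectrum
#' @return A one-row tibble: `vt`, `weighted_rss`, `n_components`,
#'   `boundary_mass`.
#' @export
glance.pet_spectrum <- function(x, ...) {
  tibble(vt = x$vt, weighted_rss = x$weighted_rss,
         n_components = sum(x$spectrum$alpha > 0),
         boundary_mass = x$boundary_mass)
}

#' Tidy a plasma input function
#'
#' @param x A `plasma_input`.
#' @param ... Unused.
#' @return A tibble: `time_s`, `parent_plasma_kBq_per_ml`,
#'   `whole_blood_kBq_per_ml`.
#' @export
tidy.plasma_input <- function(x, ...) as_tibble(x)
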