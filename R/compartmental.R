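# Reversible one- and two-tissue compartment models with fitted blood
# volume (2kbv / 4kbv).

#' Compartmental model parameters
#'
#' @param K1 Plasma-to-tissue influx rate, ml cm^-3 min^-1.
#' @param k2 Tissue-to-plasma efflux rate, min^-1.
#' @param k3,k4 Exchange rates with the specifically bound compartment,
#'   min^-1; leave `NA` for the one-tissue (2kbv) model.
#' @param bv Fractional blood volume in \[0, 1).
#' @return A `kinetic_params` object; its `model` field is `"2kbv"` or
#'   `"4kbv"` depending on whether `k3`/`k4` are given.
#' @export
kinetic_params <- function(K1, k2, k3 = NA, k4 = NA, bv = 0) {
  if (any(c(K1, k2, k3[!is.na(k3)], k4[!is.na(k4)]) < 0)) {
    abort("Rate constants must be non-negative.")
  }
  if (bv < 0 || bv >= 1) abort("`bv` must be in [0, 1).")
  if (is.na(k3) != is.na(k4)) abort("Give both `k3` and `k4`, or neither.")
  structure(
    list(K1 = K1, k2 = k2, k3 = k3, k4 = k4, bv = bv,
         model = if (is.na(k3)) "2kbv" else "4kbv"),
    class = "kinetic_params"
  )
}

#' Total volume of distribution from compartmental parameters
#'
#' `VT = K1/k2` for the one-tissue model and `VT = K1/k2 (1 + k3/k4)` for
#' the two-tissue model.
#'
#' @param p A [kinetic_params()] object.
#' @return VT in ml/cm^3.
#' @export
vt_from_params <- function(p) {
  if (!inherits(p, "kinetic_params")) abort("`p` must be `kinetic_params`.")
  if (p$k2 <= 0) abort("VT requires k2 > 0.")
  if (p$model == "2kbv") return(p$K1 / p$k2)
  if (p$k4 <= 0) abort("VT requires k4 > 0 for the two-tissue model.")
  p$K1 / p$k2 * (1 + p$k3 / p$k4)
}

# impulse-response amplitudes (per min) and eigenvalues (min^-1)
impulse_response <- function(p) {
  if (p$model == "2kbv") {
    return(list(phi = p$K1, alpha = p$k2))
  }
  s <- p$k2 + p$k3 + p$k4
  d <- sqrt(max(s^2 - 4 * p$k2 * p$k4, 0))
  a1 <- (s + d) / 2
  a2 <- (s - d) / 2
  if (a1 == a2) {
    # repeated eigenvalue; nudge apart within numerical tolerance
    a1 <- a1 * (1 + 1e-9)
  }
  phi1 <- p$K1 * (p$k3 + p$k4 - a1) / (a2 - a1)
  phi2 <- p$K1 * (a2 - p$k3 - p$k4) / (a2 - a1)
  list(phi = c(phi1, phi2), alpha = c(a1, a2))
}

# tissue concentration on the fine grid (kBq/ml); rates are min^-1 and the
# grid is seconds, hence the /60 factors
tissue_curve <- function(p, ppif_fine, tg) {
  ir <- impulse_response(p)
  dt <- tg[2] - tg[1]
  ct <- 0
  for (j in seq_along(ir$phi)) {
    ct <- ct + ir$phi[j] * exp_conv(ppif_fine, ir$alpha[j] / 60, dt)
  }
  ct / 60
}

#' Simulate a tissue time-activity curve
#'
#' Forward model: the tissue impulse response (single exponential for 2kbv,
#' two-exponential for 4kbv) convolved with the parent-plasma input on a
#' fine grid, combined with whole blood as
#' `(1 - bv) * C_tissue + bv * C_wholeblood`, then averaged over each frame.
#'
#' @param p A [kinetic_params()] object.
#' @param input A `plasma_input` (see [build_ppif()]).
#' @param schedule A [frame_schedule()].
#' @param region Label for the output curve.
#' @return A [pet_tac()] with one curve.
#' @export
simulate_tissue_tac <- function(p, input, schedule, region = "simulated") {
  if (!inherits(p, "kinetic_params")) abort("`p` must be `kinetic_params`.")
  assert_input(input)
  assert_schedule(schedule)
  tg <- fine_grid(schedule, min(1, diff(input$time[1:2])))
  if (diff(tg[1:2]) > 1) abort("Input grid spacing must be <= 1 s.")
  cur <- input_on_grid(input, tg)
  ct <- tissue_curve(p, cur$parent_plasma, tg)
  meas <- (1 - p$bv) * ct + p$bv * cur$whole_blood
  pet_tac(schedule, frame_average(meas, tg, schedule), region = region)
}

#' Fit a reversible compartment model to a regional TAC
#'
#' Minimises the weighted residual sum of squares by Nelder-Mead, starting
#' from the conventional estimates `K1 = 0.01 ml cm^-3 min^-1`,
#' `k2 (= k3 = k4) = 0.001 min^-1`, `bv = 0.05`. Rates are optimised on the
#' log scale and `bv` on the logit scale, so the constraints `rate >= 0` and
#' `0 <= bv < 1` hold by construction.
#'
#' @param tac A single-region [pet_tac()].
#' @param input A `plasma_input`.
#' @param weights Frame weights: `NULL` (equal), a numeric vector, or a
#'   [compute_frame_weights()] table (roi-normalised before use).
#' @param model `"2kbv"` or `"4kbv"`.
#' @param max_iter Maximum Nelder-Mead iterations per start.
#' @param restarts Number of restarts from the incumbent solution.
#' @return A `kinfit` object with fields `params` ([kinetic_params()]),
#'   `vt`, `weighted_rss`, `n_iter`, `converged`, `fitted` and `observed`.
#' @export
fit_compartmental <- function(tac, input, weights = NULL,
                              model = c("2kbv", "4kbv"),
                              max_iter = 5000, restarts = 3) {
  model <- match.arg(model)
  assert_tac(tac)
  assert_input(input)
  schedule <- tac_schedule(tac)
  obs <- tac_activity(tac)
  w <- weights_vector(weights, schedule, mode = "roi")
  tg <- fine_grid(schedule, min(1, diff(input$time[1:2])))
  cur <- input_on_grid(input, tg)
  if (max(abs(obs)) == 0 || stats::sd(obs) == 0) {
    abort("Degenerate flat TAC; nothing to fit.")
  }

  n_par <- if (model == "2kbv") 3L else 5L
  unpack <- function(par) {
    if (model == "2kbv") {
      kinetic_params(exp(par[1]), exp(par[2]), bv = stats::plogis(par[3]))
    } else {
      kinetic_params(exp(par[1]), exp(par[2]), exp(par[3]), exp(par[4]),
                     bv = stats::plogis(par[5]))
    }
  }
  op <- frame_avg_op(schedule, tg)
  predict_frames <- function(p) {
    ct <- tissue_curve(p, cur$parent_plasma, tg)
    as.vector(op %*% ((1 - p$bv) * ct + p$bv * cur$whole_blood))
  }
  # soft box on the log/logit scale: rates confined to [e^-18, e^6] min^-1,
  # far outside any physiology, so the simplex cannot run away on flat tails
  obj <- function(par) {
    excess <- sum(pmax(par - 6, 0)) + sum(pmax(-18 - par, 0))
    if (excess > 0) return(1e10 * (1 + excess))
    pred <- predict_frames(unpack(par))
    sum(w * (obs - pred)^2)
  }
  # the conventional start first, then two spread starts: on noisy data the
  # likelihood can trap the simplex at k4 ~ 0 (unbounded VT)
  starts <- if (model == "2kbv") {
    list(c(log(0.01), log(0.001), stats::qlogis(0.05)),
         c(log(0.1), log(0.05), stats::qlogis(0.05)),
         c(log(0.4), log(0.2), stats::qlogis(0.05)))
  } else {
    list(c(log(0.01), log(0.001), log(0.001), log(0.001), stats::qlogis(0.05)),
         c(log(0.1), log(0.05), log(0.05), log(0.05), stats::qlogis(0.05)),
         c(log(0.4), log(0.25), log(0.3), log(0.15), stats::qlogis(0.05)))
  }
  fit <- NULL
  n_iter <- 0L
  for (s0 in starts) {
    cand <- optim(s0, obj, method = "Nelder-Mead",
                  control = list(maxit = max_iter, reltol = 1e-12))
    n_iter <- n_iter + cand$counts[1]
    if (is.null(fit) || cand$value < fit$value) fit <- cand
  }
  for (r in seq_len(restarts)) {
    again <- optim(fit$par, obj, method = "Nelder-Mead",
                   control = list(maxit = max_iter, reltol = 1e-12))
    n_iter <- n_iter + again$counts[1]
    improved <- again$value < fit$value - 1e-12 * (1 + fit$value)
    fit <- if (again$value <= fit$value) again else fit
    if (!improved) break
  }
  p <- unpack(fit$par)
  pred <- predict_frames(p)
  res <- structure(
    list(
      params = p,
      model = model,
      outcome = "VT",
      vt = vt_from_params(p),
      weighted_rss = fit$value,
      n_iter = as.integer(n_iter),
      converged = fit$convergence == 0,
      weights = w,
      observed = obs,
      fitted = pred,
      schedule = schedule
    ),
    class = "kinfit"
  )
  if (!res$converged) {
    warn(sprintf("%s fit did not converge within %d iterations.", model, max_iter))
  }
  res
}

#' @export
print.kinfit <- function(x, ...) {
  cat(sprintf(
    "<kinfit:%s> %s = %.4g, weighted RSS = %.4g, converged = %s\n",
    x$model, x$outcome, x$vt, x$weighted_rss, x$converged
  ))
  invisible(x)
}

# residual-based within-fit coefficient of variation (%), used by the
# regional outlier rule
fit_residual_cv <- function(fit) {
  p <- switch(fit$model,
    "2kbv" = 3, "4kbv" = 5, "logan" = 2, "srtm" = 3
  )
  n <- length(fit$observed)
  100 * sqrt(max(fit$weighted_rss, 0) / max(n - p, 1)) / mean(fit$fitted)
}
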