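# Four-parameter sigmoid for the plasma-over-blood ratio and the parent
# (unmetabolised tracer) fraction.

#' Four-parameter sigmoid model for blood-curve corrections
#'
#' The model value at time `t` (seconds from scan start) is
#' `1 - (x1 + x2 * t_h) / ((x3 / t_h)^x4 + 1)` with `t_h = t / 3600` (hours).
#' For `x4 > 0` the value tends to 1 as `t -> 0`, so the parent fraction
#' starts at 1 and declines while metabolites accumulate; with negative
#' `x1`/`x2` the same family rises above 1, which describes the
#' plasma-over-blood ratio.
#'
#' @param x1,x2,x3,x4 Model parameters; `x3 > 0` (time scale, hours) and
#'   `x4 > 0` (shape).
#' @param kind `"parent_fraction"` (values clipped to \[0, 1\]) or
#'   `"plasma_over_blood"` (values clipped to be non-negative).
#' @return A `sigmoid_model` object.
#' @export
sigmoid_model <- function(x1, x2, x3, x4,
                          kind = c("parent_fraction", "plasma_over_blood")) {
  kind <- match.arg(kind)
  check_number(x3, "x3", lower = 0, strict_lower = TRUE)
  check_number(x4, "x4", lower = 0, strict_lower = TRUE)
  structure(
    list(x1 = x1, x2 = x2, x3 = x3, x4 = x4, kind = kind),
    class = "sigmoid_model"
  )
}

#' Evaluate a sigmoid model
#'
#' @param m A [sigmoid_model()].
#' @param t Time in seconds from scan start (non-negative).
#' @return Model values, clipped according to the model `kind`; the `t = 0`
#'   value is the analytic limit 1.
#' @export
eval_sigmoid <- function(m, t) {
  if (!inherits(m, "sigmoid_model")) abort("`m` must be a `sigmoid_model`.")
  if (any(t < 0)) abort("`t` must be non-negative.")
  th <- t / 3600
  v <- numeric(length(th))
  pos <- th > 0
  v[!pos] <- 1
  v[pos] <- 1 - (m$x1 + m$x2 * th[pos]) / ((m$x3 / th[pos])^m$x4 + 1)
  if (m$kind == "parent_fraction") pmin(pmax(v, 0), 1) else pmax(v, 0)
}

#' @export
print.sigmoid_model <- function(x, ...) {
  cat(sprintf(
    "<sigmoid_model: %s> x1 = %.4g, x2 = %.4g, x3 = %.4g h, x4 = %.4g\n",
    x$kind, x$x1, x$x2, x$x3, x$x4
  ))
  invisible(x)
}

#' Fit the sigmoid model to measured fractions
#'
#' Least-squares fit by Nelder-Mead on the sum of squared residuals, with
#' `x3` and `x4` optimised on the log scale to keep them positive. A few
#' restarts from perturbed solutions guard against premature simplex
#' collapse.
#'
#' @param time_s Sample times, seconds from scan start.
#' @param value Measured fractions (parent fraction or plasma-over-blood
#'   ratio) at `time_s`.
#' @inheritParams sigmoid_model
#' @param max_iter Maximum Nelder-Mead iterations per start.
#' @return A fitted [sigmoid_model()] with attributes `rss` (residual sum of
#'   squares) and `converged`.
#' @export
fit_sigmoid <- function(time_s, value,
                        kind = c("parent_fraction", "plasma_over_blood"),
                        max_iter = 2000) {
  kind <- match.arg(kind)
  if (length(time_s) != length(value)) {
    abort("`time_s` and `value` must have the same length.")
  }
  keep <- is.finite(time_s) & is.finite(value)
  time_s <- time_s[keep]
  value <- value[keep]
  if (length(value) < 4L) {
    abort("At least 4 data points are needed to fit the 4-parameter sigmoid.")
  }
  th <- time_s / 3600
  obj <- function(p) {
    m <- list(x1 = p[1], x2 = p[2], x3 = exp(p[3]), x4 = exp(p[4]))
    pred <- ifelse(th > 0,
      1 - (m$x1 + m$x2 * th) / ((m$x3 / th)^m$x4 + 1), 1
    )
    sum((value - pred)^2)
  }
  # data-driven start: asymptote from the latest sample, midpoint time scale
  x1_0 <- 1 - value[which.max(th)]
  t_mid <- stats::weighted.mean(range(th[th > 0]))
  start <- c(x1_0, 0, log(max(t_mid, 1e-3)), log(2))
  best <- optim(start, obj, method = "Nelder-Mead",
                control = list(maxit = max_iter, reltol = 1e-12))
  for (i in 1:2) {
    cand <- optim(best$par * (1 + 0.05 * i) + c(0.01, 0.01, 0, 0) * i, obj,
                  method = "Nelder-Mead",
                  control = list(maxit = max_iter, reltol = 1e-12))
    if (cand$value < best$value) best <- cand
    refine <- optim(best$par, obj, method = "Nelder-Mead",
                    control = list(maxit = max_iter, reltol = 1e-12))
    if (refine$value < best$value) best <- refine
  }
  m <- sigmoid_model(best$par[1], best$par[2], exp(best$par[3]),
                     exp(best$par[4]), kind = kind)
  attr(m, "rss") <- best$value
  attr(m, "converged") <- best$convergence == 0
  m
}
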