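# Fine-grid convolution machinery shared by all kinetic models.
#
# All tissue models reduce to convolutions of the input curve with decaying
# exponentials. On a uniform 1-s grid the convolution
#   y(t) = int_0^t x(s) exp(-beta (t - s)) ds
# obeys the exact trapezoid recursion
#   y[i] = a y[i-1] + dt/2 (x[i] + a x[i-1]),  a = exp(-beta dt),
# which stats::filter() evaluates in C. beta = 0 degenerates to a running
# integral, which is the correct limit.

fine_grid <- function(schedule, dt = 1) {
  assert_schedule(schedule)
  seq(0, max(schedule$t_end), by = dt)
}

exp_conv <- function(x, beta_per_s, dt) {
  a <- exp(-beta_per_s * dt)
  b <- dt / 2 * (x + a * c(0, x[-length(x)]))
  as.numeric(stats::filter(b, a, method = "recursive"))
}

# frame-averaging operator: a (n_frames x n_grid) matrix whose product with
# a fine-grid curve gives the per-frame means; built once per fit so the
# optimiser loop is a single matrix product
frame_avg_op <- function(schedule, tg) {
  nf <- n_frames(schedule)
  A <- matrix(0, nf, length(tg))
  for (i in seq_len(nf)) {
    sel <- tg >= schedule$t_start[i] & tg <= schedule$t_end[i]
    A[i, sel] <- 1 / sum(sel)
  }
  A
}

# duration-weighted mean of a fine-grid curve over each frame
frame_average <- function(curve, tg, schedule, op = NULL) {
  if (is.null(op)) op <- frame_avg_op(schedule, tg)
  as.vector(op %*% curve)
}

# interpolate a plasma_input onto a fine grid aligned with the schedule;
# the stored grid is already 1 s so this is usually the identity
input_on_grid <- function(input, tg) {
  list(
    parent_plasma = approx(input$time, input$parent_plasma, tg, rule = 2)$y,
    whole_blood   = approx(input$time, input$whole_blood, tg, rule = 2)$y
  )
}
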