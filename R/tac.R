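# Time-activity curves as tidy tibbles.

#' Construct a time-activity curve table
#'
#' A TAC holds the radioactivity concentration (kBq/ml) of one or more
#' regions (or voxels) per acquisition frame. Multiple curves share one
#' schedule and one decay-correction state, which makes a long tibble the
#' natural container.
#'
#' @param schedule A [frame_schedule()].
#' @param activity Numeric vector (one curve), matrix (frames x curves), or
#'   named list of numeric vectors.
#' @param region Region label(s); recycled to the number of curves.
#' @param decay_corrected Logical; whether `activity` is decay-corrected.
#' @return A `pet_tac` tibble with columns `region`, `frame`, `t_start`,
#'   `t_end`, `activity` and attributes `schedule`, `decay_corrected`.
#' @export
pet_tac <- function(schedule, activity, region = "roi", decay_corrected = TRUE) {
  assert_schedule(schedule)
  if (is.list(activity) && !is.data.frame(activity)) {
    region <- names(activity) %||% region
    activity <- do.call(cbind, activity)
  }
  if (is.matrix(activity)) {
    if (nrow(activity) != n_frames(schedule)) {
      abort("`activity` must have one row per frame.")
    }
    region <- rep_len(region, ncol(activity))
    act <- as.vector(activity)
    reg <- rep(region, each = n_frames(schedule))
  } else {
    if (length(activity) != n_frames(schedule)) {
      abort("`activity` must have one value per frame.")
    }
    act <- activity
    reg <- rep(region[[1]], n_frames(schedule))
  }
  if (any(!is.finite(act))) abort("TAC activity values must be finite.")
  out <- tibble(
    region  = reg,
    frame   = rep(schedule$frame, times = length(act) / n_frames(schedule)),
    t_start = rep(schedule$t_start, times = length(act) / n_frames(schedule)),
    t_end   = rep(schedule$t_end, times = length(act) / n_frames(schedule)),
    activity = act
  )
  new_pet_tac(out, schedule, decay_corrected)
}

new_pet_tac <- function(df, schedule, decay_corrected) {
  structure(df,
    schedule = schedule,
    decay_corrected = isTRUE(decay_corrected),
    class = c("pet_tac", setdiff(class(df), "pet_tac"))
  )
}

assert_tac <- function(tac) {
  if (!inherits(tac, "pet_tac")) {
    abort("Expected a `pet_tac` object (see `pet_tac()`).")
  }
  invisible(tac)
}

tac_schedule <- function(tac) attr(tac, "schedule")

is_decay_corrected <- function(tac) isTRUE(attr(tac, "decay_corrected"))

# frames x regions matrix, preserving first-appearance region order
tac_matrix <- function(tac) {
  assert_tac(tac)
  regs <- unique(tac$region)
  m <- vapply(
    regs,
    function(r) tac$activity[tac$region == r],
    numeric(n_frames(tac_schedule(tac)))
  )
  matrix(m, ncol = length(regs), dimnames = list(NULL, regs))
}

tac_activity <- function(tac, region = NULL) {
  assert_tac(tac)
  if (is.null(region)) region <- unique(tac$region)[[1]]
  tac$activity[tac$region == region]
}

#' Apply or remove radioactive decay correction
#'
#' Scales each frame value by `exp(lambda * t_mid)` (`direction = "apply"`) or
#' its inverse (`direction = "remove"`), with `t_mid` the frame midpoint.
#' Applying then removing is the identity.
#'
#' @param tac A [pet_tac()].
#' @param direction `"apply"` (correct measured data back to injection-time
#'   activity) or `"remove"` (re-impose physical decay).
#' @return A `pet_tac` with the `decay_corrected` flag flipped.
#' @export
decay_correct <- function(tac, direction = c("apply", "remove")) {
  assert_tac(tac)
  direction <- match.arg(direction)
  if (direction == "apply" && is_decay_corrected(tac)) {
    abort("TAC is already decay-corrected; cannot apply the correction twice.")
  }
  if (direction == "remove" && !is_decay_corrected(tac)) {
    abort("TAC is not decay-corrected; nothing to remove.")
  }
  schedule <- tac_schedule(tac)
  lambda <- attr(schedule, "decay_constant")
  fac <- exp(lambda * frame_midpoints(schedule))
  fac <- fac[tac$frame]
  out <- tac
  out$activity <- if (direction == "apply") tac$activity * fac else tac$activity / fac
  new_pet_tac(out, schedule, direction == "apply")
}

#' Duration-weighted summation image over a frame range
#'
#' Collapses a 4D dynamic image into the 3D duration-weighted mean of the
#' decay-corrected frame values, as used for co-registration targets, global
#' radioactivity and SUV windows. Frame indices are 1-based.
#'
#' @param dyn 4D array (x, y, z, frame), kBq/ml.
#' @param schedule The acquisition [frame_schedule()].
#' @param frames Inclusive 1-based frame index range, e.g. `c(16, 21)`.
#' @param decay_corrected Whether `dyn` is already decay-corrected; if `FALSE`
#'   the correction is applied per frame before averaging.
#' @return 3D array in kBq/ml.
#' @export
sum_frames <- function(dyn, schedule, frames = c(1, n_frames(schedule)),
                       decay_corrected = TRUE) {
  assert_schedule(schedule)
  if (length(dim(dyn)) != 4L) abort("`dyn` must be a 4D array.")
  if (dim(dyn)[4] != n_frames(schedule)) {
    abort("`dyn` must have one volume per frame of `schedule`.")
  }
  frames <- as.integer(frames)
  if (length(frames) != 2L || frames[1] > frames[2] ||
      frames[1] < 1L || frames[2] > n_frames(schedule)) {
    abort("`frames` must be an inclusive index range within the schedule.")
  }
  idx <- seq(frames[1], frames[2])
  durs <- schedule$duration[idx]
  fac <- if (decay_corrected) rep(1, length(idx)) else
    exp(attr(schedule, "decay_constant") * frame_midpoints(schedule)[idx])
  out <- array(0, dim(dyn)[1:3])
  for (k in seq_along(idx)) {
    out <- out + dyn[, , , idx[k]] * durs[k] * fac[k]
  }
  out / sum(durs)
}

# mean TAC over a voxel set given as a logical/index vector into the volume
roi_mean_tac <- function(dyn, voxels) {
  nf <- dim(dyn)[4]
  nv <- prod(dim(dyn)[1:3])
  m <- matrix(dyn, nrow = nv, ncol = nf)
  colMeans(m[voxels, , drop = FALSE])
}

#' Write or read a TAC table as CSV
#'
#' One row per region and frame: `region`, `frame_index` (1-based),
#' `t_start_s`, `t_end_s`, `activity_kBq_per_ml`. A `# decay_corrected:`
#' header comment records the correction state; the schedule's injection
#' time and decay constant travel in further header comments so the table
#' is self-describing.
#'
#' @param tac A [pet_tac()].
#' @param path File path.
#' @return `write_tac_csv()` returns `path` invisibly; `read_tac_csv()`
#'   returns a [pet_tac()].
#' @export
write_tac_csv <- function(tac, path) {
  assert_tac(tac)
  schedule <- tac_schedule(tac)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# decay_corrected: %s", tolower(is_decay_corrected(tac))),
    sprintf("# injection_time_s: %g", attr(schedule, "injection_time")),
    sprintf("# decay_constant_per_s: %g", attr(schedule, "decay_constant"))
  ), con)
  df <- data.frame(
    region = tac$region,
    frame_index = tac$frame,
    t_start_s = tac$t_start,
    t_end_s = tac$t_end,
    activity_kBq_per_ml = tac$activity
  )
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tac_csv
#' @export
read_tac_csv <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  field <- function(key, default) {
    line <- grep(key, hdr, value = TRUE)
    if (length(line) == 0) return(default)
    trimws(sub(paste0(".*", key, ":"), "", line[1]))
  }
  dc <- identical(field("decay_corrected", "true"), "true")
  inj <- as.numeric(field("injection_time_s", "30"))
  lam <- as.numeric(field("decay_constant_per_s", as.character(lambda_c11())))
  df <- utils::read.csv(path, comment.char = "#")
  first <- df[df$region == df$region[1], ]
  schedule <- frame_schedule(
    tibble(count = rep(1L, nrow(first)),
           duration_s = first$t_end_s - first$t_start_s),
    injection_time = inj, decay_constant = lam
  )
  regions <- unique(df$region)
  act <- vapply(regions,
                function(r) df$activity_kBq_per_ml[df$region == r],
                numeric(nrow(first)))
  pet_tac(schedule, matrix(act, ncol = length(regions),
                           dimnames = list(NULL, regions)),
          region = regions, decay_corrected = dc)
}
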