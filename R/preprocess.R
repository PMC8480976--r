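#' Mark blink intervals in a trace
#'
#' Every run of invalid samples (tracker signal loss) is widened by a
#' symmetric margin and set invalid, because pupil-size artifacts
#' contaminate the samples immediately around a blink. The number of
#' newly masked samples is recorded in the `blink_masked` attribute.
#'
#' @param trace An eye trace.
#' @param margin_s Margin in seconds masked on each side of every invalid
#'   run (default 0.1 s).
#' @return The trace with an updated `valid` column.
#' @export
mark_blinks <- function(trace, margin_s = 0.1) {
  stopifnot(inherits(trace, "eye_trace"), margin_s >= 0)
  m <- as.integer(round(margin_s * SAMPLE_RATE_HZ))
  valid <- trace$valid
  if (all(valid) || m == 0) {
    attr(trace, "blink_masked") <- sum(!valid)
    return(trace)
  }
  n <- length(valid)
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  newv <- valid
  for (k in which(!r$values)) {
    lo <- max(1L, starts[k] - m)
    hi <- min(n, ends[k] + m)
    newv[lo:hi] <- FALSE
  }
  trace$valid <- newv
  attr(trace, "blink_masked") <- sum(!newv)
  trace
}

#' Fit a five-point gaze calibration
#'
#' Per-axis affine least-squares fit (gain and offset) of the median raw
#' position during each calibration fixation against the known target
#' position in degrees. The fixation window is the last 1 s of each 2 s
#' presentation (skipping the saccadic approach), pooled over both
#' repetitions of each target. A target is usable if it has at least
#' 0.5 s of valid samples; at least four of the five targets must be
#' usable.
#'
#' @param trace A (filtered) [raw_trace()] of the calibration task.
#' @param sched The calibration [task_schedule()].
#' @return An object of class `calibration_model` with fields `gain_x`,
#'   `offset_x`, `gain_y`, `offset_y`, `residual_rmse`, `n_targets`.
#' @export
fit_calibration <- function(trace, sched) {
  stopifnot(inherits(trace, "raw_trace"), sched$task == "calibration")
  ev <- sched$events
  key <- paste(ev$x, ev$y)
  targets <- unique(data.frame(x = ev$x, y = ev$y, key = key))
  med <- lapply(seq_len(nrow(targets)), function(i) {
    rows <- ev[key == targets$key[i], ]
    sel <- rep(FALSE, nrow(trace))
    for (j in seq_len(nrow(rows))) {
      w0 <- max(rows$t_on[j], rows$t_off[j] - 1)
      sel <- sel | (trace$t >= w0 & trace$t < rows$t_off[j])
    }
    sel <- sel & trace$valid
    if (sum(sel) < 0.5 * SAMPLE_RATE_HZ) return(NULL)
    c(raw_x = stats::median(trace$x_raw[sel]),
      raw_y = stats::median(trace$y_raw[sel]))
  })
  usable <- !vapply(med, is.null, logical(1))
  if (sum(usable) < 4) {
    stop(sprintf("calibration failed: only %d of 5 targets have enough valid fixation data",
                 sum(usable)), call. = FALSE)
  }
  raw <- do.call(rbind, med[usable])
  deg <- targets[usable, c("x", "y")]
  fx <- affine_fit(raw[, "raw_x"], deg$x)
  fy <- affine_fit(raw[, "raw_y"], deg$y)
  if (abs(fx$gain) < 1e-12 || abs(fy$gain) < 1e-12) {
    stop("degenerate calibration: zero gain", call. = FALSE)
  }
  rmse <- sqrt(mean(c(fx$resid, fy$resid)^2))
  structure(list(gain_x = fx$gain, offset_x = fx$offset,
                 gain_y = fy$gain, offset_y = fy$offset,
                 residual_rmse = rmse, n_targets = sum(usable)),
            class = "calibration_model")
}

affine_fit <- function(raw, deg) {
  sxx <- sum((raw - mean(raw))^2)
  if (sxx < 1e-20) stop("calibration targets collapse on one raw position", call. = FALSE)
  gain <- sum((raw - mean(raw)) * (deg - mean(deg))) / sxx
  offset <- mean(deg) - gain * mean(raw)
  list(gain = gain, offset = offset, resid = deg - (gain * raw + offset))
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model: x = %.4g*raw%+.4g, y = %.4g*raw%+.4g, rmse %.3g deg, %d targets>\n",
              x$gain_x, x$offset_x, x$gain_y, x$offset_y, x$residual_rmse, x$n_targets))
  invisible(x)
}

#' Apply a calibration model to a raw trace
#'
#' @param trace A [raw_trace()].
#' @param model A `calibration_model` from [fit_calibration()].
#' @return A [calibrated_trace()] in degrees visual angle.
#' @export
apply_calibration <- function(trace, model) {
  stopifnot(inherits(trace, "raw_trace"), inherits(model, "calibration_model"))
  calibrated_trace(trace$t,
                   model$gain_x * trace$x_raw + model$offset_x,
                   model$gain_y * trace$y_raw + model$offset_y,
                   trace$valid)
}

#' Compensate the tonic eye-position offset of a task
#'
#' Removes any constant gaze offset remaining after calibration by
#' subtracting the average difference between eye position during
#' visible-target fixations and the target positions themselves. The
#' fixation window of each target event is its last second (capped at the
#' event length); the per-event median eye position is compared with the
#' target, and the mean difference over all usable events is subtracted
#' from the whole trace. Computed per task (and hence per phase), so
#' offsets never leak across tasks.
#'
#' @param trace A [calibrated_trace()].
#' @param sched The task's [task_schedule()].
#' @param min_fix_s Minimum valid fixation data per event (seconds) for
#'   the event to contribute.
#' @return The shifted trace; the applied shift is stored in the
#'   `offset_applied` attribute (`c(x, y)`).
#' @export
compensate_offset <- function(trace, sched, min_fix_s = 0.2) {
  stopifnot(inherits(trace, "calibrated_trace"))
  ev <- sched$events
  if (nrow(ev) == 0) {
    warning("no visible-target epochs; offset compensation skipped", call. = FALSE)
    attr(trace, "offset_applied") <- c(x = 0, y = 0)
    return(trace)
  }
  diffs <- matrix(NA_real_, nrow(ev), 2)
  for (j in seq_len(nrow(ev))) {
    w0 <- max(ev$t_on[j], ev$t_off[j] - 1)
    sel <- trace$t >= w0 & trace$t < ev$t_off[j] & trace$valid
    if (sum(sel) < min_fix_s * SAMPLE_RATE_HZ) next
    diffs[j, ] <- c(stats::median(trace$x[sel]) - ev$x[j],
                    stats::median(trace$y[sel]) - ev$y[j])
  }
  ok <- !is.na(diffs[, 1])
  if (!any(ok)) {
    warning("no usable target fixation; offset compensation skipped", call. = FALSE)
    attr(trace, "offset_applied") <- c(x = 0, y = 0)
    return(trace)
  }
  shift <- colMeans(diffs[ok, , drop = FALSE])
  trace$x <- trace$x - shift[1]
  trace$y <- trace$y - shift[2]
  attr(trace, "offset_applied") <- c(x = shift[1], y = shift[2])
  trace
}
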