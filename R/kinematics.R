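#' Two-point velocity of a calibrated trace
#'
#' Backward two-point differentiation: `v[i] = (x[i] - x[i-1]) / 0.02`,
#' assigned to the later sample (causal). The first sample and any sample
#' whose pair includes an invalid position are undefined (`NA`). The
#' positions are carried along so that saccade endpoints can be read off
#' the same object.
#'
#' @param trace A [calibrated_trace()].
#' @return A `data.frame` of class `velocity_trace` with columns `t`,
#'   `vx`, `vy`, `x`, `y`, `valid` (velocity validity).
#' @export
differentiate <- function(trace) {
  stopifnot(inherits(trace, "calibrated_trace"))
  n <- nrow(trace)
  vx <- c(NA_real_, diff(trace$x) / SAMPLE_DT)
  vy <- c(NA_real_, diff(trace$y) / SAMPLE_DT)
  vvalid <- trace$valid & c(FALSE, trace$valid[-n])
  vx[!vvalid] <- NA_real_
  vy[!vvalid] <- NA_real_
  fast_df(list(t = trace$t, vx = vx, vy = vy,
               x = trace$x, y = trace$y, valid = vvalid),
          c("velocity_trace", "data.frame"))
}

#' Detect saccades by velocity threshold
#'
#' A saccade is any maximal run of samples whose absolute eye velocity
#' exceeds the threshold. Onset is the sample prior to the first
#' threshold crossing; offset is the first sample after the velocity has
#' dropped below the threshold again. Events whose window touches an
#' undefined velocity sample (blink, signal loss, trace boundary) are
#' discarded, as are events still above threshold at the end of the
#' trace. The endpoint is the eye position at the offset sample.
#'
#' @param vel A [differentiate()]d velocity trace.
#' @param threshold_deg_s Absolute velocity threshold (default 15 deg/s).
#' @param speed_mode `"2d"`: threshold `sqrt(vx^2+vy^2)`;
#'   `"horizontal"`: threshold `|vx|`.
#' @return A `data.frame` of class `saccade_events` with columns
#'   `onset`, `offset` (sample indices), `onset_t`, `offset_t`,
#'   `endpoint_x`, `endpoint_y`, `amplitude`.
#' @export
detect_saccades <- function(vel, threshold_deg_s = 15,
                            speed_mode = c("2d", "horizontal")) {
  speed_mode <- match.arg(speed_mode)
  stopifnot(inherits(vel, "velocity_trace"), threshold_deg_s > 0)
  n <- nrow(vel)
  speed <- if (speed_mode == "2d") sqrt(vel$vx^2 + vel$vy^2) else abs(vel$vx)
  defined <- !is.na(speed)
  above <- defined & speed > threshold_deg_s
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i0 <- starts[r$values]
  i1 <- ends[r$values]
  on <- i0 - 1L
  off <- i1 + 1L
  keep <- i1 < n & on >= 1L
  keep[keep] <- defined[on[keep]] & defined[off[keep]]  # no masked boundary
  on <- on[keep]; off <- off[keep]
  ev <- fast_df(list(
    onset = on, offset = off,
    onset_t = vel$t[on], offset_t = vel$t[off],
    endpoint_x = vel$x[off], endpoint_y = vel$y[off],
    amplitude = sqrt((vel$x[off] - vel$x[on])^2 + (vel$y[off] - vel$y[on])^2)
  ), c("saccade_events", "data.frame"))
  ev
}

#' Remove saccadic intervals from a velocity trace
#'
#' Velocity samples from saccade onset to saccade offset (inclusive) are
#' set to missing so the slow-phase velocity can be summarized on its
#' own. An optional symmetric margin widens every mask; the pipeline uses
#' a small margin (see [analysis_config()]) to absorb the saccadic energy
#' that zero-phase filtering spreads beyond the threshold crossings.
#'
#' @param vel A velocity trace.
#' @param events Events from [detect_saccades()] on the same trace.
#' @param margin_s Seconds additionally masked on each side (default 0).
#' @return The velocity trace with masked samples set `NA`/invalid; the
#'   count of newly masked samples is in attribute `desaccaded`.
#' @export
desaccade <- function(vel, events, margin_s = 0) {
  stopifnot(inherits(vel, "velocity_trace"), margin_s >= 0)
  n <- nrow(vel)
  m <- as.integer(round(margin_s * SAMPLE_RATE_HZ))
  mask <- rep(FALSE, n)
  for (k in seq_len(nrow(events))) {
    lo <- max(1L, events$onset[k] - m)
    hi <- min(n, events$offset[k] + m)
    mask[lo:hi] <- TRUE
  }
  newly <- sum(mask & vel$valid)
  vel$vx[mask] <- NA_real_
  vel$vy[mask] <- NA_real_
  vel$valid <- vel$valid & !mask
  attr(vel, "desaccaded") <- newly
  attr(vel, "saccade_mask") <- mask
  vel
}
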