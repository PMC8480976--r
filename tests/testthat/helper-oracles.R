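# Independent oracles and small fixture builders shared across tests.

# Exhaustive per-sample saccade scan: walks the speed vector one sample
# at a time, bookkeeping threshold crossings explicitly. Kept deliberately
# naive and separate from the vectorized implementation.
brute_detect <- function(vel, thr = 15, mode = "2d") {
  n <- nrow(vel)
  speed <- if (mode == "2d") sqrt(vel$vx^2 + vel$vy^2) else abs(vel$vx)
  onsets <- integer(0); offsets <- integer(0)
  i <- 1L
  while (i <= n) {
    s <- speed[i]
    if (!is.na(s) && s > thr) {
      j <- i
      while (j + 1L <= n && !is.na(speed[j + 1L]) && speed[j + 1L] > thr) j <- j + 1L
      onset <- i - 1L
      offset <- j + 1L
      if (onset >= 1L && offset <= n &&
          !is.na(speed[onset]) && !is.na(speed[offset])) {
        onsets <- c(onsets, onset); offsets <- c(offsets, offset)
      }
      i <- j + 2L
    } else {
      i <- i + 1L
    }
  }
  data.frame(onset = onsets, offset = offsets)
}

# Build a velocity_trace directly from velocity samples (positions are
# the cumulative sum so endpoints are well-defined).
make_velocity_trace <- function(vx, vy = rep(0, length(vx)), valid = NULL) {
  n <- length(vx)
  if (is.null(valid)) valid <- !is.na(vx)
  x <- cumsum(ifelse(is.na(vx), 0, vx)) * 0.02
  y <- cumsum(ifelse(is.na(vy), 0, vy)) * 0.02
  structure(
    list(t = (seq_len(n) - 1) * 0.02, vx = vx, vy = vy, x = x, y = y,
         valid = valid & !is.na(vx)),
    row.names = c(NA_integer_, -n),
    class = c("velocity_trace", "data.frame")
  )
}

# Minimal saccade-events table for measure-level tests.
make_events <- function(offset_t, endpoint_x, endpoint_y = 0) {
  n <- length(offset_t)
  data.frame(onset = pmax(1L, as.integer(round(offset_t * 50)) - 2L),
             offset = as.integer(round(offset_t * 50)) + 1L,
             onset_t = offset_t - 0.06, offset_t = offset_t,
             endpoint_x = endpoint_x,
             endpoint_y = rep_len(endpoint_y, n),
             amplitude = rep(2, n))
}

# Noise-free raw calibration trace whose gaze sits exactly on each
# calibration target: raw = (deg - offset) / gain.
make_calibration_trace <- function(gain = c(2, 2), offset = c(10, -4),
                                   sched = calibration_schedule()) {
  n <- as.integer(sched$duration * 50)
  t <- (seq_len(n) - 1) * 0.02
  x <- numeric(n); y <- numeric(n)
  for (j in seq_len(nrow(sched$events))) {
    sel <- t >= sched$events$t_on[j] & t < sched$events$t_off[j]
    x[sel] <- sched$events$x[j]
    y[sel] <- sched$events$y[j]
  }
  raw_trace(t, (x - offset[1]) / gain[1], (y - offset[2]) / gain[2])
}

# Identity-free known calibration model for driving process_task directly
# on simulated traces (matches simulation_params() defaults).
default_model <- function() {
  structure(list(gain_x = 2, offset_x = -1, gain_y = 2, offset_y = 0.5,
                 residual_rmse = 0, n_targets = 5),
            class = "calibration_model")
}

# Amplitude of a sinusoid recovered by least squares on sin/cos terms.
fit_amplitude <- function(x, t, freq) {
  X <- cbind(1, sin(2 * pi * freq * t), cos(2 * pi * freq * t))
  cf <- qr.solve(X, x)
  sqrt(cf[2]^2 + cf[3]^2)
}
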