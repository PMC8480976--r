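#' Slow-phase (VOR) velocity estimate
#'
#' Median de-saccaded horizontal and vertical eye velocity during the
#' straight-ahead task, starting a settling period after the central
#' light is extinguished (default 5 s) and running to task end. The same
#' window and validity mask are used for both axes. If fewer than 5 s of
#' usable samples remain, the estimate is missing with a warning.
#'
#' @param vel A de-saccaded velocity trace of the straight-ahead task.
#' @param sched The straight-ahead [task_schedule()].
#' @param settle_s Settling period after light offset (seconds).
#' @return Named numeric `c(vor_h, vor_v)` (deg/s; positive = rightward /
#'   upward), possibly `NA`.
#' @export
vor_estimate <- function(vel, sched, settle_s = 5) {
  stopifnot(sched$task == "straight_ahead")
  t0 <- sched$events$t_off[1] + settle_s
  sel <- vel$t >= t0 & !is.na(vel$vx)
  if (sum(sel) < 5 * SAMPLE_RATE_HZ) {
    warning("fewer than 5 s of usable de-saccaded samples; VOR estimate missing",
            call. = FALSE)
    return(c(vor_h = NA_real_, vor_v = NA_real_))
  }
  c(vor_h = stats::median(vel$vx[sel]), vor_v = stats::median(vel$vy[sel]))
}

#' Subjective straight-ahead estimate
#'
#' Median horizontal position of saccade endpoints during the
#' straight-ahead task, starting a settling period after the central
#' light offset. The endpoints of the subject's voluntary saccades in
#' darkness proxy where the subject believes "straight ahead" is.
#'
#' @param events [detect_saccades()] output for the straight-ahead task.
#' @param sched The straight-ahead [task_schedule()].
#' @param settle_s Settling period after light offset (seconds).
#' @return Named numeric `c(ssa, n)`: the estimate in degrees (NA if no
#'   qualifying saccade) and the number of endpoints used.
#' @export
ssa_estimate <- function(events, sched, settle_s = 5) {
  stopifnot(sched$task == "straight_ahead")
  t0 <- sched$events$t_off[1] + settle_s
  sel <- events$offset_t >= t0
  if (!any(sel)) {
    warning("no qualifying saccade after the settling window; SSA missing",
            call. = FALSE)
    return(c(ssa = NA_real_, n = 0))
  }
  c(ssa = stats::median(events$endpoint_x[sel]), n = sum(sel))
}

#' Center of visual search
#'
#' Central tendency (mean by default) of horizontal saccade endpoints
#' during the target-absent epochs of the search task. A saccade belongs
#' to an epoch by its offset (endpoint) time; epochs exclude every target
#' presentation, a grace period after each target offset, and the final
#' central target.
#'
#' @param events [detect_saccades()] output for the search task.
#' @param sched The search [task_schedule()].
#' @param grace_s Grace period after each target offset (seconds).
#' @param stat `"mean"` (default) or `"median"`.
#' @return Named numeric `c(search_center, n)`.
#' @export
search_center <- function(events, sched, grace_s = 5,
                          stat = c("mean", "median")) {
  stat <- match.arg(stat)
  stopifnot(sched$task == "search")
  epochs <- analysis_epochs(sched, grace_s)
  sel <- in_epochs(events$offset_t, epochs)
  if (!any(sel)) {
    warning("no qualifying saccade in target-absent epochs; search center missing",
            call. = FALSE)
    return(c(search_center = NA_real_, n = 0))
  }
  fun <- if (stat == "mean") mean else stats::median
  c(search_center = fun(events$endpoint_x[sel]), n = sum(sel))
}
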