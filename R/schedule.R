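# Stimulus geometry of the experiment. Six search targets, one central
# target, and five calibration targets; positions in degrees visual angle
# (positive = rightward/upward).
SEARCH_TARGET_SET <- data.frame(
  x = c(-6, 6, -6, 6, -12, 12),
  y = c(5, 5, -5, -5, -1, 1)
)
CALIB_TARGET_SET <- data.frame(
  x = c(0, -6, 6, -6, 6),
  y = c(0, 5, 5, -5, -5)
)
ITI_SET_S <- c(5, 10, 15, 20, 25, 30, 35)
SEARCH_TARGET_FADE_S <- 5
SEARCH_FINAL_CENTRAL_S <- 2
CALIB_PRESENT_S <- 2
SA_FIX_S <- 5
SA_DARK_S <- 60
PHASES <- c("outside1", "inside", "outside2")
TASKS <- c("calibration", "straight_ahead", "search")

#' Schedule of a single task
#'
#' A task schedule lists the visible-target events of one task: target
#' position in degrees and on/off times in seconds from task start.
#'
#' @param task One of `"calibration"`, `"straight_ahead"`, `"search"`.
#' @param events `data.frame` with columns `x`, `y`, `t_on`, `t_off`.
#' @param duration Task duration in seconds.
#' @return An object of class `task_schedule`.
#' @export
task_schedule <- function(task, events, duration) {
  task <- match.arg(task, TASKS)
  stopifnot(is.data.frame(events),
            all(c("x", "y", "t_on", "t_off") %in% names(events)))
  events <- events[order(events$t_on), c("x", "y", "t_on", "t_off")]
  sched <- structure(list(task = task, events = events,
                          duration = as.numeric(duration)),
                     class = "task_schedule")
  validate_task_schedule(sched)
  sched
}

validate_task_schedule <- function(sched) {
  ev <- sched$events
  if (any(ev$t_off <= ev$t_on)) stop("schedule events must have t_off > t_on", call. = FALSE)
  if (nrow(ev) > 1 && any(ev$t_on[-1] < ev$t_off[-nrow(ev)] - 1e-9)) {
    stop("schedule events overlap", call. = FALSE)
  }
  if (any(ev$t_off > sched$duration + 1e-9)) {
    stop("schedule events extend beyond task duration", call. = FALSE)
  }
  switch(sched$task,
    calibration = {
      if (nrow(ev) != 10) {
        stop("calibration task must present the five calibration targets twice (10 events, got ",
             nrow(ev), ")", call. = FALSE)
      }
      key <- paste(ev$x, ev$y)
      ref <- paste(CALIB_TARGET_SET$x, CALIB_TARGET_SET$y)
      if (!all(key %in% ref)) {
        stop("calibration target position outside the five stated locations", call. = FALSE)
      }
      if (!all(table(key) == 2)) {
        stop("each calibration target must be presented exactly twice", call. = FALSE)
      }
    },
    straight_ahead = {
      if (nrow(ev) != 1 || ev$x[1] != 0 || ev$y[1] != 0) {
        stop("straight-ahead task must contain a single central fixation event", call. = FALSE)
      }
    },
    search = {
      if (nrow(ev) != 7) {
        stop("search task must contain six fading targets plus a final central target (got ",
             nrow(ev), " events)", call. = FALSE)
      }
      fade <- ev[-nrow(ev), ]
      final <- ev[nrow(ev), ]
      key <- paste(fade$x, fade$y)
      ref <- paste(SEARCH_TARGET_SET$x, SEARCH_TARGET_SET$y)
      if (!setequal(key, ref) || length(key) != length(ref)) {
        stop("search targets must be the six stated locations, each once", call. = FALSE)
      }
      if (final$x != 0 || final$y != 0 ||
          abs(final$t_off - sched$duration) > 1e-9 ||
          abs((final$t_off - final$t_on) - SEARCH_FINAL_CENTRAL_S) > 1e-9) {
        stop("search task must end with a 2 s central target", call. = FALSE)
      }
      itis <- round(c(fade$t_on[1], diff(c(fade$t_off, final$t_on))[
        seq_len(nrow(fade))]), 6)
      # gaps: before first target, between targets, and before the final
      # central target -- must be a permutation of the stated ITI set
      gaps <- c(fade$t_on[1] - 0,
                fade$t_on[-1] - fade$t_off[-nrow(fade)],
                final$t_on - fade$t_off[nrow(fade)])
      if (!setequal(round(gaps, 6), ITI_SET_S) || length(gaps) != length(ITI_SET_S)) {
        stop("search inter-target intervals must be a permutation of {",
             paste(ITI_SET_S, collapse = ", "), "} s", call. = FALSE)
      }
    }
  )
  invisible(sched)
}

#' @export
print.task_schedule <- function(x, ...) {
  cat(sprintf("<task_schedule: %s, %.0f s, %d events>\n",
              x$task, x$duration, nrow(x$events)))
  invisible(x)
}

# --- canonical task builders -------------------------------------------------

#' Canonical calibration task schedule
#'
#' Five targets (centre and the four 6/5-degree corners), presented twice
#' for 2 s each; total 20 s.
#' @return A [task_schedule()].
#' @export
calibration_schedule <- function() {
  ev <- rbind(CALIB_TARGET_SET, CALIB_TARGET_SET)
  ev$t_on <- CALIB_PRESENT_S * (seq_len(nrow(ev)) - 1)
  ev$t_off <- ev$t_on + CALIB_PRESENT_S
  task_schedule("calibration", ev, CALIB_PRESENT_S * nrow(ev))
}

#' Canonical straight-ahead task schedule
#'
#' A central light for 5 s, then 60 s of complete darkness in which the
#' subject keeps "looking straight ahead".
#' @return A [task_schedule()].
#' @export
straight_ahead_schedule <- function() {
  ev <- data.frame(x = 0, y = 0, t_on = 0, t_off = SA_FIX_S)
  task_schedule("straight_ahead", ev, SA_FIX_S + SA_DARK_S)
}

#' Canonical search task schedule
#'
#' Six targets fading in over 5 s each, separated by seven inter-target
#' intervals that are a permutation of {5, 10, ..., 35} s, closed by a 2 s
#' central target: 172 s in total, of which 140 s are target-free.
#'
#' @param target_order Integer permutation of 1:6 indexing
#'   `SEARCH_TARGET_SET` rows.
#' @param iti_order Numeric permutation of the ITI set `{5,...,35}` s.
#' @return A [task_schedule()].
#' @export
search_schedule <- function(target_order = 1:6, iti_order = ITI_SET_S) {
  stopifnot(setequal(target_order, 1:6), setequal(iti_order, ITI_SET_S))
  tgt <- SEARCH_TARGET_SET[target_order, ]
  t_on <- cumsum(iti_order[1:6]) + SEARCH_TARGET_FADE_S * (0:5)
  ev <- data.frame(x = tgt$x, y = tgt$y, t_on = t_on,
                   t_off = t_on + SEARCH_TARGET_FADE_S)
  fin_on <- ev$t_off[6] + iti_order[7]
  ev <- rbind(ev, data.frame(x = 0, y = 0, t_on = fin_on,
                             t_off = fin_on + SEARCH_FINAL_CENTRAL_S))
  task_schedule("search", ev, fin_on + SEARCH_FINAL_CENTRAL_S)
}

#' Session schedule
#'
#' A full session: three phases (`outside1`, `inside`, `outside2`), each
#' with a calibration, a straight-ahead and a search task, plus the
#' subject orientation in the scanner (`head_first` in the main
#' experiment, `feet_first` in the control that reverses the stimulation).
#'
#' @param phases Named list `outside1/inside/outside2`, each a named list
#'   of three [task_schedule()]s.
#' @param orientation `"head_first"` or `"feet_first"`.
#' @return An object of class `session_schedule`.
#' @export
session_schedule <- function(phases, orientation = c("head_first", "feet_first")) {
  orientation <- match.arg(orientation)
  stopifnot(identical(sort(names(phases)), sort(PHASES)))
  for (ph in PHASES) {
    stopifnot(identical(sort(names(phases[[ph]])), sort(TASKS)))
    for (tk in TASKS) {
      stopifnot(inherits(phases[[ph]][[tk]], "task_schedule"))
      if (phases[[ph]][[tk]]$task != tk) stop("task label mismatch in phase ", ph)
    }
  }
  structure(list(orientation = orientation, phases = phases[PHASES]),
            class = "session_schedule")
}

#' Canonical session schedule with pseudorandomized search order
#'
#' Target order and inter-target intervals of the search task are
#' permuted independently per phase, mirroring the pseudorandomization
#' across phases and participants.
#'
#' @param orientation Subject orientation.
#' @param seed Optional integer seed for the permutations.
#' @return A [session_schedule()].
#' @export
canonical_schedule <- function(orientation = "head_first", seed = NULL) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv())
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  phases <- lapply(PHASES, function(ph) {
    list(calibration = calibration_schedule(),
         straight_ahead = straight_ahead_schedule(),
         search = search_schedule(sample(6), sample(ITI_SET_S)))
  })
  names(phases) <- PHASES
  session_schedule(phases, orientation)
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.session_schedule <- function(x, ...) {
  cat(sprintf("<session_schedule: %s, %d phases x %d tasks>\n",
              x$orientation, length(x$phases), length(x$phases[[1]])))
  invisible(x)
}

# --- epoch helpers -----------------------------------------------------------

#' Target-absent epochs of a task
#'
#' Complement of the visible-target intervals within the task. On the
#' canonical search schedule these cover 140 s.
#'
#' @param sched A [task_schedule()].
#' @return `data.frame` with columns `start`, `end` (seconds).
#' @export
target_absent_epochs <- function(sched) {
  ev <- sched$events
  starts <- c(0, ev$t_off)
  ends <- c(ev$t_on, sched$duration)
  keep <- ends - starts > 1e-9
  data.frame(start = starts[keep], end = ends[keep])
}

#' Analysis epochs of a search task
#'
#' Target-absent epochs reduced by the grace period after each target
#' offset; the final central target and anything after it is excluded
#' entirely.
#'
#' @param sched A search [task_schedule()].
#' @param grace_s Grace period in seconds after every target offset.
#' @return `data.frame` with columns `start`, `end`.
#' @export
analysis_epochs <- function(sched, grace_s = 5) {
  stopifnot(sched$task == "search")
  ev <- sched$events
  fade <- ev[-nrow(ev), ]
  final_on <- ev$t_on[nrow(ev)]
  starts <- c(0, fade$t_off + grace_s)
  ends <- c(fade$t_on, final_on)
  keep <- ends - starts > 1e-9
  data.frame(start = starts[keep], end = ends[keep])
}

in_epochs <- function(t, epochs) {
  hit <- rep(FALSE, length(t))
  for (k in seq_len(nrow(epochs))) {
    hit <- hit | (t >= epochs$start[k] & t < epochs$end[k])
  }
  hit
}

# --- schedule I/O ------------------------------------------------------------

#' Read a session schedule from YAML
#'
#' The document must carry `orientation` and a `phases` map with
#' `outside1`, `inside` and `outside2`, each holding `calibration`,
#' `straight_ahead` and `search` tasks with `duration` and an `events`
#' list of `{x, y, t_on, t_off}` records. All invariants (target
#' locations, ITI set, event counts) are enforced.
#'
#' @param path Path to the YAML document.
#' @return A [session_schedule()].
#' @export
read_schedule <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$orientation) || is.null(doc$phases)) {
    stop("schedule document must contain `orientation` and `phases`", call. = FALSE)
  }
  phases <- lapply(PHASES, function(ph) {
    node <- doc$phases[[ph]]
    if (is.null(node)) stop("schedule is missing phase `", ph, "`", call. = FALSE)
    tasks <- lapply(TASKS, function(tk) {
      tnode <- node[[tk]]
      if (is.null(tnode)) stop("phase `", ph, "` is missing task `", tk, "`", call. = FALSE)
      ev <- do.call(rbind, lapply(tnode$events, function(e) {
        data.frame(x = e$x, y = e$y, t_on = e$t_on, t_off = e$t_off)
      }))
      task_schedule(tk, ev, tnode$duration)
    })
    names(tasks) <- TASKS
    tasks
  })
  names(phases) <- PHASES
  session_schedule(phases, doc$orientation)
}

#' Write a session schedule to YAML
#'
#' @param schedule A [session_schedule()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "session_schedule"))
  doc <- list(
    orientation = schedule$orientation,
    phases = lapply(schedule$phases, function(tasks) {
      lapply(tasks, function(sched) {
        list(duration = sched$duration,
             events = lapply(seq_len(nrow(sched$events)), function(i) {
               as.list(sched$events[i, c("x", "y", "t_on", "t_off")])
             }))
      })
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}
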