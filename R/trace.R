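#' Raw eye-position trace
#'
#' A raw trace holds uncalibrated tracker samples on the uniform 50 Hz
#' grid: time `t` in seconds from task start, horizontal/vertical tracker
#' coordinates `x_raw`/`y_raw` (dimensionless tracker units), and a
#' per-sample `valid` flag (tracker lock; `FALSE` during blinks or signal
#' loss).
#'
#' @param t Numeric vector of sample times (strictly increasing, constant
#'   0.02 s step).
#' @param x_raw,y_raw Numeric tracker coordinates; must be finite wherever
#'   `valid` is `TRUE`.
#' @param valid Logical vector.
#'
#' @return A `data.frame` of class `raw_trace`.
#' @export
raw_trace <- function(t, x_raw, y_raw, valid = rep(TRUE, length(t))) {
  tr <- fast_df(list(t = as.numeric(t), x_raw = as.numeric(x_raw),
                     y_raw = as.numeric(y_raw), valid = as.logical(valid)),
                c("raw_trace", "eye_trace", "data.frame"))
  validate_trace(tr)
  tr
}

# data.frame() spends most of its time on checks we do not need on
# length-matched atomic columns; traces are built thousands of times in
# simulations, so construct them directly.
fast_df <- function(cols, class) {
  n <- length(cols[[1]])
  rn <- if (n > 0) c(NA_integer_, -n) else integer(0)
  structure(cols, row.names = rn, class = class)
}

#' Calibrated eye-position trace
#'
#' Positions are in degrees visual angle; positive x is rightward,
#' positive y upward. Same sampling contract as [raw_trace()]. Valid
#' samples are sanity-bounded at |x|, |y| <= 40 deg.
#'
#' @param t,valid As in [raw_trace()].
#' @param x,y Gaze position in degrees visual angle.
#' @return A `data.frame` of class `calibrated_trace`.
#' @export
calibrated_trace <- function(t, x, y, valid = rep(TRUE, length(t))) {
  tr <- fast_df(list(t = as.numeric(t), x = as.numeric(x),
                     y = as.numeric(y), valid = as.logical(valid)),
                c("calibrated_trace", "eye_trace", "data.frame"))
  validate_trace(tr)
  tr
}

pos_cols <- function(trace) {
  if (inherits(trace, "raw_trace")) c("x_raw", "y_raw") else c("x", "y")
}

validate_trace <- function(trace) {
  t <- trace$t
  if (length(t) < 2) stop("trace must contain at least 2 samples", call. = FALSE)
  dts <- diff(t)
  if (any(dts <= 0)) stop("trace times must be strictly increasing", call. = FALSE)
  if (any(abs(dts - SAMPLE_DT) > T_STEP_TOL)) {
    stop(sprintf("trace is not sampled at %g Hz (found step %.6g s)",
                 SAMPLE_RATE_HZ, dts[which.max(abs(dts - SAMPLE_DT))]),
         call. = FALSE)
  }
  xy <- pos_cols(trace)
  v <- trace$valid
  if (anyNA(v)) stop("`valid` must not contain NA", call. = FALSE)
  for (cl in xy) {
    bad <- v & !is.finite(trace[[cl]])
    if (any(bad)) {
      stop(sprintf("column `%s` must be finite wherever valid (first offence at t=%.2f s)",
                   cl, t[which(bad)[1]]), call. = FALSE)
    }
  }
  if (inherits(trace, "calibrated_trace")) {
    out <- v & (abs(trace$x) > 40 | abs(trace$y) > 40)
    if (any(out)) {
      stop(sprintf("calibrated positions exceed the 40 deg sanity bound at t=%.2f s",
                   t[which(out)[1]]), call. = FALSE)
    }
  }
  invisible(trace)
}

#' Read a raw trace from delimiter-separated text
#'
#' The file must carry a header naming the columns `t`, `x_raw`, `y_raw`
#' and `valid` (tab-, comma- or whitespace-separated). Rows with
#' unparseable fields are rejected with a warning; structural problems
#' (missing columns, wrong sampling rate) are errors.
#'
#' @param path Path to the text file.
#' @return A [raw_trace()].
#' @export
read_trace <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, fill = TRUE)
  need <- c("t", "x_raw", "y_raw", "valid")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("trace file is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- df[need]
  for (cl in c("t", "x_raw", "y_raw")) df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
  df$valid <- parse_logical(df$valid)
  malformed <- is.na(df$t) | is.na(df$valid)
  if (any(malformed)) {
    warning(sum(malformed), " malformed row(s) rejected from ", path, call. = FALSE)
    df <- df[!malformed, , drop = FALSE]
  }
  raw_trace(df$t, df$x_raw, df$y_raw, df$valid)
}

parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(ifelse(is.na(x), NA, x != 0))
  up <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(up))
  out[up %in% c("TRUE", "T", "1")] <- TRUE
  out[up %in% c("FALSE", "F", "0")] <- FALSE
  out
}

#' Write a trace as tab-separated text
#'
#' Numeric fields are written with 17 significant digits so that
#' `read_trace(write_trace(x))` reproduces every field bit for bit.
#'
#' @param trace A [raw_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "raw_trace"))
  out <- data.frame(
    t = sprintf("%.17g", trace$t),
    x_raw = sprintf("%.17g", trace$x_raw),
    y_raw = sprintf("%.17g", trace$y_raw),
    valid = trace$valid
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
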