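# Sampling contract shared by the whole pipeline. The tracker runs at 50 Hz;
# every trace is checked against this grid.
SAMPLE_RATE_HZ <- 50
SAMPLE_DT <- 0.02
T_STEP_TOL <- 1e-9

#' Analysis configuration
#'
#' Bundles every tunable threshold of the pipeline. The defaults reproduce
#' the published analysis settings: a second-order 10 Hz low-pass filter,
#' an absolute eye-velocity saccade threshold of 15 deg/s, a 5 s grace
#' period after each search target is extinguished, a 5 s settling window
#' after the central fixation light goes off, a Shapiro-Wilk normality gate
#' at p >= 0.01, and a Bonferroni-adjusted alpha of 1.7% (0.05 / 3
#' pairwise phase contrasts per measure).
#'
#' @param filter_cutoff_hz Low-pass cutoff in Hz (must be below the 25 Hz
#'   Nyquist frequency).
#' @param filter_order Filter order (2 = biquad).
#' @param filter_phase `"zero"` for zero-phase forward-backward filtering
#'   (default) or `"causal"` for a single forward pass.
#' @param saccade_threshold_deg_s Absolute eye-velocity threshold in deg/s.
#' @param speed_mode `"2d"`: threshold the euclidean speed
#'   `sqrt(vx^2 + vy^2)` (default); `"horizontal"`: threshold `|vx|` only.
#' @param grace_after_target_s Seconds discarded after each search target
#'   is switched off, to avoid carry-over from target fixation.
#' @param settle_after_fixation_s Seconds discarded after the central light
#'   of the straight-ahead task is switched off before slow-phase velocity
#'   and straight-ahead estimates start.
#' @param desaccade_margin_s Extra seconds masked on each side of every
#'   detected saccade when de-saccading velocity traces. Zero-phase
#'   filtering spreads saccadic energy symmetrically beyond the threshold
#'   crossings; masking roughly one filter width (2 samples at 50 Hz)
#'   removes that leakage. Set to 0 to mask strictly onset-to-offset.
#' @param blink_margin_s Symmetric margin masked around every tracker
#'   signal loss.
#' @param sw_alpha Shapiro-Wilk significance level gating the paired
#'   t-test branch; differences with `sw_p < sw_alpha` are log-transformed.
#' @param bonferroni_alpha Family-adjusted alpha used when reporting the
#'   three pairwise phase contrasts of each measure.
#' @param search_center_stat `"mean"` (default) or `"median"` of horizontal
#'   saccade endpoints for the visual-search center.
#' @param rng_seed Optional integer seed recorded with the configuration.
#'
#' @return An object of class `analysis_config` (a named list).
#' @export
analysis_config <- function(filter_cutoff_hz = 10,
                            filter_order = 2,
                            filter_phase = c("zero", "causal"),
                            saccade_threshold_deg_s = 15,
                            speed_mode = c("2d", "horizontal"),
                            grace_after_target_s = 5,
                            settle_after_fixation_s = 5,
                            desaccade_margin_s = 0.04,
                            blink_margin_s = 0.1,
                            sw_alpha = 0.01,
                            bonferroni_alpha = 0.05 / 3,
                            search_center_stat = c("mean", "median"),
                            rng_seed = NULL) {
  filter_phase <- match.arg(filter_phase)
  speed_mode <- match.arg(speed_mode)
  search_center_stat <- match.arg(search_center_stat)
  stopifnot(
    filter_cutoff_hz > 0, filter_order > 0,
    saccade_threshold_deg_s > 0,
    grace_after_target_s > 0, settle_after_fixation_s > 0,
    desaccade_margin_s >= 0, blink_margin_s >= 0,
    sw_alpha > 0, sw_alpha < 1, bonferroni_alpha > 0, bonferroni_alpha < 1
  )
  if (filter_cutoff_hz >= SAMPLE_RATE_HZ / 2) {
    stop("`filter_cutoff_hz` must be below the Nyquist frequency (",
         SAMPLE_RATE_HZ / 2, " Hz)", call. = FALSE)
  }
  structure(
    list(
      filter_cutoff_hz = filter_cutoff_hz,
      filter_order = filter_order,
      filter_phase = filter_phase,
      saccade_threshold_deg_s = saccade_threshold_deg_s,
      speed_mode = speed_mode,
      grace_after_target_s = grace_after_target_s,
      settle_after_fixation_s = settle_after_fixation_s,
      desaccade_margin_s = desaccade_margin_s,
      blink_margin_s = blink_margin_s,
      sw_alpha = sw_alpha,
      bonferroni_alpha = bonferroni_alpha,
      search_center_stat = search_center_stat,
      rng_seed = rng_seed
    ),
    class = "analysis_config"
  )
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (nm in setdiff(names(x), "rng_seed")) {
    cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  }
  if (!is.null(x$rng_seed)) cat(sprintf("  %-24s %s\n", "rng_seed", x$rng_seed))
  invisible(x)
}
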