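#' Hedges g1 with noncentral-t confidence interval
#'
#' Small-sample-corrected standardized effect size for a one-sample (or
#' paired-difference) design: `g1 = J(df) * mean(x) / sd(x)` with
#' `J(df) = 1 - 3 / (4*df - 1)`. The confidence interval inverts the
#' noncentral t distribution of the observed t statistic and rescales
#' the noncentrality limits to the effect-size scale.
#'
#' @param x Numeric vector (differences for a paired design).
#' @param conf Confidence level (default 0.95).
#' @return List with `g1`, `ci` (length-2), `J`, `t`, `df`.
#' @export
hedges_g1 <- function(x, conf = 0.95) {
  n <- length(x)
  stopifnot(n >= 2)
  df <- n - 1
  J <- 1 - 3 / (4 * df - 1)
  s <- stats::sd(x)
  if (s == 0) {
    if (mean(x) != 0) stop("zero variance with nonzero mean: effect size undefined", call. = FALSE)
    return(list(g1 = 0, ci = c(0, 0), J = J, t = 0, df = df))
  }
  tval <- mean(x) / (s / sqrt(n))
  g1 <- J * mean(x) / s
  alpha <- 1 - conf
  lo <- ncp_solve(tval, df, 1 - alpha / 2)
  hi <- ncp_solve(tval, df, alpha / 2)
  list(g1 = g1, ci = c(J * lo / sqrt(n), J * hi / sqrt(n)), J = J,
       t = tval, df = df)
}

# Solve pt(t, df, ncp) = p for ncp. pt() warns about reduced precision at
# extreme noncentrality; the residual error is far below the uniroot
# tolerance, so those warnings are suppressed.
ncp_solve <- function(tval, df, p) {
  f <- function(ncp) suppressWarnings(stats::pt(tval, df, ncp)) - p
  width <- 10 + 2 * abs(tval)
  lo <- tval - width; hi <- tval + width
  while (f(lo) < 0) lo <- lo - width
  while (f(hi) > 0) hi <- hi + width
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Paired contrast with normality gate
#'
#' Computes the paired differences `d = a - b`, applies a Shapiro-Wilk
#' normality test, and analyzes `d` with a paired t-test if the
#' differences look normal (`sw_p >= sw_alpha`). Otherwise the
#' differences are natural-log transformed (requiring them to be all
#' positive) and tested against zero with a one-sample t-test, which is
#' how strongly skewed velocity differences are handled. Hedges g1 and
#' its 95% noncentral-t confidence interval are computed on the analyzed
#' scale.
#'
#' @param a,b Equal-length per-subject value vectors (no missing values,
#'   n >= 3).
#' @param tail `"two"` or `"one"`.
#' @param direction For one-tailed tests, `"greater"` (hypothesis:
#'   `mean(a - b) > 0`) or `"less"`.
#' @param sw_alpha Shapiro-Wilk gate level (default 0.01).
#' @param transform `"auto"` (gate decides), `"none"`, or `"log"`.
#' @param contrast Optional label carried into the result.
#' @return Object of class `paired_contrast`: `contrast`, `tail`,
#'   `t_stat`, `df`, `p_value`, `g1`, `g1_ci_low`, `g1_ci_high`,
#'   `transform` (`"none"` or `"log_diff"`), `sw_p`, `n`, `mean_diff`,
#'   `d` (analyzed values).
#' @export
paired_contrast <- function(a, b, tail = c("two", "one"),
                            direction = c("greater", "less"),
                            sw_alpha = 0.01,
                            transform = c("auto", "none", "log"),
                            contrast = NULL) {
  tail <- match.arg(tail)
  direction <- match.arg(direction)
  transform <- match.arg(transform)
  stopifnot(length(a) == length(b), length(a) >= 3)
  if (anyNA(a) || anyNA(b)) stop("paired contrast requires complete data", call. = FALSE)
  d <- a - b

  if (all(d == d[1])) {
    # degenerate: identical differences (e.g. a == b)
    if (d[1] != 0) stop("constant nonzero differences: t undefined", call. = FALSE)
    res <- list(contrast = contrast %||% "a vs b", tail = tail,
                t_stat = 0, df = length(d) - 1, p_value = 1,
                g1 = 0, g1_ci_low = 0, g1_ci_high = 0,
                transform = "none", sw_p = NA_real_, n = length(d),
                mean_diff = 0, d = d)
    class(res) <- "paired_contrast"
    return(res)
  }

  sw_p <- stats::shapiro.test(d)$p.value
  use_log <- switch(transform,
                    auto = sw_p < sw_alpha,
                    none = FALSE,
                    log = TRUE)
  if (use_log) {
    bad <- which(d <= 0)
    if (length(bad) > 0) {
      stop("log transform of paired differences impossible: non-positive differences at pair(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    dd <- log(d)
    transform_used <- "log_diff"
  } else {
    dd <- d
    transform_used <- "none"
  }

  n <- length(dd)
  alt <- if (tail == "two") "two.sided" else direction
  tt <- stats::t.test(dd, mu = 0, alternative = alt)
  g <- hedges_g1(dd)
  res <- list(contrast = contrast %||% "a vs b", tail = tail,
              t_stat = unname(tt$statistic), df = unname(tt$parameter),
              p_value = tt$p.value,
              g1 = g$g1, g1_ci_low = g$ci[1], g1_ci_high = g$ci[2],
              transform = transform_used, sw_p = sw_p, n = n,
              mean_diff = mean(dd), d = dd)
  class(res) <- "paired_contrast"
  res
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.failed_contrast <- function(x, ...) {
  cat(sprintf("%s: FAILED (%s)\n", x$contrast, x$error))
  invisible(x)
}

#' @export
print.paired_contrast <- function(x, ...) {
  cat(sprintf("%s: t(%d) = %.3f, p = %.4g (%s-tailed)%s\n  g1 [CI95] = %.3f [%.3f, %.3f], SW p = %.3g\n",
              x$contrast, x$df, x$t_stat, x$p_value, x$tail,
              if (x$transform == "log_diff") ", log-transformed differences" else "",
              x$g1, x$g1_ci_low, x$g1_ci_high, x$sw_p))
  invisible(x)
}

#' Within-subject standard errors (Cousineau-Morey)
#'
#' Removes the between-subject offset variance of a repeated-measures
#' matrix by centering every subject on the grand mean (Cousineau
#' normalization), then applies the Morey bias correction
#' `m / (m - 1)` to the per-condition variances (m = number of
#' conditions) before converting to standard errors.
#'
#' @param mat Numeric matrix, subjects in rows, conditions (phases) in
#'   columns; no missing cells.
#' @return Named numeric vector of per-condition standard errors.
#' @export
within_subject_se <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("within-subject SE requires a complete matrix", call. = FALSE)
  n <- nrow(mat); m <- ncol(mat)
  stopifnot(n >= 2, m >= 2)
  norm <- mat - rowMeans(mat) + mean(mat)
  v <- apply(norm, 2, stats::var) * m / (m - 1)
  se <- sqrt(v / n)
  names(se) <- colnames(mat)
  se
}

#' Regression of behavioral change on reflex change
#'
#' Ordinary least squares of per-subject changes in a behavioral measure
#' on the per-subject change in slow-phase velocity, with changes
#' defined as the inside value minus the mean of the two outside values.
#' Subjects from several experiments may be pooled.
#'
#' @param dvor Per-subject velocity deltas (predictor).
#' @param dmeasure Per-subject behavioral deltas (response).
#' @return Object of class `delta_regression`: `slope`, `intercept`,
#'   `r_squared`, `f_stat`, `df1`, `df2`, `p_value`, `n`.
#' @export
delta_regression <- function(dvor, dmeasure) {
  stopifnot(length(dvor) == length(dmeasure), length(dvor) >= 3)
  if (anyNA(dvor) || anyNA(dmeasure)) stop("deltas must be complete", call. = FALSE)
  if (stats::var(dvor) == 0) stop("zero variance in the predictor", call. = FALSE)
  fit <- stats::lm(dmeasure ~ dvor)
  sm <- summary(fit)
  fs <- sm$fstatistic
  res <- list(slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]),
              r_squared = sm$r.squared,
              f_stat = unname(fs[1]), df1 = unname(fs[2]), df2 = unname(fs[3]),
              p_value = stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE),
              n = length(dvor))
  class(res) <- "delta_regression"
  res
}

#' @export
print.delta_regression <- function(x, ...) {
  cat(sprintf("R^2 = %.3f; F(%d,%d) = %.2f; p = %.4g; slope = %.3f\n",
              x$r_squared, x$df1, x$df2, x$f_stat, x$p_value, x$slope))
  invisible(x)
}

#' Bonferroni decision gate
#'
#' @param p_values Numeric vector of p-values.
#' @param n_tests Number of tests in the family (default: length of
#'   `p_values`).
#' @param alpha Family-wise alpha (default 0.05). With the three pairwise
#'   phase contrasts per measure the adjusted alpha is 0.05/3, i.e. 1.7%.
#' @return List with `adjusted_alpha` and logical `significant`.
#' @export
bonferroni_gate <- function(p_values, n_tests = length(p_values), alpha = 0.05) {
  stopifnot(n_tests >= 1)
  adj <- alpha / n_tests
  list(adjusted_alpha = adj, significant = p_values < adj)
}

#' Per-subject deltas: inside minus mean of the outside phases
#'
#' @param measures A measures table from [cohort_measures()].
#' @param vars Measure columns to difference.
#' @return `data.frame` with `subject` and one delta column per measure.
#' @export
measure_deltas <- function(measures,
                           vars = c("vor_h", "search_center", "ssa")) {
  wide <- function(v) {
    sapply(PHASES, function(ph) {
      measures[[v]][measures$phase == ph][order(measures$subject[measures$phase == ph])]
    })
  }
  subj <- sort(unique(measures$subject))
  out <- data.frame(subject = subj)
  for (v in vars) {
    w <- wide(v)
    out[[paste0("d_", v)]] <- w[, "inside"] - (w[, "outside1"] + w[, "outside2"]) / 2
  }
  out
}

#' Full statistical battery for one cohort
#'
#' For each measure (slow-phase velocity, search center, straight-ahead;
#' vertical velocity two-tailed as a control): the three pairwise phase
#' contrasts with the tails used in the study design (one-tailed for
#' inside vs either outside phase, in the direction implied by the
#' subject orientation; two-tailed between the outside phases), plus
#' Cousineau-Morey within-subject standard errors per phase.
#'
#' @param measures A measures table from [cohort_measures()] (one row
#'   per subject and phase).
#' @param orientation `"head_first"` or `"feet_first"`; defaults to the
#'   table's `orientation` attribute.
#' @param sw_alpha Shapiro-Wilk gate level.
#' @param bonferroni_alpha Adjusted alpha used for the significance
#'   flags.
#' @return Object of class `cohort_stats`: per-measure lists of
#'   `paired_contrast` results, within-subject SEs, and decision flags.
#' @export
cohort_stats <- function(measures, orientation = NULL, sw_alpha = 0.01,
                         bonferroni_alpha = 0.05 / 3) {
  orientation <- orientation %||% attr(measures, "orientation") %||% "head_first"
  dir_in <- if (orientation == "feet_first") "less" else "greater"
  out <- list(orientation = orientation)
  specs <- list(vor_h = "one", search_center = "one", ssa = "one", vor_v = "two")
  for (v in names(specs)) {
    wide <- sapply(PHASES, function(ph) {
      measures[[v]][measures$phase == ph][order(measures$subject[measures$phase == ph])]
    })
    if (anyNA(wide)) {
      out[[v]] <- list(error = "missing measures; contrasts skipped")
      next
    }
    one <- specs[[v]] == "one"
    # a contrast can fail legitimately (e.g. the log branch refuses
    # non-positive differences); report the failure without losing the
    # other contrasts
    try_contrast <- function(x, y, tail, dir, label) {
      tryCatch(
        paired_contrast(x, y, tail = tail, direction = dir,
                        sw_alpha = sw_alpha, contrast = label),
        error = function(e) {
          structure(list(contrast = label, error = conditionMessage(e),
                         p_value = NA_real_),
                    class = "failed_contrast")
        })
    }
    cs <- list(
      inside_vs_outside1 = try_contrast(
        wide[, "inside"], wide[, "outside1"],
        if (one) "one" else "two", dir_in, paste0(v, ": inside vs outside1")),
      inside_vs_outside2 = try_contrast(
        wide[, "inside"], wide[, "outside2"],
        if (one) "one" else "two", dir_in, paste0(v, ": inside vs outside2")),
      outside1_vs_outside2 = try_contrast(
        wide[, "outside1"], wide[, "outside2"], "two", dir_in,
        paste0(v, ": outside1 vs outside2"))
    )
    pvals <- vapply(cs, function(x) x$p_value, numeric(1))
    out[[v]] <- list(
      contrasts = cs,
      phase_means = colMeans(wide),
      phase_sd = apply(wide, 2, stats::sd),
      within_subject_se = within_subject_se(wide),
      significant = bonferroni_gate(pvals, 3, alpha = 3 * bonferroni_alpha)$significant
    )
  }
  class(out) <- "cohort_stats"
  out
}

#' @export
print.cohort_stats <- function(x, ...) {
  cat(sprintf("<cohort_stats: %s>\n", x$orientation))
  for (v in setdiff(names(x), "orientation")) {
    if (!is.null(x[[v]]$error)) { cat(v, ": ", x[[v]]$error, "\n"); next }
    cat(sprintf("%s phase means: %s (within-subject SE: %s)\n", v,
                paste(sprintf("%.2f", x[[v]]$phase_means), collapse = ", "),
                paste(sprintf("%.2f", x[[v]]$within_subject_se), collapse = ", ")))
    for (cs in x[[v]]$contrasts) print(cs)
  }
  invisible(x)
}

#' Write a cohort statistics report as YAML
#'
#' Serializes every contrast (including the analyzed difference vectors,
#' Shapiro-Wilk p-values and transform flags), the per-phase means and
#' within-subject SEs.
#'
#' @param stats A [cohort_stats()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stats_report <- function(stats, path) {
  ser <- list(orientation = stats$orientation)
  for (v in setdiff(names(stats), "orientation")) {
    node <- stats[[v]]
    if (!is.null(node$error)) { ser[[v]] <- list(error = node$error); next }
    ser[[v]] <- list(
      phase_means = as.list(node$phase_means),
      within_subject_se = as.list(node$within_subject_se),
      contrasts = lapply(node$contrasts, function(cs) {
        if (inherits(cs, "failed_contrast")) {
          return(list(contrast = cs$contrast, error = cs$error))
        }
        list(contrast = cs$contrast, tail = cs$tail, t = cs$t_stat,
             df = cs$df, p = cs$p_value, g1 = cs$g1,
             g1_ci = c(cs$g1_ci_low, cs$g1_ci_high),
             transform = cs$transform, sw_p = cs$sw_p, d = cs$d)
      })
    )
  }
  yaml::write_yaml(ser, path)
  invisible(path)
}
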