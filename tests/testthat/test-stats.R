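test_that("identical vectors give the degenerate null result", {
  a <- c(1, 2, 3, 4, 5)
  res <- paired_contrast(a, a)
  expect_equal(res$t_stat, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$g1, 0)
})

test_that("t and g1 reproduce the closed-form values on d = 1..5", {
  d <- c(1, 2, 3, 4, 5)
  res <- paired_contrast(d + 10, rep(10, 5), transform = "none")
  # brute-force formulas on the five numbers
  m <- sum(d) / 5
  s <- sqrt(sum((d - m)^2) / 4)
  t_hand <- m / (s / sqrt(5))
  J <- 1 - 3 / (4 * 4 - 1)
  expect_equal(res$t_stat, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$g1, J * m / s, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * stats::pt(-t_hand, 4), tolerance = 1e-12)
  # the interval contains the estimate
  expect_lte(res$g1_ci_low, res$g1)
  expect_gte(res$g1_ci_high, res$g1)
})

test_that("one-tailed p is half the two-tailed p in the hypothesized direction", {
  set.seed(51)
  a <- rnorm(12, 1); b <- rnorm(12)
  two <- paired_contrast(a, b, tail = "two", transform = "none")
  one <- paired_contrast(a, b, tail = "one", direction = "greater",
                         transform = "none")
  expect_equal(one$p_value, two$p_value / 2, tolerance = 1e-12)
})

test_that("g1 confidence intervals tighten as n grows", {
  widths <- sapply(c(5, 10, 20, 40), function(n) {
    d <- rep(c(0.5, 1.5), length.out = n) # fixed mean 1, sd constant
    g <- hedges_g1(d)
    diff(g$ci)
  })
  expect_true(all(diff(widths) < 0))
})

test_that("the normality gate routes skewed differences into the log branch", {
  set.seed(52)
  d <- exp(rnorm(20, 0, 1.5)) + 0.01   # strongly right-skewed, positive
  res <- paired_contrast(d, rep(0, 20), sw_alpha = 0.01)
  expect_equal(res$transform, "log_diff")
  expect_lt(res$sw_p, 0.01)
  expect_equal(res$d, log(d))
  # non-positive differences make the log branch fail loudly, naming pairs
  d2 <- c(-0.5, seq(0.5, 9, length.out = 19))
  expect_error(paired_contrast(d2, rep(0, 20), transform = "log"),
               "pair\\(s\\) 1")
})

test_that("type-I error of the gated contrast stays at the nominal level", {
  set.seed(53)
  n_rep <- 2000
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    a <- rnorm(17); b <- rnorm(17)
    p <- tryCatch(paired_contrast(a, b)$p_value, error = function(e) 1)
    rej[i] <- p < 0.05
  }
  expect_gte(mean(rej), 0.04)
  expect_lte(mean(rej), 0.06)
})

test_that("power at the observed velocity effect size matches the design", {
  set.seed(54)
  # paired differences with true standardized effect 1.6, n = 17
  hits <- replicate(400, {
    d <- rnorm(17, 1.6, 1)
    res <- paired_contrast(d, rep(0, 17), tail = "one", direction = "greater",
                           transform = "none")
    res$p_value < 0.025
  })
  expect_gt(mean(hits), 0.97)
})

test_that("within-subject SEs remove pure subject offsets", {
  # every subject shares the same profile shape
  mat <- rbind(c(0, 1, 2), c(5, 6, 7), c(-3, -2, -1))
  expect_equal(unname(within_subject_se(mat)), c(0, 0, 0))
  # hand-computed 2x2 case: normalized values per phase are equal
  m2 <- rbind(c(0, 1), c(2, 3))
  expect_equal(unname(within_subject_se(m2)), c(0, 0))
  # adding a constant to one subject's phases changes nothing
  set.seed(55)
  m3 <- matrix(rnorm(12), 4, 3)
  m4 <- m3; m4[2, ] <- m4[2, ] + 100
  expect_equal(within_subject_se(m3), within_subject_se(m4), tolerance = 1e-9)
  # Morey correction factor: against the long-hand computation
  norm <- m3 - rowMeans(m3) + mean(m3)
  hand <- sqrt(apply(norm, 2, var) * (3 / 2) / 4)
  expect_equal(unname(within_subject_se(m3)), unname(hand), tolerance = 1e-12)
})

test_that("delta regression recovers structure and degrees of freedom", {
  dv <- c(1, 2, 3, 4, 5, 6)
  expect_equal(suppressWarnings(delta_regression(dv, 2 * dv + 1)$r_squared), 1)
  # pooled main (17) + control (6) cohorts give F(1, 21)
  set.seed(56)
  dvor <- rnorm(23); dm <- 2 * dvor + rnorm(23)
  fit <- delta_regression(dvor, dm)
  expect_equal(fit$df1, 1)
  expect_equal(fit$df2, 21)
  expect_error(delta_regression(rep(1, 5), rnorm(5)), "zero variance")
  # R^2 grows with the shared-gain variance fraction
  r2 <- sapply(c(0.2, 1, 5), function(sg) {
    g <- rnorm(4000, 0, sg)
    delta_regression(g + rnorm(4000), 3 * g + rnorm(4000))$r_squared
  })
  expect_true(all(diff(r2) > 0))
  # ... and matches the analytic expectation rho^2 at each level
  sg <- 1
  expect_lt(abs(r2[2] - (3 * sg^2)^2 / ((sg^2 + 1) * (9 * sg^2 + 1))), 0.03)
})

test_that("the Bonferroni gate matches the published adjusted alpha", {
  g <- bonferroni_gate(c(0.02, 0.001), n_tests = 3)
  expect_equal(g$significant, c(FALSE, TRUE))
  expect_equal(g$adjusted_alpha, 0.05 / 3)
  expect_equal(round(100 * g$adjusted_alpha, 1), 1.7)
})
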