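test_that("null dynamics yield a constant trace", {
  set.seed(41)
  p <- simulation_params(slow_phase_velocity_h = 0, noise_sd = 0,
                         fixation_saccade_rate = 0, blink_rate_per_min = 0,
                         calib_gain = c(x = 1, y = 1),
                         calib_offset = c(x = 0, y = 0))
  sim <- simulate_task(p, straight_ahead_schedule())
  expect_lt(max(abs(diff(sim$trace$x_raw))), 1e-9)
  expect_lt(max(abs(diff(sim$trace$y_raw))), 1e-9)
  expect_equal(nrow(sim$truth$saccades), 0)
})

test_that("the de-saccaded derivative of the true signal equals the drift", {
  set.seed(42)
  p <- simulation_params(slow_phase_velocity_h = 1.5)
  sim <- simulate_task(p, straight_ahead_schedule())
  d <- diff(sim$truth$true_x) / 0.02
  drift_samples <- sim$truth$labels[-1] == 1
  expect_gt(sum(drift_samples), 1000)
  expect_lt(abs(mean(d[drift_samples]) - 1.5), 0.01)
})

test_that("voluntary search endpoints center on the attention parameter", {
  set.seed(43)
  p <- simulation_params(attention_center_x = 4.7)
  eps <- unlist(lapply(1:20, function(i) {
    sim <- simulate_task(p, search_schedule())
    tru <- sim$truth$saccades
    tru$endpoint_x[tru$type == "voluntary"]
  }))
  se <- sd(eps) / sqrt(length(eps))
  expect_lt(abs(mean(eps) - 4.7), 3 * se + 0.05)
})

test_that("ground-truth saccade intervals tile the saccade-labeled samples", {
  set.seed(44)
  p <- simulation_params(slow_phase_velocity_h = 1.2, ssa_bias_x = 2)
  sim <- simulate_task(p, straight_ahead_schedule())
  tru <- sim$truth$saccades
  # intervals are ordered and non-overlapping
  expect_true(all(diff(tru$onset) > 0))
  expect_true(all(tru$offset > tru$onset))
  expect_true(all(tru$onset[-1] >= tru$offset[-nrow(tru)]))
  # the union of (onset, offset] covers exactly the saccade-class samples
  lab <- rep(FALSE, length(sim$truth$labels))
  for (k in seq_len(nrow(tru))) lab[(tru$onset[k] + 1):tru$offset[k]] <- TRUE
  expect_identical(lab, sim$truth$labels == 2)
  # blinks stay inside the task and only flip validity
  bl <- sim$truth$blinks
  expect_true(all(bl$t_start >= 0 & bl$t_end <= 65))
  expect_equal(sum(!sim$trace$valid) > 0, nrow(bl) > 0)
})

test_that("identical master seeds reproduce identical cohorts", {
  c1 <- simulate_cohort(3, seed = 99)
  c2 <- simulate_cohort(3, seed = 99)
  expect_identical(c1$subjects[[2]]$true_values, c2$subjects[[2]]$true_values)
  expect_identical(c1$subjects[[3]]$traces$inside$search$x_raw,
                   c2$subjects[[3]]$traces$inside$search$x_raw)
})

test_that("feet-first orientation negates the signed effect deltas", {
  eff <- list(slow_phase_velocity_h = c(0, 1.1, 0),
              attention_center_x = c(0, 3.5, 0))
  ch <- simulate_cohort(6, effect = eff, seed = 7, orientation = "head_first")
  cf <- simulate_cohort(6, effect = eff, seed = 7, orientation = "feet_first")
  tv <- function(co, pm) {
    sapply(co$subjects, function(s) {
      s$true_values[[pm]][s$true_values$phase == "inside"] -
        mean(s$true_values[[pm]][s$true_values$phase != "inside"])
    })
  }
  # same seed, same noise realizations: deltas differ by exactly twice the effect
  expect_equal(tv(ch, "slow_phase_velocity_h") - tv(cf, "slow_phase_velocity_h"),
               rep(2 * 1.1, 6), tolerance = 1e-9)
  expect_equal(tv(ch, "attention_center_x") - tv(cf, "attention_center_x"),
               rep(2 * 3.5, 6), tolerance = 1e-9)
})

test_that("cohorts need at least two subjects", {
  expect_error(simulate_cohort(1, seed = 1), "at least 2")
})
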