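test_that("two-point differentiation is exact on ramps, steps and constants", {
  n <- 200
  t <- (seq_len(n) - 1) * 0.02
  ramp <- calibrated_trace(t, 1.5 * t, numeric(n))
  v <- differentiate(ramp)
  expect_true(is.na(v$vx[1]))
  expect_equal(v$vx[-1], rep(1.5, n - 1), tolerance = 1e-12)

  x <- numeric(n); x[100:n] <- 2     # 2 deg step between consecutive samples
  vs <- differentiate(calibrated_trace(t, x, numeric(n)))
  expect_equal(vs$vx[100], 100)      # 2 / 0.02
  expect_equal(sum(vs$vx[-1] != 0), 1)

  vc <- differentiate(calibrated_trace(t, rep(3, n), numeric(n)))
  expect_equal(vc$vx[-1], rep(0, n - 1))
})

test_that("velocity is undefined when either contributing sample is invalid", {
  n <- 100
  valid <- rep(TRUE, n); valid[50] <- FALSE
  tr <- calibrated_trace((seq_len(n) - 1) * 0.02, rnorm(n), rnorm(n), valid)
  v <- differentiate(tr)
  expect_true(all(is.na(v$vx[c(50, 51)])))
  expect_false(is.na(v$vx[52]))
})

test_that("pure slow drift stays below threshold; quick phases are caught", {
  drift <- make_velocity_trace(c(NA, rep(1.5, 299)))
  expect_equal(nrow(detect_saccades(drift, 15)), 0)

  set.seed(21)
  p <- simulation_params(slow_phase_velocity_h = 1.5, noise_sd = 0)
  sim <- simulate_task(p, straight_ahead_schedule())
  tr <- calibrated_trace(sim$trace$t, sim$truth$true_x, sim$truth$true_y)
  ev <- detect_saccades(differentiate(tr), 15)
  # every resetting quick phase (>= 2 deg, peak far above threshold) is
  # found exactly once, with onset within one sample of ground truth
  resets <- sim$truth$saccades[sim$truth$saccades$type == "reset", ]
  hits <- sapply(resets$onset, function(o) sum(abs(ev$onset - o) <= 1))
  expect_true(all(hits == 1))
  # and nothing else is detected beyond the simulated saccades
  expect_lte(nrow(ev), nrow(sim$truth$saccades))
})

test_that("event lists match the exhaustive per-sample scan exactly", {
  set.seed(22)
  for (rep in 1:50) {
    n <- sample(20:500, 1)
    vx <- rnorm(n, 0, 12)
    vy <- rnorm(n, 0, 8)
    spikes <- sample(n, size = max(1, n %/% 20))
    vx[spikes] <- vx[spikes] + sample(c(-1, 1), length(spikes), TRUE) * runif(length(spikes), 10, 150)
    vx[sample(n, n %/% 15)] <- NA
    vx[1] <- NA
    vel <- make_velocity_trace(vx, vy)
    got <- detect_saccades(vel, 15)
    want <- brute_detect(vel, 15)
    expect_equal(got$onset, want$onset)
    expect_equal(got$offset, want$offset)
  }
})

test_that("de-saccading masks exactly the event samples (plus margin if asked)", {
  vx <- c(NA, rep(1, 300))
  vel <- make_velocity_trace(vx)
  ev <- data.frame(onset = 10L, offset = 13L)
  out <- desaccade(vel, ev)
  expect_equal(sum(is.na(out$vx)) - 1, 4)   # samples 10..13
  expect_true(all(is.na(out$vx[10:13])))
  out2 <- desaccade(vel, ev, margin_s = 0.04)
  expect_equal(sum(is.na(out2$vx)) - 1, 8)  # widened by 2 samples each side
  # no events: identity
  out0 <- desaccade(vel, ev[0, ])
  expect_equal(out0$vx, vel$vx)
})

test_that("noise-free saw-tooth de-saccades to the exact slow-phase velocity", {
  set.seed(23)
  p <- simulation_params(slow_phase_velocity_h = 1.5, noise_sd = 0,
                         blink_rate_per_min = 0)
  sim <- simulate_task(p, straight_ahead_schedule())
  tr <- calibrated_trace(sim$trace$t, sim$truth$true_x, sim$truth$true_y)
  vel <- differentiate(tr)
  ev <- detect_saccades(vel, 15)
  vds <- desaccade(vel, ev)
  med <- median(vds$vx[vds$t >= 10], na.rm = TRUE)
  expect_lt(abs(med - 1.5), 0.05)
})

test_that("slow-phase estimate is robust to adding voluntary saccades", {
  set.seed(24)
  sched <- straight_ahead_schedule()
  med_for_rate <- function(rate) {
    p <- simulation_params(slow_phase_velocity_h = 1.5,
                           fixation_saccade_rate = rate)
    sim <- simulate_task(p, sched)
    pr <- process_task(sim$trace, sched, default_model(), analysis_config())
    median(pr$vel$vx[pr$vel$t >= 10], na.rm = TRUE)
  }
  m0 <- mean(replicate(5, med_for_rate(0)))
  m1 <- mean(replicate(5, med_for_rate(1)))
  expect_lt(abs(m0 - m1), 0.1)
})

test_that("purely horizontal drift leaves the vertical channel silent", {
  set.seed(25)
  sched <- straight_ahead_schedule()
  p <- simulation_params(slow_phase_velocity_h = 1.5, ssa_bias_x = 3)
  meds <- replicate(8, {
    sim <- simulate_task(p, sched)
    pr <- process_task(sim$trace, sched, default_model(), analysis_config())
    median(pr$vel$vy[pr$vel$t >= 10], na.rm = TRUE)
  })
  expect_lt(abs(mean(meds)), 0.05)
})
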