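sa_sched <- straight_ahead_schedule()

make_cal_trace <- function(x, y = numeric(length(x)), valid = rep(TRUE, length(x))) {
  calibrated_trace((seq_along(x) - 1) * 0.02, x, y, valid)
}

test_that("a uniform shift is removed using the central fixation", {
  n <- 65 * 50
  tr <- make_cal_trace(rep(1.3, n), rep(-0.7, n))
  out <- compensate_offset(tr, sa_sched)
  expect_lt(max(abs(out$x)), 1e-9)
  expect_lt(max(abs(out$y)), 1e-9)
  expect_equal(unname(attr(out, "offset_applied")), c(1.3, -0.7))
})

test_that("unequal fixation residuals are averaged across targets", {
  # two targets at x = 0; eye sits at +1 during the first, +3 during the second
  ev <- data.frame(x = c(0, 0), y = c(0, 0), t_on = c(0, 4), t_off = c(2, 6))
  sched <- task_schedule("straight_ahead", ev[1, ], 65)  # container only
  sched$events <- ev
  n <- 65 * 50
  t <- (seq_len(n) - 1) * 0.02
  x <- numeric(n)
  x[t < 2] <- 1
  x[t >= 4 & t < 6] <- 3
  out <- compensate_offset(make_cal_trace(x), sched)
  expect_equal(unname(attr(out, "offset_applied")[1]), 2)
})

test_that("offsets are compensated per task and never leak across phases", {
  n <- 65 * 50
  tr1 <- make_cal_trace(rep(2, n))
  tr2 <- make_cal_trace(rep(-1, n))
  out1 <- compensate_offset(tr1, sa_sched)
  out2 <- compensate_offset(tr2, sa_sched)
  expect_lt(max(abs(out1$x)), 1e-9)
  expect_lt(max(abs(out2$x)), 1e-9)
})

test_that("offset compensation leaves velocity estimates untouched", {
  set.seed(5)
  n <- 65 * 50
  x <- cumsum(rnorm(n, 0, 0.05)) / 10
  tr <- make_cal_trace(x)
  shifted <- compensate_offset(make_cal_trace(x + 5), sa_sched)
  v1 <- differentiate(tr)
  v2 <- differentiate(shifted)
  expect_equal(v1$vx[-1], v2$vx[-1], tolerance = 1e-12)
})

test_that("a task without target epochs is a warned no-op", {
  sched <- sa_sched
  sched$events <- sched$events[0, ]
  tr <- make_cal_trace(rep(1, 200))
  expect_warning(out <- compensate_offset(tr, sched), "skipped")
  expect_equal(out$x, tr$x)
})

test_that("blink masking widens invalid runs by the symmetric margin", {
  n <- 500
  valid <- rep(TRUE, n)
  valid[201:210] <- FALSE           # 0.2 s tracker loss
  tr <- raw_trace((seq_len(n) - 1) * 0.02, rnorm(n), rnorm(n), valid)
  out <- mark_blinks(tr, margin_s = 0.1)
  expect_equal(sum(!out$valid), 20) # 0.2 s + 0.1 s each side = 0.4 s
  expect_false(any(out$valid[196:215]))
  expect_true(all(out$valid[c(195, 216)]))
  # fully valid trace: empty mask
  tr2 <- raw_trace((seq_len(n) - 1) * 0.02, rnorm(n), rnorm(n))
  expect_equal(sum(!mark_blinks(tr2)$valid), 0)
})

test_that("simulated blinks are almost entirely masked", {
  set.seed(12)
  p <- simulation_params(blink_rate_per_min = 12)
  covered <- replicate(10, {
    sim <- simulate_task(p, straight_ahead_schedule())
    tr <- mark_blinks(sim$trace, 0.1)
    bl <- sim$truth$blinks
    if (nrow(bl) == 0) return(NA)
    in_blink <- rep(FALSE, nrow(tr))
    for (k in seq_len(nrow(bl))) {
      in_blink <- in_blink | (tr$t >= bl$t_start[k] & tr$t <= bl$t_end[k])
    }
    mean(!tr$valid[in_blink])
  })
  expect_gt(mean(covered, na.rm = TRUE), 0.99)
})
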