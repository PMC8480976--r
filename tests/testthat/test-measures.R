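sa <- straight_ahead_schedule()
se <- search_schedule()

test_that("VOR window starts 5 s after light offset and excludes transients", {
  n <- 65 * 50
  t <- (seq_len(n) - 1) * 0.02
  vx <- rep(1, n)
  vx[t >= 5 & t < 10] <- 10          # transient inside the settling window
  vel <- make_velocity_trace(vx)
  est <- vor_estimate(vel, sa)
  expect_equal(unname(est["vor_h"]), 1)

  # zero drift stays at zero
  vel0 <- make_velocity_trace(rep(0, n))
  expect_equal(unname(vor_estimate(vel0, sa)["vor_h"]), 0)

  # too little usable data is missing with a warning
  short <- make_velocity_trace(c(rep(1, 600), rep(NA, n - 600)))
  expect_warning(out <- vor_estimate(short, sa), "missing")
  expect_true(is.na(out["vor_h"]))
})

test_that("SSA is the median endpoint after the settling window", {
  ev <- make_events(offset_t = c(20, 30, 40), endpoint_x = c(-1, 0, 1))
  expect_equal(unname(ssa_estimate(ev, sa)["ssa"]), 0)
  # endpoints before the window start are ignored
  ev2 <- make_events(offset_t = c(2, 8, 20, 30, 40), endpoint_x = c(50, 50, -1, 0, 1))
  expect_equal(unname(ssa_estimate(ev2, sa)["ssa"]), 0)
  expect_equal(unname(ssa_estimate(ev2, sa)["n"]), 3)
  expect_warning(out <- ssa_estimate(make_events(2, 1), sa), "missing")
  expect_true(is.na(out["ssa"]))
})

test_that("search center uses target-absent epochs and drops grace saccades", {
  ep <- analysis_epochs(se, 5)
  tgt <- se$events
  # one endpoint per analysis epoch, plus contaminants in target/grace windows
  good_t <- (ep$start + ep$end) / 2
  bad_t <- c(tgt$t_on[1] + 1,          # during a target
             tgt$t_off[2] + 2,         # inside the grace window
             tgt$t_on[7] + 1)          # during the final central target
  ev <- make_events(offset_t = c(good_t, bad_t),
                    endpoint_x = c(rep(2, length(good_t)), 100, 100, 100))
  est <- search_center(ev, se, 5)
  expect_equal(unname(est["search_center"]), 2)
  expect_equal(unname(est["n"]), length(good_t))
  # median variant
  est_med <- search_center(ev, se, 5, stat = "median")
  expect_equal(unname(est_med["search_center"]), 2)
})

test_that("measures are translation-equivariant", {
  set.seed(31)
  p <- simulation_params(slow_phase_velocity_h = 1.0, ssa_bias_x = 2)
  sim <- simulate_task(p, sa)
  tr <- calibrated_trace(sim$trace$t, sim$truth$true_x, sim$truth$true_y)
  shift <- 3
  tr_s <- calibrated_trace(tr$t, tr$x + shift, tr$y)
  mfor <- function(trace) {
    vel <- differentiate(trace)
    ev <- detect_saccades(vel, 15)
    vds <- desaccade(vel, ev, 0.04)
    c(vor = unname(vor_estimate(vds, sa)["vor_h"]),
      ssa = unname(ssa_estimate(ev, sa)["ssa"]))
  }
  m0 <- mfor(tr); m1 <- mfor(tr_s)
  expect_equal(m1["vor"], m0["vor"], tolerance = 1e-9)
  expect_equal(m1["ssa"], m0["ssa"] + shift, tolerance = 1e-9)
})

test_that("parameters recover across the drift x bias grid", {
  set.seed(32)
  cfg <- analysis_config()
  sch <- canonical_schedule(seed = 7)
  for (drift in c(-1.5, 0, 1.5)) {
    for (bias in c(-5, 0, 5)) {
      p <- simulation_params(slow_phase_velocity_h = drift,
                             ssa_bias_x = bias, attention_center_x = bias)
      reps <- replicate(4, {
        sim_sa <- simulate_task(p, sch$phases$inside$straight_ahead)
        sim_se <- simulate_task(p, sch$phases$inside$search)
        pr_sa <- process_task(sim_sa$trace, sch$phases$inside$straight_ahead,
                              default_model(), cfg)
        pr_se <- process_task(sim_se$trace, sch$phases$inside$search,
                              default_model(), cfg)
        c(vor = unname(vor_estimate(pr_sa$vel, sch$phases$inside$straight_ahead)["vor_h"]),
          ssa = unname(ssa_estimate(pr_sa$events, sch$phases$inside$straight_ahead)["ssa"]),
          ctr = unname(search_center(pr_se$events, sch$phases$inside$search)["search_center"]))
      })
      m <- rowMeans(reps)
      expect_lt(abs(m["vor"] - drift), 0.1)
      expect_lt(abs(m["ssa"] - bias), 0.5)
      expect_lt(abs(m["ctr"] - bias), 0.5)
    }
  }
})
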