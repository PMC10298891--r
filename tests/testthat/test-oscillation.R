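# Synthetic time course with known content.
fake_tc <- function(tt, signals) {
  structure(list(time = tt,
                 state = do.call(cbind, signals),
                 rates = matrix(0, length(tt), 0),
                 params = ebr_parameters(), eth = 0,
                 solver = list(method = "none", rtol = NA, atol = NA)),
            class = "ebr_timecourse")
}

test_that("known sinusoids are measured exactly", {
  tt <- seq(0, 200, by = 0.02)
  tc <- fake_tc(tt, list(FDP = 2 + sin(2 * pi * tt / 5),
                         GAP = rep(1.5, length(tt))))
  m <- oscillation_metrics(tc, "FDP", transient = 100)
  expect_true(m$oscillatory)
  expect_true(m$accepted)
  expect_equal(m$period, 5, tolerance = 1e-4)
  expect_equal(m$amplitude, 2, tolerance = 1e-4)

  flat <- oscillation_metrics(tc, "GAP", transient = 100)
  expect_false(flat$oscillatory)
  expect_equal(flat$amplitude, 0)
})

test_that("phase shifts recover a known lag and the self-lag is zero", {
  tt <- seq(0, 300, by = 0.05)
  tc <- fake_tc(tt, list(A = sin(2 * pi * tt / 10),
                         B = sin(2 * pi * (tt - 2.5) / 10),
                         C = -sin(2 * pi * tt / 10)))
  ph <- phase_shifts(tc, list(c("A", "A"), c("A", "B"), c("A", "C")),
                     transient = 50)
  expect_equal(ph$lag[1], 0, tolerance = 1e-6)
  expect_equal(abs(ph$lag[2]), 2.5, tolerance = 0.06)
  expect_equal(abs(ph$lag[3]), 5, tolerance = 0.06)  # antiphase = T/2
})

# One settled limit cycle just above the oscillation onset, reused by the
# remaining blocks.
cycle_tc <- local({
  ss <- steady_on_branch(alpha = 106.1, eth = 10)
  p <- ebr_parameters(alpha_ADH = 106.1, alpha_ALDH = 106.1)
  integrate_model(ss$state * 1.001, p, t_end = 400, eth = 10, n_out = 8000)
})

test_that("the limit cycle just above onset has a reproducible period", {
  m <- oscillation_metrics(cycle_tc, "FDP", transient = 150)
  expect_true(m$oscillatory)
  expect_true(m$accepted)
  # frozen from a verified run of this exact protocol
  expect_equal(m$period, 38.35, tolerance = 0.01)
  expect_gt(m$amplitude, 0.02)
  expect_lt(m$amplitude, 1)
  # every coupled variable oscillates with the same period
  for (sig in c("ATP", "AMP", "GAP", "NAD")) {
    ms <- oscillation_metrics(cycle_tc, sig, transient = 150)
    expect_true(ms$oscillatory)
    expect_equal(ms$period, m$period, tolerance = 1e-3)
  }
})

test_that("phase relations on the cycle match the oscillation mechanism", {
  ph <- phase_shifts(cycle_tc, list(c("ATP", "AMP"), c("NAD", "GAP")),
                     transient = 150)
  Tper <- ph$period[1]
  # ATP and AMP are in antiphase (high ATP means low AMP)
  expect_lt(abs(abs(ph$lag[1]) - Tper / 2), 0.1 * Tper)
  # NAD and GAP move in opposition: low NAD lets GAP pile up
  keep <- cycle_tc$time >= 150
  expect_lt(cor(cycle_tc$state[keep, "NAD"],
                cycle_tc$state[keep, "GAP"]), 0)
})

test_that("the doubled PFK rate crosses the GAPDH rate twice per cycle", {
  m <- oscillation_metrics(cycle_tc, "FDP", transient = 150)
  keep <- cycle_tc$time >= 150
  x <- 2 * cycle_tc$rates[keep, "V_PFK"] - cycle_tc$rates[keep, "V_GAPDH"]
  crossings <- sum(diff(sign(x)) != 0)
  n_periods <- (max(cycle_tc$time) - 150) / m$period
  expect_equal(crossings / n_periods, 2, tolerance = 0.2)
})

test_that("amplitude and period grow with activity across the window", {
  cur <- amplitude_period_curve(alpha = c(106.1, 106.5, 106.9), eth = 10,
                                t_end = 400, transient = 150)
  expect_true(all(cur$oscillatory))
  expect_true(all(diff(cur$amplitude) > 0))
  expect_true(all(diff(cur$period) > 0))
})
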