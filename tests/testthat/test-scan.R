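coarse <- scan_activity(alpha = seq(0, 80, by = 20), eth = 10,
                        refine = FALSE)

test_that("the stable branch responds monotonically to the enzyme load", {
  expect_true(all(coarse$exists))
  expect_true(all(coarse$regime == "STABLE"))
  v_adh <- coarse$rates[, "V_ADH"]
  nad <- coarse$states[, "NAD"]
  expect_true(all(diff(v_adh) > 0))       # consumption rises with activity
  expect_true(all(diff(nad) < 0))         # NAD is drained
  # glycolytic input flux stays essentially constant along the branch
  expect_lt(diff(range(coarse$rates[, "V_HK"])), 0.01)
})

test_that("branch states vary continuously along the scan", {
  # a branch jump (e.g. onto the collapsed zero-flux root) would change
  # concentrations by orders of magnitude between neighbouring points;
  # smooth branch growth keeps successive ratios moderate
  pos <- coarse$states[, c("G6P", "F6P", "FDP", "DAP", "GAP", "DPG23",
                           "LAC", "NAD", "PHI")]
  ratios <- pos[-1, ] / pos[-nrow(pos), ]
  expect_true(all(ratios > 0.2 & ratios < 5))
  # the slowly varying quantities barely move at all
  expect_lt(diff(range(coarse$states[, "PHI"])), 0.02)
  expect_lt(diff(range(coarse$states[, "G6P"])), 0.02)
})

test_that("steady-state flux splitting holds on the loaded branch", {
  for (i in seq_along(coarse$grid)) {
    v <- coarse$rates[i, ]
    expect_equal(unname(v["V_GAPDH"]), unname(v["V_PGK"] + v["V_DPGM"]),
                 tolerance = 1e-3)
    expect_equal(unname(v["V_DPGM"]), unname(v["V_DPGP"]),
                 tolerance = 1e-3)
    # NAD turnover closes: LDH regenerates what GAPDH + load consume
    expect_equal(unname(v["V_LDH"]),
                 unname(v["V_GAPDH"] + v["V_ADH"] + v["V_ALDH"]),
                 tolerance = 1e-3)
  }
})

test_that("a stable-branch point attracts a 1% perturbation at the rate of its leading eigenvalue", {
  ss <- steady_on_branch(alpha = 60, eth = 10)
  expect_true(ss$stable)
  p <- ebr_parameters(alpha_ADH = 60, alpha_ALDH = 60)
  tc <- integrate_model(ss$state * 1.01, p, t_end = 60, eth = 10,
                        n_out = 400)
  dev <- abs(tc$state[, "FDP"] - ss$state[["FDP"]])
  # leading eigenvalue ~ -0.13 1/h: a 60 h run shrinks the deviation by
  # far more than 20x
  expect_lt(dev[length(dev)], dev[1] * 0.05)
})

test_that("ethanol response at fixed moderate load is stable and increasing", {
  se <- scan_ethanol(eth = c(0, 5, 10, 20), alpha = 40, refine = FALSE)
  expect_true(all(se$regime == "STABLE"))
  expect_true(all(diff(se$rates[, "V_ADH"]) > 0))
  expect_true(all(diff(se$states[, "NAD"]) < 0))
})

test_that("single-point classification distinguishes the three regimes", {
  expect_identical(classify_regime(alpha = 90, eth = 10)$regime, "STABLE")
  cl <- classify_regime(alpha = 120, eth = 10)
  expect_identical(cl$regime, "ACCUMULATION")
  expect_false(cl$no_steady_state)
})
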