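test_that("the reference root is a fixed point of the integrator", {
  ss <- find_steady_state(ebr_parameters(), eth = 0)
  tc <- integrate_model(ss$state, ebr_parameters(), t_end = 100, eth = 0,
                        n_out = 60)
  drift <- abs(tc$state[nrow(tc$state), names(ss$state)] - ss$state)
  expect_lt(max(drift), 1e-4)
})

test_that("a trajectory from the printed concentrations settles onto the root", {
  ss <- find_steady_state(ebr_parameters(), eth = 0)
  tc <- integrate_model(reference_state(), ebr_parameters(), t_end = 150,
                        eth = 0, n_out = 100)
  final <- tc$state[nrow(tc$state), names(ss$state)]
  expect_lt(max(abs(final - ss$state)), 1e-4)
})

test_that("conserved pools hold at every stored point of a loaded run", {
  tc <- simulate_suspension(10, 0.5, alpha_ADH = 60, alpha_ALDH = 60,
                            t_end = 10, n_out = 400)
  st <- tc$state
  expect_lt(max(abs(st[, "NAD"] + st[, "NADH"] - 0.05)), 1e-9)
  expect_lt(max(abs(st[, "ATP"] + st[, "ADP"] + st[, "AMP"] - 1.744)),
            1e-9)
  expect_true(all(st[, "PHI"] >= 0 & st[, "PHI"] <= 1))
  expect_false(any(!is.finite(st)))
  expect_true(all(diff(tc$time) > 0))
})

test_that("suspension ethanol and acetaldehyde close their mass balances", {
  tc <- simulate_suspension(10, 0.5, alpha_ADH = 60, alpha_ALDH = 60,
                            t_end = 8, n_out = 2000)
  tt <- tc$time
  vadh <- tc$rates[, "V_ADH"]; valdh <- tc$rates[, "V_ALDH"]
  cum <- function(x) c(0, cumsum((head(x, -1) + tail(x, -1)) / 2 *
                                   diff(tt)))
  consumed <- 10 - tc$state[, "ETH"]
  expect_lt(max(abs(0.5 * cum(vadh) - consumed)) /
              max(consumed), 1e-3)
  # acetaldehyde is the small difference of the two large turnovers, so its
  # balance is checked against the cumulative turnover itself
  expect_lt(max(abs(cum(vadh - valdh) - tc$state[, "ACALD"])) /
              max(cum(vadh)), 1e-3)
})

test_that("without load enzymes suspension ethanol stays constant", {
  tc <- simulate_suspension(10, 0.5, alpha_ADH = 0, alpha_ALDH = 0,
                            t_end = 5, n_out = 50)
  expect_lt(max(abs(tc$state[, "ETH"] - 10)), 1e-8)
})

test_that("ADH without ALDH stalls at its equilibrium after ~40 uM consumed", {
  tc <- simulate_suspension(10, 0.5, alpha_ADH = 60, alpha_ALDH = 0,
                            t_end = 10, n_out = 500)
  n <- nrow(tc$state)
  consumed <- tc$state[n, "consumed_cell"] * 1000   # uM per liter cells
  acald <- tc$state[n, "ACALD"] * 1000
  # plateau: consumption and acetaldehyde agree (no ALDH drain) ...
  expect_equal(unname(consumed), unname(acald), tolerance = 1e-3)
  # ... the plateau is flat ...
  mid <- which.min(abs(tc$time - 5))
  expect_lt(abs(tc$state[n, "consumed_cell"] -
                  tc$state[mid, "consumed_cell"]) * 1000, 1)
  # ... and sits near the printed 40 uM
  expect_equal(unname(consumed), 40, tolerance = 0.05)
  # ADH is at equilibrium there
  v <- tc$rates[n, "V_ADH"]
  expect_lt(abs(v), 1e-3)
})

test_that("terminal states are robust to halving the solver tolerances", {
  p <- ebr_parameters(alpha_ADH = 60, alpha_ALDH = 60)
  a <- integrate_model(reference_state(), p, t_end = 30, eth = 10,
                       n_out = 50)
  b <- integrate_model(reference_state(), p, t_end = 30, eth = 10,
                       n_out = 50, rtol = 5e-9, atol = 5e-11)
  relchange <- abs(a$state[50, ] - b$state[50, ]) /
    pmax(abs(b$state[50, ]), 1e-8)
  expect_lt(max(relchange), 1e-3)
})
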