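ref_ss <- find_steady_state(ebr_parameters(), eth = 0)

test_that("the unloaded steady state reproduces the printed resting concentrations", {
  expect_true(ref_ss$converged)
  expect_true(ref_ss$stable)
  expect_lt(ref_ss$residual, 1e-8)
  got <- c(ref_ss$state[c("G6P", "F6P", "FDP", "DAP", "GAP", "DPG13",
                          "DPG23", "PG3", "PG2", "PEP", "PYR", "LAC",
                          "NAD")],
           ref_ss$cofactors[c("ATP", "ADP", "AMP")],
           ACALD = unname(ref_ss$state["ACALD"]))
  want <- table1_concentrations[c("G6P", "F6P", "FDP", "DAP", "GAP",
                                  "DPG13", "DPG23", "PG3", "PG2", "PEP",
                                  "PYR", "LAC", "NAD", "ATP", "ADP",
                                  "AMP", "ACALD")]
  rel <- abs(got - want) / pmax(abs(want), 1e-9)
  rel["ACALD"] <- abs(got[["ACALD"]])
  expect_lt(max(rel), 0.05)
})

test_that("steady fluxes match the printed pathway rates within 1%", {
  v <- ref_ss$rates
  expect_equal(unname(v["V_HK"]), 1.12, tolerance = 0.01)
  expect_equal(unname(v["V_PFK"]), 1.12, tolerance = 0.01)
  expect_equal(unname(v["V_GAPDH"]), 2.24, tolerance = 0.01)
  expect_equal(unname(v["V_PK"]), 2.24, tolerance = 0.01)
  expect_equal(unname(v["V_PGK"]), 1.61, tolerance = 0.01)
})

test_that("steady-state stoichiometric identities hold at the reference root", {
  v <- ref_ss$rates
  expect_equal(unname(v["V_GPI"]), unname(v["V_HK"]), tolerance = 1e-3)
  expect_equal(unname(v["V_ALD"]), unname(v["V_PFK"]), tolerance = 1e-3)
  expect_equal(unname(2 * v["V_HK"]), unname(v["V_GAPDH"]),
               tolerance = 1e-3)
  expect_equal(unname(v["V_GAPDH"]), unname(v["V_PGK"] + v["V_DPGM"]),
               tolerance = 1e-3)
  expect_equal(unname(v["V_DPGM"]), unname(v["V_DPGP"]), tolerance = 1e-3)
  expect_equal(unname(v["V_PK"]), unname(v["V_ENO"]), tolerance = 1e-3)
  expect_equal(unname(v["V_LDH"]), unname(v["V_GAPDH"]), tolerance = 1e-3)
  expect_lt(abs(v[["V_trPYR"]]), 1e-3)
  expect_equal(unname(v["V_trLAC"]), -unname(v["V_LDH"]), tolerance = 1e-3)
  # ATP closure: production balances the two ATPase sinks
  expect_equal(
    unname(v["V_PGK"] + v["V_PK"] - v["V_HK"] - v["V_PFK"]),
    unname(v["V_NaKATP"] + v["V_ATP"]), tolerance = 1e-6)
  expect_equal(unname(v["V_NaKATP"] + v["V_ATP"]), 1.61, tolerance = 0.01)
})

test_that("the root is recovered from strongly perturbed guesses", {
  set.seed(5)
  for (i in 1:5) {
    g <- ref_ss$state * runif(length(ref_ss$state), 0.8, 1.2)
    g["PHI"] <- min(g[["PHI"]], 1)
    ss <- find_steady_state(ebr_parameters(), eth = 0, guess = g)
    expect_true(ss$converged)
    expect_lt(max(abs(ss$state - ref_ss$state)), 1e-6)
  }
})

test_that("the steady state under heavy load is unstable (oscillatory regime and beyond)", {
  ss <- steady_on_branch(alpha = 110, eth = 10)
  expect_true(ss$converged)
  expect_false(ss$stable)
  # instability arrives through a complex pair
  lead <- ss$eigenvalues[which.max(Re(ss$eigenvalues))]
  expect_gt(Re(lead), 0)
  expect_gt(abs(Im(lead)), 0)
})

test_that("consumption rate is zero without load enzymes", {
  expect_equal(consumption_rate_at_steady_state(alpha = 0, eth = 10), 0,
               tolerance = 1e-10)
})
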