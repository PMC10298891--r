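test_that("implementation matches the naive oracle transcription on random states", {
  set.seed(42)
  p0 <- ebr_parameters()
  for (i in 1:100) {
    s <- random_state()
    eth <- runif(1, 0, 40)
    aadh <- runif(1, 0, 150); aaldh <- runif(1, 0, 150)
    p <- p0; p$alpha_ADH <- aadh; p$alpha_ALDH <- aaldh
    v <- reaction_rates(s, p, eth = eth)
    w <- oracle_rates(s, eth, alpha_ADH = aadh, alpha_ALDH = aaldh)
    rel <- abs(v - w[names(v)]) / pmax(abs(w[names(v)]), 1e-12)
    expect_lt(max(rel), 1e-12)
  }
})

test_that("zero substrates give zero rates for the internal reactions", {
  s <- reference_state()
  s[c("G6P", "F6P", "FDP", "DAP", "GAP", "PG3", "PG2", "PEP",
      "PYR", "LAC")] <- 0
  s[["DPG13"]] <- 0
  s[["NAD"]] <- 0.05  # NADH = 0, so no reverse fluxes either
  v <- reaction_rates(s, ebr_parameters(), eth = 0)
  for (nm in c("V_GPI", "V_ALD", "V_TPI", "V_GAPDH", "V_PGM", "V_ENO",
               "V_PK", "V_LDH", "V_DPGM"))
    expect_equal(unname(v[nm]), 0, tolerance = 1e-14)
})

test_that("load rates vanish exactly when they should", {
  p <- ebr_parameters()
  v <- reaction_rates(reference_state(), p, eth = 10)
  expect_identical(unname(v["V_ADH"]), 0)   # alpha_ADH = 0
  expect_identical(unname(v["V_ALDH"]), 0)  # ACALD = 0

  # ADH numerator vanishes at the reaction's equilibrium
  p$alpha_ADH <- 60
  s <- reference_state()
  s[["NAD"]] <- 0.048
  eth <- 10
  s[["ACALD"]] <- 2e-4 * eth * s[["NAD"]] / (0.05 - s[["NAD"]])
  v <- reaction_rates(s, p, eth = eth)
  expect_equal(unname(v["V_ADH"]), 0, tolerance = 1e-12)
})

test_that("ADH rate at the reference cofactor ratio matches hand evaluation", {
  # alpha_ADH = 60, ETH = 10, NAD = 0.048, NADH = 0.002, ACALD = 0:
  # denominator terms 7.93 + 0.624 + 0.74 + 0.48 + 0.8811 + 0.0822
  p <- ebr_parameters(alpha_ADH = 60)
  v <- reaction_rates(reference_state(), p, eth = 10)
  expect_equal(unname(v["V_ADH"]), 60 * 0.48 / 10.7373333,
               tolerance = 1e-6)
})

test_that("irreversible rates stay non-negative on random non-negative states", {
  set.seed(7)
  irrev <- c("V_HK", "V_PFK", "V_PK", "V_ALDH", "V_NaKATP", "V_ATP",
             "V_DPGM", "V_DPGP")
  p <- ebr_parameters(alpha_ADH = 80, alpha_ALDH = 80)
  for (i in 1:50) {
    v <- reaction_rates(random_state(), p, eth = runif(1, 0, 30))
    expect_true(all(v[irrev] >= 0))
  }
})

test_that("transport rates vanish at zero gradient", {
  s <- reference_state()
  s[["PYR"]] <- 0.07; s[["LAC"]] <- 1.2
  v <- reaction_rates(s, ebr_parameters(), eth = 0)
  expect_identical(unname(v["V_trPYR"]), 0)
  expect_identical(unname(v["V_trLAC"]), 0)
})

test_that("negative concentrations are rejected", {
  s <- reference_state()
  s[["FDP"]] <- -0.01
  expect_error(reaction_rates(s, ebr_parameters()), "negative")
})
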