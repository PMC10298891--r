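test_that("adenylate split reproduces the resting-cell ATP/ADP/AMP", {
  phi <- (2 * 1.471 + 0.235) / (2 * 1.744)
  ad <- adenylate_split(phi, P = 1.744, K_AK = 1)
  expect_equal(ad[["ATP"]], 1.471, tolerance = 1e-3)
  expect_equal(ad[["ADP"]], 0.235, tolerance = 3e-3)
  expect_equal(ad[["AMP"]], 0.038, tolerance = 1e-2)
})

test_that("fully charged and fully discharged limits are exact", {
  expect_equal(unname(adenylate_split(1, P = 1.744)),
               c(1.744, 0, 0), tolerance = 1e-12)
  lo <- adenylate_split(0, P = 1.744)
  expect_equal(lo[["ATP"]], 0, tolerance = 1e-12)
  expect_equal(lo[["AMP"]], 1.744, tolerance = 1e-12)
})

test_that("closed form agrees with the brute-force constraint scan", {
  # frozen case phi = 0.75, P = 2, K = 1 plus a sweep of others
  bf <- oracle_adenylate(0.75, P = 2, K = 1)
  cf <- adenylate_split(0.75, P = 2, K_AK = 1)
  expect_equal(unname(cf), unname(bf), tolerance = 1e-7)
  expect_equal(cf[["ADP"]], 0.5351838, tolerance = 1e-6)

  for (phi in c(0.1, 0.5, 0.9, 0.98)) {
    for (K in c(0.5, 1, 2)) {
      cf <- adenylate_split(phi, P = 1.744, K_AK = K)
      bf <- oracle_adenylate(phi, P = 1.744, K = K)
      expect_equal(unname(cf), unname(bf), tolerance = 1e-6)
    }
  }
})

test_that("split satisfies both constraints and non-negativity everywhere", {
  set.seed(11)
  for (i in 1:50) {
    phi <- runif(1); P <- runif(1, 0.5, 4); K <- runif(1, 0.3, 3)
    ad <- adenylate_split(phi, P, K)
    expect_true(all(ad >= 0))
    expect_equal(sum(ad), P, tolerance = 1e-10)
    expect_equal(energy_charge(ad[["ATP"]], ad[["ADP"]], ad[["AMP"]]),
                 phi, tolerance = 1e-10)
    if (ad[["ADP"]] > 1e-8)
      expect_equal(ad[["ATP"]] * ad[["AMP"]] / ad[["ADP"]]^2, K,
                   tolerance = 1e-6)
  }
})

test_that("invalid energy charge is rejected", {
  expect_error(adenylate_split(1.2), "phi")
  expect_error(adenylate_split(-0.1), "phi")
})
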