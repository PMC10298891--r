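# Independent, deliberately naive transcription of every rate law, kept
# separate from the package implementation so the two can be compared as
# implementation vs oracle. Written formula-by-formula with explicit
# constants (not the package's parameter list).

oracle_adenylate <- function(phi, P = 1.744, K = 1) {
  # brute-force 1-D scan over ADP followed by local refinement of the two
  # remaining constraints
  obj <- function(d) {
    ATP <- phi * P - d / 2
    AMP <- P - ATP - d
    if (ATP < -1e-12 || AMP < -1e-12) return(Inf)
    (ATP * AMP - K * d^2)^2
  }
  grid <- seq(0, P, length.out = 20001)
  vals <- vapply(grid, obj, numeric(1))
  d0 <- grid[which.min(vals)]
  opt <- stats::optimize(obj, c(max(0, d0 - 1e-3), min(P, d0 + 1e-3)),
                         tol = 1e-14)
  d <- opt$minimum
  c(ATP = phi * P - d / 2, ADP = d, AMP = P - (phi * P - d / 2) - d)
}

oracle_rates <- function(s, eth, alpha_ADH = 0, alpha_ALDH = 0,
                         N = 0.05, P = 1.744, Pi = 1, Na = 10,
                         PYRext = 0.07, LACext = 1.2) {
  ad <- adenylate_split(s[["PHI"]], P, 1)
  ATP <- ad[["ATP"]]; ADP <- ad[["ADP"]]; AMP <- ad[["AMP"]]
  NADH <- N - s[["NAD"]]
  G6P <- s[["G6P"]]; F6P <- s[["F6P"]]; FDP <- s[["FDP"]]
  DAP <- s[["DAP"]]; GAP <- s[["GAP"]]; DPG13 <- s[["DPG13"]]
  DPG23 <- s[["DPG23"]]; PG3 <- s[["PG3"]]; PG2 <- s[["PG2"]]
  PEP <- s[["PEP"]]; PYR <- s[["PYR"]]; LAC <- s[["LAC"]]
  NAD <- s[["NAD"]]; ACALD <- s[["ACALD"]]

  v <- numeric(0)
  v["V_HK"] <- 12 * (ATP / 1) / (1 + ATP / 1 + G6P / 0.0055)
  v["V_GPI"] <- 360 * (G6P - 3 * F6P) / 0.3 / (1 + G6P / 0.3 + F6P / 0.2)
  L <- 1e8 * (1 + ATP / 0.195)^4 /
    ((1 + AMP / 0.01)^4 * (1 + F6P / 0.00037)^4)
  v["V_PFK"] <- 380 * 1.1 * ATP * F6P *
    (1 / (1 + AMP / 0.01) + 2 * AMP / (0.01 + AMP)) /
    ((2 + ATP) * (0.1 + F6P) * (1 + L))
  v["V_ALD"] <- 76 * (FDP / 2e-4 - DAP * GAP / 1.2e-5) /
    (1 + FDP / 0.01 + DAP / 0.032 + GAP / 0.0021 +
       FDP * DAP / 0.00032 + DAP * DAP / 0.064 + DAP * GAP / 0.00208)
  v["V_TPI"] <- 19522 * (DAP - GAP / 0.45) / 0.82 /
    (1 + DAP / 0.82 + GAP / 0.43)
  v["V_GAPDH"] <- 690 * (GAP * NAD * Pi - DPG13 * NADH / 0.136) /
    (0.13 * 0.13 * 3.4) /
    (1.29 * (1 + GAP / 0.13 + DPG13 / 0.013) *
       (1 + NAD / 0.13 + NADH / 0.002))
  Aa <- (0.3 + ADP + 0.3 * ATP / 0.27) / 0.14
  Bb <- (0.4 + ATP + 0.4 * ADP / 0.14) / 0.27
  v["V_PGK"] <- 2115 * (DPG13 * ADP - PG3 * ATP / 380) / (0.0022 * 0.14) /
    (1 + ATP / 0.27 + ADP / 0.14 + Aa * DPG13 / 0.0022 + Bb * PG3 / 1.4)
  v["V_DPGM"] <- 3892 * DPG13 / (0.04 + 0.013 + DPG13 + DPG23)
  v["V_DPGP"] <- 0.65 * DPG23 / (DPG23 + 0.02 * (1 + (PG2 + PG3) / 0.006))
  v["V_PGM"] <- 1100 * (PG3 - PG2 / 0.24) / 0.27 /
    (1 + PG3 / 0.27 + PG2 / 0.02)
  v["V_ENO"] <- 120 * (PG2 - PEP / 6.7) / 0.056 /
    (1 + PG2 / 0.056 + PEP / 0.002)
  v["V_PK"] <- 120 * PEP * ADP / (0.05 * 0.43) /
    (1 + ATP / 0.35 + ADP / 0.43 + PEP / 0.05 + PEP * ADP / (0.05 * 0.43))
  Cc <- 170 * NAD + 0.1 * LAC + NAD * LAC + 170 * PYR * NAD / 0.022
  v["V_LDH"] <- 550 * (PYR * NADH - LAC * NAD / 426) / (0.022 * 0.007) /
    (1 + PYR / 0.022 + 0.14 * NADH / (0.022 * 0.007) +
       PYR * NADH / (0.022 * 0.007) +
       0.14 * LAC * NADH / (0.022 * 0.007 * 380) + Cc / (380 * 0.1))
  v["V_NaKATP"] <- 0.045 * Na * ATP
  v["V_ATP"] <- 1.6 * ATP / (ATP + 1)
  K1 <- 0.074; K2 <- 0.61; K3 <- 13; K4 <- 0.43; K5 <- 0.78
  K6 <- 0.67; K7 <- 0.11; K8 <- 0.018
  D <- K2 * K3 + K3 * NAD + K1 * eth + NAD * eth +
    K2 * K3 * NADH / K8 +
    K2 * K3 * K7 * ACALD / (K5 * K8) +
    K2 * K3 * ACALD * NADH / (K5 * K8) +
    K3 * K7 * ACALD * NAD / (K5 * K8) +
    K1 * eth * NADH / K8 +
    ACALD * eth * NAD / K6 +
    K2 * K3 * K4 * ACALD * eth * NADH / (K5 * K8)
  v["V_ADH"] <- alpha_ADH * (NAD * eth - ACALD * NADH / 2e-4) / D
  v["V_ALDH"] <- alpha_ALDH * NAD * ACALD /
    ((NAD * ACALD + 0.009 * NAD + 0.02 * ACALD + 0.07 * 0.009) *
       (1 + NADH / 0.1))
  v["V_trPYR"] <- 120 * (PYRext - PYR) /
    (PYRext + PYR + (1 + (LAC + LACext) / 11) * 1.9)
  v["V_trLAC"] <- 120 * (LACext - LAC) /
    (LACext + LAC + (1 + (PYR + PYRext) / 1.6) * 9)
  v
}

# Random plausible non-negative state for property tests.
random_state <- function() {
  ref <- reference_state()
  s <- ref * exp(stats::runif(length(ref), log(0.25), log(4)))
  s[["PHI"]] <- stats::runif(1, 0.05, 0.99)
  s[["NAD"]] <- stats::runif(1, 0.02, 0.98) * 0.05
  s[["ACALD"]] <- stats::runif(1, 0, 0.1)
  s
}

# Printed reference concentrations of the resting cell.
table1_concentrations <- c(
  G6P = 0.073, F6P = 0.024, FDP = 0.0084, DAP = 0.034, GAP = 0.015,
  DPG13 = 5.7e-4, DPG23 = 3.5, PG3 = 0.034, PG2 = 0.008, PEP = 0.01,
  PYR = 0.07, LAC = 1.43, NAD = 0.048, NADH = 0.002, ATP = 1.471,
  ADP = 0.235, AMP = 0.038, ACALD = 0)
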