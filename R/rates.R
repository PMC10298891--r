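# All nineteen rate laws of the model. `rate_core()` is the hot path: it
# assumes a clean non-negative state and returns the named rate vector.
# Glycolytic constants follow the resting-cell model; the load enzymes (ADH,
# ALDH) use ordered bi-bi and NADH-inhibited irreversible kinetics.

rate_core <- function(state, params, eth) {
  p <- params
  G6P <- state[[1L]]; F6P <- state[[2L]]; FDP <- state[[3L]]
  DAP <- state[[4L]]; GAP <- state[[5L]]; DPG13 <- state[[6L]]
  DPG23 <- state[[7L]]; PG3 <- state[[8L]]; PG2 <- state[[9L]]
  PEP <- state[[10L]]; PYR <- state[[11L]]; LAC <- state[[12L]]
  NAD <- state[[13L]]; PHI <- state[[14L]]; ACALD <- state[[15L]]

  ad <- adenylate_core(PHI, p$P, p$K_AK)
  ATP <- ad[[1L]]; ADP <- ad[[2L]]; AMP <- ad[[3L]]
  NADH <- p$N - NAD

  V_HK <- p$a_HK * (ATP / p$K_HK1) /
    (1 + ATP / p$K_HK1 + G6P / p$K_HK2)

  V_GPI <- p$a_GPI * (G6P - p$K_GPI1 * F6P) / p$K_GPI2 /
    (1 + G6P / p$K_GPI2 + F6P / p$K_GPI3)

  # PFK: Michaelis core in ATP and F6P, saturating AMP activation (at most
  # two-fold), and a concerted allosteric factor in which ATP stabilizes and
  # AMP/F6P destabilize the inactive conformation (fourth powers).
  g_amp <- 1 / (1 + AMP / p$K_PFK3) + 2 * AMP / (p$K_PFK3 + AMP)
  L <- p$L_PFK * (1 + ATP / p$K_PFK4)^4 /
    ((1 + AMP / p$K_PFK3)^4 * (1 + F6P / p$K_PFK5)^4)
  V_PFK <- p$a_PFK * p$c_PFK * ATP * F6P * g_amp /
    ((p$K_PFK2 + ATP) * (p$K_PFK1 + F6P) * (1 + L))

  V_ALD <- p$a_ALD * (FDP / p$K_ALD1 - DAP * GAP / p$K_ALD2) /
    (1 + FDP / p$K_ALD3 + DAP / p$K_ALD4 + GAP / p$K_ALD5 +
       FDP * DAP / (p$K_ALD3 * p$K_ALD4) + DAP^2 / (p$K_ALD4 * p$K_ALD6) +
       DAP * GAP / (p$K_ALD4 * p$K_ALD7))

  V_TPI <- p$a_TPI * (DAP - GAP / p$K_TPI2) / p$K_TPI1 /
    (1 + DAP / p$K_TPI1 + GAP / p$K_TPI3)

  V_GAPDH <- p$a_GAPDH *
    (GAP * NAD * p$Pi - DPG13 * NADH / p$K_GAPDH4) /
    (p$K_GAPDH1 * p$K_GAPDH2 * p$K_GAPDH3) /
    (p$c_GAPDH * (1 + GAP / p$K_GAPDH1 + DPG13 / p$K_GAPDH5) *
       (1 + NAD / p$K_GAPDH2 + NADH / p$K_GAPDH6))

  A_pgk <- (p$K_PGK4 + ADP + p$K_PGK4 * ATP / p$K_PGK5) / p$K_PGK2
  B_pgk <- (p$K_PGK7 + ATP + p$K_PGK7 * ADP / p$K_PGK2) / p$K_PGK5
  V_PGK <- p$a_PGK * (DPG13 * ADP - PG3 * ATP / p$K_PGK3) /
    (p$K_PGK1 * p$K_PGK2) /
    (1 + ATP / p$K_PGK5 + ADP / p$K_PGK2 +
       A_pgk * DPG13 / p$K_PGK1 + B_pgk * PG3 / p$K_PGK6)

  V_DPGM <- p$a_DPGM * DPG13 / (p$K_DPGM1 + p$K_DPGM2 + DPG13 + DPG23)

  V_DPGP <- p$a_DPGP * DPG23 /
    (DPG23 + p$K_DPGP1 * (1 + (PG2 + PG3) / p$K_DPGP2))

  V_PGM <- p$a_PGM * (PG3 - PG2 / p$K_PGM2) / p$K_PGM1 /
    (1 + PG3 / p$K_PGM1 + PG2 / p$K_PGM3)

  V_ENO <- p$a_ENO * (PG2 - PEP / p$K_ENO2) / p$K_ENO1 /
    (1 + PG2 / p$K_ENO1 + PEP / p$K_ENO3)

  V_PK <- p$a_PK * PEP * ADP / (p$K_PK1 * p$K_PK2) /
    (1 + ATP / p$K_PK3 + ADP / p$K_PK2 + PEP / p$K_PK1 +
       PEP * ADP / (p$K_PK1 * p$K_PK2))

  C_ldh <- p$K_LDH7 * NAD + p$K_LDH6 * LAC + NAD * LAC +
    p$K_LDH7 * PYR * NAD / p$K_LDH1
  V_LDH <- p$a_LDH * (PYR * NADH - LAC * NAD / p$K_LDH3) /
    (p$K_LDH1 * p$K_LDH2) /
    (1 + PYR / p$K_LDH1 + p$K_LDH4 * NADH / (p$K_LDH1 * p$K_LDH2) +
       PYR * NADH / (p$K_LDH1 * p$K_LDH2) +
       p$K_LDH4 * LAC * NADH / (p$K_LDH1 * p$K_LDH2 * p$K_LDH5) +
       C_ldh / (p$K_LDH5 * p$K_LDH6))

  V_NaKATP <- p$a_NaKATP * p$Na * ATP
  V_ATPase <- p$a_ATP * ATP / (ATP + p$K_ATP)

  # ADH: ordered bi-bi (A = NAD, B = ETH, P = ACALD, Q = NADH).
  D_adh <- p$K_ADH2 * p$K_ADH3 + p$K_ADH3 * NAD + p$K_ADH1 * eth +
    NAD * eth +
    p$K_ADH2 * p$K_ADH3 / p$K_ADH8 * NADH +
    p$K_ADH2 * p$K_ADH3 * p$K_ADH7 / (p$K_ADH5 * p$K_ADH8) * ACALD +
    p$K_ADH2 * p$K_ADH3 / (p$K_ADH5 * p$K_ADH8) * ACALD * NADH +
    p$K_ADH3 * p$K_ADH7 / (p$K_ADH5 * p$K_ADH8) * ACALD * NAD +
    p$K_ADH1 / p$K_ADH8 * eth * NADH +
    ACALD * eth * NAD / p$K_ADH6 +
    p$K_ADH2 * p$K_ADH3 * p$K_ADH4 / (p$K_ADH5 * p$K_ADH8) *
      ACALD * eth * NADH
  V_ADH <- p$alpha_ADH * (NAD * eth - ACALD * NADH / p$K_ADHeq) / D_adh

  V_ALDH <- p$alpha_ALDH * NAD * ACALD /
    ((NAD * ACALD + p$K_ALDH3 * NAD + p$K_ALDH1 * ACALD +
        p$K_ALDH2 * p$K_ALDH3) * (1 + NADH / p$K_ALDH4))

  V_trPYR <- p$A_trPYR * (p$PYR_ext - PYR) /
    (p$PYR_ext + PYR + (1 + (LAC + p$LAC_ext) / p$KI_trPYR) * p$Km_trPYR)
  V_trLAC <- p$A_trLAC * (p$LAC_ext - LAC) /
    (p$LAC_ext + LAC + (1 + (PYR + p$PYR_ext) / p$KI_trLAC) * p$Km_trLAC)

  c(V_HK, V_GPI, V_PFK, V_ALD, V_TPI, V_GAPDH, V_PGK, V_DPGM, V_DPGP,
    V_PGM, V_ENO, V_PK, V_LDH, V_NaKATP, V_ATPase, V_ADH, V_ALDH,
    V_trPYR, V_trLAC)
}

# named variant for user-facing callers
rate_vector <- function(state, params, eth) {
  v <- rate_core(state, params, eth)
  names(v) <- .rate_names
  v
}

#' Reaction and transport rates at a metabolic state
#'
#' Evaluates all nineteen rate laws (glycolysis, the 2,3-DPG shunt, lactate
#' dehydrogenase, the two ATPase sinks, the encapsulated ADH and ALDH, and
#' pyruvate/lactate transport) at a given state. Cofactors (ATP/ADP/AMP and
#' NADH) are derived from the energy charge and the conserved pools before
#' evaluation.
#'
#' @param state named state vector (see [reference_state()]); may include an
#'   `ETH` component in dynamic mode.
#' @param params an [ebr_parameters()] object.
#' @param eth ethanol concentration (mM) in clamped mode; defaults to
#'   `params$eth0`. Ignored when `state` carries `ETH`.
#' @return named numeric vector of the 19 rates (mM/h).
#' @examples
#' v <- reaction_rates(reference_state(), ebr_parameters())
#' v[c("V_HK", "V_GAPDH", "V_PGK")]
#' @export
reaction_rates <- function(state, params = ebr_parameters(), eth = NULL) {
  dynamic <- "ETH" %in% names(state)
  state <- check_state(state, params, dynamic = dynamic)
  if (dynamic) eth <- state[["ETH"]]
  if (is.null(eth)) eth <- params$eth0
  if (eth < 0) stop("ethanol concentration must be non-negative")
  v <- rate_vector(state[.state_names], params, eth)
  if (any(!is.finite(v)))
    stop("non-finite rate(s): ",
         paste(names(v)[!is.finite(v)], collapse = ", "))
  v
}
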