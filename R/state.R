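#' Reference metabolic state of the resting erythrocyte
#'
#' The steady-state concentrations of the unloaded cell (no ethanol, zero
#' ADH/ALDH activity) that serve as the default initial condition and
#' steady-state guess everywhere in the package. The energy charge is
#' computed from the resting ATP and ADP concentrations (1.471 and 0.235
#' mM); acetaldehyde starts at zero.
#'
#' @param eth optional ethanol concentration (mM); when supplied, an `ETH`
#'   component is appended, as used in dynamic-ethanol (suspension) mode.
#' @return a named numeric vector over the 15 dynamic variables (G6P, F6P,
#'   FDP, DAP, GAP, 1,3-DPG, 2,3-DPG, 3-PG, 2-PG, PEP, PYR, LAC, NAD, the
#'   energy charge PHI, ACALD), plus `ETH` if requested. Units mM (PHI
#'   dimensionless).
#' @export
reference_state <- function(eth = NULL) {
  s <- c(G6P = 0.073, F6P = 0.024, FDP = 0.0084, DAP = 0.034, GAP = 0.015,
         DPG13 = 5.7e-4, DPG23 = 3.5, PG3 = 0.034, PG2 = 0.008, PEP = 0.01,
         PYR = 0.07, LAC = 1.43, NAD = 0.048,
         PHI = (2 * 1.471 + 0.235) / (2 * 1.744), ACALD = 0)
  if (!is.null(eth)) s <- c(s, ETH = unname(eth))
  s
}

# Validate a state vector (names, non-negativity, pool bounds).
check_state <- function(state, params, dynamic = FALSE) {
  want <- if (dynamic) c(.state_names, "ETH") else .state_names
  if (is.null(names(state)) || !all(want %in% names(state)))
    stop("state must be a named vector with components: ",
         paste(want, collapse = ", "))
  state <- state[want]
  if (any(!is.finite(state))) stop("state contains non-finite values")
  if (any(state < -1e-12)) {
    bad <- names(state)[state < -1e-12]
    stop("negative concentration(s) in state: ", paste(bad, collapse = ", "))
  }
  if (state[["NAD"]] > params$N + 1e-9)
    stop("NAD exceeds the total pool N")
  if (state[["PHI"]] > 1 + 1e-9) stop("energy charge PHI exceeds 1")
  pmax(state, 0)
}

#' Derived cofactor concentrations of a state
#'
#' Computes NADH, ATP, ADP and AMP from the dynamic variables via the two
#' pool constraints and the adenylate-kinase equilibrium.
#'
#' @param state named state vector (see [reference_state()]).
#' @param params an [ebr_parameters()] object.
#' @return named numeric vector with `NADH`, `ATP`, `ADP`, `AMP` (mM).
#' @export
derived_cofactors <- function(state, params = ebr_parameters()) {
  ad <- adenylate_split(state[["PHI"]], params$P, params$K_AK)
  c(NADH = params$N - state[["NAD"]], ad)
}
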