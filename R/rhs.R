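# Right-hand side of the model. The first 15 equations are the clamped-
# ethanol system (ethanol enters as a parameter); in dynamic mode a 16th
# equation d[ETH]/dt = -hematocrit * V_ADH tracks the suspension ethanol
# (ethanol equilibrates across the membrane, rates are per liter of cells).

rhs_core <- function(state, params, eth) {
  v <- rate_core(state, params, eth)
  d <- c(
    v[[1L]] - v[[2L]],                         # G6P : HK - GPI
    v[[2L]] - v[[3L]],                         # F6P : GPI - PFK
    v[[3L]] - v[[4L]],                         # FDP : PFK - ALD
    v[[4L]] - v[[5L]],                         # DAP : ALD - TPI
    v[[4L]] + v[[5L]] - v[[6L]],               # GAP : ALD + TPI - GAPDH
    v[[6L]] - v[[8L]] - v[[7L]],               # 1,3-DPG : GAPDH - DPGM - PGK
    v[[8L]] - v[[9L]],                         # 2,3-DPG : DPGM - DPGP
    v[[7L]] + v[[9L]] - v[[10L]],              # 3-PG : PGK + DPGP - PGM
    v[[10L]] - v[[11L]],                       # 2-PG : PGM - ENO
    v[[11L]] - v[[12L]],                       # PEP : ENO - PK
    v[[12L]] - v[[13L]] + v[[18L]],            # PYR : PK - LDH + transport
    v[[13L]] + v[[19L]],                       # LAC : LDH + transport
    v[[13L]] - v[[6L]] - v[[16L]] - v[[17L]],  # NAD : LDH - GAPDH - ADH - ALDH
    (v[[7L]] + v[[12L]] - v[[1L]] - v[[3L]] -
       v[[15L]] - v[[14L]]) / (2 * params$P),  # PHI : ATP balance / (2P)
    v[[16L]] - v[[17L]]                        # ACALD : ADH - ALDH
  )
  list(deriv = d, rates = v)
}

#' Time derivatives of the model state
#'
#' Assembles the full right-hand side: mass balances for the glycolytic
#' intermediates, pyruvate/lactate (with membrane transport), NAD (the
#' competition between GAPDH and the load enzymes), the energy charge
#' (carrying the 1/(2P) factor), and acetaldehyde (retained inside the
#' cells). In dynamic-ethanol mode the suspension ethanol declines as
#' `-hematocrit * V_ADH`; in clamped mode ethanol is a constant parameter.
#'
#' @inheritParams reaction_rates
#' @return named numeric vector of derivatives (mM/h; 1/h for `PHI`),
#'   with a `"rates"` attribute carrying the rate vector.
#' @export
model_rhs <- function(state, params = ebr_parameters(), eth = NULL) {
  dynamic <- "ETH" %in% names(state)
  state <- check_state(state, params, dynamic = dynamic)
  if (dynamic) eth <- state[["ETH"]]
  if (is.null(eth)) eth <- params$eth0
  out <- rhs_core(state[.state_names], params, eth)
  names(out$rates) <- .rate_names
  if (any(!is.finite(out$rates)))
    stop("non-finite rate(s): ",
         paste(names(out$rates)[!is.finite(out$rates)], collapse = ", "))
  d <- out$deriv
  names(d) <- .state_names
  if (dynamic) {
    d <- c(d, ETH = -params$hematocrit * out$rates[["V_ADH"]])
  }
  attr(d, "rates") <- out$rates
  d
}

# deSolve-facing wrapper: guards trial states (the implicit solver probes
# slightly negative or out-of-range values) by clamping before evaluating
# the rate laws. `dynamic` toggles the 16th (ethanol) equation.
desolve_func <- function(params, dynamic = FALSE) {
  N <- params$N
  h <- params$hematocrit
  if (dynamic) {
    function(t, y, parms) {
      s <- pmax(y[1:15], 0)
      s[13] <- min(s[13], N)
      s[14] <- min(s[14], 1)
      eth <- max(y[16], 0)
      out <- rhs_core(s, params, eth)
      list(c(out$deriv, -h * out$rates[[16L]]))
    }
  } else {
    function(t, y, parms) {
      s <- pmax(y, 0)
      s[13] <- min(s[13], N)
      s[14] <- min(s[14], 1)
      list(rhs_core(s, params, parms)$deriv)
    }
  }
}
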