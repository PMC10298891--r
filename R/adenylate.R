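# scalar hot-path version without validation or dimnames
adenylate_core <- function(phi, P, K_AK) {
  if (phi < 0) phi <- 0 else if (phi > 1) phi <- 1
  a <- K_AK - 0.25
  b <- P / 2
  cc <- -phi * (1 - phi) * P * P
  d <- if (abs(a) < 1e-14) -cc / b else
    (-b + sqrt(b * b - 4 * a * cc)) / (2 * a)
  if (d < 0) d <- 0
  ATP <- phi * P - d / 2
  AMP <- P - ATP - d
  c(max(ATP, 0), d, max(AMP, 0))
}

#' Split the adenylate pool at adenylate-kinase equilibrium
#'
#' Given the energy charge `phi`, the total adenylate pool `P` and the
#' adenylate-kinase equilibrium constant `K_AK`, returns the unique
#' non-negative triple (ATP, ADP, AMP) satisfying
#' \deqn{2\,ATP + ADP = 2\phi P,\quad ATP+ADP+AMP = P,\quad
#'       ATP\cdot AMP = K_{AK}\, ADP^2.}
#' The three constraints reduce to a single quadratic in ADP,
#' \eqn{(K_{AK}-\tfrac14)\,d^2 + \tfrac{P}{2} d - \phi(1-\phi)P^2 = 0},
#' whose non-negative root is taken; ATP and AMP follow linearly. For
#' \eqn{\phi \in [0,1]} this root always yields three non-negative
#' concentrations.
#'
#' @param phi energy charge, in `[0, 1]` (vectorized).
#' @param P total adenylate pool (mM), `> 0`.
#' @param K_AK adenylate-kinase equilibrium constant (dimensionless), `> 0`.
#' @return a numeric vector `c(ATP, ADP, AMP)` in mM, or a 3-column matrix
#'   when `phi` has length greater than one.
#' @examples
#' adenylate_split(0.911, P = 1.744) # close to the resting red-cell split
#' @export
adenylate_split <- function(phi, P = 1.744, K_AK = 1) {
  if (any(!is.finite(phi)) || any(phi < -1e-12) || any(phi > 1 + 1e-12))
    stop("phi must lie in [0, 1]")
  if (P <= 0 || K_AK <= 0) stop("P and K_AK must be positive")
  phi <- pmin(pmax(phi, 0), 1)
  a <- K_AK - 0.25
  b <- P / 2
  cc <- -phi * (1 - phi) * P^2
  d <- if (abs(a) < 1e-14) -cc / b else
    (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
  ATP <- phi * P - d / 2
  AMP <- P - ATP - d
  # guard against roundoff at the charged/discharged limits
  d <- pmax(d, 0); ATP <- pmax(ATP, 0); AMP <- pmax(AMP, 0)
  out <- cbind(ATP = ATP, ADP = d, AMP = AMP)
  if (length(phi) == 1L) out[1L, ] else out
}

#' Energy charge of an adenylate split
#'
#' \eqn{\Phi = (2\,ATP + ADP) / (2\,(ATP+ADP+AMP))}.
#'
#' @param ATP,ADP,AMP concentrations in mM.
#' @return the dimensionless energy charge.
#' @export
energy_charge <- function(ATP, ADP, AMP) {
  (2 * ATP + ADP) / (2 * (ATP + ADP + AMP))
}
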