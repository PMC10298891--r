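# Steady-state solving and linear stability.

# Central finite-difference Jacobian of the clamped-ethanol right-hand side
# (relative step 1e-6 with absolute floor 1e-9 mM).
model_jacobian <- function(state, params, eth) {
  n <- length(.state_names)
  s <- unname(state[.state_names])
  J <- matrix(0, n, n)
  for (i in seq_len(n)) {
    h <- max(1e-6 * abs(s[i]), 1e-9)
    sp <- s; sp[i] <- sp[i] + h
    sm <- s; sm[i] <- sm[i] - h
    J[, i] <- (rhs_core(sp, params, eth)$deriv -
                 rhs_core(sm, params, eth)$deriv) / (2 * h)
  }
  dimnames(J) <- list(.state_names, .state_names)
  J
}

# Run the RNG-dependent part under a caller-controlled seed without
# disturbing the global stream.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

clamp_state <- function(s, params) {
  s <- pmax(s, 0)
  s[13L] <- min(s[13L], params$N)
  s[14L] <- min(s[14L], 1)
  s
}

# Damped Newton with central-difference Jacobian. Stays local to the guess,
# which is what branch continuation needs (a least-squares solver can slide
# off the glycolytic branch onto the collapsed zero-flux root).
newton_root <- function(params, eth, guess, tol = 1e-10, maxit = 60L) {
  s <- clamp_state(unname(guess[.state_names]), params)
  f <- rhs_core(s, params, eth)$deriv
  fn <- sqrt(sum(f * f))
  for (it in seq_len(maxit)) {
    if (!is.finite(fn)) return(NULL)
    if (fn < tol) break
    names(s) <- .state_names
    J <- model_jacobian(s, params, eth)
    dx <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(dx) || any(!is.finite(dx))) return(NULL)
    lam <- 1
    repeat {
      s2 <- clamp_state(unname(s) + lam * dx, params)
      f2 <- rhs_core(s2, params, eth)$deriv
      fn2 <- sqrt(sum(f2 * f2))
      if (is.finite(fn2) && fn2 < fn) break
      lam <- lam / 2
      if (lam < 1e-6) return(NULL)
    }
    s <- s2; f <- f2; fn <- fn2
  }
  if (fn >= max(tol, 1e-8)) return(NULL)
  names(s) <- .state_names
  list(state = s, residual = fn)
}

# Levenberg-Marquardt fallback in scaled variables (trust-region class).
lm_root <- function(params, eth, guess, maxit = 200L) {
  g <- clamp_state(unname(guess[.state_names]), params)
  scale <- pmax(abs(g), 1e-3)
  n <- params$N
  lower <- rep(0, 15) / scale
  upper <- c(rep(Inf, 12), n, 1, Inf) / scale
  res <- tryCatch(
    minpack.lm::nls.lm(
      par = g / scale, lower = lower, upper = upper,
      fn = function(z) rhs_core(z * scale, params, eth)$deriv,
      control = minpack.lm::nls.lm.control(
        maxiter = maxit, ftol = 1e-15, ptol = 1e-15, gtol = 0)),
    error = function(e) NULL)
  if (is.null(res)) return(NULL)
  s <- res$par * scale
  resid <- sqrt(sum(rhs_core(s, params, eth)$deriv^2))
  names(s) <- .state_names
  list(state = s, residual = resid)
}

solve_root <- function(params, eth, guess, maxit = 200L) {
  r <- newton_root(params, eth, guess)
  if (!is.null(r)) return(r)
  lm_root(params, eth, guess, maxit = maxit)
}

# The physiological (non-zero glycolysis) branch carries hexokinase flux of
# order 1 mM/h; the collapsed root has essentially zero flux.
on_glycolytic_branch <- function(root, params, eth, min_flux = 0.01) {
  rate_core(unname(root$state[.state_names]), params, eth)[[1L]] >= min_flux
}

#' Find a steady state of the clamped-ethanol model
#'
#' Solves `model_rhs = 0` with a Levenberg-Marquardt (trust-region class)
#' root finder, starting from `guess` and falling back to the reference
#' state plus seeded log-uniform random multi-starts. Stability is assessed
#' from the eigenvalues of a central-finite-difference Jacobian; the state
#' is declared stable when every real part is below `-1e-9` 1/h. When both
#' load activities are zero the acetaldehyde equation is identically zero
#' (structurally decoupled) and that dimension is excluded from the
#' eigenvalue analysis.
#'
#' @param params an [ebr_parameters()] object (clamped-ethanol mode).
#' @param eth clamped ethanol concentration (mM); default `params$eth0`.
#' @param guess starting state; default [reference_state()].
#' @param tol residual norm (mM/h) below which a root is accepted
#'   (default 1e-8).
#' @param n_multistart number of additional random starts tried before
#'   declaring failure (default 10).
#' @param seed seed for the random multi-starts (default 0).
#' @param branch `"glycolytic"` (default) accepts only roots on the
#'   physiological branch (hexokinase flux at least `min_flux`); `"any"`
#'   also accepts the collapsed zero-flux root that coexists at high load.
#' @param min_flux hexokinase-flux floor (mM/h) defining the glycolytic
#'   branch.
#' @return an object of class `ebr_steady_state`: list with `state` (named
#'   vector incl. derived cofactors as attribute), `rates`, `eigenvalues`
#'   (complex), `stable` (logical), `residual`, `converged`. When no root is
#'   found, `converged` is `FALSE` and the other fields are `NULL` - this is
#'   evidence of steady-state non-existence, not an error.
#' @examples
#' \donttest{
#' ss <- find_steady_state(ebr_parameters())
#' ss$rates[c("V_HK", "V_GAPDH", "V_PGK")]
#' }
#' @export
find_steady_state <- function(params = ebr_parameters(), eth = NULL,
                              guess = reference_state(), tol = 1e-8,
                              n_multistart = 10L, seed = 0L,
                              branch = c("glycolytic", "any"),
                              min_flux = 0.01) {
  branch <- match.arg(branch)
  if (is.null(eth)) eth <- params$eth0
  ok <- function(r) !is.null(r) && r$residual < tol &&
    (branch == "any" || on_glycolytic_branch(r, params, eth, min_flux))
  starts <- list(guess, reference_state())
  best <- NULL
  for (g in starts) {
    r <- solve_root(params, eth, g)
    if (ok(r)) { best <- r; break }
    best <- NULL
  }
  if (is.null(best)) {
    ref <- reference_state()
    rand <- with_local_seed(seed, lapply(seq_len(n_multistart), function(i) {
      f <- exp(stats::runif(length(.state_names), log(0.2), log(5)))
      g <- ref * f
      g[["PHI"]] <- stats::runif(1, 0.2, 0.99)
      g[["NAD"]] <- stats::runif(1, 0.1, 0.9) * params$N
      g[["ACALD"]] <- stats::runif(1, 0, 5e-3)
      g
    }))
    for (g in rand) {
      r <- solve_root(params, eth, g)
      if (ok(r)) { best <- r; break }
    }
  }
  if (is.null(best)) {
    return(structure(list(converged = FALSE, state = NULL, rates = NULL,
                          eigenvalues = NULL, stable = NA,
                          residual = NA_real_,
                          eth = eth, params = params),
                     class = "ebr_steady_state"))
  }
  s <- best$state
  J <- model_jacobian(s, params, eth)
  degenerate <- params$alpha_ADH == 0 && params$alpha_ALDH == 0
  if (degenerate) {
    keep <- setdiff(.state_names, "ACALD")
    J <- J[keep, keep]
  }
  ev <- eigen(J, only.values = TRUE)$values
  structure(list(converged = TRUE, state = s,
                 rates = rate_vector(s, params, eth),
                 cofactors = derived_cofactors(s, params),
                 eigenvalues = ev,
                 stable = all(Re(ev) < -1e-9),
                 residual = best$residual, eth = eth, params = params),
            class = "ebr_steady_state")
}

#' @export
print.ebr_steady_state <- function(x, ...) {
  if (!x$converged) {
    cat("ebr_steady_state: no root found (residual ",
        format(x$residual, digits = 3), " mM/h) - evidence of steady-state",
        " non-existence\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf(
    "ebr_steady_state (%s): residual %.2e mM/h, max Re(eig) %.3g 1/h\n",
    if (isTRUE(x$stable)) "stable" else "unstable",
    x$residual, max(Re(x$eigenvalues))))
  cat(sprintf("  V_ADH = %.4g mM/h, NAD = %.4g mM, FDP = %.4g mM\n",
              x$rates[["V_ADH"]], x$state[["NAD"]], x$state[["FDP"]]))
  invisible(x)
}

#' Steady-state ethanol consumption rate
#'
#' Convenience wrapper: the ADH rate at the steady state for equal ADH and
#' ALDH activities `alpha` and clamped ethanol `eth`. The steady-state rate
#' characterizes ethanol consumption even in the oscillatory regime, where
#' the rate oscillations remain small.
#'
#' @param params base parameters.
#' @param alpha common ADH = ALDH activity (mM/h).
#' @param eth clamped ethanol (mM).
#' @param guess starting state for the root search.
#' @return the ADH rate (mM/h) at the root; `NA` if no steady state exists.
#' @export
consumption_rate_at_steady_state <- function(params = ebr_parameters(),
                                             alpha, eth,
                                             guess = reference_state()) {
  p <- params; p$alpha_ADH <- alpha; p$alpha_ALDH <- alpha
  ss <- find_steady_state(p, eth = eth, guess = guess)
  if (!ss$converged) return(NA_real_)
  unname(ss$rates[["V_ADH"]])
}
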