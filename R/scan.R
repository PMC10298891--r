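# One-parameter regime scans: continuation of the steady-state branch,
# linear-stability classification, trajectory-based regime classification,
# and bisection refinement of the three regime boundaries (loss of
# stability, oscillation -> accumulation, loss of steady-state existence).

set_scan_params <- function(params, var, value, fixed) {
  if (var == "activity") {
    params$alpha_ADH <- value; params$alpha_ALDH <- value
    list(params = params, eth = fixed)
  } else {
    params$alpha_ADH <- fixed; params$alpha_ALDH <- fixed
    list(params = params, eth = value)
  }
}

max_re_eig <- function(state, params, eth) {
  J <- model_jacobian(state, params, eth)
  if (params$alpha_ADH == 0 && params$alpha_ALDH == 0) {
    keep <- setdiff(.state_names, "ACALD")
    J <- J[keep, keep]
  }
  max(Re(eigen(J, only.values = TRUE)$values))
}

# Root at one scan point from a continuation guess; NULL on failure.
point_root <- function(params, var, value, fixed, guess, tol = 1e-8,
                       fallback = TRUE) {
  sp <- set_scan_params(params, var, value, fixed)
  ok <- function(r) !is.null(r) && r$residual < tol &&
    on_glycolytic_branch(r, sp$params, sp$eth)
  r <- solve_root(sp$params, sp$eth, guess)
  if (!ok(r)) {
    if (!fallback) return(NULL)
    r <- solve_root(sp$params, sp$eth, reference_state())
    if (!ok(r)) return(NULL)
  }
  r$max_re <- max_re_eig(r$state, sp$params, sp$eth)
  r$rates <- rate_vector(r$state, sp$params, sp$eth)
  r
}

# Continue the branch from a known root at v_from to v_to with adaptive
# sub-steps (coarse scan grids can outrun the Newton tracker's basin).
point_bridge <- function(params, var, v_from, g_from, v_to, fixed) {
  if (v_to <= v_from) return(NULL)
  min_step <- (v_to - v_from) / 64
  g <- g_from; v <- v_from; step <- v_to - v_from
  r <- NULL
  while (v < v_to) {
    cand <- min(v + step, v_to)
    ri <- point_root(params, var, cand, fixed, g, fallback = FALSE)
    if (!is.null(ri)) {
      g <- ri$state; v <- cand; r <- ri
    } else {
      step <- step / 2
      if (step < min_step) return(NULL)
    }
  }
  r
}

bisect_sign <- function(f, lo, hi, tol) {
  # f returns TRUE when past the boundary
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (isTRUE(f(mid))) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Track the steady branch towards its fold (saddle-node) by adaptive step
# halving with a secant predictor for the next guess. Returns the last
# parameter value at which the branch root exists, to within `tol`.
track_fold <- function(params, var, fixed, p0, g0, step0, tol, p_max) {
  p <- p0; g <- g0; p_prev <- NA_real_; g_prev <- NULL
  step <- step0
  while (step >= tol && p < p_max) {
    cand <- min(p + step, p_max)
    guess <- if (!is.null(g_prev) && p > p_prev) {
      pmax(g + (g - g_prev) * (cand - p) / (p - p_prev), 0)
    } else g
    r <- point_root(params, var, cand, fixed, guess, fallback = FALSE)
    if (is.null(r))
      r <- point_root(params, var, cand, fixed, g, fallback = FALSE)
    if (!is.null(r)) {
      p_prev <- p; g_prev <- g
      p <- cand; g <- r$state
    } else {
      step <- step / 2
    }
  }
  if (p >= p_max) return(list(fold = NA_real_, state = g, at = p))
  list(fold = p + step, state = g, at = p)
}

scan_core <- function(params, var, grid, fixed, refine = TRUE,
                      boundary_tol = 0.1, classify = FALSE,
                      classify_tol = 0.1, seed = 0L, ...) {
  grid <- sort(grid)
  guess <- reference_state()
  rows <- vector("list", length(grid))
  states <- matrix(NA_real_, length(grid), length(.state_names),
                   dimnames = list(NULL, .state_names))
  rates <- matrix(NA_real_, length(grid), length(.rate_names),
                  dimnames = list(NULL, .rate_names))
  exists <- logical(length(grid)); max_re <- rep(NA_real_, length(grid))
  last_ok <- NULL; last_val <- NA_real_
  for (i in seq_along(grid)) {
    r <- point_root(params, var, grid[i], fixed, guess)
    if (is.null(r) && !is.null(last_ok))
      r <- point_bridge(params, var, last_val, last_ok$state, grid[i],
                        fixed)
    if (is.null(r) && (i == 1L || exists[i - 1L])) {
      # first failure after an existing root: confirm non-existence with
      # the full multi-start policy before declaring the branch lost
      sp <- set_scan_params(params, var, grid[i], fixed)
      ss <- find_steady_state(sp$params, eth = sp$eth,
                              guess = if (is.null(last_ok))
                                reference_state() else last_ok$state,
                              seed = seed)
      if (ss$converged) {
        r <- list(state = ss$state, residual = ss$residual,
                  max_re = max(Re(ss$eigenvalues)),
                  rates = rate_vector(ss$state, sp$params, sp$eth))
      }
    }
    if (is.null(r)) { exists[i] <- FALSE; next }
    exists[i] <- TRUE
    states[i, ] <- r$state
    rates[i, ] <- r$rates
    max_re[i] <- r$max_re
    guess <- r$state
    last_ok <- r; last_val <- grid[i]
  }
  boundaries <- list(stability = NA_real_, oscillation = NA_real_,
                     existence = NA_real_)
  fold_state <- NULL; fold_rates <- NULL
  if (refine) {
    # loss of stability (sign change of the leading eigenvalue real part)
    unst <- which(exists & max_re > 1e-9)
    stab <- which(exists & max_re <= 1e-9)
    if (length(unst) && length(stab) && min(stab) < min(unst)) {
      i1 <- max(stab[stab < min(unst)]); i2 <- min(unst)
      g <- states[i1, ]; gv <- grid[i1]
      boundaries$stability <- bisect_sign(function(v) {
        r <- point_root(params, var, v, fixed, g, fallback = FALSE)
        if (is.null(r) && v > gv)
          r <- point_bridge(params, var, gv, g, v, fixed)
        if (is.null(r)) return(TRUE)
        if (v > gv) { g <<- r$state; gv <<- v }
        r$max_re > 1e-9
      }, grid[i1], grid[i2], boundary_tol)
    }
    # loss of existence (fold): adaptive branch tracking past the last
    # grid point at which the root was found
    if (any(!exists) && any(exists) && max(which(exists)) < length(grid)) {
      i1 <- max(which(exists))
      tf <- track_fold(params, var, fixed, grid[i1], states[i1, ],
                       step0 = grid[i1 + 1L] - grid[i1],
                       tol = boundary_tol, p_max = grid[length(grid)])
      boundaries$existence <- tf$fold
      if (!is.na(tf$fold)) {
        fold_state <- tf$state
        sp <- set_scan_params(params, var, tf$at, fixed)
        fold_rates <- rate_vector(tf$state, sp$params, sp$eth)
      }
    }
    if (classify && !is.na(boundaries$stability)) {
      hi0 <- if (!is.na(boundaries$existence)) boundaries$existence else
        max(grid[exists], grid[length(grid)])
      boundaries$oscillation <- locate_oscillation_boundary(
        params, var, fixed, boundaries$stability, hi0,
        tol = classify_tol, ...)
    }
  }
  regime <- ifelse(!exists, "NO_STEADY_STATE",
                   ifelse(max_re <= 1e-9, "STABLE", "UNSTABLE"))
  if (classify) {
    b_osc <- boundaries$oscillation
    regime[exists & max_re > 1e-9] <-
      if (is.na(b_osc)) "OSCILLATORY" else "UNSTABLE"
    if (!is.na(b_osc)) {
      u <- exists & max_re > 1e-9
      regime[u & grid <= b_osc] <- "OSCILLATORY"
      regime[u & grid > b_osc] <- "ACCUMULATION"
    }
    regime[!exists] <- "NO_STEADY_STATE"
  }
  structure(list(parameter = var, fixed = fixed, grid = grid,
                 exists = exists, max_re = max_re, regime = regime,
                 states = states, rates = rates, boundaries = boundaries,
                 fold_state = fold_state, fold_rates = fold_rates,
                 params = params),
            class = "ebr_scan")
}

#' Scan the common ADH/ALDH activity at clamped ethanol
#'
#' Continues the steady-state branch over a grid of the common load-enzyme
#' activity (ADH activity equal to ALDH activity) at a fixed clamped
#' ethanol concentration, records the steady state, rates and leading
#' Jacobian eigenvalue at every point, and (optionally) refines the regime
#' boundaries by bisection: loss of stability (onset of oscillations),
#' oscillation to accumulation (trajectory-classified), and loss of
#' steady-state existence (fold). Non-existence at a grid point is declared
#' only after the full multi-start policy of [find_steady_state()] fails.
#'
#' @param params base parameters.
#' @param alpha increasing activity grid (mM/h).
#' @param eth clamped ethanol concentration (mM), default 10.
#' @param refine refine stability/existence boundaries by bisection
#'   (default TRUE).
#' @param boundary_tol bisection tolerance (mM/h), default 0.1.
#' @param classify also locate the oscillation/accumulation boundary by
#'   classifying trajectories (expensive; default FALSE).
#' @param classify_tol bisection tolerance for the classified boundary.
#' @param seed seed for the multi-start non-existence confirmation.
#' @param ... passed to [classify_regime()] (e.g. `t_end`).
#' @return an `ebr_scan` object: grids, per-point regime labels, steady
#'   states and rates, leading eigenvalues, located `boundaries`, and (when
#'   the fold is located) `fold_state`/`fold_rates`, the last steady state
#'   and rates on the branch.
#' @export
scan_activity <- function(params = ebr_parameters(),
                          alpha = seq(0, 180, by = 4), eth = 10,
                          refine = TRUE, boundary_tol = 0.1,
                          classify = FALSE, classify_tol = 0.1,
                          seed = 0L, ...) {
  scan_core(params, "activity", alpha, eth, refine = refine,
            boundary_tol = boundary_tol, classify = classify,
            classify_tol = classify_tol, seed = seed, ...)
}

#' Scan the clamped ethanol concentration at fixed activity
#'
#' As [scan_activity()], but ethanol is varied at a fixed common ADH = ALDH
#' activity.
#'
#' @param params base parameters.
#' @param eth increasing ethanol grid (mM).
#' @param alpha fixed common activity (mM/h), default 40.
#' @inheritParams scan_activity
#' @return an `ebr_scan` object.
#' @export
scan_ethanol <- function(params = ebr_parameters(),
                         eth = seq(0, 70, by = 2), alpha = 40,
                         refine = TRUE, boundary_tol = 0.1,
                         classify = FALSE, classify_tol = 0.1,
                         seed = 0L, ...) {
  scan_core(params, "ethanol", eth, alpha, refine = refine,
            boundary_tol = boundary_tol, classify = classify,
            classify_tol = classify_tol, seed = seed, ...)
}

#' @export
print.ebr_scan <- function(x, ...) {
  cat(sprintf("ebr_scan over %s (%d points, fixed %s = %g)\n",
              x$parameter, length(x$grid),
              if (x$parameter == "activity") "ethanol" else "activity",
              x$fixed))
  tab <- table(x$regime)
  cat("  regimes:", paste(names(tab), tab, sep = ":", collapse = ", "), "\n")
  b <- x$boundaries
  cat(sprintf(
    "  boundaries: stability %s, oscillation %s, existence %s\n",
    format(b$stability, digits = 6), format(b$oscillation, digits = 6),
    format(b$existence, digits = 6)))
  invisible(x)
}

#' Steady state on the glycolytic branch by activity continuation
#'
#' Walks the common ADH = ALDH activity from zero (where the branch root is
#' the reference state) up to `alpha` in steps, reusing each root as the
#' next guess, and returns the full steady-state analysis at the end point.
#' This reaches branch roots that a cold start cannot (far from the resting
#' state, or coexisting with the collapsed zero-flux root).
#'
#' @param params base parameters.
#' @param alpha target common activity (mM/h).
#' @param eth clamped ethanol concentration (mM).
#' @param step continuation step (mM/h), default 10.
#' @return an `ebr_steady_state` (see [find_steady_state()]).
#' @export
steady_on_branch <- function(params = ebr_parameters(), alpha, eth,
                             step = 10) {
  g <- reference_state()
  a_cur <- 0; st <- step
  repeat {
    if (a_cur >= alpha || st < 1e-3) break
    cand <- min(a_cur + st, alpha)
    r <- point_root(params, "activity", cand, eth, g, fallback = FALSE)
    if (is.null(r)) {
      st <- st / 2
    } else {
      g <- r$state; a_cur <- cand; st <- min(st * 1.5, step)
    }
  }
  p <- params; p$alpha_ADH <- alpha; p$alpha_ALDH <- alpha
  find_steady_state(p, eth = eth, guess = g)
}

#' Classify the long-term regime at one parameter point
#'
#' STABLE if a steady state exists (located by activity continuation along
#' the glycolytic branch) with all eigenvalue real parts negative. Otherwise
#' the model is integrated from the reference (resting) start and the FDP
#' trajectory is classified: ACCUMULATION when the FDP floor rises above
#' `fdp_threshold` and keeps rising to the end of the run (unbounded growth
#' of the FDP/DAP/GAP cluster); OSCILLATORY when the trajectory keeps
#' returning below the threshold (bounded cycles - near the upper end of
#' the window these are relaxation oscillations whose period reaches tens
#' of hours, so boundedness is judged by returns rather than by peak
#' counting). A trajectory above the threshold whose trend is falling again
#' by the end of the run is labeled UNRESOLVED. When no steady state is
#' found at all, `no_steady_state` is set in addition to the trajectory
#' label.
#'
#' @param params base parameters.
#' @param alpha common ADH = ALDH activity (mM/h).
#' @param eth clamped ethanol concentration (mM).
#' @param t_end classification horizon (h), default 600.
#' @param transient initial stretch discarded before judging (h).
#' @param fdp_threshold accumulation threshold on FDP (mM), default 50.
#' @param rtol,atol solver tolerances.
#' @return a list with `regime` (character), `no_steady_state` (logical),
#'   `steady` (the `ebr_steady_state`), and, when integrated, `timecourse`.
#' @export
classify_regime <- function(params = ebr_parameters(), alpha, eth,
                            t_end = 600, transient = 100,
                            fdp_threshold = 50, rtol = 1e-8, atol = 1e-10) {
  ss <- steady_on_branch(params, alpha = alpha, eth = eth)
  if (ss$converged && isTRUE(ss$stable))
    return(list(regime = "STABLE", no_steady_state = FALSE, steady = ss))
  p <- params; p$alpha_ADH <- alpha; p$alpha_ALDH <- alpha
  tc <- integrate_model(reference_state(), p, t_end = t_end, eth = eth,
                        n_out = 3000, rtol = rtol, atol = atol)
  fdp <- tc$state[, "FDP"]; tt <- tc$time
  post <- fdp[tt >= transient]
  tail_half <- fdp[tt >= 0.5 * t_end]
  q3 <- fdp[tt >= 0.5 * t_end & tt < 0.75 * t_end]
  q4 <- fdp[tt >= 0.75 * t_end]
  regime <- if (min(tail_half) > fdp_threshold) {
    if (mean(q4) >= mean(q3)) "ACCUMULATION" else "UNRESOLVED"
  } else if (max(post) - min(post) > 1e-3) {
    "OSCILLATORY"
  } else {
    "STABLE"
  }
  list(regime = regime, no_steady_state = !ss$converged, steady = ss,
       timecourse = tc)
}

# indices of strict interior local maxima
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

locate_oscillation_boundary <- function(params, var, fixed, lo, hi,
                                        tol = 0.1, ...) {
  cls <- function(v) {
    sp <- set_scan_params(params, var, v, fixed)
    a <- sp$params$alpha_ADH
    classify_regime(params, alpha = if (var == "activity") v else fixed,
                    eth = if (var == "activity") fixed else v, ...)$regime
  }
  chi <- cls(hi - tol / 2)
  if (chi != "ACCUMULATION") return(NA_real_)
  clo <- cls(lo + tol / 2)
  if (clo != "OSCILLATORY") return(NA_real_)
  bisect_sign(function(v) cls(v) == "ACCUMULATION", lo + tol / 2,
              hi - tol / 2, tol)
}
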