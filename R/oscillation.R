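# Limit-cycle quantification: amplitude, period, fast/slow transition and
# phase relations.

# Extract a named signal (state column, derived cofactor, or rate) from a
# time course.
tc_signal <- function(tc, name) {
  if (name %in% colnames(tc$state)) return(tc$state[, name])
  if (name %in% colnames(tc$rates)) return(tc$rates[, name])
  stop("unknown signal: ", name)
}

# Peak times by local maxima with quadratic (three-point) interpolation.
peak_times <- function(tt, x) {
  idx <- local_maxima(x)
  if (!length(idx)) return(numeric(0))
  vapply(idx, function(i) {
    t3 <- tt[(i - 1):(i + 1)]; x3 <- x[(i - 1):(i + 1)]
    h1 <- t3[2] - t3[1]; h2 <- t3[3] - t3[2]
    d1 <- (x3[2] - x3[1]) / h1; d2 <- (x3[3] - x3[2]) / h2
    a <- (d2 - d1) / (h1 + h2)
    if (a >= 0) return(t3[2])
    t3[2] + (h2 * d1 / (d1 - d2) - h1 * (1 - d1 / (d1 - d2))) / 2
  }, numeric(1))
}

#' Amplitude and period of a limit-cycle signal
#'
#' Peak-based oscillation metrics: the period is the mean spacing of
#' successive signal maxima after the transient (peak times refined by
#' quadratic interpolation), the amplitude is max minus min over the last
#' three full cycles. Peak-based rather than spectral estimation is used
#' because the cycles become strongly non-sinusoidal (relaxation-like) near
#' the slow-oscillation regime. A signal with fewer than two post-transient
#' peaks, or with negligible range, is flagged non-oscillatory rather than
#' raising an error; a limit cycle is `accepted` when at least five peaks
#' are present and the successive-period dispersion is below 1%.
#'
#' @param tc an `ebr_timecourse`.
#' @param signal name of a state variable, derived cofactor or rate (e.g.
#'   `"FDP"`, `"ATP"`, `"V_PFK"`).
#' @param transient initial stretch to discard (h), default 100.
#' @param min_range signal range below which the input is declared
#'   non-oscillatory (default 1e-6).
#' @return an object of class `ebr_oscillation`: amplitude, period (h),
#'   `n_peaks`, `period_cv` (successive-period coefficient of variation),
#'   `oscillatory`, `accepted`, and the peak times.
#' @export
oscillation_metrics <- function(tc, signal = "FDP", transient = 100,
                                min_range = 1e-6) {
  keep <- tc$time >= transient
  tt <- tc$time[keep]
  x <- tc_signal(tc, signal)[keep]
  out <- list(signal = signal, amplitude = max(x) - min(x),
              period = NA_real_, n_peaks = 0L, period_cv = NA_real_,
              oscillatory = FALSE, accepted = FALSE, peaks = numeric(0))
  if (length(x) < 3L || (max(x) - min(x)) < min_range) {
    out$amplitude <- if (length(x)) max(x) - min(x) else 0
    return(structure(out, class = "ebr_oscillation"))
  }
  pk <- peak_times(tt, x)
  out$n_peaks <- length(pk)
  out$peaks <- pk
  if (length(pk) < 2L) return(structure(out, class = "ebr_oscillation"))
  sp <- diff(pk)
  out$period <- mean(sp)
  out$period_cv <- if (length(sp) > 1L) stats::sd(sp) / mean(sp) else 0
  out$oscillatory <- TRUE
  # amplitude over the last three full cycles
  t0 <- max(min(tt), max(tt) - 3 * out$period)
  xi <- x[tt >= t0]
  out$amplitude <- max(xi) - min(xi)
  out$accepted <- out$n_peaks >= 5L && is.finite(out$period_cv) &&
    out$period_cv < 0.01
  structure(out, class = "ebr_oscillation")
}

#' @export
print.ebr_oscillation <- function(x, ...) {
  if (!x$oscillatory) {
    cat(sprintf("ebr_oscillation(%s): non-oscillatory (range %.3g)\n",
                x$signal, x$amplitude))
  } else {
    cat(sprintf(
      "ebr_oscillation(%s): amplitude %.4g, period %.4g h (%d peaks, cv %.2g%%)%s\n",
      x$signal, x$amplitude, x$period, x$n_peaks, 100 * x$period_cv,
      if (x$accepted) "" else " [not accepted as a settled limit cycle]"))
  }
  invisible(x)
}

#' Amplitude and period across the oscillatory window
#'
#' Runs the model at each activity in `alpha` (clamped ethanol), measures
#' the FDP (or chosen signal) oscillation amplitude and period, and locates
#' the sharp transition between fast low-amplitude and slow high-amplitude
#' oscillations as the largest adjacent-point jump in period.
#'
#' By default each run starts from a 0.1% perturbation of the (unstable)
#' steady state at that activity, which settles onto the local limit cycle;
#' a cold start from the resting state takes a single large excursion whose
#' recovery is far slower than the cycle itself and is only useful for
#' regime classification.
#'
#' @param params base parameters.
#' @param alpha activity grid inside the oscillatory window (mM/h).
#' @param eth clamped ethanol (mM), default 10.
#' @param signal signal to quantify (default `"FDP"`).
#' @param t_end,transient integration horizon and discarded transient (h).
#' @param start `"steady"` (perturbed branch root, default) or
#'   `"reference"` (resting-state start).
#' @param ... passed to [integrate_model()].
#' @return a data.frame with columns `alpha`, `amplitude`, `period`,
#'   `n_peaks`, `oscillatory`; the activity at the fast/slow transition is
#'   attached as attribute `"transition"`.
#' @export
amplitude_period_curve <- function(params = ebr_parameters(), alpha,
                                   eth = 10, signal = "FDP", t_end = 400,
                                   transient = 150,
                                   start = c("steady", "reference"), ...) {
  start <- match.arg(start)
  rows <- lapply(alpha, function(a) {
    p <- params; p$alpha_ADH <- a; p$alpha_ALDH <- a
    init <- reference_state()
    if (start == "steady") {
      ss <- steady_on_branch(params, alpha = a, eth = eth)
      if (ss$converged) init <- ss$state * 1.001
    }
    tc <- integrate_model(init, p, t_end = t_end, eth = eth,
                          n_out = 3000, ...)
    m <- oscillation_metrics(tc, signal = signal, transient = transient)
    data.frame(alpha = a, amplitude = m$amplitude, period = m$period,
               n_peaks = m$n_peaks, oscillatory = m$oscillatory)
  })
  out <- do.call(rbind, rows)
  per <- out$period
  trans <- NA_real_
  ok <- which(!is.na(per))
  if (length(ok) >= 2L) {
    dj <- abs(diff(per[ok]))
    j <- which.max(dj)
    trans <- mean(out$alpha[ok[c(j, j + 1L)]])
  }
  attr(out, "transition") <- trans
  out
}

#' Phase shifts between oscillating signals
#'
#' Lag of each signal pair estimated by circular cross-correlation of the
#' mean-removed signals over a whole number of cycles (the period is taken
#' from the first signal of each pair). Lags are reported modulo one period,
#' in (-T/2, T/2]; a positive lag means the second signal trails the first.
#'
#' @param tc an `ebr_timecourse` containing sustained oscillations.
#' @param pairs list of character 2-vectors, e.g.
#'   `list(c("ATP", "AMP"), c("NAD", "GAP"))`.
#' @param transient initial stretch to discard (h).
#' @return a data.frame with `signal_a`, `signal_b`, `lag` (h), `period`
#'   (h) and `lag_frac` (lag as a fraction of the period).
#' @export
phase_shifts <- function(tc, pairs, transient = 100) {
  keep <- tc$time >= transient
  tt <- tc$time[keep]
  dt <- stats::median(diff(tt))
  rows <- lapply(pairs, function(pr) {
    stopifnot(length(pr) == 2L)
    xa <- tc_signal(tc, pr[1])[keep]
    m <- oscillation_metrics(tc, pr[1], transient = transient)
    if (!m$oscillatory)
      return(data.frame(signal_a = pr[1], signal_b = pr[2],
                        lag = NA_real_, period = NA_real_,
                        lag_frac = NA_real_))
    Tper <- m$period
    ncyc <- floor((max(tt) - min(tt)) / Tper)
    n <- round(ncyc * Tper / dt)
    a <- xa[seq_len(n)]; b <- tc_signal(tc, pr[2])[keep][seq_len(n)]
    a <- a - mean(a); b <- b - mean(b)
    # circular cross-correlation via FFT
    cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)),
                        inverse = TRUE))
    k <- which.max(cc) - 1L
    lag <- k * dt
    lag <- ((lag + Tper / 2) %% Tper) - Tper / 2
    if (lag <= -Tper / 2) lag <- lag + Tper
    data.frame(signal_a = pr[1], signal_b = pr[2], lag = lag,
               period = Tper, lag_frac = lag / Tper)
  })
  do.call(rbind, rows)
}
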