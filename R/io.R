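# CSV writers/readers with metadata comment blocks, and preset experiments.

fmt_num <- function(x) {
  # full double precision so that a read round-trips bit-exactly
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

write_csv_block <- function(df, path, meta = list(), units = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(list(package = paste0("ebrglyc ",
                                  as.character(utils::packageVersion("ebrglyc"))),
                 written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), meta)
  for (k in names(meta))
    writeLines(sprintf("# %s=%s", k, paste(meta[[k]], collapse = " ")), con)
  if (!is.null(units))
    writeLines(paste0("# units: ", paste(units, collapse = ",")), con)
  writeLines(paste(colnames(df), collapse = ","), con)
  num <- vapply(df, is.numeric, logical(1))
  body <- df
  body[num] <- lapply(df[num], fmt_num)
  writeLines(do.call(paste, c(unname(body), sep = ",")), con)
  invisible(path)
}

#' Write a time course to CSV
#'
#' One row per time point; columns are the time (h), every state variable
#' (including the derived cofactors) and every reaction rate. Metadata
#' (solver settings, load activities, mode) is written as `# key=value`
#' comment lines followed by a units comment line; values are written in
#' full double precision so a round-trip read is bit-exact.
#'
#' @param tc an `ebr_timecourse`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  df <- data.frame(time = tc$time, tc$state, tc$rates, check.names = FALSE)
  p <- tc$params
  meta <- list(type = "timecourse",
               alpha_ADH = p$alpha_ADH, alpha_ALDH = p$alpha_ALDH,
               ethanol_mode = p$ethanol_mode,
               eth = if (is.null(tc$eth)) "dynamic" else tc$eth,
               hematocrit = p$hematocrit,
               solver = tc$solver$method, rtol = tc$solver$rtol,
               atol = tc$solver$atol)
  units <- c("h", rep("mM", ncol(tc$state)), rep("mM/h", ncol(tc$rates)))
  units[1 + which(colnames(tc$state) == "PHI")] <- "dimensionless"
  write_csv_block(df, path, meta, units)
  invisible(path)
}

#' Read back a time course CSV
#'
#' @param path file written by [write_timecourse()].
#' @return a data.frame (comment metadata skipped).
#' @export
read_timecourse <- function(path) {
  utils::read.csv(path, comment.char = "#", check.names = FALSE)
}

#' Write a regime scan to CSV
#'
#' One row per grid point with the regime label, leading-eigenvalue real and
#' imaginary parts, every steady concentration and every steady rate;
#' located boundaries are written in the metadata comment block.
#'
#' @param scan an `ebr_scan`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_scan <- function(scan, path) {
  lead <- vapply(seq_along(scan$grid), function(i) {
    if (!scan$exists[i]) return(c(NA_real_, NA_real_))
    sp <- set_scan_params(scan$params, scan$parameter, scan$grid[i],
                          scan$fixed)
    ev <- eigen(model_jacobian(scan$states[i, ], sp$params, sp$eth),
                only.values = TRUE)$values
    ld <- ev[which.max(Re(ev))]
    c(Re(ld), Im(ld))
  }, numeric(2))
  df <- data.frame(parameter = scan$grid, regime = scan$regime,
                   lead_re = lead[1, ], lead_im = abs(lead[2, ]),
                   scan$states, scan$rates, check.names = FALSE)
  meta <- list(type = "scan", scanned = scan$parameter, fixed = scan$fixed,
               boundary_stability = scan$boundaries$stability,
               boundary_oscillation = scan$boundaries$oscillation,
               boundary_existence = scan$boundaries$existence)
  units <- c(if (scan$parameter == "activity") "mM/h" else "mM", "label",
             "1/h", "1/h", rep("mM", ncol(scan$states)),
             rep("mM/h", ncol(scan$rates)))
  units[4 + which(colnames(scan$states) == "PHI")] <- "dimensionless"
  write_csv_block(df, path, meta, units)
  invisible(path)
}

#' Reference steady-state table
#'
#' Solves the unloaded, ethanol-free steady state and returns the 18
#' metabolite concentrations (glycolytic intermediates, pyruvate, lactate,
#' NAD/NADH, ATP/ADP/AMP, acetaldehyde) in mM.
#'
#' @param params base parameters.
#' @return a data.frame with columns `metabolite` and `concentration_mM`.
#' @export
reference_table <- function(params = ebr_parameters()) {
  p <- params; p$alpha_ADH <- 0; p$alpha_ALDH <- 0
  ss <- find_steady_state(p, eth = 0)
  stopifnot(ss$converged)
  s <- ss$state; cf <- ss$cofactors
  met <- c("G6P", "F6P", "FDP", "DAP", "GAP", "1,3-DPG", "2,3-DPG", "3-PG",
           "2-PG", "PEP", "PYR", "LAC", "NAD", "NADH", "ATP", "ADP", "AMP",
           "ACALD")
  conc <- c(s[c("G6P", "F6P", "FDP", "DAP", "GAP", "DPG13", "DPG23", "PG3",
                "PG2", "PEP", "PYR", "LAC", "NAD")],
            cf[c("NADH", "ATP", "ADP", "AMP")], s["ACALD"])
  data.frame(metabolite = met, concentration_mM = unname(conc))
}

#' Preset experiment catalogue
#'
#' Named, fully reproducible scenario presets covering the package's
#' standard in-silico experiments: suspension consumption kinetics at
#' several activities and ethanol levels, the ADH-only plateau, the 25%
#' hematocrit validation run, activity and ethanol regime scans, an
#' oscillation example, the amplitude/period window, the accumulation
#' series, phase relations, and the reference steady-state table.
#'
#' @return a named list describing each preset (`type` and arguments).
#' @export
ebr_presets <- function() {
  list(
    reference_table = list(type = "table",
      description = "steady state of the unloaded, ethanol-free cell"),
    consumption_activity_series = list(type = "suspension_series",
      description = "10 mM ethanol, 50% hematocrit, ADH=ALDH of 30/60/90 mM/h",
      runs = list(c(alpha_ADH = 30, alpha_ALDH = 30, eth0 = 10, h = 0.5),
                  c(alpha_ADH = 60, alpha_ALDH = 60, eth0 = 10, h = 0.5),
                  c(alpha_ADH = 90, alpha_ALDH = 90, eth0 = 10, h = 0.5)),
      t_end = 40),
    consumption_ethanol_series = list(type = "suspension_series",
      description = "ADH=ALDH=60 mM/h, 50% hematocrit, 5/10/20 mM ethanol",
      runs = list(c(alpha_ADH = 60, alpha_ALDH = 60, eth0 = 5, h = 0.5),
                  c(alpha_ADH = 60, alpha_ALDH = 60, eth0 = 10, h = 0.5),
                  c(alpha_ADH = 60, alpha_ALDH = 60, eth0 = 20, h = 0.5)),
      t_end = 60),
    adh_only_plateau = list(type = "suspension_series",
      description = "ADH 60 mM/h without ALDH: consumption stalls at the ADH equilibrium",
      runs = list(c(alpha_ADH = 60, alpha_ALDH = 0, eth0 = 10, h = 0.5),
                  c(alpha_ADH = 60, alpha_ALDH = 60, eth0 = 10, h = 0.5)),
      t_end = 20),
    validation_suspension = list(type = "suspension_series",
      description = "25% hematocrit, ADH 78 / ALDH 18 mM/h, 30 mM ethanol",
      runs = list(c(alpha_ADH = 78, alpha_ALDH = 18, eth0 = 30, h = 0.25)),
      t_end = 70),
    activity_scan = list(type = "scan", parameter = "activity",
      description = "steady branch vs ADH=ALDH activity at 10 mM ethanol",
      grid = seq(0, 180, by = 4), fixed = 10),
    ethanol_scan = list(type = "scan", parameter = "ethanol",
      description = "steady branch vs clamped ethanol at 40 mM/h activity",
      grid = seq(0, 64, by = 2), fixed = 40),
    oscillation_example = list(type = "oscillation",
      description = "sustained oscillations inside the computed window",
      alpha = 106.1, eth = 10, t_end = 400),
    oscillation_window = list(type = "window",
      description = "FDP amplitude and period across the oscillatory window",
      alpha = seq(105.9, 107.1, by = 0.2), eth = 10, t_end = 400),
    accumulation_series = list(type = "accumulation",
      description = "FDP and ATP kinetics at very high load activity",
      alpha = c(120, 150, 180, 240), eth = 10, t_end = 100),
    phase_relations = list(type = "phases",
      description = "time shifts among ATP, AMP, GAP, NAD, PFK and GAPDH rates",
      alpha = 106.1, eth = 10, t_end = 400)
  )
}

# settle onto the local limit cycle from a perturbed branch root
cycle_timecourse <- function(params, alpha, eth, t_end) {
  ss <- steady_on_branch(params, alpha = alpha, eth = eth)
  init <- if (ss$converged) ss$state * 1.001 else reference_state()
  p <- params; p$alpha_ADH <- alpha; p$alpha_ALDH <- alpha
  integrate_model(init, p, t_end = t_end, eth = eth, n_out = 3000)
}

#' Run a named preset experiment
#'
#' Executes one of the presets from [ebr_presets()] and writes its CSV
#' artifact(s) under `out_dir`.
#'
#' @param name preset name.
#' @param out_dir output directory (created if missing).
#' @param params base parameters.
#' @return invisibly, the list of files written.
#' @export
run_preset <- function(name, out_dir = ".", params = ebr_parameters()) {
  pr <- ebr_presets()[[name]]
  if (is.null(pr)) stop("unknown preset: ", name, "; see ebr_presets()")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  out <- function(f) file.path(out_dir, f)
  if (pr$type == "table") {
    tab <- reference_table(params)
    f <- out("reference_table.csv")
    write_csv_block(tab, f, list(type = "reference_table"),
                    units = c("name", "mM"))
    files <- f
  } else if (pr$type == "suspension_series") {
    for (r in pr$runs) {
      tc <- simulate_suspension(r[["eth0"]], r[["h"]], r[["alpha_ADH"]],
                                r[["alpha_ALDH"]], t_end = pr$t_end,
                                params = params)
      f <- out(sprintf("%s_adh%g_aldh%g_eth%g.csv", name, r[["alpha_ADH"]],
                       r[["alpha_ALDH"]], r[["eth0"]]))
      write_timecourse(tc, f)
      files <- c(files, f)
    }
  } else if (pr$type == "scan") {
    sc <- if (pr$parameter == "activity")
      scan_activity(params, alpha = pr$grid, eth = pr$fixed)
    else scan_ethanol(params, eth = pr$grid, alpha = pr$fixed)
    f <- out(paste0(name, ".csv"))
    write_scan(sc, f)
    files <- f
  } else if (pr$type == "oscillation") {
    tc <- cycle_timecourse(params, pr$alpha, pr$eth, pr$t_end)
    f <- out(paste0(name, ".csv"))
    write_timecourse(tc, f)
    files <- f
  } else if (pr$type == "window") {
    cur <- amplitude_period_curve(params, alpha = pr$alpha, eth = pr$eth,
                                  t_end = pr$t_end)
    f <- out(paste0(name, ".csv"))
    write_csv_block(cur, f,
                    list(type = "oscillation_window",
                         transition = attr(cur, "transition")),
                    units = c("mM/h", "mM", "h", "count", "logical"))
    files <- f
  } else if (pr$type == "accumulation") {
    for (a in pr$alpha) {
      p <- params; p$alpha_ADH <- a; p$alpha_ALDH <- a
      tc <- integrate_model(reference_state(), p, t_end = pr$t_end,
                            eth = pr$eth, n_out = 1000)
      f <- out(sprintf("%s_adh%g.csv", name, a))
      write_timecourse(tc, f)
      files <- c(files, f)
    }
  } else if (pr$type == "phases") {
    tc <- cycle_timecourse(params, pr$alpha, pr$eth, pr$t_end)
    ph <- phase_shifts(tc, list(c("ATP", "GAP"), c("ATP", "AMP"),
                                c("NAD", "GAP"), c("V_PFK", "V_GAPDH")),
                       transient = 150)
    f <- out(paste0(name, ".csv"))
    write_csv_block(ph, f, list(type = "phase_relations",
                                alpha = pr$alpha, eth = pr$eth),
                    units = c("name", "name", "h", "h", "fraction"))
    files <- f
  }
  invisible(files)
}
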