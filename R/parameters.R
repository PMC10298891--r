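#' @keywords internal
"_PACKAGE"

# Canonical orderings used throughout the package.
.state_names <- c("G6P", "F6P", "FDP", "DAP", "GAP", "DPG13", "DPG23",
                  "PG3", "PG2", "PEP", "PYR", "LAC", "NAD", "PHI", "ACALD")
.rate_names <- c("V_HK", "V_GPI", "V_PFK", "V_ALD", "V_TPI", "V_GAPDH",
                 "V_PGK", "V_DPGM", "V_DPGP", "V_PGM", "V_ENO", "V_PK",
                 "V_LDH", "V_NaKATP", "V_ATP", "V_ADH", "V_ALDH",
                 "V_trPYR", "V_trLAC")

.default_parameters <- list(
  # hexokinase
  a_HK = 12, K_HK1 = 1, K_HK2 = 5.5e-3,
  # glucose-6-phosphate isomerase (K_GPI1 is the dimensionless G6P/F6P
  # mass-action ratio; K_GPI2/K_GPI3 are Michaelis constants, mM)
  a_GPI = 360, K_GPI1 = 3, K_GPI2 = 0.3, K_GPI3 = 0.2,
  # phosphofructokinase (K_PFK1: F6P Km; K_PFK2: ATP Km; K_PFK3: AMP
  # activation constant; K_PFK4/K_PFK5: allosteric ATP/F6P constants;
  # L_PFK: allosteric equilibrium weight; c_PFK: printed scale factor)
  a_PFK = 380, K_PFK1 = 0.1, K_PFK2 = 2, K_PFK3 = 0.01,
  K_PFK4 = 0.195, K_PFK5 = 3.7e-4, L_PFK = 1e8, c_PFK = 1.1,
  # aldolase (K_ALD2 in mM^2)
  a_ALD = 76, K_ALD1 = 2e-4, K_ALD2 = 1.2e-5, K_ALD3 = 0.01,
  K_ALD4 = 0.032, K_ALD5 = 2.1e-3, K_ALD6 = 2, K_ALD7 = 0.065,
  # triosephosphate isomerase (K_TPI2 is the GAP/DAP equilibrium ratio)
  a_TPI = 19522, K_TPI1 = 0.82, K_TPI2 = 0.45, K_TPI3 = 0.43,
  # glyceraldehyde phosphate dehydrogenase (c_GAPDH: printed denominator
  # factor 1.29)
  a_GAPDH = 690, K_GAPDH1 = 0.13, K_GAPDH2 = 0.13, K_GAPDH3 = 3.4,
  K_GAPDH4 = 0.136, K_GAPDH5 = 0.013, K_GAPDH6 = 2e-3, c_GAPDH = 1.29,
  # phosphoglycerate kinase (K_PGK3 is the equilibrium constant)
  a_PGK = 2115, K_PGK1 = 2.2e-3, K_PGK2 = 0.14, K_PGK3 = 380,
  K_PGK4 = 0.3, K_PGK5 = 0.27, K_PGK6 = 1.4, K_PGK7 = 0.4,
  # diphosphoglycerate mutase / phosphatase (2,3-DPG shunt)
  a_DPGM = 3892, K_DPGM1 = 0.04, K_DPGM2 = 0.013,
  a_DPGP = 0.65, K_DPGP1 = 0.02, K_DPGP2 = 6e-3,
  # phosphoglycerate mutase (K_PGM2 is the 2-PG/3-PG equilibrium ratio)
  a_PGM = 1100, K_PGM1 = 0.27, K_PGM2 = 0.24, K_PGM3 = 0.02,
  # enolase (K_ENO2 is the PEP/2-PG equilibrium ratio)
  a_ENO = 120, K_ENO1 = 0.056, K_ENO2 = 6.7, K_ENO3 = 2e-3,
  # pyruvate kinase
  a_PK = 120, K_PK1 = 0.05, K_PK2 = 0.43, K_PK3 = 0.35,
  # lactate dehydrogenase (K_LDH3 is the equilibrium constant)
  a_LDH = 550, K_LDH1 = 0.022, K_LDH2 = 7e-3, K_LDH3 = 426,
  K_LDH4 = 0.14, K_LDH5 = 380, K_LDH6 = 0.1, K_LDH7 = 170,
  # ATP consumption: Na/K pump (a in mM^-1 h^-1) and lumped other ATPases
  a_NaKATP = 0.045, Na = 10, a_ATP = 1.6, K_ATP = 1,
  # alcohol dehydrogenase, ordered bi-bi (NAD + ETH <-> ACALD + NADH)
  K_ADH1 = 0.074, K_ADH2 = 0.61, K_ADH3 = 13, K_ADH4 = 0.43,
  K_ADH5 = 0.78, K_ADH6 = 0.67, K_ADH7 = 0.11, K_ADH8 = 0.018,
  K_ADHeq = 2e-4,
  # acetaldehyde dehydrogenase, irreversible, NADH-inhibited
  K_ALDH1 = 0.02, K_ALDH2 = 0.07, K_ALDH3 = 0.009, K_ALDH4 = 0.1,
  # monocarboxylate transport
  A_trPYR = 120, Km_trPYR = 1.9, KI_trPYR = 11,
  A_trLAC = 120, Km_trLAC = 9, KI_trLAC = 1.6,
  # conserved pools and clamped concentrations
  P = 1.744, N = 0.05, K_AK = 1, Pi = 1,
  PYR_ext = 0.07, LAC_ext = 1.2,
  # load enzymes and suspension settings (the varied parameters)
  alpha_ADH = 0, alpha_ALDH = 0,
  eth0 = 0, hematocrit = 0.5, ethanol_mode = "clamped"
)

#' Model parameters for the erythrocyte-bioreactor glycolysis model
#'
#' Builds the full parameter set of the kinetic model: activities and
#' Michaelis/inhibition/equilibrium constants for the nineteen reaction and
#' transport steps, the conserved adenylate pool `P` and NAD pool `N`, the
#' adenylate-kinase equilibrium constant `K_AK`, clamped concentrations
#' (orthophosphate `Pi`, `Na`, extracellular pyruvate and lactate), and the
#' varied load-enzyme activities `alpha_ADH` and `alpha_ALDH` (mM/h).
#'
#' All concentrations are in mM and all rates in mM/h, normalized per liter
#' of cells. `ethanol_mode` selects whether ethanol is a clamped parameter
#' (`"clamped"`, used for all steady-state and regime scans) or a dynamic
#' suspension-level variable (`"dynamic"`, used for consumption kinetics, in
#' which case `hematocrit` scales the cell-normalized consumption rate to
#' the suspension ethanol concentration and `eth0` is the initial ethanol).
#'
#' @param ... named overrides of the default values. Unknown names are an
#'   error.
#' @return an object of class `ebr_parameters` (a named list).
#' @examples
#' p <- ebr_parameters(alpha_ADH = 60, alpha_ALDH = 60)
#' p$alpha_ADH
#' @export
ebr_parameters <- function(...) {
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == "")))
    stop("all parameter overrides must be named")
  unknown <- setdiff(names(over), names(.default_parameters))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p <- utils::modifyList(.default_parameters, over)
  validate_parameters(p)
  structure(p, class = "ebr_parameters")
}

validate_parameters <- function(p) {
  num <- setdiff(names(.default_parameters), "ethanol_mode")
  for (nm in num) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
  }
  strict_pos <- setdiff(num, c("alpha_ADH", "alpha_ALDH", "eth0"))
  for (nm in strict_pos)
    if (p[[nm]] <= 0) stop("parameter '", nm, "' must be strictly positive")
  if (p$alpha_ADH < 0 || p$alpha_ALDH < 0)
    stop("load-enzyme activities must be non-negative")
  if (p$eth0 < 0) stop("eth0 must be non-negative")
  if (p$hematocrit > 1) stop("hematocrit must lie in (0, 1]")
  if (!p$ethanol_mode %in% c("clamped", "dynamic"))
    stop("ethanol_mode must be 'clamped' or 'dynamic'")
  invisible(p)
}

#' @export
print.ebr_parameters <- function(x, ...) {
  cat("Erythrocyte-bioreactor glycolysis model parameters\n")
  cat(sprintf("  load: alpha_ADH = %g, alpha_ALDH = %g mM/h; ethanol %s",
              x$alpha_ADH, x$alpha_ALDH, x$ethanol_mode))
  if (x$ethanol_mode == "dynamic")
    cat(sprintf(" (eth0 = %g mM, hematocrit = %g)", x$eth0, x$hematocrit))
  cat("\n")
  cat(sprintf("  pools: adenylate P = %g mM, NAD(H) N = %g mM, K_AK = %g\n",
              x$P, x$N, x$K_AK))
  cat(sprintf("  clamped: Pi = %g, Na = %g, PYR_ext = %g, LAC_ext = %g mM\n",
              x$Pi, x$Na, x$PYR_ext, x$LAC_ext))
  invisible(x)
}

#' Read model parameters from a flat YAML or JSON configuration file
#'
#' The configuration is a flat key-value document whose keys mirror the
#' parameter names of [ebr_parameters()] (e.g. `a_HK`, `K_PFK3`,
#' `alpha_ADH`). Unknown keys are rejected, as are non-positive kinetic
#' constants. An empty file yields the defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return an `ebr_parameters` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  } else if (ext == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("the 'jsonlite' package is required to read JSON configs")
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be a .yaml/.yml or .json file")
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a flat key-value mapping")
  do.call(ebr_parameters, raw)
}
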