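# Pinned physical constants. All theoretical m/z in the package derive from
# these tables; they are data, not per-call-site literals, so that printed
# reference values reproduce to 4 decimal places.

# Monoisotopic masses (u), lightest isotope, AME2020/IUPAC.
.mono_masses <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  S  = 31.97207100,
  P  = 30.97376163,
  I  = 126.904473,
  Na = 22.9897692809,
  K  = 38.96370668,
  Cl = 34.96885268,
  F  = 18.99840322,
  Br = 78.9183371
)

# Standard atomic weights (IUPAC 2021, conventional values).
.avg_masses <- c(
  H  = 1.008,
  C  = 12.011,
  N  = 14.007,
  O  = 15.999,
  S  = 32.06,
  P  = 30.973761998,
  I  = 126.90447,
  Na = 22.98976928,
  K  = 39.0983,
  Cl = 35.45,
  F  = 18.998403163,
  Br = 79.904
)

.proton_mass   <- 1.007276466   # u, CODATA
.electron_mass <- 0.00054857990907

# Average masses of the 20 standard amino-acid residues (u), ExPASy table.
.residue_avg_masses <- c(
  G = 57.0519,  A = 71.0788,  S = 87.0782,  P = 97.1167,  V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

.water_avg_mass <- 18.01528  # u, average H2O

# Recurring species in the derivatization model (Hill-notation strings,
# parsed lazily so parse_formula stays the single entry point).
.tmpa_cation_formula   <- "C9H22N3"  # quaternary tag, carries +1
.water_formula         <- "H2O"
.trimethylamine_formula <- "C3H9N"
.carbon_dioxide_formula <- "CO2"

#' Pinned mass constants
#'
#' Returns the tables of physical constants every theoretical mass in the
#' package is computed from: monoisotopic masses of the lightest isotopes,
#' IUPAC 2021 standard atomic weights, the proton and electron masses, the
#' ExPASy average amino-acid residue masses, and the elemental formulas of
#' the recurring species in the TMPA derivatization model (the TMPA cation
#' C9H22N3, water, trimethylamine, carbon dioxide).
#'
#' @return A named list with elements `monoisotopic`, `average` (named
#'   numeric vectors of element masses in u), `proton`, `electron` (u),
#'   `residue_avg` (named numeric vector, u), `water_avg` (u), and
#'   `formulas` (named character vector of Hill-notation strings).
#' @examples
#' mass_constants()$proton
#' @export
mass_constants <- function() {
  list(
    monoisotopic = .mono_masses,
    average      = .avg_masses,
    proton       = .proton_mass,
    electron     = .electron_mass,
    residue_avg  = .residue_avg_masses,
    water_avg    = .water_avg_mass,
    formulas     = c(
      tmpa_cation    = .tmpa_cation_formula,
      water          = .water_formula,
      trimethylamine = .trimethylamine_formula,
      carbon_dioxide = .carbon_dioxide_formula
    )
  )
}

# Classed error helpers: the CLI maps these onto exit codes.
data_error <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("scfamsi_data_error", "error", "condition")))
}

usage_error <- function(msg) {
  stop(errorCondition(msg, class = c("scfamsi_usage_error", "error", "condition")))
}
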