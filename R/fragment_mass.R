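# Monoisotopic masses (Da) of the elements seen in positive-ion spectra of
# glycan/OEG-SAM/gold surfaces, plus the electron mass used for cations.
.MONOISOTOPIC <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  S  = 31.97207100,
  Na = 22.9897692809,
  K  = 38.96370668,
  Au = 196.966568662
)
.ELECTRON_MASS <- 5.48579909070e-4
.ELEMENTARY_CHARGE <- 1.602176634e-19 # C

#' Monoisotopic m/z of a singly charged cation fragment
#'
#' Computes the theoretical m/z of a secondary-ion fragment from its
#' elemental formula: the monoisotopic mass of the composition minus one
#' electron mass, for charge +1. This is the mass against which observed
#' ToF-SIMS peak centroids are assigned (2-decimal comparison is
#' conventional for low-mass fragments).
#'
#' @param formula Character vector of elemental formulas, e.g. `"C2H5O"`,
#'   `"Au"`, `"AuC2H4S"`. Supported elements: C, H, N, O, S, Na, K, Au.
#' @param charge Ion charge; only `+1` (singly charged cations) is supported.
#' @return Numeric vector of m/z values (Da).
#' @examples
#' fragment_mz("Au")      # gold substrate ion
#' fragment_mz("C2H5O")   # OEG/SAM oxocarbenium fragment
#' @export
fragment_mz <- function(formula, charge = 1L) {
  if (!identical(as.integer(charge), 1L))
    stop("only singly charged cations (charge = +1) are supported")
  vapply(formula, .formula_mass_cation, numeric(1), USE.NAMES = FALSE)
}

.formula_mass_cation <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
      !nzchar(formula))
    stop("empty formula")
  # two-letter symbols first so "Na" is not parsed as N + a
  m <- gregexpr("(Au|Na|K|C|H|N|O|S)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula))
    stop("unknown element symbol in formula: ", formula)
  mass <- 0
  for (tok in tokens) {
    sym <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    mass <- mass + .MONOISOTOPIC[[sym]] * n
  }
  mass - .ELECTRON_MASS
}

#' Primary-ion dose and the static SIMS limit
#'
#' Converts beam current, acquisition time and analysed area into a
#' primary-ion dose and flags whether it stays below the static SIMS limit
#' of 1e12 ions/cm^2 (the regime in which each primary ion impact samples
#' undamaged surface).
#'
#' @param current_pA Beam current in pA.
#' @param time_s Acquisition time in seconds.
#' @param area_cm2 Rastered area in cm^2.
#' @return List with `dose` (ions/cm^2) and `below_static_limit` (logical).
#' @examples
#' ion_dose(1.3, 100, 2.5e-3)
#' @export
ion_dose <- function(current_pA, time_s, area_cm2) {
  if (current_pA < 0 || time_s < 0) stop("current and time must be >= 0")
  if (area_cm2 <= 0) stop("area must be > 0")
  dose <- (current_pA * 1e-12 * time_s / .ELEMENTARY_CHARGE) / area_cm2
  list(dose = dose, below_static_limit = dose < 1e12)
}
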