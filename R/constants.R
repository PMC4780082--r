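# Physical constants (CODATA 2018) and per-element data used throughout.
# Units policy: Hessians hartree/bohr^2, geometries Angstrom, masses amu,
# frequencies cm^-1, IR intensities km/mol.

.CONST <- list(
  hartree_J   = 4.3597447222071e-18,   # 1 E_h in J
  bohr_m      = 0.529177210903e-10,    # 1 a_0 in m
  amu_kg      = 1.66053906660e-27,     # 1 u in kg
  c_cm        = 2.99792458e10,         # speed of light, cm/s
  c_m         = 2.99792458e8,          # speed of light, m/s
  e_C         = 1.602176634e-19,       # elementary charge, C
  eps0        = 8.8541878128e-12,      # vacuum permittivity, F/m
  avogadro    = 6.02214076e23
)

# sqrt(Eh / (a0^2 amu)) / (2 pi c)  ->  cm^-1 per sqrt(hartree bohr^-2 amu^-1)
.CONST$freq_cm <- sqrt(.CONST$hartree_J / (.CONST$bohr_m^2 * .CONST$amu_kg)) /
  (2 * pi * .CONST$c_cm)

# IR intensity: I [km/mol] = ir_kmmol * |dmu/dQ|^2 with dmu/dQ in e amu^-1/2
.CONST$ir_kmmol <- .CONST$avogadro * pi * (.CONST$e_C^2 / .CONST$amu_kg) /
  (3 * .CONST$c_m^2 * 4 * pi * .CONST$eps0) / 1000

# Valence force-field unit conversions
.CONST$mdynA_to_au  <- 100 / (.CONST$hartree_J / .CONST$bohr_m^2)  # mdyn/A -> Eh/a0^2
.CONST$mdynAA_to_au <- 1e-18 / .CONST$hartree_J                    # mdyn*A -> Eh (per rad^2)
.CONST$mdyn_to_au   <- 1e-8 / (.CONST$hartree_J / .CONST$bohr_m)   # mdyn -> Eh/a0 (per rad)

.CONST$ang_to_bohr <- 1e-10 / .CONST$bohr_m

# Most-abundant-isotope masses (amu) and common isotope overrides
.MASS <- c(H = 1.00782503207, C = 12.0, N = 14.0030740048, O = 15.9949146196,
           S = 31.97207100, P = 30.97376163, F = 18.99840322)
.ISOTOPE_MASS <- c("2H" = 2.01410177812, "13C" = 13.0033548378,
                   "15N" = 15.0001088989, "18O" = 17.9991610)

# Covalent radii (Angstrom), Cordero et al. consensus values
.COVRAD <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
             F = 0.57)

#' Default atomic mass for an element symbol
#'
#' Most-abundant-isotope masses in unified atomic mass units. Isotope labels
#' such as \code{"15N"} or \code{"2H"} are also accepted.
#'
#' @param elements character vector of element symbols or isotope labels.
#' @return numeric vector of masses in amu.
#' @export
#' @examples
#' atomic_mass(c("C", "O", "15N"))
atomic_mass <- function(elements) {
  out <- numeric(length(elements))
  for (i in seq_along(elements)) {
    el <- elements[i]
    if (el %in% names(.ISOTOPE_MASS)) {
      out[i] <- .ISOTOPE_MASS[[el]]
    } else if (el %in% names(.MASS)) {
      out[i] <- .MASS[[el]]
    } else {
      stop("no mass tabulated for element '", el, "'")
    }
  }
  out
}
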