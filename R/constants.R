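#' @title Physical constants and unit conventions
#' @description
#' All internal storage uses AMBER units: kcal/mol, Angstrom, radians,
#' elementary charge.  Conversion to engine units (nm, kJ/mol, degrees)
#' happens only at the writer / param-engine boundary.
#' @name amberconv-units
#' @keywords internal
NULL

## prmtop stores charges as q * 18.2223 so that q_i*q_j/r (internal units)
## is already an energy in kcal/mol; 18.2223^2 = 332.05 = Coulomb constant.
.CHARGE_SCALE <- 18.2223

## thermochemical calorie
.KCAL_TO_KJ <- 4.184

## Coulomb constant, kcal * Angstrom / (mol e^2).  Shared by the energy
## evaluator in every unit system so the fidelity oracle is self-consistent.
.COULOMB_KCAL <- 332.0522173

## AMBER-family 1-4 scaling, shared between writers and the energy oracle
## (single definition prevents drift between emitted defaults and oracle).
.FUDGE_LJ <- 0.5
.FUDGE_QQ <- 1 / 1.2

## truncated-octahedron box angle, degrees: acos(-1/3)
.TO_ANGLE_DEG <- 109.4712190

## charge-neutrality tolerances (e): warn above the first, error above the second
.CHARGE_TOL_WARN <- 0.01
.CHARGE_TOL_ERR <- 0.1

## covalent-distance sanity window (Angstrom) for input geometry screening
.GEOM_MIN_A <- 0.5
.GEOM_MAX_A <- 3.0

## fixed float format for all emitted engine files: deterministic across
## platforms, 10 significant decimals so parameter rounding stays well below
## the 1e-6 energy-fidelity tolerance
.FLOAT_FMT <- "%.10E"

.fmt <- function(x) sprintf(.FLOAT_FMT, x)

#' Masses of the elements handled by the converter (amu)
#' @keywords internal
.ELEMENT_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.9994, S = 32.06,
  P = 30.973762, F = 18.998403, Cl = 35.453, Br = 79.904, I = 126.90447
)

## element from mass, within 1 amu
.element_from_mass <- function(mass) {
  d <- abs(.ELEMENT_MASS - mass)
  if (min(d) <= 1) names(.ELEMENT_MASS)[which.min(d)] else "X"
}
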