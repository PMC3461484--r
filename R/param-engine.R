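#' Convert an AMBER harmonic term to target-engine units and convention
#'
#' AMBER writes harmonic bonded energies as `k (x - x0)^2` in kcal/mol with
#' Angstrom/radian arguments; GROMACS-family engines use `(k/2) (x - x0)^2`
#' in kJ/mol with nm/degree arguments.  The emitted force constant therefore
#' carries a factor 2 (convention) times 4.184 (kcal to kJ) times, for
#' bonds, 100 (A^-2 to nm^-2).
#'
#' @param force_k AMBER force constant (kcal/mol/A^2 for bonds,
#'   kcal/mol/rad^2 for angles); must be non-negative
#' @param eq equilibrium value (Angstrom for bonds, radians for angles)
#' @param term_kind `"bond"` or `"angle"`
#' @return list with `eq` (nm or degrees) and `force_k` (kJ/mol/nm^2 or
#'   kJ/mol/rad^2)
#' @examples
#' convert_harmonic(100, 1.0, "bond")   # 0.1 nm, 83680 kJ/mol/nm^2
#' @export
convert_harmonic <- function(force_k, eq, term_kind = c("bond", "angle")) {
  term_kind <- match.arg(term_kind)
  if (any(force_k < 0)) parameter_error("negative harmonic force constant")
  if (term_kind == "bond") {
    list(eq = eq * 0.1, force_k = 2 * .KCAL_TO_KJ * 100 * force_k)
  } else {
    list(eq = eq * 180 / pi, force_k = 2 * .KCAL_TO_KJ * force_k)
  }
}

#' Convert one AMBER Fourier torsion component to GROMACS function-9 form
#'
#' One output line per Fourier component: multi-term quartets yield multiple
#' function-9 lines for the same atom quadruple and are never combined into
#' a single Ryckaert-Bellemans polynomial.  This keeps the exact AMBER
#' analytical form `PK (1 + cos(n phi - gamma))` in the target engine.
#'
#' @param barrier_half the prmtop `PK = Vn/2`, kcal/mol
#' @param periodicity integer periodicity `n >= 1`
#' @param phase phase `gamma` in radians
#' @return list with `phase_deg` in `[0, 360)`, `k_kj` (kJ/mol) and
#'   `periodicity`
#' @export
convert_torsion_f9 <- function(barrier_half, periodicity, phase) {
  if (any(periodicity < 1)) parameter_error("torsion periodicity must be >= 1")
  list(phase_deg = (phase * 180 / pi) %% 360,
       k_kj = barrier_half * .KCAL_TO_KJ,
       periodicity = as.integer(periodicity))
}

#' Combine a Fourier torsion series into Ryckaert-Bellemans coefficients
#'
#' Maps a dihedral series `sum_n (Vn/2) (1 + cos(n phi - gamma_n))` with up
#' to four terms and phases restricted to 0 or pi onto the six RB
#' coefficients `sum_m C_m cos(psi)^m` under the `psi = phi - 180 deg`
#' convention.  The mapping is exact: the two forms agree at every angle
#' (including the constant offset), which is verified by the package's
#' grid-equivalence tests.  Phases other than 0 or pi have no RB equivalent
#' and must stay in function-9 form.
#'
#' @param barriers numeric vector of full barriers `Vn` (kcal/mol), one per
#'   component
#' @param periodicities integer vector of periodicities (1..4, no repeats)
#' @param phases phases in radians, each 0 or pi (tolerance 1e-9)
#' @return numeric(6) of RB coefficients C0..C5 in kJ/mol (C5 always 0)
#' @export
fourier_to_rb <- function(barriers, periodicities, phases) {
  stopifnot(length(barriers) == length(periodicities),
            length(barriers) == length(phases))
  if (any(periodicities < 1 | periodicities > 4))
    parameter_error("RB mapping defined only for periodicities 1..4")
  ok <- abs(phases) < 1e-9 | abs(phases - pi) < 1e-9
  if (!all(ok))
    parameter_error(
      "RB mapping requires phases of 0 or pi; keep other terms in function-9 form")
  ## Exact expansion: V = sum Vn/2 + sum (s_n Vn/2) cos(n phi) with
  ## s_n = cos(gamma_n) = +-1, then cos(psi) = -cos(phi) under
  ## psi = phi - 180 deg.  T is the unsigned constant part, W[n] the signed
  ## cos(n phi) amplitude (repeated periodicities accumulate).
  Tconst <- sum(barriers)
  W <- numeric(4)
  s <- ifelse(abs(phases - pi) < 1e-9, -1, 1)
  for (i in seq_along(barriers))
    W[periodicities[i]] <- W[periodicities[i]] + s[i] * barriers[i]
  C <- numeric(6)
  C[1] <- Tconst / 2 - W[2] / 2 + W[4] / 2
  C[2] <- -W[1] / 2 + 3 * W[3] / 2
  C[3] <- W[2] - 4 * W[4]
  C[4] <- -2 * W[3]
  C[5] <- 4 * W[4]
  C[6] <- 0
  C * .KCAL_TO_KJ
}

#' Evaluate a Fourier dihedral series (kcal/mol)
#' @param phi angle(s) in radians
#' @inheritParams fourier_to_rb
#' @return potential in kcal/mol at each `phi`
#' @export
fourier_potential <- function(phi, barriers, periodicities, phases) {
  out <- 0
  for (i in seq_along(barriers))
    out <- out + barriers[i] / 2 *
      (1 + cos(periodicities[i] * phi - phases[i]))
  out
}

#' Evaluate a Ryckaert-Bellemans polynomial (kJ/mol)
#' @param phi dihedral angle(s) in radians (IUPAC convention)
#' @param C numeric(6) RB coefficients, kJ/mol
#' @return potential in kJ/mol at each `phi`
#' @export
rb_potential <- function(phi, C) {
  x <- cos(phi - pi)
  C[1] + C[2] * x + C[3] * x^2 + C[4] * x^3 + C[5] * x^4 + C[6] * x^5
}

#' Decode prmtop dihedral sign conventions into torsion terms
#'
#' prmtop dihedral quartets flag term kinds through index signs: a negative
#' fourth atom marks an improper, a negative third atom suppresses the 1-4
#' pair (ring closures and multi-term duplicates).  Output carries unsigned
#' indices, propers first then impropers, each group in input order.
#'
#' @param raw data.frame with signed 1-based columns `ai, aj, ak, al` plus
#'   `barrier_half`, `periodicity`, `phase`
#' @return torsion data.frame as used in [molecular_system()]
#' @export
classify_torsions <- function(raw) {
  if (!nrow(raw)) return(.empty_torsions())
  if (any(raw$ai < 0) || any(raw$aj < 0))
    structural_error("negative index in dihedral position 1 or 2 (format violation)")
  improper <- raw$al < 0
  gen14 <- raw$ak > 0 & !improper
  out <- data.frame(
    ai = abs(raw$ai), aj = abs(raw$aj), ak = abs(raw$ak), al = abs(raw$al),
    barrier_half = raw$barrier_half,
    periodicity = as.integer(raw$periodicity),
    phase = raw$phase,
    kind = ifelse(improper, "improper", "proper"),
    generates_14 = gen14,
    stringsAsFactors = FALSE)
  rbind(out[!improper, , drop = FALSE], out[improper, , drop = FALSE])
}

#' Convert AMBER 12-6 A/B coefficients to sigma/epsilon
#'
#' `A = eps rmin^12`, `B = 2 eps rmin^6` for the like pair, so
#' `sigma = (A/B)^(1/6)` (converted to nm) and `epsilon = B^2/(4A)`
#' (converted to kJ/mol).  Zero-LJ types (hydrogens on some water models)
#' map to `(0, 0)`.
#'
#' @param A kcal A^12 / mol, `>= 0`
#' @param B kcal A^6 / mol, `>= 0`
#' @return list with `sigma` (nm) and `epsilon` (kJ/mol)
#' @seealso [sigma_eps_to_lj_ab()] for the exact inverse
#' @export
lj_ab_to_sigma_eps <- function(A, B) {
  if (A < 0 || B < 0) parameter_error("negative Lennard-Jones coefficient")
  if (A == 0 || B == 0) return(list(sigma = 0, epsilon = 0))
  list(sigma = (A / B)^(1 / 6) * 0.1,
       epsilon = B^2 / (4 * A) * .KCAL_TO_KJ)
}

#' Convert sigma/epsilon to AMBER 12-6 A/B coefficients
#'
#' Exact inverse of [lj_ab_to_sigma_eps()]: round-tripping is an identity
#' to floating-point precision.
#'
#' @param sigma nm
#' @param epsilon kJ/mol
#' @return list with `A` (kcal A^12/mol) and `B` (kcal A^6/mol)
#' @export
sigma_eps_to_lj_ab <- function(sigma, epsilon) {
  if (sigma == 0 || epsilon == 0) return(list(A = 0, B = 0))
  sig_a <- sigma * 10
  eps_kcal <- epsilon / .KCAL_TO_KJ
  list(A = 4 * eps_kcal * sig_a^12, B = 4 * eps_kcal * sig_a^6)
}

#' Guess the integer net charge from partial charges
#'
#' Returns `round(sum(charges))`.  A residual above 0.01 e attaches a
#' warning; above 0.1 e the guess is refused with a non-integral-charge
#' error (guessed charges are not dependable when antechamber drift is that
#' large).
#'
#' @param charges numeric vector of partial charges (e)
#' @return integer net charge
#' @export
guess_net_charge <- function(charges) {
  s <- sum(charges)
  q <- round(s)
  dev <- abs(s - q)
  if (dev > .CHARGE_TOL_ERR)
    parameter_error(sprintf(
      "charges sum to %.4f e: %.4f e from any integer; refusing to guess",
      s, dev))
  if (dev > .CHARGE_TOL_WARN)
    .warn(sprintf("charge sum %.4f e deviates %.4f e from %d", s, dev, q))
  as.integer(q)
}

#' Screen covalent bond distances against the sanity window
#'
#' Input structures with bonded atoms closer than 0.5 Angstrom or farther
#' than 3.0 Angstrom are almost always corrupt (overlapping or missing
#' atoms) and are rejected before conversion.
#'
#' @param sys a [molecular_system()] with coordinates and bonds
#' @return an object of class `geometry_report`: list with `distances`
#'   (one per bond, Angstrom), `violations` (data.frame `bond`, `ai`, `aj`,
#'   `distance`, `rule` where rule is `"min_0.5"` or `"max_3.0"`) and
#'   `pass`
#' @export
validate_geometry <- function(sys) {
  if (is.null(sys$coords))
    structural_error("geometry validation requires coordinates")
  n <- nrow(sys$bonds)
  d <- numeric(n)
  for (b in seq_len(n))
    d[b] <- sqrt(sum((sys$coords[sys$bonds$ai[b], ] -
                        sys$coords[sys$bonds$aj[b], ])^2))
  rule <- rep(NA_character_, n)
  rule[d < .GEOM_MIN_A] <- "min_0.5"
  rule[d > .GEOM_MAX_A] <- "max_3.0"
  bad <- which(!is.na(rule))
  viol <- data.frame(bond = bad, ai = sys$bonds$ai[bad],
                     aj = sys$bonds$aj[bad], distance = d[bad],
                     rule = rule[bad], stringsAsFactors = FALSE)
  structure(list(distances = d, violations = viol,
                 pass = nrow(viol) == 0L),
            class = "geometry_report")
}

#' @export
print.geometry_report <- function(x, ...) {
  cat(sprintf("<geometry_report> %d bonds checked: %s\n",
              length(x$distances), if (x$pass) "pass" else "FAIL"))
  if (!x$pass) print(x$violations)
  invisible(x)
}
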