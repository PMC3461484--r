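#' Construct a periodic-box description
#'
#' A `box_spec` records the periodic cell of a system in the
#' lengths-plus-angles convention used by AMBER restart files.  Kinds:
#' `"none"` (vacuum), `"orthorhombic"` (all angles 90 degrees),
#' `"truncated_octahedron"` (all angles arccos(-1/3) = 109.4712 degrees)
#' and `"triclinic"` (anything else).
#'
#' @param kind one of `"none"`, `"orthorhombic"`, `"truncated_octahedron"`,
#'   `"triclinic"`
#' @param lengths numeric(3), box vector lengths in Angstrom (omit for `"none"`)
#' @param angles numeric(3), box angles in degrees (omit for `"none"`)
#' @return an object of class `box_spec`
#' @examples
#' box_spec("truncated_octahedron", lengths = c(20, 20, 20),
#'          angles = rep(109.4712190, 3))
#' @export
box_spec <- function(kind = "none", lengths = NULL, angles = NULL) {
  kind <- match.arg(kind,
    c("none", "orthorhombic", "truncated_octahedron", "triclinic"))
  if (kind == "none") {
    if (!is.null(lengths) || !is.null(angles))
      structural_error("box kind 'none' must not carry lengths or angles")
    return(structure(list(kind = kind), class = "box_spec"))
  }
  stopifnot(length(lengths) == 3L, length(angles) == 3L)
  if (kind == "truncated_octahedron" &&
      any(abs(angles - .TO_ANGLE_DEG) > 1e-4))
    structural_error(sprintf(
      "truncated_octahedron box requires all angles %.7f deg", .TO_ANGLE_DEG))
  structure(list(kind = kind, lengths = as.numeric(lengths),
                 angles = as.numeric(angles)), class = "box_spec")
}

#' Classify inpcrd box angles into a box kind
#' @keywords internal
.classify_box <- function(lengths, angles, tol = 1e-4) {
  if (all(abs(angles - 90) <= tol)) {
    box_spec("orthorhombic", lengths, angles)
  } else if (all(abs(angles - .TO_ANGLE_DEG) <= tol)) {
    box_spec("truncated_octahedron", lengths, angles)
  } else {
    box_spec("triclinic", lengths, angles)
  }
}

#' Construct a unified molecular system
#'
#' `molecular_system` is the package's central container: every reader
#' produces one and every writer consumes one.  All quantities are stored
#' in AMBER units (kcal/mol, Angstrom, radians, elementary charge); the
#' bonded force constants follow the AMBER convention `k (x - x0)^2`
#' (no 1/2 factor) and torsion barriers are half-barriers `Vn/2`.
#'
#' @param title system title string
#' @param atoms data.frame with columns `name`, `amber_type`, `charge` (e),
#'   `mass` (amu), `element`, `res_name`, `res_index`; row order defines the
#'   1-based atom indices used by every term table
#' @param coords optional n x 3 numeric matrix of coordinates in Angstrom
#' @param bonds data.frame `ai, aj, force_k, r_eq`
#' @param angles data.frame `ai, aj, ak, force_k, theta_eq` (theta in rad)
#' @param torsions data.frame `ai, aj, ak, al, barrier_half, periodicity,
#'   phase, kind, generates_14`; `kind` is `"proper"` or `"improper"`
#' @param lj_types data.frame `type_name, A, B` with AMBER 12-6 coefficients
#'   (kcal A^12/mol, kcal A^6/mol) for like-pair interactions
#' @param atom_lj integer vector, per-atom row index into `lj_types`
#' @param exclusions list of sorted integer vectors, symmetric: `j` in
#'   `exclusions[[i]]` iff `i` in `exclusions[[j]]`
#' @param box a [box_spec()]
#' @param net_charge integer total charge, or `NA` when not yet determined
#' @param validate run [validate_system()] on the result
#' @return an object of class `molecular_system`
#' @seealso [read_prmtop()], [read_mol2()], [generate_toy_system()]
#' @export
molecular_system <- function(title = "", atoms, coords = NULL,
                             bonds = .empty_bonds(), angles = .empty_angles(),
                             torsions = .empty_torsions(),
                             lj_types = .empty_lj(), atom_lj = integer(),
                             exclusions = NULL, box = box_spec("none"),
                             net_charge = NA_integer_, validate = TRUE) {
  if (is.null(exclusions)) exclusions <- rep(list(integer()), nrow(atoms))
  sys <- structure(list(
    title = title, atoms = atoms, coords = coords,
    bonds = bonds, angles = angles, torsions = torsions,
    lj_types = lj_types, atom_lj = as.integer(atom_lj),
    exclusions = exclusions, box = box,
    net_charge = net_charge
  ), class = "molecular_system")
  if (validate) validate_system(sys)
  sys
}

.empty_bonds <- function() data.frame(ai = integer(), aj = integer(),
                                      force_k = numeric(), r_eq = numeric())
.empty_angles <- function() data.frame(ai = integer(), aj = integer(),
                                       ak = integer(), force_k = numeric(),
                                       theta_eq = numeric())
.empty_torsions <- function() data.frame(
  ai = integer(), aj = integer(), ak = integer(), al = integer(),
  barrier_half = numeric(), periodicity = integer(), phase = numeric(),
  kind = character(), generates_14 = logical())
.empty_lj <- function() data.frame(type_name = character(),
                                   A = numeric(), B = numeric())

#' Validate the internal invariants of a molecular system
#'
#' Checks index ranges, positive masses, element/mass consistency, torsion
#' periodicities, exclusion-list symmetry, coordinate shape and (when a net
#' charge is set) charge conservation within 0.01 e (warning above 0.01 e,
#' error above 0.1 e).
#'
#' @param sys a [molecular_system()]
#' @return `sys`, invisibly; signals a structural error on violation
#' @export
validate_system <- function(sys) {
  n <- nrow(sys$atoms)
  need <- c("name", "amber_type", "charge", "mass", "element",
            "res_name", "res_index")
  miss <- setdiff(need, names(sys$atoms))
  if (length(miss))
    structural_error(paste("atoms table missing columns:",
                           paste(miss, collapse = ", ")))
  if (any(sys$atoms$mass <= 0)) structural_error("non-positive atom mass")
  idx_cols <- list(sys$bonds[c("ai", "aj")], sys$angles[c("ai", "aj", "ak")],
                   sys$torsions[c("ai", "aj", "ak", "al")])
  for (tab in idx_cols) {
    v <- unlist(tab, use.names = FALSE)
    if (length(v) && (any(v < 1L) || any(v > n)))
      structural_error("term references an atom index outside 1..natom")
  }
  if (nrow(sys$bonds) && any(sys$bonds$ai == sys$bonds$aj))
    structural_error("bond with identical atoms")
  if (nrow(sys$torsions)) {
    if (any(!sys$torsions$periodicity %in% 1:6))
      structural_error("torsion periodicity outside 1..6")
    if (any(sys$torsions$barrier_half < 0))
      structural_error("negative torsion barrier")
    if (any(sys$torsions$kind == "improper" & sys$torsions$generates_14))
      structural_error("improper torsion flagged as generating a 1-4 pair")
  }
  if (!is.null(sys$coords)) {
    if (!is.matrix(sys$coords) || ncol(sys$coords) != 3L ||
        nrow(sys$coords) != n)
      structural_error("coordinates must be an n x 3 matrix matching atoms")
    if (any(!is.finite(sys$coords)))
      structural_error("non-finite coordinate")
  }
  if (length(sys$exclusions) != n)
    structural_error("exclusion list length must equal atom count")
  for (i in seq_len(n)) {
    for (j in sys$exclusions[[i]]) {
      if (!(i %in% sys$exclusions[[j]]))
        structural_error(sprintf("exclusions not symmetric: %d/%d", i, j))
    }
  }
  if (length(sys$atom_lj) && nrow(sys$lj_types)) {
    if (length(sys$atom_lj) != n ||
        any(sys$atom_lj < 1L | sys$atom_lj > nrow(sys$lj_types)))
      structural_error("atom_lj must map every atom into lj_types")
    bad <- (sys$lj_types$A == 0) != (sys$lj_types$B == 0)
    if (any(bad))
      structural_error("LJ type with A = 0 xor B = 0 (must be both or neither)")
  }
  if (!is.na(sys$net_charge)) {
    dev <- abs(sum(sys$atoms$charge) - sys$net_charge)
    if (dev > .CHARGE_TOL_ERR)
      structural_error(sprintf(
        "charges sum to %.4f but net_charge is %d (deviation %.4f e)",
        sum(sys$atoms$charge), sys$net_charge, dev))
    if (dev > .CHARGE_TOL_WARN)
      .warn(sprintf("charge sum deviates from net charge by %.4f e", dev))
  }
  invisible(sys)
}

#' @export
print.molecular_system <- function(x, ...) {
  cat(sprintf("<molecular_system> %s\n", x$title))
  cat(sprintf("  atoms: %d   bonds: %d   angles: %d   torsions: %d (%d improper)\n",
              nrow(x$atoms), nrow(x$bonds), nrow(x$angles), nrow(x$torsions),
              sum(x$torsions$kind == "improper")))
  cat(sprintf("  coordinates: %s   box: %s   net charge: %s\n",
              if (is.null(x$coords)) "absent" else "present",
              x$box$kind,
              if (is.na(x$net_charge)) "unset" else x$net_charge))
  invisible(x)
}

#' @export
print.box_spec <- function(x, ...) {
  if (x$kind == "none") cat("<box_spec> none\n")
  else cat(sprintf("<box_spec> %s  lengths %s A  angles %s deg\n", x$kind,
                   paste(format(x$lengths), collapse = " "),
                   paste(format(x$angles), collapse = " ")))
  invisible(x)
}
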