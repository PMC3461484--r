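## Vacuum single-point potential energy.  No cutoffs, no periodicity: the
## evaluator certifies topology conversion on small systems, where exact
## all-pairs vacuum evaluation is engine-independent.  All reports are
## normalised to kJ/mol.

## signed dihedral angle, IUPAC convention (cis = 0), radians
.dihedral_angle <- function(coords, i, j, k, l) {
  b1 <- coords[j, ] - coords[i, ]
  b2 <- coords[k, ] - coords[j, ]
  b3 <- coords[l, ] - coords[k, ]
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  m <- cross(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m * n2), sum(n1 * n2))
}

.angle_between <- function(coords, i, j, k) {
  u <- coords[i, ] - coords[j, ]
  v <- coords[k, ] - coords[j, ]
  acos(pmin(1, pmax(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
}

.energy_report <- function(parts) {
  parts$total <- parts$bonds + parts$angles + parts$propers +
    parts$impropers + parts$lj_14 + parts$coulomb_14 + parts$lj_nb +
    parts$coulomb_nb
  structure(parts, class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  terms <- c("bonds", "angles", "propers", "impropers", "lj_14",
             "coulomb_14", "lj_nb", "coulomb_nb", "total")
  cat(sprintf("<energy_report> [%s]\n", x$unit_system))
  for (t in terms) cat(sprintf("  %-11s %18.8f kJ/mol\n", t, x[[t]]))
  invisible(x)
}

#' Format an energy report as tab-separated text
#' @param x an `energy_report`
#' @return character vector of lines `term<TAB>value`
#' @export
format_energy_tsv <- function(x) {
  terms <- c("bonds", "angles", "propers", "impropers", "lj_14",
             "coulomb_14", "lj_nb", "coulomb_nb", "total")
  c("term\tenergy_kj_mol",
    vapply(terms, function(t) sprintf("%s\t%.10f", t, x[[t]]), character(1)))
}

## shared nonbonded loop: sig/eps per atom (nm, kJ/mol), charges (e),
## coords in nm, exclusion lists, scaled 1-4 pair list
.nonbonded_energy <- function(coords_nm, sigma, eps, charge, exclusions,
                              pairs, fudge_lj, fudge_qq) {
  n <- nrow(coords_nm)
  kqq <- .COULOMB_KCAL * .KCAL_TO_KJ * 0.1  # kJ nm / (mol e^2)
  pair_set <- if (nrow(pairs)) paste(pairs$ai, pairs$aj) else character()
  lj_nb <- coulomb_nb <- lj_14 <- coulomb_14 <- 0
  for (i in seq_len(max(n - 1L, 0L))) for (j in seq.int(i + 1L, n)) {
    excluded <- j %in% exclusions[[i]]
    is_14 <- paste(i, j) %in% pair_set
    if (excluded && !is_14) next
    r <- sqrt(sum((coords_nm[i, ] - coords_nm[j, ])^2))
    if (r < 1e-7)  # 1e-6 Angstrom
      geometry_error(sprintf("atoms %d and %d overlap (r = %g nm)", i, j, r))
    sij <- (sigma[i] + sigma[j]) / 2
    eij <- sqrt(eps[i] * eps[j])
    vlj <- if (eij > 0) 4 * eij * ((sij / r)^12 - (sij / r)^6) else 0
    vqq <- kqq * charge[i] * charge[j] / r
    if (is_14) {
      lj_14 <- lj_14 + fudge_lj * vlj
      coulomb_14 <- coulomb_14 + fudge_qq * vqq
    } else {
      lj_nb <- lj_nb + vlj
      coulomb_nb <- coulomb_nb + vqq
    }
  }
  list(lj_nb = lj_nb, coulomb_nb = coulomb_nb, lj_14 = lj_14,
       coulomb_14 = coulomb_14)
}

#' Vacuum single-point energy of a molecular system
#'
#' Evaluates bonded and nonbonded terms at fixed coordinates.  In AMBER
#' form: bonds and angles as `k (x - x0)^2`, torsions as
#' `PK (1 + cos(n phi - gamma))`, Lennard-Jones from the like-pair A/B
#' coefficients with Lorentz-Berthelot combination, Coulomb with constant
#' 332.0522173 kcal A/(mol e^2).  Nonbonded interactions run over all
#' non-excluded pairs with no cutoff; 1-4 pairs are scaled by 1/2 (LJ) and
#' 1/1.2 (Coulomb).  In GROMACS form (an object returned by
#' [read_gromacs_top()]) the same physics is evaluated from nm/kJ inputs
#' with function-9 periodic or Ryckaert-Bellemans dihedrals.
#'
#' @param sys a [molecular_system()] (`form = "amber"`) or a
#'   `gromacs_topology` from [read_gromacs_top()] (GROMACS forms)
#' @param coords coordinate matrix; Angstrom for AMBER form, nm for GROMACS
#'   forms.  Defaults to `sys$coords` where present.
#' @param form `"amber"`, `"gromacs_f9"` or `"gromacs_rb"`
#' @return an `energy_report` with components `bonds`, `angles`, `propers`,
#'   `impropers`, `lj_14`, `coulomb_14`, `lj_nb`, `coulomb_nb`, `total`,
#'   all kJ/mol
#' @export
single_point_energy <- function(sys, coords = NULL,
                                form = c("amber", "gromacs_f9", "gromacs_rb")) {
  form <- match.arg(form)
  if (form == "amber") {
    if (is.null(coords)) coords <- sys$coords
    if (is.null(coords)) structural_error("energy evaluation requires coordinates")
    if (any(is.na(sys$bonds$force_k)) || any(is.na(sys$angles$force_k)))
      parameter_error("system has unparameterised bonded terms")

    e_bond <- 0
    for (b in seq_len(nrow(sys$bonds))) {
      r <- sqrt(sum((coords[sys$bonds$ai[b], ] - coords[sys$bonds$aj[b], ])^2))
      e_bond <- e_bond + sys$bonds$force_k[b] * (r - sys$bonds$r_eq[b])^2
    }
    e_angle <- 0
    for (a in seq_len(nrow(sys$angles))) {
      th <- .angle_between(coords, sys$angles$ai[a], sys$angles$aj[a],
                           sys$angles$ak[a])
      e_angle <- e_angle + sys$angles$force_k[a] * (th - sys$angles$theta_eq[a])^2
    }
    e_prop <- e_impr <- 0
    for (t in seq_len(nrow(sys$torsions))) {
      phi <- .dihedral_angle(coords, sys$torsions$ai[t], sys$torsions$aj[t],
                             sys$torsions$ak[t], sys$torsions$al[t])
      v <- sys$torsions$barrier_half[t] *
        (1 + cos(sys$torsions$periodicity[t] * phi - sys$torsions$phase[t]))
      if (sys$torsions$kind[t] == "improper") e_impr <- e_impr + v
      else e_prop <- e_prop + v
    }

    se <- lapply(seq_len(nrow(sys$lj_types)), function(t)
      lj_ab_to_sigma_eps(sys$lj_types$A[t], sys$lj_types$B[t]))
    sigma <- vapply(sys$atom_lj, function(t) se[[t]]$sigma, numeric(1))
    eps <- vapply(sys$atom_lj, function(t) se[[t]]$epsilon, numeric(1))
    pairs <- build_pairs_exclusions(sys)$pairs
    nb <- .nonbonded_energy(coords * 0.1, sigma, eps, sys$atoms$charge,
                            sys$exclusions, pairs, .FUDGE_LJ, .FUDGE_QQ)

    return(.energy_report(c(list(
      bonds = e_bond * .KCAL_TO_KJ, angles = e_angle * .KCAL_TO_KJ,
      propers = e_prop * .KCAL_TO_KJ, impropers = e_impr * .KCAL_TO_KJ),
      nb, list(unit_system = "kJ/mol (from AMBER form)"))))
  }

  ## GROMACS forms
  top <- sys
  if (!inherits(top, "gromacs_topology"))
    structural_error("GROMACS-form evaluation requires a gromacs_topology")
  if (is.null(coords)) structural_error("energy evaluation requires coordinates")

  e_bond <- 0
  for (b in seq_len(nrow(top$bonds))) {
    r <- sqrt(sum((coords[top$bonds$ai[b], ] - coords[top$bonds$aj[b], ])^2))
    e_bond <- e_bond + 0.5 * top$bonds$k[b] * (r - top$bonds$r0[b])^2
  }
  e_angle <- 0
  for (a in seq_len(nrow(top$angles))) {
    th <- .angle_between(coords, top$angles$ai[a], top$angles$aj[a],
                         top$angles$ak[a])
    e_angle <- e_angle +
      0.5 * top$angles$k[a] * (th - top$angles$theta0_deg[a] * pi / 180)^2
  }
  e_prop <- e_impr <- 0
  for (t in seq_len(nrow(top$dihedrals))) {
    phi <- .dihedral_angle(coords, top$dihedrals$ai[t], top$dihedrals$aj[t],
                           top$dihedrals$ak[t], top$dihedrals$al[t])
    v <- top$dihedrals$k[t] *
      (1 + cos(top$dihedrals$mult[t] * phi -
                 top$dihedrals$phase_deg[t] * pi / 180))
    if (top$dihedrals$func[t] == 4L) e_impr <- e_impr + v
    else e_prop <- e_prop + v
  }
  if (form == "gromacs_rb" && nrow(top$rb_dihedrals)) {
    for (t in seq_len(nrow(top$rb_dihedrals))) {
      phi <- .dihedral_angle(coords, top$rb_dihedrals$ai[t],
                             top$rb_dihedrals$aj[t], top$rb_dihedrals$ak[t],
                             top$rb_dihedrals$al[t])
      e_prop <- e_prop + rb_potential(phi, as.numeric(
        top$rb_dihedrals[t, c("C0", "C1", "C2", "C3", "C4", "C5")]))
    }
  }

  ti <- match(top$atoms$type, top$atomtypes$name)
  if (any(is.na(ti)))
    parameter_error("atom references an undeclared atom type")
  nb <- .nonbonded_energy(coords, top$atomtypes$sigma[ti],
                          top$atomtypes$epsilon[ti], top$atoms$charge,
                          top$exclusions, top$pairs,
                          top$fudge_lj, top$fudge_qq)
  .energy_report(c(list(
    bonds = e_bond, angles = e_angle, propers = e_prop, impropers = e_impr),
    nb, list(unit_system = sprintf("kJ/mol (from GROMACS %s form)",
                                   if (form == "gromacs_rb") "RB" else "f9"))))
}

#' Relative per-term difference between two energy reports
#' @keywords internal
.energy_rel_diff <- function(a, b) {
  terms <- c("bonds", "angles", "propers", "impropers", "lj_14",
             "coulomb_14", "lj_nb", "coulomb_nb", "total")
  vapply(terms, function(t) {
    denom <- max(abs(a[[t]]), abs(b[[t]]))
    if (denom < 1e-9) 0 else abs(a[[t]] - b[[t]]) / denom
  }, numeric(1))
}

#' Certify a GROMACS conversion by energy comparison
#'
#' Writes the system as a GROMACS topology, re-parses the emitted file with
#' the package's own reader, evaluates the single-point energy of both
#' representations at the same coordinates (Angstrom exactly converted to
#' nm) and reports per-term relative differences.  Any term exceeding
#' `tolerance` is flagged.
#'
#' @param sys a fully parameterised [molecular_system()]
#' @param coords coordinates in Angstrom (default `sys$coords`)
#' @param engine target engine (only `"gromacs"` has a reader)
#' @param tolerance per-term relative tolerance (default 1e-6)
#' @param settings writer settings passed to [write_gromacs_top()]
#' @return list with `source` and `converted` energy reports, `per_term`
#'   data.frame (`term`, `source`, `converted`, `rel_diff`, `flagged`),
#'   `max_rel_diff` and `pass`
#' @export
compare_conversion <- function(sys, coords = NULL, engine = "gromacs",
                               tolerance = 1e-6, settings = list()) {
  if (engine != "gromacs")
    capability_error("energy comparison is implemented for the gromacs engine")
  if (is.null(coords)) coords <- sys$coords
  e_src <- single_point_energy(sys, coords, form = "amber")

  top_file <- tempfile(fileext = ".top")
  on.exit(unlink(top_file))
  write_gromacs_top(sys, top_file, settings = settings)
  top <- read_gromacs_top(top_file)
  e_conv <- single_point_energy(top, coords * 0.1, form = "gromacs_f9")

  rd <- .energy_rel_diff(e_src, e_conv)
  per_term <- data.frame(
    term = names(rd),
    source = vapply(names(rd), function(t) e_src[[t]], numeric(1)),
    converted = vapply(names(rd), function(t) e_conv[[t]], numeric(1)),
    rel_diff = as.numeric(rd),
    flagged = as.numeric(rd) > tolerance,
    row.names = NULL, stringsAsFactors = FALSE)
  list(source = e_src, converted = e_conv, per_term = per_term,
       max_rel_diff = max(rd), pass = !any(per_term$flagged))
}
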