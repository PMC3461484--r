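## GROMACS topology emission.  Propers go out as function-9 periodic lines,
## one per Fourier component (never combined per quartet); impropers keep
## the AMBER analytic form as function-4 periodic lines.  An opt-in
## Ryckaert-Bellemans path (function 3) is available for series with
## phases 0/pi.

.gmx_settings <- function(settings) {
  s <- list(type_prefix = "ac", molecule_name = "MOL",
            dihedral_form = "f9", note_water = TRUE)
  s[names(settings)] <- settings
  s
}

.ATOMIC_NUMBER <- c(H = 1L, C = 6L, N = 7L, O = 8L, F = 9L, P = 15L,
                    S = 16L, Cl = 17L, Br = 35L, I = 53L, X = 0L)

#' Write a molecular system as a GROMACS topology
#'
#' Emits a self-contained `.top` with `[defaults]` (nonbonded function 1,
#' combination rule 2, pair generation on, LJ 1-4 scale 0.5, Coulomb 1-4
#' scale 1/1.2), `[atomtypes]` carrying sigma/epsilon in nm and kJ/mol with
#' a collision-avoidance prefix on molecule-local type names, harmonic
#' bonds/angles in engine convention, the deduplicated 1-4 `[pairs]` list,
#' propers as function-9 lines (one per Fourier component) and impropers as
#' function-4 periodic lines.  Output is deterministic: identical input
#' yields byte-identical text.
#'
#' @param sys a fully parameterised [molecular_system()]
#' @param path optional output file
#' @param settings list; recognised fields `type_prefix` (default `"ac"`),
#'   `molecule_name` (default `"MOL"`), `dihedral_form` (`"f9"` default or
#'   `"rb"` for combined Ryckaert-Bellemans propers), `note_water`
#' @return character vector of topology lines (invisibly when `path` given)
#' @export
write_gromacs_top <- function(sys, path = NULL, settings = list()) {
  s <- .gmx_settings(settings)
  if (any(is.na(sys$bonds$force_k)) || any(is.na(sys$angles$force_k)))
    parameter_error("system has unparameterised terms; run resolve_parameters")
  validate_system(sys)

  types <- sys$lj_types$type_name
  ptype <- paste0(s$type_prefix, types)
  if (anyDuplicated(ptype))
    structural_error("atom-type name collision after prefixing")

  out <- c(
    "; GROMACS topology written by amberconv",
    sprintf("; molecule: %s", if (nzchar(sys$title)) sys$title else s$molecule_name))
  if (s$note_water) {
    wm <- recognize_water(sys)
    if (wm != "none")
      out <- c(out, sprintf("; water model recognised: %s", wm))
  }
  out <- c(out,
    "",
    "[ defaults ]",
    "; nbfunc comb-rule gen-pairs fudgeLJ fudgeQQ",
    sprintf("1 2 yes %.10f %.10f", .FUDGE_LJ, .FUDGE_QQ),
    "",
    "[ atomtypes ]",
    "; name at.num mass charge ptype sigma epsilon")
  for (t in seq_along(types)) {
    se <- lj_ab_to_sigma_eps(sys$lj_types$A[t], sys$lj_types$B[t])
    first <- which(sys$atom_lj == t)[1]
    el <- if (is.na(first)) "X" else sys$atoms$element[first]
    atn <- if (el %in% names(.ATOMIC_NUMBER)) .ATOMIC_NUMBER[[el]] else 0L
    mass <- if (is.na(first)) 0 else sys$atoms$mass[first]
    out <- c(out, sprintf("%-8s %3d %12.5f 0.00000000 A %s %s",
                          ptype[t], atn, mass, .fmt(se$sigma), .fmt(se$epsilon)))
  }
  out <- c(out, "", "[ moleculetype ]", "; name nrexcl",
           sprintf("%s 3", s$molecule_name), "", "[ atoms ]",
           "; nr type resnr residue atom cgnr charge mass")
  for (i in seq_len(nrow(sys$atoms))) {
    out <- c(out, sprintf("%6d %-8s %4d %-6s %-6s %6d %s %12.5f",
                          i, ptype[sys$atom_lj[i]], sys$atoms$res_index[i],
                          sys$atoms$res_name[i], sys$atoms$name[i], i,
                          .fmt(sys$atoms$charge[i]), sys$atoms$mass[i]))
  }
  if (nrow(sys$bonds)) {
    out <- c(out, "", "[ bonds ]", "; ai aj func r0(nm) k(kJ/mol/nm2)")
    for (b in seq_len(nrow(sys$bonds))) {
      cv <- convert_harmonic(sys$bonds$force_k[b], sys$bonds$r_eq[b], "bond")
      out <- c(out, sprintf("%6d %6d 1 %s %s", sys$bonds$ai[b],
                            sys$bonds$aj[b], .fmt(cv$eq), .fmt(cv$force_k)))
    }
  }
  pe <- build_pairs_exclusions(sys)
  if (nrow(pe$pairs)) {
    out <- c(out, "", "[ pairs ]", "; ai aj func")
    for (p in seq_len(nrow(pe$pairs)))
      out <- c(out, sprintf("%6d %6d 1", pe$pairs$ai[p], pe$pairs$aj[p]))
  }
  if (nrow(sys$angles)) {
    out <- c(out, "", "[ angles ]", "; ai aj ak func theta0(deg) k(kJ/mol/rad2)")
    for (a in seq_len(nrow(sys$angles))) {
      cv <- convert_harmonic(sys$angles$force_k[a], sys$angles$theta_eq[a],
                             "angle")
      out <- c(out, sprintf("%6d %6d %6d 1 %s %s", sys$angles$ai[a],
                            sys$angles$aj[a], sys$angles$ak[a],
                            .fmt(cv$eq), .fmt(cv$force_k)))
    }
  }
  prop <- sys$torsions[sys$torsions$kind == "proper", , drop = FALSE]
  impr <- sys$torsions[sys$torsions$kind == "improper", , drop = FALSE]
  if (nrow(prop)) {
    if (s$dihedral_form == "rb") {
      out <- c(out, "", "[ dihedrals ]", "; propers, Ryckaert-Bellemans (func 3)")
      key <- paste(prop$ai, prop$aj, prop$ak, prop$al)
      for (k in unique(key)) {
        grp <- prop[key == k, , drop = FALSE]
        C <- fourier_to_rb(2 * grp$barrier_half, grp$periodicity, grp$phase)
        out <- c(out, sprintf("%6d %6d %6d %6d 3 %s", grp$ai[1], grp$aj[1],
                              grp$ak[1], grp$al[1],
                              paste(.fmt(C), collapse = " ")))
      }
    } else {
      out <- c(out, "", "[ dihedrals ]",
               "; propers, AMBER periodic form (func 9), one line per Fourier component")
      for (t in seq_len(nrow(prop))) {
        cv <- convert_torsion_f9(prop$barrier_half[t], prop$periodicity[t],
                                 prop$phase[t])
        out <- c(out, sprintf("%6d %6d %6d %6d 9 %s %s %d", prop$ai[t],
                              prop$aj[t], prop$ak[t], prop$al[t],
                              .fmt(cv$phase_deg), .fmt(cv$k_kj),
                              cv$periodicity))
      }
    }
  }
  if (nrow(impr)) {
    out <- c(out, "", "[ dihedrals ]", "; impropers, periodic form (func 4)")
    for (t in seq_len(nrow(impr))) {
      cv <- convert_torsion_f9(impr$barrier_half[t], impr$periodicity[t],
                               impr$phase[t])
      out <- c(out, sprintf("%6d %6d %6d %6d 4 %s %s %d", impr$ai[t],
                            impr$aj[t], impr$ak[t], impr$al[t],
                            .fmt(cv$phase_deg), .fmt(cv$k_kj),
                            cv$periodicity))
    }
  }
  out <- c(out, "", "[ system ]",
           if (nzchar(sys$title)) sys$title else s$molecule_name,
           "", "[ molecules ]", sprintf("%s 1", s$molecule_name))
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Write coordinates in GROMACS .gro format
#'
#' Positions are emitted in nm at the format's fixed precision (3
#' decimals); atom and residue numbers wrap modulo the 5-digit field
#' width.  The box line carries the triclinic vector components in the
#' engine's `v1x v2y v3z v1y v1z v2x v2z v3x v3y` order (off-diagonal
#' components are emitted whenever any is nonzero).
#'
#' @param coords n x 3 coordinates in Angstrom
#' @param path optional output file
#' @param box_vectors 3 x 3 matrix of row box vectors in nm (e.g. from
#'   [convert_box()]); `NULL` emits a zero box line
#' @param atoms optional atoms data.frame (names/residues); defaults to a
#'   generic naming
#' @param title title line
#' @return character vector of lines (invisibly when `path` given)
#' @export
write_gro <- function(coords, path = NULL, box_vectors = NULL, atoms = NULL,
                      title = "written by amberconv") {
  n <- nrow(coords)
  if (is.null(atoms))
    atoms <- data.frame(name = sprintf("X%d", seq_len(n)), res_name = "MOL",
                        res_index = 1L)
  nm <- coords * 0.1
  out <- c(title, sprintf("%5d", n))
  for (i in seq_len(n)) {
    out <- c(out, sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                          atoms$res_index[i] %% 100000L,
                          substr(atoms$res_name[i], 1, 5),
                          substr(atoms$name[i], 1, 5), i %% 100000L,
                          nm[i, 1], nm[i, 2], nm[i, 3]))
  }
  bv <- if (is.null(box_vectors)) matrix(0, 3, 3) else box_vectors
  comps <- c(bv[1, 1], bv[2, 2], bv[3, 3],
             bv[1, 2], bv[1, 3], bv[2, 1], bv[2, 3], bv[3, 1], bv[3, 2])
  ndig <- if (max(abs(comps)) > 0 && any(abs(comps[4:9]) > 0)) 9L else 3L
  out <- c(out, paste(sprintf("%10.5f", comps[seq_len(ndig)]), collapse = ""))
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
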