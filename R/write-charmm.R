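## CHARMM rtf/prm output.  CHARMM shares AMBER's bonded conventions
## (k (b - b0)^2, Kchi (1 + cos(n chi - delta)) with Kchi the half
## barrier), so bonded values pass through in kcal/Angstrom; only the LJ
## column convention differs (-epsilon with Rmin/2 = sigma * 2^(1/6) / 2).

#' Write a molecular system as a CHARMM rtf/prm pair
#'
#' The rtf lists MASS records and a single RESI with atoms, charges, bonds
#' and impropers; the prm carries BONDS/ANGLES/DIHEDRALS/IMPROPER/NONBONDED
#' tables with AMBER values in CHARMM conventions.  psf generation is left
#' to CHARMM itself.
#'
#' @param sys a fully parameterised [molecular_system()]
#' @param settings list; recognised fields `residue_name` (default
#'   `"MOL"`), `type_prefix` (default `""`; CHARMM types are uppercased)
#' @return list of character vectors: `rtf`, `prm`
#' @export
write_charmm <- function(sys, settings = list()) {
  resn <- toupper(if (!is.null(settings$residue_name)) settings$residue_name
                  else "MOL")
  prefix <- toupper(if (!is.null(settings$type_prefix)) settings$type_prefix
                    else "")
  if (any(is.na(sys$bonds$force_k)) || any(is.na(sys$angles$force_k)))
    parameter_error("system has unparameterised terms; run resolve_parameters")
  anm <- toupper(sys$atoms$name)
  aty <- paste0(prefix, toupper(sys$atoms$amber_type))

  rtf <- c("* CHARMM topology (rtf) written by amberconv", "*", "36 1", "")
  ut <- !duplicated(aty)
  if (anyDuplicated(aty[ut]))
    structural_error("duplicate MASS type names")
  rtf <- c(rtf, sprintf("MASS %5d %-6s %10.5f", -1L, aty[ut],
                        sys$atoms$mass[ut]), "")
  rtf <- c(rtf, sprintf("RESI %-6s % .3f", resn, sum(sys$atoms$charge)),
           "GROUP")
  rtf <- c(rtf, sprintf("ATOM %-6s %-6s %10.6f", anm, aty,
                        sys$atoms$charge))
  for (b in seq_len(nrow(sys$bonds)))
    rtf <- c(rtf, sprintf("BOND %-6s %-6s", anm[sys$bonds$ai[b]],
                          anm[sys$bonds$aj[b]]))
  imp <- sys$torsions[sys$torsions$kind == "improper", , drop = FALSE]
  for (t in seq_len(nrow(imp)))
    rtf <- c(rtf, sprintf("IMPR %-6s %-6s %-6s %-6s", anm[imp$ai[t]],
                          anm[imp$aj[t]], anm[imp$ak[t]], anm[imp$al[t]]))
  rtf <- c(rtf, "PATCHING FIRS NONE LAST NONE", "END", "")

  prm <- c("* CHARMM parameters (prm) written by amberconv", "*", "")
  prm <- c(prm, "BONDS")
  bkey <- vapply(seq_len(nrow(sys$bonds)), function(b)
    .bond_key(aty[sys$bonds$ai[b]], aty[sys$bonds$aj[b]]), character(1))
  btxt <- vapply(seq_len(nrow(sys$bonds)), function(b)
    sprintf("%-6s %-6s %10.4f %10.5f", aty[sys$bonds$ai[b]],
            aty[sys$bonds$aj[b]], sys$bonds$force_k[b], sys$bonds$r_eq[b]),
    character(1))
  prm <- c(prm, .dedup_params(bkey, btxt, "bond"), "")
  prm <- c(prm, "ANGLES")
  akey <- vapply(seq_len(nrow(sys$angles)), function(a)
    .angle_key(aty[sys$angles$ai[a]], aty[sys$angles$aj[a]],
               aty[sys$angles$ak[a]]), character(1))
  atxt <- vapply(seq_len(nrow(sys$angles)), function(a)
    sprintf("%-6s %-6s %-6s %10.4f %10.4f", aty[sys$angles$ai[a]],
            aty[sys$angles$aj[a]], aty[sys$angles$ak[a]],
            sys$angles$force_k[a], sys$angles$theta_eq[a] * 180 / pi),
    character(1))
  prm <- c(prm, .dedup_params(akey, atxt, "angle"), "")
  tor <- sys$torsions
  prop <- tor[tor$kind == "proper", , drop = FALSE]
  prm <- c(prm, "DIHEDRALS")
  if (nrow(prop)) {
    pkey <- vapply(seq_len(nrow(prop)), function(t) paste0(
      .torsion_key(aty[prop$ai[t]], aty[prop$aj[t]], aty[prop$ak[t]],
                   aty[prop$al[t]]), ":n", prop$periodicity[t]),
      character(1))
    ptxt <- vapply(seq_len(nrow(prop)), function(t)
      sprintf("%-6s %-6s %-6s %-6s %10.5f %2d %10.2f", aty[prop$ai[t]],
              aty[prop$aj[t]], aty[prop$ak[t]], aty[prop$al[t]],
              prop$barrier_half[t], prop$periodicity[t],
              prop$phase[t] * 180 / pi), character(1))
    prm <- c(prm, .dedup_params(pkey, ptxt, "dihedral"))
  }
  prm <- c(prm, "", "IMPROPER")
  if (nrow(imp)) {
    ikey <- vapply(seq_len(nrow(imp)), function(t) paste0(
      .torsion_key(aty[imp$ai[t]], aty[imp$aj[t]], aty[imp$ak[t]],
                   aty[imp$al[t]]), ":n", imp$periodicity[t]), character(1))
    itxt <- vapply(seq_len(nrow(imp)), function(t)
      sprintf("%-6s %-6s %-6s %-6s %10.5f %2d %10.2f", aty[imp$ai[t]],
              aty[imp$aj[t]], aty[imp$ak[t]], aty[imp$al[t]],
              imp$barrier_half[t], imp$periodicity[t],
              imp$phase[t] * 180 / pi), character(1))
    prm <- c(prm, .dedup_params(ikey, itxt, "improper"))
  }
  prm <- c(prm, "", "NONBONDED")
  for (i in which(ut)) {
    se <- lj_ab_to_sigma_eps(sys$lj_types$A[sys$atom_lj[i]],
                             sys$lj_types$B[sys$atom_lj[i]])
    eps_kcal <- se$epsilon / .KCAL_TO_KJ
    rmin2 <- se$sigma * 2^(1 / 6) / 2 * 10  # Angstrom
    prm <- c(prm, sprintf("%-6s %10.6f %10.6f %10.6f", aty[i], 0,
                          -eps_kcal, rmin2))
  }
  prm <- c(prm, "", "END", "")
  list(rtf = rtf, prm = prm)
}
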