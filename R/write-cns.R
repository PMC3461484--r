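## CNS/XPLOR dialect output.  CNS rejects mixed-case atom names, so every
## atom and type name is emitted uppercase.  Parameters are deduplicated by
## type tuple; conflicting values for the same tuple are an upstream error.

.cns_nb <- function(A, B) {
  ## CNS NONBonded: eps sigma eps14 sigma14 (kcal, Angstrom); the 1-4
  ## epsilon carries the AMBER LJ scale so explicit 1-4 terms match
  se <- lj_ab_to_sigma_eps(A, B)
  eps_kcal <- se$epsilon / .KCAL_TO_KJ
  sig_a <- se$sigma * 10
  c(eps_kcal, sig_a, eps_kcal * .FUDGE_LJ, sig_a)
}

.dedup_params <- function(keys, values_text, what) {
  seen <- list()
  out <- character()
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (!is.null(seen[[k]])) {
      if (!identical(seen[[k]], values_text[i]))
        parameter_error(sprintf(
          "conflicting %s parameters for type tuple (%s); resolve upstream",
          what, k))
      next
    }
    seen[[k]] <- values_text[i]
    out <- c(out, values_text[i])
  }
  out
}

#' Write a molecular system in the CNS topology/parameter dialect
#'
#' Produces three texts: a topology (masses, atoms with charges, bonds,
#' angles, dihedrals, impropers), a parameter file with unique-by-type
#' BOND/ANGLe/DIHEdral/IMPRoper/NONBonded statements in kcal/Angstrom, and
#' a minimal run-input template that loads both and computes one energy.
#' All atom and type names are uppercased (CNS does not support mixed
#' case).
#'
#' @param sys a fully parameterised [molecular_system()]
#' @param settings list; recognised field `residue_name` (default `"MOL"`)
#' @return list of character vectors: `topology`, `parameters`, `run_input`
#' @export
write_cns <- function(sys, settings = list()) {
  resn <- toupper(if (!is.null(settings$residue_name)) settings$residue_name
                  else "MOL")
  if (any(is.na(sys$bonds$force_k)) || any(is.na(sys$angles$force_k)))
    parameter_error("system has unparameterised terms; run resolve_parameters")
  anm <- toupper(sys$atoms$name)
  aty <- toupper(sys$atoms$amber_type)
  if (anyDuplicated(anm))
    structural_error("duplicate atom names after uppercasing; CNS needs unique names")
  ty <- sys$atoms$amber_type

  topo <- c("remarks CNS topology written by amberconv",
            "set echo=false end",
            "autogenerate angles=false dihedrals=false end",
            "")
  utypes <- !duplicated(aty)
  topo <- c(topo, sprintf("MASS %-4s %10.5f", aty[utypes],
                          sys$atoms$mass[utypes]), "")
  topo <- c(topo, sprintf("RESIdue %s", resn), "GROUP")
  topo <- c(topo, sprintf("  ATOM %-4s TYPE=%-4s CHARGE=%10.6f END",
                          anm, aty, sys$atoms$charge))
  topo <- c(topo, "")
  for (b in seq_len(nrow(sys$bonds)))
    topo <- c(topo, sprintf("  BOND %-4s %-4s", anm[sys$bonds$ai[b]],
                            anm[sys$bonds$aj[b]]))
  for (a in seq_len(nrow(sys$angles)))
    topo <- c(topo, sprintf("  ANGLe %-4s %-4s %-4s", anm[sys$angles$ai[a]],
                            anm[sys$angles$aj[a]], anm[sys$angles$ak[a]]))
  tor <- sys$torsions
  for (t in seq_len(nrow(tor))) {
    stmt <- if (tor$kind[t] == "improper") "IMPRoper" else "DIHEdral"
    topo <- c(topo, sprintf("  %s %-4s %-4s %-4s %-4s", stmt,
                            anm[tor$ai[t]], anm[tor$aj[t]], anm[tor$ak[t]],
                            anm[tor$al[t]]))
  }
  topo <- c(topo, "END", "")

  par <- c("remarks CNS parameters written by amberconv", "")
  bkey <- vapply(seq_len(nrow(sys$bonds)), function(b)
    .bond_key(aty[sys$bonds$ai[b]], aty[sys$bonds$aj[b]]), character(1))
  btxt <- vapply(seq_len(nrow(sys$bonds)), function(b)
    sprintf("BOND %-4s %-4s %12.6f %10.6f", aty[sys$bonds$ai[b]],
            aty[sys$bonds$aj[b]], sys$bonds$force_k[b], sys$bonds$r_eq[b]),
    character(1))
  par <- c(par, .dedup_params(bkey, btxt, "bond"))
  akey <- vapply(seq_len(nrow(sys$angles)), function(a)
    .angle_key(aty[sys$angles$ai[a]], aty[sys$angles$aj[a]],
               aty[sys$angles$ak[a]]), character(1))
  atxt <- vapply(seq_len(nrow(sys$angles)), function(a)
    sprintf("ANGLe %-4s %-4s %-4s %12.6f %12.6f", aty[sys$angles$ai[a]],
            aty[sys$angles$aj[a]], aty[sys$angles$ak[a]],
            sys$angles$force_k[a], sys$angles$theta_eq[a] * 180 / pi),
    character(1))
  par <- c(par, .dedup_params(akey, atxt, "angle"))
  if (nrow(tor)) {
    stmt <- ifelse(tor$kind == "improper", "IMPRoper", "DIHEdral")
    tkey <- vapply(seq_len(nrow(tor)), function(t) paste0(
      stmt[t], ":", .torsion_key(aty[tor$ai[t]], aty[tor$aj[t]],
                                 aty[tor$ak[t]], aty[tor$al[t]]),
      ":n", tor$periodicity[t]), character(1))
    ttxt <- vapply(seq_len(nrow(tor)), function(t)
      sprintf("%s %-4s %-4s %-4s %-4s %12.6f %2d %12.6f", stmt[t],
              aty[tor$ai[t]], aty[tor$aj[t]], aty[tor$ak[t]], aty[tor$al[t]],
              tor$barrier_half[t], tor$periodicity[t],
              tor$phase[t] * 180 / pi), character(1))
    par <- c(par, .dedup_params(tkey, ttxt, "dihedral"))
  }
  for (t in which(!duplicated(aty))) {
    nb <- .cns_nb(sys$lj_types$A[sys$atom_lj[t]],
                  sys$lj_types$B[sys$atom_lj[t]])
    par <- c(par, sprintf("NONBonded %-4s %12.6f %12.6f %12.6f %12.6f",
                          aty[t], nb[1], nb[2], nb[3], nb[4]))
  }
  par <- c(par, "")

  run <- c("remarks minimal CNS run input written by amberconv",
           "remarks reads topology and parameters, computes one energy",
           sprintf("topology @%s_cns.top end", tolower(resn)),
           sprintf("parameter @%s_cns.par end", tolower(resn)),
           sprintf("segment name=%s molecule name=%s number=1 end end",
                   substr(resn, 1, 4), resn),
           "energy end",
           "stop")
  list(topology = topo, parameters = par, run_input = run)
}
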