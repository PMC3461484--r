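## AMBER prmtop: %VERSION line, then %FLAG <NAME> / %FORMAT(...) sections.
## Parsed natively -- conversion does not shell out to ambpdb or any AMBER
## binary.

## Split a prmtop file into named sections of raw data lines plus the
## declared format. Accepts any %VERSION line; tolerates blank lines and
## trailing whitespace. %COMMENT lines are ignored.
.prmtop_sections <- function(lines) {
  secs <- list()
  cur <- NULL
  for (ln in lines) {
    if (startsWith(ln, "%VERSION") || startsWith(ln, "%COMMENT")) next
    if (startsWith(ln, "%FLAG")) {
      cur <- trimws(sub("^%FLAG", "", ln))
      secs[[cur]] <- list(format = NULL, lines = character())
    } else if (startsWith(ln, "%FORMAT")) {
      if (is.null(cur)) parse_error("%FORMAT before any %FLAG")
      secs[[cur]]$format <- trimws(ln)
    } else if (!is.null(cur)) {
      secs[[cur]]$lines <- c(secs[[cur]]$lines, ln)
    }
  }
  secs
}

## Decode a %FORMAT(20a4) / (10I8) / (5E16.8) declaration
.parse_format <- function(fmt) {
  m <- regmatches(fmt, regexec(
    "\\(\\s*([0-9]+)\\s*([aAiIeEfF])\\s*([0-9]+)(\\.[0-9]+)?\\s*\\)", fmt))[[1]]
  if (length(m) < 4) parse_error(paste("cannot parse format declaration:", fmt))
  list(per_line = as.integer(m[2]), type = tolower(m[3]),
       width = as.integer(m[4]))
}

## Fixed-width slicing of a section's data lines into tokens
.section_values <- function(sec, flag) {
  f <- .parse_format(sec$format)
  out <- character()
  for (ln in sec$lines) {
    if (!nzchar(trimws(ln))) next
    nfield <- ceiling(nchar(ln) / f$width)
    starts <- seq_len(min(nfield, f$per_line))
    for (k in starts) {
      tok <- substr(ln, (k - 1L) * f$width + 1L, k * f$width)
      if (nzchar(trimws(tok)) || f$type == "a") out <- c(out, tok)
    }
  }
  if (f$type == "a") return(out)  # keep padding for names
  v <- suppressWarnings(as.numeric(trimws(out)))
  if (any(is.na(v)))
    parse_error(sprintf("non-numeric value in %%FLAG %s", flag))
  if (f$type == "i") as.integer(round(v)) else v
}

.need_section <- function(secs, flag) {
  if (is.null(secs[[flag]]))
    parse_error(sprintf("prmtop is missing mandatory %%FLAG %s", flag))
  .section_values(secs[[flag]], flag)
}

.check_len <- function(x, n, flag) {
  if (length(x) != n)
    structural_error(sprintf(
      "%%FLAG %s has %d values but POINTERS implies %d",
      flag, length(x), n))
  x
}

#' Read an AMBER prmtop topology file
#'
#' Parses the `%VERSION`/`%FLAG`-sectioned AMBER topology format into a
#' [molecular_system()].  Charges are converted from AMBER internal units to
#' elementary charge (division by 18.2223), bond/angle/dihedral terms are
#' resolved against the in-file parameter arrays, Lennard-Jones like-pair
#' A/B coefficients are extracted per atom type, exclusion lists are
#' symmetrised, and the prmtop sign conventions on dihedral quartets are
#' decoded via [classify_torsions()] (negative fourth index = improper,
#' negative third index = no 1-4 pair).
#'
#' @param path path to a prmtop file
#' @return a [molecular_system()] without coordinates; the prmtop periodic
#'   box flag is available as `attr(x, "ifbox")`
#' @seealso [read_inpcrd()], [write_prmtop()]
#' @export
read_prmtop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  secs <- .prmtop_sections(lines)
  ptr <- .need_section(secs, "POINTERS")
  if (length(ptr) < 24) structural_error("POINTERS block too short")
  natom <- ptr[1]; ntypes <- ptr[2]
  nbonh <- ptr[3]; nbona <- ptr[13]
  ntheth <- ptr[5]; ntheta <- ptr[14]
  nphih <- ptr[7]; nphia <- ptr[15]
  nnb <- ptr[11]; nres <- ptr[12]
  numbnd <- ptr[16]; numang <- ptr[17]; nptra <- ptr[18]
  ifbox <- if (length(ptr) >= 28) ptr[28] else 0L

  title_raw <- if (!is.null(secs[["TITLE"]]))
    trimws(paste(secs[["TITLE"]]$lines, collapse = "")) else ""

  atom_name <- trimws(.check_len(.need_section(secs, "ATOM_NAME"),
                                 natom, "ATOM_NAME"))
  charge <- .check_len(.need_section(secs, "CHARGE"), natom, "CHARGE") /
    .CHARGE_SCALE
  mass <- .check_len(.need_section(secs, "MASS"), natom, "MASS")
  type_idx <- .check_len(.need_section(secs, "ATOM_TYPE_INDEX"),
                         natom, "ATOM_TYPE_INDEX")
  amber_type <- trimws(.check_len(.need_section(secs, "AMBER_ATOM_TYPE"),
                                  natom, "AMBER_ATOM_TYPE"))

  res_label <- trimws(.check_len(.need_section(secs, "RESIDUE_LABEL"),
                                 nres, "RESIDUE_LABEL"))
  res_ptr <- .check_len(.need_section(secs, "RESIDUE_POINTER"),
                        nres, "RESIDUE_POINTER")
  res_of <- findInterval(seq_len(natom), res_ptr)

  ## bonded parameter arrays
  bk <- .check_len(.need_section(secs, "BOND_FORCE_CONSTANT"), numbnd,
                   "BOND_FORCE_CONSTANT")
  br <- .check_len(.need_section(secs, "BOND_EQUIL_VALUE"), numbnd,
                   "BOND_EQUIL_VALUE")
  ak <- .check_len(.need_section(secs, "ANGLE_FORCE_CONSTANT"), numang,
                   "ANGLE_FORCE_CONSTANT")
  at <- .check_len(.need_section(secs, "ANGLE_EQUIL_VALUE"), numang,
                   "ANGLE_EQUIL_VALUE")
  dk <- .check_len(.need_section(secs, "DIHEDRAL_FORCE_CONSTANT"), nptra,
                   "DIHEDRAL_FORCE_CONSTANT")
  dn <- .check_len(.need_section(secs, "DIHEDRAL_PERIODICITY"), nptra,
                   "DIHEDRAL_PERIODICITY")
  dp <- .check_len(.need_section(secs, "DIHEDRAL_PHASE"), nptra,
                   "DIHEDRAL_PHASE")

  ## bonds: prmtop stores (i-1)*3 and a 1-based parameter index
  read_terms <- function(flag, nterms, arity) {
    v <- .check_len(.need_section(secs, flag), nterms * (arity + 1L), flag)
    if (!length(v)) return(matrix(integer(), ncol = arity + 1L))
    matrix(v, ncol = arity + 1L, byrow = TRUE)
  }
  bm <- rbind(read_terms("BONDS_INC_HYDROGEN", nbonh, 2L),
              read_terms("BONDS_WITHOUT_HYDROGEN", nbona, 2L))
  am <- rbind(read_terms("ANGLES_INC_HYDROGEN", ntheth, 3L),
              read_terms("ANGLES_WITHOUT_HYDROGEN", ntheta, 3L))
  dm <- rbind(read_terms("DIHEDRALS_INC_HYDROGEN", nphih, 4L),
              read_terms("DIHEDRALS_WITHOUT_HYDROGEN", nphia, 4L))

  bonds <- if (nrow(bm)) data.frame(
    ai = bm[, 1] %/% 3L + 1L, aj = bm[, 2] %/% 3L + 1L,
    force_k = bk[bm[, 3]], r_eq = br[bm[, 3]]) else .empty_bonds()
  angles <- if (nrow(am)) data.frame(
    ai = am[, 1] %/% 3L + 1L, aj = am[, 2] %/% 3L + 1L,
    ak = am[, 3] %/% 3L + 1L,
    force_k = ak[am[, 4]], theta_eq = at[am[, 4]]) else .empty_angles()

  torsions <- if (nrow(dm)) {
    ## decode the /3 packing but keep the sign flags for classify_torsions
    signed <- dm[, 1:4, drop = FALSE]
    dec <- sign(signed) * (abs(signed) %/% 3L + 1L)
    dec[signed == 0L] <- 1L  # index 1 stores as 0 and is always positive
    p <- dm[, 5]
    classify_torsions(data.frame(
      ai = dec[, 1], aj = dec[, 2], ak = dec[, 3], al = dec[, 4],
      barrier_half = dk[p], periodicity = as.integer(round(dn[p])),
      phase = dp[p]))
  } else .empty_torsions()

  ## Lennard-Jones like-pair coefficients per atom type
  nbidx <- .check_len(.need_section(secs, "NONBONDED_PARM_INDEX"),
                      ntypes * ntypes, "NONBONDED_PARM_INDEX")
  acoef <- .need_section(secs, "LENNARD_JONES_ACOEF")
  bcoef <- .need_section(secs, "LENNARD_JONES_BCOEF")
  lj <- data.frame(type_name = character(ntypes), A = numeric(ntypes),
                   B = numeric(ntypes))
  for (t in seq_len(ntypes)) {
    k <- nbidx[ntypes * (t - 1L) + t]
    lj$A[t] <- acoef[k]; lj$B[t] <- bcoef[k]
    first <- which(type_idx == t)[1]
    lj$type_name[t] <- if (is.na(first)) sprintf("T%d", t) else
      amber_type[first]
  }

  ## exclusion lists (prmtop stores j > i only; zero entry = none)
  nexc <- .check_len(.need_section(secs, "NUMBER_EXCLUDED_ATOMS"),
                     natom, "NUMBER_EXCLUDED_ATOMS")
  exc_flat <- .check_len(.need_section(secs, "EXCLUDED_ATOMS_LIST"),
                         nnb, "EXCLUDED_ATOMS_LIST")
  exclusions <- rep(list(integer()), natom)
  pos <- 1L
  for (i in seq_len(natom)) {
    js <- exc_flat[seq.int(pos, length.out = nexc[i])]
    pos <- pos + nexc[i]
    js <- js[js > 0L]
    for (j in js) {
      exclusions[[i]] <- c(exclusions[[i]], j)
      exclusions[[j]] <- c(exclusions[[j]], i)
    }
  }
  exclusions <- lapply(exclusions, function(v) sort(unique(v)))

  atoms <- data.frame(
    name = atom_name, amber_type = amber_type, charge = charge, mass = mass,
    element = vapply(mass, .element_from_mass, character(1)),
    res_name = res_label[res_of], res_index = res_of,
    stringsAsFactors = FALSE)

  sys <- molecular_system(
    title = title_raw, atoms = atoms, bonds = bonds, angles = angles,
    torsions = torsions, lj_types = lj, atom_lj = type_idx,
    exclusions = exclusions, box = box_spec("none"),
    net_charge = round(sum(charge)))
  attr(sys, "ifbox") <- ifbox
  sys
}
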