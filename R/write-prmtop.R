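## prmtop emission: enables loss-free round trips and programmatic fixtures.

.chunk_lines <- function(tokens, per_line) {
  if (!length(tokens)) return("")
  idx <- split(tokens, (seq_along(tokens) - 1L) %/% per_line)
  vapply(idx, paste0, character(1), collapse = "")
}

.fmt_a4 <- function(x) sprintf("%-4s", substr(x, 1, 4))

## split a free string into the 4-character tokens of an a4 field
.chunk4 <- function(s) {
  if (!nzchar(s)) return("")
  starts <- seq(1L, nchar(s), by = 4L)
  substring(s, starts, pmin(starts + 3L, nchar(s)))
}
.fmt_i8 <- function(x) sprintf("%8d", as.integer(x))
.fmt_e16 <- function(x) sprintf("%16.8E", x)

.emit_section <- function(con, flag, fmt_decl, tokens, per_line) {
  writeLines(sprintf("%%FLAG %s", flag), con)
  writeLines(sprintf("%%FORMAT(%s)", fmt_decl), con)
  writeLines(.chunk_lines(tokens, per_line), con)
}

## dedup parameters to (value table, per-term index)
.param_index <- function(df, cols, digits = 10) {
  if (!nrow(df)) return(list(table = df[0, cols, drop = FALSE],
                             idx = integer()))
  key <- apply(round(df[cols], digits), 1, paste, collapse = "|")
  uk <- unique(key)
  list(table = df[match(uk, key), cols, drop = FALSE],
       idx = match(key, uk))
}

#' Write a molecular system as an AMBER prmtop file
#'
#' Emits the `%VERSION`/`%FLAG` sectioned topology format.  Bonded
#' parameters are deduplicated into the prmtop parameter arrays; dihedral
#' quartets are re-encoded with the prmtop sign conventions; off-diagonal
#' Lennard-Jones coefficients are rebuilt from the like-pair A/B values by
#' Lorentz-Berthelot combination so the file re-reads into an equivalent
#' system.
#'
#' @param sys a fully parameterised [molecular_system()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_prmtop <- function(sys, path) {
  if (!nrow(sys$lj_types) || !length(sys$atom_lj))
    parameter_error("system has no Lennard-Jones tables; cannot write prmtop")
  validate_system(sys)
  n <- nrow(sys$atoms)
  is_h <- sys$atoms$mass < 3.0

  bp <- .param_index(sys$bonds, c("force_k", "r_eq"))
  ap <- .param_index(sys$angles, c("force_k", "theta_eq"))
  dp <- .param_index(sys$torsions, c("barrier_half", "periodicity", "phase"))

  ## term encoding: (i-1)*3 with sign flags on positions 3 (no 1-4) and 4
  ## (improper); a quartet whose third/fourth atom is index 1 is flipped so
  ## the sign flag survives the zero encoding
  enc_tors <- function(tor, idx) {
    if (!nrow(tor)) return(integer())
    out <- integer(0)
    for (r in seq_len(nrow(tor))) {
      q <- c(tor$ai[r], tor$aj[r], tor$ak[r], tor$al[r])
      neg3 <- !tor$generates_14[r] || tor$kind[r] == "improper"
      neg4 <- tor$kind[r] == "improper"
      if ((neg3 && q[3] == 1L) || (neg4 && q[4] == 1L)) q <- rev(q)
      v <- (q - 1L) * 3L
      if (neg3) v[3] <- -v[3]
      if (neg4) v[4] <- -v[4]
      out <- c(out, v, idx[r])
    }
    out
  }
  enc_pair <- function(df, idx)
    if (nrow(df)) as.integer(t(cbind((df$ai - 1L) * 3L, (df$aj - 1L) * 3L,
                                     idx))) else integer()
  enc_trip <- function(df, idx)
    if (nrow(df)) as.integer(t(cbind((df$ai - 1L) * 3L, (df$aj - 1L) * 3L,
                                     (df$ak - 1L) * 3L, idx))) else integer()

  b_h <- is_h[sys$bonds$ai] | is_h[sys$bonds$aj]
  a_h <- is_h[sys$angles$ai] | is_h[sys$angles$aj] | is_h[sys$angles$ak]
  d_h <- if (nrow(sys$torsions))
    is_h[sys$torsions$ai] | is_h[sys$torsions$aj] |
      is_h[sys$torsions$ak] | is_h[sys$torsions$al] else logical()

  ## exclusions: j > i only; empty list encoded as a single 0
  exc_counts <- integer(n); exc_flat <- integer()
  for (i in seq_len(n)) {
    js <- sort(sys$exclusions[[i]][sys$exclusions[[i]] > i])
    if (!length(js)) js <- 0L
    exc_counts[i] <- length(js)
    exc_flat <- c(exc_flat, js)
  }

  ## LJ matrices by Lorentz-Berthelot combination of like-pair values
  ntypes <- nrow(sys$lj_types)
  se <- lapply(seq_len(ntypes), function(t)
    lj_ab_to_sigma_eps(sys$lj_types$A[t], sys$lj_types$B[t]))
  npairs <- ntypes * (ntypes + 1L) / 2L
  acoef <- numeric(npairs); bcoef <- numeric(npairs)
  nbidx <- integer(ntypes * ntypes)
  for (i in seq_len(ntypes)) for (j in seq_len(i)) {
    k <- i * (i - 1L) / 2L + j
    sig <- (se[[i]]$sigma + se[[j]]$sigma) / 2
    eps <- sqrt(se[[i]]$epsilon * se[[j]]$epsilon)
    ab <- sigma_eps_to_lj_ab(sig, eps)
    acoef[k] <- ab$A; bcoef[k] <- ab$B
    nbidx[ntypes * (i - 1L) + j] <- k
    nbidx[ntypes * (j - 1L) + i] <- k
  }

  res_ptr <- which(!duplicated(sys$atoms$res_index))
  nres <- length(res_ptr)
  res_label <- sys$atoms$res_name[res_ptr]

  ptr <- integer(32)
  ptr[1] <- n; ptr[2] <- ntypes
  ptr[3] <- sum(b_h); ptr[4] <- sum(!b_h)
  ptr[5] <- sum(a_h); ptr[6] <- sum(!a_h)
  ptr[7] <- sum(d_h); ptr[8] <- sum(!d_h)
  ptr[11] <- length(exc_flat); ptr[12] <- nres
  ptr[13] <- sum(!b_h); ptr[14] <- sum(!a_h); ptr[15] <- sum(!d_h)
  ptr[16] <- nrow(bp$table); ptr[17] <- nrow(ap$table)
  ptr[18] <- nrow(dp$table); ptr[19] <- ntypes
  ptr[28] <- if (sys$box$kind == "none") 0L else
    if (sys$box$kind == "truncated_octahedron") 2L else 1L

  con <- file(path, "w")
  on.exit(close(con))
  writeLines("%VERSION  VERSION_STAMP = V0001.000  DATE = 01/01/00  00:00:00",
             con)
  ttl <- if (nzchar(sys$title)) sys$title else "converted system"
  .emit_section(con, "TITLE", "20a4", .fmt_a4(.chunk4(ttl)), 20L)
  .emit_section(con, "POINTERS", "10I8", .fmt_i8(ptr), 10L)
  .emit_section(con, "ATOM_NAME", "20a4", .fmt_a4(sys$atoms$name), 20L)
  .emit_section(con, "CHARGE", "5E16.8",
                .fmt_e16(sys$atoms$charge * .CHARGE_SCALE), 5L)
  .emit_section(con, "MASS", "5E16.8", .fmt_e16(sys$atoms$mass), 5L)
  .emit_section(con, "ATOM_TYPE_INDEX", "10I8", .fmt_i8(sys$atom_lj), 10L)
  .emit_section(con, "NUMBER_EXCLUDED_ATOMS", "10I8", .fmt_i8(exc_counts), 10L)
  .emit_section(con, "NONBONDED_PARM_INDEX", "10I8", .fmt_i8(nbidx), 10L)
  .emit_section(con, "RESIDUE_LABEL", "20a4", .fmt_a4(res_label), 20L)
  .emit_section(con, "RESIDUE_POINTER", "10I8", .fmt_i8(res_ptr), 10L)
  .emit_section(con, "BOND_FORCE_CONSTANT", "5E16.8",
                .fmt_e16(bp$table$force_k), 5L)
  .emit_section(con, "BOND_EQUIL_VALUE", "5E16.8", .fmt_e16(bp$table$r_eq), 5L)
  .emit_section(con, "ANGLE_FORCE_CONSTANT", "5E16.8",
                .fmt_e16(ap$table$force_k), 5L)
  .emit_section(con, "ANGLE_EQUIL_VALUE", "5E16.8",
                .fmt_e16(ap$table$theta_eq), 5L)
  .emit_section(con, "DIHEDRAL_FORCE_CONSTANT", "5E16.8",
                .fmt_e16(dp$table$barrier_half), 5L)
  .emit_section(con, "DIHEDRAL_PERIODICITY", "5E16.8",
                .fmt_e16(dp$table$periodicity), 5L)
  .emit_section(con, "DIHEDRAL_PHASE", "5E16.8", .fmt_e16(dp$table$phase), 5L)
  .emit_section(con, "LENNARD_JONES_ACOEF", "5E16.8", .fmt_e16(acoef), 5L)
  .emit_section(con, "LENNARD_JONES_BCOEF", "5E16.8", .fmt_e16(bcoef), 5L)
  .emit_section(con, "BONDS_INC_HYDROGEN", "10I8",
                .fmt_i8(enc_pair(sys$bonds[b_h, , drop = FALSE],
                                 bp$idx[b_h])), 10L)
  .emit_section(con, "BONDS_WITHOUT_HYDROGEN", "10I8",
                .fmt_i8(enc_pair(sys$bonds[!b_h, , drop = FALSE],
                                 bp$idx[!b_h])), 10L)
  .emit_section(con, "ANGLES_INC_HYDROGEN", "10I8",
                .fmt_i8(enc_trip(sys$angles[a_h, , drop = FALSE],
                                 ap$idx[a_h])), 10L)
  .emit_section(con, "ANGLES_WITHOUT_HYDROGEN", "10I8",
                .fmt_i8(enc_trip(sys$angles[!a_h, , drop = FALSE],
                                 ap$idx[!a_h])), 10L)
  .emit_section(con, "DIHEDRALS_INC_HYDROGEN", "10I8",
                .fmt_i8(enc_tors(sys$torsions[d_h, , drop = FALSE],
                                 dp$idx[d_h])), 10L)
  .emit_section(con, "DIHEDRALS_WITHOUT_HYDROGEN", "10I8",
                .fmt_i8(enc_tors(sys$torsions[!d_h, , drop = FALSE],
                                 dp$idx[!d_h])), 10L)
  .emit_section(con, "EXCLUDED_ATOMS_LIST", "10I8", .fmt_i8(exc_flat), 10L)
  .emit_section(con, "AMBER_ATOM_TYPE", "20a4",
                .fmt_a4(sys$atoms$amber_type), 20L)
  invisible(path)
}
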