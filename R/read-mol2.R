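## Tripos MOL2: @<TRIPOS>MOLECULE / ATOM / BOND record blocks.  The charge
## column is honoured (the "user charges" input route); bonds carry
## connectivity and order but no force-field parameters.

.mol2_blocks <- function(lines) {
  starts <- grep("^@<TRIPOS>", lines)
  if (!length(starts)) parse_error("no @<TRIPOS> blocks found")
  blocks <- list()
  for (k in seq_along(starts)) {
    name <- toupper(sub("^@<TRIPOS>", "", trimws(lines[starts[k]])))
    end <- if (k < length(starts)) starts[k + 1L] - 1L else length(lines)
    body <- lines[seq.int(starts[k] + 1L, length.out = max(end - starts[k], 0L))]
    body <- body[nzchar(trimws(body))]
    blocks[[name]] <- body
  }
  blocks
}

#' Read a Tripos MOL2 file
#'
#' Atom names, coordinates, SYBYL (or user) atom types and the per-atom
#' charge column are read; bond connectivity and order are recorded without
#' force-field parameters.  The net charge is left unset: run
#' [guess_net_charge()] on the charge column to obtain it.
#'
#' @param path path to a MOL2 file
#' @return a [molecular_system()] with coordinates and unparameterised
#'   bonds (`force_k`/`r_eq` set to `NA`); bond orders are attached as
#'   `attr(x, "bond_order")`
#' @export
read_mol2 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  blocks <- .mol2_blocks(lines)
  for (need in c("MOLECULE", "ATOM", "BOND"))
    if (is.null(blocks[[need]]))
      parse_error(sprintf("MOL2 is missing the @<TRIPOS>%s block", need))

  title <- trimws(blocks$MOLECULE[1])
  at <- strsplit(trimws(blocks$ATOM), "\\s+")
  ids <- vapply(at, function(f) as.integer(f[1]), integer(1))
  if (anyDuplicated(ids))
    structural_error("duplicate atom ids in @<TRIPOS>ATOM block")
  n <- length(ids)
  name <- vapply(at, `[`, character(1), 2)
  xyz <- t(vapply(at, function(f) as.numeric(f[3:5]), numeric(3)))
  sybyl <- vapply(at, `[`, character(1), 6)
  res_index <- vapply(at, function(f)
    if (length(f) >= 7) as.integer(f[7]) else 1L, integer(1))
  res_name <- vapply(at, function(f)
    if (length(f) >= 8) f[8] else "MOL", character(1))
  charge <- vapply(at, function(f)
    if (length(f) >= 9) as.numeric(f[9]) else 0, numeric(1))
  if (any(is.na(xyz)) || any(is.na(charge)))
    parse_error("non-numeric coordinate or charge field in ATOM block")

  bt <- strsplit(trimws(blocks$BOND), "\\s+")
  bi <- vapply(bt, function(f) as.integer(f[2]), integer(1))
  bj <- vapply(bt, function(f) as.integer(f[3]), integer(1))
  border <- vapply(bt, function(f) f[4], character(1))
  if (any(!c(bi, bj) %in% ids))
    structural_error("bond references an atom id absent from the ATOM block")
  ## map mol2 ids to 1..n row positions
  bi <- match(bi, ids); bj <- match(bj, ids)

  elem <- toupper(sub("\\..*$", "", sybyl))
  elem <- paste0(substr(elem, 1, 1),
                 tolower(substr(elem, 2, nchar(elem))))
  known <- elem %in% names(.ELEMENT_MASS)
  mass <- ifelse(known, .ELEMENT_MASS[elem], 0)
  if (any(!known)) {
    ## fall back on the first letter (e.g. user types like "c3")
    e1 <- paste0(toupper(substr(sybyl, 1, 1)), "")
    mass[!known] <- ifelse(e1[!known] %in% names(.ELEMENT_MASS),
                           .ELEMENT_MASS[e1[!known]], 12.011)
    elem[!known] <- ifelse(e1[!known] %in% names(.ELEMENT_MASS),
                           e1[!known], "C")
  }

  atoms <- data.frame(
    name = name, amber_type = sybyl, charge = charge, mass = as.numeric(mass),
    element = elem, res_name = res_name, res_index = res_index,
    stringsAsFactors = FALSE)
  bonds <- data.frame(ai = pmin(bi, bj), aj = pmax(bi, bj),
                      force_k = NA_real_, r_eq = NA_real_)
  sys <- molecular_system(title = title, atoms = atoms, coords = xyz,
                          bonds = bonds, net_charge = NA_integer_,
                          validate = FALSE)
  validate_system(sys)
  attr(sys, "bond_order") <- border
  sys
}

#' Write a molecular system as a Tripos MOL2 file
#'
#' @param sys a [molecular_system()] with coordinates
#' @param path output path
#' @param bond_order optional character vector of bond orders (defaults to
#'   `"1"` for every bond)
#' @return `path`, invisibly
#' @export
write_mol2 <- function(sys, path, bond_order = NULL) {
  if (is.null(sys$coords)) structural_error("MOL2 output requires coordinates")
  if (is.null(bond_order)) bond_order <- rep("1", nrow(sys$bonds))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@<TRIPOS>MOLECULE", con)
  writeLines(if (nzchar(sys$title)) sys$title else "MOL", con)
  writeLines(sprintf("%5d %5d %5d %5d %5d", nrow(sys$atoms), nrow(sys$bonds),
                     max(sys$atoms$res_index), 0L, 0L), con)
  writeLines("SMALL", con)
  writeLines("USER_CHARGES", con)
  writeLines("@<TRIPOS>ATOM", con)
  for (i in seq_len(nrow(sys$atoms))) {
    writeLines(sprintf("%7d %-8s %10.4f %10.4f %10.4f %-6s %3d %-8s %10.6f",
                       i, sys$atoms$name[i], sys$coords[i, 1],
                       sys$coords[i, 2], sys$coords[i, 3],
                       sys$atoms$amber_type[i], sys$atoms$res_index[i],
                       sys$atoms$res_name[i], sys$atoms$charge[i]), con)
  }
  writeLines("@<TRIPOS>BOND", con)
  for (b in seq_len(nrow(sys$bonds))) {
    writeLines(sprintf("%6d %5d %5d %-2s", b, sys$bonds$ai[b],
                       sys$bonds$aj[b], bond_order[b]), con)
  }
  invisible(path)
}
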