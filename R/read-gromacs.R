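## Reader for the GROMACS topology subset this package emits.  It exists so
## every emitted file is re-parseable in-repo and so the energy oracle can
## compare the source system against what an engine would actually read.

.top_sections <- function(lines) {
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines)
  out <- list()
  cur <- NULL
  for (ln in lines) {
    if (!nzchar(ln)) next
    m <- regmatches(ln, regexec("^\\[\\s*([a-z_]+)\\s*\\]$", ln))[[1]]
    if (length(m) == 2) {
      cur <- m[2]
      if (is.null(out[[cur]])) out[[cur]] <- character()
      next
    }
    if (is.null(cur)) parse_error("topology content before any [ section ]")
    out[[cur]] <- c(out[[cur]], ln)
  }
  out
}

#' Read a GROMACS topology written by this package
#'
#' Parses `[defaults]`, `[atomtypes]`, `[moleculetype]`, `[atoms]`,
#' `[bonds]`, `[pairs]`, `[angles]` and `[dihedrals]` (functions 9, 4 and
#' 3) into a `gromacs_topology` object in engine units (nm, kJ/mol,
#' degrees).  Nonbonded exclusions are rebuilt from the bond graph out to
#' `nrexcl` bonds, matching how the engine generates them.
#'
#' @param path path to a `.top` file
#' @return an object of class `gromacs_topology`: list with `atoms`,
#'   `atomtypes`, `bonds`, `angles`, `dihedrals`, `rb_dihedrals`, `pairs`,
#'   `exclusions`, `fudge_lj`, `fudge_qq`, `nrexcl`, `molecule_name`
#' @seealso [single_point_energy()] with `form = "gromacs_f9"`
#' @export
read_gromacs_top <- function(path) {
  secs <- .top_sections(readLines(path, warn = FALSE))
  for (need in c("defaults", "atomtypes", "atoms"))
    if (is.null(secs[[need]]))
      parse_error(sprintf("topology is missing the [ %s ] section", need))
  tok <- function(ln) strsplit(ln, "\\s+")[[1]]

  df <- tok(secs$defaults[1])
  fudge_lj <- if (length(df) >= 4) as.numeric(df[4]) else .FUDGE_LJ
  fudge_qq <- if (length(df) >= 5) as.numeric(df[5]) else .FUDGE_QQ

  at <- lapply(secs$atomtypes, tok)
  atomtypes <- data.frame(
    name = vapply(at, `[`, character(1), 1),
    sigma = vapply(at, function(f) as.numeric(f[length(f) - 1L]), numeric(1)),
    epsilon = vapply(at, function(f) as.numeric(f[length(f)]), numeric(1)),
    stringsAsFactors = FALSE)

  mt <- if (!is.null(secs$moleculetype)) tok(secs$moleculetype[1]) else
    c("MOL", "3")
  nrexcl <- as.integer(mt[2])

  am <- lapply(secs$atoms, tok)
  atoms <- data.frame(
    type = vapply(am, `[`, character(1), 2),
    res_index = vapply(am, function(f) as.integer(f[3]), integer(1)),
    res_name = vapply(am, `[`, character(1), 4),
    name = vapply(am, `[`, character(1), 5),
    charge = vapply(am, function(f) as.numeric(f[7]), numeric(1)),
    mass = vapply(am, function(f) as.numeric(f[8]), numeric(1)),
    stringsAsFactors = FALSE)
  n <- nrow(atoms)

  parse_rows <- function(sec, ncols) {
    if (is.null(sec)) return(NULL)
    t(vapply(lapply(sec, tok), function(f) as.numeric(f[seq_len(ncols)]),
             numeric(ncols)))
  }
  bm <- parse_rows(secs$bonds, 5L)
  bonds <- if (!is.null(bm)) data.frame(
    ai = as.integer(bm[, 1]), aj = as.integer(bm[, 2]),
    r0 = bm[, 4], k = bm[, 5]) else
    data.frame(ai = integer(), aj = integer(), r0 = numeric(), k = numeric())
  am2 <- parse_rows(secs$angles, 6L)
  angles <- if (!is.null(am2)) data.frame(
    ai = as.integer(am2[, 1]), aj = as.integer(am2[, 2]),
    ak = as.integer(am2[, 3]), theta0_deg = am2[, 5], k = am2[, 6]) else
    data.frame(ai = integer(), aj = integer(), ak = integer(),
               theta0_deg = numeric(), k = numeric())
  pm <- parse_rows(secs$pairs, 2L)
  pairs <- if (!is.null(pm)) data.frame(ai = as.integer(pm[, 1]),
                                        aj = as.integer(pm[, 2])) else
    data.frame(ai = integer(), aj = integer())

  dihedrals <- data.frame(ai = integer(), aj = integer(), ak = integer(),
                          al = integer(), phase_deg = numeric(),
                          k = numeric(), mult = integer(), func = integer())
  rb <- data.frame(ai = integer(), aj = integer(), ak = integer(),
                   al = integer(), C0 = numeric(), C1 = numeric(),
                   C2 = numeric(), C3 = numeric(), C4 = numeric(),
                   C5 = numeric())
  for (ln in secs$dihedrals) {
    f <- tok(ln)
    func <- as.integer(f[5])
    if (func %in% c(9L, 4L, 1L)) {
      dihedrals <- rbind(dihedrals, data.frame(
        ai = as.integer(f[1]), aj = as.integer(f[2]), ak = as.integer(f[3]),
        al = as.integer(f[4]), phase_deg = as.numeric(f[6]),
        k = as.numeric(f[7]), mult = as.integer(f[8]),
        func = if (func == 1L) 9L else func))
    } else if (func == 3L) {
      rb <- rbind(rb, data.frame(
        ai = as.integer(f[1]), aj = as.integer(f[2]), ak = as.integer(f[3]),
        al = as.integer(f[4]), C0 = as.numeric(f[6]), C1 = as.numeric(f[7]),
        C2 = as.numeric(f[8]), C3 = as.numeric(f[9]), C4 = as.numeric(f[10]),
        C5 = as.numeric(f[11])))
    } else {
      parse_error(sprintf("unsupported dihedral function %d", func))
    }
  }

  adj <- .bond_adjacency(n, bonds)
  exclusions <- lapply(seq_len(n), function(i) {
    d <- .graph_dist_from(adj, i, nrexcl)
    sort(which(!is.na(d) & d >= 1L))
  })

  structure(list(
    atoms = atoms, atomtypes = atomtypes, bonds = bonds, angles = angles,
    dihedrals = dihedrals, rb_dihedrals = rb, pairs = pairs,
    exclusions = exclusions, fudge_lj = fudge_lj, fudge_qq = fudge_qq,
    nrexcl = nrexcl, molecule_name = mt[1]),
    class = "gromacs_topology")
}

#' @export
print.gromacs_topology <- function(x, ...) {
  cat(sprintf("<gromacs_topology> %s: %d atoms, %d bonds, %d angles, %d dihedrals, %d pairs\n",
              x$molecule_name, nrow(x$atoms), nrow(x$bonds), nrow(x$angles),
              nrow(x$dihedrals) + nrow(x$rb_dihedrals), nrow(x$pairs)))
  invisible(x)
}

#' Read a GROMACS .gro coordinate file
#'
#' @param path path to a `.gro` file
#' @return list with `coords` (n x 3 matrix, nm), `box` (numeric box-line
#'   components, nm) and `atoms` (names/residues)
#' @export
read_gro <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[2]))
  if (is.na(n)) parse_error("cannot parse atom count in .gro line 2")
  if (length(lines) < 2L + n + 1L)
    structural_error(".gro shorter than its declared atom count")
  body <- lines[3:(2 + n)]
  coords <- matrix(0, n, 3)
  atoms <- data.frame(res_index = integer(n), res_name = character(n),
                      name = character(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ln <- body[i]
    atoms$res_index[i] <- as.integer(substr(ln, 1, 5))
    atoms$res_name[i] <- trimws(substr(ln, 6, 10))
    atoms$name[i] <- trimws(substr(ln, 11, 15))
    coords[i, ] <- as.numeric(c(substr(ln, 21, 28), substr(ln, 29, 36),
                                substr(ln, 37, 44)))
  }
  if (any(is.na(coords))) parse_error("non-numeric coordinate field in .gro")
  box <- as.numeric(strsplit(trimws(lines[2 + n + 1L]), "\\s+")[[1]])
  list(coords = coords, box = box, atoms = atoms)
}
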