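## AMBER parameter files.  frcmod: explicit MASS/BOND/ANGLE/DIHE/IMPROPER/
## NONBON headings.  parm-dat: the positional main-file layout (title, then
## the same record types in fixed order separated by blank lines).  Both
## feed the same section parsers after tokenisation; hyphen-separated type
## fields and the wildcard "X" are normalised there.

#' Construct an empty, labelled parameter source
#'
#' A `parameter_source` holds provenance-tagged lookup tables (mass, bond,
#' angle, proper torsion, improper torsion, Lennard-Jones) keyed by
#' canonicalised atom-type tuples.  Bond and angle keys are
#' order-independent; torsion keys match forward or reversed, with the
#' wildcard `X` allowed in the outer positions.  Ordered lists of sources
#' implement the AMBER99SB-before-GAFF fallback used by
#' [resolve_parameters()].
#'
#' @param label provenance label, e.g. `"GAFF"`, `"AMBER99SB"` or
#'   `"frcmod:<name>"`
#' @return an object of class `parameter_source`
#' @export
parameter_source <- function(label = "unnamed") {
  structure(list(label = label,
                 mass = list(), bond = list(), angle = list(),
                 torsion = list(), improper = list(), lj = list()),
            class = "parameter_source")
}

#' @export
print.parameter_source <- function(x, ...) {
  cat(sprintf("<parameter_source> %s: %d masses, %d bonds, %d angles, %d torsions, %d impropers, %d LJ\n",
              x$label, length(x$mass), length(x$bond), length(x$angle),
              length(x$torsion), length(x$improper), length(x$lj)))
  invisible(x)
}

## ---- canonical keys -------------------------------------------------------

## all canonical orderings use radix (C-locale) collation so keys are
## identical across platforms and locale settings
.rsort <- function(x) sort(x, method = "radix")

.bond_key <- function(a, b) paste(.rsort(c(a, b)), collapse = "-")

.angle_key <- function(a, b, c) {
  ends <- .rsort(c(a, c))
  paste(c(ends[1], b, ends[2]), collapse = "-")
}

## torsion key: radix-lexicographically smaller of forward and reversed
.torsion_key <- function(a, b, c, d) {
  fwd <- paste(c(a, b, c, d), collapse = "-")
  rev <- paste(c(d, c, b, a), collapse = "-")
  .rsort(c(fwd, rev))[1]
}

## improper key: third position is the central atom; outer three sorted
.improper_key <- function(a, b, c, d) {
  outer <- .rsort(c(a, b, d))
  paste(c(outer[1], outer[2], c, outer[3]), collapse = "-")
}

## split an AMBER type tuple field like "X -c3-c3-X " into types
## (fields are fixed width, so spaces may pad each 2-character slot)
.split_types <- function(field, n) {
  parts <- trimws(strsplit(field, "-", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  if (length(parts) != n)
    parse_error(sprintf("expected %d hyphen-separated atom types in '%s'",
                        n, field))
  parts
}

## split a parameter line into (type-tuple field, numeric tokens): the
## tuple is everything before the first whitespace-then-number boundary
.split_param_line <- function(ln) {
  m <- regexpr("\\s+[-+]?[0-9]", ln)
  if (m < 0) return(NULL)
  tuple <- trimws(substr(ln, 1, m - 1L))
  nums <- suppressWarnings(as.numeric(strsplit(
    trimws(substr(ln, m, nchar(ln))), "\\s+")[[1]]))
  list(tuple = tuple, nums = nums[!is.na(nums)])
}

## ---- section parsers ------------------------------------------------------

## each returns entries added into src; torsion lines with negative
## periodicity continue the Fourier series on the following line
.parse_param_sections <- function(src, sections) {
  add_dup_warn <- function(tab, key, what) {
    if (!is.null(tab[[key]]))
      .warn(sprintf("duplicate %s entry for %s: last one wins", what, key))
  }

  for (ln in sections$mass) {
    p <- .split_param_line(ln)
    if (is.null(p) || !length(p$nums)) next
    src$mass[[p$tuple]] <- p$nums[1]
  }
  for (ln in sections$bond) {
    p <- .split_param_line(ln)
    if (is.null(p) || length(p$nums) < 2) next
    tt <- .split_types(p$tuple, 2L)
    key <- .bond_key(tt[1], tt[2])
    add_dup_warn(src$bond, key, "bond")
    src$bond[[key]] <- list(force_k = p$nums[1], r_eq = p$nums[2])
  }
  for (ln in sections$angle) {
    p <- .split_param_line(ln)
    if (is.null(p) || length(p$nums) < 2) next
    tt <- .split_types(p$tuple, 3L)
    key <- .angle_key(tt[1], tt[2], tt[3])
    add_dup_warn(src$angle, key, "angle")
    src$angle[[key]] <- list(force_k = p$nums[1],
                             theta_eq = p$nums[2] * pi / 180)
  }

  ## proper torsions: IDIVF PK PHASE PN; PN < 0 means "series continues"
  pending_key <- NULL; pending_terms <- NULL
  flush_tors <- function() {
    if (!is.null(pending_key)) {
      add_dup_warn(src$torsion, pending_key, "torsion")
      src$torsion[[pending_key]] <<- pending_terms
      pending_key <<- NULL; pending_terms <<- NULL
    }
  }
  for (ln in sections$dihe) {
    p <- .split_param_line(ln)
    if (is.null(p) || length(p$nums) < 4) next
    tt <- .split_types(p$tuple, 4L)
    key <- .torsion_key(tt[1], tt[2], tt[3], tt[4])
    idivf <- p$nums[1]; pk <- p$nums[2]
    phase <- p$nums[3] * pi / 180; pn <- p$nums[4]
    term <- data.frame(barrier_half = pk / idivf,
                       periodicity = as.integer(round(abs(pn))),
                       phase = phase)
    if (is.null(pending_key)) {
      pending_key <- key; pending_terms <- term
    } else if (identical(pending_key, key)) {
      pending_terms <- rbind(pending_terms, term)
    } else {
      flush_tors()
      pending_key <- key; pending_terms <- term
    }
    if (pn >= 0) flush_tors()
  }
  if (!is.null(pending_key))
    structural_error(sprintf(
      "torsion series for %s ends on a negative periodicity (unterminated)",
      pending_key))

  ## impropers: PK PHASE PN (no divider column)
  for (ln in sections$improper) {
    p <- .split_param_line(ln)
    if (is.null(p) || length(p$nums) < 3) next
    tt <- .split_types(p$tuple, 4L)
    key <- .improper_key(tt[1], tt[2], tt[3], tt[4])
    add_dup_warn(src$improper, key, "improper")
    src$improper[[key]] <- data.frame(
      barrier_half = p$nums[1],
      periodicity = as.integer(round(abs(p$nums[3]))),
      phase = p$nums[2] * pi / 180)
  }

  ## nonbonded: TYPE RMIN/2 EPS (AMBER RE form)
  for (ln in sections$nonbon) {
    p <- .split_param_line(ln)
    if (is.null(p) || length(p$nums) < 2) next
    src$lj[[p$tuple]] <- list(rmin_half = p$nums[1], epsilon = p$nums[2])
  }
  src
}

#' Read an AMBER frcmod or parm-dat parameter file
#'
#' @param path path to the parameter file
#' @param dialect `"frcmod"` (MASS/BOND/ANGLE/DIHE/IMPROPER/NONBON section
#'   headings) or `"parm_dat"` (the positional main parameter-file layout)
#' @param label provenance label; defaults to `"frcmod:<basename>"`
#' @return a [parameter_source()]
#' @export
read_frcmod <- function(path, dialect = c("frcmod", "parm_dat"),
                        label = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(label)) label <- paste0("frcmod:", basename(path))
  lines <- readLines(path, warn = FALSE)
  src <- parameter_source(label)
  sections <- list(mass = character(), bond = character(),
                   angle = character(), dihe = character(),
                   improper = character(), nonbon = character())

  if (dialect == "frcmod") {
    headings <- c(MASS = "mass", BOND = "bond", ANGL = "angle",
                  ANGLE = "angle", DIHE = "dihe", IMPR = "improper",
                  IMPROPER = "improper", NONB = "nonbon", NONBON = "nonbon",
                  HBON = "skip")
    cur <- NULL
    for (k in seq_along(lines)) {
      ln <- lines[k]
      t <- trimws(ln)
      if (k == 1L && !toupper(t) %in% c(names(headings))) next  # title line
      if (!nzchar(t)) { cur <- NULL; next }
      word <- toupper(strsplit(t, "\\s+")[[1]][1])
      hit <- names(headings)[vapply(names(headings), function(h)
        startsWith(word, h), logical(1))]
      if (length(hit) && word %in% names(headings)) {
        cur <- headings[[word]]
        next
      }
      if (is.null(cur))
        parse_error(sprintf("unknown frcmod section heading near line %d: '%s'",
                            k, t))
      if (cur != "skip") sections[[cur]] <- c(sections[[cur]], ln)
    }
  } else {
    ## parm-dat positional layout: title / MASS block / hydrophilic-atom
    ## line / BOND / ANGLE / DIHE / IMPROPER / H-bond 10-12 / equivalence
    ## lines / MOD4 marker / NONBON / END
    body <- lines[-1]
    blanks <- which(!nzchar(trimws(body)))
    block_of <- function(i) {
      starts <- c(1L, blanks + 1L)
      ends <- c(blanks - 1L, length(body))
      if (i > length(starts)) return(character())
      body[seq.int(starts[i], length.out = max(ends[i] - starts[i] + 1L, 0L))]
    }
    sections$mass <- block_of(1L)
    bondblk <- block_of(2L)
    ## first line of the bond block is the hydrophilic atom-symbol list
    if (length(bondblk) && !grepl("-", strsplit(trimws(bondblk[1]),
                                                "\\s+")[[1]][1], fixed = TRUE))
      bondblk <- bondblk[-1]
    sections$bond <- bondblk
    sections$angle <- block_of(3L)
    sections$dihe <- block_of(4L)
    sections$improper <- block_of(5L)
    ## remaining blocks: 10-12 H-bond, equivalences, then MOD4/NONBON
    rest <- body[if (length(blanks) >= 5) seq.int(blanks[5] + 1L,
                                                  length(body)) else integer()]
    nb_start <- grep("^(MOD4|NONB)", trimws(rest))
    if (length(nb_start)) {
      nb <- rest[seq.int(nb_start[1] + 1L, length(rest))]
      nb <- nb[!grepl("^END", trimws(nb))]
      sections$nonbon <- nb[nzchar(trimws(nb))]
    }
  }
  .parse_param_sections(src, sections)
}

#' Write a parameter source as an frcmod file
#'
#' Inverse of [read_frcmod()] for the frcmod dialect; round-trips keys and
#' values exactly (identity on re-read).
#'
#' @param src a [parameter_source()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_frcmod <- function(src, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("parameter set %s", src$label), con)
  writeLines("MASS", con)
  for (k in names(src$mass))
    writeLines(sprintf("%-2s %10.5f", k, src$mass[[k]]), con)
  writeLines("", con)
  writeLines("BOND", con)
  for (k in names(src$bond)) {
    tt <- strsplit(k, "-", fixed = TRUE)[[1]]
    writeLines(sprintf("%-2s-%-2s %10.4f %10.5f", tt[1], tt[2],
                       src$bond[[k]]$force_k, src$bond[[k]]$r_eq), con)
  }
  writeLines("", con)
  writeLines("ANGLE", con)
  for (k in names(src$angle)) {
    tt <- strsplit(k, "-", fixed = TRUE)[[1]]
    writeLines(sprintf("%-2s-%-2s-%-2s %10.4f %10.4f", tt[1], tt[2], tt[3],
                       src$angle[[k]]$force_k,
                       src$angle[[k]]$theta_eq * 180 / pi), con)
  }
  writeLines("", con)
  writeLines("DIHE", con)
  for (k in names(src$torsion)) {
    tt <- strsplit(k, "-", fixed = TRUE)[[1]]
    terms <- src$torsion[[k]]
    for (r in seq_len(nrow(terms))) {
      pn <- terms$periodicity[r]
      if (r < nrow(terms)) pn <- -pn  # continuation convention
      writeLines(sprintf("%-2s-%-2s-%-2s-%-2s %4d %10.5f %10.3f %6.1f",
                         tt[1], tt[2], tt[3], tt[4], 1L,
                         terms$barrier_half[r],
                         terms$phase[r] * 180 / pi, as.numeric(pn)), con)
    }
  }
  writeLines("", con)
  writeLines("IMPROPER", con)
  for (k in names(src$improper)) {
    tt <- strsplit(k, "-", fixed = TRUE)[[1]]
    t1 <- src$improper[[k]]
    writeLines(sprintf("%-2s-%-2s-%-2s-%-2s %10.5f %10.3f %6.1f",
                       tt[1], tt[2], tt[3], tt[4], t1$barrier_half,
                       t1$phase * 180 / pi, as.numeric(t1$periodicity)), con)
  }
  writeLines("", con)
  writeLines("NONBON", con)
  for (k in names(src$lj))
    writeLines(sprintf("  %-2s %12.6f %12.6f", k, src$lj[[k]]$rmin_half,
                       src$lj[[k]]$epsilon), con)
  writeLines("", con)
  invisible(path)
}
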