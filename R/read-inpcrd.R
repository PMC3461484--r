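## AMBER inpcrd / restart coordinate files: title line, atom count, then
## fixed-width 12.7 floats six per line, optionally a final box line
## (3 lengths + 3 angles).

.read_fixed_floats <- function(lines, width = 12L) {
  out <- numeric()
  for (k in seq_along(lines)) {
    ln <- lines[k]
    nf <- ceiling(nchar(ln) / width)
    for (i in seq_len(nf)) {
      tok <- trimws(substr(ln, (i - 1L) * width + 1L, i * width))
      if (!nzchar(tok)) next
      v <- suppressWarnings(as.numeric(tok))
      if (is.na(v))
        parse_error(sprintf("non-numeric coordinate field on line %d", k))
      out <- c(out, v)
    }
  }
  out
}

#' Read an AMBER inpcrd / restart coordinate file
#'
#' @param path path to the coordinate file
#' @param has_box whether the final line carries box lengths and angles;
#'   box angles near 109.4712 degrees classify as a truncated octahedron,
#'   near 90 degrees as orthorhombic, anything else as triclinic
#' @return a list with `coords` (n x 3 matrix, Angstrom) and `box`
#'   (a [box_spec()])
#' @export
read_inpcrd <- function(path, has_box = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines)) | FALSE), 0L))]
  if (length(lines) < 2L) parse_error("inpcrd file too short")
  natom <- suppressWarnings(as.integer(strsplit(trimws(lines[2]),
                                                "\\s+")[[1]][1]))
  if (is.na(natom)) parse_error("cannot parse atom count on line 2")
  body <- lines[-(1:2)]
  vals <- .read_fixed_floats(body)
  nbox <- if (has_box) 6L else 0L
  if (length(vals) < 3L * natom + nbox)
    structural_error(sprintf(
      "inpcrd holds %d values but header implies at least %d",
      length(vals), 3L * natom + nbox))
  ## restart files may carry velocities between coordinates and box
  coords <- matrix(vals[seq_len(3L * natom)], ncol = 3L, byrow = TRUE)
  box <- if (has_box) {
    tail6 <- vals[seq.int(length(vals) - 5L, length(vals))]
    .classify_box(tail6[1:3], tail6[4:6])
  } else box_spec("none")
  list(coords = coords, box = box)
}

#' Write coordinates in AMBER inpcrd format
#'
#' @param coords n x 3 matrix of coordinates, Angstrom
#' @param path output path
#' @param title title line
#' @param box optional [box_spec()]; when not `"none"`, a final line with
#'   lengths and angles is appended
#' @return `path`, invisibly
#' @export
write_inpcrd <- function(coords, path, title = "generated", box = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(sprintf("%5d", nrow(coords)), con)
  flat <- as.vector(t(coords))
  toks <- sprintf("%12.7f", flat)
  writeLines(.chunk_lines(toks, 6L), con)
  if (!is.null(box) && box$kind != "none")
    writeLines(paste0(sprintf("%12.7f", c(box$lengths, box$angles)),
                      collapse = ""), con)
  invisible(path)
}
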