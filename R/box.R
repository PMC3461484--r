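#' Convert a periodic box to GROMACS triclinic vectors
#'
#' A truncated octahedron with edge `d` maps to the standard GROMACS
#' orientation `a = (d, 0, 0)`, `b = (-d/3, 2 sqrt(2)/3 d, 0)`,
#' `c = (-d/3, -sqrt(2)/3 d, sqrt(6)/3 d)`: all three vectors have norm `d`
#' and every mutual angle is `arccos(-1/3)`.  Orthorhombic boxes map to a
#' diagonal matrix.  When no box is present, a rectangular cell is built
#' from the coordinate bounding extent plus `2 * clearance` per axis.
#'
#' @param box a [box_spec()]
#' @param coords n x 3 coordinate matrix in Angstrom (required when
#'   `box$kind == "none"`)
#' @param clearance solute-wall clearance in nm used for computed boxes
#'   (default 1.0 nm)
#' @return 3 x 3 matrix of row box vectors in nm
#' @export
convert_box <- function(box, coords = NULL, clearance = 1.0) {
  if (box$kind == "none") {
    if (is.null(coords))
      structural_error("computing a box from extent requires coordinates")
    ext_nm <- (apply(coords, 2, max) - apply(coords, 2, min)) * 0.1
    edges <- ext_nm + 2 * clearance
    return(diag(edges))
  }
  if (box$kind == "orthorhombic")
    return(diag(box$lengths * 0.1))
  if (box$kind == "truncated_octahedron") {
    d <- box$lengths[1] * 0.1
    return(rbind(c(d, 0, 0),
                 c(-d / 3, 2 * sqrt(2) / 3 * d, 0),
                 c(-d / 3, -sqrt(2) / 3 * d, sqrt(6) / 3 * d)))
  }
  structural_error(sprintf(
    "unsupported cell: triclinic box with angles %s deg has no converter",
    paste(format(box$angles), collapse = "/")))
}
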