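#' Load the bundled reference table of 3-site water models
#'
#' The table ships as a versioned plain-text config
#' (`extdata/water_models.txt`) holding the published O/H charges and
#' oxygen Lennard-Jones parameters for TIP3P and SPC/E.
#'
#' @return data.frame with columns `model`, `q_O`, `q_H`, `sigma_O` (nm),
#'   `epsilon_O` (kJ/mol)
#' @export
water_model_table <- function() {
  path <- system.file("extdata", "water_models.txt", package = "amberconv",
                      mustWork = TRUE)
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("model", "q_O", "q_H",
                                         "sigma_O", "epsilon_O"),
                           stringsAsFactors = FALSE)
  tab
}

#' Recognise a TIP3P or SPC/E water residue in a system
#'
#' Matching is by physics, not residue name: a 3-atom O/H/H residue matches
#' a model when its charges agree within 1e-3 e and the oxygen sigma and
#' epsilon within 1e-3 relative against the bundled reference table.  The
#' first matching model is returned; systems without a matching water
#' residue return `"none"`.
#'
#' @param sys a [molecular_system()] with Lennard-Jones tables assigned
#' @return `"TIP3P"`, `"SPCE"` or `"none"`
#' @export
recognize_water <- function(sys) {
  tab <- water_model_table()
  res_ids <- unique(sys$atoms$res_index)
  for (res in res_ids) {
    rows <- which(sys$atoms$res_index == res)
    if (length(rows) != 3L) next
    el <- sys$atoms$element[rows]
    if (sum(el == "O") != 1L || sum(el == "H") != 2L) next
    o <- rows[el == "O"]; h <- rows[el == "H"]
    if (!length(sys$atom_lj) || !nrow(sys$lj_types)) next
    se <- lj_ab_to_sigma_eps(sys$lj_types$A[sys$atom_lj[o]],
                             sys$lj_types$B[sys$atom_lj[o]])
    for (m in seq_len(nrow(tab))) {
      q_ok <- abs(sys$atoms$charge[o] - tab$q_O[m]) <= 1e-3 &&
        all(abs(sys$atoms$charge[h] - tab$q_H[m]) <= 1e-3)
      lj_ok <- se$sigma > 0 &&
        abs(se$sigma - tab$sigma_O[m]) / tab$sigma_O[m] <= 1e-3 &&
        abs(se$epsilon - tab$epsilon_O[m]) / tab$epsilon_O[m] <= 1e-3
      if (q_ok && lj_ok) return(tab$model[m])
    }
  }
  "none"
}
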