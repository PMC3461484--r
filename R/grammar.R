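## Line-grammar validators for the CNS and CHARMM dialects.  No reader
## exists in-repo for these engines, so emitted files are checked against a
## statement grammar instead: every non-comment line must match one of the
## allowed statement patterns, with numeric fields where numbers are
## expected and (for CNS) no lowercase letters inside atom/type name
## fields.

.NUM_RE <- "[-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?"
.CNS_NAME <- "[A-Z0-9_'*+]+"

.grammar_check <- function(lines, patterns, skip_re) {
  bad <- list()
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (!nzchar(ln) || grepl(skip_re, ln)) next
    if (!any(vapply(patterns, function(p) grepl(p, ln), logical(1))))
      bad[[length(bad) + 1L]] <- data.frame(
        line = k, text = lines[k],
        reason = "line matches no allowed statement pattern",
        stringsAsFactors = FALSE)
  }
  if (length(bad)) do.call(rbind, bad) else
    data.frame(line = integer(), text = character(), reason = character(),
               stringsAsFactors = FALSE)
}

#' Validate text against the CNS statement grammar
#'
#' @param lines character vector of file lines
#' @param role `"topology"`, `"parameters"` or `"run_input"`
#' @return data.frame of violations (`line`, `text`, `reason`); zero rows
#'   means the text conforms
#' @export
validate_cns_text <- function(lines,
                              role = c("topology", "parameters", "run_input")) {
  role <- match.arg(role)
  n <- .CNS_NAME; x <- .NUM_RE
  patterns <- switch(role,
    topology = c(
      "^set echo=(true|false) end$",
      "^autogenerate angles=(true|false) dihedrals=(true|false) end$",
      sprintf("^MASS %s\\s+%s$", n, x),
      sprintf("^RESIdue %s$", n),
      "^GROUP$",
      sprintf("^ATOM %s\\s+TYPE=%s\\s+CHARGE=\\s*%s END$", n, n, x),
      sprintf("^BOND %s\\s+%s$", n, n),
      sprintf("^ANGLe %s\\s+%s\\s+%s$", n, n, n),
      sprintf("^DIHEdral %s(\\s+%s){3}$", n, n),
      sprintf("^IMPRoper %s(\\s+%s){3}$", n, n),
      "^END$"),
    parameters = c(
      sprintf("^BOND %s\\s+%s\\s+%s\\s+%s$", n, n, x, x),
      sprintf("^ANGLe %s\\s+%s\\s+%s\\s+%s\\s+%s$", n, n, n, x, x),
      sprintf("^DIHEdral %s(\\s+%s){3}\\s+%s\\s+[0-9]+\\s+%s$", n, n, x, x),
      sprintf("^IMPRoper %s(\\s+%s){3}\\s+%s\\s+[0-9]+\\s+%s$", n, n, x, x),
      sprintf("^NONBonded %s(\\s+%s){4}$", n, x)),
    run_input = c(
      "^topology @\\S+ end$",
      "^parameter @\\S+ end$",
      sprintf("^segment name=%s molecule name=%s number=[0-9]+ end end$", n, n),
      "^energy end$",
      "^stop$"))
  ## normalise whitespace so the format widths don't matter to the grammar
  norm <- gsub("\\s+", " ", trimws(lines))
  viol <- .grammar_check(norm, patterns, skip_re = "^remarks")
  ## CNS: atom/type fields must not contain lowercase (checked on the raw
  ## statement keywords' argument fields)
  for (k in seq_along(norm)) {
    ln <- norm[k]
    if (grepl("^(ATOM|BOND|ANGLe|DIHEdral|IMPRoper|MASS|NONBonded) ", ln)) {
      args <- sub("^(ATOM|BOND|ANGLe|DIHEdral|IMPRoper|MASS|NONBonded) ", "",
                  ln)
      fields <- strsplit(args, " ")[[1]]
      namefields <- fields[!grepl(sprintf("^%s$", .NUM_RE), fields) &
                             !grepl("^(TYPE|CHARGE)=", fields) &
                             fields != "END"]
      if (any(grepl("[a-z]", namefields)))
        viol <- rbind(viol, data.frame(
          line = k, text = lines[k],
          reason = "lowercase character in CNS atom/type name",
          stringsAsFactors = FALSE))
    }
  }
  viol
}

#' Validate text against the CHARMM rtf/prm statement grammar
#'
#' @param lines character vector of file lines
#' @param role `"rtf"` or `"prm"`
#' @return data.frame of violations; zero rows means the text conforms
#' @export
validate_charmm_text <- function(lines, role = c("rtf", "prm")) {
  role <- match.arg(role)
  x <- .NUM_RE; n <- "[A-Za-z0-9_'*+]+"
  patterns <- switch(role,
    rtf = c(
      "^[0-9]+ [0-9]+$",
      sprintf("^MASS -?[0-9]+ %s %s$", n, x),
      sprintf("^RESI %s %s$", n, x),
      "^GROUP$",
      sprintf("^ATOM %s %s %s$", n, n, x),
      sprintf("^BOND( %s %s)+$", n, n),
      sprintf("^IMPR %s %s %s %s$", n, n, n, n),
      "^PATCHING FIRS NONE LAST NONE$",
      "^END$"),
    prm = c(
      "^(BONDS|ANGLES|DIHEDRALS|IMPROPER|NONBONDED)$",
      sprintf("^%s %s %s %s$", n, n, x, x),
      sprintf("^%s %s %s %s %s$", n, n, n, x, x),
      sprintf("^%s %s %s %s %s [0-9]+ %s$", n, n, n, n, x, x),
      sprintf("^%s %s %s %s$", n, x, x, x),
      "^END$"))
  norm <- gsub("\\s+", " ", trimws(lines))
  .grammar_check(norm, patterns, skip_re = "^\\*")
}
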