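## Classed conditions so callers (and the CLI) can map failure modes to
## exit codes without string matching.

.abort <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "amberconv_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

parse_error <- function(msg, ...) .abort(msg, "amberconv_parse_error", ...)
structural_error <- function(msg, ...) .abort(msg, "amberconv_structural_error", ...)
geometry_error <- function(msg, ...) .abort(msg, "amberconv_geometry_error", ...)
parameter_error <- function(msg, ...) .abort(msg, "amberconv_parameter_error", ...)
capability_error <- function(msg, ...) .abort(msg, "amberconv_capability_error", ...)
timeout_error <- function(msg, ...) .abort(msg, "amberconv_timeout_error", ...)

.warn <- function(msg, class = "amberconv_warning") {
  warning(structure(
    class = c(class, "amberconv_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

## machine-readable reason codes used by the pipeline run report
.EXIT_CODES <- c(
  ok = 0L,
  amberconv_parse_error = 2L,
  amberconv_structural_error = 2L,
  amberconv_geometry_error = 3L,
  amberconv_parameter_error = 4L,
  amberconv_capability_error = 5L,
  amberconv_timeout_error = 6L
)

#' Map a condition to the converter's exit-code convention
#'
#' Exit codes: 0 ok, 2 input/parse error, 3 geometry violation,
#' 4 missing parameters, 5 external tool unavailable/failed, 6 timeout.
#'
#' @param cond a condition object (or `NULL` for success)
#' @return integer exit code
#' @export
exit_code_for <- function(cond) {
  if (is.null(cond)) return(0L)
  for (cl in class(cond)) {
    if (cl %in% names(.EXIT_CODES)) return(.EXIT_CODES[[cl]])
  }
  2L
}
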