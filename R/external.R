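#' Invoke an optional external AmberTools-style binary
#'
#' External tools (antechamber, tleap, sqm, obabel) are strictly optional:
#' every self-contained code path works without them.  The subprocess runs
#' in an isolated scratch directory with stdout/stderr captured and a
#' wall-clock limit enforced.  A missing binary raises a capability error
#' (distinct from parse errors and from tool failure); exceeding the limit
#' raises a timeout error with partial logs retained.
#'
#' @param tool tool name, looked up on `PATH` unless `binary` is given
#' @param args character vector of arguments
#' @param timeout wall-clock limit in seconds (default 3600)
#' @param binary explicit path to the executable (overrides `PATH` lookup)
#' @param input_files named character vector of files copied into the
#'   scratch directory before the run
#' @return list with `status`, `stdout`, `stderr`, `workdir` and `files`
#'   (paths of files produced in the scratch directory)
#' @export
invoke_external <- function(tool, args = character(), timeout = 3600,
                            binary = NULL, input_files = NULL) {
  if (timeout <= 0) structural_error("timeout must be positive")
  exe <- if (!is.null(binary)) binary else unname(Sys.which(tool))
  if (!nzchar(exe) || !file.exists(exe))
    capability_error(sprintf(
      "external tool '%s' is not installed or not on PATH", tool))

  wd <- tempfile(paste0("ext_", tool, "_"))
  dir.create(wd)
  if (!is.null(input_files))
    file.copy(input_files, file.path(wd, basename(input_files)))
  out_f <- file.path(wd, ".stdout"); err_f <- file.path(wd, ".stderr")

  owd <- setwd(wd)
  on.exit(setwd(owd))
  status <- suppressWarnings(
    system2(exe, args, stdout = out_f, stderr = err_f, timeout = timeout))
  setwd(owd)
  on.exit()

  so <- if (file.exists(out_f)) readLines(out_f, warn = FALSE) else character()
  se <- if (file.exists(err_f)) readLines(err_f, warn = FALSE) else character()
  if (identical(status, 124L))
    timeout_error(sprintf("'%s' exceeded the %ds wall-clock limit", tool,
                          timeout),
                  stdout = so, stderr = se)
  copied <- if (is.null(input_files)) character() else
    file.path(wd, basename(input_files))
  produced <- setdiff(list.files(wd, full.names = TRUE),
                      c(out_f, err_f, copied))
  list(status = status, stdout = so, stderr = se, workdir = wd,
       files = produced)
}
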