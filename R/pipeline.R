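#' Build a conversion run configuration
#'
#' @param input_path input coordinate file (MOL2 for the self-contained
#'   route; PDB/MDL need an external conversion tool)
#' @param net_charge optional integer net charge; when given it is checked
#'   against the charge column
#' @param forcefield_mode `"gaff"` (default) or `"amber"`; with `"amber"`,
#'   parameters are looked up in the AMBER-protein source first and fall
#'   back to the general source
#' @param charge_mode `"user"` (MOL2 charge column), `"bcc"` or `"gas"`
#'   (both delegate to an external antechamber)
#' @param outputs subset of `c("gromacs", "cns", "charmm")`
#' @param param_files frcmod paths forming the parameter source chain,
#'   highest priority first; defaults to the bundled synthetic subset
#' @param timeout per-external-invocation wall clock limit, seconds
#' @param seed integer seed recorded in the run manifest
#' @param clearance box clearance in nm for computed boxes
#' @param out_dir parent directory for the output folder (default: next to
#'   the input)
#' @param engine_binaries optional named character vector of explicit tool
#'   paths
#' @return an object of class `run_config`
#' @export
run_config <- function(input_path, net_charge = NULL,
                       forcefield_mode = c("gaff", "amber"),
                       charge_mode = c("user", "bcc", "gas"),
                       outputs = c("gromacs", "cns", "charmm"),
                       param_files = NULL, timeout = 3600, seed = 42L,
                       clearance = 1.0, out_dir = NULL,
                       engine_binaries = NULL) {
  forcefield_mode <- match.arg(forcefield_mode)
  charge_mode <- match.arg(charge_mode)
  outputs <- match.arg(outputs, several.ok = TRUE)
  if (timeout <= 0) structural_error("timeout must be positive")
  ext <- tolower(tools::file_ext(input_path))
  if (charge_mode == "user" && ext != "mol2")
    structural_error("charge_mode 'user' requires a MOL2 input with a charge column")
  if (is.null(param_files))
    param_files <- system.file("extdata", "gaff_subset_synthetic.frcmod",
                               package = "amberconv", mustWork = TRUE)
  structure(list(
    input_path = input_path, net_charge = net_charge,
    forcefield_mode = forcefield_mode, charge_mode = charge_mode,
    outputs = outputs, param_files = param_files, timeout = timeout,
    seed = as.integer(seed), clearance = clearance, out_dir = out_dir,
    engine_binaries = engine_binaries), class = "run_config")
}

.engine_output_set <- function(engine, files) {
  structure(list(engine = engine, files = files),
            class = "engine_output_set")
}

#' @export
print.engine_output_set <- function(x, ...) {
  cat(sprintf("<engine_output_set> %s: %s\n", x$engine,
              paste(names(x$files), collapse = ", ")))
  invisible(x)
}

.write_output_folder <- function(folder, outputs, manifest) {
  dir.create(folder, recursive = TRUE, showWarnings = FALSE)
  for (os in outputs) {
    for (role in names(os$files)) {
      fn <- switch(paste(os$engine, role),
        "gromacs topology" = "MOL_GMX.top",
        "gromacs coordinates" = "MOL_GMX.gro",
        "cns topology" = "MOL_CNS.top",
        "cns parameters" = "MOL_CNS.par",
        "cns run-input" = "MOL_CNS.inp",
        "charmm topology" = "MOL_CHARMM.rtf",
        "charmm parameters" = "MOL_CHARMM.prm",
        paste0(os$engine, "_", role, ".txt"))
      writeLines(os$files[[role]], file.path(folder, fn))
    }
  }
  writeLines(manifest, file.path(folder, "manifest.txt"))
  folder
}

## obtain per-atom charges according to charge_mode
.obtain_charges <- function(sys, config) {
  if (config$charge_mode == "user") return(sys)
  tool <- "antechamber"
  bin <- config$engine_binaries[[tool]]
  res <- invoke_external(
    tool,
    c("-i", config$input_path, "-fi", tools::file_ext(config$input_path),
      "-o", "charged.mol2", "-fo", "mol2", "-c",
      config$charge_mode, "-nc",
      as.character(if (is.null(config$net_charge)) 0L else config$net_charge)),
    timeout = config$timeout, binary = bin)
  if (res$status != 0L)
    capability_error(sprintf("antechamber failed (status %d)", res$status))
  charged <- file.path(res$workdir, "charged.mol2")
  if (!file.exists(charged))
    capability_error("antechamber produced no charged MOL2")
  newsys <- read_mol2(charged)
  sys$atoms$charge <- newsys$atoms$charge
  sys
}

#' Run the full small-molecule conversion pipeline
#'
#' Reads the input structure, screens covalent geometry (aborting on any
#' bond outside the 0.5-3.0 Angstrom window), obtains charges, guesses and
#' verifies the net charge, resolves parameters through the configured
#' source chain, generates 1-4 pairs and exclusions, writes the requested
#' engine outputs into a per-run folder `<basename>.ff<mode>/` with a
#' manifest, and certifies the GROMACS conversion with the single-point
#' energy oracle.
#'
#' @param config a [run_config()]
#' @return list with `outputs` (engine output sets), `report` (net charge,
#'   geometry, water model, fidelity comparison), `folder` (output path)
#' @export
run_convert <- function(config) {
  ext <- tolower(tools::file_ext(config$input_path))
  if (!file.exists(config$input_path))
    parse_error(sprintf("input file not found: %s", config$input_path))
  sys <- if (ext == "mol2") {
    read_mol2(config$input_path)
  } else if (ext %in% c("pdb", "mdl", "mol", "sdf")) {
    res <- invoke_external("obabel",
                           c(config$input_path, "-O", "converted.mol2"),
                           timeout = config$timeout,
                           binary = config$engine_binaries[["obabel"]])
    conv <- file.path(res$workdir, "converted.mol2")
    if (!file.exists(conv))
      capability_error("external conversion to MOL2 produced no file")
    read_mol2(conv)
  } else {
    parse_error(sprintf("unsupported input format '.%s' (need MOL2/PDB/MDL)",
                        ext))
  }

  geo <- validate_geometry(sys)
  if (!geo$pass)
    geometry_error(paste0(
      "input geometry violates the covalent-distance rules: ",
      paste(sprintf("bond %d-%d at %.2f A (%s)", geo$violations$ai,
                    geo$violations$aj, geo$violations$distance,
                    geo$violations$rule), collapse = "; ")))

  sys <- .obtain_charges(sys, config)
  guessed <- guess_net_charge(sys$atoms$charge)
  if (!is.null(config$net_charge) && guessed != config$net_charge)
    parameter_error(sprintf(
      "declared net charge %d but charges sum to %d", config$net_charge,
      guessed))
  sys$net_charge <- guessed

  sources <- lapply(config$param_files, read_frcmod)
  sys <- resolve_parameters(sys, sources)

  outputs <- list()
  report <- list(net_charge = guessed, geometry = geo,
                 water_model = recognize_water(sys))
  if ("gromacs" %in% config$outputs) {
    top <- write_gromacs_top(sys)
    gro <- write_gro(sys$coords,
                     box_vectors = convert_box(sys$box, sys$coords,
                                               config$clearance),
                     atoms = sys$atoms, title = sys$title)
    outputs[[length(outputs) + 1L]] <-
      .engine_output_set("gromacs", list(topology = top, coordinates = gro))
    report$fidelity <- compare_conversion(sys)
  }
  if ("cns" %in% config$outputs) {
    cns <- write_cns(sys)
    outputs[[length(outputs) + 1L]] <-
      .engine_output_set("cns", list(topology = cns$topology,
                                     parameters = cns$parameters,
                                     "run-input" = cns$run_input))
  }
  if ("charmm" %in% config$outputs) {
    ch <- write_charmm(sys)
    outputs[[length(outputs) + 1L]] <-
      .engine_output_set("charmm", list(topology = ch$rtf,
                                        parameters = ch$prm))
  }

  base <- tools::file_path_sans_ext(basename(config$input_path))
  parent <- if (is.null(config$out_dir)) dirname(config$input_path) else
    config$out_dir
  folder <- file.path(parent, sprintf("%s.ff%s", base,
                                      config$forcefield_mode))
  manifest <- c(
    sprintf("input=%s", basename(config$input_path)),
    sprintf("forcefield_mode=%s", config$forcefield_mode),
    sprintf("charge_mode=%s", config$charge_mode),
    sprintf("net_charge=%d", guessed),
    sprintf("water_model=%s", report$water_model),
    sprintf("seed=%d", config$seed),
    if (!is.null(report$fidelity))
      sprintf("fidelity_max_rel_diff=%.3e", report$fidelity$max_rel_diff),
    sprintf("outputs=%s", paste(config$outputs, collapse = ",")))
  .write_output_folder(folder, outputs, manifest)
  list(outputs = outputs, report = report, folder = folder)
}

#' Convert a prmtop/inpcrd pair to a GROMACS topology and coordinates
#'
#' The self-contained AMBER-to-GROMACS route: no external binaries are
#' involved.  Truncated-octahedron boxes are converted to triclinic
#' vectors; when the pair has no box, a rectangular cell is computed from
#' the coordinate extent plus `2 * clearance` per axis.  A recognised
#' TIP3P or SPC/E water is reported in the topology header and manifest.
#'
#' @param prmtop_path path to the prmtop
#' @param inpcrd_path path to the inpcrd
#' @param clearance box clearance in nm for computed boxes (default 1.0)
#' @param out_dir optional folder to write `MOL_GMX.top` / `MOL_GMX.gro`
#'   and a manifest into
#' @return list with `system` (the parsed [molecular_system()] with
#'   coordinates and box), `output` (a gromacs engine output set),
#'   `water_model`, `box_vectors` and `fidelity` (oracle comparison)
#' @export
run_amb2gmx <- function(prmtop_path, inpcrd_path, clearance = 1.0,
                        out_dir = NULL) {
  sys <- read_prmtop(prmtop_path)
  crd <- read_inpcrd(inpcrd_path, has_box = attr(sys, "ifbox") > 0L)
  if (nrow(crd$coords) != nrow(sys$atoms))
    structural_error(sprintf(
      "prmtop has %d atoms but inpcrd has %d", nrow(sys$atoms),
      nrow(crd$coords)))
  sys$coords <- crd$coords
  sys$box <- crd$box
  validate_system(sys)

  bv <- convert_box(sys$box, sys$coords, clearance)
  wm <- recognize_water(sys)
  top <- write_gromacs_top(sys)
  gro <- write_gro(sys$coords, box_vectors = bv, atoms = sys$atoms,
                   title = sys$title)
  fid <- compare_conversion(sys)
  out <- .engine_output_set("gromacs",
                            list(topology = top, coordinates = gro))
  if (!is.null(out_dir)) {
    manifest <- c(sprintf("input=%s + %s", basename(prmtop_path),
                          basename(inpcrd_path)),
                  sprintf("water_model=%s", wm),
                  sprintf("box=%s", sys$box$kind),
                  sprintf("fidelity_max_rel_diff=%.3e", fid$max_rel_diff))
    .write_output_folder(out_dir, list(out), manifest)
  }
  list(system = sys, output = out, water_model = wm, box_vectors = bv,
       fidelity = fid)
}
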