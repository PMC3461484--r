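## Deterministic toy molecular systems used as fixtures throughout the
## package: a TIP3P water, methane, a 4-atom chain with a single torsion,
## and a 6-ring exercising ring 1-4 deduplication.  Parameters live in one
## internal table shared by the system builder and the bundled synthetic
## frcmod, so the prmtop and MOL2+frcmod input routes stay consistent.

.TOY_PARAMS <- list(
  mass = list(OW = 16.00, HW = 1.008, c3 = 12.01, hc = 1.008, ca = 12.01),
  ## force_k kcal/mol/A^2, r_eq A
  bond = list("HW-OW" = c(553.0, 0.9572), "c3-hc" = c(337.3, 1.0920),
              "c3-c3" = c(300.9, 1.5350), "ca-ca" = c(478.4, 1.3870)),
  ## force_k kcal/mol/rad^2, theta deg
  angle = list("HW-OW-HW" = c(100.0, 104.52), "hc-c3-hc" = c(39.43, 107.58),
               "c3-c3-c3" = c(63.21, 110.63), "ca-ca-ca" = c(67.18, 120.0)),
  ## barrier_half kcal/mol, phase deg, periodicity
  torsion = list("X-c3-c3-X" = c(1.40, 0.0, 3), "X-ca-ca-X" = c(3.625, 180.0, 2)),
  ## A kcal A^12/mol, B kcal A^6/mol (like pair)
  lj = list(OW = c(582000.0, 595.0), HW = c(0, 0),
            c3 = c(1043080.2, 675.61247), hc = c(8908.5219, 21.817434),
            ca = c(819971.66, 531.10286))
)

.toy_lj_table <- function(types) {
  data.frame(type_name = types,
             A = vapply(types, function(t) .TOY_PARAMS$lj[[t]][1], numeric(1)),
             B = vapply(types, function(t) .TOY_PARAMS$lj[[t]][2], numeric(1)),
             stringsAsFactors = FALSE)
}

.toy_bond <- function(ai, aj, key) {
  p <- .TOY_PARAMS$bond[[key]]
  data.frame(ai = ai, aj = aj, force_k = p[1], r_eq = p[2])
}

.toy_angle <- function(ai, aj, ak, key) {
  p <- .TOY_PARAMS$angle[[key]]
  data.frame(ai = ai, aj = aj, ak = ak, force_k = p[1],
             theta_eq = p[2] * pi / 180)
}

.toy_torsion <- function(ai, aj, ak, al, key, kind = "proper",
                         generates_14 = TRUE) {
  p <- .TOY_PARAMS$torsion[[key]]
  data.frame(ai = ai, aj = aj, ak = ak, al = al, barrier_half = p[1],
             periodicity = as.integer(p[3]), phase = p[2] * pi / 180,
             kind = kind, generates_14 = generates_14 && kind == "proper",
             stringsAsFactors = FALSE)
}

#' The toy-fixture parameter set as a parameter source
#'
#' Synthetic parameter tables (values in plausible general-force-field
#' ranges, defined in this package) covering exactly the atom types used by
#' [generate_toy_system()].  The same tables ship as
#' `extdata/gaff_subset_synthetic.frcmod`.
#'
#' @return a [parameter_source()] labelled `"toy_gaff_subset"`
#' @export
toy_parameter_source <- function() {
  src <- parameter_source("toy_gaff_subset")
  src$mass <- .TOY_PARAMS$mass
  for (k in names(.TOY_PARAMS$bond)) {
    p <- .TOY_PARAMS$bond[[k]]
    tt <- strsplit(k, "-", fixed = TRUE)[[1]]
    src$bond[[.bond_key(tt[1], tt[2])]] <- list(force_k = p[1], r_eq = p[2])
  }
  for (k in names(.TOY_PARAMS$angle)) {
    p <- .TOY_PARAMS$angle[[k]]
    tt <- strsplit(k, "-", fixed = TRUE)[[1]]
    src$angle[[.angle_key(tt[1], tt[2], tt[3])]] <-
      list(force_k = p[1], theta_eq = p[2] * pi / 180)
  }
  for (k in names(.TOY_PARAMS$torsion)) {
    p <- .TOY_PARAMS$torsion[[k]]
    tt <- strsplit(k, "-", fixed = TRUE)[[1]]
    src$torsion[[.torsion_key(tt[1], tt[2], tt[3], tt[4])]] <-
      data.frame(barrier_half = p[1], periodicity = as.integer(p[3]),
                 phase = p[2] * pi / 180)
  }
  for (t in names(.TOY_PARAMS$lj)) {
    ab <- .TOY_PARAMS$lj[[t]]
    if (ab[1] == 0) {
      src$lj[[t]] <- list(rmin_half = 0, epsilon = 0)
    } else {
      src$lj[[t]] <- list(rmin_half = (2 * ab[1] / ab[2])^(1 / 6) / 2,
                          epsilon = ab[2]^2 / (4 * ab[1]))
    }
  }
  src
}

## place atom D given A-B-C positions, bond |CD|, angle BCD (rad),
## dihedral ABCD (rad)
.place_zmat <- function(a, b, c_, bond, angle, dihedral) {
  bc <- c_ - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- ab - sum(ab * bc) * bc
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- -n * cos(dihedral) + m * sin(dihedral)
  c_ + bond * (-cos(angle) * bc + sin(angle) * d2)
}

.toy_coords <- function(name) {
  deg <- pi / 180
  switch(name,
    water_tip3p = {
      r <- 0.9572; th <- 104.52 * deg
      rbind(c(0, 0, 0), c(r, 0, 0), c(r * cos(th), r * sin(th), 0))
    },
    methane = {
      r <- 1.0920 / sqrt(3)
      rbind(c(0, 0, 0), r * c(1, 1, 1), r * c(1, -1, -1),
            r * c(-1, 1, -1), r * c(-1, -1, 1))
    },
    chain4 = {
      r <- 1.5350; th <- 110.63 * deg
      p1 <- c(0, 0, 0); p2 <- c(r, 0, 0)
      p3 <- p2 + r * c(-cos(th), sin(th), 0)
      p4 <- .place_zmat(p1, p2, p3, r, th, 60 * deg)
      rbind(p1, p2, p3, p4)
    },
    ring6 = {
      R <- 1.3870
      t(vapply(0:5, function(k)
        c(R * cos(k * 60 * deg), R * sin(k * 60 * deg), 0), numeric(3)))
    })
}

#' Generate a deterministic toy molecular system with serialized files
#'
#' Builds one of four small fixture systems fully in code, applies a small
#' seeded coordinate jitter (at most 0.02 Angstrom per component, keeping
#' all bond lengths within the 0.9-1.6 Angstrom sanity range) and
#' serializes it through the package's own writers:
#'
#' * `water_tip3p` - one TIP3P water (2 bonds, 1 angle, zero-LJ hydrogens)
#' * `methane` - CH4 (4 bonds, 6 angles, no torsions)
#' * `chain4` - a 4-atom carbon chain with exactly one proper torsion
#' * `ring6` - a bare aromatic 6-ring whose six ring torsions deduplicate
#'   to three para 1-4 pairs, plus one improper
#'
#' @param name one of `"water_tip3p"`, `"methane"`, `"chain4"`, `"ring6"`
#' @param seed integer seed for the coordinate jitter (default 42); the
#'   same `(name, seed)` always yields byte-identical serializations
#' @return list with `system` (a [molecular_system()] with coordinates),
#'   and character-vector file texts `prmtop`, `inpcrd`, `mol2`, `frcmod`
#' @export
generate_toy_system <- function(name, seed = 42L) {
  valid <- c("water_tip3p", "methane", "chain4", "ring6")
  if (!name %in% valid)
    .abort(sprintf("unknown toy system '%s'; valid names: %s", name,
                   paste(valid, collapse = ", ")), "amberconv_parse_error")

  atoms <- switch(name,
    water_tip3p = data.frame(
      name = c("O", "H1", "H2"), amber_type = c("OW", "HW", "HW"),
      charge = c(-0.834, 0.417, 0.417),
      mass = c(16.00, 1.008, 1.008), element = c("O", "H", "H"),
      res_name = "WAT", res_index = 1L, stringsAsFactors = FALSE),
    methane = data.frame(
      name = c("C1", "H1", "H2", "H3", "H4"),
      amber_type = c("c3", "hc", "hc", "hc", "hc"),
      charge = c(-0.1068, rep(0.0267, 4)),
      mass = c(12.01, rep(1.008, 4)), element = c("C", rep("H", 4)),
      res_name = "MOL", res_index = 1L, stringsAsFactors = FALSE),
    chain4 = data.frame(
      name = paste0("C", 1:4), amber_type = rep("c3", 4),
      charge = c(0.1, -0.1, 0.1, -0.1),
      mass = rep(12.01, 4), element = rep("C", 4),
      res_name = "MOL", res_index = 1L, stringsAsFactors = FALSE),
    ring6 = data.frame(
      name = paste0("C", 1:6), amber_type = rep("ca", 6),
      charge = rep(c(0.115, -0.115), 3),
      mass = rep(12.01, 6), element = rep("C", 6),
      res_name = "MOL", res_index = 1L, stringsAsFactors = FALSE))

  bonds <- switch(name,
    water_tip3p = rbind(.toy_bond(1L, 2L, "HW-OW"), .toy_bond(1L, 3L, "HW-OW")),
    methane = do.call(rbind, lapply(2:5, function(h)
      .toy_bond(1L, h, "c3-hc"))),
    chain4 = do.call(rbind, lapply(1:3, function(b)
      .toy_bond(b, b + 1L, "c3-c3"))),
    ring6 = do.call(rbind, lapply(1:6, function(b)
      .toy_bond(b, if (b < 6L) b + 1L else 1L, "ca-ca"))))

  angles <- switch(name,
    water_tip3p = .toy_angle(2L, 1L, 3L, "HW-OW-HW"),
    methane = {
      cmb <- utils::combn(2:5, 2)
      do.call(rbind, lapply(seq_len(ncol(cmb)), function(k)
        .toy_angle(cmb[1, k], 1L, cmb[2, k], "hc-c3-hc")))
    },
    chain4 = rbind(.toy_angle(1L, 2L, 3L, "c3-c3-c3"),
                   .toy_angle(2L, 3L, 4L, "c3-c3-c3")),
    ring6 = do.call(rbind, lapply(1:6, function(j) {
      i <- if (j == 1L) 6L else j - 1L
      k <- if (j == 6L) 1L else j + 1L
      .toy_angle(i, j, k, "ca-ca-ca")
    })))

  torsions <- switch(name,
    water_tip3p = .empty_torsions(),
    methane = .empty_torsions(),
    chain4 = .toy_torsion(1L, 2L, 3L, 4L, "X-c3-c3-X"),
    ring6 = {
      ## all six ring torsions carry the 1-4 flag; the para pairs they
      ## generate twice each are deduplicated downstream
      prop <- do.call(rbind, lapply(1:6, function(i) {
        q <- ((i - 1L):(i + 2L)) %% 6L + 1L
        .toy_torsion(q[1], q[2], q[3], q[4], "X-ca-ca-X")
      }))
      imp <- data.frame(ai = 1L, aj = 3L, ak = 2L, al = 5L,
                        barrier_half = 1.1, periodicity = 2L,
                        phase = pi, kind = "improper",
                        generates_14 = FALSE, stringsAsFactors = FALSE)
      rbind(prop, imp)
    })

  coords <- .toy_coords(name)
  ## seeded jitter, isolated from the caller's RNG stream
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed + match(name, valid))
  coords <- coords + matrix(stats::runif(length(coords), -0.02, 0.02),
                            ncol = 3L)
  if (is.null(old_seed)) {
    rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old_seed, envir = globalenv())
  dimnames(coords) <- NULL

  types <- unique(atoms$amber_type)
  sys <- molecular_system(
    title = paste0("toy ", name), atoms = atoms, coords = coords,
    bonds = bonds, angles = angles, torsions = torsions,
    lj_types = .toy_lj_table(types),
    atom_lj = match(atoms$amber_type, types),
    net_charge = 0L, validate = FALSE)
  sys$exclusions <- build_pairs_exclusions(sys)$exclusions
  validate_system(sys)

  td <- tempfile("toy")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  f <- function(fn) file.path(td, fn)
  write_prmtop(sys, f("p.prmtop"))
  write_inpcrd(coords, f("c.inpcrd"), title = sys$title, box = sys$box)
  write_mol2(sys, f("m.mol2"))
  write_frcmod(toy_parameter_source(), f("t.frcmod"))
  list(system = sys,
       prmtop = readLines(f("p.prmtop")),
       inpcrd = readLines(f("c.inpcrd")),
       mol2 = readLines(f("m.mol2")),
       frcmod = readLines(f("t.frcmod")))
}
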