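test_that("GROMACS topology carries the AMBER-family defaults and term layout", {
  top <- write_gromacs_top(toy("chain4")$system)
  dl <- grep("^1 2 yes", top, value = TRUE)
  expect_length(dl, 1L)
  f <- strsplit(dl, "\\s+")[[1]]
  expect_equal(as.numeric(f[4]), 0.5)
  expect_equal(as.numeric(f[5]), 1 / 1.2, tolerance = 1e-9)

  ## chain4: exactly one pairs line and one function-9 dihedral line
  sec <- function(top, name) {
    starts <- grep("^\\[", top)
    i <- grep(sprintf("^\\[ %s \\]$", name), top)
    unlist(lapply(i, function(s) {
      e <- c(starts[starts > s], length(top) + 1L)[1] - 1L
      body <- top[(s + 1L):e]
      body[nzchar(body) & !startsWith(body, ";")]
    }))
  }
  expect_length(sec(top, "pairs"), 1L)
  d9 <- grep("^\\s*\\d+\\s+\\d+\\s+\\d+\\s+\\d+\\s+9\\s", sec(top, "dihedrals"),
             value = TRUE)
  expect_length(d9, 1L)

  ## a 3-component quartet emits 3 function-9 lines for the same quartet
  top3 <- write_gromacs_top(chain4_multiterm())
  d3 <- grep("^\\s*\\d+\\s+\\d+\\s+\\d+\\s+\\d+\\s+9\\s", top3, value = TRUE)
  expect_length(d3, 3L)
  quart <- unique(vapply(strsplit(trimws(d3), "\\s+"),
                         function(x) paste(x[1:4], collapse = " "),
                         character(1)))
  expect_length(quart, 1L)

  ## impropers keep the periodic form as function 4
  topr <- write_gromacs_top(toy("ring6")$system)
  d4 <- grep("^\\s*\\d+\\s+\\d+\\s+\\d+\\s+\\d+\\s+4\\s", topr, value = TRUE)
  expect_length(d4, 1L)

  ## atom types carry the collision-avoidance prefix
  expect_true(any(grepl("^acc3 ", top)))
})

test_that("writers are pure: identical input gives byte-identical output", {
  s <- toy("ring6")$system
  expect_identical(write_gromacs_top(s), write_gromacs_top(s))
  expect_identical(write_cns(s), write_cns(s))
  expect_identical(write_charmm(s), write_charmm(s))
  expect_identical(write_gro(s$coords, atoms = s$atoms),
                   write_gro(s$coords, atoms = s$atoms))
})

test_that("emitted GROMACS topology re-parses into the same physics", {
  for (nm in FIXTURE_NAMES) {
    sys <- toy(nm)$system
    f <- tempfile(fileext = ".top")
    write_gromacs_top(sys, f)
    top <- read_gromacs_top(f)
    expect_equal(nrow(top$atoms), nrow(sys$atoms), label = nm)
    expect_equal(nrow(top$bonds), nrow(sys$bonds), label = nm)
    expect_equal(nrow(top$pairs),
                 nrow(build_pairs_exclusions(sys)$pairs), label = nm)
    e1 <- single_point_energy(sys)
    e2 <- single_point_energy(top, sys$coords * 0.1, form = "gromacs_f9")
    expect_equal(e2$total, e1$total, tolerance = 1e-6, label = nm)
  }
})

test_that(".gro output follows the fixed-width format and box conventions", {
  s <- toy("water_tip3p")$system
  zero <- write_gro(matrix(0, 3, 3), atoms = s$atoms)
  expect_length(zero, 2 + 3 + 1)  # title, count, 3 atoms, box line
  expect_true(all(grepl("^\\s*0\\.000\\s+0\\.000\\s+0\\.000",
                        substr(zero[3:5], 21, 44))))

  ## octahedron box: 9 components, specific off-diagonal signs
  bv <- convert_box(box_spec("truncated_octahedron", c(20, 20, 20),
                             rep(109.4712190, 3)))
  g <- write_gro(s$coords, box_vectors = bv, atoms = s$atoms)
  box <- as.numeric(strsplit(trimws(g[length(g)]), "\\s+")[[1]])
  expect_length(box, 9L)
  expect_equal(box[1], 2.0, tolerance = 1e-5)             # v1x
  expect_equal(box[6], -2 / 3, tolerance = 1e-5)          # v2x
  expect_equal(box[8], -2 / 3, tolerance = 1e-5)          # v3x
  expect_equal(box[9], -sqrt(2) / 3 * 2, tolerance = 1e-5)  # v3y
  rg <- read_gro(write_fixture_file(g, ".gro"))
  ## positions carry the format's 3-decimal (nm) precision
  expect_lt(max(abs(rg$coords - s$coords * 0.1)), 6e-4)

  ## numbering wraps within the 5-digit field width
  big <- matrix(0, 3, 3)
  at <- data.frame(name = "X", res_name = "MOL", res_index = 123456L)
  gb <- write_gro(big, atoms = at)
  expect_equal(substr(gb[3], 1, 5), sprintf("%5d", 123456L %% 100000L))
})

test_that("CNS output is uppercase and passes its grammar", {
  s <- toy("chain4")$system
  s$atoms$name[1] <- "Br1"  # mixed case must be uppercased
  out <- write_cns(s)
  expect_true(any(grepl("ATOM BR1 ", gsub("\\s+", " ", out$topology))))
  expect_false(any(grepl("Br1", out$topology, fixed = TRUE)))

  expect_equal(nrow(validate_cns_text(out$topology, "topology")), 0L)
  expect_equal(nrow(validate_cns_text(out$parameters, "parameters")), 0L)
  expect_equal(nrow(validate_cns_text(out$run_input, "run_input")), 0L)

  ## chain4: 3 BOND statements in topology, deduplicated parameters
  expect_length(grep("^\\s*BOND ", out$topology), 3L)
  expect_lte(length(grep("^BOND ", out$parameters)), 3L)
  expect_length(grep("^BOND ", out$parameters), 1L)  # one unique type pair

  ## the validator does flag lowercase names
  bad <- c("BOND ca CB 1.0 2.0")
  expect_gt(nrow(validate_cns_text(bad, "parameters")), 0L)

  ## conflicting parameters for one type tuple must error
  s2 <- toy("chain4")$system
  s2$bonds$force_k[2] <- 99
  expect_error(write_cns(s2), "conflicting",
               class = "amberconv_parameter_error")
})

test_that("CHARMM rtf/prm follow their conventions and grammar", {
  s <- toy("ring6")$system
  out <- write_charmm(s)
  expect_equal(nrow(validate_charmm_text(out$rtf, "rtf")), 0L)
  expect_equal(nrow(validate_charmm_text(out$prm, "prm")), 0L)

  ## RESI line total charge equals the net charge
  resi <- grep("^RESI ", out$rtf, value = TRUE)
  expect_equal(as.numeric(strsplit(gsub("\\s+", " ", resi), " ")[[1]][3]),
               s$net_charge)

  ## MASS record type names unique
  mass_types <- vapply(strsplit(gsub("\\s+", " ",
                                     grep("^MASS", out$rtf, value = TRUE)),
                                " "), `[`, character(1), 3)
  expect_false(anyDuplicated(mass_types) > 0)

  ## LJ column: sigma 0.1 nm corresponds to Rmin/2 = 0.5612 A
  sig <- 0.1
  expect_equal(sig * 2^(1 / 6) / 2 * 10, 0.5612, tolerance = 1e-4)
  ## no prefix configured by default: type ca uppercases to CA; the
  ## NONBONDED entry is the last CA-leading line in the file
  nb <- grep("^CA\\s", out$prm, value = TRUE)
  f <- as.numeric(strsplit(gsub("\\s+", " ", nb[length(nb)]), " ")[[1]][-1])
  se <- lj_ab_to_sigma_eps(s$lj_types$A[1], s$lj_types$B[1])
  expect_equal(f[2], -se$epsilon / 4.184, tolerance = 1e-5)
  expect_equal(f[3], se$sigma * 2^(1 / 6) / 2 * 10, tolerance = 1e-5)
})

test_that("the opt-in RB dihedral path is energy-equivalent to function 9", {
  s <- chain4_multiterm()
  ## strip charges and LJ so only the torsion term differs from zero
  f9 <- tempfile(fileext = ".top"); rb <- tempfile(fileext = ".top")
  write_gromacs_top(s, f9)
  write_gromacs_top(s, rb, settings = list(dihedral_form = "rb"))
  t9 <- read_gromacs_top(f9)
  t3 <- read_gromacs_top(rb)
  expect_gt(nrow(t3$rb_dihedrals), 0L)
  e9 <- single_point_energy(t9, s$coords * 0.1, form = "gromacs_f9")
  e3 <- single_point_energy(t3, s$coords * 0.1, form = "gromacs_rb")
  expect_equal(e3$propers, e9$propers, tolerance = 1e-9)
  expect_equal(e3$total, e9$total, tolerance = 1e-9)
})
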