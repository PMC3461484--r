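test_that("toy generator builds the documented systems deterministically", {
  c4 <- toy("chain4")$system
  expect_equal(nrow(c4$atoms), 4L)
  expect_equal(nrow(c4$bonds), 3L)
  expect_equal(nrow(c4$angles), 2L)
  expect_equal(sum(c4$torsions$kind == "proper"), 1L)

  w <- toy("water_tip3p")$system
  expect_equal(nrow(w$atoms), 3L)
  expect_equal(nrow(w$bonds), 2L)
  expect_equal(w$net_charge, 0L)

  m <- toy("methane")$system
  expect_equal(nrow(m$bonds), 4L)
  expect_equal(nrow(m$angles), 6L)

  ## same (name, seed) twice -> identical bytes; different seed differs
  a <- generate_toy_system("ring6", 7L)
  b <- generate_toy_system("ring6", 7L)
  expect_identical(a$prmtop, b$prmtop)
  expect_identical(a$mol2, b$mol2)
  expect_false(identical(a$inpcrd, generate_toy_system("ring6", 8L)$inpcrd))

  expect_error(generate_toy_system("benzene"), "valid names")

  ## chemically sane: every bond within the covalent window
  for (nm in FIXTURE_NAMES) {
    sys <- toy(nm)$system
    expect_true(validate_geometry(sys)$pass, label = nm)
    d <- validate_geometry(sys)$distances
    expect_true(all(d > 0.9 & d < 1.6), label = nm)
  }
})

test_that("prmtop charges decode through the AMBER internal unit constant", {
  ## 18.2223^2 is the Coulomb constant in kcal A/mol/e^2
  expect_equal(18.2223^2, 332.0522173, tolerance = 1e-6)
  f <- write_fixture_file(toy("water_tip3p")$prmtop, ".prmtop")
  lines <- readLines(f)
  sys <- read_prmtop(f)
  ## raw CHARGE value for the oxygen is q * 18.2223
  i <- grep("%FLAG CHARGE", lines) + 2L
  raw_o <- as.numeric(substr(lines[i], 1, 16))
  expect_equal(raw_o / 18.2223, sys$atoms$charge[1], tolerance = 1e-9)
  expect_equal(sys$atoms$charge[1], -0.834, tolerance = 1e-7)
  ## the worked conversion: -15.190727 internal units is -0.8336 e
  expect_equal(round(-15.190727 / 18.2223, 4), -0.8336)
})

test_that("prmtop reader populates terms, LJ tables, exclusions and box flag", {
  sys <- read_prmtop(write_fixture_file(toy("ring6")$prmtop, ".prmtop"))
  expect_equal(nrow(sys$atoms), 6L)
  expect_equal(nrow(sys$bonds), 6L)
  expect_equal(nrow(sys$angles), 6L)
  expect_equal(sum(sys$torsions$kind == "proper"), 6L)
  expect_equal(sum(sys$torsions$kind == "improper"), 1L)
  expect_equal(attr(sys, "ifbox"), 0L)
  expect_equal(nrow(sys$lj_types), 1L)
  expect_gt(sys$lj_types$A[1], 0)
  ## exclusion symmetry
  for (i in seq_along(sys$exclusions))
    for (j in sys$exclusions[[i]])
      expect_true(i %in% sys$exclusions[[j]])
})

test_that("prmtop reader rejects missing flags and inconsistent lengths", {
  lines <- toy("methane")$prmtop
  no_charge <- lines[!grepl("CHARGE", lines)]
  ## drop the CHARGE data lines too (between flag and next flag)
  i <- grep("%FLAG CHARGE", lines)
  j <- grep("^%FLAG", lines)
  nxt <- min(j[j > i])
  expect_error(read_prmtop(write_fixture_file(lines[-(i:(nxt - 1L))],
                                              ".prmtop")),
               "CHARGE", class = "amberconv_parse_error")

  ## NATOM says 5 but CHARGE block holds 4 values
  trunc <- lines
  ci <- grep("%FLAG CHARGE", trunc) + 2L
  trunc[ci] <- substr(trunc[ci], 1, 64)  # keep 4 of the 5 fixed-width values
  expect_error(read_prmtop(write_fixture_file(trunc, ".prmtop")),
               "POINTERS implies", class = "amberconv_structural_error")
})

test_that("prmtop round trip is byte-stable and value-preserving", {
  for (nm in FIXTURE_NAMES) {
    f1 <- write_fixture_file(toy(nm)$prmtop, ".prmtop")
    s1 <- read_prmtop(f1)
    f2 <- tempfile()
    write_prmtop(s1, f2)
    expect_identical(readLines(f2), readLines(f1), label = nm)
    s2 <- read_prmtop(f2)
    expect_equal(s2$atoms$charge, s1$atoms$charge, tolerance = 1e-6)
    expect_equal(s2$bonds, s1$bonds, tolerance = 1e-6)
    expect_equal(s2$torsions, s1$torsions, tolerance = 1e-6)
    expect_identical(s2$exclusions, s1$exclusions)
  }
})

test_that("prmtop writer refuses unparameterisable or charge-violating systems", {
  sys <- toy("methane")$system
  sys$lj_types <- sys$lj_types[0, ]
  sys$atom_lj <- integer()
  expect_error(write_prmtop(sys, tempfile()), "Lennard-Jones",
               class = "amberconv_parameter_error")

  sys2 <- toy("methane")$system
  sys2$atoms$charge[1] <- sys2$atoms$charge[1] + 0.5
  expect_error(write_prmtop(sys2, tempfile()),
               class = "amberconv_structural_error")
})

test_that("inpcrd reading handles boxes and malformed input", {
  t <- toy("chain4")
  f <- write_fixture_file(t$inpcrd, ".inpcrd")
  r <- read_inpcrd(f)
  expect_equal(dim(r$coords), c(4L, 3L))
  expect_equal(r$box$kind, "none")
  expect_equal(r$coords, t$system$coords, tolerance = 1e-6)

  ## truncated-octahedron box line
  boxed <- c(t$inpcrd, paste0(sprintf("%12.7f",
    c(20, 20, 20, 109.471219, 109.471219, 109.471219)), collapse = ""))
  rb <- read_inpcrd(write_fixture_file(boxed, ".inpcrd"), has_box = TRUE)
  expect_equal(rb$box$kind, "truncated_octahedron")
  expect_equal(rb$box$lengths, c(20, 20, 20))

  ortho <- c(t$inpcrd, paste0(sprintf("%12.7f", c(15, 16, 17, 90, 90, 90)),
                              collapse = ""))
  expect_equal(read_inpcrd(write_fixture_file(ortho, ".inpcrd"),
                           has_box = TRUE)$box$kind, "orthorhombic")

  ## header/atom-count mismatch
  short <- t$inpcrd
  short[2] <- "    9"
  expect_error(read_inpcrd(write_fixture_file(short, ".inpcrd")),
               class = "amberconv_structural_error")
  ## non-numeric field
  bad <- t$inpcrd
  bad[3] <- sub("[0-9]", "q", bad[3])
  expect_error(read_inpcrd(write_fixture_file(bad, ".inpcrd")),
               "line", class = "amberconv_parse_error")
})

test_that("MOL2 reading recovers atoms, bonds and the charge column", {
  f <- write_fixture_file(toy("methane")$mol2, ".mol2")
  sys <- read_mol2(f)
  expect_equal(nrow(sys$atoms), 5L)
  expect_equal(nrow(sys$bonds), 4L)
  expect_true(is.na(sys$net_charge))
  expect_equal(sum(sys$atoms$charge), 0, tolerance = 1e-6)

  ## all-zero charge column is valid
  zeros <- toy("methane")$mol2
  at <- grep("^@<TRIPOS>ATOM", zeros)
  bd <- grep("^@<TRIPOS>BOND", zeros)
  zeros[(at + 1):(bd - 1)] <- sub("[-0-9.]+\\s*$", "0.000000",
                                  zeros[(at + 1):(bd - 1)])
  sz <- read_mol2(write_fixture_file(zeros, ".mol2"))
  expect_true(all(sz$atoms$charge == 0))

  ## bond to a nonexistent atom id
  bad <- toy("methane")$mol2
  bad[bd + 1L] <- "     1     1    99 1"
  expect_error(read_mol2(write_fixture_file(bad, ".mol2")),
               class = "amberconv_structural_error")

  ## missing BOND block
  expect_error(read_mol2(write_fixture_file(toy("methane")$mol2[1:(bd - 1)],
                                            ".mol2")),
               "BOND", class = "amberconv_parse_error")
})

test_that("frcmod parsing folds continuation series and round-trips", {
  src <- read_frcmod(write_fixture_file(toy("chain4")$frcmod, ".frcmod"))
  expect_s3_class(src, "parameter_source")
  expect_equal(length(src$bond), 4L)
  expect_equal(src$bond[["c3-hc"]]$force_k, 337.3)
  expect_equal(src$angle[["c3-c3-c3"]]$theta_eq, 110.63 * pi / 180,
               tolerance = 1e-9)

  ## negative periodicity folds the next line into one Fourier series
  multi <- c("test multi-term torsion", "DIHE",
             "c3-c3-c3-c3   1    1.500      0.0   -2.0",
             "c3-c3-c3-c3   1    0.750    180.0    3.0", "")
  ms <- read_frcmod(write_fixture_file(multi, ".frcmod"))
  terms <- ms$torsion[["c3-c3-c3-c3"]]
  expect_equal(nrow(terms), 2L)
  expect_equal(terms$periodicity, c(2L, 3L))
  expect_equal(terms$phase, c(0, pi), tolerance = 1e-9)

  ## a series that ends on a negative periodicity is malformed
  expect_error(read_frcmod(write_fixture_file(
    c("t", "DIHE", "c3-c3-c3-c3   1  1.5  0.0  -2.0", ""), ".frcmod")),
    "negative periodicity", class = "amberconv_structural_error")

  ## empty file parses to an empty, valid source
  empty <- read_frcmod(write_fixture_file(character(), ".frcmod"))
  expect_equal(length(empty$bond) + length(empty$angle) +
                 length(empty$torsion), 0L)

  ## duplicate key: last wins, with a warning
  dup <- c("t", "BOND", "c3-c3  300.0  1.500", "c3-c3  310.0  1.540", "")
  expect_warning(ds <- read_frcmod(write_fixture_file(dup, ".frcmod")),
                 "last one wins")
  expect_equal(ds$bond[["c3-c3"]]$r_eq, 1.54)

  ## write -> read identity on keys and values
  s1 <- toy_parameter_source()
  f <- tempfile()
  write_frcmod(s1, f)
  s2 <- read_frcmod(f)
  expect_setequal(names(s2$bond), names(s1$bond))
  expect_setequal(names(s2$torsion), names(s1$torsion))
  for (k in names(s1$bond))
    expect_equal(s2$bond[[k]]$force_k, s1$bond[[k]]$force_k,
                 tolerance = 1e-4)
  for (k in names(s1$lj))
    expect_equal(s2$lj[[k]]$epsilon, s1$lj[[k]]$epsilon, tolerance = 1e-4)
})

test_that("parm-dat positional dialect feeds the same section parsers", {
  dat <- c(
    "synthetic main parameter file",
    "OW 16.000",
    "HW  1.008",
    "c3 12.010",
    "",
    "OW HW",
    "HW-OW  553.0    0.9572",
    "c3-c3  300.9    1.5350",
    "",
    "HW-OW-HW   100.0  104.52",
    "",
    "X -c3-c3-X    1   1.400    0.0  3.0",
    "",
    "X -X -c3-c3  1.1  180.0  2.0",
    "",
    "",
    "",
    "MOD4      RE",
    "  OW  1.7683  0.1521",
    "  c3  1.9080  0.1094",
    "END")
  src <- read_frcmod(write_fixture_file(dat, ".dat"), dialect = "parm_dat")
  expect_equal(src$mass[["OW"]], 16.0)
  expect_equal(src$bond[["HW-OW"]]$r_eq, 0.9572)
  expect_equal(src$angle[["HW-OW-HW"]]$force_k, 100.0)
  expect_equal(nrow(src$torsion[[1]]), 1L)
  expect_equal(src$lj[["c3"]]$rmin_half, 1.908)
})
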