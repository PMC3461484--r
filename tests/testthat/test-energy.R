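test_that("bonded terms vanish at their equilibrium geometry", {
  ## two bonded atoms at exactly r0
  atoms <- data.frame(name = c("C1", "C2"), amber_type = "c3",
                      charge = 0, mass = 12.01, element = "C",
                      res_name = "MOL", res_index = 1L,
                      stringsAsFactors = FALSE)
  sys <- molecular_system(
    title = "pair", atoms = atoms,
    coords = rbind(c(0, 0, 0), c(1.535, 0, 0)),
    bonds = data.frame(ai = 1L, aj = 2L, force_k = 300.9, r_eq = 1.535),
    lj_types = data.frame(type_name = "c3", A = 0, B = 0),
    atom_lj = c(1L, 1L),
    exclusions = list(2L, 1L), net_charge = 0L)
  e <- single_point_energy(sys)
  expect_equal(e$bonds, 0)
  expect_equal(e$total, 0)

  ## single proper torsion n=1, gamma=0 at phi=180 deg contributes zero
  s4 <- toy("chain4")$system
  s4$torsions$periodicity <- 1L
  s4$torsions$phase <- 0
  ## flatten to an exact trans conformation
  s4$coords <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.3, 0),
                     c(3.7, 1.3, 0))
  phi <- amberconv:::.dihedral_angle(s4$coords, 1, 2, 3, 4)
  expect_equal(abs(phi), pi, tolerance = 1e-3)
  e4 <- single_point_energy(s4)
  expect_lt(e4$propers, 1e-4)
})

test_that("energy report totals its components and tags its units", {
  e <- single_point_energy(toy("ring6")$system)
  parts <- e$bonds + e$angles + e$propers + e$impropers + e$lj_14 +
    e$coulomb_14 + e$lj_nb + e$coulomb_nb
  expect_equal(e$total, parts, tolerance = 1e-12)
  expect_match(e$unit_system, "kJ/mol")
  expect_true(all(is.finite(unlist(e[c("bonds", "angles", "propers",
                                       "impropers", "total")]))))
})

test_that("energy is invariant under rigid-body transforms", {
  set.seed(42)
  for (nm in c("chain4", "ring6")) {
    sys <- toy(nm)$system
    e0 <- single_point_energy(sys)$total
    for (rep in 1:5) {
      q <- qr.Q(qr(matrix(rnorm(9), 3)))
      if (det(q) < 0) q[, 1] <- -q[, 1]
      shift <- matrix(rnorm(3, sd = 5), nrow(sys$coords), 3, byrow = TRUE)
      e1 <- single_point_energy(sys, sys$coords %*% q + shift)$total
      expect_equal(e1, e0, tolerance = 1e-9, label = nm)
    }
  }
})

test_that("bonded terms scale linearly with their force constants", {
  sys <- toy("ring6")$system
  e1 <- single_point_energy(sys)
  sys2 <- sys
  sys2$bonds$force_k <- 2 * sys2$bonds$force_k
  sys2$angles$force_k <- 2 * sys2$angles$force_k
  sys2$torsions$barrier_half <- 2 * sys2$torsions$barrier_half
  e2 <- single_point_energy(sys2)
  expect_equal(e2$bonds, 2 * e1$bonds)
  expect_equal(e2$angles, 2 * e1$angles)
  expect_equal(e2$propers, 2 * e1$propers)
  expect_equal(e2$impropers, 2 * e1$impropers)
})

test_that("removing an exclusion adds back exactly that pair interaction", {
  sys <- toy("water_tip3p")$system  # H-H is a 1-3 exclusion
  e_with <- single_point_energy(sys)
  sys2 <- sys
  sys2$exclusions <- lapply(seq_along(sys2$exclusions), function(i)
    setdiff(sys2$exclusions[[i]],
            if (i == 2L) 3L else if (i == 3L) 2L else integer()))
  e_without <- single_point_energy(sys2)
  r_nm <- sqrt(sum((sys$coords[2, ] - sys$coords[3, ])^2)) * 0.1
  manual_qq <- 332.0522173 * 4.184 * 0.1 * 0.417^2 / r_nm
  ## hydrogens have zero LJ, so the difference is pure Coulomb
  expect_equal(e_without$total - e_with$total, manual_qq, tolerance = 1e-9)
})

test_that("AMBER and converted GROMACS forms agree for every fixture", {
  for (nm in FIXTURE_NAMES) {
    cc <- compare_conversion(toy(nm)$system)
    expect_true(cc$pass, label = nm)
    expect_lt(cc$max_rel_diff, 1e-6)
  }
})

test_that("the oracle flags a corrupted conversion", {
  sys <- toy("chain4")$system
  f <- tempfile(fileext = ".top")
  write_gromacs_top(sys, f)
  top <- read_gromacs_top(f)
  top$bonds$k <- top$bonds$k * 2  # injected fault
  e_src <- single_point_energy(sys)
  e_bad <- single_point_energy(top, sys$coords * 0.1, form = "gromacs_f9")
  rd <- amberconv:::.energy_rel_diff(e_src, e_bad)
  expect_gt(rd[["bonds"]], 1e-6)
  expect_lt(rd[["angles"]], 1e-9)
})

test_that("degenerate and invalid inputs are rejected", {
  sys <- toy("methane")$system
  sys$coords[2, ] <- sys$coords[3, ]  # overlapping nonbonded pair
  ## atoms 2 and 3 are 1-3 excluded; overlap two non-excluded atoms instead
  sys2 <- toy("chain4")$system
  sys2$coords[4, ] <- sys2$coords[1, ]
  sys2$exclusions <- lapply(sys2$exclusions, function(v)
    setdiff(v, c(1L, 4L)))
  sys2$exclusions[[1]] <- setdiff(sys2$exclusions[[1]], 4L)
  sys2$torsions <- sys2$torsions[0, ]
  expect_error(single_point_energy(sys2), "overlap",
               class = "amberconv_geometry_error")

  nop <- toy("chain4")$system
  nop$bonds$force_k <- NA_real_
  expect_error(single_point_energy(nop),
               class = "amberconv_parameter_error")

  expect_error(single_point_energy(toy("chain4")$system, coords = NULL,
                                   form = "gromacs_f9"),
               class = "amberconv_structural_error")
})
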