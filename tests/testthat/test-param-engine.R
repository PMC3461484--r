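test_that("harmonic conversion applies the unit and half-k convention factors", {
  b <- convert_harmonic(100, 1.0, "bond")
  expect_equal(b$eq, 0.1)
  expect_equal(b$force_k, 83680.0)

  z <- convert_harmonic(0, 1.2, "bond")
  expect_equal(z$force_k, 0)
  expect_equal(z$eq, 0.12)

  a <- convert_harmonic(63.0, 1.9111, "angle")
  ## independent unit algebra: 2 * 4.184 * 63 and rad -> deg
  expect_equal(a$force_k, 2 * 4.184 * 63.0)
  expect_equal(a$force_k, 527.184)
  expect_equal(a$eq, 1.9111 * 180 / pi, tolerance = 1e-12)
  expect_equal(a$eq, 109.499, tolerance = 1e-4)

  expect_error(convert_harmonic(-1, 1, "bond"),
               class = "amberconv_parameter_error")

  ## homogeneity in the force constant
  expect_equal(convert_harmonic(34, 1.1, "bond")$force_k,
               2 * convert_harmonic(17, 1.1, "bond")$force_k)
})

test_that("function-9 torsion conversion keeps components separate", {
  cv <- convert_torsion_f9(1.4, 2L, pi)
  expect_equal(cv$phase_deg, 180.0)
  expect_equal(cv$k_kj, 5.8576)
  expect_equal(cv$periodicity, 2L)

  z <- convert_torsion_f9(0, 3L, 0)
  expect_equal(z$k_kj, 0)  # zero-barrier terms are retained, not dropped

  expect_error(convert_torsion_f9(1, 0L, 0),
               class = "amberconv_parameter_error")

  ## linearity in the barrier
  expect_equal(convert_torsion_f9(2.8, 2L, pi)$k_kj, 2 * cv$k_kj)
})

test_that("Fourier-to-RB mapping reproduces the potential at every angle", {
  phi <- seq(0, 2 * pi, length.out = 360)

  ## V1-only, phase 0: V = 1 + cos(phi) kcal/mol
  C <- fourier_to_rb(2, 1L, 0)
  expect_equal(C[1], 4.184)
  expect_equal(C[2], -4.184)
  expect_equal(C[3:6], rep(0, 4))
  expect_equal(rb_potential(phi, C), (1 + cos(phi)) * 4.184,
               tolerance = 1e-12)

  ## all-zero series
  expect_equal(fourier_to_rb(0, 1L, 0), rep(0, 6))

  ## V3-only series
  C3 <- fourier_to_rb(3, 3L, 0)
  expect_equal(C3[1], 3 / 2 * 4.184)
  expect_equal(C3[2], 3 * 3 / 2 * 4.184)
  expect_equal(C3[4], -2 * 3 * 4.184)
  expect_equal(rb_potential(phi, C3),
               fourier_potential(phi, 3, 3L, 0) * 4.184, tolerance = 1e-12)

  ## phases other than 0/pi have no RB equivalent
  expect_error(fourier_to_rb(1, 2L, pi / 2),
               class = "amberconv_parameter_error")
})

test_that("100 random Fourier series match their RB form on a dense grid", {
  set.seed(42)
  phi <- seq(0, 2 * pi, length.out = 360)
  worst <- 0
  for (rep in 1:100) {
    k <- sample(1:4, 1)
    ns <- sample(1:4, k)
    Vn <- runif(k, 0, 20)
    ph <- sample(c(0, pi), k, replace = TRUE)
    C <- fourier_to_rb(Vn, ns, ph)
    diff <- max(abs(fourier_potential(phi, Vn, ns, ph) * 4.184 -
                      rb_potential(phi, C)))
    worst <- max(worst, diff)
  }
  expect_lt(worst, 1e-9)
})

test_that("prmtop dihedral sign conventions classify into torsion kinds", {
  raw <- data.frame(ai = c(1L, 1L, 1L), aj = c(2L, 2L, 2L),
                    ak = c(3L, -3L, 3L), al = c(-4L, 4L, 4L),
                    barrier_half = 1, periodicity = 2L, phase = 0)
  out <- classify_torsions(raw)
  ## propers first, then impropers, each in input order
  expect_equal(out$kind, c("proper", "proper", "improper"))
  expect_equal(out$generates_14, c(FALSE, TRUE, FALSE))
  expect_true(all(out$ai > 0 & out$aj > 0 & out$ak > 0 & out$al > 0))

  expect_error(classify_torsions(transform(raw, ai = -ai)),
               class = "amberconv_structural_error")
})

test_that("1-4 pairs equal the graph-distance-3 oracle on every fixture", {
  for (nm in FIXTURE_NAMES) {
    sys <- toy(nm)$system
    got <- build_pairs_exclusions(sys)$pairs
    want <- brute_force_pairs14(sys)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, label = nm)
  }
  ## hexagon: six generating torsion paths, three unique para pairs
  r6 <- build_pairs_exclusions(toy("ring6")$system)$pairs
  expect_equal(nrow(r6), 3L)
  expect_equal(r6, data.frame(ai = 1:3, aj = 4:6))
  ## 4-ring: every candidate is also 1-2 or 1-3 connected -> no pairs
  expect_equal(nrow(build_pairs_exclusions(ring4_system())$pairs), 0L)
  expect_equal(nrow(brute_force_pairs14(ring4_system())), 0L)
  ## chain4: exactly the (1,4) pair
  expect_equal(build_pairs_exclusions(toy("chain4")$system)$pairs,
               data.frame(ai = 1L, aj = 4L))
})

test_that("exclusion lists cover 1-2/1-3/1-4 neighbours symmetrically", {
  pe <- build_pairs_exclusions(toy("chain4")$system)
  expect_equal(pe$exclusions[[1]], 2:4)
  expect_equal(pe$exclusions[[2]], c(1L, 3L, 4L))
  for (i in seq_along(pe$exclusions))
    for (j in pe$exclusions[[i]])
      expect_true(i %in% pe$exclusions[[j]])
})

test_that("LJ A/B and sigma/epsilon interconvert exactly", {
  ## zero-LJ hydrogens
  expect_equal(lj_ab_to_sigma_eps(0, 0), list(sigma = 0, epsilon = 0))
  expect_equal(sigma_eps_to_lj_ab(0, 0), list(A = 0, B = 0))

  ## A = B symmetry case: sigma exactly 0.1 nm, eps = B * 4.184 / 4
  se <- lj_ab_to_sigma_eps(7.5, 7.5)
  expect_equal(se$sigma, 0.1)
  expect_equal(se$epsilon, 7.5 * 4.184 / 4)

  ## TIP3P oxygen scale
  se_o <- lj_ab_to_sigma_eps(582000.0, 595.0)
  expect_equal(se_o$sigma, (582000 / 595)^(1 / 6) * 0.1, tolerance = 1e-12)
  expect_equal(se_o$sigma, 0.3151, tolerance = 1e-3)
  expect_equal(se_o$epsilon, 595^2 / (4 * 582000) * 4.184, tolerance = 1e-12)
  expect_equal(se_o$epsilon, 0.636, tolerance = 1e-3)

  ## 1000-point random round trip
  set.seed(42)
  sig <- runif(1000, 0.05, 0.6)
  eps <- runif(1000, 1e-4, 5)
  worst <- 0
  for (i in seq_along(sig)) {
    ab <- sigma_eps_to_lj_ab(sig[i], eps[i])
    back <- lj_ab_to_sigma_eps(ab$A, ab$B)
    worst <- max(worst, abs(back$sigma - sig[i]) / sig[i],
                 abs(back$epsilon - eps[i]) / eps[i])
  }
  expect_lt(worst, 1e-10)

  expect_error(lj_ab_to_sigma_eps(-1, 2),
               class = "amberconv_parameter_error")
})

test_that("box conversion produces correct vectors for every kind", {
  ## truncated octahedron, d = 20 A
  bv <- convert_box(box_spec("truncated_octahedron", c(20, 20, 20),
                             rep(109.4712190, 3)))
  norms <- apply(bv, 1, function(v) sqrt(sum(v^2)))
  expect_equal(norms, rep(2.0, 3), tolerance = 1e-9)
  ang <- function(u, v) acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
  ref <- acos(-1 / 3)
  expect_equal(ang(bv[1, ], bv[2, ]), ref, tolerance = 1e-9)
  expect_equal(ang(bv[2, ], bv[3, ]), ref, tolerance = 1e-9)
  expect_equal(ang(bv[1, ], bv[3, ]), ref, tolerance = 1e-9)

  ## orthorhombic
  expect_equal(convert_box(box_spec("orthorhombic", c(10, 10, 10),
                                    c(90, 90, 90))), diag(3))

  ## no box: extent plus clearance on each side
  pts <- rbind(c(0, 0, 0), c(10, 10, 10))  # 1 nm span
  expect_equal(convert_box(box_spec("none"), pts, clearance = 1.0),
               diag(rep(3.0, 3)))

  expect_error(convert_box(box_spec("triclinic", c(10, 10, 10),
                                    c(80, 95, 100))),
               "unsupported cell", class = "amberconv_structural_error")
})

test_that("water models are recognised by charges and LJ, not names", {
  expect_equal(recognize_water(toy("water_tip3p")$system), "TIP3P")
  expect_equal(recognize_water(toy("methane")$system), "none")

  ## rename the residue: recognition must not change
  w <- toy("water_tip3p")$system
  w$atoms$res_name <- "XXX"
  expect_equal(recognize_water(w), "TIP3P")

  ## SPC/E charges and oxygen LJ
  spce <- toy("water_tip3p")$system
  spce$atoms$charge <- c(-0.8476, 0.4238, 0.4238)
  ab <- sigma_eps_to_lj_ab(0.316557, 0.649775)
  spce$lj_types$A[1] <- ab$A
  spce$lj_types$B[1] <- ab$B
  expect_equal(recognize_water(spce), "SPCE")

  ## wrong charges -> none
  off <- toy("water_tip3p")$system
  off$atoms$charge <- c(-0.80, 0.40, 0.40)
  expect_equal(recognize_water(off), "none")
})

test_that("net-charge guessing rounds, warns and refuses per thresholds", {
  expect_equal(guess_net_charge(c(-0.5, -0.5002)), -1L)
  expect_equal(guess_net_charge(numeric()), 0L)
  expect_warning(q <- guess_net_charge(c(0.02, 0.03)), "deviates")
  expect_equal(q, 0L)
  expect_error(guess_net_charge(c(0.2, 0.2)),
               class = "amberconv_parameter_error")
})

test_that("geometry screening applies the covalent-distance window", {
  sys <- toy("methane")$system
  rep_ok <- validate_geometry(sys)
  expect_true(rep_ok$pass)
  expect_equal(nrow(rep_ok$violations), 0L)

  ## plant a 0.3 A bond and a 3.5 A bond
  bad <- sys
  bad$coords[2, ] <- bad$coords[1, ] + c(0.3, 0, 0)
  bad$coords[3, ] <- bad$coords[1, ] + c(3.5, 0, 0)
  rep_bad <- validate_geometry(bad)
  expect_false(rep_bad$pass)
  expect_equal(nrow(rep_bad$violations), 2L)
  expect_setequal(rep_bad$violations$rule, c("min_0.5", "max_3.0"))
  ## the 1.09 A bonds still pass
  expect_false(any(rep_bad$violations$ai == 1 & rep_bad$violations$aj %in%
                     c(4, 5)))

  nocoord <- sys
  nocoord$coords <- NULL
  expect_error(validate_geometry(nocoord),
               class = "amberconv_structural_error")
})

test_that("parameters resolve through the source chain with provenance", {
  sys <- read_mol2(write_fixture_file(toy("chain4")$mol2, ".mol2"))
  sys$net_charge <- guess_net_charge(sys$atoms$charge)

  full <- toy_parameter_source()
  ## primary source missing the c3-c3 bond key: must fall back
  primary <- full
  primary$label <- "primary"
  primary$bond[["c3-c3"]] <- NULL
  fallback <- full
  fallback$label <- "fallback"

  r <- resolve_parameters(sys, list(primary, fallback))
  prov <- attr(r, "provenance")
  expect_true(all(prov$bonds == "fallback"))
  expect_true(all(prov$angles == "primary"))
  expect_equal(r$bonds$force_k, rep(300.9, 3))

  ## first-match rule: key present in the primary wins
  r2 <- resolve_parameters(sys, list(fallback, primary))
  expect_true(all(attr(r2, "provenance")$bonds == "fallback"))

  ## absent everywhere: error naming the tuple
  neither <- full
  neither$bond[["c3-c3"]] <- NULL
  expect_error(resolve_parameters(sys, list(neither)), "c3-c3",
               class = "amberconv_parameter_error")
})

test_that("wildcard torsion keys match after exact keys", {
  sys <- read_mol2(write_fixture_file(toy("chain4")$mol2, ".mol2"))
  sys$net_charge <- 0L
  src <- toy_parameter_source()
  ## add an exact key that must shadow the X-c3-c3-X wildcard
  src$torsion[["c3-c3-c3-c3"]] <-
    data.frame(barrier_half = 9.9, periodicity = 1L, phase = 0)
  r <- resolve_parameters(sys, list(src))
  expect_equal(r$torsions$barrier_half[r$torsions$kind == "proper"], 9.9)
  src$torsion[["c3-c3-c3-c3"]] <- NULL
  r2 <- resolve_parameters(sys, list(src))
  expect_equal(r2$torsions$barrier_half[r2$torsions$kind == "proper"], 1.4)
})
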