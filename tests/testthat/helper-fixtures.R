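## Shared fixture helpers.  Toy systems are generated once per test run and
## cached; all fixture files live under tempdir().

.fixture_cache <- new.env(parent = emptyenv())

toy <- function(name, seed = 42L) {
  key <- paste(name, seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_toy_system(name, seed)
  .fixture_cache[[key]]
}

FIXTURE_NAMES <- c("water_tip3p", "methane", "chain4", "ring6")

write_fixture_file <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

## a 4-membered ring where every torsion end-pair is also 1-2 or 1-3
## connected: the canonical zero-1-4-pair case
ring4_system <- function() {
  atoms <- data.frame(
    name = paste0("C", 1:4), amber_type = rep("c3", 4),
    charge = c(0.05, -0.05, 0.05, -0.05), mass = rep(12.01, 4),
    element = rep("C", 4), res_name = "MOL", res_index = 1L,
    stringsAsFactors = FALSE)
  bonds <- data.frame(ai = 1:4, aj = c(2:4, 1L), force_k = 300.9,
                      r_eq = 1.55)
  tors <- do.call(rbind, lapply(1:4, function(i) {
    q <- ((i - 1L):(i + 2L)) %% 4L + 1L
    data.frame(ai = q[1], aj = q[2], ak = q[3], al = q[4],
               barrier_half = 0.5, periodicity = 3L, phase = 0,
               kind = "proper", generates_14 = TRUE,
               stringsAsFactors = FALSE)
  }))
  molecular_system(title = "ring4", atoms = atoms, bonds = bonds,
                   torsions = tors, net_charge = 0L, validate = FALSE)
}

## chain4 variant whose single torsion quartet carries a 3-component
## Fourier series
chain4_multiterm <- function() {
  sys <- toy("chain4")$system
  t1 <- sys$torsions[1, ]
  t2 <- t1; t2$barrier_half <- 0.8; t2$periodicity <- 1L
  t2$generates_14 <- FALSE
  t3 <- t1; t3$barrier_half <- 0.3; t3$periodicity <- 2L; t3$phase <- pi
  t3$generates_14 <- FALSE
  sys$torsions <- rbind(t1, t2, t3)
  validate_system(sys)
  sys
}

## independent shortest-path oracle (igraph) for 1-4 pair checks
brute_force_pairs14 <- function(sys) {
  skip_if_not_installed("igraph")
  n <- nrow(sys$atoms)
  g <- igraph::graph_from_edgelist(
    as.matrix(sys$bonds[, c("ai", "aj")]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  d <- igraph::distances(g)
  idx <- which(d == 3 & upper.tri(d), arr.ind = TRUE)
  out <- data.frame(ai = idx[, 1], aj = idx[, 2])
  out[order(out$ai, out$aj), , drop = FALSE]
}

expect_rel_equal <- function(actual, expected, tol) {
  denom <- pmax(abs(expected), 1e-300)
  expect_lt(max(abs(actual - expected) / denom), tol)
}
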