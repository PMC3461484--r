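## Parameter assignment: each bonded term and LJ type takes its values from
## the FIRST source in an ordered list that holds its key (e.g. AMBER99SB
## before GAFF), recording provenance per term.  Within a source, exact
## torsion keys are tried before single-wildcard and double-wildcard keys.

## enumerate angles (i-j-k) and proper torsions (i-j-k-l) from connectivity
.enumerate_angles <- function(adj) {
  out <- list()
  for (j in seq_along(adj)) {
    nb <- sort(adj[[j]])
    if (length(nb) < 2L) next
    cmb <- utils::combn(nb, 2L)
    for (c_ in seq_len(ncol(cmb)))
      out[[length(out) + 1L]] <- c(cmb[1, c_], j, cmb[2, c_])
  }
  if (!length(out)) return(matrix(integer(), ncol = 3L))
  do.call(rbind, out)
}

.enumerate_torsions <- function(adj, bonds) {
  out <- list(); seen <- character()
  for (b in seq_len(nrow(bonds))) {
    j <- bonds$ai[b]; k <- bonds$aj[b]
    for (i in setdiff(adj[[j]], k)) for (l in setdiff(adj[[k]], j)) {
      if (i == l) next  # 3-ring closure, not a torsion
      key <- paste(min(i, l), j, k, max(i, l))
      rkey <- paste(min(i, l), k, j, max(i, l))
      if (key %in% seen || rkey %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- c(i, j, k, l)
    }
  }
  if (!length(out)) return(matrix(integer(), ncol = 4L))
  do.call(rbind, out)
}

## torsion lookup: exact > single-X > double-X, forward or reversed
.lookup_torsion <- function(sources, t1, t2, t3, t4) {
  keysets <- list(
    .torsion_key(t1, t2, t3, t4),
    c(.torsion_key("X", t2, t3, t4), .torsion_key(t1, t2, t3, "X")),
    .torsion_key("X", t2, t3, "X"))
  for (src in sources) for (keys in keysets) for (k in keys) {
    if (!is.null(src$torsion[[k]]))
      return(list(terms = src$torsion[[k]], label = src$label))
  }
  NULL
}

.lookup_improper <- function(sources, outer, central) {
  keysets <- list(.improper_key(outer[1], outer[2], central, outer[3]))
  ## single then double wildcard on the outer positions
  singles <- unique(vapply(1:3, function(i) {
    o <- outer; o[i] <- "X"
    .improper_key(o[1], o[2], central, o[3])
  }, character(1)))
  doubles <- unique(vapply(1:3, function(i) {
    o <- rep("X", 3); o[i] <- outer[i]
    .improper_key(o[1], o[2], central, o[3])
  }, character(1)))
  keysets <- c(keysets, list(singles), list(doubles))
  for (src in sources) for (keys in keysets) for (k in keys) {
    if (!is.null(src$improper[[k]]))
      return(list(terms = src$improper[[k]], label = src$label))
  }
  NULL
}

## mark generates_14 so each graph-distance-3 end pair is flagged once
.mark_generates_14 <- function(torsions, adj) {
  if (!nrow(torsions)) return(torsions)
  dist_ok <- function(i, l) {
    d <- .graph_dist_from(adj, i, 3L)
    identical(d[l], 3L)
  }
  seen <- character()
  gen <- logical(nrow(torsions))
  for (r in seq_len(nrow(torsions))) {
    if (torsions$kind[r] == "improper") next
    i <- torsions$ai[r]; l <- torsions$al[r]
    key <- paste(min(i, l), max(i, l))
    if (!(key %in% seen) && dist_ok(i, l)) {
      gen[r] <- TRUE
      seen <- c(seen, key)
    }
  }
  torsions$generates_14 <- gen
  torsions
}

#' Assign force-field parameters from an ordered source chain
#'
#' Enumerates angles and proper torsions from the bond graph when the
#' system carries only connectivity (the MOL2 route), then resolves every
#' bond, angle, torsion and Lennard-Jones parameter from the first
#' [parameter_source()] in `sources` containing its canonical type key.
#' Impropers are generated for atoms with exactly three bonded neighbours
#' whose type tuple matches an improper table entry (central atom third,
#' outer atoms in index order).  Missing keys raise a parameter error
#' naming the type tuple.
#'
#' @param sys a [molecular_system()] whose atoms carry force-field types
#' @param sources list of [parameter_source()] objects, highest priority
#'   first
#' @return the parameterised system; per-term provenance labels are
#'   attached as `attr(x, "provenance")` (list with `bonds`, `angles`,
#'   `torsions`, `lj`)
#' @export
resolve_parameters <- function(sys, sources) {
  if (!length(sources)) parameter_error("at least one parameter source required")
  if (inherits(sources, "parameter_source")) sources <- list(sources)
  ty <- sys$atoms$amber_type
  n <- nrow(sys$atoms)
  adj <- .bond_adjacency(n, sys$bonds)

  first_hit <- function(table_name, key) {
    for (src in sources)
      if (!is.null(src[[table_name]][[key]]))
        return(list(val = src[[table_name]][[key]], label = src$label))
    NULL
  }

  ## bonds
  bprov <- character(nrow(sys$bonds))
  for (b in seq_len(nrow(sys$bonds))) {
    key <- .bond_key(ty[sys$bonds$ai[b]], ty[sys$bonds$aj[b]])
    hit <- first_hit("bond", key)
    if (is.null(hit))
      parameter_error(sprintf("no bond parameters for type tuple (%s)", key))
    sys$bonds$force_k[b] <- hit$val$force_k
    sys$bonds$r_eq[b] <- hit$val$r_eq
    bprov[b] <- hit$label
  }

  ## angles (enumerate when absent)
  if (!nrow(sys$angles)) {
    am <- .enumerate_angles(adj)
    sys$angles <- if (nrow(am)) data.frame(
      ai = am[, 1], aj = am[, 2], ak = am[, 3],
      force_k = NA_real_, theta_eq = NA_real_) else .empty_angles()
  }
  aprov <- character(nrow(sys$angles))
  for (a in seq_len(nrow(sys$angles))) {
    key <- .angle_key(ty[sys$angles$ai[a]], ty[sys$angles$aj[a]],
                      ty[sys$angles$ak[a]])
    hit <- first_hit("angle", key)
    if (is.null(hit))
      parameter_error(sprintf("no angle parameters for type tuple (%s)", key))
    sys$angles$force_k[a] <- hit$val$force_k
    sys$angles$theta_eq[a] <- hit$val$theta_eq
    aprov[a] <- hit$label
  }

  ## proper torsions (enumerate when absent), expanding Fourier series
  tors_quartets <- if (nrow(sys$torsions))
    as.matrix(sys$torsions[sys$torsions$kind == "proper", c("ai", "aj", "ak", "al")])
  else .enumerate_torsions(adj, sys$bonds)
  rows <- list(); tprov <- character()
  for (q in seq_len(nrow(tors_quartets))) {
    at4 <- tors_quartets[q, ]
    hit <- .lookup_torsion(sources, ty[at4[1]], ty[at4[2]], ty[at4[3]],
                           ty[at4[4]])
    if (is.null(hit))
      parameter_error(sprintf(
        "no torsion parameters for type tuple (%s)",
        paste(ty[at4], collapse = "-")))
    for (r in seq_len(nrow(hit$terms))) {
      rows[[length(rows) + 1L]] <- data.frame(
        ai = at4[1], aj = at4[2], ak = at4[3], al = at4[4],
        barrier_half = hit$terms$barrier_half[r],
        periodicity = hit$terms$periodicity[r],
        phase = hit$terms$phase[r],
        kind = "proper", generates_14 = FALSE,
        stringsAsFactors = FALSE)
      tprov <- c(tprov, hit$label)
    }
  }

  ## impropers: atoms with exactly three neighbours and a matching entry
  for (centre in seq_len(n)) {
    nb <- sort(adj[[centre]])
    if (length(nb) != 3L) next
    hit <- .lookup_improper(sources, ty[nb], ty[centre])
    if (is.null(hit)) next
    rows[[length(rows) + 1L]] <- data.frame(
      ai = nb[1], aj = nb[2], ak = centre, al = nb[3],
      barrier_half = hit$terms$barrier_half[1],
      periodicity = hit$terms$periodicity[1],
      phase = hit$terms$phase[1],
      kind = "improper", generates_14 = FALSE,
      stringsAsFactors = FALSE)
    tprov <- c(tprov, hit$label)
  }
  sys$torsions <- if (length(rows)) do.call(rbind, rows) else .empty_torsions()
  sys$torsions <- .mark_generates_14(sys$torsions, adj)

  ## Lennard-Jones per distinct atom type (frcmod RE form -> A/B)
  utypes <- unique(ty)
  lj <- data.frame(type_name = utypes, A = NA_real_, B = NA_real_)
  ljprov <- character(length(utypes))
  for (t in seq_along(utypes)) {
    hit <- first_hit("lj", utypes[t])
    if (is.null(hit))
      parameter_error(sprintf("no Lennard-Jones parameters for type (%s)",
                              utypes[t]))
    rmin <- 2 * hit$val$rmin_half
    lj$A[t] <- hit$val$epsilon * rmin^12
    lj$B[t] <- 2 * hit$val$epsilon * rmin^6
    ljprov[t] <- hit$label
  }
  sys$lj_types <- lj
  sys$atom_lj <- match(ty, utypes)

  ## masses from the source chain when available
  for (i in seq_len(n)) {
    hit <- first_hit("mass", ty[i])
    if (!is.null(hit)) {
      sys$atoms$mass[i] <- hit$val
      sys$atoms$element[i] <- .element_from_mass(hit$val)
    }
  }

  pe <- build_pairs_exclusions(sys)
  sys$exclusions <- pe$exclusions
  validate_system(sys)
  attr(sys, "provenance") <- list(bonds = bprov, angles = aprov,
                                  torsions = tprov, lj = ljprov)
  sys
}
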