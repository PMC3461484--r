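## 1-4 pair and exclusion bookkeeping over the bond graph.
##
## GROMACS lists 1-4 interactions explicitly as scaled [pairs] and excludes
## 1-2/1-3/1-4 neighbours from the plain nonbonded loop; AMBER encodes the
## same information through exclusion lists and dihedral sign flags.  Pairs
## are generated from proper torsions but deduplicated and masked by the
## bond-graph distance, which handles rings correctly: a hexagon's six
## torsion paths collapse to its three para pairs, and a 4-ring (where
## every torsion end-pair is also 1-2 or 1-3 connected) yields none.

## adjacency list from the bond table
.bond_adjacency <- function(n, bonds) {
  adj <- rep(list(integer()), n)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds$ai[b]; j <- bonds$aj[b]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, unique)
}

## BFS shortest path lengths from one atom, capped at `cap` bonds
.graph_dist_from <- function(adj, start, cap = 3L) {
  n <- length(adj)
  d <- rep(NA_integer_, n)
  d[start] <- 0L
  frontier <- start
  depth <- 0L
  while (length(frontier) && depth < cap) {
    depth <- depth + 1L
    nxt <- integer()
    for (v in frontier) for (w in adj[[v]]) {
      if (is.na(d[w])) { d[w] <- depth; nxt <- c(nxt, w) }
    }
    frontier <- nxt
  }
  d
}

#' Build the 1-4 pair list and nonbonded exclusion lists
#'
#' Candidate pairs are the (first, fourth) atoms of proper torsions flagged
#' as generating a 1-4 interaction.  A candidate is kept only when the two
#' atoms are exactly three bonds apart (pairs that are also 1-2 or 1-3
#' connected, as in small rings, are dropped); duplicates arising from
#' multiple torsion paths are emitted once.  Exclusions cover all 1-2, 1-3
#' and 1-4 neighbours, symmetrically.
#'
#' @param sys a [molecular_system()] with bonds and torsions populated
#' @return list with `pairs` (data.frame `ai`, `aj`, canonical `ai < aj`)
#'   and `exclusions` (list of sorted integer vectors, one per atom)
#' @export
build_pairs_exclusions <- function(sys) {
  n <- nrow(sys$atoms)
  idx <- unlist(sys$torsions[c("ai", "aj", "ak", "al")], use.names = FALSE)
  if (length(idx) && (any(idx < 1L) || any(idx > n)))
    structural_error("torsion references an atom outside the system")
  adj <- .bond_adjacency(n, sys$bonds)

  dist3 <- lapply(seq_len(n), function(i) .graph_dist_from(adj, i, 3L))

  cand <- sys$torsions[sys$torsions$kind == "proper" &
                         sys$torsions$generates_14, , drop = FALSE]
  pi_ <- pmin(cand$ai, cand$al); pj_ <- pmax(cand$ai, cand$al)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand)))
    keep[r] <- identical(dist3[[pi_[r]]][pj_[r]], 3L)
  key <- paste(pi_, pj_)[keep]
  uniq <- !duplicated(key)
  pairs <- data.frame(ai = pi_[keep][uniq], aj = pj_[keep][uniq])
  if (nrow(pairs)) pairs <- pairs[order(pairs$ai, pairs$aj), , drop = FALSE]
  rownames(pairs) <- NULL

  exclusions <- lapply(seq_len(n), function(i) {
    d <- dist3[[i]]
    sort(which(!is.na(d) & d >= 1L & d <= 3L))
  })
  list(pairs = pairs, exclusions = exclusions)
}
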