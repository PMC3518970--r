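# Directed motif classes, census, significance against rewiring nulls,
# and per-region participation.

# permutations of 1..k
all_perms <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(k - 1L)) {
    for (pos in 0:(k - 1L)) out[[length(out) + 1L]] <- append(p, k,
                                                              after = pos)
  }
  out
}

# off-diagonal cells in row-major order; bit 1 is the most significant
offdiag_rowmajor <- function(k) {
  cells <- expand.grid(j = seq_len(k), i = seq_len(k))[, c(2L, 1L)]
  cells <- cells[cells$i != cells$j, ]
  as.matrix(cells)
}

# environment-level cache: class tables and permutation machinery per k
.motif_cache <- new.env(parent = emptyenv())

motif_machinery <- function(k) {
  key <- as.character(k)
  if (!is.null(.motif_cache[[key]])) return(.motif_cache[[key]])
  cells <- offdiag_rowmajor(k)
  nb <- nrow(cells)
  perms <- all_perms(k)
  # position map: bit at position q of the permuted matrix reads the bit
  # at position permpos[q, p] of the original
  permpos <- vapply(perms, function(p) {
    moved <- cbind(p[cells[, 1L]], p[cells[, 2L]])
    match(paste(moved[, 1L], moved[, 2L]),
          paste(cells[, 1L], cells[, 2L]))
  }, integer(nb))
  weights <- 2^((nb - 1L):0L)
  m <- list(k = k, cells = cells, nb = nb, permpos = permpos,
            weights = weights)
  .motif_cache[[key]] <- m
  m
}

# canonical code of a k-node 0/1 adjacency matrix: the minimum, over all
# node permutations, of its row-major off-diagonal bitstring
canonical_code <- function(A, m = motif_machinery(nrow(A))) {
  bits <- A[m$cells]
  min(colSums(matrix(bits[m$permpos], nrow = m$nb) * m$weights))
}

weakly_connected_bits <- function(A) {
  k <- nrow(A)
  U <- (A + t(A)) > 0
  seen <- logical(k)
  seen[1L] <- TRUE
  frontier <- 1L
  while (length(frontier) > 0L) {
    nxt <- which(colSums(U[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Enumerate directed motif classes
#'
#' Enumerates all isomorphism classes of weakly connected, loop-free
#' digraphs on `k` nodes by scanning every arc configuration and grouping
#' by canonical code (the minimum row-major adjacency bitstring over node
#' permutations). Classes are numbered `k-NN` by ascending arc count,
#' ties broken by ascending canonical code; under this order `3-01`,
#' `3-02` and `3-03` are the two-arc divergent/chain/convergent classes,
#' `3-07` is the directed 3-cycle and `3-13` the fully reciprocal triad.
#' There are 2 classes for `k = 2`, 13 for `k = 3` and 199 for `k = 4`.
#'
#' @param k Motif size: 2 (diagnostic), 3 or 4.
#' @return A data.frame with columns `motif_id`, `k`, `arc_count`,
#'   `canonical_code`; the attribute `"representatives"` holds one 0/1
#'   adjacency matrix per class.
#' @export
enumerate_motif_classes <- function(k) {
  if (!k %in% 2:4) {
    stop_mesoconn("motif size must be 2, 3 or 4",
                  "mesoconn_infeasible_params")
  }
  key <- paste0("classes", k)
  if (!is.null(.motif_cache[[key]])) return(.motif_cache[[key]])
  m <- motif_machinery(k)
  codes <- integer(0)
  arcs <- integer(0)
  reps <- list()
  for (cfg in 0:(2^m$nb - 1L)) {
    bits <- bitwAnd(bitwShiftR(cfg, (m$nb - 1L):0L), 1L)
    A <- matrix(0L, k, k)
    A[m$cells] <- bits
    if (!weakly_connected_bits(A)) next
    cc <- canonical_code(A, m)
    if (!(cc %in% codes)) {
      codes <- c(codes, cc)
      arcs <- c(arcs, sum(A))
      reps[[length(reps) + 1L]] <- A
    }
  }
  ord <- order(arcs, codes)
  out <- data.frame(
    motif_id = sprintf("%d-%02d", k, seq_along(ord)),
    k = k, arc_count = arcs[ord], canonical_code = codes[ord],
    stringsAsFactors = FALSE)
  attr(out, "representatives") <- reps[ord]
  .motif_cache[[key]] <- out
  out
}

# map from igraph isomorphism-class index (0-based) to motif_id, per k
isoclass_map <- function(k) {
  key <- paste0("isomap", k)
  if (!is.null(.motif_cache[[key]])) return(.motif_cache[[key]])
  classes <- enumerate_motif_classes(k)
  reps <- attr(classes, "representatives")
  idx <- vapply(reps, function(A) {
    g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
    igraph::isomorphism_class(g)
  }, 0)
  map <- stats::setNames(classes$motif_id, as.character(idx))
  .motif_cache[[key]] <- map
  map
}

#' Directed motif census
#'
#' Counts, for every motif class, the number of `k`-node subsets whose
#' induced subgraph is weakly connected and isomorphic to that class
#' (induced counting: each eligible subset contributes to exactly one
#' class).
#'
#' @param c A [connectome()] with at least `k` nodes.
#' @param k Motif size (3 or 4; 2 supported diagnostically).
#' @return Named integer vector of counts, in motif id order.
#' @export
count_motifs <- function(c, k = 3L) {
  classes <- enumerate_motif_classes(k)
  n <- length(c$nodes)
  if (n < k) {
    stop_mesoconn("graph smaller than motif size",
                  "mesoconn_infeasible_params")
  }
  counts <- stats::setNames(integer(nrow(classes)), classes$motif_id)
  if (k == 2L) {
    A <- binary_adjacency(c)
    mutual <- sum(A * t(A)) / 2
    counts["2-01"] <- sum(A) - 2 * mutual
    counts["2-02"] <- mutual
    return(counts)
  }
  raw <- igraph::motifs(as_igraph(c), k)
  map <- isoclass_map(k)
  present <- as.integer(names(map))
  counts[map] <- as.integer(raw[present + 1L])
  counts
}

#' Motif significance against degree-preserving rewiring
#'
#' Compares the real census with `n_rand` rewired replicates (exact in-
#' and out-degree preservation, see [null_rewire()]). For every class the
#' replicate mean and SD, the z-score `(f_real - mean) / sd` (0 when the
#' SD is 0) and the upper-tail probability `p` (fraction of replicates
#' whose count is at least the real count) are reported: `p = 0` marks
#' motifs more frequent in the real network than in every replicate,
#' `p = 1` motifs at most as frequent as in every replicate.
#'
#' @param c A [connectome()].
#' @param k Motif size.
#' @param n_rand Number of rewired replicates.
#' @param swap_multiplier Successful swaps per arc in each replicate.
#' @param seed Integer seed.
#' @return Data.frame: `motif_id`, `arc_count`, `f_real`, `rand_mean`,
#'   `rand_sd`, `z`, `p`.
#' @export
motif_significance <- function(c, k = 3L, n_rand = 1000L,
                               swap_multiplier = 10L, seed = NULL) {
  classes <- enumerate_motif_classes(k)
  f_real <- count_motifs(c, k)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_rand))
  null_counts <- matrix(0L, n_rand, nrow(classes),
                        dimnames = list(NULL, classes$motif_id))
  for (i in seq_len(n_rand)) {
    null_counts[i, ] <- count_motifs(
      null_rewire(c, swap_multiplier, seeds[i]), k)
  }
  mu <- colMeans(null_counts)
  sdv <- apply(null_counts, 2L, stats::sd)
  z <- ifelse(sdv > 0, (f_real - mu) / sdv, 0)
  p <- colMeans(sweep(null_counts, 2L, f_real, ">=") * 1)
  data.frame(motif_id = classes$motif_id, arc_count = classes$arc_count,
             f_real = as.integer(f_real), rand_mean = mu, rand_sd = sdv,
             z = z, p = p, stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-region motif participation
#'
#' For one motif class, counts for every region the number of censused
#' node subsets containing it whose induced subgraph belongs to that
#' class. Summed over regions this equals `k` times the class count.
#'
#' @param c A [connectome()].
#' @param motif_id A class id such as `"3-13"`.
#' @return Named integer vector over regions, in node order.
#' @export
motif_participation <- function(c, motif_id) {
  k <- as.integer(sub("-.*", "", motif_id))
  classes <- enumerate_motif_classes(k)
  row <- match(motif_id, classes$motif_id)
  if (is.na(row)) {
    stop_mesoconn(paste("unknown motif id:", motif_id),
                  "mesoconn_unknown_motif")
  }
  target_code <- classes$canonical_code[row]
  m <- motif_machinery(k)
  A <- binary_adjacency(c)
  n <- nrow(A)
  part <- stats::setNames(integer(n), c$nodes)
  combs <- utils::combn(n, k)
  for (s in seq_len(ncol(combs))) {
    idx <- combs[, s]
    S <- A[idx, idx]
    if (!weakly_connected_bits(S)) next
    if (canonical_code(S, m) == target_code) {
      part[idx] <- part[idx] + 1L
    }
  }
  part
}
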