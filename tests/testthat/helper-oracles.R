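# Brute-force oracles, written independently of the implementation paths
# they check: distances by hand-rolled BFS, SCC via reachability closure,
# Shapley by full permutation enumeration, motif classification by
# pairwise isomorphism tests, modularity by exhaustive partition search.

# hop distances by BFS on the adjacency matrix (no igraph)
oracle_distances <- function(c) {
  A <- adjacency_matrix(c) > 0
  n <- nrow(A)
  D <- matrix(Inf, n, n, dimnames = dimnames(A))
  for (s in seq_len(n)) {
    D[s, s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- which(apply(A[frontier, , drop = FALSE], 2, any) &
                     is.infinite(D[s, ]))
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

oracle_harmonic_closeness <- function(c) {
  D <- oracle_distances(c)
  n <- nrow(D)
  vapply(seq_len(n), function(i) sum(1 / D[i, -i]) / (n - 1), 0)
}

oracle_mean_closeness_drop <- function(c, drop_node = NULL,
                                       drop_arc = NULL) {
  base <- mean(oracle_harmonic_closeness(c))
  reduced <- if (!is.null(drop_node)) {
    keep <- setdiff(c$nodes, drop_node)
    arcs <- c$arcs[c$arcs$source %in% keep & c$arcs$target %in% keep, ]
    connectome(keep, arcs)
  } else {
    keep_arc <- !(c$arcs$source == drop_arc[1] &
                    c$arcs$target == drop_arc[2])
    connectome(c$nodes, c$arcs[keep_arc, ])
  }
  100 * (base - mean(oracle_harmonic_closeness(reduced))) / base
}

# SCC count via reachability closure: mutual reachability is an
# equivalence relation; count its classes
oracle_scc_count <- function(A) {
  n <- nrow(A)
  if (n == 0) return(0L)
  R <- diag(TRUE, n) | (A > 0)
  repeat {
    R2 <- R | ((R %*% R) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  mutual <- R & t(R)
  length(unique(apply(mutual, 1, paste, collapse = "")))
}

# Shapley by enumerating every arrival order (feasible to n = 8)
oracle_shapley <- function(c) {
  n <- length(c$nodes)
  A <- adjacency_matrix(c) > 0
  v <- integer(2^n)
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) != 0)
    v[mask + 1] <- oracle_scc_count(A[idx, idx, drop = FALSE])
  }
  perm_list <- function(v_) {
    if (length(v_) == 1) return(list(v_))
    out <- list()
    for (i in seq_along(v_)) {
      for (p in perm_list(v_[-i])) out[[length(out) + 1]] <- c(v_[i], p)
    }
    out
  }
  sh <- numeric(n)
  perms <- perm_list(seq_len(n))
  for (p in perms) {
    mask <- 0L
    prev <- 0L
    for (node in p) {
      mask <- mask + bitwShiftL(1L, node - 1L)
      val <- v[mask + 1]
      sh[node] <- sh[node] + (val - prev)
      prev <- val
    }
  }
  stats::setNames(sh / length(perms), c$nodes)
}

# classify every k-subset by pairwise isomorphism against the class
# representatives (independent of the canonical-code machinery)
oracle_census <- function(c, k) {
  classes <- enumerate_motif_classes(k)
  reps <- lapply(attr(classes, "representatives"), function(A) {
    igraph::graph_from_adjacency_matrix(A, mode = "directed")
  })
  A <- adjacency_matrix(c) > 0
  counts <- stats::setNames(integer(nrow(classes)), classes$motif_id)
  for (subset in utils::combn(length(c$nodes), k, simplify = FALSE)) {
    S <- A[subset, subset] * 1
    U <- (S + t(S)) > 0
    gu <- igraph::graph_from_adjacency_matrix(U, mode = "undirected")
    if (!igraph::is_connected(gu)) next
    gs <- igraph::graph_from_adjacency_matrix(S, mode = "directed")
    for (m in seq_along(reps)) {
      if (igraph::isomorphic(gs, reps[[m]])) {
        counts[m] <- counts[m] + 1L
        break
      }
    }
  }
  counts
}

# betweenness and stress by enumerating all simple paths per ordered pair
oracle_bc_stress <- function(c) {
  A <- adjacency_matrix(c) > 0
  n <- nrow(A)
  bc <- numeric(n)
  st <- numeric(n)
  all_paths <- function(s, t) {
    found <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == t) {
        found[[length(found) + 1]] <<- path
        return(invisible())
      }
      for (nxt in which(A[last, ])) {
        if (!(nxt %in% path)) walk(c(path, nxt))
      }
    }
    walk(s)
    found
  }
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t) next
      paths <- all_paths(s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, length, 0L)
      geos <- paths[lens == min(lens)]
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        through <- sum(vapply(geos, function(p) v %in% p, TRUE))
        st[v] <- st[v] + through
        bc[v] <- bc[v] + through / length(geos)
      }
    }
  }
  list(bc = bc, st = st)
}

# exhaustive directed-modularity maximum over all set partitions (n <= 6)
oracle_best_modularity <- function(c) {
  A <- (adjacency_matrix(c) > 0) * 1
  e <- sum(A)
  if (e == 0) return(0)
  B <- A / e - outer(rowSums(A), colSums(A)) / e^2
  n <- nrow(A)
  best <- -Inf
  assign_next <- function(membership, n_used) {
    k <- length(membership)
    if (k == n) {
      q <- sum(B * outer(membership, membership, "=="))
      best <<- max(best, q)
      return(invisible())
    }
    for (m in seq_len(n_used + 1)) {
      assign_next(c(membership, m), max(n_used, m))
    }
  }
  assign_next(1L, 1L)
  best
}

# exhaustive staged-chain count by scanning every node tuple
oracle_staged_count <- function(c, sets) {
  A <- adjacency_matrix(c) > 0
  tuples <- expand.grid(lapply(sets, function(s) match(s, c$nodes)))
  ok <- apply(tuples, 1, function(tp) {
    if (anyDuplicated(tp)) return(FALSE)
    all(vapply(seq_len(length(tp) - 1),
               function(i) A[tp[i], tp[i + 1]], TRUE))
  })
  sum(ok)
}
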