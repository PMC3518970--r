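# Per-region parameter table: degrees, Katz, eccentricities, clustering
# variants, neighbourhood statistics, closeness, betweenness, eigenvector,
# stress, Shapley rates, module roles, radiality, centroid values.

neighbor_sets <- function(A) {
  n <- nrow(A)
  list(out = lapply(seq_len(n), function(i) which(A[i, ] > 0)),
       inn = lapply(seq_len(n), function(i) which(A[, i] > 0)),
       all = lapply(seq_len(n), function(i) {
         union(which(A[i, ] > 0), which(A[, i] > 0))
       }))
}

# Directed-variant clustering: density of arcs among the out- (or in-)
# neighbour set; the "all" variant is the classic coefficient of the
# underlying undirected graph.
directional_clustering <- function(A, nbs) {
  vapply(nbs, function(s) {
    k <- length(s)
    if (k < 2L) return(0)
    sum(A[s, s]) / (k * (k - 1L))
  }, 0)
}

# 2nd-neighbour sets: neighbours (in or out) of the 1st ring, excluding
# the node and the ring itself
second_ring <- function(nb_all, v) {
  ring1 <- nb_all[[v]]
  setdiff(unique(unlist(nb_all[ring1])), c(v, ring1))
}

# Locality: of all arcs with at least one endpoint in the closed 1st
# neighbourhood of v, the fraction with both endpoints inside it.
locality <- function(A, nb_all, v) {
  inside <- c(v, nb_all[[v]])
  touch <- which(A > 0, arr.ind = TRUE)
  touches <- (touch[, 1L] %in% inside) | (touch[, 2L] %in% inside)
  if (!any(touches)) return(0)
  both <- (touch[, 1L] %in% inside) & (touch[, 2L] %in% inside)
  sum(both) / sum(touches)
}

# shared feature block: also the 6-dimensional PCA feature vector
local_features <- function(c) {
  A <- binary_adjacency(c)
  n <- nrow(A)
  nbs <- neighbor_sets(A)
  deg_all <- valency(c)
  cc_all <- undirected_clustering(c)
  avg_nb <- numeric(n); vc_nb <- numeric(n)
  cc2 <- numeric(n); loc <- numeric(n)
  for (v in seq_len(n)) {
    ring1 <- nbs$all[[v]]
    if (length(ring1) > 0L) {
      dv <- deg_all[ring1]
      avg_nb[v] <- mean(dv)
      vc_nb[v] <- if (length(dv) > 1L && mean(dv) > 0) {
        sqrt(mean((dv - mean(dv))^2)) / mean(dv)
      } else 0
    }
    ring2 <- second_ring(nbs$all, v)
    cc2[v] <- if (length(ring2) > 0L) mean(cc_all[ring2]) else 0
    loc[v] <- locality(A, nbs$all, v)
  }
  data.frame(region = c$nodes, DG_all = deg_all, AvgDG_nb = avg_nb,
             CluC_all = as.numeric(cc_all), CluC_2 = cc2, VC_DG = vc_nb,
             Loc = loc, stringsAsFactors = FALSE)
}

katz_centrality <- function(A, alpha_scale = 0.9) {
  n <- nrow(A)
  lambda <- max(Mod(eigen(A, only.values = TRUE)$values))
  alpha <- if (lambda > 0) alpha_scale / lambda else 0.5
  as.numeric(solve(diag(n) - alpha * t(A), rep(1, n)))
}

eigenvector_in <- function(A) {
  n <- nrow(A)
  if (sum(A) == 0) return(rep(0, n))
  es <- eigen(t(A))
  lead <- which.max(Re(es$values))
  v <- abs(Re(es$vectors[, lead]))
  if (max(v) < 1e-12) return(rep(0, n))
  v / max(v)
}

# geodesic-count machinery: sigma[s, t] = number of shortest s->t paths
geodesic_counts <- function(A, D) {
  n <- nrow(A)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  finite_d <- D[is.finite(D) & D > 0]
  if (length(finite_d) > 0L) {
    W <- diag(n)
    for (d in seq_len(max(finite_d))) {
      W <- W %*% A
      sel <- which(D == d)
      sigma[sel] <- W[sel]
    }
  }
  sigma
}

stress_centrality <- function(A, D, sigma) {
  n <- nrow(A)
  st <- numeric(n)
  for (v in seq_len(n)) {
    through <- outer(sigma[, v], sigma[v, ])
    on_geo <- outer(D[, v], D[v, ], "+") == D & is.finite(D)
    on_geo[v, ] <- FALSE; on_geo[, v] <- FALSE
    diag(on_geo) <- FALSE
    st[v] <- sum(through[on_geo])
  }
  st
}

module_roles <- function(A, membership, mode) {
  n <- nrow(A)
  nb_count <- function(v, members) {
    switch(mode,
           out = sum(A[v, members]),
           inn = sum(A[members, v]),
           all = sum(A[v, members]) + sum(A[members, v]))
  }
  k_total <- switch(mode, out = rowSums(A), inn = colSums(A),
                    all = rowSums(A) + colSums(A))
  z <- numeric(n); pc <- numeric(n)
  mods <- sort(unique(membership))
  k_in_mod <- vapply(seq_len(n), function(v) {
    nb_count(v, which(membership == membership[v]))
  }, 0)
  for (m in mods) {
    idx <- which(membership == m)
    mu <- mean(k_in_mod[idx])
    sdv <- sqrt(mean((k_in_mod[idx] - mu)^2))
    z[idx] <- if (sdv > 0) (k_in_mod[idx] - mu) / sdv else 0
  }
  for (v in seq_len(n)) {
    if (k_total[v] == 0) { pc[v] <- 0; next }
    per_mod <- vapply(mods, function(m) nb_count(v, which(membership == m)),
                      0)
    pc[v] <- 1 - sum((per_mod / k_total[v])^2)
  }
  list(z = z, pc = pc)
}

radiality <- function(D) {
  n <- nrow(D)
  fin <- finite_offdiag(D)
  if (length(fin) == 0L) return(rep(0, n))
  diam <- max(fin)
  Dv <- D
  diag(Dv) <- NA
  vapply(seq_len(n), function(v) {
    d <- Dv[v, ]
    d <- d[!is.na(d)]
    sum(pmax(diam + 1 - d[is.finite(d)], 0)) / (n - 1)
  }, 0)
}

centroid_value <- function(D) {
  n <- nrow(D)
  cen <- integer(n)
  for (v in seq_len(n)) {
    best <- Inf
    for (w in seq_len(n)) {
      if (w == v) next
      others <- setdiff(seq_len(n), c(v, w))
      gamma_vw <- sum(D[v, others] < D[w, others])
      gamma_wv <- sum(D[w, others] < D[v, others])
      best <- min(best, gamma_vw - gamma_wv)
    }
    cen[v] <- if (is.finite(best)) as.integer(best) else 0L
  }
  cen
}

#' Per-region parameter table
#'
#' Computes the full local parameter set for every region of a
#' connectome: degrees (`DGa = DGo + DGi`), Katz status (attenuation
#' `0.9 / spectral radius`, unit exogenous input), out/in eccentricity
#' over reachable nodes, directed and undirected clustering variants,
#' clustering of the 2nd-neighbour ring (`CC2`), average and variation
#' coefficient of neighbour degree, locality, harmonic out/in closeness
#' normalized by `n - 1`, unnormalized directed betweenness and stress,
#' eigenvector centrality of the in-direction influence normalized to a
#' maximum of 1, Shapley rates of the strongly-connected-component
#' coalition game, within-module degree z-scores and participation
#' coefficients for out/in/all degree, out/in radiality and centroid
#' values.
#'
#' @param c A non-empty [connectome()].
#' @param partition Named module membership (from
#'   [modularity_partition()]); computed on the fly when `NULL`.
#' @param shapley_mode,shapley_perms,seed Passed to [shapley_rates()]
#'   (plus the modularity heuristic when `partition` is `NULL`).
#' @return A data.frame, one row per region in node order, sorted by
#'   nothing (sort by `DGa` yourself for the classic presentation).
#' @export
local_table <- function(c, partition = NULL, shapley_mode = "auto",
                        shapley_perms = 2000L, seed = NULL) {
  n <- length(c$nodes)
  stopifnot(n >= 1L)
  if (is.null(partition)) {
    partition <- modularity_partition(c, seed = seed)$membership
  }
  partition <- partition[c$nodes]
  A <- binary_adjacency(c)
  g <- as_igraph(c)
  D <- hop_distances(c)
  sigma <- geodesic_counts(A, D)
  nbs <- neighbor_sets(A)
  feats <- local_features(c)
  deg_out <- rowSums(A)
  deg_in <- colSums(A)
  ecc <- function(dv) { f <- dv[is.finite(dv)]; if (length(f)) max(f) else 0 }
  hc_out <- harmonic_closeness(c, mode = "out")
  hc_in <- harmonic_closeness(c, mode = "in")
  roles_o <- module_roles(A, partition, "out")
  roles_i <- module_roles(A, partition, "inn")
  roles_a <- module_roles(A, partition, "all")
  shap <- shapley_rates(c, mode = shapley_mode, n_perms = shapley_perms,
                        seed = seed)
  data.frame(
    region = c$nodes,
    DGa = deg_out + deg_in, DGo = deg_out, DGi = deg_in,
    Katz = katz_centrality(A),
    Ecco = vapply(seq_len(n), function(v) ecc(D[v, -v]), 0),
    Ecci = vapply(seq_len(n), function(v) ecc(D[-v, v]), 0),
    CCo = directional_clustering(A, nbs$out),
    CCi = directional_clustering(A, nbs$inn),
    CCa = feats$CluC_all,
    CC2 = feats$CluC_2,
    ADG = feats$AvgDG_nb,
    VC = feats$VC_DG,
    Loc = feats$Loc,
    Co = as.numeric(hc_out), Ci = as.numeric(hc_in),
    BC = as.numeric(igraph::betweenness(g, directed = TRUE,
                                        weights = NA)),
    EC = eigenvector_in(A),
    St = stress_centrality(A, D, sigma),
    Shapley = as.numeric(shap[c$nodes]),
    Zo = roles_o$z, Zi = roles_i$z, Za = roles_a$z,
    PCo = roles_o$pc, PCi = roles_i$pc, PCa = roles_a$pc,
    Ro = radiality(D), Ri = radiality(t(D)),
    Ceno = centroid_value(D), Ceni = centroid_value(t(D)),
    stringsAsFactors = FALSE)
}

# characteristic function table: v(S) = number of strongly connected
# components of the induced subgraph, for every node subset (bitmask + 1)
scc_value_table <- function(c) {
  n <- length(c$nodes)
  g <- as_igraph(c)
  v <- integer(2^n)
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    v[mask + 1L] <- igraph::count_components(
      igraph::induced_subgraph(g, idx), mode = "strong")
  }
  v
}

popcount <- function(x) {
  n <- 0L
  res <- integer(length(x))
  while (any(x > 0L)) {
    res <- res + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  res
}

#' Shapley rates of the strongly-connected-component game
#'
#' Treats the regions as players of a cooperative game whose
#' characteristic function assigns each coalition the number of strongly
#' connected components of its induced subgraph. A region's Shapley value
#' is its average marginal contribution over arrival orders; values sum
#' to the SCC count of the whole network, and low (negative) values mark
#' regions whose arrival merges many components, i.e. structurally
#' important regions.
#'
#' @param c A [connectome()].
#' @param mode `"exact"` (subset-weighted sum; requires <= 10 nodes),
#'   `"monte_carlo"` (average over `n_perms` random arrival orders), or
#'   `"auto"` (exact when feasible).
#' @param n_perms Number of Monte-Carlo permutations.
#' @param seed Integer seed for Monte-Carlo sampling.
#' @return Named numeric vector of Shapley values in node order.
#' @export
shapley_rates <- function(c, mode = c("auto", "exact", "monte_carlo"),
                          n_perms = 10000L, seed = NULL) {
  mode <- match.arg(mode)
  n <- length(c$nodes)
  if (n == 0L) return(stats::setNames(numeric(0), character(0)))
  if (mode == "auto") mode <- if (n <= 10L) "exact" else "monte_carlo"
  if (mode == "exact") {
    if (n > 10L) {
      stop_mesoconn("exact Shapley enumeration is limited to 10 nodes",
                    "mesoconn_infeasible_params")
    }
    v <- scc_value_table(c)
    masks <- 0:(2^n - 1L)
    sizes <- popcount(masks)
    w_by_size <- factorial(0:(n - 1L)) * factorial(n - 1L - (0:(n - 1L))) /
      factorial(n)
    sh <- numeric(n)
    for (i in seq_len(n)) {
      bit <- bitwShiftL(1L, i - 1L)
      without <- masks[bitwAnd(masks, bit) == 0L]
      marg <- v[without + bit + 1L] - v[without + 1L]
      sh[i] <- sum(w_by_size[sizes[without + 1L] + 1L] * marg)
    }
    return(stats::setNames(sh, c$nodes))
  }
  # Monte Carlo
  stopifnot(n_perms >= 1L)
  if (n <= 12L) {
    v <- scc_value_table(c)
    with_seed(seed, {
      sh <- numeric(n)
      counts <- integer(n)
      block <- 10000L
      remaining <- n_perms
      while (remaining > 0L) {
        b <- min(block, remaining)
        perms <- vapply(seq_len(b), function(i) sample.int(n), integer(n))
        bits <- matrix(bitwShiftL(1L, perms - 1L), nrow = n)
        cmask <- apply(bits, 2L, cumsum)
        vals <- matrix(v[cmask + 1L], nrow = n)
        marg <- rbind(vals[1L, ], diff(vals))
        sh <- sh + as.numeric(rowsum(as.numeric(marg), as.integer(perms)))
        remaining <- remaining - b
      }
      stats::setNames(sh / n_perms, c$nodes)
    })
  } else {
    g <- as_igraph(c)
    with_seed(seed, {
      sh <- numeric(n)
      for (p in seq_len(n_perms)) {
        perm <- sample.int(n)
        prev <- 0L
        for (k in seq_len(n)) {
          val <- igraph::count_components(
            igraph::induced_subgraph(g, perm[seq_len(k)]), mode = "strong")
          sh[perm[k]] <- sh[perm[k]] + (val - prev)
          prev <- val
        }
      }
      stats::setNames(sh / n_perms, c$nodes)
    })
  }
}

#' Directed cycle counts through a region
#'
#' Counts distinct directed cycles of exactly 2 or 3 arcs passing through
#' a region; each cycle orientation is counted once per anchor region
#' (so a reciprocal pair contributes one 2-cycle to each of its two
#' regions).
#'
#' @param c A [connectome()].
#' @param r A region id in `c`.
#' @param length Cycle length in arcs: 2 or 3.
#' @return Integer count.
#' @export
cycle_counts <- function(c, r, length = 2L) {
  stopifnot(length %in% c(2L, 3L))
  i <- match(r, c$nodes)
  if (is.na(i)) {
    stop_mesoconn(paste("unknown region:", r), "mesoconn_unknown_region")
  }
  A <- binary_adjacency(c)
  W <- if (length == 2L) A %*% A else A %*% A %*% A
  as.integer(W[i, i])
}
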