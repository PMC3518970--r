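# Whole-network parameters: density, valency, heterogeneity, path length,
# clustering, centrality, small-worldness, power-law fit error, modularity.

valency <- function(c) {
  tabulate(match(c$arcs$source, c$nodes), length(c$nodes)) +
    tabulate(match(c$arcs$target, c$nodes), length(c$nodes))
}

finite_offdiag <- function(D) {
  diag(D) <- Inf
  D[is.finite(D)]
}

# local clustering of the underlying undirected simple graph, one value
# per node, 0 for valency < 2 nodes
undirected_clustering <- function(c) {
  g <- igraph::as_undirected(as_igraph(c), mode = "collapse")
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[is.na(cc)] <- 0
  stats::setNames(cc, c$nodes)
}

#' Global network summary
#'
#' Computes the whole-network parameter set used to characterize a
#' condensed connectome: node and arc counts, average valency `2E/N`, line
#' density `100 E / (N (N-1))` in percent, heterogeneity (population SD of
#' valency over its mean), average shortest path length over reachable
#' ordered pairs (with the reachable fraction reported alongside),
#' average cluster coefficient of the underlying undirected graph, average
#' degree centrality `valency / (2 (N-1))` (mean harmonic closeness
#' available via `centrality = "closeness"`), the power-law fit error of
#' the valency distribution, and Newman modularity of the partition found
#' by [modularity_partition()].
#'
#' @param c A [connectome()] with at least one node.
#' @param centrality `"degree"` (default) or `"closeness"`; which notion
#'   the `avg_centrality` field averages.
#' @param n_rand Erdos-Renyi replicates for small-worldness; 0 (default)
#'   skips it (`NA`).
#' @param seed Seed for small-worldness replicates and the modularity
#'   heuristic.
#' @return A list of class `global_metrics`. Undefined quantities (path
#'   length of a single-node graph, power-law error with fewer than three
#'   distinct valencies) are `NA`, never 0.
#' @export
global_summary <- function(c, centrality = c("degree", "closeness"),
                           n_rand = 0L, seed = NULL) {
  centrality <- match.arg(centrality)
  n <- length(c$nodes)
  stopifnot(n >= 1L)
  e <- nrow(c$arcs)
  val <- valency(c)
  D <- hop_distances(c)
  reach <- finite_offdiag(D)
  hc <- harmonic_closeness(c)
  list_out <- list(
    n_nodes = n,
    n_arcs = e,
    avg_valency = 2 * e / n,
    line_density = if (n > 1L) 100 * e / (n * (n - 1)) else NA_real_,
    heterogeneity = if (mean(val) > 0) {
      sqrt(mean((val - mean(val))^2)) / mean(val)
    } else NA_real_,
    avg_path_length = if (length(reach) > 0L) mean(reach) else NA_real_,
    reachable_pair_fraction = if (n > 1L) {
      length(reach) / (n * (n - 1))
    } else NA_real_,
    avg_cluster_coefficient = mean(undirected_clustering(c)),
    avg_centrality = if (n > 1L) {
      if (centrality == "degree") mean(val / (2 * (n - 1))) else mean(hc)
    } else NA_real_,
    powerlaw_delta_error = powerlaw_delta_error(c),
    small_worldness = NA_real_,
    modularity_Q = NA_real_
  )
  mp <- modularity_partition(c, seed = seed)
  list_out$modularity_Q <- mp$Q
  if (n_rand > 0L) {
    list_out$small_worldness <- small_worldness(c, n_rand, seed)
  }
  class(list_out) <- "global_metrics"
  list_out
}

#' @export
print.global_metrics <- function(x, ...) {
  for (f in names(x)) cat(sprintf("%-24s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Small-worldness against an Erdos-Renyi ensemble
#'
#' `S = (C / mean C_ER) / (L / mean L_ER)` where `C` is the average
#' cluster coefficient, `L` the average path length over reachable pairs,
#' and the ensemble consists of `n_rand` Erdos-Renyi digraphs with the
#' same node and arc count. `S > 1` together with `L` close to the random
#' expectation is the classic small-world signature.
#'
#' @param c A non-empty [connectome()] (condense first).
#' @param n_rand Number of replicates.
#' @param seed Integer seed.
#' @return The ratio, or `NA` when the ensemble clustering averages 0.
#' @export
small_worldness <- function(c, n_rand = 100L, seed = NULL) {
  n <- length(c$nodes)
  e <- nrow(c$arcs)
  stopifnot(n >= 2L, n_rand >= 1L)
  c_real <- mean(undirected_clustering(c))
  l_real <- mean(finite_offdiag(hop_distances(c)))
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_rand))
  cs <- numeric(n_rand)
  ls <- numeric(n_rand)
  for (i in seq_len(n_rand)) {
    g <- null_erdos_renyi(n, e, seeds[i])
    cs[i] <- mean(undirected_clustering(g))
    d <- finite_offdiag(hop_distances(g))
    ls[i] <- if (length(d) > 0L) mean(d) else NA_real_
  }
  if (mean(cs) == 0 || !is.finite(mean(ls, na.rm = TRUE))) return(NA_real_)
  (c_real / mean(cs)) / (l_real / mean(ls, na.rm = TRUE))
}

#' Power-law fit error of the valency distribution
#'
#' Fits `P(k) ~ k^(-gamma)` by least squares on the log-log histogram of
#' valencies (zero-count bins excluded) and returns 100 times the mean
#' absolute deviation between the empirical relative frequencies and the
#' fitted curve. Small values indicate a scale-free-like valency
#' distribution.
#'
#' @param c A [connectome()], or a numeric vector of valencies.
#' @return The error on the x100 scale, or `NA` when fewer than three
#'   distinct positive valencies exist.
#' @export
powerlaw_delta_error <- function(c) {
  val <- if (inherits(c, "connectome")) valency(c) else as.numeric(c)
  val <- val[val > 0]
  if (length(unique(val)) < 3L) return(NA_real_)
  tab <- table(val)
  k <- as.numeric(names(tab))
  p <- as.numeric(tab) / length(val)
  fit <- stats::lm(log(p) ~ log(k))
  p_hat <- exp(stats::fitted(fit))
  100 * mean(abs(p - p_hat))
}

# directed Newman modularity of a membership vector
directed_modularity <- function(A, membership, e = sum(A)) {
  if (e == 0) return(0)
  kout <- rowSums(A)
  kin <- colSums(A)
  same <- outer(membership, membership, "==")
  sum((A / e - outer(kout, kin) / e^2) * same)
}

#' Community structure by directed modularity maximization
#'
#' Maximizes the directed Newman modularity
#' `Q = sum_ij (A_ij/E - kout_i kin_j / E^2) delta(c_i, c_j)` over the
#' binarized graph by greedy agglomeration of communities followed by
#' repeated single-node reassignment sweeps. The heuristic is
#' deterministic under a fixed seed (the seed only orders the refinement
#' sweeps).
#'
#' @param c A non-empty [connectome()].
#' @param seed Integer seed.
#' @return A list with `membership` (named integer vector, modules
#'   numbered 1..m in node order) and `Q`.
#' @export
modularity_partition <- function(c, seed = NULL) {
  n <- length(c$nodes)
  stopifnot(n >= 1L)
  A <- binary_adjacency(c)
  e <- sum(A)
  if (e == 0) {
    return(list(membership = stats::setNames(seq_len(n), c$nodes), Q = 0))
  }
  membership <- seq_len(n)
  B <- A / e - outer(rowSums(A), colSums(A)) / e^2   # modularity matrix
  q_of <- function(m) sum(B * outer(m, m, "=="))
  q <- q_of(membership)
  # greedy agglomeration
  repeat {
    mods <- unique(membership)
    if (length(mods) == 1L) break
    best <- list(gain = 0, merge = NULL)
    for (i in seq_along(mods)[-length(mods)]) {
      for (j in seq((i + 1L), length(mods))) {
        m2 <- membership
        m2[m2 == mods[j]] <- mods[i]
        gain <- q_of(m2) - q
        if (gain > best$gain + 1e-12) best <- list(gain = gain,
                                                   merge = c(i, j))
      }
    }
    if (is.null(best$merge)) break
    membership[membership == mods[best$merge[2L]]] <-
      mods[best$merge[1L]]
    q <- q + best$gain
  }
  # single-node refinement sweeps
  with_seed(seed, {
    repeat {
      improved <- FALSE
      for (v in sample.int(n)) {
        mods <- unique(membership)
        current <- membership[v]
        for (m in mods) {
          if (m == current) next
          m2 <- membership
          m2[v] <- m
          q2 <- q_of(m2)
          if (q2 > q + 1e-12) {
            membership <- m2
            q <- q2
            improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
  })
  membership <- match(membership, unique(membership))
  list(membership = stats::setNames(membership, c$nodes), Q = q)
}
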