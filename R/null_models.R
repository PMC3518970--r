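#' Random-network null models
#'
#' Generators used as baselines for global parameters and motif
#' significance. All are deterministic under a fixed seed and return
#' simple loop-free digraphs as [connectome()] objects (arc weight code 1,
#' `n_studies` 1). `null_erdos_renyi()`, `null_watts_strogatz()`,
#' `null_barabasi_albert()` and `null_ozik()` match the reference network
#' only in node and arc count; [null_rewire()] preserves the exact in- and
#' out-degree of every node.
#'
#' The classic Watts-Strogatz and Barabasi-Albert models are undirected;
#' the directed adaptations used here are: WS starts from a directed ring
#' lattice whose arcs point both ways round the ring before random target
#' rewiring, and BA attaches each new node by choosing partners
#' preferentially by total (in+out) degree with uniformly random arc
#' direction. The modified Ozik-Hunt-Ott growth inserts each new node at a
#' random position on a ring and wires it to its nearest ring neighbours
#' (alternating arc direction); its published form is an undirected
#' interpolation growth, so this directed reading is a documented
#' assumption of the package.
#'
#' @param n Number of nodes.
#' @param e Number of arcs; must satisfy `0 <= e <= n*(n-1)`.
#' @param seed Integer seed (or `NULL` to use the current RNG state).
#' @return A [connectome()] with `n` nodes and exactly `e` arcs.
#' @name null_models
NULL

null_nodes <- function(n) sprintf("v%03d", seq_len(n))

check_e <- function(n, e) {
  if (e < 0 || e > n * (n - 1)) {
    stop_mesoconn(sprintf("arc count %d infeasible for %d nodes", e, n),
                  "mesoconn_infeasible_params")
  }
}

arcs_from_pairs <- function(nodes, src, tgt) {
  if (length(src) == 0L) return(empty_arcs())
  ord <- order(src, tgt)
  data.frame(source = nodes[src[ord]], target = nodes[tgt[ord]],
             weight = 1L, n_studies = 1L, stringsAsFactors = FALSE)
}

#' @rdname null_models
#' @export
null_erdos_renyi <- function(n, e, seed = NULL) {
  check_e(n, e)
  nodes <- null_nodes(n)
  with_seed(seed, {
    idx <- sample.int(n * (n - 1L), e)   # uniform over ordered pairs
    src <- (idx - 1L) %/% (n - 1L) + 1L
    off <- (idx - 1L) %% (n - 1L) + 1L
    tgt <- ifelse(off >= src, off + 1L, off)
    connectome(nodes, arcs_from_pairs(nodes, src, tgt))
  })
}

#' Degree-preserving rewiring
#'
#' Randomizes a connectome by repeated double-arc swaps
#' (`a->b, c->d  =>  a->d, c->b`), rejecting swaps that would create a
#' self-loop or a duplicate arc. Every node's in-degree and out-degree are
#' preserved exactly. The procedure performs `swap_multiplier * E`
#' successful swaps; if no legal swap exists (e.g. a complete digraph) the
#' input is returned unchanged. Swapped arcs keep the weight and study
#' count of the arc that contributed their source.
#'
#' @param c A [connectome()].
#' @param swap_multiplier Successful swaps per arc (default 10).
#' @param seed Integer seed.
#' @return A rewired [connectome()] on the same nodes.
#' @export
null_rewire <- function(c, swap_multiplier = 10L, seed = NULL) {
  e <- nrow(c$arcs)
  if (e < 2L) return(c)
  n <- length(c$nodes)
  src <- match(c$arcs$source, c$nodes)
  tgt <- match(c$arcs$target, c$nodes)
  exists <- matrix(FALSE, n, n)
  exists[cbind(src, tgt)] <- TRUE
  target_swaps <- max(1L, as.integer(round(swap_multiplier * e)))
  done <- 0L
  with_seed(seed, {
    attempts <- 0L
    max_attempts <- max(1000L, 200L * target_swaps)
    while (done < target_swaps && attempts < max_attempts) {
      attempts <- attempts + 1L
      ab <- sample.int(e, 2L)
      a <- ab[1L]; b <- ab[2L]
      sa <- src[a]; ta <- tgt[a]; sb <- src[b]; tb <- tgt[b]
      if (sa == tb || sb == ta) next            # would create self-loop
      if (exists[sa, tb] || exists[sb, ta]) next # would duplicate an arc
      exists[sa, ta] <- FALSE; exists[sb, tb] <- FALSE
      exists[sa, tb] <- TRUE;  exists[sb, ta] <- TRUE
      tgt[a] <- tb; tgt[b] <- ta
      done <- done + 1L
    }
  })
  if (done == 0L) return(c)
  arcs <- c$arcs
  arcs$source <- c$nodes[src]
  arcs$target <- c$nodes[tgt]
  ord <- order(src, tgt)
  connectome(c$nodes, arcs[ord, , drop = FALSE])
}

#' @rdname null_models
#' @param p_rewire Per-arc probability of redirecting the arc's target to
#'   a uniformly random node (Watts-Strogatz style).
#' @export
null_watts_strogatz <- function(n, e, p_rewire = 0.1, seed = NULL) {
  check_e(n, e)
  nodes <- null_nodes(n)
  if (e == 0L || n < 2L) return(connectome(nodes))
  # directed ring lattice: arcs to the d-th neighbour both ways round the
  # ring for d = 1..K, then the leading remainder arcs of shell K+1
  ring_shell <- function(d, count) {
    i <- seq_len(count)
    fw <- cbind(i, (i + d - 1L) %% n + 1L)
    bw <- cbind(i, (i - d - 1L) %% n + 1L)
    rbind(fw, bw)
  }
  pairs <- matrix(integer(0), 0, 2)
  d <- 1L
  while (nrow(pairs) + 2L * n <= e && d <= (n - 1L) %/% 2L) {
    pairs <- rbind(pairs, ring_shell(d, n))
    d <- d + 1L
  }
  if (nrow(pairs) < e) {
    extra <- ring_shell(d, n)
    extra <- extra[!duplicated(rbind(pairs, extra))[-seq_len(nrow(pairs))], ,
                   drop = FALSE]
    extra <- extra[extra[, 1L] != extra[, 2L], , drop = FALSE]
    pairs <- rbind(pairs, extra[seq_len(min(e - nrow(pairs), nrow(extra))), ,
                                drop = FALSE])
  }
  pairs <- pairs[seq_len(min(e, nrow(pairs))), , drop = FALSE]
  with_seed(seed, {
    exists <- matrix(FALSE, n, n)
    exists[pairs] <- TRUE
    if (p_rewire > 0) {
      for (a in seq_len(nrow(pairs))) {
        if (stats::runif(1) < p_rewire) {
          s <- pairs[a, 1L]
          cand <- which(!exists[s, ] & seq_len(n) != s)
          if (length(cand) > 0L) {
            new_t <- sample_from(cand, 1L)
            exists[s, pairs[a, 2L]] <- FALSE
            exists[s, new_t] <- TRUE
            pairs[a, 2L] <- new_t
          }
        }
      }
    }
    connectome(nodes, arcs_from_pairs(nodes, pairs[, 1L], pairs[, 2L]))
  })
}

# distribute e arcs over sequentially added nodes, capped per node by the
# number of possible arcs to earlier nodes
growth_quota <- function(n, e) {
  cap <- 2L * (seq_len(n) - 1L)
  if (e > sum(cap)) {
    stop_mesoconn("arc count infeasible for growth construction",
                  "mesoconn_infeasible_params")
  }
  q <- integer(n)
  remaining <- e
  while (remaining > 0L) {
    room <- which(q < cap)
    take <- room[seq_len(min(length(room), remaining))]
    q[take] <- q[take] + 1L
    remaining <- remaining - length(take)
  }
  q
}

#' @rdname null_models
#' @export
null_barabasi_albert <- function(n, e, seed = NULL) {
  check_e(n, e)
  nodes <- null_nodes(n)
  if (e == 0L || n < 2L) return(connectome(nodes))
  quota <- growth_quota(n, e)
  with_seed(seed, {
    exists <- matrix(FALSE, n, n)
    deg <- numeric(n)
    for (t in seq_len(n)[-1L]) {
      placed <- 0L
      guard <- 0L
      while (placed < quota[t] && guard < 10000L) {
        guard <- guard + 1L
        partner <- sample_from(seq_len(t - 1L), 1L,
                               prob = deg[seq_len(t - 1L)] + 1)
        if (stats::runif(1) < 0.5) { s <- t; tt <- partner }
        else { s <- partner; tt <- t }
        if (exists[s, tt]) next
        exists[s, tt] <- TRUE
        deg[s] <- deg[s] + 1; deg[tt] <- deg[tt] + 1
        placed <- placed + 1L
      }
    }
    idx <- which(exists, arr.ind = TRUE)
    connectome(nodes, arcs_from_pairs(nodes, idx[, 1L], idx[, 2L]))
  })
}

#' @rdname null_models
#' @export
null_ozik <- function(n, e, seed = NULL) {
  check_e(n, e)
  nodes <- null_nodes(n)
  if (e == 0L || n < 2L) return(connectome(nodes))
  quota <- growth_quota(n, e)
  with_seed(seed, {
    exists <- matrix(FALSE, n, n)
    ring <- c(1L)
    for (t in seq_len(n)[-1L]) {
      pos <- if (length(ring) == 1L) 1L else sample.int(length(ring), 1L)
      ring <- append(ring, t, after = pos)
      # nearest ring neighbours, alternating sides outward
      at <- match(t, ring)
      m <- length(ring)
      order_nb <- integer(0)
      for (d in seq_len(m - 1L)) {
        left <- ring[(at - d - 1L) %% m + 1L]
        right <- ring[(at + d - 1L) %% m + 1L]
        order_nb <- c(order_nb, right, left)
      }
      order_nb <- unique(order_nb[order_nb != t])
      # first pass: one arc per partner, direction alternating with the
      # partner's rank; second pass: the reverse arcs, so every quota up
      # to the 2(t-1) cap is reachable
      placed <- 0L
      for (pass in 1:2) {
        for (q in seq_along(order_nb)) {
          if (placed >= quota[t]) break
          outward <- (q %% 2L == 1L) == (pass == 1L)
          arc <- if (outward) c(t, order_nb[q]) else c(order_nb[q], t)
          if (!exists[arc[1L], arc[2L]]) {
            exists[arc[1L], arc[2L]] <- TRUE
            placed <- placed + 1L
          }
        }
      }
    }
    idx <- which(exists, arr.ind = TRUE)
    connectome(nodes, arcs_from_pairs(nodes, idx[, 1L], idx[, 2L]))
  })
}

#' Run a null-model ensemble
#'
#' Generates `replicates` null networks and summarises each with
#' [global_summary()]; optionally streams the per-replicate rows to a TSV.
#'
#' @param kind One of `"erdos_renyi"`, `"watts_strogatz"`,
#'   `"barabasi_albert"`, `"ozik"` or `"rewire"` (which requires
#'   `reference`).
#' @param n,e Node/arc counts for the size-matched generators.
#' @param replicates Number of replicates.
#' @param seed Integer seed for the whole ensemble.
#' @param reference Reference [connectome()] (required for `"rewire"`).
#' @param swap_multiplier Passed to [null_rewire()].
#' @param p_rewire Passed to [null_watts_strogatz()].
#' @param path Optional TSV path for the per-replicate summary table.
#' @return Data.frame: one row per replicate (`replicate`, `seed`, and the
#'   scalar [global_summary()] columns).
#' @export
null_ensemble <- function(kind, n = NULL, e = NULL, replicates = 100L,
                          seed = 1L, reference = NULL,
                          swap_multiplier = 10L, p_rewire = 0.1,
                          path = NULL) {
  kind <- match.arg(kind, c("erdos_renyi", "watts_strogatz",
                            "barabasi_albert", "ozik", "rewire"))
  if (kind == "rewire" && is.null(reference)) {
    stop_mesoconn("rewire ensembles need a reference connectome",
                  "mesoconn_infeasible_params")
  }
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, replicates))
  rows <- lapply(seq_len(replicates), function(i) {
    g <- switch(kind,
      erdos_renyi = null_erdos_renyi(n, e, seeds[i]),
      watts_strogatz = null_watts_strogatz(n, e, p_rewire, seeds[i]),
      barabasi_albert = null_barabasi_albert(n, e, seeds[i]),
      ozik = null_ozik(n, e, seeds[i]),
      rewire = null_rewire(reference, swap_multiplier, seeds[i]))
    gs <- global_summary(g)
    data.frame(replicate = i, seed = seeds[i],
               n_nodes = gs$n_nodes, n_arcs = gs$n_arcs,
               avg_valency = gs$avg_valency, line_density = gs$line_density,
               heterogeneity = gs$heterogeneity,
               avg_path_length = gs$avg_path_length,
               avg_cluster_coefficient = gs$avg_cluster_coefficient,
               avg_centrality = gs$avg_centrality)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}
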