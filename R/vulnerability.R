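# Node and arc vulnerability: relative change of mean harmonic closeness
# under deletion.

#' Harmonic closeness
#'
#' `(1 / (n - 1)) * sum over j != i of 1 / d(i, j)`, with unreachable
#' nodes contributing 0. Harmonic (rather than raw inverse-sum) closeness
#' stays defined when deletions disconnect the graph, and coincides with
#' the classic definition up to normalization on strongly connected
#' graphs.
#'
#' @param c A [connectome()].
#' @param mode `"out"` (distances from the node) or `"in"` (towards it).
#' @return Named numeric vector in `[0, 1]`.
#' @export
harmonic_closeness <- function(c, mode = c("out", "in")) {
  mode <- match.arg(mode)
  n <- length(c$nodes)
  if (n < 2L) return(stats::setNames(rep(0, n), c$nodes))
  D <- hop_distances(c, mode = mode)
  inv <- 1 / D
  diag(inv) <- 0
  inv[is.infinite(D)] <- 0
  stats::setNames(rowSums(inv) / (n - 1), c$nodes)
}

#' Node vulnerability
#'
#' For every region, the percent change of the network's mean harmonic
#' closeness when that region is removed:
#' `100 * (Cbar_before - Cbar_after) / Cbar_before`, where `Cbar_after`
#' averages over the surviving regions only. Positive values mean the
#' removal harms the network (paths lengthen or vanish); negative values
#' are possible when a region mostly dilutes the average.
#'
#' @param c A [connectome()] with at least 3 nodes.
#' @return Named numeric vector of significances (percent), node order.
#' @export
node_significance <- function(c) {
  n <- length(c$nodes)
  if (n < 3L) {
    stop_mesoconn("node vulnerability needs at least 3 nodes",
                  "mesoconn_infeasible_params")
  }
  base <- mean(harmonic_closeness(c))
  if (base == 0) {
    return(stats::setNames(rep(NA_real_, n), c$nodes))
  }
  vapply(stats::setNames(c$nodes, c$nodes), function(r) {
    reduced <- induced_connectome(c, setdiff(c$nodes, r))
    100 * (base - mean(harmonic_closeness(reduced))) / base
  }, 0)
}

#' Arc vulnerability matrix
#'
#' Entry `(i, j)` is the percent change of mean harmonic closeness (node
#' set unchanged) when the arc i->j is deleted; cells without an arc are
#' `NA`. Deleting an arc can only lengthen distances, so values are
#' nonnegative up to floating-point noise.
#'
#' @param c A [connectome()].
#' @return A square numeric matrix in node order.
#' @export
edge_vulnerability_matrix <- function(c) {
  n <- length(c$nodes)
  out <- matrix(NA_real_, n, n, dimnames = list(c$nodes, c$nodes))
  if (nrow(c$arcs) == 0L || n < 2L) return(pair_matrix(out, "arc_vuln"))
  base <- mean(harmonic_closeness(c))
  if (base == 0) return(pair_matrix(out, "arc_vuln"))
  for (a in seq_len(nrow(c$arcs))) {
    reduced <- connectome(c$nodes, c$arcs[-a, , drop = FALSE])
    out[c$arcs$source[a], c$arcs$target[a]] <-
      100 * (base - mean(harmonic_closeness(reduced))) / base
  }
  pair_matrix(out, "arc_vuln")
}
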