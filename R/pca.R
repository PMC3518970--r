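# PCA of 6-feature local-connectivity vectors, Parzen-window densities,
# and neighbourhood ring summaries.

#' Local-connectivity feature table
#'
#' The 6-dimensional per-region feature vector used for connectivity
#' profiling: degree all (`DG_all`), average total degree of the combined
#' in/out neighbourhood (`AvgDG_nb`), undirected clustering (`CluC_all`),
#' mean clustering over the 2nd-neighbour ring (`CluC_2`), variation
#' coefficient of neighbour degree (`VC_DG`), and locality (`Loc`, the
#' fraction of arcs touching the closed 1st neighbourhood that stay
#' inside it). Isolated regions get 0 for every neighbourhood feature.
#'
#' @param c A [connectome()].
#' @return A data.frame with a `region` column and the 6 features.
#' @export
feature_table <- function(c) {
  local_features(c)
}

#' PCA of the feature table
#'
#' Z-score standardizes the features (they mix raw degrees with [0, 1]
#' coefficients; disable with `standardize = FALSE`), drops zero-variance
#' features with a warning, and eigendecomposes the remaining
#' correlation structure. Components are ordered by decreasing explained
#' share; each component's sign is fixed so that its largest-magnitude
#' loading is positive.
#'
#' @param features Output of [feature_table()] (>= 3 regions).
#' @param standardize Standardize features before decomposition.
#' @return A list of class `connectome_pca`: `loadings` (feature x
#'   component), `shares` (percent variance, sums to 100), `scores`
#'   (region x component), `scores_plane` (components 1-2), `dropped`
#'   (zero-variance feature names).
#' @export
pca_profile <- function(features, standardize = TRUE) {
  stopifnot(is.data.frame(features), nrow(features) >= 3L)
  x <- as.matrix(features[, setdiff(names(features), "region")])
  rownames(x) <- features$region
  sds <- apply(x, 2L, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped) > 0L) {
    warning("dropping zero-variance features: ",
            paste(dropped, collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = standardize)
  flip <- apply(pc$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  loadings <- sweep(pc$rotation, 2L, flip, "*")
  scores <- sweep(pc$x, 2L, flip, "*")
  shares <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = loadings, shares = shares, scores = scores,
                 scores_plane = scores[, seq_len(min(2L, ncol(scores))),
                                       drop = FALSE],
                 dropped = dropped),
            class = "connectome_pca")
}

#' @export
print.connectome_pca <- function(x, ...) {
  cat("PCA of", nrow(x$scores), "regions,", ncol(x$loadings),
      "components\nShares (%):",
      paste(sprintf("%.2f", x$shares), collapse = " "), "\n")
  invisible(x)
}

#' Parzen-window density over the PCA plane
#'
#' Isotropic Gaussian kernel average over the score points, evaluated on
#' a regular grid padded 4 bandwidths beyond the data hull so that the
#' grid integral is ~1.
#'
#' @param scores Two-column matrix of plane coordinates.
#' @param bandwidth Kernel SD; default is the mean of Silverman's
#'   rule-of-thumb per dimension.
#' @param grid_n Grid points per axis.
#' @return A list: `x`, `y` (grid axes), `z` (density matrix,
#'   `z[i, j]` at `(x[i], y[j])`), `bandwidth`, `integral` (trapezoidal
#'   grid integral, ~1).
#' @export
parzen_density <- function(scores, bandwidth = NULL, grid_n = 64L) {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == 2L, nrow(scores) >= 1L)
  if (is.null(bandwidth)) {
    n <- nrow(scores)
    silverman <- function(v) {
      s <- stats::sd(v)
      if (!is.finite(s) || s == 0) s <- 1
      1.06 * s * n^(-1 / 5)
    }
    bandwidth <- mean(c(silverman(scores[, 1L]), silverman(scores[, 2L])))
  }
  if (bandwidth <= 0) {
    stop_mesoconn("bandwidth must be positive",
                  "mesoconn_infeasible_params")
  }
  pad <- 4 * bandwidth
  gx <- seq(min(scores[, 1L]) - pad, max(scores[, 1L]) + pad,
            length.out = grid_n)
  gy <- seq(min(scores[, 2L]) - pad, max(scores[, 2L]) + pad,
            length.out = grid_n)
  kx <- stats::dnorm(outer(gx, scores[, 1L], "-"), sd = bandwidth)
  ky <- stats::dnorm(outer(gy, scores[, 2L], "-"), sd = bandwidth)
  z <- (kx %*% t(ky)) / nrow(scores)
  dx <- mean(diff(gx)); dy <- mean(diff(gy))
  wx <- rep(1, grid_n); wx[c(1L, grid_n)] <- 0.5
  integral <- as.numeric(t(wx) %*% z %*% wx) * dx * dy
  list(x = gx, y = gy, z = z, bandwidth = bandwidth, integral = integral)
}

#' Neighbourhood rings of a region
#'
#' The 1st ring is the combined in/out neighbourhood of the region; the
#' 2nd ring are the neighbours of the 1st ring, excluding the region and
#' the 1st ring. Arc tallies count arcs within the 1st ring, between the
#' rings (either direction) and within the 2nd ring.
#'
#' @param c A [connectome()].
#' @param r A region id.
#' @return A list: `ring1`, `ring2` (character vectors) and `arc_counts`
#'   (named vector `within_ring1`, `between_rings`, `within_ring2`).
#' @export
neighborhood_rings <- function(c, r) {
  v <- match(r, c$nodes)
  if (is.na(v)) {
    stop_mesoconn(paste("unknown region:", r), "mesoconn_unknown_region")
  }
  A <- binary_adjacency(c)
  nbs <- neighbor_sets(A)
  ring1 <- nbs$all[[v]]
  ring2 <- second_ring(nbs$all, v)
  count_arcs <- function(from, to) sum(A[from, to, drop = FALSE])
  list(ring1 = c$nodes[ring1], ring2 = c$nodes[ring2],
       arc_counts = c(
         within_ring1 = count_arcs(ring1, ring1),
         between_rings = count_arcs(ring1, ring2) +
           count_arcs(ring2, ring1),
         within_ring2 = count_arcs(ring2, ring2)))
}
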