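# Pairwise matrices: shortest-path distance, communicability, and
# connectivity matching (Jaccard overlap of neighbour sets).

pair_matrix <- function(values, kind) {
  attr(values, "kind") <- kind
  values
}

#' Distance matrix
#'
#' Unweighted shortest directed path lengths in node order; the diagonal
#' is 0 and unreachable pairs are `Inf`.
#'
#' @param c A [connectome()].
#' @return A square numeric matrix (attribute `kind = "distance"`).
#' @export
distance_matrix <- function(c) {
  D <- hop_distances(c)
  pair_matrix(D[c$nodes, c$nodes, drop = FALSE], "distance")
}

#' Communicability matrix
#'
#' The matrix exponential of the binarized adjacency matrix: entry
#' `(i, j)` sums walks of every length from i to j weighted by the
#' inverse factorial of the length, so many short paths give large
#' values. Weights are ignored (the ordinal codes are labels, not flow
#' capacities).
#'
#' @param c A [connectome()].
#' @return A square numeric matrix (attribute `kind = "communicability"`).
#' @export
communicability_matrix <- function(c) {
  A <- binary_adjacency(c)
  E <- as.matrix(Matrix::expm(Matrix::Matrix(A, sparse = FALSE)))
  dimnames(E) <- list(c$nodes, c$nodes)
  pair_matrix(E, "communicability")
}

#' Connectivity matching matrix
#'
#' Jaccard overlap of the in-, out- or combined neighbour sets of every
#' region pair, the pair itself excluded from both sets: 1 means
#' identical connection patterns, 0 disjoint ones (and, by convention,
#' also an empty union). The diagonal is 1.
#'
#' @param c A [connectome()].
#' @param mode `"in"`, `"out"` or `"all"`.
#' @return A symmetric numeric matrix in `[0, 1]`.
#' @export
matching_matrix <- function(c, mode = c("all", "in", "out")) {
  mode <- match.arg(mode)
  A <- binary_adjacency(c)
  n <- nrow(A)
  M <- switch(mode, `in` = t(A) > 0, out = A > 0, all = (A + t(A)) > 0)
  out <- diag(1, n)
  dimnames(out) <- list(c$nodes, c$nodes)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        keep <- setdiff(seq_len(n), c(i, j))
        a <- M[i, keep]; b <- M[j, keep]
        uni <- sum(a | b)
        out[i, j] <- out[j, i] <- if (uni == 0L) 0 else sum(a & b) / uni
      }
    }
  }
  pair_matrix(out, paste0("matching_", mode))
}

#' Write a pairwise matrix as dense TSV
#'
#' Unreachable distances are spelled `inf`.
#'
#' @param m A matrix from [distance_matrix()], [communicability_matrix()]
#'   or [matching_matrix()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pair_matrix <- function(m, path) {
  out <- m
  storage.mode(out) <- "character"
  out[is.infinite(m)] <- "inf"
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}
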