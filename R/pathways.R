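# Constrained staged pathway search: chains with one node per stage,
# stages resolved transhierarchically.

#' Staged pathway search
#'
#' Finds every chain of connectome nodes with exactly one node per stage
#' and an arc between consecutive nodes. Stage members are resolved
#' transhierarchically: a stage region matches every connectome node in
#' its subtree (or itself when it is not in the hierarchy but is a node).
#' Chains never revisit a node. Each hop reports the arc's ordinal
#' weight, its supporting study count, and whether the reverse arc also
#' exists (a reciprocal hop).
#'
#' @param c A [connectome()].
#' @param h A [region_hierarchy()] (or `NULL` to match stage ids against
#'   nodes directly).
#' @param stages A list of at least two character vectors of region ids.
#' @return A data.frame with one row per chain: columns `node_1..node_k`,
#'   `weight_1..weight_(k-1)`, `n_studies_*`, `reciprocal_*`. Zero rows
#'   when no chain exists.
#' @export
staged_paths <- function(c, h, stages) {
  stopifnot(is.list(stages), length(stages) >= 2L)
  resolve_stage <- function(stage) {
    members <- character(0)
    for (s in stage) {
      if (!is.null(h) && s %in% h$regions$id) {
        members <- c(members, intersect(subtree(h, s), c$nodes))
      } else if (s %in% c$nodes) {
        members <- c(members, s)
      } else {
        stop_mesoconn(paste("unresolvable stage region:", s),
                      "mesoconn_unresolved_region")
      }
    }
    members <- unique(members)
    # canonical node order keeps output independent of stage listing order
    members[order(match(members, c$nodes))]
  }
  sets <- lapply(stages, resolve_stage)
  if (any(lengths(sets) == 0L)) {
    stop_mesoconn("a stage resolves to no connectome node",
                  "mesoconn_unresolved_region")
  }
  k <- length(sets)
  arc_key <- paste(c$arcs$source, c$arcs$target, sep = "\r")
  has_arc <- function(a, b) paste(a, b, sep = "\r") %in% arc_key
  chains <- list()
  extend <- function(chain) {
    depth <- length(chain)
    if (depth == k) {
      chains[[length(chains) + 1L]] <<- chain
      return(invisible())
    }
    for (nxt in sets[[depth + 1L]]) {
      if (nxt %in% chain) next
      if (depth > 0L && !has_arc(chain[depth], nxt)) next
      extend(c(chain, nxt))
    }
  }
  extend(character(0))
  hop_cols <- function(field) {
    vapply(chains, function(ch) {
      vapply(seq_len(k - 1L), function(i) {
        row <- which(c$arcs$source == ch[i] & c$arcs$target == ch[i + 1L])
        switch(field,
               weight = as.numeric(c$arcs$weight[row]),
               n_studies = as.numeric(c$arcs$n_studies[row]),
               reciprocal = as.numeric(has_arc(ch[i + 1L], ch[i])))
      }, 0)
    }, numeric(k - 1L))
  }
  if (length(chains) == 0L) {
    out <- as.data.frame(matrix(character(0), 0, k))
    names(out) <- paste0("node_", seq_len(k))
    return(out)
  }
  nodes_mat <- t(vapply(chains, identity, character(k)))
  out <- as.data.frame(nodes_mat, stringsAsFactors = FALSE)
  names(out) <- paste0("node_", seq_len(k))
  for (field in c("weight", "n_studies", "reciprocal")) {
    vals <- hop_cols(field)
    vals <- if (k == 2L) matrix(vals, ncol = 1L) else t(vals)
    colnames(vals) <- paste0(field, "_", seq_len(k - 1L))
    out <- cbind(out, as.data.frame(vals))
  }
  out
}
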