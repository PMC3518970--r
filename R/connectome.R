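#' Connectomes
#'
#' A connectome is a simple directed graph over an ordered list of region
#' ids. Arcs carry an ordinal weight code (1..9, the semiquantitative
#' tract-tracing strength; code 0 means "reported absent" and never becomes
#' an arc) and the number of supporting studies. No self-loops and no
#' parallel arcs are permitted: every analysis in the package assumes a
#' loop-free simple digraph.
#'
#' @param nodes Character vector of region ids; its order is the canonical
#'   matrix row/column order.
#' @param arcs Data.frame with columns `source`, `target`, `weight`
#'   (integer 1..9) and `n_studies` (integer >= 1). May have zero rows.
#' @return An object of class `connectome`.
#' @export
connectome <- function(nodes, arcs = empty_arcs()) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) {
    stop_mesoconn("duplicate node ids", "mesoconn_bad_connectome")
  }
  arcs <- as.data.frame(arcs)
  if (nrow(arcs) == 0L) {
    arcs <- empty_arcs()
  } else {
    arcs$source <- as.character(arcs$source)
    arcs$target <- as.character(arcs$target)
    if (is.null(arcs$n_studies)) arcs$n_studies <- 1L
    bad <- !(arcs$source %in% nodes) | !(arcs$target %in% nodes)
    if (any(bad)) {
      stop_mesoconn("arc endpoint not among nodes", "mesoconn_bad_connectome")
    }
    if (any(arcs$source == arcs$target)) {
      stop_mesoconn("self-loop arc", "mesoconn_bad_connectome")
    }
    if (anyDuplicated(paste(arcs$source, arcs$target))) {
      stop_mesoconn("parallel arcs", "mesoconn_bad_connectome")
    }
    if (any(arcs$n_studies < 1L)) {
      stop_mesoconn("n_studies must be >= 1", "mesoconn_bad_connectome")
    }
  }
  rownames(arcs) <- NULL
  structure(list(nodes = nodes, arcs = arcs), class = "connectome")
}

empty_arcs <- function() {
  data.frame(source = character(0), target = character(0),
             weight = integer(0), n_studies = integer(0),
             stringsAsFactors = FALSE)
}

#' @export
print.connectome <- function(x, ...) {
  cat("Connectome:", length(x$nodes), "nodes,", nrow(x$arcs), "arcs\n")
  invisible(x)
}

#' Number of nodes / arcs of a connectome
#' @param c A [connectome()].
#' @return Integer count.
#' @export
n_nodes <- function(c) length(c$nodes)

#' @rdname n_nodes
#' @export
n_arcs <- function(c) nrow(c$arcs)

#' Convert a connectome to an igraph object
#'
#' Vertices keep the connectome's node order; arcs carry `weight` and
#' `n_studies` attributes.
#'
#' @param c A [connectome()].
#' @return A directed `igraph` graph.
#' @export
as_igraph <- function(c) {
  igraph::graph_from_data_frame(c$arcs, directed = TRUE, vertices = c$nodes)
}

#' Read connection records
#'
#' Records are delimited text with a header line naming at least
#' `source`, `target`, `laterality` and `weight`; the optional provenance
#' columns `tracer`, `transport`, `case` and `reference` are kept when
#' present. Laterality must be `ipsilateral` or `contralateral`; weight is
#' an integer code 0..9 (0 = connection investigated and reported absent);
#' transport, when present, must be `anterograde`, `retrograde` or
#' `bidirectional`.
#'
#' @param path CSV (".csv") or TSV file path.
#' @return A validated data.frame of connection records.
#' @export
read_records <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  validate_records(df)
}

#' @rdname read_records
#' @param records A data.frame of records to validate in place.
#' @export
validate_records <- function(records) {
  need <- c("source", "target", "laterality", "weight")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L) {
    stop_mesoconn(paste("record table lacks columns:",
                        paste(miss, collapse = ", ")),
                  "mesoconn_bad_records")
  }
  ok_lat <- records$laterality %in% c("ipsilateral", "contralateral")
  if (!all(ok_lat)) {
    stop_mesoconn(paste("unknown laterality token:",
                        records$laterality[!ok_lat][1L]),
                  "mesoconn_bad_records")
  }
  w <- records$weight
  if (!is.numeric(w) || any(w != floor(w)) || any(w < 0 | w > 9)) {
    stop_mesoconn("weight codes must be integers in 0..9",
                  "mesoconn_bad_records")
  }
  if (!is.null(records$transport)) {
    ok <- records$transport %in% c("anterograde", "retrograde",
                                   "bidirectional")
    if (!all(ok)) {
      stop_mesoconn(paste("unknown transport token:",
                          records$transport[!ok][1L]),
                    "mesoconn_bad_records")
    }
  }
  records$source <- as.character(records$source)
  records$target <- as.character(records$target)
  records
}

#' Write connection records
#' @param records A record data.frame.
#' @param path Output path (".csv" for CSV, otherwise TSV).
#' @return The path, invisibly.
#' @export
write_records <- function(records, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(records, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Build a connectome from connection records
#'
#' Each record's endpoints are resolved against the visible leaves of a
#' hierarchy view: a record attached at a descendant of a visible leaf
#' aggregates up to that leaf. Results of independent experiments are
#' integrated per ordered region pair: the arc weight is the maximum code
#' over supporting records and `n_studies` their count. Records whose
#' aggregated maximum code is 0 (reported absent) produce no arc, and
#' records that become self-projections after aggregation are dropped.
#'
#' In `"unilateral"` mode only ipsilateral records are used and nodes are
#' the leaves themselves. In `"bilateral"` mode every leaf appears once per
#' hemisphere (ids prefixed `L.` and `R.`); each ipsilateral record is
#' mirrored within both hemispheres and each contralateral record crosses
#' the midline in both directions.
#'
#' @param records Validated record data.frame (see [read_records()]).
#' @param leaf_order Character vector: the visible leaves, in canonical
#'   order (from [leaves_at_view()]).
#' @param hierarchy Optional [region_hierarchy()] used to aggregate records
#'   attached below a visible leaf. When `NULL`, record regions must match
#'   `leaf_order` directly.
#' @param side `"unilateral"` or `"bilateral"`.
#' @return A [connectome()].
#' @export
build_connectome <- function(records, leaf_order, hierarchy = NULL,
                             side = c("unilateral", "bilateral")) {
  side <- match.arg(side)
  records <- validate_records(as.data.frame(records))
  resolve <- stats::setNames(leaf_order, leaf_order)
  if (!is.null(hierarchy)) {
    assert_region(hierarchy, leaf_order)
    resolve <- character(0)
    for (leaf in leaf_order) {
      members <- subtree(hierarchy, leaf)
      resolve[members] <- leaf
    }
  }
  if (nrow(records) > 0L) {
    bad <- setdiff(c(records$source, records$target), names(resolve))
    if (length(bad) > 0L) {
      stop_mesoconn(paste("record region not under any visible leaf:",
                          paste(unique(bad), collapse = ", ")),
                    "mesoconn_unresolved_region")
    }
    records$source <- unname(resolve[records$source])
    records$target <- unname(resolve[records$target])
  }
  if (side == "unilateral") {
    recs <- records[records$laterality == "ipsilateral", , drop = FALSE]
    nodes <- leaf_order
  } else {
    ip <- records[records$laterality == "ipsilateral", , drop = FALSE]
    co <- records[records$laterality == "contralateral", , drop = FALSE]
    recs <- rbind(
      transform_sides(ip, "L.", "L."), transform_sides(ip, "R.", "R."),
      transform_sides(co, "L.", "R."), transform_sides(co, "R.", "L."))
    nodes <- c(paste0("L.", leaf_order), paste0("R.", leaf_order))
  }
  recs <- recs[recs$source != recs$target, , drop = FALSE]
  if (nrow(recs) == 0L) return(connectome(nodes))
  key <- paste(recs$source, recs$target, sep = "\r")
  agg_w <- tapply(recs$weight, key, max)
  agg_n <- tapply(recs$weight, key, length)
  parts <- strsplit(names(agg_w), "\r", fixed = TRUE)
  arcs <- data.frame(source = vapply(parts, `[`, "", 1L),
                     target = vapply(parts, `[`, "", 2L),
                     weight = as.integer(agg_w),
                     n_studies = as.integer(agg_n),
                     stringsAsFactors = FALSE)
  arcs <- arcs[arcs$weight > 0L, , drop = FALSE]
  # canonical arc order: by source then target position in node order
  pos <- stats::setNames(seq_along(nodes), nodes)
  arcs <- arcs[order(pos[arcs$source], pos[arcs$target]), , drop = FALSE]
  connectome(nodes, arcs)
}

transform_sides <- function(recs, src_prefix, tgt_prefix) {
  if (nrow(recs) == 0L) return(recs)
  recs$source <- paste0(src_prefix, recs$source)
  recs$target <- paste0(tgt_prefix, recs$target)
  recs
}

#' Condense a connectome
#'
#' Iteratively removes nodes lacking either any input or any output (and
#' their arcs) until every remaining node has indegree >= 1 and
#' outdegree >= 1. Node order is preserved. The condensed network is the
#' canonical object of study: regions without documented afferents or
#' efferents cannot carry information flow and would bias all comparisons
#' with randomized networks.
#'
#' @param c A [connectome()].
#' @return The condensed [connectome()]; possibly empty.
#' @export
condense <- function(c) {
  repeat {
    if (length(c$nodes) == 0L) return(c)
    deg_in <- table(factor(c$arcs$target, levels = c$nodes))
    deg_out <- table(factor(c$arcs$source, levels = c$nodes))
    keep <- c$nodes[deg_in > 0L & deg_out > 0L]
    if (length(keep) == length(c$nodes)) return(c)
    c <- induced_connectome(c, keep)
  }
}

#' Drop isolated nodes
#' @param c A [connectome()].
#' @return The [connectome()] without total-degree-0 nodes.
#' @export
remove_isolated <- function(c) {
  used <- unique(c(c$arcs$source, c$arcs$target))
  induced_connectome(c, intersect(c$nodes, used))
}

induced_connectome <- function(c, keep) {
  arcs <- c$arcs[c$arcs$source %in% keep & c$arcs$target %in% keep, ,
                 drop = FALSE]
  connectome(keep, arcs)
}

#' Adjacency matrix of a connectome
#'
#' Rows are sources, columns targets, both in node order. Entries hold the
#' ordinal weight code; 0 marks an absent arc (weight codes of stored arcs
#' are always >= 1, so 0 is unambiguous).
#'
#' @param c A [connectome()].
#' @return An integer matrix with node ids as dimnames.
#' @export
adjacency_matrix <- function(c) {
  n <- length(c$nodes)
  A <- matrix(0L, n, n, dimnames = list(c$nodes, c$nodes))
  if (nrow(c$arcs) > 0L) {
    A[cbind(match(c$arcs$source, c$nodes), match(c$arcs$target, c$nodes))] <-
      as.integer(c$arcs$weight)
  }
  A
}

# 0/1 adjacency, used by all topological analyses (weights are ordinal
# labels, not flow capacities)
binary_adjacency <- function(c) {
  (adjacency_matrix(c) > 0L) * 1L
}

# unweighted shortest-path hop counts; the ordinal weight codes must
# never enter distance computations
hop_distances <- function(c, mode = "out") {
  igraph::distances(as_igraph(c), mode = mode, weights = NA)
}

#' Rebuild a connectome from an adjacency matrix
#'
#' Inverse of [adjacency_matrix()]: nonzero entries become arcs with the
#' entry as weight and `n_studies = 1`.
#'
#' @param A Square matrix with node ids as dimnames; 0 = absent.
#' @return A [connectome()].
#' @export
connectome_from_adjacency <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  nodes <- rownames(A) %||% as.character(seq_len(nrow(A)))
  idx <- which(A != 0, arr.ind = TRUE)
  idx <- idx[idx[, 1L] != idx[, 2L], , drop = FALSE]
  ord <- order(idx[, 1L], idx[, 2L])
  idx <- idx[ord, , drop = FALSE]
  arcs <- data.frame(source = nodes[idx[, 1L]], target = nodes[idx[, 2L]],
                     weight = as.integer(A[idx]),
                     n_studies = 1L, stringsAsFactors = FALSE)
  connectome(nodes, arcs)
}

#' Export a connectome
#'
#' `write_connectome_graphml()` writes a directed GraphML graph with
#' `weight` and `n_studies` arc attributes; `write_adjacency_tsv()` writes
#' the dense ordinal adjacency matrix as TSV.
#'
#' @param c A [connectome()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_connectome_graphml <- function(c, path) {
  igraph::write_graph(as_igraph(c), path, format = "graphml")
  invisible(path)
}

#' @rdname write_connectome_graphml
#' @export
write_adjacency_tsv <- function(c, path) {
  A <- adjacency_matrix(c)
  utils::write.table(A, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}
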