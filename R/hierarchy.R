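#' Region hierarchies
#'
#' A region hierarchy is a rooted tree of "is part" relations over named
#' brain regions. Leaves of the tree (or of a user-defined view that
#' collapses some branches) define the canonical row/column order of every
#' connectivity matrix produced by the package: matrices are never ordered
#' alphabetically but by the curated depth-first sequence of the tree.
#'
#' @param regions A data.frame with columns `id`, `name`, `abbreviation`,
#'   `parent` (`NA` for the root), and optionally `side`
#'   (`"left"`, `"right"` or `"unpaired"`, default `"unpaired"`).
#'   Child order within a parent follows row order.
#' @return An object of class `region_hierarchy` with elements `regions`
#'   (the validated data.frame, with a computed `level` column, root = 1),
#'   `children` (named list, document child order) and `root` (region id).
#' @examples
#' h <- region_hierarchy(data.frame(
#'   id = c("Am", "CE", "ME"), name = c("amygdala", "central", "medial"),
#'   abbreviation = c("Am", "CE", "ME"), parent = c(NA, "Am", "Am")))
#' leaves_at_view(h)
#' @export
region_hierarchy <- function(regions) {
  stopifnot(is.data.frame(regions))
  need <- c("id", "name", "abbreviation", "parent")
  missing_cols <- setdiff(need, names(regions))
  if (length(missing_cols) > 0L) {
    stop_mesoconn(paste("hierarchy table lacks columns:",
                        paste(missing_cols, collapse = ", ")),
                  "mesoconn_bad_hierarchy")
  }
  regions$id <- as.character(regions$id)
  regions$parent <- as.character(regions$parent)
  if (is.null(regions$side)) regions$side <- "unpaired"
  if (anyDuplicated(regions$id)) {
    stop_mesoconn(paste("duplicate region id:",
                        regions$id[duplicated(regions$id)][1L]),
                  "mesoconn_duplicate_id")
  }
  roots <- regions$id[is.na(regions$parent)]
  if (length(roots) == 0L) {
    stop_mesoconn("no root region (every region has a parent)",
                  "mesoconn_no_root")
  }
  if (length(roots) > 1L) {
    stop_mesoconn(paste("multiple roots:", paste(roots, collapse = ", ")),
                  "mesoconn_multiple_roots")
  }
  known <- regions$parent %in% regions$id | is.na(regions$parent)
  if (!all(known)) {
    stop_mesoconn(paste("region references missing parent:",
                        regions$id[!known][1L]),
                  "mesoconn_missing_parent")
  }
  children <- split(regions$id[!is.na(regions$parent)],
                    factor(regions$parent[!is.na(regions$parent)],
                           levels = regions$id))
  children <- children[lengths(children) > 0L]

  # level assignment by BFS from the root; anything unreached sits on a cycle
  level <- stats::setNames(rep(NA_integer_, nrow(regions)), regions$id)
  level[roots] <- 1L
  frontier <- roots
  while (length(frontier) > 0L) {
    nxt <- character(0)
    for (p in frontier) {
      kids <- children[[p]]
      if (!is.null(kids)) {
        level[kids] <- level[[p]] + 1L
        nxt <- c(nxt, kids)
      }
    }
    frontier <- nxt
  }
  if (anyNA(level)) {
    stop_mesoconn(paste("cycle detected: unreachable region",
                        names(level)[is.na(level)][1L]),
                  "mesoconn_cycle")
  }
  regions$level <- as.integer(level[regions$id])
  structure(list(regions = regions, children = children, root = roots),
            class = "region_hierarchy")
}

#' Read a region hierarchy from a JSON document
#'
#' The document is a single nested object: `{"id": ..., "name": ...,
#' "abbreviation": ..., "side": ..., "children": [ ... ]}` with the same
#' shape recursively. Child order in the document is preserved and defines
#' the depth-first leaf order.
#'
#' @param source Path to a JSON file, or a JSON string.
#' @return A [region_hierarchy()].
#' @export
load_hierarchy <- function(source) {
  doc <- jsonlite::fromJSON(source, simplifyVector = FALSE)
  rows <- list()
  walk <- function(node, parent) {
    if (is.null(node$id)) {
      stop_mesoconn("hierarchy node without id", "mesoconn_bad_hierarchy")
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      id = as.character(node$id),
      name = as.character(node$name %||% node$id),
      abbreviation = as.character(node$abbreviation %||% node$id),
      parent = if (is.null(parent)) NA_character_ else parent,
      side = as.character(node$side %||% "unpaired"),
      stringsAsFactors = FALSE)
    for (ch in node$children %||% list()) walk(ch, as.character(node$id))
  }
  walk(doc, NULL)
  region_hierarchy(do.call(rbind, rows))
}

#' @export
print.region_hierarchy <- function(x, ...) {
  cat("Region hierarchy:", nrow(x$regions), "regions,",
      length(leaves_at_view(x)), "leaves, depth",
      max(x$regions$level), "\n")
  invisible(x)
}

assert_region <- function(h, ids) {
  bad <- setdiff(ids, h$regions$id)
  if (length(bad) > 0L) {
    stop_mesoconn(paste("unknown region id:", paste(bad, collapse = ", ")),
                  "mesoconn_unknown_region")
  }
}

#' Leaf regions of a hierarchy view
#'
#' A view collapses selected branches: a collapsed region hides its whole
#' subtree and acts as a leaf. The returned order is the depth-first
#' document order, the canonical matrix row/column order.
#'
#' @param h A [region_hierarchy()].
#' @param collapsed Character vector of region ids to collapse.
#' @return Character vector of region ids (the view's leaves) in
#'   depth-first order.
#' @export
leaves_at_view <- function(h, collapsed = character()) {
  assert_region(h, collapsed)
  out <- character(0)
  walk <- function(id) {
    kids <- h$children[[id]]
    if (id %in% collapsed || is.null(kids)) {
      out[[length(out) + 1L]] <<- id
    } else {
      for (k in kids) walk(k)
    }
  }
  walk(h$root)
  out
}

#' All regions of a subtree
#'
#' @param h A [region_hierarchy()].
#' @param r A region id.
#' @return Character vector: `r` and all its descendants (depth-first).
#' @export
subtree <- function(h, r) {
  assert_region(h, r)
  out <- character(0)
  walk <- function(id) {
    out[[length(out) + 1L]] <<- id
    for (k in h$children[[id]] %||% character(0)) walk(k)
  }
  walk(r)
  out
}

#' Export a hierarchy
#'
#' `write_hierarchy_graphml()` writes the tree as a directed GraphML graph
#' (parent to child arcs); `write_hierarchy_table()` writes a tab-separated
#' id/parent/level table.
#'
#' @param h A [region_hierarchy()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_hierarchy_graphml <- function(h, path) {
  df <- h$regions
  edges <- df[!is.na(df$parent), c("parent", "id")]
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = df[, c("id", "name",
                                                       "abbreviation",
                                                       "level", "side")])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_hierarchy_graphml
#' @export
write_hierarchy_table <- function(h, path) {
  utils::write.table(h$regions[, c("id", "parent", "level")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
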