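#' Parameters for the synthetic connectome generator
#'
#' Defaults emulate the regime of a condensed intrinsic meso-scale
#' connectome: 49 leaf regions under an 8-level hierarchy, ~20% line
#' density (so ~464 arcs), a strong excess of reciprocal arcs over the
#' density baseline, three communities, and heavy-tailed valencies.
#'
#' @param n_leaves Number of leaf regions.
#' @param hierarchy_depth Maximum tree depth (root = level 1).
#' @param branching Children per internal node of the generated tree.
#' @param density Fraction of ordered node pairs carrying an arc.
#' @param reciprocity_excess Probability boost that the arc j->i exists
#'   given i->j: the conditional probability is
#'   `density + reciprocity_excess * (1 - density)`, so 0 gives an
#'   independence-level reciprocity and 1 makes every arc reciprocal.
#' @param n_modules Number of planted communities (contiguous leaf blocks).
#' @param mixing Relative propensity of cross-module pairs (1 = no
#'   community structure, 0 = fully disconnected modules).
#' @param weight_distribution Probabilities over ordinal weight codes 1..9.
#' @param heavy_tail_exponent Pareto tail exponent of the per-node
#'   attachment propensities (smaller = heavier tail).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(n_leaves = 49L,
                         hierarchy_depth = 8L,
                         branching = 2L,
                         density = 464 / (49 * 48),
                         reciprocity_excess = 0.6,
                         n_modules = 3L,
                         mixing = 0.4,
                         weight_distribution = c(0.05, 0.15, 0.20, 0.20,
                                                 0.15, 0.10, 0.07, 0.05,
                                                 0.03),
                         heavy_tail_exponent = 3,
                         seed = 1L) {
  stopifnot(n_leaves >= 1L, density >= 0, density <= 1,
            reciprocity_excess >= 0, reciprocity_excess <= 1,
            n_modules >= 1L, mixing >= 0, mixing <= 1,
            length(weight_distribution) == 9L,
            all(weight_distribution >= 0), sum(weight_distribution) > 0,
            heavy_tail_exponent > 1)
  structure(list(n_leaves = as.integer(n_leaves),
                 hierarchy_depth = as.integer(hierarchy_depth),
                 branching = as.integer(branching),
                 density = density,
                 reciprocity_excess = reciprocity_excess,
                 n_modules = as.integer(n_modules),
                 mixing = mixing,
                 weight_distribution = weight_distribution /
                   sum(weight_distribution),
                 heavy_tail_exponent = heavy_tail_exponent,
                 seed = as.integer(seed)),
            class = "synth_params")
}

# Balanced recursive split of ordered leaves into a tree of the requested
# depth; returns the hierarchy data.frame rows.
build_synth_tree <- function(leaf_ids, depth_budget, branching) {
  rows <- data.frame(id = "root", name = "synthetic root",
                     abbreviation = "root", parent = NA_character_,
                     stringsAsFactors = FALSE)
  counter <- 0L
  split_group <- function(ids, parent, levels_left) {
    if (length(ids) == 1L || levels_left <= 1L) {
      for (id in ids) {
        rows[nrow(rows) + 1L, ] <<- c(id, id, id, parent)
      }
      return(invisible())
    }
    k <- min(branching, length(ids))
    parts <- split(ids, cut(seq_along(ids), k, labels = FALSE))
    for (part in parts) {
      if (length(part) == 1L) {
        rows[nrow(rows) + 1L, ] <<- c(part, part, part, parent)
      } else {
        counter <<- counter + 1L
        gid <- sprintf("grp%03d", counter)
        rows[nrow(rows) + 1L, ] <<- c(gid, gid, gid, parent)
        split_group(part, gid, levels_left - 1L)
      }
    }
  }
  split_group(leaf_ids, "root", depth_budget - 1L)
  rows
}

#' Generate a synthetic hierarchical connectome
#'
#' Draws a random simple digraph over generated leaf regions with planted
#' community structure, heavy-tailed attachment propensities and a
#' controlled excess of reciprocal arcs, and emits it as connection
#' records under a generated hierarchy, i.e. in exactly the form the
#' record reader and [build_connectome()] consume. Arcs are sampled per
#' unordered pair: each direction has marginal probability equal to the
#' pair's density, and the conditional probability of the reverse arc
#' given one direction is boosted by `reciprocity_excess` (see
#' [synth_params()]), which directly plants the enrichment of fully
#' reciprocal triads that motif significance analysis should detect.
#'
#' @param p A [synth_params()] object.
#' @return A list with elements `hierarchy` (a [region_hierarchy()]),
#'   `records` (a connection-record data.frame, all ipsilateral) and
#'   `modules` (named integer vector: planted module per leaf).
#' @export
generate_connectome <- function(p = synth_params()) {
  stopifnot(inherits(p, "synth_params"))
  if (p$density == 0 && p$n_leaves > 1L) {
    stop_mesoconn("infeasible parameters: density 0 generates no arcs",
                  "mesoconn_infeasible_params")
  }
  leaf_ids <- sprintf("R%02d", seq_len(p$n_leaves))
  h <- region_hierarchy(build_synth_tree(leaf_ids, p$hierarchy_depth,
                                         p$branching))
  modules <- stats::setNames(
    as.integer(cut(seq_len(p$n_leaves), p$n_modules, labels = FALSE)),
    leaf_ids)
  records <- with_seed(p$seed, {
    n <- p$n_leaves
    if (n == 1L) {
      empty <- validate_records(data.frame(
        source = character(0), target = character(0),
        laterality = character(0), weight = integer(0)))
      empty
    } else {
      # heavy-tailed per-node propensities (Pareto with the configured
      # tail exponent, capped to keep pair probabilities < 1)
      a <- (1 - stats::runif(n))^(-1 / (p$heavy_tail_exponent - 1))
      a <- pmin(a, stats::quantile(a, 0.99) * 2)
      pair <- utils::combn(n, 2L)
      w <- a[pair[1L, ]] * a[pair[2L, ]]
      cross <- modules[pair[1L, ]] != modules[pair[2L, ]]
      w[cross] <- w[cross] * p$mixing
      # renormalize so the mean pair density equals the target even after
      # clamping
      d <- w
      for (it in 1:6) {
        d <- d * (p$density * length(d) / sum(d))
        d <- pmin(d, 0.98)
      }
      if (p$density >= 1) d <- rep(1, length(d))
      rho <- d + p$reciprocity_excess * (1 - d)
      p_both <- d * rho
      p_single <- d * (1 - rho)            # each direction separately
      u <- stats::runif(length(d))
      src <- integer(0); tgt <- integer(0)
      both <- u < p_both
      fwd <- !both & u < p_both + p_single
      bwd <- !both & !fwd & u < p_both + 2 * p_single
      src <- c(pair[1L, both], pair[2L, both], pair[1L, fwd], pair[2L, bwd])
      tgt <- c(pair[2L, both], pair[1L, both], pair[2L, fwd], pair[1L, bwd])
      m <- length(src)
      recs <- data.frame(
        source = leaf_ids[src], target = leaf_ids[tgt],
        laterality = "ipsilateral",
        weight = sample_from(1:9, m, replace = TRUE,
                             prob = p$weight_distribution),
        tracer = "synthetic", transport = "anterograde",
        case = "sim", reference = "synthetic-generator",
        stringsAsFactors = FALSE)
      ord <- order(src, tgt)
      recs[ord, , drop = FALSE]
    }
  })
  rownames(records) <- NULL
  list(hierarchy = h, records = records, modules = modules)
}

#' Write a synthetic dataset to a directory
#'
#' Emits `hierarchy.json`, `records.tsv` and `modules.tsv` in the formats
#' the package's readers consume.
#'
#' @param p A [synth_params()].
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_synthetic_dataset <- function(p, dir) {
  dataset <- generate_connectome(p)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_hierarchy_json(dataset$hierarchy, file.path(dir, "hierarchy.json"))
  write_records(dataset$records, file.path(dir, "records.tsv"))
  utils::write.table(
    data.frame(region = names(dataset$modules), module = dataset$modules),
    file.path(dir, "modules.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}

#' Serialize a hierarchy to the nested JSON document format
#' @param h A [region_hierarchy()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_hierarchy_json <- function(h, path) {
  as_node <- function(id) {
    row <- h$regions[h$regions$id == id, ]
    node <- list(id = id, name = row$name, abbreviation = row$abbreviation,
                 side = row$side)
    kids <- h$children[[id]]
    if (!is.null(kids)) node$children <- lapply(kids, as_node)
    node
  }
  jsonlite::write_json(as_node(h$root), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Small fixed validation network
#'
#' An 8-node, 14-arc strongly connected digraph (three reciprocal pairs,
#' two interlocking cycles) under a 3-level hierarchy. Every node has at
#' least one input and one output, so [condense()] leaves it unchanged.
#' Small enough that every metric in the package can be cross-checked by
#' brute-force enumeration.
#'
#' @return A list with elements `hierarchy` and `connectome`.
#' @export
fixture_small <- function() {
  nodes <- paste0("F", 1:8)
  h <- region_hierarchy(data.frame(
    id = c("FIX", "grpA", "grpB", nodes),
    name = c("fixture root", "group A", "group B", nodes),
    abbreviation = c("FIX", "gA", "gB", nodes),
    parent = c(NA, "FIX", "FIX", rep("grpA", 4), rep("grpB", 4)),
    stringsAsFactors = FALSE))
  arcs <- data.frame(
    source = c("F1", "F2", "F2", "F3", "F3", "F4", "F5", "F5", "F6",
               "F6", "F7", "F8", "F2", "F4"),
    target = c("F2", "F1", "F3", "F2", "F4", "F5", "F1", "F6", "F5",
               "F7", "F8", "F6", "F5", "F8"),
    weight = c(5L, 3L, 4L, 2L, 6L, 7L, 1L, 5L, 4L, 3L, 2L, 6L, 8L, 1L),
    n_studies = c(2L, 1L, 1L, 1L, 3L, 1L, 1L, 2L, 1L, 1L, 1L, 1L, 1L, 1L),
    stringsAsFactors = FALSE)
  list(hierarchy = h, connectome = connectome(nodes, arcs))
}
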