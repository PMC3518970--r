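# Full analysis pipeline over a dataset: condense -> global -> local ->
# motifs -> matrices -> vulnerability -> PCA, with every artifact written
# as a diff-able TSV/GraphML file and the full configuration recorded.

#' Run the full analysis pipeline
#'
#' Loads a hierarchy and connection records (paths or in-memory objects),
#' builds and condenses the connectome for the selected view, and writes
#' the complete analysis report: global metrics (with an Erdos-Renyi and
#' a rewiring ensemble comparison), the local parameter table, motif
#' censuses with rewiring significance, distance/communicability/matching
#' matrices, node and arc vulnerability, and the PCA profile with its
#' Parzen density grid. All randomness flows from `seed`; rerunning with
#' the same inputs and configuration reproduces every artifact
#' byte-identically.
#'
#' @param hierarchy A [region_hierarchy()] or path to a hierarchy JSON.
#' @param records A record data.frame or path to a records CSV/TSV.
#' @param out_dir Output directory (created; must be writable).
#' @param collapsed Region ids to collapse in the view.
#' @param side `"unilateral"` or `"bilateral"`.
#' @param seed Master seed.
#' @param n_rand Replicates for ensembles and motif significance.
#' @param motif_k Motif sizes to census.
#' @param swap_multiplier Swaps per arc for rewiring nulls.
#' @param shapley_perms Monte-Carlo permutations when the network is too
#'   large for exact Shapley enumeration.
#' @return The output directory, invisibly.
#' @export
run_report <- function(hierarchy, records, out_dir,
                       collapsed = character(), side = "unilateral",
                       seed = 1L, n_rand = 100L, motif_k = c(3L, 4L),
                       swap_multiplier = 10L, shapley_perms = 2000L) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_mesoconn(sprintf("stage '%s' failed: %s", name,
                            conditionMessage(e)),
                    "mesoconn_stage_failure")
    })
  }
  cfg <- list(collapsed = collapsed, side = side, seed = seed,
              n_rand = n_rand, motif_k = motif_k,
              swap_multiplier = swap_multiplier,
              shapley_perms = shapley_perms)
  h <- stage("load_hierarchy", {
    if (inherits(hierarchy, "region_hierarchy")) hierarchy
    else if (is.character(hierarchy) && file.exists(hierarchy)) {
      load_hierarchy(hierarchy)
    } else stop("hierarchy input missing or unreadable")
  })
  recs <- stage("load_records", {
    if (is.data.frame(records)) validate_records(records)
    else if (is.character(records) && file.exists(records)) {
      read_records(records)
    } else stop("records input missing or unreadable")
  })
  # all inputs validated; only now touch the output directory
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name, rows = FALSE) {
    utils::write.table(x, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = rows,
                       col.names = if (rows) NA else TRUE)
  }
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  net <- stage("condense", {
    leaves <- leaves_at_view(h, collapsed)
    condense(build_connectome(recs, leaves, h, side))
  })
  if (length(net$nodes) < 3L) {
    stop_mesoconn("condensed network too small to analyse",
                  "mesoconn_stage_failure")
  }
  write_connectome_graphml(net, file.path(out_dir, "connectome.graphml"))
  tsv(adjacency_matrix(net), "adjacency.tsv", rows = TRUE)

  stage("global", {
    gs <- global_summary(net, n_rand = n_rand, seed = seed)
    tsv(as.data.frame(unclass(gs)), "global.tsv")
    er <- null_ensemble("erdos_renyi", n = length(net$nodes),
                        e = nrow(net$arcs), replicates = n_rand,
                        seed = seed + 1L)
    rw <- null_ensemble("rewire", replicates = n_rand, seed = seed + 2L,
                        reference = net, swap_multiplier = swap_multiplier)
    summarize <- function(df, kind) {
      metrics <- setdiff(names(df), c("replicate", "seed"))
      data.frame(kind = kind, metric = metrics,
                 mean = vapply(df[metrics], mean, 0),
                 sd = vapply(df[metrics], stats::sd, 0))
    }
    tsv(rbind(summarize(er, "erdos_renyi"), summarize(rw, "rewire")),
        "global_nulls.tsv")
  })

  partition <- stage("modularity", modularity_partition(net, seed = seed))
  tsv(data.frame(region = names(partition$membership),
                 module = partition$membership), "modules.tsv")

  stage("local", {
    lt <- local_table(net, partition = partition$membership,
                      shapley_perms = shapley_perms, seed = seed)
    tsv(lt[order(-lt$DGa), ], "local.tsv")
  })

  stage("motifs", {
    for (k in motif_k) {
      ms <- motif_significance(net, k, n_rand = n_rand,
                               swap_multiplier = swap_multiplier,
                               seed = seed + k)
      tsv(ms, sprintf("motifs_k%d.tsv", k))
    }
  })

  stage("matrices", {
    write_pair_matrix(distance_matrix(net),
                      file.path(out_dir, "distance.tsv"))
    write_pair_matrix(communicability_matrix(net),
                      file.path(out_dir, "communicability.tsv"))
    for (m in c("in", "out", "all")) {
      write_pair_matrix(matching_matrix(net, m),
                        file.path(out_dir, sprintf("matching_%s.tsv", m)))
    }
  })

  stage("vulnerability", {
    sig <- node_significance(net)
    tsv(data.frame(region = names(sig), significance = sig)[
      order(-sig), ], "vulnerability_nodes.tsv")
    write_pair_matrix(edge_vulnerability_matrix(net),
                      file.path(out_dir, "vulnerability_arcs.tsv"))
  })

  stage("pca", {
    feats <- feature_table(net)
    tsv(feats, "pca_features.tsv")
    pr <- pca_profile(feats)
    tsv(data.frame(feature = rownames(pr$loadings), pr$loadings,
                   check.names = FALSE), "pca_loadings.tsv")
    tsv(data.frame(component = seq_along(pr$shares),
                   share_percent = pr$shares), "pca_shares.tsv")
    tsv(data.frame(region = rownames(pr$scores), pr$scores,
                   check.names = FALSE), "pca_scores.tsv")
    dens <- parzen_density(pr$scores_plane)
    tsv(dens$z, "pca_density.tsv", rows = TRUE)
  })
  invisible(out_dir)
}
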