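test_that("class enumeration finds the canonical counts", {
  expect_equal(nrow(enumerate_motif_classes(2)), 2L)
  expect_equal(nrow(enumerate_motif_classes(3)), 13L)
  expect_equal(nrow(enumerate_motif_classes(4)), 199L)
  expect_error(enumerate_motif_classes(5),
               class = "mesoconn_infeasible_params")
})

test_that("anchor classes sit at their conventional ids", {
  cl <- enumerate_motif_classes(3)
  reps <- attr(cl, "representatives")
  # ids ascend by arc count
  expect_equal(cl$arc_count, sort(cl$arc_count))
  expect_equal(cl$arc_count[1:3], rep(2L, 3))       # 3-01..3-03 two-arc
  # 3-07 is the directed 3-cycle
  cyc <- matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3, 3, byrow = TRUE)
  expect_true(igraph::isomorphic(
    igraph::graph_from_adjacency_matrix(reps[[7]]),
    igraph::graph_from_adjacency_matrix(cyc)))
  # 3-13 is the fully reciprocal triad
  expect_equal(sum(reps[[13]]), 6)
  expect_true(all(reps[[13]] == t(reps[[13]])))
  # stability across calls
  expect_identical(cl$canonical_code,
                   enumerate_motif_classes(3)$canonical_code)
})

test_that("census classifies forced subgraphs correctly", {
  counts <- count_motifs(cycle3(), 3)
  expect_equal(unname(counts["3-07"]), 1L)
  expect_equal(sum(counts), 1L)
  triad <- connectome(c("A", "B", "C"),
                      arc_df(c("A", "B", "B", "C", "A", "C"),
                             c("B", "A", "C", "B", "C", "A")))
  expect_equal(unname(count_motifs(triad, 3)["3-13"]), 1L)
  k4 <- complete_digraph(4)
  expect_equal(unname(count_motifs(k4, 3)["3-13"]), 4L)
  expect_equal(unname(count_motifs(k4, 4)["4-199"]), 1L)
  pair <- reciprocal_pair()
  expect_equal(unname(count_motifs(pair, 2)["2-02"]), 1L)
})

test_that("census equals the classify-every-subset oracle", {
  for (seed in 1:8) {
    g <- rand_connectome(7 + seed %% 4, 0.3, seed + 70)
    expect_equal(count_motifs(g, 3), oracle_census(g, 3))
  }
  g <- rand_connectome(7, 0.35, 99)
  expect_equal(count_motifs(g, 4), oracle_census(g, 4))
})

test_that("census totals count the weakly connected subsets", {
  g <- rand_connectome(10, 0.25, 5)
  A <- adjacency_matrix(g) > 0
  connected_subsets <- sum(vapply(
    utils::combn(10, 3, simplify = FALSE),
    function(s) {
      U <- (A[s, s] | t(A[s, s])) * 1
      igraph::is_connected(igraph::graph_from_adjacency_matrix(
        U, mode = "undirected"))
    }, TRUE))
  expect_equal(sum(count_motifs(g, 3)), connected_subsets)
})

test_that("census is invariant under node relabeling", {
  g <- rand_connectome(9, 0.3, 14)
  set.seed(21)
  perm <- sample(g$nodes)
  arcs <- g$arcs
  relabel <- stats::setNames(perm, g$nodes)
  arcs$source <- unname(relabel[arcs$source])
  arcs$target <- unname(relabel[arcs$target])
  g2 <- connectome(perm, arcs)
  expect_equal(count_motifs(g2, 3), count_motifs(g, 3))
})

test_that("significance on a saturated graph degenerates gracefully", {
  ms <- motif_significance(complete_digraph(4), 3, n_rand = 10, seed = 1)
  full <- ms[ms$motif_id == "3-13", ]
  expect_equal(full$rand_sd, 0)
  expect_equal(full$z, 0)
  expect_equal(full$p, 1)
})

test_that("a reciprocity-enriched network shows 3-13 excess, p = 0", {
  ds <- generate_connectome(synth_params(n_leaves = 30L,
                                         reciprocity_excess = 0.6,
                                         seed = 17L))
  net <- condense(build_connectome(ds$records,
                                   leaves_at_view(ds$hierarchy),
                                   ds$hierarchy))
  ms <- motif_significance(net, 3, n_rand = 50, seed = 18)
  row <- ms[ms$motif_id == "3-13", ]
  expect_equal(row$p, 0)
  expect_gt(row$z, 2)
  # determinism of the whole significance table
  expect_identical(ms, motif_significance(net, 3, n_rand = 50, seed = 18))
})

test_that("an ER graph is unremarkable against its own rewiring null", {
  g <- null_erdos_renyi(15, 60, seed = 23)
  ms <- motif_significance(g, 3, n_rand = 100, seed = 24)
  expect_gte(sum(abs(ms$z) < 3), 11L)
})

test_that("participation counts regions inside matching subsets", {
  triad <- connectome(c("A", "B", "C"),
                      arc_df(c("A", "B", "B", "C", "A", "C"),
                             c("B", "A", "C", "B", "C", "A")))
  expect_equal(unname(motif_participation(triad, "3-13")), rep(1L, 3))
  k4 <- complete_digraph(4)
  expect_equal(unname(motif_participation(k4, "3-13")), rep(3L, 4))
  g <- rand_connectome(9, 0.3, 31)
  counts <- count_motifs(g, 3)
  for (id in c("3-02", "3-07", "3-13")) {
    expect_equal(sum(motif_participation(g, id)),
                 3L * unname(counts[id]))
  }
  expect_error(motif_participation(g, "3-99"),
               class = "mesoconn_unknown_motif")
})
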