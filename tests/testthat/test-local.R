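test_that("degree identities hold on random graphs", {
  for (seed in 1:3) {
    g <- rand_connectome(9, 0.3, seed)
    lt <- local_table(g, seed = 1)
    expect_equal(lt$DGa, lt$DGo + lt$DGi)
    expect_equal(sum(lt$DGo), n_arcs(g))
    expect_equal(sum(lt$DGi), n_arcs(g))
    expect_true(all(lt$PCa >= 0 & lt$PCa <= 1))
    if (n_arcs(g) > 0) expect_equal(max(lt$EC), 1)
  }
})

test_that("the directed 3-cycle has unit betweenness everywhere", {
  lt <- local_table(cycle3(), seed = 1)
  expect_equal(lt$BC, rep(1, 3))
  expect_equal(lt$St, rep(1, 3))
  expect_equal(lt$Co, rep(0.75, 3))   # distances 1 and 2: (1 + 1/2)/2
  expect_equal(lt$Ecco, rep(2, 3))
})

test_that("complete digraphs give identical rows with EC = 1", {
  lt <- local_table(complete_digraph(4), seed = 1)
  for (col in setdiff(names(lt), "region")) {
    expect_lt(diff(range(lt[[col]])), 1e-9)
  }
  expect_equal(lt$EC, rep(1, 4))
  expect_equal(lt$CCa, rep(1, 4))
  expect_equal(lt$Co, rep(1, 4))
})

test_that("betweenness and stress match the all-geodesics oracle", {
  for (seed in 1:6) {
    g <- rand_connectome(6, 0.35, seed + 10)
    lt <- local_table(g, seed = 1)
    oracle <- oracle_bc_stress(g)
    expect_equal(lt$BC, oracle$bc, tolerance = 1e-10)
    expect_equal(lt$St, oracle$st, tolerance = 1e-10)
  }
})

test_that("Shapley values follow the coalition-game closed forms", {
  iso <- connectome(c("A", "B", "C"))
  expect_equal(unname(shapley_rates(iso, mode = "exact")), rep(1, 3))
  expect_equal(unname(shapley_rates(reciprocal_pair(), mode = "exact")),
               c(0.5, 0.5))
  expect_equal(unname(shapley_rates(cycle3(), mode = "exact")),
               rep(1 / 3, 3))
  expect_error(shapley_rates(null_erdos_renyi(12, 30, 1), mode = "exact"),
               class = "mesoconn_infeasible_params")
})

test_that("exact Shapley equals full permutation enumeration", {
  for (seed in 1:3) {
    g <- rand_connectome(5, 0.4, seed + 30)
    expect_equal(shapley_rates(g, mode = "exact"), oracle_shapley(g),
                 tolerance = 1e-12)
  }
})

test_that("Shapley values sum to the number of SCCs", {
  for (seed in 1:5) {
    g <- rand_connectome(8, 0.25, seed + 40)
    sh <- shapley_rates(g, mode = "exact")
    expect_equal(sum(sh), oracle_scc_count(adjacency_matrix(g) > 0),
                 tolerance = 1e-10)
  }
})

test_that("Monte-Carlo Shapley is seed-deterministic in both regimes", {
  fx <- fixture_small()$connectome
  a <- shapley_rates(fx, mode = "monte_carlo", n_perms = 500, seed = 9)
  expect_identical(a, shapley_rates(fx, mode = "monte_carlo",
                                    n_perms = 500, seed = 9))
  big <- null_erdos_renyi(15, 60, seed = 1)
  b <- shapley_rates(big, mode = "monte_carlo", n_perms = 20, seed = 9)
  expect_identical(b, shapley_rates(big, mode = "monte_carlo",
                                    n_perms = 20, seed = 9))
  expect_equal(sum(b), 1, tolerance = 0.5)  # within Monte-Carlo noise
})

test_that("cycle counts enumerate 2- and 3-cycles through a region", {
  expect_equal(cycle_counts(reciprocal_pair(), "A", 2), 1L)
  expect_equal(cycle_counts(cycle3(), "A", 2), 0L)
  expect_equal(cycle_counts(cycle3(), "A", 3), 1L)
  k3 <- complete_digraph(3)
  expect_equal(cycle_counts(k3, "A", 2), 2L)
  expect_equal(cycle_counts(k3, "A", 3), 2L)
  expect_error(cycle_counts(cycle3(), "Z", 2),
               class = "mesoconn_unknown_region")
})

test_that("module roles respond to the planted partition", {
  g <- connectome(LETTERS[1:6],
                  arc_df(c("A", "B", "C", "D", "E", "F", "A"),
                         c("B", "C", "A", "E", "F", "D", "D")))
  partition <- stats::setNames(c(1L, 1L, 1L, 2L, 2L, 2L), LETTERS[1:6])
  lt <- local_table(g, partition = partition, seed = 1)
  # A is the only node with a cross-module arc: positive participation
  expect_gt(lt$PCo[lt$region == "A"], 0)
  expect_equal(lt$PCo[lt$region == "B"], 0)
})
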