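test_that("feature vectors respect symmetry and hand counts", {
  ft <- feature_table(complete_digraph(4))
  for (col in setdiff(names(ft), "region")) {
    expect_equal(length(unique(ft[[col]])), 1L)
  }
  # star: hub with 4 reciprocal spokes
  star <- connectome(c("H", "S1", "S2", "S3", "S4"),
                     arc_df(c("H", "H", "H", "H", "S1", "S2", "S3", "S4"),
                            c("S1", "S2", "S3", "S4", "H", "H", "H", "H")))
  ft_star <- feature_table(star)
  expect_equal(ft_star$DG_all[ft_star$region == "H"], 8)
  expect_equal(ft_star$AvgDG_nb[ft_star$region == "S1"], 8)
  expect_equal(ft_star$VC_DG[ft_star$region == "S1"], 0)  # single neighbour
  expect_equal(ft_star$Loc[ft_star$region == "H"], 1)     # all arcs inside
})

test_that("PCA shares always sum to 100 and components are orthonormal", {
  g <- condense(build_connectome(
    generate_connectome(synth_params(n_leaves = 25L, seed = 5L))$records,
    sprintf("R%02d", 1:25)))
  pr <- pca_profile(feature_table(g))
  expect_equal(sum(pr$shares), 100, tolerance = 1e-6)
  gram <- t(pr$loadings) %*% pr$loadings
  expect_equal(unname(gram), diag(ncol(pr$loadings)), tolerance = 1e-8)
  # sign convention: the dominant loading of each component is positive
  for (j in seq_len(ncol(pr$loadings))) {
    v <- pr$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
})

test_that("collinear features concentrate all variance on component 1", {
  f <- data.frame(region = paste0("r", 1:6),
                  DG_all = 1:6, AvgDG_nb = 2 * (1:6) + 3,
                  CluC_all = -(1:6), CluC_2 = 0.5 * (1:6),
                  VC_DG = 1:6, Loc = 3 * (1:6))
  pr <- pca_profile(f)
  expect_equal(pr$shares[1], 100, tolerance = 1e-8)
})

test_that("scores reproduce an independent spectral decomposition", {
  set.seed(8)
  f <- data.frame(region = paste0("r", 1:20),
                  matrix(rnorm(120), 20, 6,
                         dimnames = list(NULL, c("DG_all", "AvgDG_nb",
                                                 "CluC_all", "CluC_2",
                                                 "VC_DG", "Loc"))))
  pr <- pca_profile(f)
  x <- scale(as.matrix(f[, -1]))
  eg <- eigen(stats::cor(as.matrix(f[, -1])))
  oracle_scores <- x %*% eg$vectors
  for (j in 1:2) {
    got <- pr$scores[, j]
    expect_true(max(abs(got - oracle_scores[, j])) < 1e-8 ||
                  max(abs(got + oracle_scores[, j])) < 1e-8)
  }
  expect_equal(pr$shares, 100 * eg$values / sum(eg$values),
               tolerance = 1e-8)
})

test_that("zero-variance features are dropped with a warning", {
  f <- data.frame(region = paste0("r", 1:5), DG_all = 1:5,
                  AvgDG_nb = rnorm(5), CluC_all = 1, CluC_2 = rnorm(5),
                  VC_DG = rnorm(5), Loc = rnorm(5))
  expect_warning(pr <- pca_profile(f), "zero-variance")
  expect_equal(pr$dropped, "CluC_all")
  expect_equal(ncol(pr$loadings), 5L)
})

test_that("the Parzen surface is a normalized, relabel-invariant density", {
  set.seed(10)
  pts <- matrix(rnorm(60), 30, 2)
  d <- parzen_density(pts)
  expect_equal(d$integral, 1, tolerance = 0.02)
  d2 <- parzen_density(pts[sample(30), ])
  expect_equal(d$z, d2$z)
  # single point: the mode sits at the point
  d1 <- parzen_density(matrix(c(1, 2), 1, 2), bandwidth = 0.5)
  peak <- which(d1$z == max(d1$z), arr.ind = TRUE)
  expect_equal(d1$x[peak[1]], 1, tolerance = 0.05)
  expect_equal(d1$y[peak[2]], 2, tolerance = 0.05)
  # two far points: two equal local maxima
  d2p <- parzen_density(rbind(c(-10, 0), c(10, 0)), bandwidth = 1)
  zx <- apply(d2p$z, 1, max)
  left <- max(zx[d2p$x < 0]); right <- max(zx[d2p$x > 0])
  expect_equal(left, right, tolerance = 1e-10)
  expect_error(parzen_density(pts, bandwidth = -1),
               class = "mesoconn_infeasible_params")
})

test_that("neighbourhood rings partition the local environment", {
  star <- connectome(c("H", "S1", "S2"),
                     arc_df(c("H", "H", "S1", "S2"),
                            c("S1", "S2", "H", "H")))
  rings <- neighborhood_rings(star, "H")
  expect_setequal(rings$ring1, c("S1", "S2"))
  expect_length(rings$ring2, 0L)
  chain <- connectome(c("A", "B", "C", "D"),
                      arc_df(c("A", "B", "B", "C", "C", "D"),
                             c("B", "A", "C", "B", "D", "C")))
  rings_a <- neighborhood_rings(chain, "A")
  expect_equal(rings_a$ring1, "B")
  expect_equal(rings_a$ring2, "C")
  expect_equal(unname(rings_a$arc_counts["between_rings"]), 2)
  k4 <- complete_digraph(4)
  expect_length(neighborhood_rings(k4, "A")$ring2, 0L)
  expect_error(neighborhood_rings(k4, "Z"),
               class = "mesoconn_unknown_region")
})
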