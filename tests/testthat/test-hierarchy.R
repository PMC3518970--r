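test_that("hierarchy validation rejects malformed trees", {
  base <- data.frame(id = c("a", "b"), name = c("a", "b"),
                     abbreviation = c("a", "b"), parent = c(NA, "a"))
  expect_s3_class(region_hierarchy(base), "region_hierarchy")
  dup <- rbind(base, data.frame(id = "b", name = "b2", abbreviation = "b2",
                                parent = "a"))
  expect_error(region_hierarchy(dup), class = "mesoconn_duplicate_id")
  two_roots <- data.frame(id = c("a", "b"), name = c("a", "b"),
                          abbreviation = c("a", "b"),
                          parent = c(NA, NA))
  expect_error(region_hierarchy(two_roots),
               class = "mesoconn_multiple_roots")
  orphan <- data.frame(id = c("a", "b"), name = c("a", "b"),
                       abbreviation = c("a", "b"),
                       parent = c(NA, "ghost"))
  expect_error(region_hierarchy(orphan), class = "mesoconn_missing_parent")
  cyclic <- data.frame(id = c("a", "b", "c"), name = c("a", "b", "c"),
                       abbreviation = c("a", "b", "c"),
                       parent = c(NA, "c", "b"))
  expect_error(region_hierarchy(cyclic), class = "mesoconn_cycle")
})

test_that("a single-region document is root and leaf at once", {
  h <- load_hierarchy('{"id": "solo", "name": "solo"}')
  expect_equal(nrow(h$regions), 1L)
  expect_equal(leaves_at_view(h), "solo")
  expect_equal(h$regions$level, 1L)
})

test_that("binary tree traversal yields leaves in depth-first order", {
  h <- binary_hierarchy()
  expect_equal(nrow(h$regions), 7L)
  expect_equal(leaves_at_view(h), c("LL", "LR", "RL", "RR"))
  expect_equal(h$regions$level[h$regions$id == "RR"], 3L)
})

test_that("collapsing substitutes whole subtrees by their root", {
  h <- binary_hierarchy()
  expect_equal(leaves_at_view(h, collapsed = c("L", "R")), c("L", "R"))
  expect_equal(leaves_at_view(h, collapsed = "L"), c("L", "RL", "RR"))
  expect_equal(leaves_at_view(h, collapsed = "root"), "root")
  expect_error(leaves_at_view(h, collapsed = "nope"),
               class = "mesoconn_unknown_region")
})

test_that("every true leaf has exactly one ancestor-or-self in any view", {
  h <- binary_hierarchy()
  true_leaves <- leaves_at_view(h)
  views <- list(character(0), "L", "R", c("L", "R"), "root", "LL")
  for (collapsed in views) {
    view <- leaves_at_view(h, collapsed)
    for (leaf in true_leaves) {
      covering <- vapply(view, function(v) leaf %in% subtree(h, v), TRUE)
      expect_equal(sum(covering), 1L)
    }
  }
})

test_that("relative order of surviving regions is stable under collapse", {
  h <- binary_hierarchy()
  full <- leaves_at_view(h)
  partial <- leaves_at_view(h, collapsed = "L")
  surviving <- intersect(full, partial)
  expect_equal(match(surviving, partial), sort(match(surviving, partial)))
})

test_that("subtree returns the region plus all descendants", {
  h <- binary_hierarchy()
  expect_equal(subtree(h, "LL"), "LL")
  expect_length(subtree(h, "root"), 7L)
  expect_setequal(subtree(h, "R"), c("R", "RL", "RR"))
  expect_error(subtree(h, "missing"), class = "mesoconn_unknown_region")
})

test_that("JSON and table exports round-trip the structure", {
  h <- binary_hierarchy()
  json_path <- withr::local_tempfile(fileext = ".json")
  write_hierarchy_json(h, json_path)
  h2 <- load_hierarchy(json_path)
  expect_setequal(h2$regions$id, h$regions$id)
  expect_equal(leaves_at_view(h2), leaves_at_view(h))
  expect_equal(subtree(h2, "L"), subtree(h, "L"))

  tab_path <- withr::local_tempfile(fileext = ".tsv")
  write_hierarchy_table(h, tab_path)
  tab <- read.delim(tab_path)
  expect_equal(nrow(tab), 7L)
  expect_equal(sort(tab$level), c(1L, 2L, 2L, 3L, 3L, 3L, 3L))

  gml_path <- withr::local_tempfile(fileext = ".graphml")
  write_hierarchy_graphml(h, gml_path)
  g <- igraph::read_graph(gml_path, format = "graphml")
  expect_equal(igraph::vcount(g), 7L)
  expect_equal(igraph::ecount(g), 6L)
})
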