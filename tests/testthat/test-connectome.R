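test_that("records aggregate by maximum weight and study count", {
  recs <- record_row(c("A", "A"), c("B", "B"), weight = c(3L, 5L))
  c <- build_connectome(recs, c("A", "B"))
  expect_equal(nrow(c$arcs), 1L)
  expect_equal(c$arcs$weight, 5L)
  expect_equal(c$arcs$n_studies, 2L)
})

test_that("records below a visible leaf aggregate up to it", {
  h <- binary_hierarchy()
  recs <- record_row("LL", "RL")      # LL sits under collapsed L
  c <- build_connectome(recs, leaves_at_view(h, collapsed = "L"), h)
  expect_equal(c$arcs$source, "L")
  expect_equal(c$arcs$target, "RL")
  # record at a region under no visible leaf is an error
  expect_error(
    build_connectome(record_row("ghost", "RL"),
                     leaves_at_view(h, collapsed = "L"), h),
    class = "mesoconn_unresolved_region")
})

test_that("laterality filtering and bilateral mirroring behave", {
  recs <- record_row("A", "B", laterality = "contralateral")
  uni <- build_connectome(recs, c("A", "B"), side = "unilateral")
  expect_equal(nrow(uni$arcs), 0L)
  bi <- build_connectome(recs, c("A", "B"), side = "bilateral")
  expect_setequal(paste(bi$arcs$source, bi$arcs$target),
                  c("L.A R.B", "R.A L.B"))
  # mirror-symmetric record sets give a graph automorphic under side swap
  mixed <- rbind(record_row("A", "B"), recs)
  bi2 <- build_connectome(mixed, c("A", "B"), side = "bilateral")
  swap <- function(x) {
    ifelse(startsWith(x, "L."), sub("^L\\.", "R.", x),
           sub("^R\\.", "L.", x))
  }
  swapped <- sort(paste(swap(bi2$arcs$source), swap(bi2$arcs$target)))
  expect_equal(swapped, sort(paste(bi2$arcs$source, bi2$arcs$target)))
})

test_that("weight code 0 records never become arcs", {
  recs <- record_row(c("A", "A"), c("B", "C"), weight = c(0L, 2L))
  c <- build_connectome(recs, c("A", "B", "C"))
  expect_equal(paste(c$arcs$source, c$arcs$target), "A C")
})

test_that("record validation rejects unknown tokens and bad codes", {
  expect_error(validate_records(record_row("A", "B", laterality = "both")),
               class = "mesoconn_bad_records")
  expect_error(validate_records(record_row("A", "B", weight = 12L)),
               class = "mesoconn_bad_records")
  bad_transport <- record_row("A", "B")
  bad_transport$transport <- "sideways"
  expect_error(validate_records(bad_transport),
               class = "mesoconn_bad_records")
})

test_that("condensation cascades to the fixpoint", {
  chain <- connectome(c("A", "B", "C"),
                      arc_df(c("A", "B"), c("B", "C")))
  expect_equal(n_nodes(condense(chain)), 0L)
  expect_equal(condense(cycle3())$nodes, cycle3()$nodes)
  pendant <- connectome(c("A", "B", "C", "D"),
                        arc_df(c("A", "B", "C", "A"),
                               c("B", "C", "A", "D")))
  condensed <- condense(pendant)
  expect_equal(condensed$nodes, c("A", "B", "C"))
  deg <- in_out_degrees(condensed)
  expect_true(all(deg$out >= 1L) && all(deg$inn >= 1L))
})

test_that("isolated nodes are dropped, connected ones kept", {
  c <- connectome(c("A", "B", "C", "D", "E", "F", "G"),
                  arc_df(c("A", "C"), c("B", "D")))
  expect_equal(remove_isolated(c)$nodes, c("A", "B", "C", "D"))
  expect_equal(remove_isolated(cycle3())$nodes, cycle3()$nodes)
})

test_that("adjacency matrix round-trips arcs and weights exactly", {
  fx <- fixture_small()$connectome
  A <- adjacency_matrix(fx)
  expect_equal(dim(A), c(8L, 8L))
  rebuilt <- connectome_from_adjacency(A)
  expect_equal(rebuilt$nodes, fx$nodes)
  expect_equal(adjacency_matrix(rebuilt), A)
  expect_equal(dim(adjacency_matrix(connectome(character(0)))), c(0L, 0L))
  one <- connectome(c("A", "B"), arc_df("A", "B", weight = 4L))
  expect_equal(adjacency_matrix(one)["A", "B"], 4L)
  expect_equal(sum(adjacency_matrix(one)), 4L)
  A3 <- adjacency_matrix(cycle3())
  expect_equal(rowSums(A3 > 0), c(A = 1, B = 1, C = 1))
  expect_equal(colSums(A3 > 0), c(A = 1, B = 1, C = 1))
})

test_that("connectome exports are readable round trips", {
  fx <- fixture_small()$connectome
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_connectome_graphml(fx, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), 14)
  expect_setequal(igraph::vertex_attr(g, "name"), fx$nodes)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_adjacency_tsv(fx, tsv)
  A <- as.matrix(read.delim(tsv, row.names = 1))
  expect_equal(unname(A), unname(adjacency_matrix(fx)),
               ignore_attr = TRUE)
  csvp <- withr::local_tempfile(fileext = ".csv")
  recs <- record_row(c("A", "B"), c("B", "C"))
  write_records(recs, csvp)
  expect_equal(read_records(csvp)$target, c("B", "C"))
})
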