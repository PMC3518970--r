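# Small graph constructors used across tests.

arc_df <- function(src, tgt, weight = 1L, n_studies = 1L) {
  data.frame(source = src, target = tgt, weight = weight,
             n_studies = n_studies, stringsAsFactors = FALSE)
}

cycle3 <- function() {
  connectome(c("A", "B", "C"), arc_df(c("A", "B", "C"), c("B", "C", "A")))
}

complete_digraph <- function(n) {
  nodes <- LETTERS[seq_len(n)]
  pairs <- expand.grid(s = nodes, t = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$s != pairs$t, ]
  connectome(nodes, arc_df(pairs$s, pairs$t))
}

reciprocal_pair <- function() {
  connectome(c("A", "B"), arc_df(c("A", "B"), c("B", "A")))
}

# uniformly random simple digraph as a connectome
rand_connectome <- function(n, p = 0.3, seed = NULL) {
  e <- withr::with_seed(seed, stats::rbinom(1, n * (n - 1), p))
  null_erdos_renyi(n, e, seed)
}

record_row <- function(source, target, laterality = "ipsilateral",
                       weight = 3L, ...) {
  data.frame(source = source, target = target, laterality = laterality,
             weight = weight, ..., stringsAsFactors = FALSE)
}

# 7-region balanced binary hierarchy (root, 2 internal, 4 leaves)
binary_hierarchy <- function() {
  region_hierarchy(data.frame(
    id = c("root", "L", "R", "LL", "LR", "RL", "RR"),
    name = paste("region", 1:7),
    abbreviation = c("root", "L", "R", "LL", "LR", "RL", "RR"),
    parent = c(NA, "root", "root", "L", "L", "R", "R"),
    stringsAsFactors = FALSE))
}

in_out_degrees <- function(c) {
  list(out = as.integer(table(factor(c$arcs$source, levels = c$nodes))),
       inn = as.integer(table(factor(c$arcs$target, levels = c$nodes))))
}
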