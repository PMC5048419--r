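make_tf_collection <- function() {
  gene_set_collection("tfs", "tf_target",
                      list(TFa = c("A", "B", "C", "D"),
                           TFb = c("E", "F", "G"),
                           TFc = c("H", "I", "J", "K")))
}

test_that("a correlated set identical to one TF's targets ranks that TF first", {
  col <- make_tf_collection()
  assoc <- tf_associations(list(l1 = c("A", "B", "C", "D")), col)
  expect_identical(assoc$tf[1], "TFa")
  expect_identical(assoc$k[1], 4L)
  # every TF is reported, disjoint ones with k = 0 and p = 1
  expect_identical(nrow(assoc), 3L)
  expect_true(all(assoc$p_hyper[assoc$k == 0] == 1))

  disjoint <- tf_associations(list(l1 = c("E", "F")),
                              gene_set_collection("tfs", "tf_target",
                                                  list(TFa = c("A", "B")),
                                                  universe = LETTERS[1:6]))
  expect_identical(disjoint$k, 0L)
  expect_identical(disjoint$p_hyper, 1)
})

test_that("empty correlated sets are skipped with a warning", {
  col <- make_tf_collection()
  expect_warning(assoc <- tf_associations(
    list(l1 = c("A", "B"), l2 = character()), col), "empty")
  expect_setequal(unique(assoc$lncrna), "l1")
  expect_error(tf_associations(list(), col), class = "lncnet_value_error")
  expect_error(tf_associations(list(l1 = "A"),
                               gene_set_collection("t", "term",
                                                   list(s = "A"))),
               class = "lncnet_value_error")
})

test_that("duplicate (TF, lncRNA) records collapse to the best p", {
  assoc <- data.frame(lncrna = c("l1", "l1", "l2"),
                      tf = c("TFa", "TFa", "TFa"),
                      N = 10L, K = 4L, n = 3L, k = c(3L, 1L, 2L),
                      p_hyper = c(0.01, 0.4, 0.1), fdr = NA_real_,
                      overlap = "", stringsAsFactors = FALSE)
  net <- build_lncrna_tf_network(assoc, top_pairs = 10)
  s <- network_stats(net)
  expect_identical(s$n_edges, 2L)
  expect_identical(s$n_nodes, 3L)
})

test_that("the lncRNA-TF network honours top_pairs and forms stars", {
  assoc <- data.frame(lncrna = sprintf("l%d", 1:5),
                      tf = c("TFa", "TFa", "TFa", "TFa", "TFb"),
                      N = 10L, K = 4L, n = 3L, k = 2L,
                      p_hyper = c(.01, .02, .03, .04, .05), fdr = NA_real_,
                      overlap = "", stringsAsFactors = FALSE)
  net2 <- build_lncrna_tf_network(assoc, top_pairs = 2)
  s2 <- network_stats(net2)
  expect_identical(s2$n_edges, 2L)
  expect_lte(s2$n_nodes, 4L)
  star <- build_lncrna_tf_network(assoc[1:4, ], top_pairs = 10)
  ss <- network_stats(star)
  expect_identical(ss$n_nodes, 5L)
  expect_identical(ss$n_edges, 4L)
  expect_identical(ss$hubs$degree[ss$hubs$id == "TFa"], 4L)
  # edge count = min(top_pairs, deduplicated associations)
  expect_identical(network_stats(build_lncrna_tf_network(
    assoc, top_pairs = 100))$n_edges, 5L)
})

test_that("the tripartite network is constructed by explicit counting", {
  lnc <- c("l1", "l2")
  assoc <- data.frame(lncrna = c("l1", "l1", "l2", "l3"),
                      tf = c("TFa", "TFb", "TFc", "TFa"),
                      N = 20L, K = 5L, n = 4L, k = 2L,
                      p_hyper = c(.001, .002, .003, .0001), fdr = NA_real_,
                      overlap = "", stringsAsFactors = FALSE)
  pairs <- data.frame(lncrna_probe = c("l1", "l1", "l2", "l2", "l3"),
                      mrna_probe = sprintf("m%d", 1:5),
                      mrna_symbol = c("G1", "G2", "G2", "G3", "G4"),
                      r = c(.99, .98, .97, .96, .95),
                      p_value = c(.001, .002, .003, .004, .005))
  net <- build_lncrna_target_tf_network(lnc, pairs, assoc,
                                        top_tfs = 10, top_mrnas = 10)
  s <- network_stats(net)
  # nodes: 2 lncRNAs + 3 TFs (l3's record excluded) + 3 mRNA symbols
  expect_identical(s$n_nodes, 8L)
  # edges: 3 TF->lncRNA + 4 lncRNA->mRNA
  expect_identical(s$n_edges, 7L)
  expect_identical(as.integer(s$nodes_by_role[c("TF", "lncRNA", "mRNA")]),
                   c(3L, 2L, 3L))
  # no associations passing: isolated lncRNA nodes, zero TF edges
  none <- build_lncrna_target_tf_network(
    lnc, pairs[0, ], assoc[assoc$lncrna == "l3", ], 10, 10)
  sn <- network_stats(none)
  expect_identical(sn$n_nodes, 2L)
  expect_identical(sn$n_edges, 0L)
  # union bound on node count
  expect_lte(s$n_nodes, 2 + 10 + 10)
})

test_that("SIF and GraphML exports round-trip", {
  assoc <- data.frame(lncrna = sprintf("l%d", 1:4), tf = "TFa",
                      N = 10L, K = 4L, n = 3L, k = 2L,
                      p_hyper = c(.01, .02, .03, .04), fdr = NA_real_,
                      overlap = "", stringsAsFactors = FALSE)
  star <- build_lncrna_tf_network(assoc, top_pairs = 10)
  sif <- withr::local_tempfile(fileext = ".sif")
  export_graph(star, sif, "sif")
  lines <- readLines(sif)
  expect_identical(length(lines), 4L)
  expect_true(all(grepl("^TFa\ttf_regulates_lncrna\tl[1-4]$", lines)))

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_graph(star, gml, "graphml")
  back <- read_graphml_network(gml)
  nodes0 <- igraph::as_data_frame(star$graph, "vertices")
  nodes1 <- igraph::as_data_frame(back$graph, "vertices")
  edges0 <- igraph::as_data_frame(star$graph, "edges")
  edges1 <- igraph::as_data_frame(back$graph, "edges")
  expect_identical(nodes1[order(nodes1$name), ],
                   nodes0[order(nodes0$name), ], ignore_attr = TRUE)
  o0 <- order(edges0$from, edges0$to); o1 <- order(edges1$from, edges1$to)
  expect_identical(edges1$to[o1], edges0$to[o0])
  expect_equal(edges1$weight[o1], edges0$weight[o0], tolerance = 1e-9)

  # empty network still exports valid files
  empty <- build_lncrna_tf_network(assoc[0, ], top_pairs = 1)
  export_graph(empty, sif, "sif")
  expect_identical(length(readLines(sif)), 0L)
  export_graph(empty, gml, "graphml")
  expect_identical(network_stats(read_graphml_network(gml))$n_edges, 0L)
})

test_that("network invariants reject malformed graphs", {
  nodes <- data.frame(id = c("a", "b"), role = c("TF", "lncRNA"))
  loop <- data.frame(from = "a", to = "a", role = "tf_regulates_lncrna",
                     weight = 1)
  expect_error(lncnet:::new_typed_network(nodes, loop),
               class = "lncnet_network_error")
  dup <- data.frame(from = c("a", "a"), to = c("b", "b"),
                    role = "tf_regulates_lncrna", weight = 1)
  expect_error(lncnet:::new_typed_network(nodes, dup),
               class = "lncnet_network_error")
  dangling <- data.frame(from = "a", to = "z",
                         role = "tf_regulates_lncrna", weight = 1)
  expect_error(lncnet:::new_typed_network(nodes, dangling),
               class = "lncnet_network_error")
})

test_that("planted TF regulators are recovered from correlated sets", {
  recovered <- 0L; total <- 0L
  for (seed in 1:5) {
    sim <- generate_dataset(simulation_config(
      n_lncrna_probes = 40, n_mrna_probes = 300, n_tfs = 4,
      module_size = 20, n_regulated_lncrnas_per_tf = 3,
      de_fraction = 0, seed = seed))
    ds <- log2_transform(sim$dataset)
    lnc <- unlist(sim$truth$tf_lncrnas, use.names = FALSE)
    mrna <- rownames(ds$intensities)[probe_biotypes(ds) == "mRNA"]
    pairs <- coexpression_pairs(ds, lnc, mrna)
    sets <- lapply(lnc, function(id) correlated_mrna_set(pairs, id))
    names(sets) <- lnc
    assoc <- suppressWarnings(tf_associations(sets, sim$tf_targets))
    for (tf in names(sim$truth$tf_lncrnas)) {
      for (id in sim$truth$tf_lncrnas[[tf]]) {
        a <- assoc[assoc$lncrna == id, ]
        if (nrow(a) == 0) { total <- total + 1L; next }
        rank_true <- match(tf, a$tf)
        total <- total + 1L
        if (!is.na(rank_true) && rank_true <= 3) recovered <- recovered + 1L
      }
    }
  }
  expect_gte(recovered / total, 0.8)
})
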