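test_that("the worked t-test example is reproduced from the formulas", {
  # control [1,2,3], treatment [4,5,6]: diff = 3, s1 = s2 = 1,
  # t = 3 / sqrt(2/3) = 3.674, Welch df = 4, p = 2*pt(-t, 4) = 0.02131
  ds <- make_dataset(matrix(c(1, 2, 3, 4, 5, 6), 1), scale = "log2")
  de <- differential_expression(ds)
  expect_equal(de$log2fc, 3)
  expect_equal(de$fc_linear, 8)
  expect_equal(de$t_stat, 3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(de$df, 4)
  expect_equal(de$p_value, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-10)
  expect_identical(de$direction, "up")
  expect_true(de$is_de)
})

test_that("null probes and boundary calls behave per contract", {
  # identical group means: log2fc = 0, t = 0, p = 1, not DE
  ds <- make_dataset(matrix(c(1, 2, 3, 3, 2, 1), 1), scale = "log2")
  de <- differential_expression(ds)
  expect_equal(de$log2fc, 0)
  expect_equal(de$t_stat, 0)
  expect_equal(de$p_value, 1)
  expect_false(de$is_de)

  # thresholds are inclusive: fc exactly 2 with small p is called DE
  ds2 <- make_dataset(matrix(c(0, 0.01, -0.01, 1, 1.01, 0.99), 1),
                      scale = "log2")
  de2 <- differential_expression(ds2)
  expect_equal(de2$fc_linear, 2, tolerance = 1e-12)
  expect_true(de2$p_value <= 0.05)
  expect_true(de2$is_de)
})

test_that("zero-variance probes are flagged, not NaN", {
  ds <- make_dataset(rbind(c(1, 1, 1, 2, 2, 2),   # means differ, no variance
                           c(5, 5, 5, 5, 5, 5)),  # identical everywhere
                     scale = "log2")
  de <- differential_expression(ds)
  r1 <- de[de$probe_id == "P01", ]; r2 <- de[de$probe_id == "P02", ]
  expect_true(r1$zero_variance)
  expect_identical(r1$p_value, .Machine$double.xmin)
  expect_true(r1$is_de)
  expect_identical(r2$p_value, 1)
  expect_false(anyNA(de$p_value))
})

test_that("swapping group labels negates log2fc and preserves p", {
  set.seed(3)
  m <- matrix(rnorm(60, 8), 10, 6)
  ds <- make_dataset(m, scale = "log2")
  swapped <- make_dataset(m[, c(4:6, 1:3)], scale = "log2")
  colnames(swapped$intensities) <- colnames(ds$intensities)
  a <- differential_expression(ds)
  b <- differential_expression(swapped)
  b <- b[match(a$probe_id, b$probe_id), ]
  expect_equal(b$log2fc, -a$log2fc)
  expect_equal(b$p_value, a$p_value)
})

test_that("vectorised Welch and Student formulas match stats::t.test", {
  set.seed(101)
  for (i in 1:250) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- rnorm(n1, sd = runif(1, .1, 3)); y <- rnorm(n2, sd = runif(1, .1, 3))
    m <- matrix(c(x, y), 1)
    ds <- make_dataset(m, scale = "log2")
    ds$design$group <- rep(c("control", "treatment"), c(n1, n2))
    for (variant in c("welch", "student")) {
      de <- differential_expression(ds, variant = variant)
      ref <- t.test(y, x, var.equal = (variant == "student"))
      expect_equal(de$t_stat, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(de$df, unname(ref$parameter), tolerance = 1e-10)
      expect_equal(de$p_value, ref$p.value, tolerance = 1e-10)
    }
  }
})

test_that("p-values are uniform under the null (Student variant)", {
  sim <- generate_dataset(simulation_config(
    n_lncrna_probes = 2000, n_mrna_probes = 2000, de_fraction = 0,
    tf_activity_sd = 0, seed = 5))
  de <- differential_expression(log2_transform(sim$dataset),
                                variant = "student")
  d <- suppressWarnings(ks.test(de$p_value, "punif"))$statistic
  expect_lt(unname(d), 1.628 / sqrt(nrow(de)))  # alpha = 0.01 critical value
})

test_that("top-DE selection ranks by |log2fc| with deterministic tie-breaks", {
  rec <- data.frame(
    probe_id = sprintf("p%d", 1:6),
    biotype = "lncRNA", gene_symbol = sprintf("g%d", 1:6),
    log2fc = c(3, 2.5, 4, -3, -5, 2.5),
    p_value = c(.001, .01, .002, .001, .004, .02),
    direction = c("up", "up", "up", "down", "down", "up"),
    is_de = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  top <- select_top_de(rec, n_up = 2, n_down = 2)
  expect_identical(top$probe_id[1:2], c("p3", "p1"))
  expect_identical(top$probe_id[3:4], c("p5", "p4"))
  # equal |log2fc|: smaller p first
  tie <- rec[rec$log2fc == 2.5 | rec$probe_id == "p6", ]
  tie$is_de <- TRUE
  t2 <- select_top_de(tie, n_up = 1, n_down = 0)
  expect_identical(t2$probe_id, "p2")
  # shortfall: request more than available
  expect_warning(short <- select_top_de(rec, n_up = 10, n_down = 0),
                 "shortfall")
  expect_identical(nrow(short), 3L)
  expect_identical(attr(short, "shortfall")[["up"]], 7)
})

test_that("hierarchical clustering merges correlated probes first", {
  base <- c(1, 2, 3, 4, 5, 6)
  m <- rbind(base, base * 2 + 1, -base)
  rownames(m) <- NULL
  ds <- make_dataset(m, scale = "log2")
  cl <- hierarchical_cluster(ds)
  # brute-force distances: d(1,2) = 0 (r = 1), d(1,3) = d(2,3) = 2
  merge <- cl$probe_hclust$merge
  first <- sort(-merge[1, ])
  expect_identical(rownames(ds$intensities)[first], c("P01", "P02"))
  expect_equal(cl$probe_hclust$height[1], 0, tolerance = 1e-12)

  # identical rows merge at height zero
  m2 <- rbind(base, base, rev(base)); rownames(m2) <- NULL
  ds2 <- make_dataset(m2, scale = "log2")
  cl2 <- hierarchical_cluster(ds2)
  expect_equal(cl2$probe_hclust$height[1], 0, tolerance = 1e-12)
})

test_that("samples split by diet group when strong DE structure is planted", {
  hits <- 0L
  for (seed in 1:20) {
    sim <- generate_dataset(simulation_config(
      n_lncrna_probes = 100, n_mrna_probes = 100, de_fraction = 0.3,
      planted_log2fc = 3, noise_sd = 0.25, tf_activity_sd = 0,
      n_tfs = 2, module_size = 5, n_regulated_lncrnas_per_tf = 2,
      seed = seed))
    ds <- log2_transform(sim$dataset)
    cl <- hierarchical_cluster(ds)
    groups <- cutree(cl$sample_hclust, 2)
    want <- sim$dataset$design$group[match(names(groups),
                                           sim$dataset$design$sample_id)]
    if (length(unique(paste(groups, want))) == 2L) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("clustering exports Newick trees and leaf orders", {
  ds <- make_dataset(matrix(rnorm(36, 8), 6, 6), scale = "log2")
  cl <- hierarchical_cluster(ds)
  dir <- withr::local_tempdir()
  paths <- write_clustering(cl, dir)
  tree <- ape::read.tree(paths[["probes"]])
  expect_setequal(tree$tip.label, rownames(ds$intensities))
  lo <- read.delim(paths[["leaf_order"]])
  expect_identical(nrow(lo), 12L)
})
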