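test_that("expression TSV files round-trip through write and read", {
  ds <- make_dataset(matrix(c(5, 2, 3, 4, 1, 2, 7.25, 0.5, 3.125,
                              10, 20, 30, 40, 50, 60, 1e-3, 123456.789, 2),
                            nrow = 3))
  dir <- withr::local_tempdir()
  paths <- write_expression_tsv(ds, dir)
  back <- read_expression_tsv(paths[["intensities"]], paths[["flags"]],
                              paths[["annotation"]], paths[["design"]])
  expect_identical(dim(back), dim(ds))
  expect_identical(rownames(back$intensities), rownames(ds$intensities))
  expect_identical(colnames(back$intensities), colnames(ds$intensities))
  expect_equal(back$intensities, ds$intensities, tolerance = 1e-12)
  expect_identical(back$flags, ds$flags)
  expect_identical(back$scale, "linear")
  expect_identical(back$control, "control")
  expect_identical(length(unique(back$design$group)), 2L)

  # log2 scale survives via the sidecar metadata line
  ds2 <- ds; ds2$scale <- "log2"
  paths2 <- write_expression_tsv(ds2, withr::local_tempdir())
  back2 <- read_expression_tsv(paths2[["intensities"]], paths2[["flags"]],
                               paths2[["annotation"]], paths2[["design"]])
  expect_identical(back2$scale, "log2")
})

test_that("write-read identity holds on randomly generated datasets", {
  for (seed in 1:4) {
    sim <- generate_dataset(simulation_config(
      n_lncrna_probes = 20, n_mrna_probes = 30, n_tfs = 2,
      module_size = 5, n_regulated_lncrnas_per_tf = 2, seed = seed))
    dir <- withr::local_tempdir()
    p <- write_expression_tsv(sim$dataset, dir)
    back <- read_expression_tsv(p[["intensities"]], p[["flags"]],
                                p[["annotation"]], p[["design"]])
    expect_equal(back$intensities, sim$dataset$intensities,
                 tolerance = 1e-12)
    expect_identical(back$flags, sim$dataset$flags)
    expect_identical(back$annotation$biotype, sim$dataset$annotation$biotype)
  }
})

test_that("validation rejects each invariant breach with its named error", {
  ok <- matrix(1:12, nrow = 2,
               dimnames = list(c("a", "b"),
                               c("c1", "c2", "c3", "t1", "t2", "t3")))
  flg <- matrix("P", 2, 6, dimnames = dimnames(ok))
  ann <- data.frame(probe_id = c("a", "b"), biotype = c("lncRNA", "mRNA"),
                    gene_symbol = c("A", "B"))
  des <- data.frame(sample_id = colnames(ok),
                    group = rep(c("control", "treatment"), each = 3))

  bad_flag <- flg; bad_flag[1, 1] <- "X"
  expect_error(expression_dataset(ok, bad_flag, ann, des),
               class = "lncnet_flag_error")
  expect_error(expression_dataset(ok, flg[, 1:5], ann, des),
               class = "lncnet_dim_error")
  expect_error(expression_dataset(ok, flg, ann[1, ], des),
               class = "lncnet_annotation_error")
  expect_error(expression_dataset(ok, flg, ann, des[1:5, ]),
               class = "lncnet_design_error")
  dup <- ok; rownames(dup) <- c("a", "a")
  dupf <- flg; rownames(dupf) <- c("a", "a")
  dupann <- ann; dupann$probe_id <- c("a", "a")
  expect_error(expression_dataset(dup, dupf, dupann, des),
               class = "lncnet_duplicate_error")
  neg <- ok; neg[1, 1] <- -1
  expect_error(expression_dataset(neg, flg, ann, des, scale = "linear"),
               class = "lncnet_value_error")
  one_grp <- des; one_grp$group <- "control"
  expect_error(expression_dataset(ok, flg, ann, one_grp),
               class = "lncnet_design_error")
})

test_that("reading malformed files raises the specific failure", {
  ds <- make_dataset(matrix(1:18, nrow = 3))
  dir <- withr::local_tempdir()
  p <- write_expression_tsv(ds, dir)
  # corrupt the flags with an unknown symbol
  lines <- readLines(p[["flags"]])
  writeLines(gsub("\tP\t", "\tX\t", lines), p[["flags"]])
  expect_error(read_expression_tsv(p[["intensities"]], p[["flags"]],
                                   p[["annotation"]], p[["design"]]),
               class = "lncnet_flag_error")
  # drop one probe from the annotation
  p <- write_expression_tsv(ds, withr::local_tempdir())
  ann <- read.delim(p[["annotation"]])
  write.table(ann[-1, ], p[["annotation"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_expression_tsv(p[["intensities"]], p[["flags"]],
                                   p[["annotation"]], p[["design"]]),
               class = "lncnet_annotation_error")
})

test_that("empty datasets are refused at write time", {
  ds <- make_dataset(matrix(1:18, nrow = 3))
  ds$intensities <- ds$intensities[0, , drop = FALSE]
  ds$flags <- ds$flags[0, , drop = FALSE]
  expect_error(write_expression_tsv(ds, withr::local_tempdir()),
               class = "lncnet_value_error")
})

test_that("GMT reading honours the universe policy", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("s1\tdesc\tA\tB\tC", "s2\tdesc\tB\tD"), path)
  col <- read_gmt(path)
  expect_setequal(col$universe, c("A", "B", "C", "D"))
  expect_identical(col$sets$s1, c("A", "B", "C"))

  col5 <- read_gmt(path, universe = c("A", "B", "C", "D", "E"))
  expect_identical(length(col5$universe), 5L)

  expect_error(read_gmt(path, universe = c("A", "B")),
               class = "lncnet_universe_error")
  writeLines(c("s1\tdesc\tA", "s1\tdesc\tB"), path)
  expect_error(read_gmt(path), class = "lncnet_gmt_error")
  writeLines(c("s1\tdesc"), path)
  expect_error(read_gmt(path), class = "lncnet_gmt_error")
})

test_that("GMT round-trips and agrees with an independent reader", {
  skip_if_not_installed("fgsea")
  sets <- list(alpha = c("A", "B", "C"), beta = c("B", "D", "E"))
  col <- gene_set_collection("x", "term", sets)
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(col, path)
  back <- read_gmt(path)
  expect_identical(back$sets, col$sets)
  ref <- fgsea::gmtPathways(path)
  expect_identical(ref[names(col$sets)], col$sets)
})

test_that("CRLF line endings are accepted", {
  path <- withr::local_tempfile(fileext = ".gmt")
  con <- file(path, "wb")
  writeLines(c("s1\tdesc\tA\tB", "s2\tdesc\tC"), con, sep = "\r\n")
  close(con)
  col <- read_gmt(path)
  expect_identical(col$sets$s1, c("A", "B"))
})

test_that("qPCR tables validate Ct positivity and reference pairing", {
  df <- data.frame(sample = c("s1", "s1", "s2", "s2"),
                   group = c("control", "control", "treatment", "treatment"),
                   gene = c("tgt", "ref", "tgt", "ref"),
                   ct = c(25, 20, 23, 20))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  q <- read_qpcr_table(path, reference_gene = "ref")
  expect_identical(nrow(q), 4L)
  expect_identical(attr(q, "reference_gene"), "ref")

  bad <- df; bad$ct[1] <- 0
  expect_error(qpcr_table(bad, reference_gene = "ref"),
               class = "lncnet_value_error")
  unpaired <- df[df$gene == "tgt" | df$sample == "s1", ]
  expect_error(qpcr_table(unpaired, reference_gene = "ref"),
               class = "lncnet_pairing_error")
})
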