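#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. Selection constants
#' default to the standard workflow values: the 500 top correlation pairs
#' feed functional enrichment; the 400 strongest DE lncRNAs (200 up, 200
#' down) feed TF inference; the 200 best lncRNA-TF pairs form the TF
#' network; the 20 strongest DE lncRNAs (10 up, 10 down) with the 100 best
#' TF associations and 200 best correlated mRNAs form the tripartite
#' network.
#'
#' @param inputs either an `lncnet_simulation` (see [generate_dataset()]),
#'   or a named list of file paths with elements `intensities`, `flags`,
#'   `annotation`, `design`, `tf_targets`, `terms`, and optionally `qpcr`
#'   (a Ct table) and `universe` (one background gene symbol per line,
#'   declaring the collections' universe — GMT itself carries none).
#' @param fc_threshold,p_threshold,variant differential-expression
#'   thresholds and t-test variant (see [differential_expression()]).
#' @param normalize_order preprocessing order (see [preprocess()]).
#' @param flag_rule flag-filter rule (see [filter_by_flags()]).
#' @param log2_offset offset for [log2_transform()].
#' @param cor_p_cutoff per-pair significance cutoff for correlated sets.
#' @param top_pairs correlation pairs kept for enrichment, default 500.
#' @param top_lnc_up,top_lnc_down DE lncRNAs feeding TF inference,
#'   default 200 each.
#' @param top_tf_pairs lncRNA-TF pairs in the TF network, default 200.
#' @param top20_up,top20_down lncRNAs in the tripartite network, default 10
#'   each.
#' @param top_tfs,top_mrnas association/pair records in the tripartite
#'   network, defaults 100 and 200.
#' @param universe_policy `"array"` (restrict collections to symbols on the
#'   filtered array; default — the query is drawn from the array, so a
#'   genome-wide universe would inflate significance) or `"collection"`
#'   (keep the GMT universe).
#' @param qpcr_genes gene symbols to verify by qPCR when a simulation is
#'   used as input (default: up to 4 of the strongest planted DE genes);
#'   ignored for file inputs, where a `qpcr` path is used if present.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(inputs,
                           fc_threshold = 2, p_threshold = 0.05,
                           variant = "welch",
                           normalize_order = "normalize_then_filter",
                           flag_rule = "all_present_one_group",
                           log2_offset = 1,
                           cor_p_cutoff = 0.05,
                           top_pairs = 500,
                           top_lnc_up = 200, top_lnc_down = 200,
                           top_tf_pairs = 200,
                           top20_up = 10, top20_down = 10,
                           top_tfs = 100, top_mrnas = 200,
                           universe_policy = c("array", "collection"),
                           qpcr_genes = NULL) {
  universe_policy <- match.arg(universe_policy)
  cfg <- as.list(environment())
  topk <- c("top_pairs", "top_lnc_up", "top_lnc_down", "top_tf_pairs",
            "top20_up", "top20_down", "top_tfs", "top_mrnas")
  if (any(unlist(cfg[topk]) < 1))
    lnc_abort("lncnet_config_error", "every top-k parameter must be >= 1")
  if (cfg$cor_p_cutoff <= 0 || cfg$cor_p_cutoff >= 1)
    lnc_abort("lncnet_config_error", "cor_p_cutoff must be in (0, 1)")
  if (!inherits(inputs, "lncnet_simulation")) {
    need <- c("intensities", "flags", "annotation", "design",
              "tf_targets", "terms")
    miss <- setdiff(need, names(inputs))
    if (length(miss))
      lnc_abort("lncnet_config_error", "inputs missing element(s): %s",
                paste(miss, collapse = ", "))
    for (p in unlist(inputs[c(need, intersect(c("qpcr", "universe"),
                                              names(inputs)))]))
      if (!file.exists(p))
        lnc_abort("lncnet_io_error", "input file not found: %s", p)
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the complete chain — quantile normalization, flag filtering,
#' log2 transform, differential expression in the lncRNA and mRNA strata,
#' lncRNA-mRNA co-expression, functional enrichment of the top correlated
#' mRNAs, lncRNA-TF inference, both networks, and (when qPCR input exists)
#' ddCt concordance — writing every stage output under `out_dir` with
#' deterministic names and content. Identical config and inputs give
#' byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory, created if needed.
#' @return a `run_manifest` (list: config snapshot, input checksums,
#'   per-stage record counts, package version, timestamp), invisibly
#'   carrying all in-memory stage results in `$results`. The manifest file
#'   `manifest.json` omits the timestamp so reruns are byte-identical.
#' @export
run_full <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      lnc_abort("lncnet_stage_error", "stage '%s' failed: %s", name,
                conditionMessage(e))
    })
    res
  }

  # --- inputs -------------------------------------------------------------
  if (inherits(config$inputs, "lncnet_simulation")) {
    sim <- config$inputs
    input_dir <- file.path(out_dir, "inputs")
    input_paths <- write_simulation(sim, input_dir)
    raw <- sim$dataset
    tf_coll <- sim$tf_targets
    term_coll <- sim$terms
    qpcr <- NULL   # built later, once DE genes are known
  } else {
    sim <- NULL
    input_paths <- unlist(config$inputs)
    raw <- stage("read_inputs", read_expression_tsv(
      config$inputs$intensities, config$inputs$flags,
      config$inputs$annotation, config$inputs$design))
    univ <- if (!is.null(config$inputs$universe))
      readLines(config$inputs$universe, encoding = "UTF-8") else NULL
    tf_coll <- read_gmt(config$inputs$tf_targets, kind = "tf_target",
                        universe = univ)
    term_coll <- read_gmt(config$inputs$terms, kind = "term",
                          universe = univ)
    qpcr <- if (!is.null(config$inputs$qpcr))
      read_qpcr_table(config$inputs$qpcr) else NULL
  }
  checksums <- tools::md5sum(unname(input_paths))
  names(checksums) <- basename(names(checksums))
  counts$input_probes <- nrow(raw$intensities)

  # --- preprocess ---------------------------------------------------------
  pre <- stage("preprocess", preprocess(
    raw, order = config$normalize_order, rule = config$flag_rule,
    offset = config$log2_offset))
  dataset <- pre$dataset
  write_filter_report(pre$report, file.path(out_dir, "filter_report.tsv"))
  counts$probes_kept <- pre$report$probes_kept

  # restrict collections to the measured mRNA symbols
  if (config$universe_policy == "array") {
    measured <- unique(probe_symbols(dataset)[probe_biotypes(dataset) ==
                                                "mRNA"])
    tf_coll <- restrict_universe(tf_coll, measured)
    term_coll <- restrict_universe(term_coll, measured)
  }

  # --- differential expression -------------------------------------------
  de <- stage("diffexp", differential_expression(
    dataset, fc_threshold = config$fc_threshold,
    p_threshold = config$p_threshold, variant = config$variant))
  de_lnc <- de[de$biotype == "lncRNA", , drop = FALSE]
  de_mrna <- de[de$biotype == "mRNA", , drop = FALSE]
  write_tsv(as.data.frame(de_lnc), file.path(out_dir, "de_lncrna.tsv"))
  write_tsv(as.data.frame(de_mrna), file.path(out_dir, "de_mrna.tsv"))
  counts$de_lncrna <- sum(de_lnc$is_de)
  counts$de_mrna <- sum(de_mrna$is_de)

  de_lnc_ids <- de_lnc$probe_id[de_lnc$is_de]
  de_mrna_ids <- de_mrna$probe_id[de_mrna$is_de]

  # --- co-expression ------------------------------------------------------
  pairs <- NULL; top_pairs <- NULL; enr <- NULL
  if (length(de_lnc_ids) && length(de_mrna_ids)) {
    pairs <- stage("coexpression",
                   coexpression_pairs(dataset, de_lnc_ids, de_mrna_ids))
    top_pairs <- select_top_pairs(pairs, config$top_pairs)
    write_tsv(as.data.frame(top_pairs),
              file.path(out_dir, "top_pairs.tsv"))
    counts$pairs <- nrow(pairs)
    counts$top_pairs <- nrow(top_pairs)

    # --- enrichment of the top correlated mRNAs ---------------------------
    enr <- stage("enrichment", enrich(
      unique(top_pairs$mrna_symbol), term_coll,
      query_label = sprintf("top%d-correlated", config$top_pairs)))
    write_tsv(as.data.frame(enr), file.path(out_dir, "enrichment.tsv"))
    counts$enriched_terms <- nrow(enr)
  } else {
    counts$pairs <- 0L; counts$top_pairs <- 0L; counts$enriched_terms <- 0L
  }

  # --- TF inference and networks -----------------------------------------
  assoc <- NULL; tf_net <- NULL; tri_net <- NULL
  if (!is.null(pairs)) {
    sel_lnc <- select_top_de(de_lnc, n_up = config$top_lnc_up,
                             n_down = config$top_lnc_down)
    corr_sets <- stage("correlated_sets", {
      s <- lapply(sel_lnc$probe_id, function(id)
        correlated_mrna_set(pairs, id, config$cor_p_cutoff))
      stats::setNames(s, sel_lnc$probe_id)
    })
    nonempty <- vapply(corr_sets, length, integer(1)) > 0L
    if (any(nonempty)) {
      assoc <- stage("tf_associations",
                     suppressWarnings(tf_associations(corr_sets, tf_coll)))
      write_tsv(as.data.frame(assoc),
                file.path(out_dir, "tf_associations.tsv"))
      counts$tf_associations <- nrow(assoc)

      tf_net <- stage("lncrna_tf_network",
                      build_lncrna_tf_network(assoc, config$top_tf_pairs))
      export_graph(tf_net, file.path(out_dir, "lncrna_tf_network.sif"),
                   "sif")
      export_graph(tf_net, file.path(out_dir, "lncrna_tf_network.graphml"),
                   "graphml")

      top20 <- select_top_de(de_lnc, n_up = config$top20_up,
                             n_down = config$top20_down)
      tri_net <- stage("lncrna_target_tf_network",
                       build_lncrna_target_tf_network(
                         top20$probe_id, pairs, assoc,
                         top_tfs = config$top_tfs,
                         top_mrnas = config$top_mrnas))
      export_graph(tri_net,
                   file.path(out_dir, "lncrna_target_tf_network.sif"), "sif")
      export_graph(tri_net,
                   file.path(out_dir, "lncrna_target_tf_network.graphml"),
                   "graphml")
      for (nm in c("tf", "tripartite")) {
        net <- if (nm == "tf") tf_net else tri_net
        s <- network_stats(net)
        counts[[paste0(nm, "_network_nodes")]] <- s$n_nodes
        counts[[paste0(nm, "_network_edges")]] <- s$n_edges
      }
    } else {
      counts$tf_associations <- 0L
    }
  }

  # --- qPCR concordance ---------------------------------------------------
  concord <- NULL
  if (!is.null(sim)) {
    de_sym <- de$gene_symbol[de$is_de &
                               de$probe_id %in% sim$truth$de$probe_id]
    genes <- config$qpcr_genes
    if (is.null(genes)) genes <- utils::head(de_sym, 4)
    if (length(genes)) {
      qpcr <- generate_qpcr_table(sim, genes)
      write_qpcr_table(qpcr, file.path(out_dir, "qpcr.tsv"))
    }
  }
  if (!is.null(qpcr)) {
    targets <- setdiff(unique(qpcr$gene), attr(qpcr, "reference_gene"))
    rqs <- stage("qpcr", lapply(targets, function(g)
      delta_delta_ct(qpcr, g)))
    concord <- suppressWarnings(concordance_report(rqs, de))
    write_tsv(as.data.frame(concord),
              file.path(out_dir, "qpcr_concordance.tsv"))
    counts$qpcr_genes <- nrow(concord)
  }

  cfg_snapshot <- config
  cfg_snapshot$inputs <- if (is.null(sim)) as.list(input_paths) else
    list(simulation_seed = sim$config$seed,
         simulation = unclass(sim$config))
  manifest <- structure(list(
    package_version = as.character(utils::packageVersion("lncnet")),
    config = unclass(cfg_snapshot),
    input_checksums = as.list(checksums),
    stage_counts = counts,
    timestamp = format(Sys.time(), tz = "UTC")), class = "run_manifest")
  mf <- manifest
  mf$timestamp <- NULL   # keep the file byte-identical across reruns
  jsonlite::write_json(unclass(mf), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$results <- list(dataset = dataset, filter_report = pre$report,
                           de = de, pairs = pairs, top_pairs = top_pairs,
                           enrichment = enr, tf_associations = assoc,
                           tf_network = tf_net, tripartite_network = tri_net,
                           concordance = concord)
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("run_manifest (lncnet %s)\n", x$package_version))
  for (nm in names(x$stage_counts))
    cat(sprintf("  %-24s %s\n", nm, x$stage_counts[[nm]]))
  invisible(x)
}
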