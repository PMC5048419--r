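#' Simulation configuration
#'
#' Parameters of the synthetic two-group single-channel array experiment.
#' The generative model for the log2 intensity of probe i in sample s is
#'
#' `y_is = baseline_i + delta_i * 1[s in treatment] + sum_t beta_it * a_ts + eps_is`
#'
#' where `delta_i = ±planted_log2fc` for planted differentially expressed
#' probes and 0 otherwise, `beta_it = 1` iff probe i belongs to latent
#' transcription factor t's module (as a target mRNA or a regulated
#' lncRNA), TF activities `a_ts ~ N(0, tf_activity_sd)` and residuals
#' `eps_is ~ N(0, noise_sd)`. Intensities are exported on the linear scale
#' (`2^y`). Two probes sharing a TF module have expected Pearson
#' correlation `tf_activity_sd^2 / (tf_activity_sd^2 + noise_sd^2)`.
#'
#' @param n_lncrna_probes,n_mrna_probes probe counts.
#' @param n_control,n_treatment samples per group (default 3 and 3, the
#'   canonical small-array design).
#' @param n_tfs number of latent regulators.
#' @param module_size target mRNAs per TF (modules are disjoint).
#' @param n_regulated_lncrnas_per_tf regulated lncRNA probes per TF
#'   (disjoint across TFs).
#' @param de_fraction fraction of all probes with a planted group effect.
#' @param planted_log2fc magnitude of the planted effect, log2 units.
#' @param noise_sd residual s.d., log2 units.
#' @param tf_activity_sd s.d. of latent TF activities across samples.
#' @param flag_absent_rate probability that a lowest-decile intensity is
#'   flagged `A` (absent); all other measurements are flagged `P`.
#' @param baseline_log2_mean,baseline_log2_sd baseline intensity
#'   distribution, log2 units.
#' @param seed integer seed; generation is a pure function of it.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(n_lncrna_probes = 2000, n_mrna_probes = 3000,
                              n_control = 3, n_treatment = 3,
                              n_tfs = 10, module_size = 30,
                              n_regulated_lncrnas_per_tf = 5,
                              de_fraction = 0.05, planted_log2fc = 3,
                              noise_sd = 0.5, tf_activity_sd = 1,
                              flag_absent_rate = 0.3,
                              baseline_log2_mean = 8, baseline_log2_sd = 1.5,
                              seed = 1L) {
  cfg <- list(n_lncrna_probes = as.integer(n_lncrna_probes),
              n_mrna_probes = as.integer(n_mrna_probes),
              n_control = as.integer(n_control),
              n_treatment = as.integer(n_treatment),
              n_tfs = as.integer(n_tfs),
              module_size = as.integer(module_size),
              n_regulated_lncrnas_per_tf =
                as.integer(n_regulated_lncrnas_per_tf),
              de_fraction = de_fraction, planted_log2fc = planted_log2fc,
              noise_sd = noise_sd, tf_activity_sd = tf_activity_sd,
              flag_absent_rate = flag_absent_rate,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              seed = as.integer(seed))
  counts <- cfg[c("n_lncrna_probes", "n_mrna_probes", "n_control",
                  "n_treatment", "n_tfs", "module_size",
                  "n_regulated_lncrnas_per_tf")]
  if (any(unlist(counts) < 1L))
    lnc_abort("lncnet_config_error", "all counts must be >= 1")
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1 ||
      cfg$flag_absent_rate < 0 || cfg$flag_absent_rate > 1)
    lnc_abort("lncnet_config_error", "fractions must lie in [0, 1]")
  if (cfg$noise_sd <= 0)
    lnc_abort("lncnet_config_error", "noise_sd must be > 0")
  if (cfg$tf_activity_sd < 0 || cfg$baseline_log2_sd < 0)
    lnc_abort("lncnet_config_error", "standard deviations must be >= 0")
  if (cfg$n_tfs * cfg$module_size > cfg$n_mrna_probes)
    lnc_abort("lncnet_config_error",
              "TF modules demand %d mRNA probes but only %d exist",
              cfg$n_tfs * cfg$module_size, cfg$n_mrna_probes)
  if (cfg$n_tfs * cfg$n_regulated_lncrnas_per_tf > cfg$n_lncrna_probes)
    lnc_abort("lncnet_config_error",
              "TF modules demand %d lncRNA probes but only %d exist",
              cfg$n_tfs * cfg$n_regulated_lncrnas_per_tf,
              cfg$n_lncrna_probes)
  structure(cfg, class = "simulation_config")
}

#' Read a simulation configuration from YAML
#'
#' The YAML file carries the [simulation_config()] fields by name; `seed`
#' is mandatory.
#'
#' @param path YAML file path.
#' @return a `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed))
    lnc_abort("lncnet_config_error", "simulation config must name a seed")
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    lnc_abort("lncnet_config_error", "unknown config field(s): %s",
              paste(unknown, collapse = ", "))
  do.call(simulation_config, y)
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Draws a dataset from the latent-factor model described in
#' [simulation_config()], together with the TF target-set collection built
#' exactly from the planted modules, a functional-term collection formed by
#' partitioning the mRNA symbols into disjoint pathway-like sets (the
#' planted modules among them), and the ground-truth records needed for
#' recovery testing. Identical seeds give byte-identical output.
#'
#' @param config a [simulation_config()].
#' @return an `lncnet_simulation`: list with elements `dataset` (an
#'   [expression_dataset], linear scale), `tf_targets` and `terms` (both
#'   [gene_set_collection]), `truth` (list: `de` — data frame `probe_id`,
#'   `planted_log2fc`; `tf_targets` — TF to target mRNA symbols;
#'   `tf_lncrnas` — TF to regulated lncRNA probe ids; `activities` — TF by
#'   sample matrix), and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_local_seed(config$seed, {
    n_lnc <- config$n_lncrna_probes; n_mrna <- config$n_mrna_probes
    lnc_ids <- sprintf("LNC_%05d", seq_len(n_lnc))
    mrna_ids <- sprintf("MRNA_%05d", seq_len(n_mrna))
    probe_ids <- c(lnc_ids, mrna_ids)
    lnc_sym <- sprintf("Lnc%04d", seq_len(n_lnc))
    mrna_sym <- sprintf("Gene%04d", seq_len(n_mrna))
    symbols <- c(lnc_sym, mrna_sym)
    n_probes <- length(probe_ids)
    samples <- c(sprintf("ctrl_%d", seq_len(config$n_control)),
                 sprintf("trt_%d", seq_len(config$n_treatment)))
    n_samp <- length(samples)
    treat <- rep(c(0, 1), c(config$n_control, config$n_treatment))
    tf_names <- sprintf("TF%02d", seq_len(config$n_tfs))

    # disjoint TF modules over randomly permuted probes
    mrna_pick <- sample.int(n_mrna)
    tf_targets_idx <- split(
      mrna_pick[seq_len(config$n_tfs * config$module_size)],
      rep(seq_len(config$n_tfs), each = config$module_size))
    lnc_pick <- sample.int(n_lnc)
    tf_lnc_idx <- split(
      lnc_pick[seq_len(config$n_tfs * config$n_regulated_lncrnas_per_tf)],
      rep(seq_len(config$n_tfs), each = config$n_regulated_lncrnas_per_tf))

    # planted DE probes with signed effects
    n_de <- round(config$de_fraction * n_probes)
    de_idx <- if (n_de > 0) sort(sample.int(n_probes, n_de)) else integer()
    delta <- numeric(n_probes)
    if (n_de > 0)
      delta[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
        config$planted_log2fc

    baseline <- stats::rnorm(n_probes, config$baseline_log2_mean,
                             config$baseline_log2_sd)
    activities <- matrix(stats::rnorm(config$n_tfs * n_samp,
                                      0, config$tf_activity_sd),
                         config$n_tfs, n_samp,
                         dimnames = list(tf_names, samples))
    y <- baseline + outer(delta, treat) +
      matrix(stats::rnorm(n_probes * n_samp, 0, config$noise_sd),
             n_probes, n_samp)
    for (t in seq_len(config$n_tfs)) {
      members <- c(n_lnc + tf_targets_idx[[t]], tf_lnc_idx[[t]])
      y[members, ] <- y[members, ] +
        rep(activities[t, ], each = length(members))
    }
    dimnames(y) <- list(probe_ids, samples)
    intensities <- 2^y

    # absent calls sit on the dimmest measurements
    thr <- stats::quantile(intensities, 0.1)
    flags <- matrix("P", n_probes, n_samp,
                    dimnames = dimnames(intensities))
    low <- intensities <= thr
    flags[low & matrix(stats::runif(n_probes * n_samp), n_probes, n_samp) <
            config$flag_absent_rate] <- "A"

    annotation <- data.frame(
      probe_id = probe_ids,
      biotype = rep(c("lncRNA", "mRNA"), c(n_lnc, n_mrna)),
      gene_symbol = symbols, stringsAsFactors = FALSE)
    design <- data.frame(sample_id = samples,
                         group = rep(c("control", "treatment"),
                                     c(config$n_control, config$n_treatment)),
                         stringsAsFactors = FALSE)
    dataset <- expression_dataset(intensities, flags, annotation, design,
                                  scale = "linear", control = "control",
                                  treatment = "treatment")

    tf_target_sets <- lapply(tf_targets_idx, function(i) mrna_sym[sort(i)])
    names(tf_target_sets) <- tf_names
    tf_collection <- gene_set_collection(
      "planted_tf_targets", "tf_target", tf_target_sets,
      universe = mrna_sym)

    # terms: the planted modules plus a disjoint partition of the rest
    rest <- mrna_sym[sort(mrna_pick[-seq_len(config$n_tfs *
                                               config$module_size)])]
    extra <- if (length(rest))
      split(rest, ceiling(seq_along(rest) / config$module_size))
    else list()
    term_sets <- c(stats::setNames(tf_target_sets,
                                   sprintf("PATHWAY_%s", tf_names)),
                   stats::setNames(extra,
                                   sprintf("PATHWAY_R%03d",
                                           seq_along(extra))))
    branches <- stats::setNames(
      rep(c("Biological Process", "Molecular Function",
            "Cellular Component", "KEGG"),
          length.out = length(term_sets)), names(term_sets))
    term_collection <- gene_set_collection(
      "planted_terms", "term", term_sets, universe = mrna_sym,
      branches = branches)

    truth <- list(
      de = data.frame(probe_id = probe_ids[de_idx],
                      planted_log2fc = delta[de_idx],
                      stringsAsFactors = FALSE),
      tf_targets = tf_target_sets,
      tf_lncrnas = stats::setNames(
        lapply(tf_lnc_idx, function(i) lnc_ids[sort(i)]), tf_names),
      activities = activities)

    structure(list(dataset = dataset, tf_targets = tf_collection,
                   terms = term_collection, truth = truth, config = config),
              class = "lncnet_simulation")
  })
}

#' @export
print.lncnet_simulation <- function(x, ...) {
  cat(sprintf("lncnet_simulation (seed %d): %d lncRNA + %d mRNA probes, %d + %d samples\n",
              x$config$seed, x$config$n_lncrna_probes,
              x$config$n_mrna_probes, x$config$n_control,
              x$config$n_treatment))
  cat(sprintf("  planted: %d DE probes (|log2FC| = %g), %d TFs x %d targets + %d lncRNAs\n",
              nrow(x$truth$de), x$config$planted_log2fc, x$config$n_tfs,
              x$config$module_size, x$config$n_regulated_lncrnas_per_tf))
  invisible(x)
}

#' Generate a synthetic qPCR Ct table
#'
#' Ct values consistent with the planted effects at 100% amplification
#' efficiency: `Ct = c0 − y` (one cycle per log2 unit), with
#' `y = baseline + delta * 1[treatment] + eps`, the planted `delta` taken
#' from the simulation truth (0 for non-DE genes), and a reference gene
#' with no group effect. With `noise_sd = 0` the relative quantity is
#' exactly `2^delta`.
#'
#' @param sim an `lncnet_simulation` from [generate_dataset()].
#' @param genes gene symbols to assay; must exist in the simulation.
#' @param noise_sd measurement noise on Ct, default 0 (noiseless).
#' @param c0 intercept cycle count, default 30.
#' @param reference_gene reference gene name, default `"β-actin"`.
#' @return a `qpcr_table`.
#' @export
generate_qpcr_table <- function(sim, genes, noise_sd = 0, c0 = 30,
                                reference_gene = "β-actin") {
  stopifnot(inherits(sim, "lncnet_simulation"))
  ann <- sim$dataset$annotation
  idx <- match(genes, ann$gene_symbol)
  if (any(is.na(idx)))
    lnc_abort("lncnet_value_error", "unknown gene(s): %s",
              paste(genes[is.na(idx)], collapse = ", "))
  probes <- ann$probe_id[idx]
  delta <- numeric(length(genes))
  hit <- match(probes, sim$truth$de$probe_id)
  delta[!is.na(hit)] <- sim$truth$de$planted_log2fc[hit[!is.na(hit)]]

  des <- sim$dataset$design
  treat <- as.numeric(des$group == sim$dataset$treatment)
  with_local_seed(sim$config$seed + 1L, {
    rows <- lapply(seq_along(genes), function(g) {
      base_g <- sim$config$baseline_log2_mean
      y <- base_g + delta[g] * treat +
        stats::rnorm(nrow(des), 0, noise_sd)
      data.frame(sample = des$sample_id, group = des$group,
                 gene = genes[g], ct = c0 - y, stringsAsFactors = FALSE)
    })
    y_ref <- sim$config$baseline_log2_mean / 2 +
      stats::rnorm(nrow(des), 0, noise_sd)
    ref <- data.frame(sample = des$sample_id, group = des$group,
                      gene = reference_gene, ct = c0 - y_ref,
                      stringsAsFactors = FALSE)
    qpcr_table(rbind(do.call(rbind, rows), ref),
               reference_gene = reference_gene,
               control = sim$dataset$control,
               treatment = sim$dataset$treatment)
  })
}

#' Write all simulated inputs plus the ground truth to disk
#'
#' Writes the dataset tables (via [write_expression_tsv()]), the two GMT
#' collections, and `truth.json` into `out_dir`.
#'
#' @param sim an `lncnet_simulation`.
#' @param out_dir output directory, created if needed.
#' @return named character vector of file paths, invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_expression_tsv(sim$dataset, out_dir)
  paths <- c(paths,
             tf_targets = file.path(out_dir, "tf_targets.gmt"),
             terms = file.path(out_dir, "terms.gmt"),
             universe = file.path(out_dir, "universe.txt"),
             truth = file.path(out_dir, "truth.json"))
  write_gmt(sim$tf_targets, paths[["tf_targets"]])
  write_gmt(sim$terms, paths[["terms"]])
  # GMT carries no universe; ship the declared background separately
  con <- file(paths[["universe"]], "wb", encoding = "UTF-8")
  writeLines(sim$tf_targets$universe, con, sep = "\n")
  close(con)
  truth <- sim$truth
  truth$activities <- list(tf = rownames(truth$activities),
                           sample = colnames(truth$activities),
                           values = unname(as.data.frame(t(truth$activities))))
  jsonlite::write_json(truth, paths[["truth"]], digits = NA,
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(paths)
}
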