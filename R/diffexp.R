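#' Two-group differential expression
#'
#' Per-probe two-sample t-test (Welch by default, Student's pooled-variance
#' variant by option) on log2 intensities, with fold change defined on the
#' log2 group means (i.e. a geometric-mean fold change on the linear scale).
#' A probe is called differentially expressed when its linear fold change
#' and p-value pass the thresholds, both boundaries inclusive
#' (FC >= `fc_threshold`, p <= `p_threshold`).
#'
#' Probes with zero variance in both groups are handled conservatively: if
#' the group means differ the p-value is set to the smallest representable
#' positive double and the probe flagged in the `zero_variance` column; if
#' the means are equal, t = 0 and p = 1.
#'
#' @param x an [expression_dataset] on log2 scale; both groups need at least
#'   two samples.
#' @param fc_threshold linear fold-change threshold, default 2.
#' @param p_threshold p-value threshold, default 0.05.
#' @param variant `"welch"` (unequal variances, Welch–Satterthwaite df) or
#'   `"student"` (pooled variance).
#' @return a `de_table`: data frame with one row per probe — `probe_id`,
#'   `biotype`, `gene_symbol`, `mean_log2_control`, `mean_log2_treatment`,
#'   `log2fc` (treatment − control), `fc_linear` (2^|log2fc|), `t_stat`,
#'   `df`, `p_value`, `direction` (`up`/`down`/`none` by sign of log2fc),
#'   `is_de`, `zero_variance` — sorted by p ascending, ties by |log2fc|
#'   descending, then probe id.
#' @export
differential_expression <- function(x, fc_threshold = 2, p_threshold = 0.05,
                                    variant = c("welch", "student")) {
  variant <- match.arg(variant)
  if (x$scale != "log2")
    lnc_abort("lncnet_scale_error",
              "differential expression expects log2 intensities")
  if (fc_threshold < 1 || p_threshold <= 0 || p_threshold >= 1)
    lnc_abort("lncnet_value_error", "invalid DE thresholds")
  grp <- group_samples(x)
  n1 <- length(grp$control); n2 <- length(grp$treatment)
  if (n1 < 2L || n2 < 2L)
    lnc_abort("lncnet_design_error",
              "both groups need >= 2 samples for a t-test (have %d and %d)",
              n1, n2)
  xc <- x$intensities[, grp$control, drop = FALSE]
  xt <- x$intensities[, grp$treatment, drop = FALSE]
  m1 <- rowMeans(xc); m2 <- rowMeans(xt)
  v1 <- rowSums((xc - m1)^2) / (n1 - 1)
  v2 <- rowSums((xt - m2)^2) / (n2 - 1)
  diff <- m2 - m1
  if (variant == "welch") {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep.int(n1 + n2 - 2, length(diff))
  }
  t_stat <- diff / sqrt(se2)
  p <- 2 * stats::pt(-abs(t_stat), df)
  zero_var <- se2 == 0
  if (any(zero_var)) {
    eq <- zero_var & diff == 0
    ne <- zero_var & diff != 0
    t_stat[eq] <- 0; p[eq] <- 1; df[eq] <- NA_real_
    t_stat[ne] <- sign(diff[ne]) * Inf
    p[ne] <- .Machine$double.xmin; df[ne] <- NA_real_
  }
  res <- data.frame(
    probe_id = rownames(x$intensities),
    biotype = probe_biotypes(x),
    gene_symbol = probe_symbols(x),
    mean_log2_control = m1, mean_log2_treatment = m2,
    log2fc = diff, fc_linear = 2^abs(diff),
    t_stat = t_stat, df = df, p_value = p,
    direction = ifelse(diff > 0, "up", ifelse(diff < 0, "down", "none")),
    zero_variance = zero_var,
    stringsAsFactors = FALSE, row.names = NULL)
  res$is_de <- res$fc_linear >= fc_threshold & res$p_value <= p_threshold
  ord <- order(res$p_value, -abs(res$log2fc), res$probe_id)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("de_table", "data.frame"),
            fc_threshold = fc_threshold, p_threshold = p_threshold,
            variant = variant, n_control = n1, n_treatment = n2)
}

#' @export
print.de_table <- function(x, ...) {
  cat(sprintf("de_table: %d probes tested (%s t-test, FC >= %g, p <= %g)\n",
              nrow(x), attr(x, "variant"), attr(x, "fc_threshold"),
              attr(x, "p_threshold")))
  de <- x[x$is_de, , drop = FALSE]
  cat(sprintf("  %d differentially expressed: %d up, %d down\n",
              nrow(de), sum(de$direction == "up"),
              sum(de$direction == "down")))
  if (nrow(de)) {
    cat("  top records:\n")
    print.data.frame(utils::head(
      de[c("probe_id", "biotype", "gene_symbol", "log2fc", "p_value",
           "direction")], 5), digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.de_table <- function(object, ...) {
  de <- object[object$is_de, , drop = FALSE]
  out <- list(tested = nrow(object), de = nrow(de),
              up = sum(de$direction == "up"),
              down = sum(de$direction == "down"),
              by_biotype = table(de$biotype))
  class(out) <- "summary.de_table"
  out
}

#' @export
print.summary.de_table <- function(x, ...) {
  cat(sprintf("%d tested, %d DE (%d up / %d down)\n",
              x$tested, x$de, x$up, x$down))
  print(x$by_biotype)
  invisible(x)
}

#' Select the strongest up- and down-regulated probes
#'
#' Ranks differentially expressed records by |log2fc| descending (ties by p
#' ascending, then probe id) and returns the requested number in each
#' direction. If fewer DE records exist than requested, all are returned and
#' the shortfall recorded in the `shortfall` attribute (and warned about).
#'
#' @param records a `de_table`.
#' @param n_up,n_down number of up-/down-regulated records to keep.
#' @param rank_key `"fc"` (default: |log2fc|, ties by p) or `"p"` (p, ties
#'   by |log2fc|).
#' @return subset of `records` (up block first), with attribute `shortfall`.
#' @export
select_top_de <- function(records, n_up = 10, n_down = 10,
                          rank_key = c("fc", "p")) {
  rank_key <- match.arg(rank_key)
  if (n_up < 0 || n_down < 0)
    lnc_abort("lncnet_value_error", "n_up and n_down must be >= 0")
  de <- records[records$is_de, , drop = FALSE]
  pick <- function(dir, n) {
    d <- de[de$direction == dir, , drop = FALSE]
    ord <- if (rank_key == "fc")
      order(-abs(d$log2fc), d$p_value, d$probe_id)
    else order(d$p_value, -abs(d$log2fc), d$probe_id)
    utils::head(d[ord, , drop = FALSE], n)
  }
  up <- pick("up", n_up); down <- pick("down", n_down)
  shortfall <- c(up = n_up - nrow(up), down = n_down - nrow(down))
  if (any(shortfall > 0))
    lnc_warn("top-DE shortfall: requested %d up / %d down, found %d / %d",
             n_up, n_down, nrow(up), nrow(down))
  out <- rbind(up, down)
  rownames(out) <- NULL
  attr(out, "shortfall") <- shortfall
  out
}

#' Hierarchical clustering of probes and samples
#'
#' Agglomerative clustering for heatmap rendering: by default the distance
#' is 1 − Pearson correlation on log2 values and the linkage is average
#' (UPGMA), applied both to the probe subset and to the samples. Probes (or
#' samples) with zero variance have no defined correlation; their distance
#' to everything is set to 1 (no information) and they are reported.
#'
#' @param x an [expression_dataset] on log2 scale.
#' @param probe_subset probe ids to cluster (default: all probes).
#' @param distance `"correlation"` (1 − Pearson r) or `"euclidean"`.
#' @param linkage linkage method passed to [stats::hclust()], default
#'   `"average"`.
#' @return an `expression_clustering`: list with `probe_hclust`,
#'   `sample_hclust`, `probe_order`, `sample_order` (leaf orders as ids),
#'   and `constant_probes`.
#' @export
hierarchical_cluster <- function(x, probe_subset = rownames(x$intensities),
                                 distance = c("correlation", "euclidean"),
                                 linkage = "average") {
  distance <- match.arg(distance)
  if (length(probe_subset) < 2L)
    lnc_abort("lncnet_value_error", "need >= 2 probes to cluster")
  mat <- x$intensities[probe_subset, , drop = FALSE]
  dist_of <- function(m) {
    if (distance == "euclidean") return(stats::dist(m))
    sds <- apply(m, 1L, stats::sd)
    d <- 1 - suppressWarnings(stats::cor(t(m)))
    d[!is.finite(d)] <- 1   # zero-variance rows: no information
    diag(d) <- 0
    stats::as.dist(d)
  }
  constant <- rownames(mat)[apply(mat, 1L, stats::sd) == 0]
  probe_hc <- stats::hclust(dist_of(mat), method = linkage)
  sample_hc <- stats::hclust(dist_of(t(mat)), method = linkage)
  structure(list(probe_hclust = probe_hc, sample_hclust = sample_hc,
                 probe_order = rownames(mat)[probe_hc$order],
                 sample_order = colnames(mat)[sample_hc$order],
                 constant_probes = constant,
                 distance = distance, linkage = linkage),
            class = "expression_clustering")
}

#' @export
print.expression_clustering <- function(x, ...) {
  cat(sprintf("expression_clustering: %d probes x %d samples (%s distance, %s linkage)\n",
              length(x$probe_order), length(x$sample_order),
              x$distance, x$linkage))
  cat("  sample leaf order:", paste(x$sample_order, collapse = ", "), "\n")
  invisible(x)
}

#' Export a clustering as Newick trees plus leaf orders
#'
#' Writes `probes.nwk`, `samples.nwk` (Newick, via \pkg{ape}) and
#' `leaf_order.tsv` into `out_dir`.
#'
#' @param clustering an `expression_clustering`.
#' @param out_dir output directory.
#' @return named character vector of file paths, invisibly.
#' @export
write_clustering <- function(clustering, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(probes = file.path(out_dir, "probes.nwk"),
             samples = file.path(out_dir, "samples.nwk"),
             leaf_order = file.path(out_dir, "leaf_order.tsv"))
  ape::write.tree(ape::as.phylo(clustering$probe_hclust), paths[["probes"]])
  ape::write.tree(ape::as.phylo(clustering$sample_hclust), paths[["samples"]])
  lo <- data.frame(
    axis = c(rep("probe", length(clustering$probe_order)),
             rep("sample", length(clustering$sample_order))),
    position = c(seq_along(clustering$probe_order),
                 seq_along(clustering$sample_order)),
    id = c(clustering$probe_order, clustering$sample_order),
    stringsAsFactors = FALSE)
  write_tsv(lo, paths[["leaf_order"]])
  invisible(paths)
}
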