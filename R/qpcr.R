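#' Relative quantification by the 2^(-ddCt) method
#'
#' For each sample, dCt = Ct(target) − Ct(reference); the group-mean dCt of
#' the control group anchors the comparison, ddCt = mean dCt(treatment) −
#' mean dCt(control), and the relative quantity is RQ = 2^(−ddCt) (100%
#' amplification efficiency: one cycle per doubling). Per-sample RQs are
#' computed against the control-group mean dCt, with their standard
#' deviation per group. Group significance is a two-sided unpaired
#' Student's t-test on the per-sample dCt values (when both groups have at
#' least two samples).
#'
#' @param qpcr a `qpcr_table` (see [read_qpcr_table()]).
#' @param target_gene gene to quantify.
#' @param reference_gene endogenous reference; defaults to the table's
#'   designated reference.
#' @return a `relative_quantification`: list with `gene`, `reference`,
#'   `per_sample` (data frame `sample`, `group`, `delta_ct`, `rq`),
#'   `delta_ct_control`, `delta_ct_treatment` (group means), `delta_delta_ct`,
#'   `rq`, `rq_sd` (named per-group s.d. of per-sample RQs), `p_value`.
#' @export
delta_delta_ct <- function(qpcr, target_gene,
                           reference_gene = attr(qpcr, "reference_gene")) {
  df <- as.data.frame(qpcr)
  if (!target_gene %in% df$gene)
    lnc_abort("lncnet_value_error", "unknown target gene '%s'", target_gene)
  if (!reference_gene %in% df$gene)
    lnc_abort("lncnet_value_error", "unknown reference gene '%s'",
              reference_gene)
  tgt <- df[df$gene == target_gene, , drop = FALSE]
  ref <- df[df$gene == reference_gene, , drop = FALSE]
  idx <- match(tgt$sample, ref$sample)
  if (any(is.na(idx)))
    lnc_abort("lncnet_pairing_error",
              "sample(s) lack reference Ct: %s",
              paste(tgt$sample[is.na(idx)], collapse = ", "))
  per <- data.frame(sample = tgt$sample, group = tgt$group,
                    delta_ct = tgt$ct - ref$ct[idx],
                    stringsAsFactors = FALSE)
  ctrl <- attr(qpcr, "control"); trt <- attr(qpcr, "treatment")
  dct_c <- per$delta_ct[per$group == ctrl]
  dct_t <- per$delta_ct[per$group == trt]
  if (length(dct_c) < 1L || length(dct_t) < 1L)
    lnc_abort("lncnet_design_error",
              "target '%s' needs >= 1 sample per group", target_gene)
  ddct <- mean(dct_t) - mean(dct_c)
  per$rq <- 2^(-(per$delta_ct - mean(dct_c)))
  rq_sd <- c(stats::sd(per$rq[per$group == ctrl]),
             stats::sd(per$rq[per$group == trt]))
  names(rq_sd) <- c(ctrl, trt)
  p <- if (length(dct_c) >= 2L && length(dct_t) >= 2L &&
           (stats::sd(dct_c) > 0 || stats::sd(dct_t) > 0))
    stats::t.test(dct_c, dct_t, var.equal = TRUE)$p.value
  else NA_real_
  structure(list(gene = target_gene, reference = reference_gene,
                 per_sample = per,
                 delta_ct_control = mean(dct_c),
                 delta_ct_treatment = mean(dct_t),
                 delta_delta_ct = ddct, rq = 2^(-ddct),
                 rq_sd = rq_sd, p_value = p),
            class = "relative_quantification")
}

#' @export
print.relative_quantification <- function(x, ...) {
  cat(sprintf("relative_quantification: %s (reference %s)\n",
              x$gene, x$reference))
  cat(sprintf("  mean dCt control %.3f, treatment %.3f; ddCt = %.3f\n",
              x$delta_ct_control, x$delta_ct_treatment, x$delta_delta_ct))
  cat(sprintf("  RQ = 2^(-ddCt) = %.4g", x$rq))
  if (is.finite(x$p_value)) cat(sprintf("  (t-test on dCt: p = %.4g)", x$p_value))
  cat("\n")
  invisible(x)
}

#' Direction concordance between qPCR and array calls
#'
#' For each quantified gene, compares the qPCR direction (RQ > 1 up,
#' RQ < 1 down) with the array direction of the best-supported (smallest p)
#' probe of the same gene symbol, and reports log2(RQ) next to the array
#' log2 fold change. Genes with no matching symbol in the array records are
#' reported with `NA` agreement rather than failing.
#'
#' @param rq_results a list of `relative_quantification` objects (or one).
#' @param de_records a `de_table`.
#' @return a `concordance_report` data frame: `gene`, `array_probe`,
#'   `array_log2fc`, `array_direction`, `qpcr_log2rq`, `qpcr_direction`,
#'   `agree`.
#' @export
concordance_report <- function(rq_results, de_records) {
  if (inherits(rq_results, "relative_quantification"))
    rq_results <- list(rq_results)
  de <- as.data.frame(de_records)
  rows <- lapply(rq_results, function(rq) {
    hit <- de[de$gene_symbol == rq$gene, , drop = FALSE]
    if (nrow(hit) == 0L) {
      lnc_warn("gene '%s' not found among array records", rq$gene)
      return(data.frame(gene = rq$gene, array_probe = NA_character_,
                        array_log2fc = NA_real_,
                        array_direction = NA_character_,
                        qpcr_log2rq = log2(rq$rq),
                        qpcr_direction = if (rq$rq > 1) "up" else
                          if (rq$rq < 1) "down" else "none",
                        agree = NA, stringsAsFactors = FALSE))
    }
    hit <- hit[order(hit$p_value, -abs(hit$log2fc), hit$probe_id), ,
               drop = FALSE][1, ]
    qdir <- if (rq$rq > 1) "up" else if (rq$rq < 1) "down" else "none"
    data.frame(gene = rq$gene, array_probe = hit$probe_id,
               array_log2fc = hit$log2fc, array_direction = hit$direction,
               qpcr_log2rq = log2(rq$rq), qpcr_direction = qdir,
               agree = qdir == hit$direction, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("concordance_report", "data.frame"))
}

#' @export
print.concordance_report <- function(x, ...) {
  n_ok <- sum(x$agree, na.rm = TRUE)
  n <- sum(!is.na(x$agree))
  cat(sprintf("concordance_report: %d/%d genes agree in direction\n",
              n_ok, n))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
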