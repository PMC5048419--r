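#' Quantile normalization
#'
#' Classic quantile normalization: each column's sorted values are replaced
#' by the across-column mean of sorted values, so that afterwards every
#' sample has an identical empirical intensity distribution. Tied values
#' within a column receive the mean of the sorted-mean values across their
#' tied rank span, which keeps the procedure deterministic and symmetric in
#' the tied entries. Flags are left untouched.
#'
#' @param x an [expression_dataset] on linear scale.
#' @return the dataset with normalized intensities.
#' @export
quantile_normalize <- function(x) {
  validate_expression_dataset(x)
  ints <- x$intensities
  if (any(!is.finite(ints)))
    lnc_abort("lncnet_value_error", "non-finite intensities")
  if (ncol(ints) >= 2L && nrow(ints) >= 1L) {
    sorted_means <- rowMeans(apply(ints, 2L, sort))
    out <- apply(ints, 2L, function(col) {
      v <- numeric(length(col))
      v[order(col)] <- sorted_means
      # ave() groups equal values: mean over the tied rank span
      stats::ave(v, col, FUN = mean)
    })
    dimnames(out) <- dimnames(ints)
    x$intensities <- out
  }
  x
}

#' Detection-flag filtering
#'
#' Retains the probes considered reliably detected: under the default rule a
#' probe is kept iff *all* samples of at least one group (control or
#' treatment) carry flag `"P"`. The alternative rule `"any_present"` keeps a
#' probe with at least one `"P"` anywhere. Dropped probes are removed from
#' the intensity matrix, the flags and the annotation, and hence from every
#' downstream universe.
#'
#' @param x an [expression_dataset].
#' @param rule `"all_present_one_group"` (default) or `"any_present"`.
#' @return list with elements `dataset` (the filtered dataset) and `report`
#'   (a `filter_report`: counts plus per-probe keep decision and reason).
#' @export
filter_by_flags <- function(x, rule = c("all_present_one_group",
                                        "any_present")) {
  rule <- match.arg(rule)
  validate_expression_dataset(x)
  grp <- group_samples(x)
  p <- x$flags == "P"
  if (rule == "all_present_one_group") {
    all_ctrl <- rowSums(p[, grp$control, drop = FALSE]) == length(grp$control)
    all_trt <- rowSums(p[, grp$treatment, drop = FALSE]) == length(grp$treatment)
    keep <- all_ctrl | all_trt
    reason <- ifelse(keep,
                     ifelse(all_ctrl & all_trt, "all_P_both_groups",
                            ifelse(all_ctrl, "all_P_control", "all_P_treatment")),
                     "no_group_fully_present")
  } else {
    keep <- rowSums(p) >= 1L
    reason <- ifelse(keep, "P_somewhere", "no_P_anywhere")
  }
  report <- structure(
    list(rule = rule,
         probes_in = nrow(x$intensities),
         probes_kept = sum(keep),
         probes_dropped = sum(!keep),
         decisions = data.frame(probe_id = rownames(x$intensities),
                                kept = keep, reason = reason,
                                stringsAsFactors = FALSE)),
    class = "filter_report")
  kept_ids <- rownames(x$intensities)[keep]
  if (length(kept_ids) == 0L)
    lnc_abort("lncnet_value_error", "flag filter removed every probe")
  list(dataset = subset_probes(x, kept_ids), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report (%s): %d probes in, %d kept, %d dropped\n",
              x$rule, x$probes_in, x$probes_kept, x$probes_dropped))
  invisible(x)
}

#' Write a filter report as TSV
#'
#' @param report a `filter_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  write_tsv(report$decisions, path,
            comment_lines = sprintf("rule=%s; in=%d; kept=%d; dropped=%d",
                                    report$rule, report$probes_in,
                                    report$probes_kept, report$probes_dropped))
}

#' Log2 transformation
#'
#' Moves a linear-scale dataset to log2, adding a small offset to guard
#' zero intensities: `log2(intensity + offset)`. Refuses to transform a
#' dataset that is already on log2 scale.
#'
#' @param x an [expression_dataset] on linear scale.
#' @param offset additive offset, default 1.
#' @return the dataset on log2 scale.
#' @export
log2_transform <- function(x, offset = 1) {
  if (x$scale == "log2")
    lnc_abort("lncnet_scale_error", "dataset is already on log2 scale")
  if (any(x$intensities + offset <= 0))
    lnc_abort("lncnet_value_error",
              "non-positive intensity after offset %g", offset)
  x$intensities <- log2(x$intensities + offset)
  x$scale <- "log2"
  x
}

#' Standard preprocessing chain
#'
#' Quantile normalization, flag filtering and log2 transformation in the
#' conventional single-channel array order (normalize on linear intensities
#' first, then filter, then log). The order of the first two steps can be
#' swapped for sensitivity checks.
#'
#' @param x an [expression_dataset] on linear scale.
#' @param order `"normalize_then_filter"` (default) or
#'   `"filter_then_normalize"`.
#' @inheritParams filter_by_flags
#' @inheritParams log2_transform
#' @return list with `dataset` (log2 scale, filtered, normalized) and
#'   `report` (the `filter_report`).
#' @export
preprocess <- function(x, order = c("normalize_then_filter",
                                    "filter_then_normalize"),
                       rule = "all_present_one_group", offset = 1) {
  order <- match.arg(order)
  if (order == "normalize_then_filter") {
    flt <- filter_by_flags(quantile_normalize(x), rule = rule)
  } else {
    flt <- filter_by_flags(x, rule = rule)
    flt$dataset <- quantile_normalize(flt$dataset)
  }
  list(dataset = log2_transform(flt$dataset, offset = offset),
       report = flt$report)
}
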