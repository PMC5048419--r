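#' Pearson correlation coefficient
#'
#' Sample Pearson correlation of two equal-length vectors, exactly ±1 for
#' perfectly (anti-)linear inputs. If either vector has zero variance the
#' correlation is undefined and `NA` is returned; downstream pair builders
#' exclude and count such cases.
#'
#' @param x,y numeric vectors of equal length >= 3, finite values.
#' @return the correlation, or `NA_real_` if undefined.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y))
    lnc_abort("lncnet_value_error", "vectors differ in length")
  if (length(x) < 3L)
    lnc_abort("lncnet_value_error", "need >= 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    lnc_abort("lncnet_value_error", "non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Correlation p-value
#'
#' Two-sided p-value for a Pearson correlation from `m` paired samples via
#' the t transform `t = r * sqrt((m - 2) / (1 - r^2))` referred to a t
#' distribution with `m - 2` degrees of freedom. `|r| = 1` maps to the
#' smallest representable positive double. Vectorised over `r`; `NA`
#' correlations give `NA` p-values.
#'
#' @param r Pearson correlation(s), `|r| <= 1`.
#' @param m number of paired samples, >= 3.
#' @return two-sided p-value(s) in (0, 1].
#' @export
correlation_p <- function(r, m) {
  if (m < 3L)
    lnc_abort("lncnet_value_error", "need m >= 3 samples")
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    lnc_abort("lncnet_value_error", "|r| must be <= 1")
  r <- pmin(pmax(r, -1), 1)
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r)
  exact1 <- ok & abs(r) == 1
  mid <- ok & !exact1
  tstat <- r[mid] * sqrt((m - 2) / (1 - r[mid]^2))
  p[mid] <- 2 * stats::pt(-abs(tstat), df = m - 2)
  p[exact1] <- .Machine$double.xmin
  p
}

#' All lncRNA-mRNA co-expression pairs
#'
#' Computes the Pearson correlation and its p-value for every requested
#' lncRNA probe against every requested mRNA probe, across *all* samples
#' (both groups pooled — with three samples per group a within-group
#' correlation carries almost no information). Pairs whose correlation is
#' undefined (a constant probe) are excluded and counted in the
#' `n_excluded` attribute.
#'
#' @param x an [expression_dataset] on log2 scale.
#' @param lncrna_ids,mrna_ids probe ids present in `x`.
#' @return a `coexpression_pairs` data frame: `lncrna_probe`, `mrna_probe`,
#'   `mrna_symbol`, `r`, `p_value`; attributes `n_samples`, `n_excluded`.
#' @export
coexpression_pairs <- function(x, lncrna_ids, mrna_ids) {
  if (length(lncrna_ids) == 0L || length(mrna_ids) == 0L)
    lnc_abort("lncnet_value_error", "empty probe list")
  if (x$scale != "log2")
    lnc_abort("lncnet_scale_error", "co-expression expects log2 intensities")
  missing <- setdiff(c(lncrna_ids, mrna_ids), rownames(x$intensities))
  if (length(missing))
    lnc_abort("lncnet_value_error", "unknown probe id(s): %s",
              paste(utils::head(missing, 5), collapse = ", "))
  m <- ncol(x$intensities)
  lmat <- t(x$intensities[lncrna_ids, , drop = FALSE])
  mmat <- t(x$intensities[mrna_ids, , drop = FALSE])
  R <- suppressWarnings(stats::cor(lmat, mmat))
  pairs <- data.frame(
    lncrna_probe = rep(lncrna_ids, times = length(mrna_ids)),
    mrna_probe = rep(mrna_ids, each = length(lncrna_ids)),
    r = as.vector(R), stringsAsFactors = FALSE)
  n_total <- nrow(pairs)
  pairs <- pairs[!is.na(pairs$r), , drop = FALSE]
  pairs$p_value <- correlation_p(pairs$r, m)
  pairs$mrna_symbol <- probe_symbols(x, pairs$mrna_probe)
  pairs <- pairs[c("lncrna_probe", "mrna_probe", "mrna_symbol", "r",
                   "p_value")]
  rownames(pairs) <- NULL
  structure(pairs, class = c("coexpression_pairs", "data.frame"),
            n_samples = m, n_excluded = n_total - nrow(pairs))
}

#' Top correlated pairs by p-value
#'
#' Orders pairs by p ascending, ties by |r| descending, then by
#' (lncRNA id, mRNA id), and returns the first `k` with ranks 1..k. The
#' ordering is total, so repeated calls give identical output.
#'
#' @param pairs a `coexpression_pairs` data frame.
#' @param k number of pairs to keep, default 500; if more than available,
#'   all are returned.
#' @return the top pairs with an added `rank` column.
#' @export
select_top_pairs <- function(pairs, k = 500) {
  if (k < 1) lnc_abort("lncnet_value_error", "k must be >= 1")
  ord <- order(pairs$p_value, -abs(pairs$r), pairs$lncrna_probe,
               pairs$mrna_probe)
  out <- utils::head(pairs[ord, , drop = FALSE], k)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Significantly correlated mRNA symbols of one lncRNA
#'
#' The distinct gene symbols of the mRNA probes whose pair with the given
#' lncRNA has p strictly below the cutoff; multiple probes of one symbol
#' collapse to a single entry.
#'
#' @param pairs a `coexpression_pairs` data frame.
#' @param lncrna_id a lncRNA probe id present in `pairs`.
#' @param p_cutoff significance cutoff, default 0.05.
#' @return character vector of gene symbols (possibly empty), sorted.
#' @export
correlated_mrna_set <- function(pairs, lncrna_id, p_cutoff = 0.05) {
  if (p_cutoff <= 0 || p_cutoff >= 1)
    lnc_abort("lncnet_value_error", "p_cutoff must be in (0, 1)")
  sel <- pairs$lncrna_probe == lncrna_id
  if (!any(sel))
    lnc_abort("lncnet_value_error", "unknown lncRNA id '%s'", lncrna_id)
  sort(unique(pairs$mrna_symbol[sel & pairs$p_value < p_cutoff]))
}
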