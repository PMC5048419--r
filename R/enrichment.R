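#' Hypergeometric upper-tail probability
#'
#' The over-representation statistic used throughout: the probability of
#' observing an overlap of at least `k` between a random draw of `n`
#' elements and a fixed set of `K` elements in a universe of `N`,
#' `P[X >= k] = sum_{i=k}^{min(K,n)} C(K,i) C(N-K,n-i) / C(N,n)`.
#' Terms are accumulated in log space (via `lchoose`) for numerical
#' stability; `k = 0` returns exactly 1.
#'
#' @param N universe size.
#' @param K set size within the universe.
#' @param n draw (query) size within the universe.
#' @param k observed overlap, `0 <= k <= min(K, n)`.
#' @return `P[X >= k]`, in (0, 1].
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  vals <- c(N = N, K = K, n = n, k = k)
  if (any(vals != round(vals)) || any(vals < 0))
    lnc_abort("lncnet_value_error", "N, K, n, k must be non-negative integers")
  if (K > N || n > N || k > min(K, n))
    lnc_abort("lncnet_value_error",
              "inconsistent counts: need k <= min(K, n) <= N")
  if (k == 0) return(1)
  i <- k:min(K, n)
  lt <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  mx <- max(lt)
  p <- exp(mx + log(sum(exp(lt - mx))))
  # keep the (0, 1] contract even when the tail underflows double range
  min(max(p, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, preserving input order:
#' `adj_i = min_{j >= rank(i)} (m * p_(j) / j)`, capped at 1.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return adjusted values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    lnc_abort("lncnet_value_error", "p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Over-representation of a query set in a collection
#'
#' Guilt-by-association enrichment: tests a query symbol set against every
#' set of a [gene_set_collection] with the hypergeometric upper tail. The
#' query is intersected with the collection universe before testing;
#' N = universe size, K = set size, n = query size, k = overlap. BH
#' adjustment is applied across all sets of the collection, then records
#' with overlap below `min_overlap` are dropped. Results are sorted by p
#' ascending, ties by set name.
#'
#' @param query_symbols character vector of gene symbols.
#' @param collection a [gene_set_collection].
#' @param min_overlap minimum overlap `k` for a set to be reported,
#'   default 1; use 0 to report every set.
#' @param query_label label carried in the `query` column, default
#'   `"query"`.
#' @return an `association_table`: data frame with `query`, `set_name`,
#'   `branch` (if the collection carries branch labels), `N`, `K`, `n`,
#'   `k`, `p_hyper`, `fdr`, `overlap` (semicolon-joined symbols).
#' @export
enrich <- function(query_symbols, collection, min_overlap = 1,
                   query_label = "query") {
  universe <- collection$universe
  query <- intersect(unique(trimws(query_symbols)), universe)
  if (length(query) == 0L) {
    lnc_warn("query has no symbols in the collection universe")
    out <- data.frame(query = character(), set_name = character(),
                      N = integer(), K = integer(), n = integer(),
                      k = integer(), p_hyper = numeric(), fdr = numeric(),
                      overlap = character(), stringsAsFactors = FALSE)
    return(structure(out, class = c("association_table", "data.frame")))
  }
  N <- length(universe); n <- length(query)
  set_names <- names(collection$sets)
  K <- vapply(collection$sets, length, integer(1))
  ov <- lapply(collection$sets, intersect, query)
  k <- vapply(ov, length, integer(1))
  p <- vapply(seq_along(set_names), function(i)
    hypergeom_upper_tail(N, K[[i]], n, k[[i]]), numeric(1))
  fdr <- bh_adjust(p)
  out <- data.frame(query = query_label, set_name = set_names,
                    N = N, K = unname(K), n = n, k = unname(k),
                    p_hyper = p, fdr = fdr,
                    overlap = vapply(ov, function(s)
                      paste(sort(s), collapse = ";"), character(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(collection$branches))
    out$branch <- unname(collection$branches[out$set_name])
  out <- out[out$k >= min_overlap, , drop = FALSE]
  out <- out[order(out$p_hyper, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("association_table", "data.frame"),
            collection = collection$name)
}

#' @export
print.association_table <- function(x, ...) {
  cat(sprintf("association_table: %d records", nrow(x)))
  if (!is.null(attr(x, "collection")))
    cat(sprintf(" (collection '%s')", attr(x, "collection")))
  cat("\n")
  if (nrow(x))
    print.data.frame(utils::head(
      x[intersect(c("query", "set_name", "k", "K", "p_hyper", "fdr"),
                  names(x))], 5), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Top enriched sets, per branch when branch labels exist
#'
#' Returns the first `top_n` records (already sorted by p, ties by set
#' name) — per branch label when the records carry a `branch` column, so a
#' GO collection reports its top sets per Molecular Function / Biological
#' Process / Cellular Component.
#'
#' @param records an `association_table` sorted per [enrich()].
#' @param top_n records to keep (per branch), default 10.
#' @return subset of `records`.
#' @export
top_terms <- function(records, top_n = 10) {
  if (nrow(records) == 0L) return(records)
  if (!is.null(records$branch) && !all(is.na(records$branch))) {
    parts <- split(seq_len(nrow(records)), records$branch)
    idx <- sort(unlist(lapply(parts, utils::head, top_n), use.names = FALSE))
    out <- records[idx, , drop = FALSE]
  } else {
    out <- utils::head(records, top_n)
  }
  rownames(out) <- NULL
  out
}
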