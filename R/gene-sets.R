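#' Gene-set collection
#'
#' A named collection of gene-symbol sets — functional terms (GO/KEGG-style)
#' or transcription-factor target sets (ENCODE-style) — together with a
#' declared universe. Every member of every set must lie in the universe;
#' set names are unique and sets non-empty. Symbols are compared
#' case-sensitively after whitespace stripping; no alias resolution is
#' attempted (alias mapping would silently change overlap counts).
#'
#' @param name collection name.
#' @param kind `"term"` or `"tf_target"`.
#' @param sets named list of character vectors of gene symbols.
#' @param universe explicit universe of gene symbols, or `NULL` to use the
#'   union of all members.
#' @param descriptions optional named character vector of set descriptions.
#' @param branches optional named character vector assigning each set a
#'   branch label (e.g. the GO branch: Molecular Function, Biological
#'   Process, Cellular Component), used by [top_terms()] for per-branch
#'   reporting.
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(name, kind = c("term", "tf_target"), sets,
                                universe = NULL, descriptions = NULL,
                                branches = NULL) {
  kind <- match.arg(kind)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    lnc_abort("lncnet_gmt_error", "every set must be named")
  if (anyDuplicated(names(sets)))
    lnc_abort("lncnet_gmt_error", "duplicate set name(s): %s",
              paste(unique(names(sets)[duplicated(names(sets))]),
                    collapse = ", "))
  sets <- lapply(sets, function(s) unique(trimws(as.character(s))))
  empty <- vapply(sets, length, integer(1)) == 0L
  if (any(empty))
    lnc_abort("lncnet_gmt_error", "empty set(s): %s",
              paste(names(sets)[empty], collapse = ", "))
  members <- unique(unlist(sets, use.names = FALSE))
  if (is.null(universe)) {
    universe <- sort(members)
  } else {
    universe <- unique(trimws(as.character(universe)))
    uncovered <- setdiff(members, universe)
    if (length(uncovered))
      lnc_abort("lncnet_universe_error",
                "set member(s) outside the declared universe: %s",
                paste(utils::head(uncovered, 5), collapse = ", "))
  }
  structure(list(name = name, kind = kind, sets = sets, universe = universe,
                 descriptions = descriptions, branches = branches),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- vapply(x$sets, length, integer(1))
  cat(sprintf("gene_set_collection '%s' (%s): %d sets, universe %d symbols\n",
              x$name, x$kind, length(x$sets), length(x$universe)))
  cat(sprintf("  set sizes: min %d / median %g / max %d\n",
              min(sizes), stats::median(sizes), max(sizes)))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Restrict a collection to a new universe
#'
#' Intersects every set and the universe with `symbols`; sets that become
#' empty are dropped. Used to re-universe a collection to the symbols
#' actually measured on the filtered array.
#'
#' @param collection a [gene_set_collection].
#' @param symbols character vector of gene symbols.
#' @return a [gene_set_collection].
#' @export
restrict_universe <- function(collection, symbols) {
  symbols <- unique(trimws(as.character(symbols)))
  new_universe <- intersect(collection$universe, symbols)
  sets <- lapply(collection$sets, intersect, new_universe)
  keep <- vapply(sets, length, integer(1)) > 0L
  gene_set_collection(collection$name, collection$kind, sets[keep],
                      universe = new_universe,
                      descriptions = collection$descriptions[names(sets)[keep]],
                      branches = collection$branches[names(sets)[keep]])
}
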