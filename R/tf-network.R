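#' lncRNA-TF associations by target-set overlap
#'
#' Infers which transcription factors plausibly regulate each lncRNA: a
#' lncRNA's significantly correlated mRNA set is tested for overlap against
#' every TF's target-gene set with the hypergeometric upper tail (the
#' guilt-by-association logic of [enrich()], with every TF reported,
#' including zero overlaps). Records are pooled across lncRNAs and ordered
#' globally by p ascending, ties by TF name then lncRNA id. If the same
#' (TF, lncRNA) pair arises more than once (multiple probes of a symbol),
#' only the record with the smallest p is kept.
#'
#' @param correlated_sets named list mapping each lncRNA id to its
#'   correlated mRNA symbol set (see [correlated_mrna_set()]). lncRNAs with
#'   empty sets are skipped with a warning.
#' @param tf_collection a [gene_set_collection] of kind `"tf_target"`.
#' @return an `association_table` with columns `lncrna`, `tf`, `N`, `K`,
#'   `n`, `k`, `p_hyper`, `fdr`, `overlap`.
#' @export
tf_associations <- function(correlated_sets, tf_collection) {
  if (tf_collection$kind != "tf_target")
    lnc_abort("lncnet_value_error",
              "tf_collection must have kind 'tf_target'")
  if (length(correlated_sets) == 0L)
    lnc_abort("lncnet_value_error", "no correlated sets supplied")
  empty <- vapply(correlated_sets, length, integer(1)) == 0L
  if (any(empty))
    lnc_warn("skipping %d lncRNA(s) with empty correlated sets", sum(empty))
  correlated_sets <- correlated_sets[!empty]
  recs <- lapply(names(correlated_sets), function(id) {
    r <- enrich(correlated_sets[[id]], tf_collection, min_overlap = 0,
                query_label = id)
    if (nrow(r)) names(r)[names(r) == "query"] <- "lncrna"
    r
  })
  out <- do.call(rbind, lapply(recs, as.data.frame))
  if (is.null(out) || nrow(out) == 0L) {
    out <- data.frame(lncrna = character(), tf = character(), N = integer(),
                      K = integer(), n = integer(), k = integer(),
                      p_hyper = numeric(), fdr = numeric(),
                      overlap = character(), stringsAsFactors = FALSE)
    return(structure(out, class = c("association_table", "data.frame")))
  }
  names(out)[names(out) == "set_name"] <- "tf"
  # dedup (tf, lncrna): keep smallest p
  ord <- order(out$p_hyper, out$tf, out$lncrna)
  out <- out[ord, , drop = FALSE]
  out <- out[!duplicated(out[c("tf", "lncrna")]), , drop = FALSE]
  out <- out[order(out$p_hyper, out$tf, out$lncrna),
             c("lncrna", "tf", "N", "K", "n", "k", "p_hyper", "fdr",
               "overlap"), drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("association_table", "data.frame"),
            collection = tf_collection$name)
}

# -log10 p as a Cytoscape-friendly continuous edge weight
edge_weight <- function(p) -log10(pmax(p, .Machine$double.xmin))

new_typed_network <- function(nodes, edges) {
  # nodes: data.frame(id, role); edges: data.frame(from, to, role, weight)
  if (anyDuplicated(nodes$id))
    lnc_abort("lncnet_network_error", "duplicate node id(s)")
  if (nrow(edges)) {
    if (any(edges$from == edges$to))
      lnc_abort("lncnet_network_error", "self-loop edge")
    if (anyDuplicated(edges[c("from", "to", "role")]))
      lnc_abort("lncnet_network_error", "duplicate edge")
    bad <- setdiff(c(edges$from, edges$to), nodes$id)
    if (length(bad))
      lnc_abort("lncnet_network_error", "edge endpoint(s) missing: %s",
                paste(utils::head(bad, 5), collapse = ", "))
  }
  g <- igraph::graph_from_data_frame(
    edges[c("from", "to", "role", "weight")],
    directed = TRUE, vertices = nodes)
  structure(list(graph = g), class = "typed_network")
}

#' @export
print.typed_network <- function(x, ...) {
  s <- network_stats(x)
  cat(sprintf("typed_network: %d nodes, %d edges\n", s$n_nodes, s$n_edges))
  if (length(s$nodes_by_role))
    cat("  nodes by role:",
        paste(sprintf("%s=%d", names(s$nodes_by_role), s$nodes_by_role),
              collapse = ", "), "\n")
  invisible(x)
}

#' Top lncRNA-TF pair network
#'
#' Builds the heterogeneous network of the most related lncRNA-TF pairs:
#' associations are ordered by p (ties by TF name, then lncRNA id),
#' duplicate (TF, lncRNA) pairs are collapsed to their best p, and the
#' first `top_pairs` become directed TF → lncRNA edges (role
#' `tf_regulates_lncrna`, weight −log10 p) with their incident nodes.
#'
#' @param associations an `association_table` from [tf_associations()].
#' @param top_pairs number of edges to keep, default 200.
#' @return a `typed_network`.
#' @export
build_lncrna_tf_network <- function(associations, top_pairs = 200) {
  if (top_pairs < 1)
    lnc_abort("lncnet_value_error", "top_pairs must be >= 1")
  a <- as.data.frame(associations)
  if (nrow(a)) {
    a <- a[order(a$p_hyper, a$tf, a$lncrna), , drop = FALSE]
    a <- a[!duplicated(a[c("tf", "lncrna")]), , drop = FALSE]
    a <- utils::head(a, top_pairs)
  }
  nodes <- data.frame(
    id = c(unique(a$tf), unique(a$lncrna)),
    role = c(rep("TF", length(unique(a$tf))),
             rep("lncRNA", length(unique(a$lncrna)))),
    stringsAsFactors = FALSE)
  edges <- data.frame(from = a$tf, to = a$lncrna,
                      role = rep("tf_regulates_lncrna", nrow(a)),
                      weight = edge_weight(a$p_hyper),
                      stringsAsFactors = FALSE)
  new_typed_network(nodes, edges)
}

#' Tripartite lncRNA-target-TF network
#'
#' The network around the strongest differentially expressed lncRNAs:
#' TF → lncRNA edges are the best `top_tfs` association records (by p)
#' restricted to the given lncRNAs, and lncRNA → mRNA edges are the best
#' `top_mrnas` correlation-pair records (by p; duplicates per
#' (lncRNA, symbol) collapsed to the best p) restricted to the same
#' lncRNAs. mRNA nodes are gene symbols. All requested lncRNAs appear as
#' nodes even when isolated.
#'
#' @param top_lncrnas character vector of lncRNA probe ids (typically from
#'   [select_top_de()], 10 up + 10 down).
#' @param pairs a `coexpression_pairs` data frame.
#' @param associations an `association_table` from [tf_associations()].
#' @param top_tfs number of TF → lncRNA association records to keep,
#'   default 100.
#' @param top_mrnas number of lncRNA → mRNA correlation records to keep,
#'   default 200.
#' @return a `typed_network` with roles `lncRNA`, `TF`, `mRNA`.
#' @export
build_lncrna_target_tf_network <- function(top_lncrnas, pairs, associations,
                                           top_tfs = 100, top_mrnas = 200) {
  if (top_tfs < 1 || top_mrnas < 1)
    lnc_abort("lncnet_value_error", "top_tfs and top_mrnas must be >= 1")
  a <- as.data.frame(associations)
  a <- a[a$lncrna %in% top_lncrnas, , drop = FALSE]
  a <- a[order(a$p_hyper, a$tf, a$lncrna), , drop = FALSE]
  a <- a[!duplicated(a[c("tf", "lncrna")]), , drop = FALSE]
  a <- utils::head(a, top_tfs)

  p <- as.data.frame(pairs)
  p <- p[p$lncrna_probe %in% top_lncrnas, , drop = FALSE]
  p <- p[order(p$p_value, -abs(p$r), p$lncrna_probe, p$mrna_symbol), ,
         drop = FALSE]
  p <- p[!duplicated(p[c("lncrna_probe", "mrna_symbol")]), , drop = FALSE]
  p <- utils::head(p, top_mrnas)

  role_nodes <- function(ids, role)
    data.frame(id = ids, role = rep(role, length(ids)),
               stringsAsFactors = FALSE)
  nodes <- rbind(
    role_nodes(top_lncrnas, "lncRNA"),
    role_nodes(unique(a$tf), "TF"),
    role_nodes(setdiff(unique(p$mrna_symbol), top_lncrnas), "mRNA"))
  edges <- rbind(
    data.frame(from = a$tf, to = a$lncrna,
               role = rep("tf_regulates_lncrna", nrow(a)),
               weight = edge_weight(a$p_hyper), stringsAsFactors = FALSE),
    data.frame(from = p$lncrna_probe, to = p$mrna_symbol,
               role = rep("lncrna_correlates_mrna", nrow(p)),
               weight = edge_weight(p$p_value), stringsAsFactors = FALSE))
  new_typed_network(nodes, edges)
}

#' Export a typed network for Cytoscape
#'
#' SIF uses the edge role as the interaction token (`source role target`,
#' tab-separated, plus one bare line per isolated node). GraphML (written
#' via \pkg{igraph}) carries the node `role` and edge `role`/`weight`
#' attributes and round-trips exactly through [read_graphml_network()].
#'
#' @param network a `typed_network`.
#' @param path output file path.
#' @param format `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(network, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  g <- network$graph
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(g, what = "edges")
    lines <- if (nrow(el))
      paste(el$from, el$role, el$to, sep = "\t") else character()
    deg <- igraph::degree(g, mode = "all")
    isolated <- names(deg)[deg == 0]
    con <- file(path, open = "wb", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(c(lines, isolated), con, sep = "\n")
  }
  invisible(path)
}

#' Read a GraphML file back into a typed network
#'
#' @param path GraphML file written by [export_graph()].
#' @return a `typed_network`.
#' @export
read_graphml_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::as_data_frame(g, what = "vertices")
  edges <- igraph::as_data_frame(g, what = "edges")
  nodes <- data.frame(id = nodes$name, role = nodes$role,
                      stringsAsFactors = FALSE)
  if (!nrow(edges))
    edges <- data.frame(from = character(), to = character(),
                        role = character(), weight = numeric())
  new_typed_network(nodes, edges[c("from", "to", "role", "weight")])
}

#' Summary statistics of a typed network
#'
#' @param network a `typed_network`.
#' @param n_hubs number of top-degree hubs to report per role, default 5.
#' @return a `network_stats` list: `n_nodes`, `n_edges`, `nodes_by_role`,
#'   `edges_by_role`, `degree` (named vector, total degree), `hubs`
#'   (data frame `id`, `role`, `degree`).
#' @export
network_stats <- function(network, n_hubs = 5) {
  g <- network$graph
  nodes <- igraph::as_data_frame(g, what = "vertices")
  edges <- igraph::as_data_frame(g, what = "edges")
  deg <- igraph::degree(g, mode = "all")
  hubs <- do.call(rbind, lapply(split(nodes, nodes$role), function(nd) {
    d <- sort(deg[nd$name], decreasing = TRUE)
    d <- utils::head(d[order(-d, names(d))], n_hubs)
    data.frame(id = names(d), role = nd$role[1], degree = as.integer(d),
               stringsAsFactors = FALSE)
  }))
  rownames(hubs) <- NULL
  structure(list(
    n_nodes = nrow(nodes), n_edges = nrow(edges),
    nodes_by_role = if (nrow(nodes))
      table(nodes$role) else table(character()),
    edges_by_role = if (nrow(edges))
      table(edges$role) else table(character()),
    degree = deg, hubs = hubs), class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf("network: %d nodes, %d edges\n", x$n_nodes, x$n_edges))
  if (length(x$nodes_by_role)) {
    cat("  nodes:", paste(sprintf("%s=%d", names(x$nodes_by_role),
                                  x$nodes_by_role), collapse = ", "), "\n")
  }
  if (!is.null(x$hubs) && nrow(x$hubs)) {
    cat("  top hubs:\n")
    print.data.frame(x$hubs, row.names = FALSE)
  }
  invisible(x)
}
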