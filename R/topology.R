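#' Per-node topology metrics of a protein network
#'
#' Computes, on the undirected simple graph, each node's degree,
#' betweenness centrality (unnormalized shortest-path counting with even
#' split across equal-length paths, the standard convention), local
#' clustering coefficient (nodes of degree < 2 get 0) and eigenvector
#' centrality. Eigenvector centrality is computed per connected
#' component and scaled so the maximum is 1; isolated nodes get 0.
#'
#' @param network A `protein_network` or an undirected `igraph` graph.
#' @param normalized Normalize betweenness by the number of node pairs
#'   (default `FALSE`).
#' @param hub_rule,hub_param Rule used to set the `hub_flag` column; see
#'   [find_hubs()]. Defaults to the 0.9 degree quantile.
#' @return Data frame (class `topology_report`) with one row per node:
#'   `accession`, `degree`, `betweenness`, `clustering_coefficient`,
#'   `eigenvector_centrality`, `hub_flag`; sorted by accession.
#' @export
compute_topology <- function(network, normalized = FALSE,
                             hub_rule = "degree_quantile", hub_param = 0.9) {
  g <- if (inherits(network, "igraph")) network else as_igraph(network)
  if (igraph::vcount(g) == 0L) {
    stop("cannot compute topology of an empty network", call. = FALSE)
  }
  g <- igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = normalized)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  cc[deg < 2] <- 0
  names(cc) <- igraph::V(g)$name

  eig <- stats::setNames(numeric(igraph::vcount(g)), igraph::V(g)$name)
  comp <- igraph::components(g)
  for (k in seq_len(comp$no)) {
    members <- which(comp$membership == k)
    if (length(members) == 1L) next  # isolated node stays 0
    sub <- igraph::induced_subgraph(g, members)
    ev <- igraph::eigen_centrality(sub)$vector  # scaled to max 1 per component
    eig[igraph::V(sub)$name] <- ev
  }

  report <- data.frame(
    accession = igraph::V(g)$name,
    degree = as.integer(deg),
    betweenness = as.numeric(btw),
    clustering_coefficient = as.numeric(cc),
    eigenvector_centrality = as.numeric(eig),
    hub_flag = FALSE,
    stringsAsFactors = FALSE
  )
  report <- report[order(report$accession), , drop = FALSE]
  rownames(report) <- NULL
  hubs <- find_hubs(report, rule = hub_rule, param = hub_param)
  report$hub_flag <- report$accession %in% hubs
  class(report) <- c("topology_report", "data.frame")
  report
}

#' Select hub nodes from a topology report
#'
#' Nodes are ranked by degree (descending, ties broken by accession
#' ascending, so the selection is deterministic).
#'
#' @param report A [compute_topology()] result.
#' @param rule `"degree_top_k"` (take the `param` highest-degree nodes,
#'   clamped to the node count) or `"degree_quantile"` (take nodes whose
#'   degree is at or above the `param` quantile of the degree
#'   distribution).
#' @param param `k >= 1` for `degree_top_k`; a probability in \[0, 1\]
#'   for `degree_quantile`.
#' @return Character vector of hub accessions, in rank order.
#' @export
find_hubs <- function(report, rule = c("degree_top_k", "degree_quantile"),
                      param) {
  rule <- match.arg(rule)
  stopifnot(is.data.frame(report), "degree" %in% names(report))
  ord <- order(-report$degree, report$accession)
  ranked <- report[ord, , drop = FALSE]
  if (rule == "degree_top_k") {
    if (!is.numeric(param) || length(param) != 1L || param < 1) {
      stop("degree_top_k needs k >= 1", call. = FALSE)
    }
    k <- min(as.integer(param), nrow(ranked))
    return(ranked$accession[seq_len(k)])
  }
  if (!is.numeric(param) || length(param) != 1L || param < 0 || param > 1) {
    stop("degree_quantile needs a probability in [0, 1]", call. = FALSE)
  }
  q <- stats::quantile(report$degree, probs = param, names = FALSE)
  ranked$accession[ranked$degree >= q]
}

#' Write a topology report as TSV
#' @param report A [compute_topology()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
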