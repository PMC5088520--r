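# protein_network: nodes/edges data frames plus scope and seed pathway.
# Edges are unordered canonical accession pairs; parallel relations of
# different categories are merged into one edge carrying a category set.

new_protein_network <- function(nodes, edges, scope, seed_pathway) {
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, scope = scope,
                 seed_pathway = seed_pathway),
            class = "protein_network")
}

empty_nodes <- function() {
  data.frame(accession = character(0), gene_symbol = character(0),
             origin = character(0), state = character(0),
             score = numeric(0), stringsAsFactors = FALSE)
}

empty_edges <- function() {
  data.frame(protein_a = character(0), protein_b = character(0),
             categories = I(list()), display_category = character(0),
             pathway_ids = I(list()), ppi_supported = logical(0),
             stringsAsFactors = FALSE)
}

nodes_from_proteins <- function(proteins, origin) {
  if (nrow(proteins) == 0L) return(empty_nodes())
  data.frame(accession = proteins$accession,
             gene_symbol = proteins$gene_symbol,
             origin = origin, state = NA_character_, score = NA_real_,
             stringsAsFactors = FALSE)
}

# merge relation rows (one per pair+category) into one edge per pair
edges_from_relations <- function(relations) {
  if (nrow(relations) == 0L) return(empty_edges())
  key <- paste(relations$protein_a, relations$protein_b, sep = "\r")
  keys <- sort(unique(key))
  idx <- split(seq_len(nrow(relations)), key)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  cats <- lapply(keys, function(k) set_sort(relations$category[idx[[k]]]))
  data.frame(
    protein_a = vapply(parts, `[`, "", 1),
    protein_b = vapply(parts, `[`, "", 2),
    categories = I(cats),
    display_category = vapply(cats, display_category, ""),
    pathway_ids = I(lapply(keys, function(k)
      set_sort(unlist(relations$pathway_ids[idx[[k]]])))),
    ppi_supported = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Build the local network of one pathway
#'
#' The local network strictly contains the proteins of the canonical
#' pathway and the undirected edges derived from its own relations.
#' Proteins without any relation are kept as isolated nodes.
#'
#' @param store A [build_store()] result.
#' @param pathway_id Pathway id present in the store.
#' @return A `protein_network` with `scope = "local"`.
#' @export
build_local <- function(store, pathway_id) {
  stopifnot(inherits(store, "pathway_store"))
  known <- store_pathways(store)
  if (!pathway_id %in% known) {
    stop("pathway '", pathway_id, "' not in store; known pathways: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  q <- suppressWarnings(query_pathway(store, pathway_id))
  new_protein_network(nodes_from_proteins(q$proteins, "local"),
                      edges_from_relations(q$relations),
                      "local", pathway_id)
}

#' Build the global (one-hop expanded) network of a pathway
#'
#' Starts from the local network and adds every store relation, from any
#' pathway of the corpus, that touches a local protein, together with the
#' external endpoint proteins of those relations (flagged
#' `origin = "external"`). Expansion is one hop: neighbours of external
#' nodes are not pulled in.
#'
#' @inheritParams build_local
#' @return A `protein_network` with `scope = "global"`.
#' @export
build_global <- function(store, pathway_id) {
  local <- build_local(store, pathway_id)
  local_acc <- local$nodes$accession
  touch <- store$relations$protein_a %in% local_acc |
           store$relations$protein_b %in% local_acc
  rel <- store$relations[touch, , drop = FALSE]
  edges <- edges_from_relations(rel)
  ext_acc <- setdiff(unique(c(rel$protein_a, rel$protein_b)), local_acc)
  ext <- store$proteins[store$proteins$accession %in% ext_acc, , drop = FALSE]
  nodes <- rbind(local$nodes, nodes_from_proteins(ext, "external"))
  nodes <- nodes[order(nodes$accession), , drop = FALSE]
  new_protein_network(nodes, edges, "global", pathway_id)
}

#' Load a physical-interaction pair list
#'
#' Reads a two-column TSV of protein accession pairs (APID-style). Pairs
#' are canonicalized (unordered) and deduplicated; self-pairs are
#' dropped. A header row is auto-detected on the accession pattern.
#'
#' @param path TSV file, two accessions per line.
#' @return Data frame with columns `protein_a`, `protein_b`.
#' @export
load_ppi <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(protein_a = character(0), protein_b = character(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad)) {
    stop("PPI file ", path, ": expected 2 tab-separated columns at line ",
         bad[1], call. = FALSE)
  }
  if (!grepl(.ACCESSION_RE, fields[[1]][1])) fields <- fields[-1]
  a <- vapply(fields, `[`, "", 1)
  b <- vapply(fields, `[`, "", 2)
  keep <- a != b
  cp <- canonical_pair(a[keep], b[keep])
  out <- unique(data.frame(protein_a = cp$a, protein_b = cp$b,
                           stringsAsFactors = FALSE))
  out[order(out$protein_a, out$protein_b), , drop = FALSE]
}

#' Overlay physical-interaction evidence on a network
#'
#' Flags every network edge whose unordered accession pair also occurs
#' in an external protein-protein interaction list
#' (`ppi_supported = TRUE`). By default PPI pairs absent from the
#' network are ignored — the evidence decorates pathway edges rather
#' than extending the network; with `add_edges = TRUE` pairs between two
#' existing nodes are added as new edges of category `"other"` with no
#' pathway provenance. The node set is never changed.
#'
#' @param network A `protein_network`.
#' @param ppi_pairs Data frame of accession pairs (see [load_ppi()]) or a
#'   path to a pair-list TSV.
#' @param add_edges Add PPI-only edges between existing nodes
#'   (default `FALSE`).
#' @return The network with updated flags; the number of matched edges is
#'   available as `attr(result, "ppi_matched")`.
#' @export
merge_ppi <- function(network, ppi_pairs, add_edges = FALSE) {
  stopifnot(inherits(network, "protein_network"))
  if (is.character(ppi_pairs) && length(ppi_pairs) == 1L) {
    ppi_pairs <- load_ppi(ppi_pairs)
  }
  cp <- canonical_pair(as.character(ppi_pairs[[1]]), as.character(ppi_pairs[[2]]))
  ppi_key <- unique(paste(cp$a, cp$b, sep = "\r"))
  edge_key <- paste(network$edges$protein_a, network$edges$protein_b, sep = "\r")
  hit <- edge_key %in% ppi_key
  network$edges$ppi_supported <- network$edges$ppi_supported | hit
  if (isTRUE(add_edges)) {
    nodes <- network$nodes$accession
    new_key <- setdiff(ppi_key, edge_key)
    parts <- strsplit(new_key, "\r", fixed = TRUE)
    a <- vapply(parts, `[`, "", 1)
    b <- vapply(parts, `[`, "", 2)
    keep <- a %in% nodes & b %in% nodes
    if (any(keep)) {
      extra <- data.frame(
        protein_a = a[keep], protein_b = b[keep],
        categories = I(replicate(sum(keep), "other", simplify = FALSE)),
        display_category = "other",
        pathway_ids = I(replicate(sum(keep), character(0), simplify = FALSE)),
        ppi_supported = TRUE, stringsAsFactors = FALSE
      )
      network$edges <- rbind(network$edges, extra)
      o <- order(network$edges$protein_a, network$edges$protein_b)
      network$edges <- network$edges[o, , drop = FALSE]
      rownames(network$edges) <- NULL
    }
  }
  attr(network, "ppi_matched") <- sum(hit)
  network
}

#' Convert a protein network to an igraph object
#'
#' Vertex attributes: `gene_symbol`, `origin`, `state`, `score`; edge
#' attributes: `display_category`, `categories` and `pathway_ids`
#' (semicolon-joined), `ppi_supported`.
#'
#' @param network A `protein_network`.
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "protein_network"))
  ed <- network$edges
  edf <- data.frame(
    from = ed$protein_a, to = ed$protein_b,
    display_category = ed$display_category,
    categories = vapply(ed$categories, join_set, ""),
    pathway_ids = vapply(ed$pathway_ids, join_set, ""),
    ppi_supported = ed$ppi_supported, stringsAsFactors = FALSE
  )
  vdf <- data.frame(
    name = network$nodes$accession,
    gene_symbol = network$nodes$gene_symbol,
    origin = network$nodes$origin,
    state = ifelse(is.na(network$nodes$state), "", network$nodes$state),
    score = ifelse(is.na(network$nodes$score), "", as.character(network$nodes$score)),
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
  g <- igraph::set_graph_attr(g, "scope", network$scope)
  igraph::set_graph_attr(g, "seed_pathway", network$seed_pathway)
}

igraph_to_network <- function(g) {
  vdf <- igraph::as_data_frame(g, what = "vertices")
  edf <- igraph::as_data_frame(g, what = "edges")
  nodes <- data.frame(
    accession = vdf$name, gene_symbol = vdf$gene_symbol,
    origin = vdf$origin,
    state = ifelse(nzchar(vdf$state), vdf$state, NA_character_),
    score = suppressWarnings(
      ifelse(nzchar(vdf$score), as.numeric(vdf$score), NA_real_)),
    stringsAsFactors = FALSE
  )
  nodes <- nodes[order(nodes$accession), , drop = FALSE]
  if (nrow(edf)) {
    cp <- canonical_pair(edf$from, edf$to)
    edges <- data.frame(
      protein_a = cp$a, protein_b = cp$b,
      categories = I(lapply(edf$categories, split_set)),
      display_category = edf$display_category,
      pathway_ids = I(lapply(edf$pathway_ids, split_set)),
      ppi_supported = as.logical(edf$ppi_supported),
      stringsAsFactors = FALSE
    )
    edges <- edges[order(edges$protein_a, edges$protein_b), , drop = FALSE]
  } else {
    edges <- empty_edges()
  }
  new_protein_network(nodes, edges,
                      igraph::graph_attr(g, "scope"),
                      igraph::graph_attr(g, "seed_pathway"))
}

#' Export a network to GraphML, SIF or TSV
#'
#' GraphML carries all node attributes (state, score, origin) and edge
#' attributes (display category, category set, pathway ids, PPI support)
#' and round-trips losslessly through [import_network()]; both GraphML
#' and SIF load directly into Cytoscape. SIF writes one
#' `A <TAB> display_category <TAB> B` line per edge (isolated nodes as
#' bare single-field lines). TSV writes two sorted tables,
#' `<path>_nodes.tsv` and `<path>_edges.tsv`.
#'
#' @param network A `protein_network`.
#' @param path Output file path (for `"tsv"`, a path prefix).
#' @param format `"graphml"`, `"sif"` or `"tsv"`.
#' @return Invisibly, the path(s) written.
#' @export
export_network <- function(network, path, format = c("graphml", "sif", "tsv")) {
  stopifnot(inherits(network, "protein_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
    return(invisible(path))
  }
  if (format == "sif") {
    ed <- network$edges
    lines <- sprintf("%s\t%s\t%s", ed$protein_a, ed$display_category, ed$protein_b)
    isolated <- setdiff(network$nodes$accession,
                        c(ed$protein_a, ed$protein_b))
    writeLines(c(lines, isolated), path)
    return(invisible(path))
  }
  # tsv
  prefix <- sub("\\.tsv$", "", path)
  npath <- paste0(prefix, "_nodes.tsv")
  epath <- paste0(prefix, "_edges.tsv")
  nd <- network$nodes[order(network$nodes$accession), , drop = FALSE]
  utils::write.table(nd, npath, sep = "\t", quote = FALSE, row.names = FALSE)
  ed <- network$edges
  ed_flat <- data.frame(
    protein_a = ed$protein_a, protein_b = ed$protein_b,
    display_category = ed$display_category,
    categories = vapply(ed$categories, join_set, ""),
    pathway_ids = vapply(ed$pathway_ids, join_set, ""),
    ppi_supported = ed$ppi_supported, stringsAsFactors = FALSE
  )
  ed_flat <- ed_flat[order(ed_flat$protein_a, ed_flat$protein_b), , drop = FALSE]
  utils::write.table(ed_flat, epath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(npath, epath))
}

#' Import a network from a GraphML file written by [export_network()]
#' @param path GraphML file path.
#' @return A `protein_network`.
#' @export
import_network <- function(path) {
  igraph_to_network(igraph::read_graph(path, format = "graphml"))
}

#' @export
print.protein_network <- function(x, ...) {
  cat("<protein_network> scope=", x$scope, " seed=", x$seed_pathway, "\n", sep = "")
  n_ext <- sum(x$nodes$origin == "external")
  cat("  nodes: ", nrow(x$nodes),
      if (n_ext) paste0(" (", n_ext, " external)"), "\n", sep = "")
  cat("  edges: ", nrow(x$edges),
      if (any(x$edges$ppi_supported))
        paste0(" (", sum(x$edges$ppi_supported), " PPI-supported)"),
      "\n", sep = "")
  st <- x$nodes$state
  if (any(!is.na(st))) {
    cat("  states: ON=", sum(st == "ON", na.rm = TRUE),
        " OFF=", sum(st == "OFF", na.rm = TRUE),
        " NA=", sum(st == "NA", na.rm = TRUE), "\n", sep = "")
  }
  invisible(x)
}
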