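# Independent brute-force oracles for topology metrics, deliberately
# naive: explicit simple-path enumeration and direct triangle counting.
# Only usable on tiny graphs (n <= 10 or so).

# adjacency list from an edge matrix (2 columns of vertex indices)
adj_from_edges <- function(n, edges) {
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  adj
}

# all simple paths from s to t, as a list of vertex sequences
all_simple_paths_brute <- function(adj, s, t) {
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) { out[[length(out) + 1L]] <<- path; return(invisible()) }
    for (w in adj[[v]]) if (!w %in% path) walk(c(path, w))
  }
  walk(s)
  out
}

# unnormalized betweenness by shortest-path enumeration with even split
betweenness_brute <- function(n, edges) {
  adj <- adj_from_edges(n, edges)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in seq((s + 1), n)) {
    paths <- all_simple_paths_brute(adj, s, t)
    if (length(paths) == 0) next
    lens <- lengths(paths)
    shortest <- paths[lens == min(lens)]
    sigma <- length(shortest)
    interior <- unlist(lapply(shortest, function(p) p[-c(1, length(p))]))
    if (length(interior)) {
      counts <- table(interior)
      idx <- as.integer(names(counts))
      btw[idx] <- btw[idx] + as.numeric(counts) / sigma
    }
  }
  btw
}

# local clustering coefficient by direct neighbour-pair counting
clustering_brute <- function(n, edges) {
  adj <- adj_from_edges(n, edges)
  vapply(seq_len(n), function(v) {
    nb <- adj[[v]]
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
      if (nb[j] %in% adj[[nb[i]]]) links <- links + 1
    }
    2 * links / (k * (k - 1))
  }, numeric(1))
}

# random connected-ish simple graph on n nodes as an edge matrix
random_graph_edges <- function(n, p = 0.4) {
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p
  # always include a spanning path so most instances are connected
  spine <- cbind(seq_len(n - 1), seq(2, n))
  unique(rbind(pairs[keep, , drop = FALSE], spine))
}

# protein_network with given vertex names and index edge matrix
network_from_edges <- function(names_, edges) {
  k <- length(names_)
  nodes <- data.frame(accession = names_, gene_symbol = names_,
                      origin = rep("local", k),
                      state = rep(NA_character_, k),
                      score = rep(NA_real_, k), stringsAsFactors = FALSE)
  if (nrow(edges)) {
    a <- names_[edges[, 1]]; b <- names_[edges[, 2]]
    swap <- a > b
    pa <- ifelse(swap, b, a); pb <- ifelse(swap, a, b)
    edf <- data.frame(protein_a = pa, protein_b = pb,
                      categories = I(replicate(length(pa), "other",
                                               simplify = FALSE)),
                      display_category = "other",
                      pathway_ids = I(replicate(length(pa), "hsa90001",
                                                simplify = FALSE)),
                      ppi_supported = FALSE, stringsAsFactors = FALSE)
  } else {
    edf <- data.frame(protein_a = character(0), protein_b = character(0),
                      categories = I(list()),
                      display_category = character(0),
                      pathway_ids = I(list()), ppi_supported = logical(0),
                      stringsAsFactors = FALSE)
  }
  pathexnet:::new_protein_network(nodes, edf, "local", "hsa90001")
}

# barcode-fraction resource from a named score list per context
resource_from_scores <- function(...) {
  cols <- list(...)
  genes <- sort(unique(unlist(lapply(cols, names))))
  m <- matrix(NA_real_, length(genes), length(cols),
              dimnames = list(genes, names(cols)))
  for (ctx in names(cols)) m[names(cols[[ctx]]), ctx] <- cols[[ctx]]
  expression_resource(m, "barcode_fraction")
}
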