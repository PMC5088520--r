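#' Construct an expression resource
#'
#' An expression resource is a gene-or-accession x context score table
#' plus the threshold rule of its kind. Barcode-style resources hold the
#' fraction of samples in which each gene was called expressed (values
#' in \[0, 1\]; default ON threshold 0.4); FPKM and EST resources hold
#' non-negative abundances and require a user-supplied absolute
#' threshold — no default is claimed for those.
#'
#' @param values Numeric matrix or data frame, genes in rows (rownames =
#'   ids), contexts in columns.
#' @param kind One of `"barcode_fraction"`, `"fpkm"`, `"est_count"`,
#'   `"custom"`.
#' @param threshold ON/OFF threshold. Defaults to 0.4 for
#'   `barcode_fraction`; mandatory for the other kinds.
#' @return An object of class `expression_resource`.
#' @export
expression_resource <- function(values,
                                kind = c("barcode_fraction", "fpkm",
                                         "est_count", "custom"),
                                threshold = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression values need rownames (gene/accession ids) and colnames (contexts)",
         call. = FALSE)
  }
  v <- values[!is.na(values)]
  if (kind == "barcode_fraction") {
    if (any(v < 0 | v > 1)) {
      stop("barcode_fraction scores must lie in [0, 1]", call. = FALSE)
    }
    if (is.null(threshold)) threshold <- 0.4
    if (threshold < 0 || threshold > 1) {
      stop("threshold must lie in [0, 1] for barcode_fraction resources",
           call. = FALSE)
    }
  } else {
    if (any(v < 0)) stop(kind, " values must be non-negative", call. = FALSE)
    if (is.null(threshold)) {
      stop("an absolute ON/OFF threshold must be supplied for kind '",
           kind, "'", call. = FALSE)
    }
  }
  structure(list(kind = kind, values = values, threshold = threshold),
            class = "expression_resource")
}

#' Read an expression score table from TSV/CSV
#'
#' First column holds the gene or accession id; remaining columns are
#' contexts (cell types / tissues).
#'
#' @param path File path; comma- or tab-separated, inferred from the
#'   extension (`.csv` vs anything else).
#' @inheritParams expression_resource
#' @return An `expression_resource`.
#' @export
read_expression <- function(path, kind = "barcode_fraction", threshold = NULL) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  expression_resource(m, kind = kind, threshold = threshold)
}

#' Barcode-style fraction-of-samples-expressed scores
#'
#' Simplified barcode caller: a gene is called expressed in a sample when
#' its value exceeds the gene's unexpressed reference distribution by
#' more than `z_cutoff` standard deviations, i.e.
#' `(x - mu) / sigma > z_cutoff`; the score is the fraction of samples
#' (all from one context) in which the gene is called expressed. Full
#' microarray preprocessing (fRMA) is out of scope — this operates on an
#' already-normalized gene x sample matrix.
#'
#' @param expr_matrix Numeric matrix, genes in rows, samples in columns.
#' @param reference Data frame with columns `gene`, `mu`, `sigma` (the
#'   unexpressed null per gene), or a matrix with those columns and gene
#'   rownames.
#' @param z_cutoff Z-score above which a sample is called expressed
#'   (default 5).
#' @return List with `scores` (named vector of fractions in \[0, 1\] for
#'   genes present in the reference) and `missing` (genes absent from
#'   the reference, reported, not scored).
#' @export
barcode_scores <- function(expr_matrix, reference, z_cutoff = 5) {
  expr_matrix <- as.matrix(expr_matrix)
  if (is.matrix(reference)) {
    reference <- data.frame(gene = rownames(reference),
                            mu = reference[, "mu"], sigma = reference[, "sigma"],
                            stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene", "mu", "sigma") %in% names(reference)))
  if (any(reference$sigma <= 0)) {
    stop("reference sigma must be > 0 for all genes", call. = FALSE)
  }
  genes <- rownames(expr_matrix)
  hit <- genes %in% reference$gene
  missing <- genes[!hit]
  if (length(missing)) {
    warning(length(missing), " gene(s) absent from the reference: ",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ...", call. = FALSE)
  }
  idx <- match(genes[hit], reference$gene)
  z <- (expr_matrix[hit, , drop = FALSE] - reference$mu[idx]) / reference$sigma[idx]
  scores <- rowMeans(z > z_cutoff)
  names(scores) <- genes[hit]
  list(scores = scores, missing = missing)
}

#' Assign ON/OFF/NA states to the nodes of a network
#'
#' A node is ON when its score is strictly above the threshold, OFF when
#' the score is less than or equal to the threshold, and NA when the
#' protein (and all of its mapped gene ids) is absent from the resource
#' — the protein cannot be measured on the platform. When the resource
#' is keyed by gene ids rather than accessions, supply the mapping
#' table; an accession covered by several gene-level rows takes the
#' maximum score by default ("any evidence of expression"), or the mean
#' with `combine = "mean"`.
#'
#' @param network A `protein_network`.
#' @param resource An [expression_resource()].
#' @param context Column name of the resource (cell type / tissue).
#' @param threshold Override of the resource threshold (default
#'   `NULL`, use the resource's own; 0.4 for barcode fractions).
#' @param mapping Optional [mapping_table()] from the resource's gene id
#'   namespace to accessions.
#' @param combine `"max"` (default) or `"mean"` across multiple
#'   gene-level rows per accession.
#' @return An object of class `state_assignment`: list with `context`,
#'   `threshold`, `states` (named character, values ON/OFF/NA) and
#'   `scores` (named numeric, `NA` where unmeasured).
#' @export
assign_states <- function(network, resource, context, threshold = NULL,
                          mapping = NULL, combine = c("max", "mean")) {
  stopifnot(inherits(network, "protein_network"),
            inherits(resource, "expression_resource"))
  combine <- match.arg(combine)
  if (!context %in% colnames(resource$values)) {
    stop("context '", context, "' not in resource; available contexts: ",
         paste(colnames(resource$values), collapse = ", "), call. = FALSE)
  }
  if (is.null(threshold)) threshold <- resource$threshold
  if (resource$kind == "barcode_fraction" && (threshold < 0 || threshold > 1)) {
    stop("threshold must lie in [0, 1] for barcode_fraction resources",
         call. = FALSE)
  }
  col <- resource$values[, context]
  acc2genes <- NULL
  if (!is.null(mapping)) {
    stopifnot(inherits(mapping, "mapping_table"))
    acc2genes <- split(mapping$pairs$source_id, mapping$pairs$accession)
  }
  accs <- network$nodes$accession
  scores <- vapply(accs, function(a) {
    ids <- a
    if (!is.null(acc2genes) && !is.null(acc2genes[[a]])) {
      ids <- unique(c(a, acc2genes[[a]]))
    }
    vals <- col[ids[ids %in% names(col)]]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) return(NA_real_)
    if (combine == "max") max(vals) else mean(vals)
  }, numeric(1))
  states <- ifelse(is.na(scores), "NA",
                   ifelse(scores > threshold, "ON", "OFF"))
  names(states) <- accs
  structure(list(context = context, threshold = threshold,
                 states = states, scores = scores),
            class = "state_assignment")
}

#' Write states and scores onto the network nodes
#' @param network A `protein_network`.
#' @param assignment A [assign_states()] result covering all nodes.
#' @return The network with node `state` and `score` columns filled.
#' @export
set_states <- function(network, assignment) {
  stopifnot(inherits(network, "protein_network"),
            inherits(assignment, "state_assignment"))
  miss <- setdiff(network$nodes$accession, names(assignment$states))
  if (length(miss)) {
    stop("no state assigned for node(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  network$nodes$state <- unname(assignment$states[network$nodes$accession])
  network$nodes$score <- unname(assignment$scores[network$nodes$accession])
  network
}

#' Filter a network to its expression-specific subnetwork
#'
#' Removes every OFF node and all its incident edges; ON nodes and NA
#' nodes (not measurable on the platform) are retained, as are edges
#' whose two endpoints survive. Attribute provenance is preserved and
#' the result carries the states and scores of the assignment.
#'
#' @param network A `protein_network`.
#' @param assignment A [assign_states()] result covering all nodes.
#' @return The filtered `protein_network`; the removal counts
#'   (`n_ON`, `n_NA`, `n_OFF_removed`, `edges_kept`, `edges_removed`)
#'   are available via [filter_report()].
#' @export
filter_network <- function(network, assignment) {
  network <- set_states(network, assignment)
  st <- network$nodes$state
  keep <- st %in% c("ON", "NA")
  kept_acc <- network$nodes$accession[keep]
  ed <- network$edges
  ekeep <- ed$protein_a %in% kept_acc & ed$protein_b %in% kept_acc
  report <- list(
    n_ON = sum(st == "ON"), n_NA = sum(st == "NA"),
    n_OFF_removed = sum(st == "OFF"),
    edges_kept = sum(ekeep), edges_removed = sum(!ekeep)
  )
  out <- new_protein_network(network$nodes[keep, , drop = FALSE],
                             ed[ekeep, , drop = FALSE],
                             network$scope, network$seed_pathway)
  attr(out, "filter_report") <- report
  out
}

#' Removal counts of a filtered network
#' @param network A [filter_network()] result.
#' @return List with `n_ON`, `n_NA`, `n_OFF_removed`, `edges_kept`,
#'   `edges_removed`.
#' @export
filter_report <- function(network) {
  rep <- attr(network, "filter_report")
  if (is.null(rep)) stop("network carries no filter report", call. = FALSE)
  rep
}

#' Compare node states across cellular contexts
#'
#' Builds the wide accession x context state table for two or more
#' assignments over the same network and lists the discordant genes —
#' those ON in at least one context and OFF in at least one other (NA
#' never contributes to discordance).
#'
#' @param network A `protein_network`.
#' @param assignments List of [assign_states()] results over the same
#'   node set.
#' @return List with `table` (data frame: `accession`, one state column
#'   per context) and `discordant` (character vector of accessions).
#' @export
compare_contexts <- function(network, assignments) {
  stopifnot(inherits(network, "protein_network"), length(assignments) >= 2L)
  accs <- sort(network$nodes$accession)
  for (a in assignments) {
    stopifnot(inherits(a, "state_assignment"))
    if (!setequal(names(a$states), network$nodes$accession)) {
      stop("assignment for context '", a$context,
           "' covers a different node set than the network", call. = FALSE)
    }
  }
  ctx <- vapply(assignments, `[[`, "", "context")
  if (anyDuplicated(ctx)) {
    ctx <- make.unique(ctx)
  }
  tab <- data.frame(accession = accs, stringsAsFactors = FALSE)
  for (i in seq_along(assignments)) {
    tab[[ctx[i]]] <- unname(assignments[[i]]$states[accs])
  }
  st <- as.matrix(tab[, -1, drop = FALSE])
  disc <- accs[apply(st, 1, function(r) any(r == "ON") && any(r == "OFF"))]
  list(table = tab, discordant = disc)
}

#' @export
print.state_assignment <- function(x, ...) {
  cat("<state_assignment> context=", x$context,
      " threshold=", x$threshold, "\n", sep = "")
  cat("  ON=", sum(x$states == "ON"), " OFF=", sum(x$states == "OFF"),
      " NA=", sum(x$states == "NA"), "\n", sep = "")
  invisible(x)
}
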