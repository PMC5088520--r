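#' Construct an identifier mapping table
#'
#' A mapping table unifies KEGG gene identifiers (or Ensembl gene
#' identifiers) to UniProt accessions, the key identifier space of the
#' protein store and networks. The mapping may be many-to-many in both
#' directions; dash-suffixed isoform accessions are collapsed to their
#' canonical stem.
#'
#' @param pairs Data frame with columns `source_id` and `accession`.
#' @param source_namespace One of `"kegg_gene"`, `"ensembl_gene"`.
#' @return An object of class `mapping_table`.
#' @export
mapping_table <- function(pairs, source_namespace = c("kegg_gene", "ensembl_gene")) {
  source_namespace <- match.arg(source_namespace)
  stopifnot(is.data.frame(pairs), all(c("source_id", "accession") %in% names(pairs)))
  acc <- sub("-.*$", "", as.character(pairs$accession))
  bad <- acc[!grepl(.ACCESSION_RE, acc)]
  if (length(bad)) {
    stop("invalid UniProt accession(s): ",
         paste(sort(unique(bad)), collapse = ", "), call. = FALSE)
  }
  df <- unique(data.frame(source_id = as.character(pairs$source_id),
                          accession = acc, stringsAsFactors = FALSE))
  df <- df[order(df$source_id, df$accession), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(source_namespace = source_namespace, pairs = df),
            class = "mapping_table")
}

#' Load an identifier mapping table from a two-column TSV file
#'
#' The file holds one `source_id <TAB> uniprot_accession` pair per line.
#' A header line is auto-detected: if the first field of the first row
#' does not look like an identifier of `namespace`, the row is skipped.
#' Duplicate rows are collapsed; gzip-compressed files (`.gz`) are read
#' transparently.
#'
#' @param path TSV (or TSV.gz) file path.
#' @param namespace `"kegg_gene"` (ids like `hsa:4851`) or
#'   `"ensembl_gene"` (ids like `ENSG00000148400`).
#' @return A [mapping_table()].
#' @export
load_mapping <- function(path, namespace = c("kegg_gene", "ensembl_gene")) {
  namespace <- match.arg(namespace)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty mapping file: ", path, call. = FALSE)
    return(mapping_table(data.frame(source_id = character(0),
                                    accession = character(0)), namespace))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad)) {
    stop("mapping file ", path, ": expected 2 tab-separated columns at line ",
         bad[1], call. = FALSE)
  }
  id_re <- switch(namespace,
                  kegg_gene = "^[a-z]{2,4}:", ensembl_gene = "^ENS")
  if (!grepl(id_re, fields[[1]][1])) fields <- fields[-1]  # header row
  df <- data.frame(source_id = vapply(fields, `[`, "", 1),
                   accession = vapply(fields, `[`, "", 2),
                   stringsAsFactors = FALSE)
  mapping_table(df, namespace)
}

#' Map source identifiers to UniProt accessions
#'
#' Every input id appears as a key of the result; ids absent from the
#' table map to an empty accession set and are additionally returned as
#' the unmapped report. One id mapping to several accessions yields all
#' of them (full many-to-many expansion).
#'
#' @param ids Character vector of source identifiers.
#' @param table A [mapping_table()].
#' @return A list with `mapping` (named list, id -> character vector of
#'   accessions) and `unmapped` (character vector of ids with no match).
#' @export
map_ids <- function(ids, table) {
  stopifnot(inherits(table, "mapping_table"))
  ids <- unique(as.character(ids))
  by_id <- split(table$pairs$accession, table$pairs$source_id)
  mapping <- lapply(ids, function(id) set_sort(by_id[[id]]))
  names(mapping) <- ids
  list(mapping = mapping, unmapped = ids[lengths(mapping) == 0L])
}

#' @export
print.mapping_table <- function(x, ...) {
  cat("<mapping_table> ", x$source_namespace, " -> uniprot: ",
      nrow(x$pairs), " pairs (", length(unique(x$pairs$source_id)),
      " source ids, ", length(unique(x$pairs$accession)),
      " accessions)\n", sep = "")
  invisible(x)
}
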