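#' Build the two-table relational pathway store from a KGML corpus
#'
#' Parses every KGML file in a directory, expands group entries, maps
#' KEGG gene ids to UniProt accessions, and unifies all pathway
#' relations into two indexed tables: a protein table (one row per
#' accession) and a relation table (one row per unique unordered
#' accession pair and category). A relation between entries carrying m
#' and n mapped accessions expands to m x n candidate pairs; self-pairs
#' are dropped; pairs are stored in canonical (lexicographic) order and
#' deduplicated on (pair, category), unioning the contributing pathway
#' ids and raw KGML subtype names. Relation subtypes collapse to four
#' categories: activation; inhibition (incl. repression); expression;
#' everything else (or no subtype) is "other". Relations through
#' compounds (`PCrel`) and `maplink` relations contribute no protein
#' pairs, and only `gene`-type entries become proteins.
#'
#' @param kgml_dir Directory containing `.xml` KGML files (or a character
#'   vector of file paths).
#' @param mapping A [mapping_table()] from KEGG gene ids to accessions.
#' @return An object of class `pathway_store`: list with `proteins`
#'   (columns `accession`, `gene_symbol`, `kegg_gene_ids` (list),
#'   `pathway_ids` (list)), `relations` (columns `protein_a`,
#'   `protein_b`, `category`, `raw_subtypes` (list), `pathway_ids`
#'   (list)), `organism`, `unmapped` (entries that contributed no
#'   protein) and `skipped_files`.
#' @details Files that fail to parse are skipped with a warning and the
#'   build continues; an input set yielding no parseable file is an
#'   error. The build is deterministic: tables are sorted canonically.
#' @export
build_store <- function(kgml_dir, mapping) {
  stopifnot(inherits(mapping, "mapping_table"))
  files <- if (length(kgml_dir) == 1L && dir.exists(kgml_dir)) {
    list.files(kgml_dir, pattern = "\\.xml$", full.names = TRUE)
  } else {
    as.character(kgml_dir)
  }
  files <- sort(files)
  if (length(files) == 0L) {
    stop("no KGML (.xml) files found in ", kgml_dir, call. = FALSE)
  }

  by_id <- split(mapping$pairs$accession, mapping$pairs$source_id)
  skipped <- character(0)
  unmapped <- list()
  prot_rows <- list()
  rel_rows <- list()
  organism <- NA_character_

  for (f in files) {
    pw <- tryCatch(parse_kgml(f), error = function(e) {
      warning("skipping ", basename(f), ": ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(pw)) { skipped <- c(skipped, f); next }
    pw <- expand_groups(pw)
    if (is.na(organism)) organism <- pw$organism

    en <- pw$entries
    is_gene <- en$entry_type == "gene"
    # accessions per entry id (sorted unique over all its KEGG gene ids)
    acc_of <- lapply(seq_len(nrow(en)), function(i) {
      if (!is_gene[i]) return(character(0))
      set_sort(unlist(by_id[en$kegg_names[[i]]], use.names = FALSE))
    })
    names(acc_of) <- en$entry_id

    no_map <- which(is_gene & lengths(acc_of) == 0L)
    if (length(no_map)) {
      unmapped[[length(unmapped) + 1L]] <- data.frame(
        pathway_id = pw$pathway_id, entry_id = en$entry_id[no_map],
        kegg_names = vapply(en$kegg_names[no_map], join_set, ""),
        stringsAsFactors = FALSE
      )
    }

    for (i in which(is_gene & lengths(acc_of) > 0L)) {
      for (acc in acc_of[[i]]) {
        prot_rows[[length(prot_rows) + 1L]] <- list(
          accession = acc, gene_symbol = en$graphics_name[i],
          kegg_gene_ids = en$kegg_names[[i]], pathway_id = pw$pathway_id
        )
      }
    }

    rel <- pw$relations
    keep <- rel$relation_type %in% c("PPrel", "GErel", "ECrel")
    for (i in which(keep)) {
      a1 <- acc_of[[rel$entry1[i]]]
      a2 <- acc_of[[rel$entry2[i]]]
      if (length(a1) == 0L || length(a2) == 0L) next
      grid <- expand.grid(a = a1, b = a2, KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
      grid <- grid[grid$a != grid$b, , drop = FALSE]
      if (nrow(grid) == 0L) next
      cp <- canonical_pair(grid$a, grid$b)
      cat_i <- collapse_category(rel$subtypes[[i]])
      for (j in seq_len(nrow(grid))) {
        rel_rows[[length(rel_rows) + 1L]] <- list(
          protein_a = cp$a[j], protein_b = cp$b[j], category = cat_i,
          raw_subtypes = rel$subtypes[[i]], pathway_id = pw$pathway_id
        )
      }
    }
  }

  if (length(skipped) == length(files)) {
    stop("no parseable KGML files among ", length(files), " input file(s)",
         call. = FALSE)
  }

  proteins <- aggregate_proteins(prot_rows)
  relations <- aggregate_relations(rel_rows)
  unmapped <- if (length(unmapped)) do.call(rbind, unmapped) else
    data.frame(pathway_id = character(0), entry_id = character(0),
               kegg_names = character(0), stringsAsFactors = FALSE)

  structure(
    list(proteins = proteins, relations = relations, organism = organism,
         unmapped = unmapped, skipped_files = skipped),
    class = "pathway_store"
  )
}

aggregate_proteins <- function(rows) {
  if (length(rows) == 0L) {
    return(data.frame(accession = character(0), gene_symbol = character(0),
                      kegg_gene_ids = I(list()), pathway_ids = I(list()),
                      stringsAsFactors = FALSE))
  }
  acc <- vapply(rows, `[[`, "", "accession")
  keys <- sort(unique(acc))
  idx <- split(seq_along(rows), acc)
  out <- data.frame(
    accession = keys,
    gene_symbol = vapply(keys, function(k) {
      syms <- vapply(rows[idx[[k]]], `[[`, "", "gene_symbol")
      syms <- set_sort(syms[nzchar(syms)])
      if (length(syms)) syms[1] else ""
    }, ""),
    kegg_gene_ids = I(lapply(keys, function(k)
      set_sort(unlist(lapply(rows[idx[[k]]], `[[`, "kegg_gene_ids"))))),
    pathway_ids = I(lapply(keys, function(k)
      set_sort(vapply(rows[idx[[k]]], `[[`, "", "pathway_id")))),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

aggregate_relations <- function(rows) {
  if (length(rows) == 0L) {
    return(data.frame(protein_a = character(0), protein_b = character(0),
                      category = character(0), raw_subtypes = I(list()),
                      pathway_ids = I(list()), stringsAsFactors = FALSE))
  }
  key <- vapply(rows, function(r)
    paste(r$protein_a, r$protein_b, r$category, sep = "\r"), "")
  keys <- sort(unique(key))
  idx <- split(seq_along(rows), key)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    protein_a = vapply(parts, `[`, "", 1),
    protein_b = vapply(parts, `[`, "", 2),
    category = vapply(parts, `[`, "", 3),
    raw_subtypes = I(lapply(keys, function(k)
      set_sort(unlist(lapply(rows[idx[[k]]], `[[`, "raw_subtypes"))))),
    pathway_ids = I(lapply(keys, function(k)
      set_sort(vapply(rows[idx[[k]]], `[[`, "", "pathway_id")))),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' List the pathway ids present in a store
#' @param store A `pathway_store`.
#' @return Sorted character vector of pathway ids.
#' @export
store_pathways <- function(store) {
  stopifnot(inherits(store, "pathway_store"))
  set_sort(unlist(c(store$proteins$pathway_ids, store$relations$pathway_ids)))
}

#' Query the store for one pathway
#'
#' Returns exactly the protein and relation rows tagged with the given
#' pathway id. An unknown id yields empty tables with a warning, not an
#' error.
#'
#' @param store A `pathway_store`.
#' @param pathway_id Pathway id string, e.g. `"hsa04330"`.
#' @return List with `proteins` and `relations` data frames.
#' @export
query_pathway <- function(store, pathway_id) {
  stopifnot(inherits(store, "pathway_store"))
  if (!pathway_id %in% store_pathways(store)) {
    warning("pathway '", pathway_id, "' not present in store", call. = FALSE)
  }
  pk <- vapply(store$proteins$pathway_ids, function(p) pathway_id %in% p, TRUE)
  rk <- vapply(store$relations$pathway_ids, function(p) pathway_id %in% p, TRUE)
  list(proteins = store$proteins[pk, , drop = FALSE],
       relations = store$relations[rk, , drop = FALSE])
}

sql_quote <- function(x) paste0("'", gsub("'", "''", x, fixed = TRUE), "'")
sql_unquote <- function(x) gsub("''", "'", sub("^'", "", sub("'$", "", x)), fixed = TRUE)

#' Write the store as a portable SQL dump
#'
#' Emits `CREATE TABLE` plus one `INSERT` per row for the two tables
#' (`proteins`, `relations`); set-valued fields are serialized as
#' semicolon-joined sorted strings. [read_sql_dump()] reconstructs the
#' store exactly, and the dump is valid input for any SQL engine.
#'
#' @param store A `pathway_store`.
#' @param path Output `.sql` file path.
#' @return `path`, invisibly.
#' @export
dump_sql <- function(store, path) {
  stopifnot(inherits(store, "pathway_store"))
  lines <- c(
    paste0("-- pathway store SQL dump; organism: ", store$organism),
    "CREATE TABLE proteins (",
    "  uniprot_accession TEXT PRIMARY KEY,",
    "  gene_symbol TEXT,",
    "  kegg_gene_ids TEXT,",
    "  pathway_ids TEXT",
    ");",
    "CREATE TABLE relations (",
    "  protein_a TEXT NOT NULL,",
    "  protein_b TEXT NOT NULL,",
    "  category TEXT NOT NULL,",
    "  raw_subtypes TEXT,",
    "  pathway_ids TEXT,",
    "  PRIMARY KEY (protein_a, protein_b, category)",
    ");"
  )
  p <- store$proteins
  if (nrow(p)) {
    lines <- c(lines, sprintf(
      "INSERT INTO proteins VALUES (%s, %s, %s, %s);",
      sql_quote(p$accession), sql_quote(p$gene_symbol),
      sql_quote(vapply(p$kegg_gene_ids, join_set, "")),
      sql_quote(vapply(p$pathway_ids, join_set, ""))
    ))
  }
  r <- store$relations
  if (nrow(r)) {
    lines <- c(lines, sprintf(
      "INSERT INTO relations VALUES (%s, %s, %s, %s, %s);",
      sql_quote(r$protein_a), sql_quote(r$protein_b), sql_quote(r$category),
      sql_quote(vapply(r$raw_subtypes, join_set, "")),
      sql_quote(vapply(r$pathway_ids, join_set, ""))
    ))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Reload a store from its SQL dump
#' @param path A `.sql` file written by [dump_sql()].
#' @return A `pathway_store` equal to the dumped one.
#' @export
read_sql_dump <- function(path) {
  lines <- readLines(path)
  organism <- sub(".*organism: ", "", grep("^-- .*organism:", lines, value = TRUE)[1])
  parse_insert <- function(line, table) {
    body <- sub(paste0("^INSERT INTO ", table, " VALUES \\((.*)\\);$"), "\\1", line)
    # fields are 'quoted', comma-space separated; quotes inside doubled
    vals <- strsplit(body, "', '", fixed = TRUE)[[1]]
    sql_unquote(vals)
  }
  pl <- grep("^INSERT INTO proteins ", lines, value = TRUE)
  rl <- grep("^INSERT INTO relations ", lines, value = TRUE)
  proteins <- if (length(pl)) {
    m <- unname(t(vapply(pl, parse_insert, character(4), table = "proteins")))
    data.frame(accession = m[, 1], gene_symbol = m[, 2],
               kegg_gene_ids = I(lapply(m[, 3], split_set)),
               pathway_ids = I(lapply(m[, 4], split_set)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(accession = character(0), gene_symbol = character(0),
               kegg_gene_ids = I(list()), pathway_ids = I(list()),
               stringsAsFactors = FALSE)
  }
  relations <- if (length(rl)) {
    m <- unname(t(vapply(rl, parse_insert, character(5), table = "relations")))
    data.frame(protein_a = m[, 1], protein_b = m[, 2], category = m[, 3],
               raw_subtypes = I(lapply(m[, 4], split_set)),
               pathway_ids = I(lapply(m[, 5], split_set)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(protein_a = character(0), protein_b = character(0),
               category = character(0), raw_subtypes = I(list()),
               pathway_ids = I(list()), stringsAsFactors = FALSE)
  }
  rownames(proteins) <- NULL
  rownames(relations) <- NULL
  structure(
    list(proteins = proteins, relations = relations, organism = organism,
         unmapped = data.frame(pathway_id = character(0),
                               entry_id = character(0),
                               kegg_names = character(0),
                               stringsAsFactors = FALSE),
         skipped_files = character(0)),
    class = "pathway_store"
  )
}

#' Export the store tables as canonical sorted TSV files
#'
#' Writes both tables with set-valued fields joined by semicolons, rows
#' in canonical order, so two equal stores produce byte-identical files.
#'
#' @param store A `pathway_store`.
#' @param proteins_path,relations_path Output TSV paths.
#' @return Invisibly, the two paths.
#' @export
store_to_tsv <- function(store, proteins_path, relations_path) {
  stopifnot(inherits(store, "pathway_store"))
  p <- data.frame(
    accession = store$proteins$accession,
    gene_symbol = store$proteins$gene_symbol,
    kegg_gene_ids = vapply(store$proteins$kegg_gene_ids, join_set, ""),
    pathway_ids = vapply(store$proteins$pathway_ids, join_set, ""),
    stringsAsFactors = FALSE
  )
  r <- data.frame(
    protein_a = store$relations$protein_a,
    protein_b = store$relations$protein_b,
    category = store$relations$category,
    raw_subtypes = vapply(store$relations$raw_subtypes, join_set, ""),
    pathway_ids = vapply(store$relations$pathway_ids, join_set, ""),
    stringsAsFactors = FALSE
  )
  utils::write.table(p, proteins_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(r, relations_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(proteins_path, relations_path))
}

#' @export
print.pathway_store <- function(x, ...) {
  cat("<pathway_store> organism ", x$organism, "\n", sep = "")
  cat("  proteins:  ", nrow(x$proteins), "\n")
  cat("  relations: ", nrow(x$relations), "\n")
  cat("  pathways:  ", length(store_pathways(x)), "\n")
  if (nrow(x$unmapped)) cat("  unmapped entries:", nrow(x$unmapped), "\n")
  if (length(x$skipped_files)) cat("  skipped files:", length(x$skipped_files), "\n")
  invisible(x)
}
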