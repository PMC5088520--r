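#' Parse a KGML pathway file
#'
#' Reads a KEGG Markup Language (KGML) document into an in-memory pathway
#' model holding the pathway's entries (gene / ortholog / compound / map /
#' group boxes) and its typed relations. The KGML `name` attribute of an
#' entry is space-split into individual KEGG identifiers, so a single
#' multi-protein box yields several gene IDs; the literal name
#' `"undefined"` yields none. `reaction` elements and graphics coordinates
#' are ignored: downstream networks are built from relations only.
#'
#' @param source Path to a KGML XML file, a literal XML string, or an
#'   `xml2::xml_document`.
#' @return An object of class `kegg_pathway`: a list with elements
#'   `pathway_id`, `organism`, `title`, `entries` (data frame with columns
#'   `entry_id`, `entry_type`, `kegg_names` (list), `component_ids` (list),
#'   `graphics_name`) and `relations` (data frame with columns `entry1`,
#'   `entry2`, `relation_type`, `subtypes` (list)).
#' @details Relation endpoints are validated against the entry table; a
#'   relation referencing a missing entry id is an error listing every
#'   dangling reference. XML namespaces, if present, are stripped before
#'   element matching.
#' @seealso [expand_groups()], [write_kgml()], [build_store()]
#' @export
parse_kgml <- function(source) {
  doc <- if (inherits(source, "xml_document")) {
    source
  } else {
    xml2::read_xml(source, encoding = "UTF-8")
  }
  xml2::xml_ns_strip(doc)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "pathway") {
    stop("not a KGML document: root element is <", xml2::xml_name(root),
         ">, expected <pathway>", call. = FALSE)
  }

  raw_name <- xml2::xml_attr(root, "name")
  pathway_id <- sub("^path:", "", raw_name %||% "")
  organism <- xml2::xml_attr(root, "org")
  if (is.na(organism) || !nzchar(organism)) {
    organism <- sub("[0-9]+$", "", pathway_id)
  }
  title <- xml2::xml_attr(root, "title")
  if (is.na(title)) title <- ""

  entry_nodes <- xml2::xml_find_all(root, "./entry")
  entries <- if (length(entry_nodes) == 0L) empty_entries() else {
    data.frame(
      entry_id = xml2::xml_attr(entry_nodes, "id"),
      entry_type = xml2::xml_attr(entry_nodes, "type"),
      kegg_names = I(lapply(entry_nodes, function(n) {
        nm <- xml2::xml_attr(n, "name")
        if (is.na(nm) || !nzchar(nm) || identical(nm, "undefined")) character(0)
        else strsplit(nm, " ", fixed = TRUE)[[1]]
      })),
      component_ids = I(lapply(entry_nodes, function(n) {
        xml2::xml_attr(xml2::xml_find_all(n, "./component"), "id")
      })),
      graphics_name = vapply(entry_nodes, function(n) {
        g <- xml2::xml_find_first(n, "./graphics")
        nm <- if (inherits(g, "xml_missing")) NA_character_ else xml2::xml_attr(g, "name")
        if (is.na(nm)) "" else trimws(strsplit(nm, ",", fixed = TRUE)[[1]][1])
      }, character(1)),
      stringsAsFactors = FALSE
    )
  }

  rel_nodes <- xml2::xml_find_all(root, "./relation")
  relations <- if (length(rel_nodes) == 0L) empty_relations() else {
    data.frame(
      entry1 = xml2::xml_attr(rel_nodes, "entry1"),
      entry2 = xml2::xml_attr(rel_nodes, "entry2"),
      relation_type = xml2::xml_attr(rel_nodes, "type"),
      subtypes = I(lapply(rel_nodes, function(n) {
        xml2::xml_attr(xml2::xml_find_all(n, "./subtype"), "name")
      })),
      stringsAsFactors = FALSE
    )
  }

  pw <- structure(
    list(pathway_id = pathway_id, organism = organism, title = title,
         entries = entries, relations = relations),
    class = "kegg_pathway"
  )
  validate_pathway(pw)
  pw
}

`%||%` <- function(x, y) if (is.null(x) || (length(x) == 1L && is.na(x))) y else x

#' @keywords internal
validate_pathway <- function(pw) {
  if (!grepl(.PATHWAY_ID_RE, pw$pathway_id)) {
    stop("invalid pathway id: '", pw$pathway_id, "'", call. = FALSE)
  }
  ids <- pw$entries$entry_id
  if (anyDuplicated(ids)) {
    stop("duplicate entry ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  dangling <- setdiff(unique(c(pw$relations$entry1, pw$relations$entry2)), ids)
  if (length(dangling)) {
    stop("relation(s) reference missing entry id(s): ",
         paste(sort(dangling), collapse = ", "), call. = FALSE)
  }
  is_group <- pw$entries$entry_type == "group"
  comp <- unlist(pw$entries$component_ids[is_group], use.names = FALSE)
  if (any(is_group & lengths(pw$entries$component_ids) == 0L)) {
    stop("group entry with no components: ",
         paste(ids[is_group & lengths(pw$entries$component_ids) == 0L],
               collapse = ", "), call. = FALSE)
  }
  bad_comp <- setdiff(comp, ids)
  if (length(bad_comp)) {
    stop("group component(s) not resolvable: ",
         paste(sort(bad_comp), collapse = ", "), call. = FALSE)
  }
  is_gene <- pw$entries$entry_type == "gene"
  gene_names <- unlist(pw$entries$kegg_names[is_gene], use.names = FALSE)
  prefix <- paste0(pw$organism, ":")
  bad <- gene_names[!startsWith(gene_names, prefix)]
  if (length(bad)) {
    stop("gene entry KEGG id(s) without organism prefix '", prefix, "': ",
         paste(sort(unique(bad)), collapse = ", "), call. = FALSE)
  }
  invisible(pw)
}

#' Serialize a pathway model back to KGML
#'
#' Writes a `kegg_pathway` as a KGML XML document; re-parsing the file
#' with [parse_kgml()] recovers an equal model (entry and relation
#' multisets, ids, types and subtypes).
#'
#' @param pathway A `kegg_pathway`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kgml <- function(pathway, path) {
  stopifnot(inherits(pathway, "kegg_pathway"))
  doc <- xml2::xml_new_root(
    "pathway",
    name = paste0("path:", pathway$pathway_id),
    org = pathway$organism,
    number = sub("^[a-z]+", "", pathway$pathway_id),
    title = pathway$title
  )
  en <- pathway$entries
  for (i in seq_len(nrow(en))) {
    nm <- if (length(en$kegg_names[[i]]) == 0L) "undefined"
          else paste(en$kegg_names[[i]], collapse = " ")
    node <- xml2::xml_add_child(doc, "entry", id = en$entry_id[i],
                                name = nm, type = en$entry_type[i])
    if (nzchar(en$graphics_name[i])) {
      xml2::xml_add_child(node, "graphics", name = en$graphics_name[i],
                          type = "rectangle")
    }
    for (cid in en$component_ids[[i]]) {
      xml2::xml_add_child(node, "component", id = cid)
    }
  }
  rel <- pathway$relations
  for (i in seq_len(nrow(rel))) {
    node <- xml2::xml_add_child(doc, "relation", entry1 = rel$entry1[i],
                                entry2 = rel$entry2[i],
                                type = rel$relation_type[i])
    for (s in rel$subtypes[[i]]) {
      xml2::xml_add_child(node, "subtype", name = s, value = "--")
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Fan out group entries into their component relations
#'
#' KGML `group` entries bundle several entries into one complex box.
#' Every relation endpoint that is a group is replaced by one relation
#' per component (a relation between two groups of sizes m and n fans
#' out to m x n relations); group entries are then removed. The
#' operation is idempotent, and a pathway without groups is returned
#' unchanged.
#'
#' @param pathway A `kegg_pathway`.
#' @return A `kegg_pathway` with no group entries.
#' @export
expand_groups <- function(pathway) {
  stopifnot(inherits(pathway, "kegg_pathway"))
  validate_pathway(pathway)
  en <- pathway$entries
  is_group <- en$entry_type == "group"
  if (!any(is_group)) return(pathway)

  members <- en$component_ids[is_group]
  names(members) <- en$entry_id[is_group]
  fan <- function(id) if (id %in% names(members)) members[[id]] else id

  rel <- pathway$relations
  out <- vector("list", nrow(rel))
  for (i in seq_len(nrow(rel))) {
    e1 <- fan(rel$entry1[i])
    e2 <- fan(rel$entry2[i])
    grid <- expand.grid(entry1 = e1, entry2 = e2,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$relation_type <- rel$relation_type[i]
    grid$subtypes <- rep(rel$subtypes[i], nrow(grid))
    out[[i]] <- grid
  }
  new_rel <- if (length(out)) do.call(rbind, out) else empty_relations()
  if (nrow(new_rel)) {
    new_rel <- data.frame(
      entry1 = new_rel$entry1, entry2 = new_rel$entry2,
      relation_type = new_rel$relation_type, subtypes = I(new_rel$subtypes),
      stringsAsFactors = FALSE
    )
    rownames(new_rel) <- NULL
  } else {
    new_rel <- empty_relations()
  }

  pathway$entries <- en[!is_group, , drop = FALSE]
  rownames(pathway$entries) <- NULL
  pathway$relations <- new_rel
  validate_pathway(pathway)
  pathway
}

#' @export
print.kegg_pathway <- function(x, ...) {
  cat("<kegg_pathway> ", x$pathway_id,
      if (nzchar(x$title)) paste0(" (", x$title, ")") else "", "\n", sep = "")
  tab <- table(x$entries$entry_type)
  cat("  entries:  ", nrow(x$entries),
      if (length(tab)) paste0(" (", paste(names(tab), tab, sep = ":", collapse = ", "), ")"),
      "\n", sep = "")
  cat("  relations:", nrow(x$relations), "\n")
  invisible(x)
}
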