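# inline KGML builders for unit fixtures

kgml_doc <- function(pathway_id = "hsa04330", org = "hsa",
                     entries = "", relations = "", title = "Test pathway") {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<pathway name="path:', pathway_id, '" org="', org,
    '" number="', sub("^[a-z]+", "", pathway_id),
    '" title="', title, '">\n',
    entries, relations, "</pathway>\n"
  )
}

kgml_entry <- function(id, name, type = "gene", components = character(0)) {
  comp <- paste0('    <component id="', components, '"/>\n', collapse = "")
  if (length(components) == 0) comp <- ""
  paste0('  <entry id="', id, '" name="', name, '" type="', type, '">\n',
         comp, "  </entry>\n")
}

kgml_relation <- function(e1, e2, type = "PPrel", subtypes = "activation") {
  st <- paste0('    <subtype name="', subtypes, '" value="--"/>\n',
               collapse = "")
  if (length(subtypes) == 0) st <- ""
  paste0('  <relation entry1="', e1, '" entry2="', e2, '" type="', type,
         '">\n', st, "  </relation>\n")
}

write_kgml_text <- function(text, dir = tempfile("kgml_"),
                            file = "pathway.xml") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, file)
  writeLines(text, path)
  path
}

# corpus of one pathway: 2-gene entry -- 3-gene entry, one activation
two_by_three_corpus <- function(dir = tempfile("c23_")) {
  txt <- kgml_doc(
    "hsa90001",
    entries = paste0(
      kgml_entry("1", "hsa:101 hsa:102"),
      kgml_entry("2", "hsa:103 hsa:104 hsa:105")
    ),
    relations = kgml_relation("1", "2", subtypes = "activation")
  )
  write_kgml_text(txt, dir, "hsa90001.xml")
  dir
}

t23_mapping <- function() {
  make_mapping(sprintf("hsa:%d", 101:105), sprintf("P%05d", 101:105))
}

# mapping table built in code, 1:1 kegg id -> accession
make_mapping <- function(kegg_ids, accessions) {
  mapping_table(data.frame(source_id = kegg_ids, accession = accessions,
                           stringsAsFactors = FALSE), "kegg_gene")
}

# canonical comparable form of a pathway model (entry/relation multisets)
pathway_canon <- function(pw) {
  en <- pw$entries
  e <- sort(vapply(seq_len(nrow(en)), function(i) paste(
    en$entry_id[i], en$entry_type[i],
    paste(en$kegg_names[[i]], collapse = " "),
    paste(sort(en$component_ids[[i]]), collapse = " "), sep = "|"), ""))
  rl <- pw$relations
  r <- sort(vapply(seq_len(nrow(rl)), function(i) paste(
    rl$entry1[i], rl$entry2[i], rl$relation_type[i],
    paste(rl$subtypes[[i]], collapse = " "), sep = "|"), ""))
  list(id = pw$pathway_id, org = pw$organism, entries = e, relations = r)
}
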