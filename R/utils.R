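# shared internal helpers

# UniProt accession: 6 or 10 alphanumerics starting with a letter
.ACCESSION_RE <- "^[A-Za-z][A-Za-z0-9]{5}([A-Za-z0-9]{4})?$"
.PATHWAY_ID_RE <- "^[a-z]{2,4}[0-9]{5}$"

# display/collapse precedence over edge categories
.CATEGORY_LEVELS <- c("activation", "inhibition", "expression", "other")

#' @keywords internal
subtype_to_category <- function(subtypes) {
  vapply(subtypes, function(s) {
    switch(s,
      activation = "activation",
      inhibition = "inhibition",
      repression = "inhibition",
      expression = "expression",
      "other"
    )
  }, character(1), USE.NAMES = FALSE)
}

# one category per relation: precedence activation > inhibition > expression > other
collapse_category <- function(subtypes) {
  if (length(subtypes) == 0L) return("other")
  cats <- subtype_to_category(subtypes)
  .CATEGORY_LEVELS[min(match(cats, .CATEGORY_LEVELS))]
}

# pick the display category of an edge from its category set
display_category <- function(categories) {
  .CATEGORY_LEVELS[min(match(categories, .CATEGORY_LEVELS))]
}

# canonical (lexicographic) order for an unordered accession pair
canonical_pair <- function(a, b) {
  swap <- a > b
  pa <- ifelse(swap, b, a)
  pb <- ifelse(swap, a, b)
  list(a = pa, b = pb)
}

# sorted-unique character vector (empty stays character(0))
set_sort <- function(x) sort(unique(as.character(x)))

# join / split a string set for flat-file serialization
join_set <- function(x) paste(set_sort(x), collapse = ";")
split_set <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}

# run expr with a temporary RNG seed, restoring global state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# zero-row scaffolds so empty and non-empty objects share a schema
empty_entries <- function() {
  data.frame(
    entry_id = character(0), entry_type = character(0),
    kegg_names = I(list()), component_ids = I(list()),
    graphics_name = character(0), stringsAsFactors = FALSE
  )
}

empty_relations <- function() {
  data.frame(
    entry1 = character(0), entry2 = character(0),
    relation_type = character(0), subtypes = I(list()),
    stringsAsFactors = FALSE
  )
}
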