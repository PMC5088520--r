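# two-pathway corpus: pathway 1 has X linked inside; pathway 2 links the
# shared protein X to an extra protein Y (external to pathway 1)
shared_corpus <- function(dir = tempfile("shared_")) {
  p1 <- kgml_doc(
    "hsa90001",
    entries = paste0(kgml_entry("1", "hsa:101"), kgml_entry("2", "hsa:102"),
                     kgml_entry("3", "hsa:103")),
    relations = paste0(kgml_relation("1", "2", subtypes = "activation"),
                       kgml_relation("2", "3", subtypes = "inhibition"))
  )
  p2 <- kgml_doc(
    "hsa90002",
    entries = paste0(kgml_entry("1", "hsa:101"), kgml_entry("2", "hsa:201")),
    relations = kgml_relation("1", "2", subtypes = "expression")
  )
  write_kgml_text(p1, dir, "hsa90001.xml")
  write_kgml_text(p2, dir, "hsa90002.xml")
  dir
}

shared_mapping <- function() {
  make_mapping(c("hsa:101", "hsa:102", "hsa:103", "hsa:201"),
               c("P00101", "P00102", "P00103", "P00201"))
}

test_that("build_local returns exactly the pathway's proteins and relations", {
  txt <- kgml_doc(
    "hsa90001",
    entries = paste0(vapply(1:5, function(i)
      kgml_entry(as.character(i), paste0("hsa:", 100 + i)), ""),
      collapse = ""),
    relations = paste0(kgml_relation("1", "2"), kgml_relation("2", "3"),
                       kgml_relation("3", "4"), kgml_relation("4", "5"))
  )
  dir <- tempfile(); write_kgml_text(txt, dir, "hsa90001.xml")
  m <- make_mapping(sprintf("hsa:%d", 101:105), sprintf("P%05d", 101:105))
  net <- build_local(build_store(dir, m), "hsa90001")
  expect_equal(nrow(net$nodes), 5L)
  expect_equal(nrow(net$edges), 4L)
  expect_equal(net$scope, "local")
  expect_true(all(net$nodes$origin == "local"))
})

test_that("isolated proteins stay in the local network with degree zero", {
  txt <- kgml_doc(
    "hsa90001",
    entries = paste0(kgml_entry("1", "hsa:101"), kgml_entry("2", "hsa:102"),
                     kgml_entry("3", "hsa:103")),
    relations = kgml_relation("1", "2")
  )
  dir <- tempfile(); write_kgml_text(txt, dir, "hsa90001.xml")
  net <- build_local(build_store(dir, shared_mapping()), "hsa90001")
  expect_true("P00103" %in% net$nodes$accession)
  top <- compute_topology(net)
  expect_equal(top$degree[top$accession == "P00103"], 0L)
})

test_that("unknown pathway ids error and list the known ids", {
  store <- build_store(shared_corpus(), shared_mapping())
  expect_error(build_local(store, "hsa99999"), "hsa90001")
})

test_that("global networks add one-hop external partners; local does not", {
  store <- build_store(shared_corpus(), shared_mapping())
  loc <- build_local(store, "hsa90001")
  glob <- build_global(store, "hsa90001")
  expect_false("P00201" %in% loc$nodes$accession)
  expect_true("P00201" %in% glob$nodes$accession)
  expect_equal(glob$nodes$origin[glob$nodes$accession == "P00201"], "external")
  # local is a subgraph of global
  expect_true(all(loc$nodes$accession %in% glob$nodes$accession))
  key <- function(n) paste(n$edges$protein_a, n$edges$protein_b)
  expect_true(all(key(loc) %in% key(glob)))
})

test_that("with a single-pathway store the global network equals the local one", {
  store <- build_store(two_by_three_corpus(), t23_mapping())
  loc <- build_local(store, "hsa90001")
  glob <- build_global(store, "hsa90001")
  expect_equal(glob$nodes, loc$nodes)
  expect_equal(glob$edges, loc$edges)
})

test_that("a seed protein with k external partners adds exactly k external nodes", {
  dir <- tempfile("k_ext_")
  seedp <- kgml_doc("hsa90001", entries = kgml_entry("1", "hsa:101"))
  write_kgml_text(seedp, dir, "hsa90001.xml")
  k <- 0L
  for (p in 2:4) {
    partners <- 1 + (p - 2) * 2 + seq_len(2)   # two fresh partners each
    k <- k + 2L
    ent <- paste0(kgml_entry("1", "hsa:101"),
                  paste0(vapply(seq_along(partners), function(i)
                    kgml_entry(as.character(i + 1),
                               paste0("hsa:", 300 + partners[i])), ""),
                    collapse = ""))
    rel <- paste0(vapply(seq_along(partners), function(i)
      kgml_relation("1", as.character(i + 1)), ""), collapse = "")
    write_kgml_text(kgml_doc(sprintf("hsa9000%d", p),
                             entries = ent, relations = rel),
                    dir, sprintf("hsa9000%d.xml", p))
  }
  ids <- c("hsa:101", sprintf("hsa:%d", 301:307))
  m <- make_mapping(ids, sprintf("P%05d", c(101, 301:307)))
  store <- build_store(dir, m)
  glob <- build_global(store, "hsa90001")
  expect_equal(sum(glob$nodes$origin == "external"), k)
})

test_that("merge_ppi flags unordered matches and never alters the graph", {
  store <- build_store(shared_corpus(), shared_mapping())
  net <- build_local(store, "hsa90001")
  # reversed order must still match
  flipped <- data.frame(protein_a = "P00102", protein_b = "P00101")
  out <- merge_ppi(net, flipped)
  expect_equal(attr(out, "ppi_matched"), 1L)
  expect_true(out$edges$ppi_supported[out$edges$protein_a == "P00101"])
  expect_equal(out$nodes, net$nodes)
  expect_equal(out$edges[names(out$edges) != "ppi_supported"],
               net$edges[names(net$edges) != "ppi_supported"])
  # disjoint list is a no-op
  none <- merge_ppi(net, data.frame(a = "P99998", b = "P99999"))
  expect_equal(attr(none, "ppi_matched"), 0L)
  expect_equal(none$edges$ppi_supported, rep(FALSE, nrow(net$edges)))
})

test_that("merge_ppi counts matched edges on a partially covered network", {
  txt <- kgml_doc(
    "hsa90001",
    entries = paste0(vapply(1:5, function(i)
      kgml_entry(as.character(i), paste0("hsa:", 100 + i)), ""),
      collapse = ""),
    relations = paste0(kgml_relation("1", "2"), kgml_relation("2", "3"),
                       kgml_relation("3", "4"), kgml_relation("4", "5"))
  )
  dir <- tempfile(); write_kgml_text(txt, dir, "hsa90001.xml")
  m <- make_mapping(sprintf("hsa:%d", 101:105), sprintf("P%05d", 101:105))
  net <- build_local(build_store(dir, m), "hsa90001")
  ppi <- data.frame(a = c("P00102", "P00104"), b = c("P00101", "P00103"))
  out <- merge_ppi(net, ppi)
  expect_equal(attr(out, "ppi_matched"), 2L)
  expect_equal(sum(out$edges$ppi_supported), 2L)
})

test_that("union mode adds PPI-only edges between existing nodes as 'other'", {
  store <- build_store(shared_corpus(), shared_mapping())
  net <- build_local(store, "hsa90001")
  ppi <- data.frame(a = c("P00101", "P00101"), b = c("P00103", "P99999"))
  out <- merge_ppi(net, ppi, add_edges = TRUE)
  expect_equal(nrow(out$edges), nrow(net$edges) + 1L)  # P99999 not a node
  added <- out$edges[out$edges$protein_a == "P00101" &
                     out$edges$protein_b == "P00103", ]
  expect_equal(added$display_category, "other")
  expect_true(added$ppi_supported)
  expect_length(added$pathway_ids[[1]], 0L)
  expect_equal(out$nodes, net$nodes)
})

test_that("SIF export writes one line per edge plus isolated nodes", {
  tri <- network_from_edges(c("A00001", "B00001", "C00001"),
                            rbind(c(1, 2), c(2, 3), c(1, 3)))
  sif <- tempfile(fileext = ".sif")
  export_network(tri, sif, "sif")
  expect_length(readLines(sif), 3L)
})

test_that("multi-category edges display under the precedence rule", {
  dir <- tempfile("multi_")
  txt <- kgml_doc(
    "hsa90001",
    entries = paste0(kgml_entry("1", "hsa:101"), kgml_entry("2", "hsa:102")),
    relations = paste0(
      kgml_relation("1", "2", subtypes = "binding/association"),  # -> other
      kgml_relation("1", "2", subtypes = "activation")
    )
  )
  write_kgml_text(txt, dir, "hsa90001.xml")
  net <- build_local(build_store(dir, shared_mapping()), "hsa90001")
  expect_equal(nrow(net$edges), 1L)   # parallel categories merge to one edge
  expect_setequal(net$edges$categories[[1]], c("activation", "other"))
  expect_equal(net$edges$display_category, "activation")
  sif <- tempfile(fileext = ".sif")
  export_network(net, sif, "sif")
  expect_match(readLines(sif), "\tactivation\t")
})

test_that("GraphML export/import round-trips all attributes", {
  fx <- generate_corpus(fixture_spec(seed = 31), tempfile())
  store <- build_store(fx$dir, load_mapping(fx$mapping, "kegg_gene"))
  pid <- store_pathways(store)[1]
  net <- merge_ppi(build_global(store, pid), fx$ppi)
  res <- read_expression(fx$expression)
  net <- set_states(net, assign_states(net, res, "ctx_A"))
  gml <- tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  back <- import_network(gml)
  ord <- order(net$nodes$accession)
  expect_equal(back$nodes, net$nodes[ord, ], ignore_attr = TRUE)
  eord <- order(net$edges$protein_a, net$edges$protein_b)
  expect_equal(back$edges, net$edges[eord, ], ignore_attr = TRUE)
  expect_equal(back$scope, net$scope)
  expect_equal(back$seed_pathway, net$seed_pathway)
})

test_that("local networks are subgraphs of global networks across a corpus", {
  fx <- generate_corpus(fixture_spec(n_pathways = 4, seed = 17,
                                     shared_protein_fraction = 0.4),
                        tempfile())
  store <- build_store(fx$dir, load_mapping(fx$mapping, "kegg_gene"))
  for (pid in store_pathways(store)) {
    loc <- build_local(store, pid)
    glob <- build_global(store, pid)
    expect_true(all(loc$nodes$accession %in% glob$nodes$accession))
    key <- function(n) paste(n$edges$protein_a, n$edges$protein_b)
    expect_true(all(key(loc) %in% key(glob)))
  }
})
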