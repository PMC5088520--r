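# Synthetic fixture corpora: KGML files, mapping tables, expression score
# tables and PPI lists with a machine-readable ground-truth manifest, so
# the whole pipeline is testable offline with known expected counts.

#' Specification of a synthetic fixture corpus
#'
#' All randomness of [generate_corpus()] flows from the single `seed`;
#' the same spec always produces a byte-identical corpus.
#'
#' @param n_pathways Number of pathways (KGML files).
#' @param genes_per_pathway Integer range `c(min, max)` of genes per
#'   pathway.
#' @param multi_gene_entry_prob Probability that an entry is a
#'   multi-protein box (2-3 genes) rather than a single gene.
#' @param relation_density Probability that any two gene entries of a
#'   pathway are linked by a relation.
#' @param subtype_distribution Named probability vector over KGML subtype
#'   names; the reserved name `"none"` produces a relation without
#'   subtype elements.
#' @param shared_protein_fraction Fraction of each pathway's genes drawn
#'   from genes already used by earlier pathways (cross-pathway overlap).
#' @param contexts Named list of per-context expression settings, each a
#'   list with `fraction_on` (probability a measured gene is ON).
#' @param na_fraction Fraction of genes absent from the expression table
#'   (NA in every context).
#' @param on_range,off_range Score ranges for ON and OFF genes; the
#'   defaults keep all scores strictly away from the threshold.
#' @param threshold ON/OFF threshold the ground truth is computed at.
#' @param boundary_scores Inject one exact-threshold score per context
#'   (an exact-threshold gene is OFF under the strict `>` rule).
#' @param seed Integer seed fixing all randomness.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_pathways = 3,
                         genes_per_pathway = c(8, 16),
                         multi_gene_entry_prob = 0.25,
                         relation_density = 0.25,
                         subtype_distribution = c(
                           activation = 0.35, inhibition = 0.2,
                           expression = 0.15, phosphorylation = 0.1,
                           "binding/association" = 0.1,
                           "indirect effect" = 0.05, none = 0.05),
                         shared_protein_fraction = 0.2,
                         contexts = list(
                           ctx_A = list(fraction_on = 0.6),
                           ctx_B = list(fraction_on = 0.4)),
                         na_fraction = 0.05,
                         on_range = c(0.45, 0.99),
                         off_range = c(0.01, 0.35),
                         threshold = 0.4,
                         boundary_scores = FALSE,
                         seed = 1) {
  probs <- c(multi_gene_entry_prob, relation_density,
             shared_protein_fraction, na_fraction, subtype_distribution,
             vapply(contexts, `[[`, 1, "fraction_on"))
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(subtype_distribution) - 1) > 1e-8) {
    stop("subtype_distribution must sum to 1", call. = FALSE)
  }
  stopifnot(length(genes_per_pathway) == 2L,
            genes_per_pathway[1] >= 1,
            genes_per_pathway[2] >= genes_per_pathway[1],
            n_pathways >= 1)
  structure(
    list(n_pathways = n_pathways, genes_per_pathway = genes_per_pathway,
         multi_gene_entry_prob = multi_gene_entry_prob,
         relation_density = relation_density,
         subtype_distribution = subtype_distribution,
         shared_protein_fraction = shared_protein_fraction,
         contexts = contexts, na_fraction = na_fraction,
         on_range = on_range, off_range = off_range,
         threshold = threshold, boundary_scores = boundary_scores,
         seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

# build a kegg_pathway object in code
make_pathway <- function(pathway_id, title, entries, relations,
                         organism = sub("[0-9]+$", "", pathway_id)) {
  pw <- structure(
    list(pathway_id = pathway_id, organism = organism, title = title,
         entries = entries, relations = relations),
    class = "kegg_pathway"
  )
  validate_pathway(pw)
  pw
}

# ground truth bookkeeping: mirrors the documented store/overlay rules on
# the generator's own knowledge of gene membership (1:1 gene->accession)
corpus_ground_truth <- function(pathways, gene2acc, scores, threshold,
                                ppi_pairs) {
  pair_rows <- list()   # key "a\rb\rcat" -> set of pathway ids
  gt_pathways <- list()
  for (pw in pathways) {
    pwx <- expand_groups(pw)
    en <- pwx$entries
    is_gene <- en$entry_type == "gene"
    acc_of <- lapply(seq_len(nrow(en)), function(i) {
      if (!is_gene[i]) return(character(0))
      set_sort(unname(gene2acc[en$kegg_names[[i]]]))
    })
    names(acc_of) <- en$entry_id
    local_pairs <- character(0)
    rel <- pwx$relations
    for (i in seq_len(nrow(rel))) {
      if (!rel$relation_type[i] %in% c("PPrel", "GErel", "ECrel")) next
      a1 <- acc_of[[rel$entry1[i]]]
      a2 <- acc_of[[rel$entry2[i]]]
      if (!length(a1) || !length(a2)) next
      grid <- expand.grid(a = a1, b = a2, KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
      grid <- grid[grid$a != grid$b, , drop = FALSE]
      if (!nrow(grid)) next
      cp <- canonical_pair(grid$a, grid$b)
      cat_i <- collapse_category(rel$subtypes[[i]])
      keys <- paste(cp$a, cp$b, cat_i, sep = "\r")
      for (k in keys) {
        pair_rows[[k]] <- union(pair_rows[[k]], pw$pathway_id)
      }
      local_pairs <- c(local_pairs, paste(cp$a, cp$b, sep = "\r"))
    }
    local_pairs <- unique(local_pairs)
    local_acc <- set_sort(unlist(acc_of))
    gt_pathways[[pw$pathway_id]] <- list(
      n_entries = nrow(pw$entries),
      n_relations = nrow(pw$relations),
      n_gene_entries = sum(pw$entries$entry_type == "gene"),
      local_nodes = length(local_acc),
      local_edges = length(local_pairs),
      accessions = local_acc,
      local_pairs = local_pairs
    )
  }

  all_acc <- set_sort(unlist(lapply(gt_pathways, `[[`, "accessions")))
  contexts <- lapply(stats::setNames(colnames(scores), colnames(scores)),
    function(ctx) {
      sc <- scores[, ctx]
      state_of <- function(a) {
        v <- if (a %in% names(sc)) sc[[a]] else NA_real_
        if (is.na(v)) "NA" else if (v > threshold) "ON" else "OFF"
      }
      states <- vapply(all_acc, state_of, "")
      per_pathway <- lapply(gt_pathways, function(g) {
        st <- states[g$accessions]
        kept <- g$accessions[st != "OFF"]
        parts <- strsplit(g$local_pairs, "\r", fixed = TRUE)
        ekeep <- vapply(parts, function(p) all(p %in% kept), TRUE)
        list(n_ON = sum(st == "ON"), n_OFF = sum(st == "OFF"),
             n_NA = sum(st == "NA"),
             filtered_nodes = length(kept),
             filtered_edges = sum(ekeep))
      })
      list(states = as.list(states), pathways = per_pathway)
    })

  pair_keys <- if (length(pair_rows)) names(pair_rows) else character(0)
  store_pairs <- unique(vapply(strsplit(pair_keys, "\r", fixed = TRUE),
                               function(p) paste(p[1], p[2], sep = "\r"), ""))
  list(
    pathways = lapply(gt_pathways, function(g)
      g[c("n_entries", "n_relations", "n_gene_entries",
          "local_nodes", "local_edges")]),
    store = list(n_proteins = length(all_acc),
                 n_relations = length(pair_rows),
                 n_unique_pairs = length(store_pairs)),
    contexts = contexts,
    ppi = list(n_pairs = nrow(ppi_pairs)),
    threshold = threshold
  )
}

write_corpus_files <- function(out_dir, pathways, gene2acc, symbols,
                               scores, ppi_pairs, ground_truth) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  kgml_files <- vapply(pathways, function(pw) {
    f <- file.path(out_dir, paste0(pw$pathway_id, ".xml"))
    write_kgml(pw, f)
    f
  }, "")

  mapping_path <- file.path(out_dir, "mapping.tsv")
  mp <- data.frame(source_id = names(gene2acc), accession = unname(gene2acc),
                   stringsAsFactors = FALSE)
  mp <- mp[order(mp$source_id), , drop = FALSE]
  utils::write.table(mp, mapping_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  expr_path <- file.path(out_dir, "expression.tsv")
  keep <- rowSums(!is.na(scores)) > 0
  em <- scores[keep, , drop = FALSE]
  em <- em[order(rownames(em)), , drop = FALSE]
  df <- data.frame(accession = rownames(em), em, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ppi_path <- file.path(out_dir, "ppi.tsv")
  utils::write.table(ppi_pairs, ppi_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  manifest_path <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(ground_truth, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  list(dir = out_dir, kgml_files = unname(kgml_files),
       mapping = mapping_path, expression = expr_path, ppi = ppi_path,
       manifest = manifest_path, ground_truth = ground_truth)
}

#' Generate a synthetic KGML corpus with ground truth
#'
#' Writes, under `out_dir`: one KGML file per pathway (gene entries —
#' some multi-protein boxes — plus one compound and one map entry with a
#' `PCrel`/`maplink` relation each, which must contribute nothing to the
#' store), a KEGG-to-UniProt `mapping.tsv`, a per-context
#' `expression.tsv` of barcode-style scores, a `ppi.tsv` pair list, and
#' `ground_truth.json` recording the expected entry/relation counts,
#' store row counts, per-context ON/OFF/NA states and filtered
#' node/edge counts that the pipeline must reproduce.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the file paths and the `ground_truth`
#'   list.
#' @export
generate_corpus <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, generate_corpus_impl(spec, out_dir))
}

generate_corpus_impl <- function(spec, out_dir) {
  gene_acc <- function(k) sprintf("P9%04d", k)
  gene_kegg <- function(k) sprintf("hsa:%d", 10000 + k)
  gene_sym <- function(k) sprintf("G%04d", k)

  n_genes_total <- 0L
  used_genes <- integer(0)
  pathways <- list()

  for (p in seq_len(spec$n_pathways)) {
    pid <- sprintf("hsa9%04d", p)
    n_g <- sample(seq(spec$genes_per_pathway[1], spec$genes_per_pathway[2]), 1)
    n_shared <- if (p > 1) min(round(spec$shared_protein_fraction * n_g),
                               length(used_genes)) else 0L
    shared <- if (n_shared > 0) sample(used_genes, n_shared) else integer(0)
    fresh <- n_genes_total + seq_len(n_g - n_shared)
    n_genes_total <- n_genes_total + n_g - n_shared
    genes <- sample(c(shared, fresh))  # shuffled pathway gene set
    used_genes <- union(used_genes, genes)

    # partition genes into entries; some are multi-protein boxes
    entry_genes <- list()
    i <- 1L
    while (i <= length(genes)) {
      size <- if (stats::runif(1) < spec$multi_gene_entry_prob)
        min(sample(2:3, 1), length(genes) - i + 1L) else 1L
      entry_genes[[length(entry_genes) + 1L]] <- genes[i:(i + size - 1L)]
      i <- i + size
    }
    n_gene_entries <- length(entry_genes)
    entries <- data.frame(
      entry_id = as.character(seq_len(n_gene_entries + 2L)),
      entry_type = c(rep("gene", n_gene_entries), "compound", "map"),
      kegg_names = I(c(lapply(entry_genes, gene_kegg),
                       list("cpd:C00001", "path:hsa00010"))),
      component_ids = I(replicate(n_gene_entries + 2L, character(0),
                                  simplify = FALSE)),
      graphics_name = c(vapply(entry_genes, function(g) gene_sym(g[1]), ""),
                        "C00001", "TCA cycle"),
      stringsAsFactors = FALSE
    )

    # relations between gene entries
    rel_list <- list()
    if (n_gene_entries >= 2) {
      for (a in seq_len(n_gene_entries - 1L)) {
        for (b in seq((a + 1L), n_gene_entries)) {
          if (stats::runif(1) >= spec$relation_density) next
          st <- sample(names(spec$subtype_distribution), 1,
                       prob = spec$subtype_distribution)
          subtypes <- if (st == "none") character(0) else st
          rtype <- if (identical(st, "expression")) "GErel" else "PPrel"
          ends <- if (stats::runif(1) < 0.5) c(a, b) else c(b, a)
          rel_list[[length(rel_list) + 1L]] <- list(
            entry1 = as.character(ends[1]), entry2 = as.character(ends[2]),
            relation_type = rtype, subtypes = subtypes)
        }
      }
    }
    # compound / map relations: present in KGML, excluded from the store
    # (omitted entirely at density 0, where pathways carry no relations)
    if (spec$relation_density > 0) {
      rel_list[[length(rel_list) + 1L]] <- list(
        entry1 = "1", entry2 = as.character(n_gene_entries + 1L),
        relation_type = "PCrel", subtypes = "compound")
      rel_list[[length(rel_list) + 1L]] <- list(
        entry1 = "1", entry2 = as.character(n_gene_entries + 2L),
        relation_type = "maplink", subtypes = "compound")
    }

    relations <- data.frame(
      entry1 = vapply(rel_list, `[[`, "", "entry1"),
      entry2 = vapply(rel_list, `[[`, "", "entry2"),
      relation_type = vapply(rel_list, `[[`, "", "relation_type"),
      subtypes = I(lapply(rel_list, `[[`, "subtypes")),
      stringsAsFactors = FALSE
    )
    pathways[[pid]] <- make_pathway(pid, paste("synthetic pathway", p),
                                    entries, relations)
  }

  all_k <- sort(used_genes)
  gene2acc <- stats::setNames(gene_acc(all_k), gene_kegg(all_k))
  symbols <- stats::setNames(gene_sym(all_k), gene_acc(all_k))

  # expression scores per accession x context; NA genes are absent rows
  accs <- unname(gene2acc)
  is_na_gene <- stats::runif(length(accs)) < spec$na_fraction
  ctx_names <- names(spec$contexts)
  scores <- matrix(NA_real_, length(accs), length(ctx_names),
                   dimnames = list(accs, ctx_names))
  for (ctx in ctx_names) {
    f_on <- spec$contexts[[ctx]]$fraction_on
    on <- stats::runif(length(accs)) < f_on
    s <- ifelse(on,
                stats::runif(length(accs), spec$on_range[1], spec$on_range[2]),
                stats::runif(length(accs), spec$off_range[1], spec$off_range[2]))
    s[is_na_gene] <- NA_real_
    if (spec$boundary_scores) {
      cand <- which(!is_na_gene & !on)
      if (length(cand)) s[cand[1]] <- spec$threshold  # exact threshold -> OFF
    }
    scores[, ctx] <- s
  }

  # PPI list: half of the expected store pairs plus decoy pairs
  pair_keys <- unlist(lapply(pathways, function(pw) {
    pwx <- expand_groups(pw)
    en <- pwx$entries
    acc_of <- lapply(seq_len(nrow(en)), function(i) {
      if (en$entry_type[i] != "gene") return(character(0))
      set_sort(unname(gene2acc[en$kegg_names[[i]]]))
    })
    names(acc_of) <- en$entry_id
    rel <- pwx$relations
    keys <- character(0)
    for (i in seq_len(nrow(rel))) {
      if (!rel$relation_type[i] %in% c("PPrel", "GErel", "ECrel")) next
      a1 <- acc_of[[rel$entry1[i]]]; a2 <- acc_of[[rel$entry2[i]]]
      if (!length(a1) || !length(a2)) next
      grid <- expand.grid(a = a1, b = a2, KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
      grid <- grid[grid$a != grid$b, , drop = FALSE]
      cp <- canonical_pair(grid$a, grid$b)
      keys <- c(keys, paste(cp$a, cp$b, sep = "\t"))
    }
    keys
  }), use.names = FALSE)
  pair_keys <- sort(unique(pair_keys))
  n_take <- floor(length(pair_keys) / 2)
  taken <- if (n_take > 0) sample(pair_keys, n_take) else character(0)
  decoys <- character(0)
  if (length(accs) >= 2) {
    for (d in 1:3) {
      pr <- sort(sample(accs, 2))
      key <- paste(pr[1], pr[2], sep = "\t")
      if (!key %in% pair_keys) decoys <- c(decoys, key)
    }
  }
  ppi_keys <- sort(unique(c(taken, decoys)))
  parts <- strsplit(ppi_keys, "\t", fixed = TRUE)
  ppi_pairs <- data.frame(
    protein_a = vapply(parts, `[`, "", 1),
    protein_b = vapply(parts, `[`, "", 2), stringsAsFactors = FALSE)

  gt <- corpus_ground_truth(pathways, gene2acc, scores, spec$threshold,
                            ppi_pairs)
  gt$seed <- spec$seed
  invisible(write_corpus_files(out_dir, pathways, gene2acc, symbols,
                               scores, ppi_pairs, gt))
}

#' The packaged NOTCH-like demonstration fixture
#'
#' A deterministic synthetic corpus whose structure mirrors the shape of
#' a NOTCH-signalling case study in lymphocytes, without claiming any
#' real pathway content: one pathway of 48 proteins grouped into
#' multi-protein boxes (receptors, ligands, the gamma-secretase complex,
#' transcription-complex members), and three expression contexts — a
#' B-cell-like context with more ON proteins than two T-cell-like
#' contexts. Two proteins are absent from the expression platform (NA
#' in every context) and the five ligand-like proteins are OFF
#' everywhere. A `DTX1`-like regulator scores 1.00 / 0.41 / 0.17 across
#' the three contexts, so at the default 0.4 threshold it is ON in the
#' first two and OFF in the third. All accessions are synthetic.
#'
#' @param out_dir Output directory (default: fresh temporary directory).
#' @return Invisibly, the same file-path + ground-truth list as
#'   [generate_corpus()].
#' @export
notch_like_fixture <- function(out_dir = tempfile("notch_like_")) {
  with_seed(20161025L, notch_like_impl(out_dir))
}

notch_like_impl <- function(out_dir) {
  symbols <- c(
    "NOTCH1", "NOTCH2", "NOTCH3", "NOTCH4",
    "JAG1", "JAG2", "DLL1", "DLL3", "DLL4",
    "DTX1", "DTX2", "DTX3", "DTX3L", "DTX4",
    "HES1", "HES5", "HEY1", "HEYL",
    "RBPJ", "RBPJL", "MAML1", "MAML2", "MAML3",
    "ADAM17", "PSEN1", "PSEN2", "PSENEN", "NCSTN", "APH1A", "APH1B",
    "LFNG", "MFNG", "RFNG", "NUMB", "NUMBL",
    "DVL1", "DVL2", "DVL3", "CREBBP", "EP300", "SNW1",
    "CTBP1", "CTBP2", "HDAC1", "HDAC2", "CIR1", "KAT2A", "KAT2B"
  )
  stopifnot(length(symbols) == 48L)
  accs <- sprintf("P6%04d", seq_along(symbols))
  names(accs) <- symbols
  kegg <- sprintf("hsa:%d", 60000 + seq_along(symbols))
  gene2acc <- stats::setNames(accs, kegg)
  sym_of_acc <- stats::setNames(symbols, accs)

  entry_syms <- list(
    c("NOTCH1", "NOTCH2", "NOTCH3", "NOTCH4"),   # 1 receptors
    c("JAG1", "JAG2"),                           # 2 ligands
    c("DLL1", "DLL3", "DLL4"),                   # 3 ligands
    c("DTX1", "DTX2", "DTX3", "DTX3L", "DTX4"),  # 4
    c("HES1", "HES5"),                           # 5
    c("HEY1", "HEYL"),                           # 6
    c("RBPJ", "RBPJL"),                          # 7
    c("MAML1", "MAML2", "MAML3"),                # 8
    "ADAM17",                                    # 9
    c("PSEN1", "PSEN2"),                         # 10
    c("PSENEN", "NCSTN"),                        # 11
    c("APH1A", "APH1B"),                         # 12
    c("LFNG", "MFNG", "RFNG"),                   # 13
    c("NUMB", "NUMBL"),                          # 14
    c("DVL1", "DVL2", "DVL3"),                   # 15
    c("CREBBP", "EP300"),                        # 16
    "SNW1",                                      # 17
    c("CTBP1", "CTBP2"),                         # 18
    c("HDAC1", "HDAC2"),                         # 19
    "CIR1",                                      # 20
    c("KAT2A", "KAT2B")                          # 21
  )
  kegg_of_sym <- stats::setNames(kegg, symbols)
  entries <- data.frame(
    entry_id = as.character(seq_along(entry_syms)),
    entry_type = "gene",
    kegg_names = I(lapply(entry_syms, function(s) unname(kegg_of_sym[s]))),
    component_ids = I(replicate(length(entry_syms), character(0),
                                simplify = FALSE)),
    graphics_name = vapply(entry_syms, `[`, "", 1),
    stringsAsFactors = FALSE
  )

  rel_def <- list(
    list(2, 1, "activation"), list(3, 1, "activation"),
    list(9, 1, "activation"),
    list(10, 1, "binding/association"), list(11, 1, "binding/association"),
    list(12, 1, "binding/association"),
    list(13, 1, "inhibition"), list(14, 1, "inhibition"),
    list(15, 1, "inhibition"),
    list(1, 4, "binding/association"), list(1, 7, "activation"),
    list(8, 7, "activation"), list(17, 7, "binding/association"),
    list(16, 7, "activation"), list(21, 7, "activation"),
    list(18, 7, "inhibition"), list(19, 7, "inhibition"),
    list(20, 7, "inhibition"),
    list(7, 5, "expression"), list(7, 6, "expression")
  )
  relations <- data.frame(
    entry1 = vapply(rel_def, function(r) as.character(r[[1]]), ""),
    entry2 = vapply(rel_def, function(r) as.character(r[[2]]), ""),
    relation_type = vapply(rel_def, function(r)
      if (identical(r[[3]], "expression")) "GErel" else "PPrel", ""),
    subtypes = I(lapply(rel_def, function(r) r[[3]])),
    stringsAsFactors = FALSE
  )
  pw <- make_pathway("hsa94330", "NOTCH-like signaling (synthetic)",
                     entries, relations)

  na_genes <- c("DTX3L", "RBPJL")
  ligands_off <- c("JAG1", "JAG2", "DLL1", "DLL3", "DLL4")
  off_b_extra <- c("NOTCH3", "NOTCH4", "DTX2", "DTX3", "DTX4",
                   "HES5", "HEYL", "RFNG", "NUMBL")
  on_b <- setdiff(symbols, c(na_genes, ligands_off, off_b_extra))
  on_cd4 <- setdiff(on_b, c("HES1", "HEY1", "MFNG", "NUMB",
                            "DVL1", "DVL2", "DVL3", "KAT2B"))
  on_cd8 <- setdiff(on_cd4, c("DTX1", "CREBBP"))
  stopifnot(length(on_b) == 32L, length(on_cd4) == 24L, length(on_cd8) == 22L)

  ctxs <- c("Bcell_CD19", "Tcell_CD4", "Tcell_CD8")
  on_sets <- list(Bcell_CD19 = on_b, Tcell_CD4 = on_cd4, Tcell_CD8 = on_cd8)
  scores <- matrix(NA_real_, length(symbols), length(ctxs),
                   dimnames = list(unname(accs), ctxs))
  for (ctx in ctxs) {
    on <- symbols %in% on_sets[[ctx]]
    s <- ifelse(on, stats::runif(length(symbols), 0.55, 0.99),
                stats::runif(length(symbols), 0.01, 0.30))
    s[symbols %in% na_genes] <- NA_real_
    scores[, ctx] <- round(s, 2)
  }
  # the DTX1-like regulator: strongly ON in B, borderline ON in CD4+, OFF in CD8+
  scores[accs[["DTX1"]], ] <- c(1.00, 0.41, 0.17)

  # PPI: a sample of the pathway's expanded pairs plus decoys
  pairs_all <- local({
    en_acc <- lapply(entry_syms, function(s) sort(unname(accs[s])))
    keys <- character(0)
    for (r in rel_def) {
      a1 <- en_acc[[r[[1]]]]; a2 <- en_acc[[r[[2]]]]
      grid <- expand.grid(a = a1, b = a2, KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
      cp <- canonical_pair(grid$a, grid$b)
      keys <- c(keys, paste(cp$a, cp$b, sep = "\t"))
    }
    sort(unique(keys))
  })
  taken <- sort(sample(pairs_all, 40))
  decoys <- character(0)
  while (length(decoys) < 3) {
    pr <- sort(sample(unname(accs), 2))
    key <- paste(pr[1], pr[2], sep = "\t")
    if (!key %in% pairs_all && !key %in% decoys) decoys <- c(decoys, key)
  }
  parts <- strsplit(sort(unique(c(taken, decoys))), "\t", fixed = TRUE)
  ppi_pairs <- data.frame(protein_a = vapply(parts, `[`, "", 1),
                          protein_b = vapply(parts, `[`, "", 2),
                          stringsAsFactors = FALSE)

  gt <- corpus_ground_truth(list(pw), gene2acc, scores, 0.4, ppi_pairs)
  gt$seed <- 20161025L
  gt$symbols <- as.list(sym_of_acc)
  gt$na_genes <- unname(accs[na_genes])
  gt$always_off <- unname(accs[ligands_off])

  # construction guarantee: B-like strictly exceeds each T-like context
  bp <- gt$contexts$Bcell_CD19$pathways$hsa94330
  for (tctx in c("Tcell_CD4", "Tcell_CD8")) {
    tp <- gt$contexts[[tctx]]$pathways$hsa94330
    stopifnot(bp$n_ON > tp$n_ON, bp$filtered_edges > tp$filtered_edges)
  }

  invisible(write_corpus_files(out_dir, list(pw), gene2acc,
                               sym_of_acc, scores, ppi_pairs, gt))
}

#' @export
print.fixture_spec <- function(x, ...) {
  cat("<fixture_spec> ", x$n_pathways, " pathway(s), ",
      x$genes_per_pathway[1], "-", x$genes_per_pathway[2],
      " genes each, seed ", x$seed, "\n", sep = "")
  invisible(x)
}
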