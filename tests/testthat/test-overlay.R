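test_that("barcode scores are the fraction of samples above the z cutoff", {
  # gene1: all samples at mu -> 0; gene2: 13 of 32 shifted by 8 sigma;
  # gene3: all samples shifted -> 1
  n <- 32
  mu <- c(g1 = 4, g2 = 5, g3 = 6)
  sigma <- c(g1 = 0.5, g2 = 0.4, g3 = 0.3)
  m <- rbind(
    g1 = rep(mu["g1"], n),
    g2 = c(rep(mu["g2"] + 8 * sigma["g2"], 13), rep(mu["g2"], n - 13)),
    g3 = rep(mu["g3"] + 8 * sigma["g3"], n)
  )
  ref <- data.frame(gene = names(mu), mu = unname(mu), sigma = unname(sigma))
  sc <- barcode_scores(m, ref, z_cutoff = 5)
  expect_equal(unname(sc$scores["g1"]), 0)
  expect_equal(unname(sc$scores["g2"]), 13 / 32)
  expect_equal(unname(sc$scores["g3"]), 1)
  expect_length(sc$missing, 0L)
})

test_that("genes absent from the reference are reported, bad sigma errors", {
  m <- rbind(g1 = c(1, 2), gX = c(3, 4))
  ref <- data.frame(gene = "g1", mu = 1, sigma = 1)
  expect_warning(sc <- barcode_scores(m, ref), "absent")
  expect_equal(sc$missing, "gX")
  expect_false("gX" %in% names(sc$scores))
  bad <- data.frame(gene = "g1", mu = 1, sigma = 0)
  expect_error(barcode_scores(m, bad), "sigma")
})

test_that("adding unexpressed samples can only lower a barcode score", {
  set.seed(2)
  ref <- data.frame(gene = "g", mu = 3, sigma = 0.5)
  base <- matrix(c(3, 3 + 8 * 0.5, 3 + 8 * 0.5), 1,
                 dimnames = list("g", NULL))
  s0 <- barcode_scores(base, ref)$scores
  for (extra in 1:4) {
    grown <- cbind(base, matrix(rep(3, extra), 1))
    rownames(grown) <- "g"
    s1 <- barcode_scores(grown, ref)$scores
    expect_lte(s1, s0)
  }
})

test_that("states follow the strict >0.4 rule; absent accessions are NA", {
  net <- network_from_edges(sprintf("P%05d", 1:5),
                            rbind(c(1, 2), c(2, 3), c(3, 4)))
  sc <- c(P00001 = 0.17, P00002 = 0.40, P00003 = 0.41, P00004 = 1.00)
  res <- resource_from_scores(lymph = sc)   # P00005 absent -> NA
  asg <- assign_states(net, res, "lymph")
  expect_equal(unname(asg$states[sprintf("P%05d", 1:5)]),
               c("OFF", "OFF", "ON", "ON", "NA"))
  expect_equal(asg$threshold, 0.4)
  expect_error(assign_states(net, res, "nosuch"), "lymph")
})

test_that("gene-level rows reach accessions through the mapping table", {
  net <- network_from_edges(c("P00001", "P00002"), rbind(c(1, 2)))
  m <- mapping_table(data.frame(
    source_id = c("hsa:11", "hsa:12", "hsa:21"),
    accession = c("P00001", "P00001", "P00002")), "kegg_gene")
  res <- resource_from_scores(ctx = c("hsa:11" = 0.2, "hsa:12" = 0.9,
                                      "hsa:21" = 0.1))
  asg_max <- assign_states(net, res, "ctx", mapping = m)
  expect_equal(unname(asg_max$scores["P00001"]), 0.9)  # max over gene rows
  expect_equal(unname(asg_max$states["P00001"]), "ON")
  asg_mean <- assign_states(net, res, "ctx", mapping = m, combine = "mean")
  expect_equal(unname(asg_mean$scores["P00001"]), 0.55)
})

test_that("filtering removes OFF nodes with their edges and keeps ON and NA", {
  # all ON -> identity
  net <- network_from_edges(sprintf("P%05d", 1:4),
                            rbind(c(1, 2), c(2, 3), c(3, 4)))
  res_all <- resource_from_scores(c1 = c(P00001 = 0.9, P00002 = 0.8,
                                         P00003 = 0.7, P00004 = 0.6))
  f <- filter_network(net, assign_states(net, res_all, "c1"))
  expect_equal(nrow(f$nodes), 4L)
  expect_equal(nrow(f$edges), 3L)
  expect_equal(filter_report(f)$n_OFF_removed, 0L)

  # star with the centre OFF -> leaves only, no edges
  star <- network_from_edges(sprintf("P%05d", 1:5),
                             cbind(1, 2:5))
  res_star <- resource_from_scores(c1 = c(P00001 = 0.1, P00002 = 0.9,
                                          P00003 = 0.9, P00004 = 0.9,
                                          P00005 = 0.9))
  fs <- filter_network(star, assign_states(star, res_star, "c1"))
  expect_equal(nrow(fs$nodes), 4L)
  expect_equal(nrow(fs$edges), 0L)
  expect_equal(filter_report(fs)$edges_removed, 4L)
})

test_that("a 6 ON / 2 NA / 2 OFF network keeps 8 nodes and sheds OFF-incident edges", {
  names_ <- sprintf("P%05d", 1:10)
  # 12 edges, of which 5 touch an OFF node (9 or 10)
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6), c(6, 1),
                 c(1, 3),
                 c(9, 1), c(9, 2), c(9, 10), c(10, 3), c(10, 4))
  net <- network_from_edges(names_, edges)
  sc <- c(P00001 = 0.9, P00002 = 0.8, P00003 = 0.7, P00004 = 0.6,
          P00005 = 0.5, P00006 = 0.45, P00009 = 0.1, P00010 = 0.2)
  # P00007, P00008 absent -> NA
  res <- resource_from_scores(c1 = sc)
  f <- filter_network(net, assign_states(net, res, "c1"))
  rep <- filter_report(f)
  expect_equal(rep$n_ON, 6L)
  expect_equal(rep$n_NA, 2L)
  expect_equal(rep$n_OFF_removed, 2L)
  expect_equal(nrow(f$nodes), 8L)
  expect_equal(nrow(f$edges), 7L)
  expect_equal(rep$edges_removed, 5L)
})

test_that("filter conservation and threshold monotonicity hold on random networks", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:12, 1)
    names_ <- sprintf("P%05d", seq_len(n))
    net <- network_from_edges(names_, random_graph_edges(n, 0.3))
    sc <- round(stats::runif(n), 3)
    sc[sample(n, 1)] <- NA   # at least one NA node
    present <- !is.na(sc)
    res <- resource_from_scores(c1 = stats::setNames(sc[present],
                                                     names_[present]))
    prev_on <- NULL
    for (thr in seq(0, 1, by = 0.25)) {
      asg <- assign_states(net, res, "c1", threshold = thr)
      f <- filter_network(net, asg)
      rep <- filter_report(f)
      expect_equal(rep$n_ON + rep$n_OFF_removed + rep$n_NA, n)
      on_set <- names(asg$states)[asg$states == "ON"]
      if (!is.null(prev_on)) expect_true(all(on_set %in% prev_on))
      prev_on <- on_set
      # every NA node is retained
      na_nodes <- names(asg$states)[asg$states == "NA"]
      expect_true(all(na_nodes %in% f$nodes$accession))
      # retained edges have both endpoints retained
      expect_true(all(f$edges$protein_a %in% f$nodes$accession))
      expect_true(all(f$edges$protein_b %in% f$nodes$accession))
    }
  }
})

test_that("compare_contexts finds discordant genes and ignores NA", {
  net <- network_from_edges(sprintf("P%05d", 1:3), rbind(c(1, 2), c(2, 3)))
  res <- resource_from_scores(
    A = c(P00001 = 0.9, P00002 = 0.9),
    B = c(P00001 = 0.1, P00002 = 0.9)
  )  # P00003 NA everywhere
  a <- assign_states(net, res, "A")
  b <- assign_states(net, res, "B")
  same <- compare_contexts(net, list(a, a))
  expect_length(same$discordant, 0L)
  cmp <- compare_contexts(net, list(a, b))
  expect_equal(cmp$discordant, "P00001")
  expect_false("P00003" %in% cmp$discordant)
  expect_equal(cmp$table$accession, sprintf("P%05d", 1:3))
  # assignments over a different node set are rejected
  other <- network_from_edges(c("P00001", "P00009"), rbind(c(1, 2)))
  oth_asg <- assign_states(other, resource_from_scores(
    A = c(P00001 = 0.9, P00009 = 0.9)), "A")
  expect_error(compare_contexts(net, list(a, oth_asg)), "node set")
})
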