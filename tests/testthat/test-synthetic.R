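test_that("generation is deterministic under a fixed config and seed", {
  cfg <- syntheticConfig(n_genes = 800, seed = 14)
  b1 <- generateBundle(cfg)
  b2 <- generateBundle(cfg)
  expect_identical(b1[names(b1) != "config"], b2[names(b2) != "config"])

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeBundle(b1, d1)
  writeBundle(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("planted class fractions land within binomial noise", {
  cfg <- syntheticConfig(n_genes = 10000, seed = 15,
                         fraction_duplicate = 0.6,
                         fraction_ambiguous = 0.05,
                         fraction_wgd_of_duplicate = 0.5,
                         unalignable_count = 0)
  u <- generateUniverse(cfg)
  n <- nrow(u)
  for (spec in list(c(0.60, sum(u$class == "duplicate")),
                    c(0.05, sum(u$class == "ambiguous")),
                    c(0.35, sum(u$class == "singleton")))) {
    p <- spec[1]
    expect_lt(abs(spec[2] - n * p), 3 * sqrt(n * p * (1 - p)) + 1)
  }
  nDup <- sum(u$class == "duplicate")
  nWGD <- sum(u$mechanism == "WGD", na.rm = TRUE)
  expect_lt(abs(nWGD - nDup / 2), 3 * sqrt(nDup * 0.25) + 1)

  u0 <- generateUniverse(syntheticConfig(n_genes = 200, seed = 2,
                                         fraction_duplicate = 0,
                                         fraction_ambiguous = 0,
                                         unalignable_count = 0))
  expect_true(all(u0$class == "singleton"))
})

test_that("similarity hits round-trip to the planted labels", {
  cfg <- syntheticConfig(n_genes = 3000, seed = 16, unalignable_count = 25)
  u <- generateUniverse(cfg)
  hits <- generateSimilarityHits(u, cfg)
  calls <- classifySimilarity(u$gene_id, hits)
  expect_equal(setNames(calls$verdict, calls$gene_id)[u$gene_id],
               setNames(u$class, u$gene_id))
  expect_equal(sum(calls$verdict == "excluded"), 25L)

  cfg0 <- syntheticConfig(n_genes = 300, seed = 16, fraction_duplicate = 0)
  u0 <- generateUniverse(cfg0)
  h0 <- generateSimilarityHits(u0, cfg0)
  c0 <- classifySimilarity(u0$gene_id, h0)
  expect_equal(sum(c0$verdict == "duplicate"), 0L)
})

test_that("self-loop rates honour the base rate when no effects are planted", {
  cfg <- syntheticConfig(n_genes = 6000, seed = 18,
                         self_interaction_base_rate = 0.2,
                         degree_self_coupling = 0,
                         planted_or_self_vs_duplicate = 1)
  u <- generateUniverse(cfg)
  net <- generateNetwork(u, cfg)
  tr <- merge(u, net$truth, by = "gene_id")
  for (cls in c("duplicate", "singleton")) {
    x <- tr$self[tr$class == cls]
    expect_lt(abs(sum(x) - 0.2 * length(x)),
              3 * sqrt(length(x) * 0.2 * 0.8) + 1)
  }
  # edges-per-gene m gives ~ m*n non-self edges
  nNonself <- sum(net$edges$from != net$edges$to)
  expect_equal(nNonself, cfg$edges_per_gene * nrow(u),
               tolerance = 0.01)
})

test_that("ortholog, ohnolog and annotation outputs are mutually consistent", {
  cfg <- syntheticConfig(n_genes = 1200, seed = 19, reclassified_count = 30)
  b <- generateBundle(cfg)
  ids <- b$universe$gene_id
  expect_true(all(b$orthologs$human_id %in% ids))
  expect_true(all(b$ohnologs %in% ids))
  expect_true(all(b$annotations$gene_id %in% ids))
  expect_true(all(c(b$ks$gene1, b$ks$gene2) %in% ids))
  expect_true(all(c(b$edges$from, b$edges$to) %in% ids))
  expect_true(all(b$annotations$term_id %in% b$slim_map$full_term_id))

  # planted reclassified count round-trips through assign_mechanism
  calls <- classifySimilarity(ids, b$hits)
  m <- assignMechanism(calls, b$ohnologs)
  expect_equal(attr(m, "report")$n_reclassified, 30L)

  # one2many disabled -> orthology classifier finds no duplicates
  cfg0 <- syntheticConfig(n_genes = 400, seed = 20, one2many_prob = 0)
  b0 <- generateBundle(cfg0)
  o0 <- classifyOrthology(b0$universe$gene_id, b0$orthologs)
  expect_equal(sum(o0$verdict == "duplicate"), 0L)
})

test_that("written bundles re-read into the same data (parse fixpoint)", {
  cfg <- syntheticConfig(n_genes = 500, seed = 22)
  b <- generateBundle(cfg)
  d <- withr::local_tempdir()
  writeBundle(b, d)

  net <- loadNetwork(file.path(d, "ppi_edges.tsv"))
  expect_equal(nrow(networkEdges(net)),
               nrow(unique(canonical <- data.frame(
                 from = pmin(b$edges$from, b$edges$to),
                 to = pmax(b$edges$from, b$edges$to)))))
  hits <- readSimilarityHits(file.path(d, "similarity_hits.tsv"))
  expect_equal(nrow(hits), nrow(b$hits))
  orth <- readOrthologMap(file.path(d, "orthologs.tsv"))
  expect_equal(orth, b$orthologs)
  expect_equal(readIdList(file.path(d, "ohnolog_ids.txt")), b$ohnologs)
  expect_equal(readKsTable(file.path(d, "ks_pairs.tsv")), b$ks)
  expect_equal(readAnnotations(file.path(d, "annotations.tsv")),
               b$annotations)

  # re-emitting the parsed files is byte-stable
  d2 <- withr::local_tempdir()
  writeBundle(b, d2)
  expect_identical(readLines(file.path(d, "similarity_hits.tsv")),
                   readLines(file.path(d2, "similarity_hits.tsv")))
})

test_that("infeasible configurations are rejected", {
  expect_error(syntheticConfig(fraction_duplicate = 0.8,
                               fraction_ambiguous = 0.3), "exceeds 1")
  expect_error(syntheticConfig(n_genes = 100, unalignable_count = 101),
               "unalignable")
  expect_error(syntheticConfig(self_interaction_base_rate = 0))
})
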