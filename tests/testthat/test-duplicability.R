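test_that("best non-self hit follows E-value, bit score, subject-id ordering", {
  onlySelf <- makeHits("A", "A", 0)
  expect_null(bestNonselfHit(onlySelf))

  two <- makeHits(c("A", "A"), c("B", "C"), c(1e-5, 1e-30))
  expect_equal(bestNonselfHit(two)$subject_id, "C")

  set.seed(51)
  h <- makeHits(rep("Q", 50), sprintf("s%02d", sample(50)),
                evalue = 10^sample(-40:-1, 50, replace = TRUE),
                bits = sample(50:500, 50, replace = TRUE))
  best <- bestNonselfHit(h)
  o <- h[order(h$evalue, -h$bit_score, h$subject_id), ]
  expect_equal(best, o[1, ], ignore_attr = TRUE)
})

test_that("similarity classification applies the E-value and coverage thresholds", {
  hits <- rbind(
    makeHits("dup", "dup", 0),
    makeHits("dup", "x", 1e-25, alen = 160, qlen = 200, slen = 228),  # 0.8/0.7
    makeHits("amb", "amb", 0),
    makeHits("amb", "x", 1e-5),
    makeHits("cov", "cov", 0),
    makeHits("cov", "x", 1e-25, alen = 60, qlen = 200, slen = 200),   # 0.3
    makeHits("sing", "sing", 0),
    makeHits("sing", "x", 0.5)
  )
  calls <- classifySimilarity(c("dup", "amb", "cov", "sing", "nohit"), hits)
  v <- setNames(calls$verdict, calls$gene_id)
  expect_equal(unname(v[c("dup", "amb", "cov", "sing", "nohit")]),
               c("duplicate", "ambiguous", "ambiguous", "singleton",
                 "excluded"))
  expect_equal(calls$reason[calls$gene_id == "nohit"], "unalignable")
  expect_equal(calls$reason[calls$gene_id == "cov"], "low_aligned_fraction")

  bad <- makeHits("A", "B", 1e-30, qlen = 0)
  expect_error(classifySimilarity("A", bad), "non-positive length")
  expect_error(classifySimilarity("A", makeHits("A", "B", 1e-5),
                                  eSingleton = 1e-30, eDuplicate = 1e-20))
})

test_that("verdicts partition the universe and grow monotonically in e_duplicate", {
  cfg <- syntheticConfig(n_genes = 1500, seed = 8)
  b <- generateBundle(cfg)
  calls <- classifySimilarity(b$universe$gene_id, b$hits)
  expect_setequal(calls$gene_id, b$universe$gene_id)
  expect_equal(anyDuplicated(calls$gene_id), 0L)
  expect_true(all(calls$verdict %in%
                    c("singleton", "duplicate", "ambiguous", "excluded")))

  # raising e_duplicate toward e_singleton never shrinks the duplicate set
  dupSets <- lapply(c(1e-20, 1e-10, 1e-4), function(ed) {
    c2 <- classifySimilarity(b$universe$gene_id, b$hits, eDuplicate = ed)
    c2$gene_id[c2$verdict == "duplicate"]
  })
  expect_true(all(dupSets[[1]] %in% dupSets[[2]]))
  expect_true(all(dupSets[[2]] %in% dupSets[[3]]))
  # and no gene ever moves duplicate -> singleton
  cLow <- classifySimilarity(b$universe$gene_id, b$hits, eDuplicate = 1e-20)
  cHigh <- classifySimilarity(b$universe$gene_id, b$hits, eDuplicate = 1e-4)
  moved <- cLow$verdict == "duplicate" & cHigh$verdict == "singleton"
  expect_false(any(moved))
})

test_that("orthology classification maps cardinality to duplicability", {
  m <- data.frame(
    human_id = c("H1", "H2", "H2", "H3"),
    mouse_id = c("M1", "M2", "M3", "M4"),
    relation = c("one2one", "one2many", "one2many", "other"),
    stringsAsFactors = FALSE
  )
  calls <- classifyOrthology(c("H1", "H2", "H3", "H4"), m)
  expect_equal(calls$verdict, c("singleton", "duplicate", "excluded",
                                "excluded"))
  expect_equal(calls$reason[3:4], c("relation_other", "no_ortholog_record"))

  badMap <- data.frame(human_id = "H1", mouse_id = "M1",
                       relation = "one2many", stringsAsFactors = FALSE)
  expect_error(classifyOrthology("H1", badMap), "fewer than 2")
})

test_that("mechanism assignment merges the ohnolog list over similarity calls", {
  calls <- data.frame(
    gene_id = c("d1", "d2", "s1", "a1", "e1"),
    verdict = c("duplicate", "duplicate", "singleton", "ambiguous",
                "excluded"),
    stringsAsFactors = FALSE
  )
  expect_warning(m <- assignMechanism(calls, c("d1", "s1", "a1", "ghost")),
                 "skipped")
  rec <- setNames(m$source, m$gene_id)
  expect_equal(unname(rec[c("d1", "s1", "a1", "d2")]),
               c("ohnolog_list", "reclassified", "reclassified",
                 "similarity_only"))
  expect_equal(setNames(m$mechanism, m$gene_id)[["d2"]], "SSD")
  expect_false("e1" %in% m$gene_id)  # excluded, not on the list
  # WGD and SSD disjoint, union = duplicates + listed genes
  expect_equal(anyDuplicated(m$gene_id), 0L)
  rep <- attr(m, "report")
  expect_equal(rep$n_reclassified, 2L)
  expect_equal(rep$n_ohnolog_skipped, 1L)
  expect_equal(sum(rep$reclassified_by_prior_verdict), 2L)
})

test_that("reclassified bookkeeping equals the ohnolog/non-duplicate overlap", {
  cfg <- syntheticConfig(n_genes = 1500, seed = 9)
  b <- generateBundle(cfg)
  calls <- classifySimilarity(b$universe$gene_id, b$hits)
  m <- assignMechanism(calls, b$ohnologs)
  nonDup <- calls$gene_id[calls$verdict != "duplicate"]
  expect_equal(attr(m, "report")$n_reclassified,
               length(intersect(b$ohnologs, nonDup)))
  expect_length(intersect(m$gene_id[m$mechanism == "WGD"],
                          m$gene_id[m$mechanism == "SSD"]), 0L)
})
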