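test_that("simulated expected counts match hypergeometric moments", {
  expect_equal(simulateExpected(0, 50, 10, 100, seed = 1),
               list(mean = 0, sd = 0))
  expect_equal(simulateExpected(50, 50, 10, 100, seed = 1),
               list(mean = 10, sd = 0))

  s <- simulateExpected(20, 100, 25, 50000, seed = 42)
  hyMean <- 25 * 20 / 100
  hyVar <- 25 * (20 / 100) * (80 / 100) * (75 / 99)
  mcSE <- sqrt(hyVar / 50000)
  expect_lt(abs(s$mean - hyMean), 3 * mcSE)
  expect_equal(s$sd, sqrt(hyVar), tolerance = 0.05)
  # reproducible under seed
  expect_identical(s, simulateExpected(20, 100, 25, 50000, seed = 42))
  expect_error(simulateExpected(5, 10, 5, 0, seed = 1), "nSims")
})

test_that("hypergeometric tail equals subset enumeration on small universes", {
  # N=10, K=4, n=5, obs=4: 6 of the 252 draws have >= 4 annotated
  expect_equal(hypergeomTailP(4, 4, 10, 5), 6 / 252, tolerance = 1e-12)
  # symmetric case: observing the central value leaves at least half the mass
  expect_gte(hypergeomTailP(round(5 * 5 / 10), 5, 10, 5), 0.5 - 1e-12)
  expect_error(hypergeomTailP(6, 4, 10, 5), "inconsistent")

  # direct enumeration over all n-subsets for a band of small cases
  for (N in c(6, 9)) {
    for (n in c(2, 4)) {
      subsets <- combn(N, n)
      for (K in c(0, 2, N - 1)) {
        counts <- colSums(subsets <= K)
        for (obs in max(0, n + K - N):min(K, n)) {
          pEnum <- if (obs >= n * K / N) mean(counts >= obs)
                   else mean(counts <= obs)
          expect_equal(hypergeomTailP(obs, K, N, n), pEnum,
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("enrichment finds a planted over-represented term first", {
  set.seed(55)
  N <- 2000
  genes <- sprintf("g%04d", 1:N)
  focal <- sample(genes, 400)
  inFocal <- genes %in% focal
  terms <- sprintf("T%02d", 1:12)
  rate <- runif(12, 0.05, 0.2)
  ann <- do.call(rbind, lapply(1:12, function(i) {
    r <- rep(rate[i], N)
    if (i == 5) r[inFocal] <- r[inFocal] * 3  # planted 3x enrichment
    a <- runif(N) < r
    data.frame(gene_id = genes[a], term_id = terms[i],
               stringsAsFactors = FALSE)
  }))
  tns <- data.frame(term_id = terms, namespace = "biological_process",
                    stringsAsFactors = FALSE)
  r <- runEnrichment(focal, genes, ann, tns, nSims = 1000, seed = 3)
  expect_equal(r$term_id[1], "T05")
  expect_equal(r$direction[1], "over")
  expect_true(r$significant[1])
  # Bonferroni bookkeeping: m = terms in the namespace, p_adj = min(1, m p)
  expect_true(all(r$m == 12L))
  expect_equal(r$p_adjusted, pmin(1, 12 * r$p_raw))
  expect_equal(sort(r$p_adjusted),
               sort(unname(stats::p.adjust(r$p_raw, "bonferroni"))))
})

test_that("enrichment of the background against itself is null", {
  set.seed(56)
  genes <- sprintf("g%03d", 1:300)
  ann <- data.frame(gene_id = sample(genes, 150, replace = TRUE),
                    term_id = sample(c("A", "B", "C"), 150, replace = TRUE),
                    stringsAsFactors = FALSE)
  tns <- data.frame(term_id = c("A", "B", "C"),
                    namespace = c("biological_process",
                                  "molecular_function",
                                  "molecular_function"),
                    stringsAsFactors = FALSE)
  r <- runEnrichment(genes, genes, ann, tns, nSims = 200, seed = 5)
  expect_equal(r$observed, r$K)
  expect_equal(r$sd, rep(0, nrow(r)))          # focal = background: no spread
  expect_false(any(r$z_available))             # z unavailable when sd = 0
  expect_true(all(r$p_raw == 1))               # exact p still reported
  # namespaces carry their own Bonferroni multiplier
  expect_equal(r$m[r$namespace == "biological_process"][1], 1L)
  expect_equal(r$m[r$namespace == "molecular_function"][1], 2L)
  expect_error(runEnrichment(c(genes, "zz"), genes, ann, tns,
                             nSims = 10, seed = 1), "subset")
})

test_that("enrichment results are order-invariant and seed-reproducible", {
  set.seed(57)
  genes <- sprintf("g%03d", 1:200)
  focal <- sample(genes, 60)
  ann <- data.frame(gene_id = sample(genes, 300, replace = TRUE),
                    term_id = sample(sprintf("T%d", 1:6), 300, replace = TRUE),
                    stringsAsFactors = FALSE)
  tns <- data.frame(term_id = sprintf("T%d", 1:6),
                    namespace = "biological_process",
                    stringsAsFactors = FALSE)
  r1 <- runEnrichment(focal, genes, ann, tns, nSims = 300, seed = 11)
  r2 <- runEnrichment(sample(focal), sample(genes),
                      ann[sample(nrow(ann)), ], tns,
                      nSims = 300, seed = 11)
  expect_equal(r1, r2)
})

test_that("GO-slim mapping collapses fine terms before analysis", {
  ann <- data.frame(gene_id = c("g1", "g1", "g2", "g3"),
                    term_id = c("F1", "F2", "F1", "Funmapped"),
                    stringsAsFactors = FALSE)
  slim <- data.frame(full = c("F1", "F2"), slim = c("S", "S"),
                     stringsAsFactors = FALSE)
  out <- applyGoSlim(ann, slim)
  expect_equal(out, data.frame(gene_id = c("g1", "g2"),
                               term_id = c("S", "S"),
                               stringsAsFactors = FALSE))
})
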