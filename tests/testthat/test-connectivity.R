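test_that("equal-frequency bins split near-equally with remainder up front", {
  b9 <- equalFrequencyBins(letters[1:9], c(5, 3, 8, 1, 9, 2, 7, 4, 6), 3)
  expect_equal(b9$summary$n, c(3L, 3L, 3L))
  b10 <- equalFrequencyBins(letters[1:10], sample(100, 10), 3)
  expect_equal(b10$summary$n, c(4L, 3L, 3L))
  expect_error(equalFrequencyBins(letters[1:3], 1:3, 0), "nBins")
  expect_error(equalFrequencyBins(letters[1:3], 1:3, 5), "exceeds")
})

test_that("tied values never straddle a boundary; sizes match the walk oracle", {
  set.seed(91)
  for (i in 1:10) {
    v <- sample(1:20, 200, replace = TRUE)  # heavy ties
    ids <- sprintf("i%03d", 1:200)
    bins <- equalFrequencyBins(ids, v, 7)
    a <- bins$assignment
    # every item in exactly one bin
    expect_equal(nrow(a), 200L)
    expect_equal(anyDuplicated(a$id), 0L)
    # equal values share a bin
    expect_true(all(tapply(a$bin, a$value, function(b) length(unique(b))) == 1))
    expect_equal(bins$summary$n, oracleBinSizes(v, 7))
    # ranges ordered and non-overlapping
    s <- bins$summary
    expect_true(all(s$lo[-1] > s$hi[-nrow(s)]))
  }
})

test_that("per-bin proportions pool back to the global proportion", {
  set.seed(92)
  ids <- sprintf("i%03d", 1:500)
  bins <- equalFrequencyBins(ids, rnorm(500), 10)
  expect_equal(binProportions(bins, ids)$proportion, rep(1, 10))
  expect_equal(binProportions(bins, character(0))$proportion, rep(0, 10))
  marked <- sample(ids, 137)
  p <- binProportions(bins, marked)
  expect_equal(sum(p$n_marked) / sum(p$n), 137 / 500)
  expect_equal(sum(p$proportion * p$n), 137)
  expect_error(binProportions(bins, "zzz"), "not among")
})

test_that("planted degree-WGD coupling yields rising WGD proportions across bins", {
  cfg <- syntheticConfig(n_genes = 5000, seed = 12, degree_wgd_coupling = 0.1)
  b <- generateBundle(cfg)
  dup <- b$truth[b$truth$class == "duplicate", ]
  bins <- equalFrequencyBins(dup$gene_id, dup$degree, 8)
  p <- binProportions(bins, dup$gene_id[dup$mechanism == "WGD"])
  expect_gt(cor(p$bin, p$proportion, method = "spearman"), 0)
})

test_that("logistic regression recovers planted slopes and flags degenerate input", {
  # null: outcome independent of degree
  set.seed(7)
  k <- rpois(2000, 6)
  y <- rbinom(2000, 1, 0.4)
  f0 <- fitDegreeLogistic(y, k)
  expect_gt(f0$p_slope, 0.01)
  expect_lt(abs(f0$slope), 0.1)
  expect_true(f0$converged)

  # planted slope 0.1 per unit degree at n = 5000
  set.seed(17)
  k <- rpois(5000, 8)
  y <- rbinom(5000, 1, plogis(-0.8 + 0.1 * k))
  f1 <- fitDegreeLogistic(y, k)
  expect_gt(f1$slope, 0.07)
  expect_lt(f1$slope, 0.13)

  expect_error(fitDegreeLogistic(rep(1, 10), 1:10), "single class")
  expect_error(fitDegreeLogistic(rep(0:1, 5), rep(3, 10)), "constant")

  # complete separation is flagged, not fatal
  sep <- fitDegreeLogistic(c(rep(0, 20), rep(1, 20)),
                           c(seq(1, 5, length.out = 20),
                             seq(6, 10, length.out = 20)))
  expect_false(sep$converged)
  expect_true(sep$separation)
})

test_that("logistic fit covers its own generating parameters at 3 SE", {
  set.seed(27)
  hits <- vapply(1:200, function(i) {
    k <- rpois(400, 6)
    y <- rbinom(400, 1, plogis(-0.5 + 0.12 * k))
    f <- fitDegreeLogistic(y, k)
    abs(f$slope - 0.12) <= 3 * f$se_slope &&
      abs(f$intercept - (-0.5)) <= 3 * f$se_intercept
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("Ks-binned mean connectivity behaves on degenerate and planted input", {
  ks <- data.frame(gene1 = c("a", "c"), gene2 = c("b", "d"),
                   ks = c(0.2, 1.5), stringsAsFactors = FALSE)
  deg <- c(a = 4, b = 4, c = 4, d = 4)
  km <- ksBinMeans(ks, deg, 2)
  expect_equal(km$mean_degree, c(4, 4))

  # 2 gene records per pair: two bins hold one pair each
  deg2 <- c(a = 2, b = 4, c = 6, d = 8)
  km2 <- ksBinMeans(ks, deg2, 2)
  expect_equal(km2$mean_degree, c(3, 7))

  expect_error(ksBinMeans(ks, c(a = 1, b = 2, c = 3), 2), "no degree.*d")

  # permutation invariance
  set.seed(37)
  ksBig <- data.frame(gene1 = sprintf("p%03d", 1:300),
                      gene2 = sprintf("q%03d", 1:300),
                      ks = round(rlnorm(300, 0, 0.6), 3),
                      stringsAsFactors = FALSE)
  degBig <- setNames(rpois(600, 5) + 1,
                     c(ksBig$gene1, ksBig$gene2))
  a <- ksBinMeans(ksBig, degBig, 6)
  b <- ksBinMeans(ksBig[sample(300), ], degBig, 6)
  expect_equal(a, b)
})

test_that("older (high-Ks) duplicates show higher mean connectivity when planted", {
  cfg <- syntheticConfig(n_genes = 4000, seed = 13,
                         degree_wgd_coupling = 0.15,
                         ks_mean_wgd = 1.5, ks_mean_ssd = 0.4)
  b <- generateBundle(cfg)
  deg <- setNames(b$truth$degree, b$truth$gene_id)
  km <- ksBinMeans(b$ks, deg, 8)
  expect_gt(cor(km$bin, km$mean_degree, method = "spearman"), 0)
  # top Ks bin is WGD-majority when WGD pairs are much older
  mech <- setNames(b$truth$mechanism, b$truth$gene_id)
  pairMech <- mech[b$ks$gene1]
  topThird <- b$ks$ks >= quantile(b$ks$ks, 2 / 3)
  expect_gt(mean(pairMech[topThird] == "WGD"), 0.5)
})
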