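test_that("t statistics and p-values match the textbook formulas", {
  case <- c(0.60, 0.70, 0.68)
  control <- c(0.30, 0.29, 0.31)
  for (variant in c("student", "welch")) {
    got <- groupTTest(case, control, variant = variant)
    want <- tOracle(case, control, variant = variant)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
    expect_equal(got$p.value, want$p.value, tolerance = 1e-10)
  }
  set.seed(4)
  for (i in 1:50) {
    x <- rnorm(sample(2:6, 1)); y <- rnorm(sample(2:6, 1), sd = runif(1, .5, 2))
    for (variant in c("student", "welch")) {
      got <- groupTTest(x, y, variant = variant)
      want <- tOracle(x, y, variant = variant)
      expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
      expect_equal(got$p.value, want$p.value, tolerance = 1e-10)
    }
  }
})

test_that("t-test symmetry and degenerate groups behave", {
  x <- c(0.2, 0.3, 0.4)
  expect_equal(groupTTest(x, x), list(statistic = 0, p.value = 1))
  a <- c(0.6, 0.7, 0.65); b <- c(0.2, 0.25, 0.22)
  fwd <- groupTTest(a, b); rev <- groupTTest(b, a)
  expect_equal(fwd$statistic, -rev$statistic)
  expect_equal(fwd$p.value, rev$p.value)
  # zero variance in both groups, unequal means: degenerate, flagged
  expect_warning(d <- groupTTest(c(1, 1), c(0, 0)), "degenerate")
  expect_equal(d$p.value, 0)
  expect_true(is.infinite(d$statistic) && d$statistic > 0)
})

test_that("log2 fold change reproduces the published worked examples", {
  expect_equal(round(log2FoldChange(0.660, 0.293), 2), 1.17)
  expect_equal(round(log2FoldChange(0.336, 0.804), 2), -1.26)
  expect_equal(log2FoldChange(0.37, 0.37), 0)
  expect_equal(log2FoldChange(0.482, 0.241), 1)   # exactly 2-fold
  expect_error(log2FoldChange(0, 0.5), "positive")
})

test_that("BH adjustment matches a quadratic-time oracle", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.3), 0.3)
  set.seed(77)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    got <- bhAdjust(p)
    expect_equal(got, bhOracle(p), tolerance = 1e-12)
    expect_true(all(got >= p & got <= 1))
    o <- order(p)
    expect_true(all(diff(got[o]) >= -1e-15))  # monotone in the order stats
  }
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("DM classification pins the inclusive fold-change boundary", {
  expect_equal(as.character(classifyDM(1.17, 0.016)), "up")
  expect_equal(as.character(classifyDM(1.00, 0.045)), "up")  # |FC| >= 2
  expect_equal(as.character(classifyDM(-1.00, 0.04)), "down")
  expect_equal(as.character(classifyDM(0.90, 0.001)), "ns")
  expect_equal(as.character(classifyDM(2.00, 0.05)), "ns")   # p strict
  expect_equal(as.character(classifyDM(1.14, 0.049)), "up")
})

test_that("runDifferential recovers a planted effect and ignores order", {
  sim <- simulateExperiment(noiseFreeConfig(n = 50, seed = 19))
  me <- quantifyMethylation(sim$raw, sim$annotation)
  # plant one exactly 2.5x transcript by hand on the noise-free fractions
  pm <- pctModified(me)
  pm["TX_00007", sampleGroups(me) == "case"] <-
    pmin(pm["TX_00007", sampleGroups(me) == "case"] * 2.5, 0.99) +
    c(1e-4, 0, -1e-4)   # tiny jitter so the variance is nonzero
  me2 <- m6Aarray:::newMethylationExperiment(
    pm, rowData(me)$geneSymbol, rowData(me)$biotype, colData(me))
  dm <- runDifferential(me2)
  expect_equal(as.character(
    dm$direction[dm$transcriptId == "TX_00007"]), "up")

  perm <- sample(ncol(me2))
  dmPerm <- runDifferential(me2[, perm])
  expect_equal(dmPerm, dm, tolerance = 1e-12)
})

test_that("FDR is adjusted within each biotype stratum", {
  sim <- simulateExperiment(
    simulationConfig(nMrna = 60, nLncrna = 30, nMirna = 15, nDM = 10,
                     seed = 55))
  dm <- runDifferential(quantifyMethylation(sim$raw, sim$annotation))
  for (bt in unique(dm$biotype)) {
    i <- dm$biotype == bt
    expect_equal(dm$fdr[i], bhOracle(dm$pValue[i]), tolerance = 1e-12)
  }
  # pooled adjustment would generally differ
  expect_false(isTRUE(all.equal(dm$fdr, bhOracle(dm$pValue))))
  expect_true(all(dm$fdr >= dm$pValue & dm$fdr <= 1))
  expect_equal(sign(dm$log2fc), sign(dm$caseMean - dm$controlMean))
})

test_that("type-I error is near nominal under the null model", {
  sim <- simulateExperiment(
    simulationConfig(nMrna = 2000, nLncrna = 0, nMirna = 0, nDM = 0,
                     seed = 42))
  dm <- runDifferential(quantifyMethylation(sim$raw, sim$annotation))
  rate <- mean(dm$pValue < 0.05)
  # 99.9% binomial band around 0.05 at n = 2000
  expect_gt(rate, 0.05 - 3.29 * sqrt(0.05 * 0.95 / 2000))
  expect_lt(rate, 0.05 + 3.29 * sqrt(0.05 * 0.95 / 2000))
})

test_that("transcripts with missing values are excluded with a message", {
  sim <- simulateExperiment(noiseFreeConfig(n = 20, seed = 23))
  me <- quantifyMethylation(sim$raw, sim$annotation)
  pm <- pctModified(me)
  pm[3, 1] <- NA
  me2 <- m6Aarray:::newMethylationExperiment(
    pm, rowData(me)$geneSymbol, rowData(me)$biotype, colData(me))
  expect_message(dm <- runDifferential(me2), "1 transcripts with missing")
  expect_equal(nrow(dm), 19)
})
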