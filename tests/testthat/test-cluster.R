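test_that("hand-computed merges on three collinear points", {
  m <- matrix(c(0, 1, 3), ncol = 1,
              dimnames = list(c("a", "b", "c"), "x"))
  dend <- hierarchicalCluster(m, "rows")   # euclidean, complete
  expect_equal(mergeHeights(dend), c(1, 3))
  sets <- mergeLeafSets(dend@merge)
  expect_equal(sets[[1]], c(1, 2))         # {0,1} first, at height 1
  expect_equal(sets[[2]], c(1, 2, 3))      # then joined with {3} at 3
})

test_that("identical rows merge first at height zero", {
  m <- rbind(a = c(1, 2), b = c(5, 5), c = c(1, 2))
  dend <- hierarchicalCluster(m, "rows")
  expect_equal(mergeHeights(dend)[1], 0)
  expect_equal(mergeLeafSets(dend@merge)[[1]], c(1, 3))
  # constant matrix: all merges at height 0, no error
  const <- matrix(0.4, 4, 3, dimnames = list(letters[1:4], NULL))
  expect_equal(mergeHeights(hierarchicalCluster(const, "rows")),
               rep(0, 3))
})

test_that("dendrograms match an exhaustive-search reference agglomerator", {
  set.seed(61)
  for (i in 1:100) {
    m <- matrix(rnorm(36), 6, 6, dimnames = list(paste0("r", 1:6), NULL))
    for (linkage in c("complete", "average")) {
      dend <- hierarchicalCluster(m, "rows", linkage = linkage)
      ref <- refAgglomerate(m, linkage = linkage)
      expect_equal(canonMerges(mergeHeights(dend),
                               mergeLeafSets(dend@merge)),
                   canonMerges(ref$heights, ref$merges))
      expect_setequal(leafOrder(dend), 1:6)
      expect_true(all(diff(mergeHeights(dend)) >= -1e-12))
    }
  }
})

test_that("heatmap writes image plus reordered matrix in leaf order", {
  dir <- withr::local_tempdir()
  set.seed(3)
  m <- matrix(runif(18), 3, 6,
              dimnames = list(paste0("t", 1:3), paste0("s", 1:6)))
  path <- file.path(dir, "hm.png")
  res <- renderHeatmap(m, path, groups = rep(c("case", "control"), each = 3))
  expect_true(file.exists(path))
  reordered <- readMatrixTSV(res$reorderedMatrix)
  expect_identical(rownames(reordered),
                   rownames(m)[leafOrder(res$rowDendrogram)])
  expect_identical(colnames(reordered),
                   colnames(m)[leafOrder(res$colDendrogram)])
  expect_equal(unname(reordered),
               unname(m[leafOrder(res$rowDendrogram),
                        leafOrder(res$colDendrogram)]))
})

test_that("single-row heatmap drops the row dendrogram", {
  dir <- withr::local_tempdir()
  m <- matrix(runif(6), 1, 6,
              dimnames = list("t1", paste0("s", 1:6)))
  res <- renderHeatmap(m, file.path(dir, "one.png"))
  expect_null(res$rowDendrogram)
  expect_true(file.exists(file.path(dir, "one.png")))
})

test_that("planted group structure drives the top column split", {
  sim <- simulateExperiment(
    simulationConfig(nMrna = 300, nLncrna = 0, nMirna = 0, nDM = 40,
                     baselineAlpha = 2, baselineBeta = 10,
                     effectLogOdds = 2.5, noiseLogSd = 0.05,
                     arrayScaleLogSd = 0.1, flagAbsentProb = 0,
                     seed = 42))
  me <- quantifyMethylation(sim$raw, sim$annotation)
  dm <- runDifferential(me)
  dmTx <- dm$transcriptId[dm$direction != "ns"]
  dend <- hierarchicalCluster(pctModified(me)[dmTx, ], "columns")
  top <- cutree(as.hclust(dend), k = 2)
  expect_equal(length(unique(top[sampleGroups(me) == "case"])), 1)
  expect_equal(length(unique(top[sampleGroups(me) == "control"])), 1)
  expect_false(top[1] == top[ncol(me)])
})

test_that("volcano plot colors agree with the classification counts", {
  dir <- withr::local_tempdir()
  dm <- data.frame(
    log2fc = c(1.17, -1.26, 0, 2, -3),
    pValue = c(0.016, 0.005, 0.5, 0.2, 0.01))
  dm$direction <- classifyDM(dm$log2fc, dm$pValue)
  gg <- volcanoPlot(dm, file.path(dir, "v.png"))
  expect_true(file.exists(file.path(dir, "v.png")))
  built <- ggplot2::ggplot_build(gg)$data[[1]]
  counts <- table(built$colour)
  expect_equal(unname(counts[["red"]]), sum(dm$direction == "up"))
  expect_equal(unname(counts[["green3"]]), sum(dm$direction == "down"))
  expect_equal(unname(counts[["gray60"]]), sum(dm$direction == "ns"))
  # zero p-values are clamped, not dropped
  dm0 <- data.frame(log2fc = 1.5, pValue = 0,
                    direction = classifyDM(1.5, 0))
  expect_message(volcanoPlot(dm0, file.path(dir, "v0.png")), "clamped")
})
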