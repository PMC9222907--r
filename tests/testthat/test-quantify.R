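# helper: a RawArraySet built by hand for arithmetic checks
handRaw <- function(ip, sup, flags = NULL, spike, group) {
  if (is.null(flags)) flags <- matrix("P", nrow(ip), ncol(ip))
  RawArraySet(ip, sup, flags, spike, group)
}

test_that("spike-in calibration matches hand arithmetic", {
  # probe raw 1024 with spike-in raws {512, 2048}: mean log2 spike-in = 10,
  # so the normalized log2 is 10 - 10 = 0
  ip <- matrix(c(1024, 512, 2048), 3, 2,
               dimnames = list(c("pr", "sp1", "sp2"), c("s1", "s2")))
  raw <- handRaw(ip, ip, spike = c(FALSE, TRUE, TRUE),
                 group = c("case", "control"))
  norm <- spikeinNormalize(raw)
  expect_equal(unname(assay(norm, "ipLog2")["pr", ]), c(0, 0))
  expect_equal(unname(spikeinLog2Mean(norm)["cy5", ]), c(10, 10))
  # spike-ins themselves average to zero after normalization
  expect_equal(mean(assay(norm, "ipLog2")[c("sp1", "sp2"), "s1"]), 0)
})

test_that("all-ones spike-ins leave plain log2 intensities", {
  ip <- matrix(c(8, 1), 2, 2, dimnames = list(c("pr", "sp"), c("a", "b")))
  sup <- matrix(c(2, 1), 2, 2, dimnames = dimnames(ip))
  raw <- handRaw(ip, sup, spike = c(FALSE, TRUE),
                 group = c("case", "control"))
  norm <- spikeinNormalize(raw)
  expect_equal(unname(assay(norm, "ipLog2")["pr", ]), c(3, 3))
  expect_equal(unname(assay(norm, "supLog2")["pr", ]), c(1, 1))
})

test_that("per-channel rescaling of one array cancels exactly", {
  sim <- simulateExperiment(simulationConfig(nMrna = 60, nLncrna = 0,
                                             nMirna = 0, nDM = 10,
                                             seed = 33))
  raw <- sim$raw
  ip8 <- ipRaw(raw)
  ip8[, 2] <- ip8[, 2] * 8   # whole Cy5 channel of one array, spike-ins too
  scaled <- RawArraySet(ip8, supRaw(raw), qcFlags(raw), isSpikeIn(raw),
                        as.character(sampleGroups(raw)))
  n1 <- spikeinNormalize(raw)
  n2 <- spikeinNormalize(scaled)
  expect_equal(assay(n1, "ipLog2"), assay(n2, "ipLog2"), tolerance = 1e-12)
  m1 <- percentModified(n1, annotation = sim$annotation)
  m2 <- percentModified(n2, annotation = sim$annotation)
  expect_equal(pctModified(m1), pctModified(m2), tolerance = 1e-12)
})

test_that("arrays with dead spike-ins are refused by name", {
  ip <- matrix(c(8, 0), 2, 2, dimnames = list(c("pr", "sp"), c("a", "b")))
  raw <- handRaw(ip, ip, spike = c(FALSE, TRUE),
                 group = c("case", "control"))
  expect_error(suppressMessages(spikeinNormalize(raw)),
               "array a.*spike-in")
  noSpike <- handRaw(matrix(1, 1, 2, dimnames = list("pr", c("a", "b"))),
                     matrix(1, 1, 2), spike = FALSE,
                     group = c("case", "control"))
  expect_error(spikeinNormalize(noSpike), "no spike-in probes")
})

test_that("non-positive intensities are floored and counted", {
  ip <- matrix(c(0, 4), 2, 2, dimnames = list(c("pr", "sp"), c("a", "b")))
  sup <- matrix(c(16, 4), 2, 2, dimnames = dimnames(ip))
  raw <- handRaw(ip, sup, spike = c(FALSE, TRUE),
                 group = c("case", "control"))
  expect_message(norm <- spikeinNormalize(raw, epsilon = 1),
                 "2 non-positive intensities floored")
  # floored ip raw = 1 -> log2 = 0; calibration = 2
  expect_equal(unname(assay(norm, "ipLog2")["pr", ]), c(-2, -2))
})

test_that("QC retention implements the P/M in >= minPM rule", {
  flags <- rbind(AAAAAA = rep("A", 6),
                 PAAAAA = c("P", rep("A", 5)),
                 MAAAAA = c("M", rep("A", 5)),
                 PPPPPP = rep("P", 6))
  ip <- matrix(100, 5, 6,
               dimnames = list(c(rownames(flags), "sp"), paste0("s", 1:6)))
  raw <- handRaw(ip, ip, rbind(flags, sp = rep("P", 6)),
                 spike = c(rep(FALSE, 4), TRUE),
                 group = rep(c("case", "control"), each = 3))
  expect_setequal(qcFilter(raw), c("PAAAAA", "MAAAAA", "PPPPPP"))
  expect_setequal(qcFilter(raw, minPM = 2), "PPPPPP")
  expect_message(r <- qcFilter(raw, minPM = 7), "retained no probes")
  expect_length(r, 0)
})

test_that("%Modified follows IP/(IP + Sup) on the de-logged scale", {
  # normalized ip log2 = 3, sup log2 = 1  ->  8 / (8 + 2) = 0.8
  ip <- matrix(c(8, 1), 2, 2, dimnames = list(c("pr", "sp"), c("a", "b")))
  sup <- matrix(c(2, 1), 2, 2, dimnames = dimnames(ip))
  raw <- handRaw(ip, sup, spike = c(FALSE, TRUE),
                 group = c("case", "control"))
  me <- percentModified(spikeinNormalize(raw))
  expect_equal(unname(pctModified(me)["pr", ]), c(0.8, 0.8))

  # equal channels give exactly one half
  eq <- handRaw(ip, ip, spike = c(FALSE, TRUE),
                group = c("case", "control"))
  expect_equal(unname(pctModified(percentModified(
    spikeinNormalize(eq)))["pr", ]), c(0.5, 0.5))

  # floored Sup against a large IP approaches 1 from below
  big <- handRaw(matrix(c(2^20, 4), 2, 2,
                        dimnames = list(c("pr", "sp"), c("a", "b"))),
                 matrix(c(0, 4), 2, 2), spike = c(FALSE, TRUE),
                 group = c("case", "control"))
  v <- suppressMessages(
    pctModified(percentModified(spikeinNormalize(big)))["pr", ])
  expect_true(all(v < 1 & v > 0.999))
})

test_that("calibration constants differing between channels are honoured", {
  # Cy5 spike-ins at 16 (cal 4), Cy3 spike-ins at 4 (cal 2): the linear
  # reconstruction must use the normalized, not the raw, intensities
  ip <- matrix(c(32, 16), 2, 2, dimnames = list(c("pr", "sp"), c("a", "b")))
  sup <- matrix(c(8, 4), 2, 2, dimnames = dimnames(ip))
  raw <- handRaw(ip, sup, spike = c(FALSE, TRUE),
                 group = c("case", "control"))
  me <- percentModified(spikeinNormalize(raw))
  # normalized: ip 2^(5-4)=2, sup 2^(3-2)=2 -> 0.5; raw would give 0.8
  expect_equal(unname(pctModified(me)["pr", 1]), 0.5)
})

test_that("multi-probe transcripts aggregate by the mean", {
  ip <- matrix(c(8, 2, 4), 3, 2,
               dimnames = list(c("p1", "p2", "sp"), c("a", "b")))
  sup <- matrix(c(2, 8, 4), 3, 2, dimnames = dimnames(ip))
  raw <- handRaw(ip, sup, spike = c(FALSE, FALSE, TRUE),
                 group = c("case", "control"))
  ann <- S4Vectors::DataFrame(
    probeId = c("p1", "p2"), transcriptId = c("T1", "T1"),
    geneSymbol = c("G1", "G1"), biotype = c("mRNA", "mRNA"),
    row.names = c("p1", "p2"))
  me <- percentModified(spikeinNormalize(raw), annotation = ann)
  expect_equal(nrow(me), 1)
  expect_equal(unname(pctModified(me)["T1", 1]), mean(c(0.8, 0.2)))
})

test_that("%Modified always lies inside [0, 1] under random inputs", {
  set.seed(14)
  for (i in 1:5) {
    sim <- simulateExperiment(
      simulationConfig(nMrna = 40, nLncrna = 10, nMirna = 5, nDM = 8,
                       noiseLogSd = runif(1, 0, 0.6),
                       arrayScaleLogSd = runif(1, 0, 0.8),
                       seed = sample.int(1e6, 1)))
    me <- suppressMessages(quantifyMethylation(sim$raw, sim$annotation))
    expect_true(all(pctModified(me) >= 0 & pctModified(me) <= 1))
  }
})
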