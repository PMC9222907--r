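#' Configure the synthetic m6A array generator
#'
#' Builds a [SimulationConfig-class] describing a two-channel MeRIP array
#' experiment with known ground truth. Defaults give a desk-scale version
#' of a 3-case vs 3-control design (2,000 mRNA, 500 lncRNA and 200 small
#' ncRNA probes); the full-size array layout of ~36,790 mRNA, 8,540 lncRNA
#' and 2,377 small-ncRNA probes is obtained by raising the counts.
#'
#' The generative model works on the true methylation fraction f of each
#' transcript: f ~ Beta(baselineAlpha, baselineBeta); for the \code{nDM}
#' transcripts with a planted effect, cases get
#' plogis(qlogis(f) + effectLogOdds), which keeps the fraction inside
#' (0, 1) for any effect size. Total transcript abundance is log-normal;
#' the IP channel measures abundance x f and the Sup channel
#' abundance x (1 - f), each multiplied by a per-array per-channel scale
#' factor (shared with the spike-in probes, which carry the calibration
#' signal) and by log-normal measurement noise.
#'
#' @param nMrna,nLncrna,nMirna transcript probes per RNA biotype.
#' @param nSpikein number of spike-in control probes.
#' @param nCase,nControl group sizes.
#' @param baselineAlpha,baselineBeta Beta shape parameters of the baseline
#'   methylation fraction.
#' @param nDM number of transcripts with a planted case effect.
#' @param effectLogOdds planted shift on the log-odds (logit) scale.
#' @param abundanceLogMean,abundanceLogSd natural-log mean and sd of the
#'   per-transcript per-array total abundance.
#' @param arrayScaleLogSd natural-log sd of per-array per-channel scale
#'   factors (0 disables scale offsets).
#' @param noiseLogSd natural-log sd of multiplicative measurement noise.
#' @param flagAbsentProb probability a transcript-probe measurement is
#'   flagged Absent.
#' @param flagMarginalProb probability a detected measurement is flagged
#'   Marginal rather than Present.
#' @param spikeinLadder true spike-in abundances, recycled over the
#'   spike-in probes; identical in both channels.
#' @param seed integer seed; \code{NA} leaves the RNG state alone.
#' @return a validated [SimulationConfig-class].
#' @seealso [simulateExperiment()]
#' @export
simulationConfig <- function(nMrna = 2000L, nLncrna = 500L, nMirna = 200L,
                             nSpikein = 16L, nCase = 3L, nControl = 3L,
                             baselineAlpha = 2, baselineBeta = 4,
                             nDM = 40L, effectLogOdds = 2.5,
                             abundanceLogMean = 7, abundanceLogSd = 1,
                             arrayScaleLogSd = 0.3, noiseLogSd = 0.15,
                             flagAbsentProb = 0.1, flagMarginalProb = 0.05,
                             spikeinLadder = 1000 * 4^(0:3),
                             seed = NA_integer_) {
  new("SimulationConfig",
      nMrna = as.integer(nMrna), nLncrna = as.integer(nLncrna),
      nMirna = as.integer(nMirna), nSpikein = as.integer(nSpikein),
      nCase = as.integer(nCase), nControl = as.integer(nControl),
      baselineAlpha = baselineAlpha, baselineBeta = baselineBeta,
      nDM = as.integer(nDM), effectLogOdds = effectLogOdds,
      abundanceLogMean = abundanceLogMean, abundanceLogSd = abundanceLogSd,
      arrayScaleLogSd = arrayScaleLogSd, noiseLogSd = noiseLogSd,
      flagAbsentProb = flagAbsentProb, flagMarginalProb = flagMarginalProb,
      spikeinLadder = spikeinLadder, seed = as.integer(seed))
}

# log-normal draws, resampling the (practically impossible) non-finite or
# underflowed values rather than emitting them
rlnormSafe <- function(n, meanlog, sdlog) {
  x <- exp(stats::rnorm(n, meanlog, sdlog))
  bad <- !is.finite(x) | x <= 0
  while (any(bad)) {
    x[bad] <- exp(stats::rnorm(sum(bad), meanlog, sdlog))
    bad <- !is.finite(x) | x <= 0
  }
  x
}

#' Simulate a two-channel m6A array experiment with known truth
#'
#' Draws raw Cy5/IP and Cy3/Sup probe intensities under the generative
#' model described in [simulationConfig()] and returns them together with
#' the ground truth (per-transcript true fractions and planted effects,
#' per-array per-channel scale factors) and a probe annotation table.
#' Identical seeds give identical output.
#'
#' @param config a [SimulationConfig-class].
#' @return a list with elements \code{raw} (\linkS4class{RawArraySet}),
#'   \code{truth} (\linkS4class{SimulationTruth}) and \code{annotation}
#'   (DataFrame: probeId, transcriptId, geneSymbol, biotype).
#' @examples
#' sim <- simulateExperiment(simulationConfig(nMrna = 50, nLncrna = 10,
#'                                            nMirna = 5, seed = 1))
#' sim$raw
#' sim$truth
#' @export
simulateExperiment <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  if (!is.na(config@seed)) set.seed(config@seed)

  nT <- config@nMrna + config@nLncrna + config@nMirna
  nS <- config@nCase + config@nControl
  samples <- c(if (config@nCase) paste0("case_", seq_len(config@nCase)),
               if (config@nControl)
                 paste0("control_", seq_len(config@nControl)))
  group <- rep(c("case", "control"), c(config@nCase, config@nControl))
  biotypes <- rep(BIOTYPE_LEVELS,
                  c(config@nMrna, config@nLncrna, config@nMirna))

  txId <- sprintf("TX_%05d", seq_len(nT))
  gene <- sprintf("GENE%05d", seq_len(nT))
  probeTx <- sprintf("PR_%05d", seq_len(nT))
  probeSpike <- if (config@nSpikein)
    sprintf("SPIKE_%02d", seq_len(config@nSpikein)) else character()

  # per-transcript truth
  f0 <- stats::rbeta(nT, config@baselineAlpha, config@baselineBeta)
  f0 <- pmin(pmax(f0, 1e-6), 1 - 1e-6)
  isDM <- rep(FALSE, nT)
  if (config@nDM > 0L) isDM[sample.int(nT, config@nDM)] <- TRUE
  fCase <- ifelse(isDM, stats::plogis(stats::qlogis(f0) +
                                        config@effectLogOdds), f0)

  # per-array per-channel scale factors (carried by the spike-ins)
  scale <- matrix(rlnormSafe(2L * nS, 0, config@arrayScaleLogSd), nrow = 2,
                  dimnames = list(c("cy5", "cy3"), samples))

  nP <- nT + config@nSpikein
  ip <- matrix(0, nP, nS, dimnames = list(c(probeTx, probeSpike), samples))
  sup <- ip
  spikeTruth <- if (config@nSpikein)
    rep_len(config@spikeinLadder, config@nSpikein) else numeric()

  for (j in seq_len(nS)) {
    f <- if (group[j] == "case") fCase else f0
    abund <- rlnormSafe(nT, config@abundanceLogMean, config@abundanceLogSd)
    ip[seq_len(nT), j] <- abund * f * scale["cy5", j] *
      rlnormSafe(nT, 0, config@noiseLogSd)
    sup[seq_len(nT), j] <- abund * (1 - f) * scale["cy3", j] *
      rlnormSafe(nT, 0, config@noiseLogSd)
    if (config@nSpikein) {
      idx <- nT + seq_len(config@nSpikein)
      ip[idx, j] <- spikeTruth * scale["cy5", j] *
        rlnormSafe(config@nSpikein, 0, config@noiseLogSd)
      sup[idx, j] <- spikeTruth * scale["cy3", j] *
        rlnormSafe(config@nSpikein, 0, config@noiseLogSd)
    }
  }

  # Absent/Marginal/Present detection calls; spike-ins always Present
  u <- matrix(stats::runif(nP * nS), nP, nS)
  v <- matrix(stats::runif(nP * nS), nP, nS)
  flags <- matrix("P", nP, nS, dimnames = dimnames(ip))
  flags[v < config@flagMarginalProb] <- "M"
  flags[u < config@flagAbsentProb] <- "A"
  if (config@nSpikein) flags[nT + seq_len(config@nSpikein), ] <- "P"

  raw <- RawArraySet(ip, sup, flags,
                     isSpikeIn = c(rep(FALSE, nT),
                                   rep(TRUE, config@nSpikein)),
                     group = group)
  truth <- new("SimulationTruth",
    transcripts = DataFrame(transcriptId = txId, geneSymbol = gene,
                            biotype = biotypes, baselineFraction = f0,
                            caseFraction = fCase, isDM = isDM,
                            row.names = probeTx),
    arrayScale = scale)
  annotation <- DataFrame(probeId = probeTx, transcriptId = txId,
                          geneSymbol = gene, biotype = biotypes,
                          row.names = probeTx)
  list(raw = raw, truth = truth, annotation = annotation)
}
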