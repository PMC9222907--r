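# m6Aarray

Analysis of **m6A epitranscriptomic two-channel microarrays** — the
MeRIP array design in which each RNA sample is split by an anti-m6A
antibody into an immunoprecipitated fraction (IP, Cy5-labelled) and a
supernatant fraction (Sup, Cy3-labelled), both hybridized to the same
probes. The package is for analysts who get the raw two-channel
intensity exports of such arrays (e.g. from small case/control brain or
tissue studies) and need a transparent, testable route to differential
methylation calls.

## What it computes

Per array and channel, intensities are calibrated against exogenous
spike-in controls on the log2 scale,

```
log2(IP_norm) = log2(IP_raw) − mean[ log2(IP_spike-in,raw) ]
```

(and identically for Sup/Cy3), probes are filtered on
Present/Marginal/Absent detection flags (retained when P or M in ≥ 1
array by default), and the **m6A methylation level** of each transcript
is the fraction of modified RNA

```
%Modified = IP / (IP + Sup)          ∈ [0, 1]
```

on the normalized linear scale. Downstream:

* **differential methylation** — per-transcript two-sample t-test
  (Student pooled-variance by default, Welch selectable),
  `log2FC = log2(mean_case / mean_control)`, classification at
  |FC| ≥ 2 (inclusive) and p < 0.05 (strict), Benjamini–Hochberg FDR
  within each RNA biotype (mRNA / lncRNA / miRNA);
* **gene-set over-representation** — one-sided Fisher exact
  (hypergeometric upper tail) of DM gene symbols against GMT libraries,
  with the measured genes as universe and BH per library;
* **hierarchical clustering** (euclidean/complete by default) with
  red–green heatmaps, volcano plots, and the reordered matrix written as
  a bit-stable TSV;
* a **synthetic-data generator** with full ground truth (baseline Beta
  fractions, logit-scale planted effects, spike-in-carried scale
  factors, log-normal noise, P/M/A flags) so the entire pipeline is
  testable without any download.

## Worked example

Desk-scale check against a published DM table (3 AUD cases vs 3
controls, postmortem nucleus accumbens), bundled as
`audNacDMTable()` — the printed group means reproduce the printed log2
fold changes:

```r
library(m6Aarray)
tab <- audNacDMTable()
lfc <- log2FoldChange(tab$CaseMean, tab$ControlMean)
head(data.frame(RNA = tab$RNA, log2fc = round(lfc, 2), printed = tab$Log2FC), 3)
#>        RNA log2fc printed
#> 1      IL6   1.17    1.17
#> 2 RNASEH2C   1.14    1.14
#> 3    IL17F   1.15    1.15
```

A full synthetic run with known truth:

```r
sim <- simulateExperiment(simulationConfig(
  nMrna = 500, nLncrna = 100, nMirna = 50, nDM = 30,
  baselineBeta = 10, effectLogOdds = 2.5, noiseLogSd = 0.05, seed = 1))
sim$raw
#> RawArraySet: 666 probes x 6 arrays
#>   spike-in probes: 16
#>   groups: control=3, case=3

me <- quantifyMethylation(sim$raw, sim$annotation)
dm <- runDifferential(me)
table(dm$biotype, dm$direction)
#>          up down  ns
#> lncRNA    7    0  93
#> miRNA     2    0  48
#> mRNA     20    0 480
```

29 of the 30 planted effects are recovered (the `up`/`down` counts above
include them), and the top hits show the expected pattern — case mean
several-fold above control mean with tiny p and FDR:

```r
head(dm[order(dm$pValue), c("geneSymbol", "caseMean", "controlMean",
                            "log2fc", "pValue", "fdr", "direction")], 2)
#>     geneSymbol  caseMean controlMean   log2fc       pValue          fdr direction
#> 27   GENE00027 0.5991272   0.1116454 2.423938 4.415807e-08 9.685936e-06        up
#> 462  GENE00462 0.7072665   0.1649502 2.100223 4.842925e-08 9.685936e-06        up
```

`runPipeline(pipelineConfig(...))` chains all stages (simulate/load →
normalize → QC → quantify → DM → enrichment → figures) and writes every
table, a log and a JSON manifest with filter-stage counts.

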