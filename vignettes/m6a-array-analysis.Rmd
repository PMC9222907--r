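---
title: "Quantifying and comparing m6A methylation from two-channel epitranscriptomic arrays"
author: "m6Aarray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and comparing m6A methylation from two-channel epitranscriptomic arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6Aarray)
```

# The measurement and its model

MeRIP epitranscriptomic microarrays split each RNA sample into an
immunoprecipitated fraction (IP: transcripts bound by the anti-m6A
antibody, labelled Cy5) and a supernatant fraction (Sup: unbound
transcripts, labelled Cy3), and hybridize both to the same probe set. If
a transcript's methylated copies partition into the IP channel and its
unmethylated copies into the Sup channel, the fraction of methylated RNA
— the *m6A methylation level* — is

$$\%Modified \;=\; \frac{\mathrm{IP}}{\mathrm{IP} + \mathrm{Sup}},$$

a number in $[0,1]$ per transcript and sample. Everything downstream
(differential testing, clustering, enrichment) works on this statistic.

Two nuisance effects stand between raw scanner intensities and that
fraction:

* **array/channel scale.** Labelling efficiency, dye chemistry and
  scanner gain multiply every intensity of one channel on one array by an
  unknown constant. Each sample therefore receives a fixed amount of
  exogenous spike-in RNA in both fractions; on the log2 scale the
  calibration is a subtraction:
  $$\log_2 \mathrm{IP}_{norm} = \log_2 \mathrm{IP}_{raw} -
    \overline{\log_2 \mathrm{IP}_{spike,raw}},$$
  and identically for Sup/Cy3. `spikeinNormalize()` implements exactly
  this; because the subtracted constant is shared by all probes of an
  array/channel, any common multiplicative factor cancels — a property
  the test suite verifies by injecting known scale factors and checking
  they vanish to machine precision.
* **detection quality.** Feature extraction assigns each probe
  measurement a Present/Marginal/Absent call. `qcFilter()` retains a
  probe when it is P or M in at least `minPM` arrays; the default
  `minPM = 1` reproduces the permissive "P or M in at least 1 of 6
  samples" retention rule of a 3-vs-3 design.

`percentModified()` then de-logs the normalized intensities and forms
IP/(IP + Sup). Two details are deliberate choices rather than forced
moves. First, the ratio is taken on the *normalized* linear scale, not
the raw scale: when the Cy5 and Cy3 calibration constants differ, the
two disagree, and only the normalized version measures a fraction of
calibrated abundance (a unit test pins this with spike-in ladders that
differ between channels). Second, when several probes map to one
transcript, probe-level fractions are aggregated by the arithmetic
mean — vendor sheets report transcript-level values without stating an
aggregation, and the mean of fractions keeps the result inside $[0,1]$.

Raw intensities at or below zero (background-subtracted exports can
produce them) cannot be logged; they are floored at `epsilon` (default 1
raw unit) and counted. Strictly positive small values are left alone, so
the floor never distorts data that can be logged.

# Differential methylation

`runDifferential()` compares case against control %Modified per
transcript:

* **t-test.** A two-sided two-sample t-test. The pooled-variance Student
  test is the default — it is what array-vendor differential workflows
  conventionally compute — with Welch selectable via
  `variant = "welch"`. With three samples per group, neither variant has
  meaningful power advantages; the choice is recorded in the output.
  Degenerate inputs are resolved explicitly: zero variance in both
  groups gives $t = 0, p = 1$ at equal means, and an infinite $t$ with
  $p = 0$ plus a warning at unequal means.
* **fold change.** $\log_2(\bar{x}_{case} / \bar{x}_{control})$, the
  ratio of group means (not the mean of per-sample ratios — the two
  differ, and only the former reproduces published worked examples such
  as a 0.482/0.241 pair printing exactly 1.00).
* **classification.** `up` when $\log_2 FC \ge 1$ and $p < 0.05$,
  `down` symmetric, else `ns`. The fold bound is *inclusive* ("at least
  2-fold") and the p bound strict; thresholds are configurable on the
  fold scale.
* **FDR.** Benjamini–Hochberg within each RNA biotype separately. mRNA,
  lncRNA and miRNA probes populate testing universes that differ by an
  order of magnitude, and published per-class tables show FDR patterns
  (constant within one class, varying in another) consistent with
  class-wise adjustment; pooling would let the large mRNA stratum set
  the adjusted values of the small miRNA stratum.

# Gene-set over-representation

`fisherEnrich()` replaces a web enrichment service with the statistic
itself: the one-sided ("greater") Fisher exact test, i.e. the
hypergeometric upper tail $P(X \ge k)$ for drawing $k$ set members among
$n$ DM genes from a universe of $N$ measured genes of which $K$ are in
the set, computed via `stats::phyper`. Choices:

* **universe = measured genes**, not the genome: the array's coverage is
  the sampling frame from which DM genes were drawn. Web tools use their
  own (database-version-dependent) backgrounds, which is precisely why
  published GO/KEGG p-values are not a reproduction target for a local
  reimplementation — the inputs (GMT release, background size) are not
  recoverable.
* **BH within each library** (GO-BP, GO-MF, GO-CC, KEGG separately),
  mirroring how per-library adjusted p-values are reported.
* Ordering is ascending p with alphabetical tie-break, making output
  deterministic.

# Clustering and figures

`hierarchicalCluster()` wraps `stats::hclust` on `stats::dist` and
returns the merge sequence, heights and leaf order as a first-class
object. Euclidean distance with complete linkage is the default — the
base-R `hclust` convention — since published heatmaps rarely state
metric or linkage; both are configurable, and %Modified values are
clustered as-is (they are already on a common $[0,1]$ scale, so no
per-row standardization is imposed). Correctness is checked against an
exhaustive-search agglomerator on random matrices; ties in real-valued
distance data have probability zero, so tie-break conventions do not
affect those comparisons.

`renderHeatmap()` writes the image (red–green gradient, group color
bar) *and* the clustering-reordered matrix as TSV. The TSV is the
bit-stable artifact that tests and downstream consumers rely on;
rendering details of the PNG are not pinned. `volcanoPlot()` draws
$(\log_2 FC, -\log_{10} p)$ with guide lines at the thresholds; zero
p-values are clamped to the smallest positive double for display only.

# The synthetic generator

No raw arrays accompany the published study this package is patterned
on, so `simulateExperiment()` provides ground-truth input by inverting
the measurement model:

1. baseline fraction $f_t \sim \mathrm{Beta}(\alpha, \beta)$ per
   transcript (defaults $\alpha = 2, \beta = 4$: right-skewed fractions
   centred near 1/3, the range published %Modified tables occupy);
2. a planted effect for `nDM` transcripts, applied on the log-odds
   scale — $f^{case} = \mathrm{logit}^{-1}(\mathrm{logit}(f) + \delta)$
   — which keeps fractions inside $(0,1)$ for any effect size;
3. total abundance $T_{ta}$ log-normal per transcript and array; the IP
   channel measures $T f$, the Sup channel $T(1-f)$;
4. per-array per-channel scale factors $S_{a,c}$ (log-normal, sd
   `arrayScaleLogSd`) multiplying transcript and spike-in probes alike —
   the spike-ins carry the calibration signal, as on the real array. The
   spike-in "mix" is a fixed 4-level geometric ladder
   ($1000 \times 4^k$), identical in both channels, since the real
   product's composition is proprietary; identical ladders also make the
   noise-free round trip exact, because the two channels' calibration
   constants then cancel in the fraction;
5. log-normal measurement noise per intensity, and independent
   Absent/Marginal/Present flags per probe/array (spike-ins always
   Present).

The default design is 3 cases vs 3 controls with 2,000 mRNA, 500 lncRNA
and 200 small-ncRNA probes — a deliberately desk-scale stand-in for the
~36,790/8,540/2,377 probes of the full array, which remains available by
configuration.

**What the generator does not emulate:** probe sequence bias, dye-swap
designs, spatial artifacts, background structure, correlated
transcripts, or antibody non-specificity. Passing tests therefore
demonstrate that the *pipeline arithmetic* is correct and that effects
of the modelled kind are recovered — not that the biology of any real
dataset would be.

## Study conditions used by the validation checks

Fixed once, as the conditions under which the properties are asserted:

* *Round trip and scale removal*: zero noise, zero abundance spread;
  equality to truth within $10^{-9}$ (observed: machine epsilon).
* *Type-I error*: 2,000 null transcripts at default noise; the rate of
  $p < 0.05$ must fall in the 99.9% binomial band around 0.05.
* *Effect recovery*: baseline $\mathrm{Beta}(2, 10)$, $\delta = 2.5$
  log-odds, noise sd 0.05, 50 planted among 500. The skewed baseline
  matters: a logit shift multiplies small fractions by up to
  $e^\delta$ but compresses near 1, so only low-baseline transcripts can
  double their fraction. Under these conditions ≥ 98% of planted
  transcripts have a true fraction ratio ≥ 2, and the check asserts
  ≥ 80% recovery as `up` calls.
* *Oracle agreement*: BH vs a quadratic-time step-up, Fisher vs an
  enumerated hypergeometric tail, clustering vs exhaustive search — all
  on randomized small instances, at $10^{-10}$ or exact.

# Numerical and degenerate-input policy

* non-positive raw intensities: floored at `epsilon`, counted, reported;
* all spike-ins non-positive on an array/channel: hard error naming the
  array (calibration impossible);
* IP + Sup underflow to zero after de-logging: guarded error (cannot
  occur after flooring);
* both-groups-constant t-tests, $p = 0$ in volcano plots, empty QC
  retention, single-row heatmaps, zero-transcript simulations: all
  defined, non-erroring behaviours described above;
* all file formats are plain TSV/GMT/YAML/JSON; matrix TSVs round-trip
  doubles via 17 significant digits.

# Limitations

The package analyses exactly the published design: two groups, no
covariates (a logistic model with confounders is the natural extension
for larger samples), no background subtraction or within-array spatial
correction, and no attempt to reproduce database-dependent web
enrichment numbers. Printed demographic t statistics of the motivating
study are not reconstructible from its printed summary statistics; the
test suite documents this rather than chasing it.
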