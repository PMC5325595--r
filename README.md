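# neurocycle

Cell-type-resolved circadian transcriptome analysis for around-the-clock
RNA-seq of sorted neuron populations.

Small groups of *Drosophila* brain neurons — the LNv, LNd and DN1 clock
neurons and, as a non-circadian outgroup, dopaminergic (TH) neurons — can
be sorted and sequenced across the day: two independent time courses of
six timepoints at 4-h spacing per group.  Such libraries are 3'-biased and
noisy, and the questions asked of them are specific: which transcripts are
enriched in circadian neurons or in a single group, which transcripts
cycle with a 24-h period in each group, at what phase, and how do cycling
programs compare across groups.  `neurocycle` implements this full
analysis chain, plus a synthetic-data generator that emulates the design
so every stage is testable end to end without any download.

## What it computes

* **3'-end quantification** (`quantifyThreePrime()`): read 3' positions
  counted in 300-bp terminal windows at every isoform 3' end (merged
  within a gene), normalized to reads per million (RPM).
* **Enrichment classification** (`runEnrichment()`): a 10-RPM expression
  filter per replicate set, a 2-fold pre-screen, one-way ANOVA across
  groups with Tukey HSD and Benjamini–Hochberg correction, then two
  rules — *common-circadian* (≥ 5-fold over the outgroup in ≥ 2 circadian
  groups, `classifyCommonCircadian()`) and *group-specific* (> 5-fold over
  one and > 2-fold over the other circadian group,
  `classifyGroupSpecific()`) — plus a short/intronless candidate
  neuropeptide screen (`flagCandidateNeuropeptides()`).
* **Cycling detection** (`runCycling()`): two independent statistics per
  gene and group —

  F24, the 24-h Fourier power fraction of the max-normalized 12-point
  series,

  `F24 = |X2|^2 / sum(|Xk|^2, k = 1..6)`,

  with the peak phase from `arg(X2)`; and a JTK-style rank test comparing
  the series to lagged 24-h cosine references via Kendall's S, with an
  *exact* tie-aware null (`jtkNullDistribution()`, Gaussian q-multinomial
  by polynomial convolution) and Bonferroni correction over rank-distinct
  lags.  Genes passing both (F24 > 0.5 or JTK p < 0.05, each with
  amplitude fold > 2 and mean RPM > 5) are high-confidence (HC) cyclers,
  exactly one low-confidence (LC).
* **Phase analysis**: circular phase histograms (`phaseHistogram()`),
  core-clock circular mean phase (`coreClockPhase()`), cross-group overlap
  tables (`overlapAnalysis()`), and the morning- vs evening-phase
  large/small-cell expression-ratio test (`morningEveningRatioTest()`).
* **Simulation** (`simulateExpression()`, `simulateReads()`,
  `simulateGeneModels()`, `simulateLsRatios()`): the full design — 4
  groups × 2 replicate sets × 6 timepoints, DN1 grid offset +1 h — with
  cosine cyclers of programmed phase/amplitude, group-restricted and
  low-expression genes, negative-binomial count noise and 3'-biased read
  placement, returning ground truth for every gene.

See the methods vignette (`vignettes/neurocycle-methods.Rmd`) for the
statistical details and design choices.

## Worked example

```r
library(neurocycle)

cfg <- SimulationConfig(n_genes = 500, frac_cyclers = 0.15, seed = 101)
sim <- simulateExpression(cfg)

cyc <- runCycling(sim$experiment)
S4Vectors::metadata(cyc)$summary
#>   group hc lc overlap_fraction
#> 1   LNv 74  4        0.9487179
#> 2   LNd 86  1        0.9885057
#> 3   DN1 83  2        0.9764706
#> 4    TH 67  1        0.9852941

overlapAnalysis(cyc, c("LNv", "LNd", "DN1"))$exactly_k
#> in_1_groups in_2_groups in_3_groups
#>         143          44           4

head(phaseHistogram(cyc, "LNv"), 4)
#>   bin_start bin_end count   percent
#> 1         0       2     8 10.810811
#> 2         2       4     8 10.810811
#> 3         4       6     3  4.054054
#> 4         6       8     5  6.756757

enr <- runEnrichment(sim$experiment)
sum(enr$common_circadian)     # 26 genes enriched across circadian groups
sum(!is.na(enr$specific))     # 34 genes specific to one group
```

The cycling summary reports, per neuron group, the number of
high-confidence cyclers (called by both the Fourier and the rank test),
low-confidence cyclers (one method), and the overlap fraction of the two
methods.  With 15% of 500 genes programmed to cycle at amplitude fold 4,
the pipeline recovers ~75–86 HC cyclers per group.  The overlap table
shows most cycling is group-specific (143 genes cycle in exactly one
circadian group); the histogram gives the percentage of LNv cyclers
peaking in each 2-h phase bin.

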