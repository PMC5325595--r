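---
title: "Methods: detecting cell-type-resolved circadian transcript cycling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting cell-type-resolved circadian transcript cycling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurocycle)
```

# The experimental design this package models

Around-the-clock RNA-seq of sorted neuron populations: several neuron
groups (three circadian clock-neuron groups and a dopaminergic outgroup in
the motivating design), each profiled as **two independent time courses of
six timepoints at 4-h spacing** under a 12:12 light:dark cycle.  Zeitgeber
time (ZT) is hours after lights-on; one group (DN1) is sampled on a grid
offset by +1 h (ZT3, 7, ..., 23) relative to the others (ZT2, 6, ..., 22).
All statistics in the package work in absolute ZT, so offset grids need no
realignment.  Libraries from 50–100 sorted cells are strongly 3'-biased
and noisy, which shapes both the quantification strategy and the noise
model of the synthetic-data generator.

# 3'-end window quantification

Because low-input oligo-dT-primed libraries concentrate signal at
transcript 3' ends, expression is quantified by counting read 3' positions
in **terminal windows**: for every isoform a window extends 300 bp (the
`window_size` default) upstream of the isoform 3' end in spliced
coordinates, projected through the exon structure; a transcript shorter
than the window contributes a truncated window.  Windows of one gene's
isoforms are merged where they overlap so a shared 3' end is counted once.
Counting near the 3' end only makes the measure insensitive to gene
length.  Two choices here are deliberately simple and recorded in output
metadata rather than hidden:

* a read falling in windows of two genes is counted for both, with the
  number of such ambiguous reads reported;
* the reads-per-million (RPM) denominator is the **window-assigned** read
  total of the sample, not all mapped reads, so every RPM column sums to
  exactly $10^6$.

Duplicate read positions are retained: with 3'-anchored chemistry,
identical positions are expected rather than diagnostic of PCR
duplication.

# Cycling detection: two independent statistics

Per gene and group, the 12 values are ordered as (set 1 at ascending ZT,
set 2 at ascending ZT) and treated as one series spanning two consecutive
24-h days.

## F24 score and phase

Each 6-point replicate set is first divided by its own maximum
(an all-zero set maps to zeros), putting the two days on a common scale.
The discrete Fourier transform of the 12-point series has its 24-h
component at harmonic 2; the score is

$$F_{24} = \frac{|X_2|^2}{\sum_{k=1}^{6} |X_k|^2},$$

the 24-h power over all non-DC power (Nyquist counted once).  $F_{24}$ is
1 for a pure 24-h cosine repeated identically on both days, 0 for a
constant or a pure 12-h oscillation, and invariant to positive scaling of
the raw series.  The phase is the ZT at which the fitted 24-h cosine
peaks, read off the argument of $X_2$ and mapped to absolute ZT using the
group's grid origin.  Amplitude is measured separately on **unnormalized**
RPM as the peak/trough ratio of per-ZT means (the average of the two
replicate values at each ZT), with a 0.1-RPM floor on the trough;
normalizing first would erase cross-set amplitude information, which is
why amplitude precedes normalization here.

## JTK-style exact rank test

The nonparametric test compares the observed series with cosine reference
waveforms of 24-h period evaluated on the doubled ZT grid, one reference
per lag on a 4-h lag grid (6 lags, covering all phases including the
antiphase).  Agreement is measured by Kendall's S (concordant minus
discordant pairs; pairs tied in the reference are excluded, and sign
handles ties in the observations).  References are heavily tied — every ZT
appears in both replicate sets and cosine symmetry adds more — so the null
distribution of S is computed **exactly** for the reference's tie
structure: under a random ordering of the observations, the number of
discordant cross-tie-group pairs is distributed as the coefficients of the
Gaussian (q-)multinomial $[n; t_1, \dots, t_g]_q$, which
`jtkNullDistribution()` evaluates by polynomial convolution of q-binomial
factors.  The per-lag p-value is the one-sided upper tail $P(S \ge s)$;
one-sided is the correct choice because the lag grid already contains the
sign-flipped reference, and a two-sided tail would count that alternative
twice.  The reported p-value is the best lag's p multiplied (Bonferroni)
by the number of *rank-distinct* references, computed at run time rather
than assumed, and capped at 1.  A constant series has S = 0 at every lag
and returns p = 1.  As a rank statistic the p-value is invariant under
strictly monotone transforms, so whether it is fed raw or max-normalized
values is immaterial.

## Consensus calls

A gene passes the Fourier criterion when $F_{24} > 0.5$, amplitude fold
$> 2$ and mean RPM $> 5$; it passes the JTK criterion when $p < 0.05$ with
the same amplitude and expression cutoffs.  Genes passing both are
**high-confidence (HC)** cyclers, exactly one **low-confidence (LC)**,
neither non-cycling.  The per-group summary records the overlap fraction
of the two methods.

# Enrichment classification

The rule chain for differential expression across groups:

1. **Expression filter**: a gene participates for a group only if its mean
   RPM is at least 10 in *each* of the two replicate sets ("at least"
   read inclusively, `>= 10`); failures are flagged LR (low reads).  The
   separate "expressed" predicate used for presence/absence statements is
   a strict `> 5` RPM on the group mean — the two thresholds follow their
   respective verbal definitions exactly.
2. **Pre-screen**: only genes with a 2-fold change between some pair of
   group means are tested further.
3. **ANOVA + Tukey + BH**: one-way ANOVA across groups per gene, computed
   on `log2(RPM + 1)`.  The log scale is a variance-stabilization choice:
   RPM derived from overdispersed counts has variance growing with the
   mean, and the F-test holds its nominal size much better on the log
   scale.  Fold changes, by contrast, stay on raw group means (the ratio
   of averages).  Benjamini–Hochberg adjustment is applied to the
   gene-level ANOVA p-values over the pre-screened set, and Tukey's HSD
   supplies pairwise p-values; a pair is "significant" when the BH-adjusted
   q and the pair's Tukey p are both below 0.05.  The source description
   of this chain is ambiguous about which level each correction applies
   to; applying BH at the gene level and Tukey at the pair level uses each
   correction at its natural level.  Genes with zero within-group variance
   everywhere have an undefined F statistic and are reported as NA and
   excluded from the adjustment, with a log message.
4. **Common-circadian rule**: enriched when, in at least 2 of the 3
   circadian groups, the log2 fold over the outgroup reaches $\log_2 5$
   with the pair significant; LR groups neither qualify nor disqualify.
5. **Group-specific rule**: specific to group $g$ when expressed there,
   more than 5-fold above one other circadian group and more than 2-fold
   above the remaining one, both pairs significant.  The 5-fold
   requirement makes specificity to two groups impossible; the code
   asserts this rather than silently resolving it.

A zero denominator in any fold change receives a 0.1-RPM pseudo-value
(only then), so presence/absence patterns like a neuropeptide expressed in
a single group produce large finite folds.

Candidate neuropeptide flagging is a structural screen on top of
enrichment: genes whose longest isoform is at most 2 kb spliced
(configurable) and, by default, whose isoforms are all single-exon —
the short, intronless architecture typical of neuropeptide precursor
genes.  Sequence-based pro-neuropeptide scoring is out of scope.

# Phase summaries

Phases (always the F24 phase, for LC as well as HC cyclers, so the two
methods never mix conventions in one histogram) are binned on a 2-h grid
aligned to ZT0; binning is circular, percentages sum to 100 over cyclers
with defined phase.  The core-clock phase is the circular mean of the
fitted phases of *vri*, *Pdp1*, *per* and *tim*.  Overlap analysis is
plain set arithmetic on gene ids with inclusion–exclusion-consistent
counts, plus an optional annotation splitting single-group cyclers by
whether they are expressed (> 5 RPM) in any other group.  The
morning-versus-evening comparison assigns cyclers to closed phase bins
(ZT3–8 and ZT14–19 by default; the interval notation is read as closed,
so a phase of exactly 8 h is morning) and compares large-cell/small-cell
expression ratios between bins on the log2 scale with Welch's t-test
(a pooled-variance test is available via `var_equal = TRUE`); log2
treats enrichment toward either cell class symmetrically.  Ratio
semantics follow the source convention: a value below 1 means higher
expression in the small cells.

# The synthetic-data generator

`simulateExpression()` emulates the study design, not any particular real
dataset: per-gene log-normal baselines (median 50 RPM, `sdlog` 1), a
configurable fraction of cyclers per group with cosine mean
$b\,(1 + m\cos(2\pi(t-\phi)/24))$, $m = (a-1)/(a+1)$, so the time average
is the baseline and the peak/trough ratio is exactly the programmed
amplitude fold $a$ (default 4); group-restricted genes expressed in a
random proper subset of groups (others at 0.5 RPM, below the "expressed"
threshold); a fraction of genes held below the 10-RPM filter; raw counts
drawn negative-binomially with dispersion 0.04 (CV ≈ 0.2 at high
expression — a stand-in calibrated to the modest replicate
reproducibility reported for low-input neuronal libraries, since no noise
model is published for them) and normalized to RPM.  The two replicate
sets are two independent days: same mean model, independent noise.  With
`dispersion = 0` the generator returns the mean model itself on the RPM
scale (no sampling, no renormalization), which is what the closed-form
tests use.  Phase is defined as the ZT of the cosine peak throughout.

`simulateReads()` adds the read level: per-gene read counts multinomial in
the target RPM, isoform drawn uniformly, and the read 3' position placed
at an exponentially distributed spliced distance (decay length 30 bp by
default) upstream of the isoform 3' end, truncated to the transcript —
the 3' bias the quantifier assumes.  `simulateGeneModels()` provides toy
multi-isoform gene structures, including alternative 3' ends.
`simulateLsRatios()` programs a log2 shift between morning- and
evening-phase cyclers for the ratio test.

What the generator does **not** emulate: cell-type heterogeneity within a
group, amplification jackpots, rRNA/ambient contamination, mappability,
and correlated noise between genes.  Passing recovery tests on these
simulations therefore demonstrates correctness of the statistical
machinery under the stated model, not performance guarantees on real
libraries.

# Numerical choices and degenerate inputs

* All-zero replicate sets max-normalize to zero; all-zero series get
  $F_{24} = 0$ and an undefined (NA) phase.
* The amplitude trough and all fold-change denominators share the 0.1-RPM
  floor/pseudo-value.
* Reference waveforms are rounded to 9 decimals before ranking so cosine
  symmetry produces exact ties.
* The Bonferroni factor counts rank-distinct references only.
* Circular means with a near-zero resultant return NA.
* `checkDesign()` fails fast when a group lacks the complete
  2-sets-by-6-ZT grid, since every downstream statistic assumes it.

# Problem sizes used in validation

The test suite validates the exact S null by exhaustive enumeration at
n = 5, agreement with a $10^5$-draw permutation oracle for 50 random
12-point series, detection and phase recovery on 2,000 simulated genes
across the full 4-group design, ANOVA size on 2,000 null genes,
enrichment-specificity recovery on 600 genes, and quantifier recovery at
$10^6$ reads over 150 genes.  These sizes give Monte-Carlo standard
errors comfortably below the tolerances asserted.

# Known limitations

* The "sliding" 300-bp window of the original 3'-tag tool is implemented
  as a single terminal window per isoform 3' end; the tool's stated
  purpose (removing gene-length bias) is achieved by terminal windows,
  and a maximum-over-scan variant would only matter for annotation errors
  larger than the window.
* Period is fixed at 24 h; free-running designs and period estimation are
  out of scope.
* The JTK null assumes untied observations; ties in the data shrink S
  toward zero, making the test conservative, and the permutation-oracle
  tests pin this behavior on continuous data only.
* Enrichment ANOVA treats all 12 samples per group as exchangeable
  replicates (the replicate-set structure is not modeled as a blocking
  factor); with two sets of six this costs little and matches the
  original analysis as far as it is described.
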