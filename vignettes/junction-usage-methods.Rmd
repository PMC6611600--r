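---
title: "Splice-junction usage, cassette-exon inclusion, and cross statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splice-junction usage, cassette-exon inclusion, and cross statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sjusage)
```

## The problem

A heterozygous deletion of a single coding exon in a spliceosomal gene is
expected to leave half of all transcripts lacking that exon, while the
question of interest is whether the *rest* of the transcriptome splices
normally when the gene product is reduced. `sjusage` implements the
junction-level read-out of that question for bulk RNA-seq of mouse embryo
pools, together with the genetics and embryo-culture statistics such a
study produces: Mendelian ratio tests across developmental stages and
ordinal scoring of blastocysts cultured *ex vivo*.

The package deliberately starts from splice-junction count tables (the
STAR `SJ.out.tab` dialect: 1-based, fully closed intron coordinates) and a
lightweight annotation, not from reads: trimming, alignment and gene-level
quantification are upstream, solved problems. Only unique-read counts
enter any statistic; multi-mapped counts are parsed and retained but never
used, the conservative choice when the provenance of a junction read
matters more than depth.

## Differential junction usage

An *anchor set* is all junctions sharing a donor coordinate
(`shared_start`) or, conversely, an acceptor coordinate (`shared_end`).
Every junction belongs to exactly one set per side; a junction is
therefore tested twice, and an event can be called on either side.
Within an anchor set and sample, usage is the junction's count divided by
the set total; by construction defined usages in a set sum to 1 per
sample, and a sample whose set total is zero has *undefined* usage —
excluded pairwise rather than imputed, so 0/0 never fabricates a value.

Filters precede testing, applied to raw (unnormalised) counts since the
thresholds are on the raw-count scale:

* gene expressed: mean count ≥ 100 in the WT group **and** in the HET
  group (boundary inclusive);
* junction retained: mean unique count ≥ 10 in at least one group;
* junction-to-gene assignment requires both intron ends inside the gene
  span; a junction spanning several overlapping genes counts for all of
  them.

Per junction and side, a two-sided two-sample t-test compares usage
between groups. The flavour is a config switch; the default is Welch
(unequal variances), the safer choice when nothing is known about the
variance structure. With three samples per group Welch's
Satterthwaite-approximated degrees of freedom make the test mildly
conservative (observed null rejection ≈ 0.03–0.04 at nominal 0.05 in the
package's own simulations; Student's pooled flavour sits at ≈ 0.05). A
junction is *significant* under the dual rule `p < 0.05` and
`|Δusage| ≥ 0.20`, where Δ is the HET mean minus the WT mean; the
effect-size arm is what keeps high-depth but biologically trivial shifts
out. A Benjamini–Hochberg re-analysis over all tested (junction, side)
pairs jointly is always reported (`p_adjusted`, `significant_fdr`).

Degenerate cases are resolved deterministically: zero variance in both
groups with unequal means is the limit of the t statistic, reported as
p = 0 with a `degenerate` flag; with equal means, p = 1, same flag. A
(junction, side) with fewer than two defined usages in either group, or a
singleton anchor set (usage identically 1), is reported untested with a
reason code rather than silently dropped.

## Cassette-exon inclusion

For a cassette exon with two inclusion junctions (upstream exon →
cassette, cassette → downstream exon) and one skipping junction, the
per-sample inclusion level is

$$\Psi = \frac{I/2}{I/2 + S}$$

with $I$ the summed inclusion-junction count and $S$ the skipping count.
Halving $I$ corrects for the inclusion isoform contributing two junctions
per molecule against one for the skipping isoform, so $\Psi$ estimates the
fraction of transcripts containing the exon. $\Psi$ is 1 when $S = 0$ and
$I > 0$, undefined at $I = S = 0$ (excluded from group summaries with a
warning), bounded in $[0, 1]$, increasing in $I$ and decreasing in $S$.
Group means and standard deviations summarise each genotype.

## Unannotated junction burden

Per sample, among junctions detected (count > 0) on expressed genes, the
fraction absent from the annotation's transcript-derived junction set,
compared between groups by the same t-test machinery. Fractions are used
internally; percentages appear only at the reporting boundary, which
avoids an entire class of 100× unit bugs.

## Mendelian ratio statistics

`chisq_gof` is the plain Pearson goodness-of-fit: expected counts are the
ratio-normalised total, the statistic $\sum (O-E)^2/E$, no continuity
correction (the classical large-sample test; with a 1:2:1 cross at n = 142
the printed reference value p = 0.3405 is reproduced to four decimals),
df = (categories with non-zero expectation) − 1. Ratio weights may be
scaled arbitrarily; a category with zero expected weight (a genotype the
cross cannot produce) is dropped with a warning. Untyped and resorbed
embryos never enter the test — they are bookkept in the stage tables,
whose printed-style `total` column counts typed embryos only.

In the tests the asymptotic p-value is cross-checked against a 100,000-draw
multinomial Monte-Carlo null using the mid-p convention (half weight on
ties of the discrete statistic), the continuity-matched way to compare a
discrete null distribution with a continuous reference tail; the raw
`≥`-tie tail differs from the asymptotic value by ~0.014 at this sample
size, which is discreteness, not error.

## Blastocyst culture scoring

Daily records are scored on the ordinal ladder compacted morula <
blastocyst < expanded blastocyst < hatched < outgrowth, with `dead`
absorbing and a `pre_morula` pre-ladder status accepted for anomalous
records. Validation enforces monotone non-dead trajectories and no status
after death. Summaries count each embryo once per day at its current
status; deaths are reported as that day's new deaths plus a cumulative
percentage of the cohort, rounded to one decimal in tables; final-day
outcome rates (e.g. percent hatched-or-beyond) are rounded to integer
percent, matching the two reporting conventions such tables use.

## The synthetic-data generator

The generator emulates the study design the analyses assume, and its
defaults *are* those conditions: 3 WT and 3 HET pooled samples, each
litter contributing one WT and one HET pool; ~300 expected unique reads
per expressed junction (a desk-scale stand-in for ~60M-read libraries);
negative-binomial counts with dispersion 0.1; a log-normal litter batch
effect with log-scale SD 0.3; one planted heterozygous cassette-exon
deletion with skip fraction f = 0.5 (expected HET inclusion 1 − f = 0.5,
WT inclusion exactly 1); a 2% rate of low-count unannotated noise
junctions per gene and sample.

Two structural choices matter and were made once:

* **Dispersion is expression-level, not splice-ratio-level.** Each gene ×
  sample draws a shared Gamma multiplier (mean 1, variance α) and junction
  counts are Poisson conditional on it. Marginally every junction count is
  negative-binomial with variance $\mu + \alpha\mu^2$, but junctions of a
  gene are correlated, so usage ratios carry only counting noise — as in
  real RNA-seq, where biological overdispersion acts on expression.
  Putting independent NB noise on each junction would inflate per-sample
  usage SD to ~0.11 at default depth and make junction usage an unusable
  read-out at n = 3.
* **Null data must be testable.** Constitutive genes produce only
  singleton anchor sets, which are untestable by definition, so a null
  simulation made purely of constitutive genes exercises nothing. Every
  non-planted gene therefore carries an annotated alternative acceptor on
  its first intron whose usage fraction (drawn once per gene, uniform on
  0.2–0.8) is identical in both groups: a genuine null alternative-splicing
  event. The planted gene's skipping junction is deliberately absent from
  the annotation, as an engineered deletion's junction would be.

The cross simulator draws multinomial genotypes per litter (Poisson litter
sizes), records genotypes dead before the collection stage as untyped
resorptions, and untypes a small background fraction of survivors. The
culture simulator advances embryos one ladder step per day with
probability 0.65; hatch-blocked genotypes cap at expanded blastocyst and
die with hazard 0.6/day there, against a 0.005/day baseline — under a
1:2:1 cohort with blocked homozygotes this loses ≈ 25% of embryos over
five days, the cohort-level mortality the design targets.

All randomness derives from one root seed through labelled substreams, so
identical seed and configuration give byte-identical outputs, and the
emitted truth record (planted junction keys, per-sample true inclusion,
litter effects) suffices to compute every downstream expectation without
re-simulation.

What the generator does **not** emulate: sequence content and alignment
artefacts, 3'/5' coverage bias, intron retention, more than one planted
event by default, and any coupling between expression level and splicing.
Passing tests on this generator therefore demonstrate correctness of the
statistical machinery under the stated model, not robustness to every
pathology of real libraries.

## Problem sizes and numerical choices

The test suite runs the default 200-gene, 6-sample design for replicate
studies (100 replicates for inclusion recovery and planted-event
detection) and two 2,600-gene null simulations to accumulate over 10,000
tested junction-sides for the FDR re-analysis — sizes chosen so the full
suite completes in well under a minute while keeping Monte-Carlo error far
below the tolerances asserted. Usage normalisation is checked to 1e-12;
BH monotonicity exactly; inclusion recovery to a mean absolute error of
0.03 across skip fractions {0, 0.25, 0.5, 0.75}.

Known limitations: the t-test on n = 3 usage fractions is an approximation
(bounded data, small samples) and slightly conservative in its Welch
flavour; litter pairing is exposed in the sample sheet but the default
test is unpaired, matching the two-group design the thresholds were
stated for; the DE-table classifier applies thresholds to an externally
produced differential-expression table and does not fit the expression
model itself.
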