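---
title: "Discovering and dissecting drug-responsive transcriptional modules"
author: "stridemod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and dissecting drug-responsive transcriptional modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stridemod)
```

## The analysis problem

A single injection of a drug of abuse (cocaine, methamphetamine, morphine,
heroin, ethanol or nicotine) triggers waves of transcription in the striatum
that unfold over hours. Expression profiling of such an experiment produces
a probes x samples matrix over a drug x time factorial design with saline
and naive controls, hybridized in batches. Two features make the analysis
non-trivial: the diurnal cycle moves thousands of transcripts (a large
"time factor" background against which drug effects must be isolated), and
the drug-responsive transcriptome is small (on the order of a hundred
transcripts) but organized into temporally coherent co-expression modules
-- a fast immediate-early-gene wave driven by psychostimulants (pattern A)
and progressively later waves driven mainly by opioids and ethanol
(patterns B1, B2, B3).

`stridemod` implements the full chain from raw intensities to a regulatory
network: normalization, per-probe two-way ANOVA with multiple-testing
control and a true-positive/FDR curve, hierarchical pattern extraction with
correlation-based extension, gene-set and conserved-promoter TFBS
over-representation, a percent-inhibition statistic for pharmacological
dissection experiments, phenotype correlation, and network assembly. A
synthetic-data generator with planted ground truth stands in for the
original microarray data, so every stage is testable against known truth.

## Preprocessing

The processing chain is quantile normalization, log2 transformation, and
per-probe z-score standardization within each hybridization batch.

* **Quantile normalization** maps each array onto the common reference
  distribution (row means of the column-sorted matrix). Ties within a
  column receive the mean of the reference values over the tied rank span.
  The transform is idempotent.
* **Standardization axis.** Only "z-score transformation to reduce batch
  effects" is specified by the processing chain this package follows; we
  standardize *per probe within each batch*, which removes per-batch
  location and scale exactly (any affine per-batch distortion cancels)
  while preserving treatment contrasts, because every treatment group is
  represented in every batch. A `per_array` mode is available. Probes that
  are constant within a batch (which quantile normalization can produce)
  are set to 0 and counted in a warning rather than propagating `NaN`.

## Discovery: two-way ANOVA and the true-positive curve

Each probe is tested with a two-way ANOVA for the factors drug (six drugs
plus saline; naive animals are excluded from the model) and time (1, 2, 4,
8 h), with the interaction included by default. Balanced designs use
classical sums of squares computed in one vectorized pass over all probes
(verified against `aov` per probe in the tests); unbalanced designs fall
back to per-probe Type II sums of squares via `car::Anova`. Probes with
zero residual variance are flagged `degenerate` and reported with p = 1 so
downstream counts stay stable.

Raw p-values are adjusted two ways: Bonferroni (the discovery list;
`m` defaults to the number of probes actually tested, while the published
genome-wide threshold arithmetic 0.05/48,000 = 1e-6 is checked as
arithmetic) and Benjamini-Hochberg. The BH q-values drive the
**true-positive curve**: at an FDR level q (percent), `N(q)` probes are
discovered and `TP(q) = round(N(q) * (1 - q/100))` of them are estimated
true. For the drug factor this curve is flat over a wide range of q -- the
drug-responsive transcriptome is small and robust. `tp_curve()` reports the
maximum and its level (the convention used for headline counts), the
plateau band, and a **plateau height** estimated as the median of TP over
the FDR grid. The median is the estimator the recovery tests use: for a
flat curve measured with sampling noise, the maximum over grid levels is
biased upward (at high q the discovery count is dominated by null probes
and its fluctuations are amplified), while the median estimates the common
level of the flat region without that bias.

Drug-versus-saline calls use Tukey's HSD over the family of all drug x
time cell means, surfacing only each drug's contrast against time-matched
saline with its sign. The studentized-range p-values are verified against
`TukeyHSD` in the tests.

## Patterns: clustering and correlation extension

Profiles for clustering are **standardized saline-referenced group means**:
per probe, the mean standardized value of each drug x time group minus the
time-matched saline mean (24 columns for the default design). Group-mean
profiles are used rather than per-array values for clustering stability.

Clustering is agglomerative with Euclidean distance and average linkage.
Genes are sorted by ID before clustering so the result is input-order
invariant. The classical cut at height `h = 13` is retained as the default
but is scale-dependent -- it was an arbitrary threshold on the original
data's scale, and standardized group-mean profiles live on a different
scale -- so a `k`-based cut is provided and the pipeline cuts at `k = 4`,
the number of temporally distinct modules the dendrogram analysis
identifies. Cluster labels `P1, P2, ...` are assigned by decreasing size.

Each core cluster is extended by Pearson correlation of every gene's
profile with the cluster centroid (columnwise mean). Significance uses
`t = r * sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom and the strict
inclusion threshold `p < 1e-10`; with 24-column profiles this corresponds
to `|r| >~ 0.90`, which keeps the expected false-inclusion rate among
thousands of background genes essentially at zero. Overlap between
extended lists is reported relative to the smaller list, with the
denominator convention recorded in the output (published overlap
percentages cannot pin the convention down, so it is surfaced rather than
assumed). An outlying core member can be removed manually; no automatic
outlier rule is applied.

## Over-representation analysis

`ora()` is a one-sided Fisher / hypergeometric upper-tail test with fold
enrichment `(k/n)/(K/N)` (0 when `k = 0`), and `screen_collection()` runs
it over a GMT-style collection, BH-adjusting across the whole collection
per query and retaining terms with at least 3 overlapping genes, flagging
raw `p < 0.05` (the screening convention for annotation terms; the q-value
is reported alongside). The background universe defaults to all probes on
the array -- here, all simulated probes. No functional-annotation
clustering heuristics are reproduced: the screen returns flat
term/fold/p triples. Cell-type labels are assigned from a fold-enrichment
table at the inclusive tiers 2, 5 and 20.

## Conserved-promoter TFBS scanning

Promoters are aligned target/ortholog pairs over -5000..+1000 around the
TSS. The **conservation mask** slides a 50-column window along the
alignment; a target position is conserved iff some covering window reaches
70% identity (gaps and `N` count as mismatches). The window size is this
package's choice; the 70% threshold and the -5000..+1000 window follow the
promoter-analysis convention this module re-implements.

PWM scanning uses log2 odds with an additive pseudocount distributed
proportionally to the background (total mass 0.8 per column), `N` scoring
as background (0 contribution), and a **relative score** threshold of 0.80
-- the conventional default of Perl-TFBS-style scanners. Hits must lie
entirely inside the conservation mask; at most **50 conserved hits per
promoter and per matrix** are retained (top-scoring, ties by position then
strand). The "maximum of 50" cap admits several readings (per promoter,
per matrix, or across matrices); per promoter-per-matrix is implemented
and surfaced in the configuration. Enrichment contrasts per-gene presence
of at least one conserved hit between a foreground gene list and the
background universe (fold of rates; one-sided hypergeometric p). Because
the scanning threshold of the original promoter database is not published,
its printed fold values are not point-reproducible; the recovery tests
instead verify that planted motifs (0.6 foreground / 0.1 background
planting rates) are detected at fold >= 3 and p < 0.01.

## Pharmacological dissection

For an inhibitor/antagonist experiment with arms saline+vehicle,
drug+vehicle and drug+inhibitor, each pattern gene's linear-scale fold
change is `FC = 2^(mean log2 arm - mean log2 saline+vehicle)`; pattern
activations are `a_d = mean(FC_drug) - 1` and `a_i = mean(FC_inh) - 1`,
and the percent inhibition is

`phi = (1 - a_i / a_d) * 100`

with 0% = no effect, 100% = complete block, above 100% = reversal below
the saline baseline (126% = 26% of the induction below basal level), below
0% = amplification. Fold changes are linear-scale (mean-of-FC, switchable)
because the statistic's "percent below basal" semantics are linear.
Significance is a paired two-tailed t-test across pattern genes of the
inhibitor-arm versus drug-arm fold changes (the gene is the pairing unit;
configurable); results with `|a_d|` below 0.1 are flagged unreliable since
the ratio is ill-conditioned near zero activation. Per-gene up/down arrows
come from two-sample t-tests at `p < 0.05`.

## Phenotype correlation and the network

Pattern activation is the mean profile value over pattern genes, summed
over all time points for one-score-per-drug phenotypes (conditioned place
preference) or kept per drug x time for time-resolved phenotypes
(locomotor activity); the summed score is exactly the sum of the per-time
scores. Correlations use Pearson (t approximation) or Spearman. With six
drugs the CPP correlation has n = 6; an option adds saline as a
zero-activation, zero-preference point since significance at n = 6
requires r >~ 0.81 and the exact sample behind published significance
claims at smaller r is ambiguous -- neither mode is asserted as "the"
convention.

`build_network()` assembles typed evidence: gene-gene coexpression edges
where the profile correlation **strictly** exceeds 0.6, TF-to-gene edges
where a conserved binding site exists, and signaling-to-pattern edges
where a dissection experiment is significant at p < 0.1. GraphML export is
lossless; SIF keeps only the triples. The literature-derived signaling
scaffold is not inferred -- it would be supplied as a static node/edge
file.

## The synthetic-data generator

`simulate_expression()` emulates the study design: 6 drugs + saline +
naive x 4 time points x 3 replicate arrays, two hybridization batches with
every group represented in both and overall batch sizes balanced (the odd
replicate alternates across groups), ~130 drug-responsive probes among
5000 in four planted patterns, a sinusoidal 24 h diurnal trend on 30% of
probes affecting all groups equally, per-probe batch shifts
(sd 0.1 log2), and Gaussian log2 noise (sd 0.2). The default effect table
(`default_effect_profile()`) encodes the pattern timing -- A at 1-2 h for
psychostimulants and 4 h for opioids, B1 at 1-2 h for every drug, B2 at
2-4 h without cocaine/nicotine, B3 at 4 h for ethanol/morphine/heroin --
with magnitudes capped at 1.5 log2 units and graded across drugs
(psychostimulants/opioids > ethanol > nicotine for B1), because the
modules were induced by different drugs to different degrees and the
phenotype link needs cross-drug variance in activation. Within a pattern
the planted effect is uniform across genes; real modules have per-gene
effect heterogeneity, so recovery rates on real data would be lower at
equal noise.

Companion generators produce aligned promoter pairs (conserved windows
with a low internal mutation rate against a high-background rate of 0.55,
chosen so background windows sit clearly below the 70% identity
threshold; consensus instances of a sharp synthetic 14-bp motif planted
into conserved windows at 0.6/0.1 foreground/background rates), behavioral
tables (CPP = slope x summed B1 activation + noise, locomotion = slope x
per-time A activation + noise, noise sd 0.15 on an activation scale of
0-3), and four-arm inhibitor experiments in which the drug+inhibitor
activation is exactly `(1 - phi/100)` times the drug+vehicle activation.

What the generator does *not* emulate: bead-level intensities, scanner
artifacts, probe-sequence effects, animal-level pooling (replicate arrays
are drawn directly, with the noise sd interpreted as post-pooling
variability), per-gene effect heterogeneity within patterns, and array
version differences beyond a batch shift. Passing recovery tests therefore
demonstrate correctness of the statistical machinery under the declared
generative model, not performance on real arrays.

## Numerical choices and problem sizes

* Quantile-normalization ties: mean of the reference over the tied rank
  span. Degenerate ANOVA probes: p = 1 plus a flag, never `NaN`.
* Thresholds are strict where the contract says "greater than"
  (coexpression r > 0.6) and inclusive where tiers are named
  (cell-type folds 2/5/20).
* Conserved-hit cap tie-break: score, then position, then strand.
* Test and validation problem sizes: 5000-probe simulations for
  calibration (20 seeds) and recovery (5 seeds), 50 seeds for
  percent-inhibition recovery at a 30-gene pattern, 20 seeds for
  promoter-motif recovery at 38 foreground / 400 background promoters,
  100 seeds for the phenotype link. These sizes give the binomial margins
  the assertions need while keeping the default suite fast.

## Known limitations

* The `h = 13` default cut is only meaningful on data scaled like the
  original; use `k` on standardized group-mean profiles.
* The percent-inhibition statistic is undefined at zero drug activation
  and unstable near it; the `reliable` flag must be honored.
* The TFBS module scans pre-aligned promoter pairs; it does not compute
  alignments, reproduce any particular promoter database, or model
  familial binding profiles.
* Published headline counts and folds from the original arrays (42
  Bonferroni genes, 104 true positives, specific enrichment folds,
  phenotype correlations) depend on the deposited data and are not
  targets of the synthetic validation, which checks recovery of planted
  truth instead.
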