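---
title: "Detecting differential alternative splicing with splicing-ratio-difference scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting differential alternative splicing with splicing-ratio-difference scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srdetect)
```

## The statistical model

An alternative-splicing event is a competition between two splice junctions
that share a splice site. The usage of each junction in a sample is its
**splicing ratio** (SR): its uniquely mapped read count divided by the
summed counts of all junctions sharing the same 5' splice site (5' SR) or
the same 3' splice site (3' SR). Within a site group the ratios sum to 1;
for a two-junction event the inclusion and skipping ratios are complementary,
so the inclusion-junction SR estimates the percent-spliced-in (PSI) of the
event from junction evidence alone.

For one event in treatment sample $j$, with control ratios
$\mathrm{SR}_{c1},\dots,\mathrm{SR}_{cN_c}$, the **splicing-ratio-difference
score** is

$$ \mathrm{srd} \;=\;
\frac{1 + \sum_{i=1}^{N_c}\left(\mathrm{SR}_{tj} - \mathrm{SR}_{ci}\right)}
     {1 + \mathrm{s.d.}(\mathrm{SR}_c)/N_c}. $$

The numerator *sums* (does not average) the treatment-minus-control
differences, so the score scales with the number of controls; the
denominator discounts events whose control ratios are themselves variable.
When the treatment ratio equals every control ratio with zero spread the
score is exactly 1. The standard deviation uses the sample ($N_c-1$)
divisor, the natural reading for small control groups, and at least two
controls are required. An averaged-numerator variant is available
(`average = TRUE` in `compute_srd()`, `--srd-average` in the CLI) for
comparisons across designs with different $N_c$, but the summed form is the
canonical score and the default.

An event has two junctions, and by SR conservation a fall in one is a rise
in the other. The event-level score in a sample is the **larger** of its two
junctions' srd values, so both splicing directions surface in the upper
tail of one distribution; ties break toward the inclusion junction. The
reported direction of a cassette event follows the sign of the mean
inclusion-junction SR change: negative is exon exclusion (EX), positive is
inclusion (IN); alternative-splice-site events are reported as down/up.

## Tail significance

The srd scores of one treatment sample across all events form a
heavy-tailed distribution: a bulk near 1 (unchanged events) and a sparse
upper tail. Significance is assessed against a continuous power-law tail
$f(x) \propto (x/x_{\min})^{-\alpha}$ fitted by maximum likelihood, with the
cutoff $x_{\min}$ chosen to minimise the Kolmogorov–Smirnov distance between
the tail's empirical distribution and the fitted model (the Clauset
procedure, implemented in `fit_power_law()`). A score's significance is the
fitted tail's complementary CDF, $p = (x/x_{\min})^{1-\alpha}$ for
$x \ge x_{\min}$; scores below the cutoff are outside the modelled tail and
receive $p = 1$. The fit requires at least `min_tail` (default 10) tail
points and refuses degenerate (all-equal) data; when the data have more
than 200 distinct values the cutoff scan uses 200 rank-spaced candidates,
which keeps the scan $O(200\,n)$ with no measurable loss of accuracy at the
problem sizes the package targets (thousands of events per sample).

## Candidate selection

Each event's significance values across treatment samples are summarised by
their **median**, demanding replicate support. The selection threshold is
set *dynamically* from the background: each control sample is treated in
turn as a pseudo-treatment against the remaining controls (hence at least
three controls are required), giving each event a background median
significance. The threshold is the $q$-th quantile (default $q = 0.05$) of
the informative background medians. Two refinements proved necessary and
are deliberate design choices:

* The atom of background medians at $p = 1$ (events outside every fitted
  tail, usually the large majority) carries no ranking information, so the
  quantile is computed over the sub-1 background medians only. Without
  this, the threshold degenerates to 1 whenever fewer than $q$ of the
  background medians are informative, and the selection rule would admit
  every event — including events with identical ratios in all samples,
  which must never be selected.
* An event whose median significance is exactly 1 is never selected,
  whatever the threshold.

Selected candidates are finally ranked by corroborating isoform evidence:
the sum of absolute treatment-minus-control differences in
inclusion-isoform and skipping-isoform expression (`rank_candidates()`),
which demotes events whose large scores reflect low expression rather than
real splicing change. Events with no mapped isoform rank last with score 0.
When two treatment conditions are compared separately (replicate shRNAs,
say), `intersect_comparisons()` keeps events selected in all comparisons
with concordant direction and reports discordant ones.

Missing ratios (a site group with zero coverage in some sample) cause the
event to be skipped in that comparison rather than imputed: the score has
no missing-data rule, and imputation would manufacture evidence. Events
missing in every treatment sample get no median and are never selected.

## Event typing

Types are decided from the relative genomic positions of the three exons
involved. A junction pair sharing a donor with two acceptors is a cassette
exon (CA) when the nearer acceptor lands on an annotated exon start whose
exon ends before the farther acceptor — a skippable middle exon — and an
alternative 3' splice site (A3SS) otherwise; shared acceptors are symmetric
(CA vs A5SS). Donor and acceptor are assigned transcriptionally, so the
same geometry on the minus strand swaps A3SS and A5SS. Mutually exclusive
exons (MXE) are recognised as reciprocal CA pairs over non-overlapping
middle exons whose skipping junctions land exactly on each other's middle
exon and whose middle exons are never annotated in the same transcript —
the minimal geometry consistent with mutual exclusion. Without annotation
support a pair defaults to A3SS/A5SS and is flagged low-confidence, since
calling a cassette requires evidence that a skippable exon exists.
Annotation-based typing was chosen over purely positional heuristics
because the positional rule alone cannot distinguish a cassette from an
alternative splice site into a long exon.

## The synthetic-data generator

`simulate_gene_models()` builds one gene per planted event — alternating
strands, every type realised exactly as the classifier defines it — and
`simulate_junction_counts()` overlays counts: per-gene baseline PSI drawn
from Beta(2, 2) (symmetric, bounded away from the extremes), inclusion
junctions with negative-binomial counts at mean `depth * PSI`, skipping
junctions at `depth * (1 - PSI)`, dispersion 0.05 by default to match bulk
RNA-seq overdispersion (0 gives Poisson). Planted genes shift their PSI by
`delta_psi` in every treatment sample; the shift direction is drawn among
the directions that keep PSI inside (0.01, 0.99), so the planted effect
size really is `delta_psi` — clipping (with a warning) only occurs when no
direction has room. The default design is 2 treatment against 3 control
samples, the smallest design the background rule supports and the shape of
a two-replicate knockdown experiment.

`simulate_cohort()` emulates the downstream tumor-cohort stage: Bernoulli
event occurrence at a configured frequency, a binary group label whose
planted events have their occurrence odds multiplied by a planted odds
ratio in one stratum, exponential survival whose hazard is multiplied by a
planted hazard ratio per carried event, and independent exponential
censoring. `simulate_spot_table()` emulates duplicate-spot microarray
statistics with planted binders separated from background by a wide margin.

What the generator does **not** emulate — and what passing tests therefore
do not demonstrate — includes: read-level artefacts (mapping bias, overhang
filters), shared junctions between overlapping genes, annotation
incompleteness, correlated PSI across events, batch effects between
treatment and control libraries, non-proportional hazards, and microarray
spatial artefacts. Results on real data depend on upstream alignment
quality in ways these simulations cannot probe.

## Downstream cohort stage and microarray filter

Cohort events are first screened by frequency (strictly greater than 5% of
samples by default). Group association uses a two-sided Fisher's exact
test computed by exhaustive hypergeometric enumeration over tables with
fixed margins (probabilities no greater than the observed table's, with the
conventional `1 + 1e-7` tie tolerance). Survival association reports both a
log-rank test and the hazard ratio from a single-covariate Cox
proportional-hazards fit with Breslow tie handling (the simplest standard
choice); when one group has no observed events the hazard ratio is reported
as unbounded rather than numerically exploded. Raw p-values drive the
default selection (cutoff 0.05) to mirror how such screens are usually
reported, with Benjamini–Hochberg-adjusted columns always present for the
safer reading.

The proteome-microarray filter computes, per spot,
$\mathrm{SNR} = (\mathrm{F635\,mean} - \mathrm{B635\,mean}) /
\mathrm{B635\,s.d.}$ and fold change
$= \mathrm{F635\,median}/\mathrm{B635\,median}$, and across the two
duplicate spots the coefficient of variation of the background-subtracted
mean signal (the same quantity the SNR numerator uses — the CV's input is
otherwise underdetermined). Cutoffs are SNR ≥ 3 and fold ≥ 5 applied to
*each* spot (the stricter reading; `mode = "mean"` applies them to the
duplicate mean) and CV < 0.15. All three statistics are ratios, so the
filter is invariant under rescaling of the fluorescence units.

## Numerical and testing choices

Tables are written with 17 significant digits so every numeric round-trips
bit-exactly; rows are sorted by their id column so repeated runs are
byte-identical. Junctions with undefined strand (STAR code 0) are kept and
grouped with plus-strand geometry among themselves rather than dropped.
All generators take explicit seeds (default 17) and the whole
simulate→detect→cohort path is deterministic given them. The test suite
exercises detection at 300–1,000 genes, 5 samples and depth 20–100, sizes
chosen to give stable recovery statistics while keeping a full run fast;
the power-law recovery checks use 5,000-point tails over 20 replicates,
where the maximum-likelihood exponent's standard error is about 0.02.

## Known limitations

* Intron retention and alternative first/last exons are out of scope; only
  junction-pair events are considered.
* The per-event score uses the shared-site group of the defining junction
  pair; a third junction in the same group changes both members' ratios,
  which is correct behaviour but means an event's PSI interpretation is
  only exact for two-junction groups.
* The power-law tail is an approximation to whatever the true null tail
  is; its significance values are calibration devices for ranking and
  thresholding, not literal tail probabilities.
* With two treatment samples the median rule is an average of two
  correlated values (both compare against the same controls), so the
  selected fraction under the null is conservative rather than exactly
  $q$; occasional seeds produce a looser threshold and a higher false
  discovery fraction.

## A worked run

```{r, eval = FALSE}
models <- simulate_gene_models(c(CA = 1000))
sim <- simulate_junction_counts(models, n_treatment = 2, n_control = 3,
                                depth = 100, n_planted = 50,
                                delta_psi = 0.3, seed = 1)
fit <- srd_detect(sim$junctions, sim$treatment, sim$control,
                  annotation = models$annotation)
print(fit)
detection_performance(fit, sim$truth$gene_id[sim$truth$planted])
```
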