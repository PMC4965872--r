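---
title: "Measuring isoform-specific translational efficiency from polysome-fractionated 5' end sequencing"
author: "isoTE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring isoform-specific translational efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoTE)
```

## The problem

Alternative transcription start sites (TSSs) give one gene several mRNA
isoforms that differ only in their 5' untranslated regions. Because
translation initiation is rate limiting and is controlled almost entirely
through the 5'UTR, two isoforms of the same gene can be loaded with very
different numbers of ribosomes. `isoTE` implements a complete computational
pipeline for measuring this isoform-specific translational efficiency (TE)
from polysome-fractionated 5' end sequencing: RNA from seven sucrose-gradient
fractions (free RNP, 40S/60S, 80S monosome, and four polysome pools) is
5'-end-sequenced, so each capped-transcript tag simultaneously reports which
TSS produced the mRNA and how many ribosomes that mRNA carried.

## The TE model

Each gradient fraction $j$ carries a characteristic mean ribosome load
$r_j$: $r_1 = r_2 = 0$, $r_3 = 1$ (80S), and $r_4..r_7 = 2.5, 4.5, 7.5, 12$
for the polysome pools. For isoform $i$ with spike-normalized tag counts
$C_{ij}$,

$$T_i = \sum_j C_{ij}, \qquad R_i = \sum_j r_j C_{ij}, \qquad
\mathrm{TE}_i = \frac{R_i}{l_i\, T_i},$$

with $l_i$ the ORF length in nt (we use CDS length including the stop codon;
the convention cancels in every ratio). $R_i/T_i$ is the average number of
ribosomes per mRNA and is bounded by $[0, 12]$; TE is invariant to any
uniform rescaling of the counts. Gene-level TE pools the isoform counts per
fraction before applying the same formula.

Counts are made comparable across fractions with exogenous spike-in RNA:
spike clusters with more than 10 tags in every fraction of every replicate
are retained and the per-fraction factor is the upper quartile of their
counts. We additionally rescale factors by their within-replicate geometric
mean; this choice only fixes the (arbitrary) absolute scale and leaves all
TE ratios untouched.

## TSS discovery

Tags are pooled over the seven fractions per replicate. A position is
considered expressed when its tag count strictly exceeds the local
background, defined as the maximum of (i) the mean tag coverage in the
500-nt window centered on the position and (ii) the depth-normalized RNA-seq
coverage over a strand-oriented window from 500 nt upstream to 1,500 nt
downstream. Expressed positions within 20 nt of each other are merged into
clusters; clusters wider than 100 nt are refined by raising the background
in steps of 0.5x up to 3x until all sub-clusters are narrow enough, with
unresolvable plateaus emitted flagged at the 3x partition.

One rule is the package's own: a cluster must additionally beat a one-sided
Poisson test of its tag total against the summed local background (default
$\alpha = 10^{-5}$). The strict `count > background` rule alone would call
single stray tags wherever the background expectation is below one tag per
nt, which is the normal situation for featureless genomic background; the
Poisson filter removes exactly those calls while leaving any genuine tag
tower untouched (a 50-tag tower against a 0.1/nt background has
$p < 10^{-80}$). Numerical tie-break: cluster summits with tied counts go to
the most 5' position, so calling is deterministic.

Reproducibility across the two replicates is scored with an irreproducible
discovery rate: matched cluster pairs (any strand-aware overlap, best
overlap wins) are rank-transformed to normal scores and fit with a
two-component bivariate normal mixture by EM — a null component fixed at
standard normal with zero correlation, and a reproducible component with
elevated mean and positive correlation. The local idr of a pair is its
posterior null probability and the reported IDR is the running mean of
local idr along the ranking; pairs with IDR $\le 0.05$ are kept. Because
only ranks enter, the score is invariant to monotone transformations of the
signal. This is a deliberately plain reading of the copula-mixture model
(we fit the rank-normal scores directly rather than iterating the
pseudo-likelihood re-ranking); a count-threshold fallback mode is provided
for inputs too small for the EM (< 10 matched pairs).

## Testing TE divergence between isoform pairs

For every within-gene isoform pair (numerator = the isoform with the longer
5'UTR), uncertainty is quantified by bootstrap: each replicate dataset
resamples every fraction at its original depth. For per-cluster counts this
is exactly a per-fraction multinomial draw over {cluster A, cluster B,
everything else} with probabilities proportional to the observed counts, so
we draw multinomials instead of resampling reads. Each of the B = 1,000
draws yields a log2 TE fold change; their mean $\mu_b$ and standard
deviation $\sigma_b$ summarize the distribution (draws with a zero resampled
total or non-finite fold change are dropped and counted). The p-value is the
two-sided normal tail of $Z = \mu_b / \sigma_b$, BH-adjusted within each
replicate. A pair is called significant when adjusted $p < 0.01$ and the
fold change exceeds 1.5 in the same direction in both replicates.

The empirical false discovery rate of that dual-replicate rule is estimated
by label permutation: the assignment of replicate-2 results to pairs is
shuffled 100 times, breaking cross-replicate concordance while preserving
both marginal distributions; FDR = mean shuffled pass count / real pass
count. The exact construction of the published permutation was not fully
specified by its source; ours is documented here rather than asserted as
identical. Adjusted p-values are computed within replicate (the joint
alternative was also unspecified).

## 5'UTR reconstruction and cis-element features

The mature 5'UTR runs from the TSS (cluster summit) to the annotated start
codon. Splicing inside that span is resolved through percent-spliced-in
values computed from junction-supporting reads, with annotation
pseudo-reads stabilising shallow coverage: annotated constitutive events
get 10 pseudo splice-out reads, annotated alternative events 5 + 5, novel
events none. Events with PSI $\le 0.1$ are excised, PSI $\ge 0.9$ retained,
and any intermediate event marks the isoform ambiguous and excludes it from
sequence analyses. We treat the PSI of an event as intron-retention PSI
(splice-in = the region stays in the transcript), which makes the
pseudo-read rules self-consistent; the original convention was not pinned
down by its description.

From each resolved UTR we extract: length; uORFs (an upstream AUG with an
in-frame stop codon fully inside the UTR — nested and overlapping uORFs
count separately); upstream AUGs without such a stop, split by frame
relative to the main ORF (uAUGs whose open frame runs into the CDS are
deliberately classified as uAUGs, not uORFs); a 5' TOP flag (cap-site C
followed by at least 4 pyrimidines — no upper bound on the run is
enforced); occurrence counts over the 3,841 AUG-free hexamers; and RNA
secondary-structure energies. For pairs, features are computed on the
divergent region — the 5' segment unique to the longer isoform, well
defined because the shorter mature UTR must be a suffix of the longer one
(pairs violating this, e.g. through downstream alternative splicing, are
flagged and excluded).

Folding uses a pluggable engine. The `vienna` engine shells out to the
RNAfold binary (partition function on, 37°C) and returns thermodynamic MFE
and ensemble free energy, against which the conventional stability cutoffs
(MFE < -30 kcal/mol for the 50-nt cap window, < -35 kcal/mol for 50-nt
sliding windows further downstream) are meaningful. The `builtin` engine is
a self-contained stacking-weighted base-pair-maximisation dynamic program
(GC/AU/GU weights -3/-2/-1, minimum loop 3, stacking bonus) which preserves
relative stability ordering and keeps the package fully functional without
external software, but its absolute values should not be read against
kcal/mol thresholds. The default (`auto`) uses RNAfold when present. The
sliding-window step defaults to 10 nt in the pipeline (1 nt is available);
at 50-nt windows this loses almost no stable-window detections and is an
order of magnitude cheaper.

## Association statistics

Because 5'UTR length difference itself predicts TE divergence, every
two-group comparison is preceded by matching of the pair-level
length-difference distributions: deltas are binned (100-nt bins by
default), each bin down-sampled to the smaller group's count, and bins
empty in either group dropped. Group differences are tested with
Mann-Whitney (exact null for tie-free groups of at most 20, normal
approximation with tie correction otherwise); enrichment of a binary
feature among pairs whose longer isoform translates lower uses Fisher's
exact test; a per-hexamer scan applies the matched Mann-Whitney comparison
to every AUG-free hexamer present in 3 to n-3 divergent regions and
BH-adjusts across the tested set. TOP effects are evaluated by comparing
log2 TE ratios of TOP over non-TOP isoforms against control genes whose
ratio orientation is randomized (seeded).

## Quantitative models

Per-pair log2 TE divergence (replicate mean) is modelled from
long-minus-short feature differences with additive multivariate adaptive
regression splines, implemented in full: the forward pass greedily adds
reflected hinge pairs $\max(0, x - t)/\max(0, t - x)$ with candidate knots
at observed predictor values (exhaustive search, no fast approximations),
stopping when the best candidate's $R^2$ gain falls below 0.001 or the term
budget $\min(21, 2p + 1)$ is reached; the backward pass prunes basis
columns one at a time and keeps the subset minimising
$\mathrm{GCV} = (\mathrm{RSS}/n) / (1 - C/n)^2$ with
$C = k + 2\,(k - 1)/2$. Interactions are disabled (degree 1). Collinear
candidate pairs fall back to their identifiable single hinge.

Feature contributions are decomposed as in the underlying study:
single-feature models give individual variance explained; features are then
added in descending order of individual contribution, and the successive
differences of the cumulative $R^2$ quantify the information each feature
adds given the ones before it (all significant hexamers enter as one
feature group). Generalisation is measured by 10-fold cross-validation
repeated over random partitions, with the held-out variance explained
pooled over the folds of a repeat; we report plain (not GCV-corrected)
$R^2$ throughout and expose the GCV alongside.

## The synthetic data generator

Real studies of this kind rest on deep 5' end sequencing plus genome and
annotation resources; the generator replaces them with a fully controlled
stand-in so that every stage of the pipeline is testable against ground
truth.

Each gene sits on its own contig: 1,250 nt of flank, a 5'UTR block hosting
one to three TSSs, a CDS of random sense codons, and a 3' pad. Per-mRNA
ribosome counts are Poisson with the isoform's mean load, right-censored at
12, and mapped to fractions as K = 0 to the free/40S-60S fractions (split
evenly — both carry zero weight, so the split cannot affect TE), K = 1 to
the monosome, and K in 2-3 / 4-5 / 6-9 / 10+ to the four polysome pools.
This map is a simulator choice consistent with the fraction weights; it is
configurable and its induced expectation (`expected_ribosome_load()`) is
the oracle the estimator-consistency tests compare against. Isoform copy
numbers are log-normal (median 1,500 — deep-coverage conditions); tags
scatter geometrically downstream of the true TSS (mean 2 nt); background
tags arrive uniformly at 0.002 tags/nt/fraction; per-fraction library
distortions (fixed factors between 0.78 and 1.30) multiply all emitted
counts and drive the spike-in table, so normalization has real work to do.
Two replicates share all truth and differ only in sampling noise, enabling
IDR and the dual-replicate rule.

5'UTR backgrounds are drawn from the {A, C, G} alphabet: with no T (U)
they can contain neither AUGs nor stop codons in any frame, so planted
elements are recoverable verbatim and a planted uAUG can never gain an
accidental in-frame stop. Features are planted only in divergent segments
(so pairs differ by construction) and one optional splice event only in the
shared segment (so the two never interact); genes carry features or a
splice event, not both. Planted elements: uORFs (AUG + AUG-free codons +
UAA), frame-placed uAUGs (always the 3'-most elements, so nothing
downstream can give them a stop), a cap TOP tract, GC hairpins (20-bp stem,
GAAA tetraloop — about -55 kcal/mol, comfortably past the -30/-35
thresholds), and a literal effect hexamer. Each planted feature
multiplies the isoform's mean ribosome load by its effect size; defaults
emulate strong repressors (uORF 0.5 per copy, TOP 0.5, hairpin 0.6,
out/in-frame uAUG 0.75/0.9, effect hexamer 0.35 — the last in line with
reporter assays of multi-copy repressive motifs, and strong enough that a
~20% plant rate is detectable through a BH-corrected scan of all 3,841
hexamers). Setting all effect sizes to 1 while leaving the planting on
yields the matched null study used for type-I-error and
false-discovery checks.

What the generator does *not* emulate — and what passing tests therefore do
not demonstrate about real data: mappability and alignment artefacts,
sequence-dependent library biases, correlated (bursty) background,
incomplete or wrong annotation, multi-gene loci with overlapping
transcription, and natural background uAUGs in the UTRs. The T-free
background in particular makes feature recovery exact by construction;
counter correctness on realistic sequence is covered separately by
brute-force-oracle tests on uniform-random ACGT sequences.

## Problem sizes and numerical choices

The shipped tests run the pipeline at moderate scale, chosen as the
smallest sizes at which every statistical property is comfortably inside
its tolerance: 300-gene studies (about 500-650 TSSs, 350-400 testable
pairs) for the end-to-end analyses, 2,000 simulated pairs for type-I error,
1,000 random sequences for counter oracles, and B = 600-1,000 bootstrap
replicates. Degenerate inputs are handled explicitly rather than by
accident: zero-total isoforms are dropped with a logged reason, bootstrap
draws with zero totals or non-finite fold changes are excluded and counted,
$\sigma_b = 0$ maps to p = 0 or 1 depending on the mean, empty tracks yield
empty cluster lists, and all-tied rank tests return p = 1.

## Known limitations

The IDR fit is a simplified copula mixture; on pathological inputs
(e.g. heavy ties at zero) the EM can sit at a boundary, which the fallback
mode sidesteps. The permutation null and the PSI orientation follow
documented package conventions where the original descriptions were
under-specified. The builtin folding engine is for relative comparisons
only. MARS knot search is exhaustive over observed values, which is exact
but quadratic-ish in sample size; for the problem sizes here (hundreds of
pairs, a dozen predictors) fits take well under a second.
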