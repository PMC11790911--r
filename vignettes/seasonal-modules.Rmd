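---
title: "Detecting seasonal modules in marine microbiome time series"
author: "seasonwheel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting seasonal modules in marine microbiome time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seasonwheel)
```

## The problem

High-latitude marine microbiomes cycle through pronounced seasonal states:
polar night mixing, a spring bloom, summer stratification, autumn decline.
Multi-year mooring time series of amplicon sequence variants (ASVs) and
metagenome-derived gene clusters make it possible to ask which community
members recur each year, how tightly their timing repeats, and whether the
environment selects for organisms or for functions. `seasonwheel`
implements the analysis chain for such data: per-feature oscillation
detection, inter-annual recurrence statistics, co-oscillation network
modules with environmental coupling, functional-redundancy structuring of
gene clusters within functions, rarefaction-based diversity, and TAD80
transcription summaries. A synthetic community generator with planted
ground truth makes every stage testable without any sequencing data.

## Oscillation signals

Each feature's relative-abundance series, sampled irregularly at roughly
weekly-to-fortnightly intervals, is linearly interpolated onto a uniform
7-day grid (finer than the sampling, coarse enough not to invent
structure; no extrapolation past the observed range). The series is
mean-centred and decomposed by the discrete Fourier transform; the
reconstruction keeps the DC term plus the `n_components = 3` non-DC
frequencies of largest amplitude, with their conjugate pairs so the
inverse transform is real. Three components are enough to represent one
to two seasonal peaks per year while suppressing sampling noise; the
selection rule is by amplitude rank, a documented substitute for a
significance-based component choice, and the count is exposed as a
parameter.

The *oscillation signal* of a feature is the number of reconstructed
local maxima per annual cycle, counting only peaks whose topographic
prominence reaches `prominence_frac = 0.1` of the signal range (an
amplitude criterion; shallow ripples left over from component truncation
do not count). Annual windows are calendar years (leap-aware, boundary
Jan 1); years covered by fewer than 182 grid days are not scored. The
consensus signal is the modal per-year count with ties broken toward the
smaller count — a conservative rule, so a feature is only called an
*annual oscillator* (consensus 1, a single peak and trough per year) when
that is the majority behaviour across years. Phase-rectified signal
averaging (`prsa()`) is provided for visual confirmation of periodicity:
windows centred on increase events (each sample exceeding its
predecessor) are averaged, cancelling phase variability.

## Recurrence

For annual oscillators, the per-year peak day-of-year matrix feeds two
statistics. A feature is *window-consistent* when some circular arc of 30
days contains all of its yearly peaks; the arc is circular, not a linear
range, because winter-peaking features straddle Jan 1. It is
*order-consistent* when its within-year rank by peak day (ties by feature
ID) is identical in every year — the definition of "same order" is
rank-based because order is a property of the cohort, not of absolute
dates; it is invariant to any strictly monotone warping of peak days
within a year. We treat the 30-day window as sliding rather than anchored
to calendar months, which is the weaker (more generous) reading and the
only one that is rotation-invariant.

## The co-oscillation network

Pairwise Pearson correlations are computed between the *reconstructed*
signals of all annual oscillators — ASVs and functional clusters, the
latter's abundance being the sum of their member gene clusters.
Correlating reconstructions rather than raw series suppresses count noise
and is the reason only defined oscillators enter. Two-sided p values come
from the t statistic with n − 2 degrees of freedom, and a single
Benjamini–Hochberg correction is applied over all unordered pairs
(global control; the per-class alternative is not more conservative and
is harder to reproduce). Edges require r > 0.7 and q < 0.05, positive
correlations only: negative edges distort modularity-based partitions.

Louvain community detection is order-dependent, so it is restarted 20
times under sub-seeds of one master seed and the highest-modularity
partition kept, making the result reproducible. Modules are relabelled
M1, M2, … by size, then by earliest member peak day, so labels are
phenologically stable. Only modules with at least 5 nodes are reported as
community states; smaller components are typically noise edges. Module
profiles (summed member relative abundance per feature class) are
correlated against environmental covariates pairwise-complete with one
further BH correction across the (module × class × covariate) grid.
Robustness is checked by rarefying counts to the minimum depth (and
optionally keeping one sample per calendar month) and recomputing module
component diversity.

## Redundancy of gene clusters within functions

Functional clusters group gene clusters by shared annotation, prioritised
CAZy > KEGG > PFAM; a function's abundance is the sum of its members.
Three per-module statistics describe how selection acts within functions:

* the fraction of functions with ≥ 2 member gene clusters
  (multi-cluster fraction, a redundancy proxy);
* among multi-cluster functions, the fraction whose within-function
  member Shannon diversity (members renormalised to sum 1 per time point;
  time points with the function absent excluded, diversity being
  undefined at zero) has a significant positive ordinary-least-squares
  relationship with the function's relative abundance — concurrent
  growth of metabolically overlapping members;
* the fraction of functions dominated by the *same* member gene cluster
  at the function's abundance peak of every year (exact ties resolved to
  the lexicographically smallest ID and flagged).

The regression p value (two-sided, 0.05) is deliberately unadjusted: the
question is posed per function and summarised as a fraction over tested
functions, not as a family-wise claim.

## Diversity

Alpha diversity uses 100 iterations of rarefying to the minimum sample
depth (the standard choice when no depth is given) followed by Richness
R, Shannon H′ (nats) and Evenness; Evenness is Pielou's J = H′/ln R, the
standard companion of Shannon with range [0, 1], undefined when a
rarefied sample keeps fewer than two features. Beta diversity is
Bray–Curtis on Hellinger-transformed profiles (square root of per-sample
proportions), ordinated by non-metric multidimensional scaling with 50
random starts, Kruskal stress-1, and a final principal-axes rotation so
the configuration is reproducible under a fixed seed. Month-group
cohesion across years is the convex hull area of each month's samples in
the 2-D ordination (shoelace formula; groups with fewer than 3 distinct
points get area 0). Hull areas are computed per month pooled across
years — the pooled reading is what makes the area an *inter-annual*
cohesion measure.

## TAD80

The 80% truncated average depth of a coverage vector sorts per-position
depths, discards the lowest and highest `floor(n × 0.1)` positions and
averages the rest; `floor` is the conservative resolution of the
boundary rounding the definition leaves open, and a tiny epsilon guards
the count against floating-point drift in `n × 0.1`. BedGraph input is
treated as 0-based half-open intervals expanded by run length. Module
transcription is the arithmetic mean TAD80 over the module's functions,
also expressed as a proportion of the summed module means.

## The synthetic generator

The generator emulates the study conditions the pipeline is meant for:
4 annual cycles sampled every 14 ± 3 days (integer uniform jitter,
strictly increasing dates starting Jan 1 so calendar years align with
cycles), five seasonal cohorts peaking on days 330, 60, 135, 200 and 270
(early polar night, late polar night, spring, summer, autumn), a
background of arrhythmic features, and six seasonally phased covariates —
PAR clipped at zero through the polar night window and mixed layer depth
anti-phase to temperature by construction.

Cohort features follow a von-Mises-shaped annual pulse,
exp(κ(cos(2π(t − μ)/365) − 1)), which is smooth, circular and strictly
unimodal per cycle; κ is derived from the pulse's full width at half
maximum. The default width is 90 days: wide enough that the fourth
harmonic carries only ~3% of the fundamental's amplitude — i.e. the
planted signal lies within the descriptive capacity of the default
3-component reconstruction — while cross-cohort correlations at the
minimum 60-day peak separation stay near 0.2, far below the 0.7 edge
threshold. Arrhythmic features are Gaussian random walks (step SD 0.12),
smoothed by a 3-point moving average and exponentiated: positive,
autocorrelated, non-seasonal. Latent abundances are closed to proportions
and counts drawn negative-binomially at a library size of 10^5 with
dispersion 0.1 (variance μ + 0.1μ²), a sequencing-realistic
overdispersion; dispersion 0 gives deterministic rounded counts. The real
study's noise level is unknown, so these defaults are chosen once for
realism and testability, not fidelity.

Function maps plant three redundancy classes per cohort: *single*
(one member), *multi-covarying* (members share the cohort pulse, but one
anchor member keeps a 0.35 year-round baseline against a 0.65 pulse, so
within-function diversity genuinely rises with function abundance) and
*multi-switching* (rotating per-year amplitude schedules, 2× versus
0.15×, so a different member dominates each year). The anchor split was
set so that the anchor itself remains a clean annual oscillator after
compositional closure — at 0.6 baseline the anchor's relative series is
dominated by closure fluctuations and stops being unimodal, which would
contradict the generator's own ground-truth labels.

What the generator does **not** emulate: realistic richness (thousands of
ASVs), long-term trends or regime shifts, missing samples and covariate
gaps, phylogenetic or taxonomic structure, lagged interactions between
cohorts, and read-level artefacts. Passing the recovery tests therefore
shows the pipeline is correct and well-calibrated on clean planted
structure of realistic shape and noise — not that every real feature
would be classified as cleanly.

## Numerical choices and degenerate inputs

* Interpolation needs ≥ 8 observed points; fewer is an error, not a
  guess.
* Zero-variance signals get NA correlations rather than ±1 artefacts.
* A flat reconstruction (range < 1e−12) scores 0 oscillations.
* Rarefaction depth above a sample's total is an error naming the sample;
  prevalence filtering uses strict inequalities (> 3 counts in > 3
  samples by default).
* The consensus tie-break (smaller count), the dominance tie-break
  (lexicographic, flagged) and the order-consistency tie-break (feature
  ID) are all deterministic so repeated runs agree exactly.
* All stochastic steps (timeline jitter, count draws, rarefaction, NMDS
  and Louvain restarts) run under explicit seeds; `alphaIterated()`
  additionally fixes its internal row order so results are invariant to
  how the caller ordered features.

## Problem sizes used in the test-suite

The packaged recovery experiments run the default synthetic community —
100 features (45 ASVs, 40 gene clusters mapping to 20 functions, 15
arrhythmic) over 105 samples and 4 years — across ten seeds for module
recovery, classification accuracy and redundancy recovery. These sizes
give stable fractions (a planted multi-cluster fraction of 0.5 over 20
functions, classification over 850 planted pulses) while keeping the
whole suite fast enough to run routinely.

## Known limitations

* The Fourier grid interpolation assumes gaps small relative to the
  annual period; long gaps would demand a gap-aware spectral method
  (Lomb–Scargle), which is out of scope.
* Component selection by amplitude rank has no significance test; a
  feature dominated by a non-annual frequency can still be reconstructed
  and scored, which is intended, but the retained-component count is a
  modelling choice the user should vary for sensitivity.
* Order consistency requires a peak in every scored year and is strict:
  one swapped pair in one year marks both features inconsistent. With
  many co-seasonal features of nearly identical phase, the expected
  consistent fraction is small — rank order within a tight cohort is
  essentially arbitrary.
* Network edges are contemporaneous; lagged (predator–prey style)
  relationships are invisible by design.
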