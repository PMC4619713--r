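---
title: "Methods: spatially balanced seabed surveys and design-based habitat estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatially balanced seabed surveys and design-based habitat estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(benthoscape)
```

`benthoscape` implements a complete workflow for establishing quantitative
habitat baselines on poorly mapped continental shelves: a spatially balanced
probability design (GRTS) over many small sites, acoustic substrate
classification at those sites, design-based estimation of substrate
percentages and sessile-biota extent with confidence intervals, and
classification accuracy assessment — all validated end to end against a
synthetic seascape with known ground truth. This vignette documents the
models, the parameters that matter, the numerical choices, and what the
validation does and does not demonstrate.

## The GRTS design

The sampling frame is a finite set of candidate sites (here, 200 m × 200 m
= 0.04 km² tiles). GRTS draws a sample by hierarchical randomization: the
frame extent is recursively partitioned into quadrants, with an independent
uniform permutation of the four children at every node. Concatenating the
permuted quadrant digits maps every unit to a position on a randomized
base-4 address line on which spatial neighbours remain close. Units occupy
segments of length proportional to their normalized inclusion probability
$\pi_i$ (rescaled so $\sum_i \pi_i = n$, with the standard certainty-unit
loop when any rescaled value exceeds 1), and a systematic sample of step 1
with a uniform random start selects exactly $n$ units with first-order
inclusion probability exactly $\pi_i$.

Implementation notes:

* Recursion depth: $\lceil \log_4 N \rceil + 2$ levels, capped at 14;
  co-located units are separated by seeded jitter of $10^{-6}$ of the
  extent. Randomization is realized as one uniform key per (node, child)
  pair and a lexicographic sort, which is exactly an independent permutation
  at every node but runs vectorized.
* **Reverse hierarchical ordering.** The $n$ selections, taken in line
  order, are re-ordered by the bit-reversed (van der Corput) value of their
  rank, so every prefix repeatedly bisects the address line and is itself
  spatially balanced. We use radix 2 rather than a coarser radix because
  bit reversal gives low-discrepancy prefixes at *every* length; coarser
  radixes cluster prefixes whose length falls between radix powers. A
  prefix is necessarily a subset of a fixed systematic selection, so a
  30-site prefix of a 100-site master sample is slightly less even than a
  direct 30-site draw; the measured balance-loss ratio (about 1.2 in the
  bundled tests) is the price of the flexibility.
* **Spatial balance metric.** Every frame unit is assigned to its nearest
  selected site; the loss is the variance across sites of the total
  normalized inclusion probability captured (ideal value 1 per site). The
  reference value is the mean loss of internally replicated simple random
  samples of the same size.
* **Points along a line** (subsampling images along a camera transect) use
  the 1-D analogue carried to maximal stratification: $n$ equal segments,
  one uniformly jittered point each, returned in bit-reversed segment order.
  Consecutive sorted positions are then never more than two segment widths
  apart, and prefixes remain balanced on the line.
* `adjust_inclusion()` rescales $\pi$ by realized/planned effort, so
  estimation remains valid when a survey is cut short (or extended) along
  the master-sample order.

## Route planning

Vessels transit from an anchorage, so routes are open paths from a supplied
start point, recomputed per effort increment (site sets nest; routes need
not). Construction is nearest-neighbour (ties broken by lowest unit id),
improved by alternating 2-opt segment reversals and single-site relocation,
restarted from up to eight deterministic alternative first sites. Plain
2-opt alone stalls in local optima on open paths (up to ~13% above the
exhaustive optimum on small instances in our tests); with relocation and
restarts the bundled tests find it within 5% of the brute-force optimum on
all 50 random instances with $n \le 7$.

## Substrate classification

Two independent classifiers produce hard / mixed / soft rasters.

**Decision rules** (the manual-mapping criteria made executable): soft
requires slope below 1° and backscatter inside $[-30, -25]$ dB; hard
candidates need relief of 1–5 m above the local seabed datum and
backscatter above $-25$ dB, grouped into 4-connected components that are
confirmed hard only if they reach 100 m² and exhibit flank gradients of at
least 5°; everything else is mixed. The local datum is the median depth in
a 25 × 25-cell moving window — the raised-feature criterion presumes a
datum, and a windowed median tracks the regional depth gradient while
ignoring the reef itself provided the window exceeds the patch size. The
gradient criterion is applied at component level (a raised feature has
steep flanks; its flat top does not), which matters at 2 m grid resolution
where the criteria were formulated. The classifier is total and
deterministic.

**ARC p-hard**: each cell's angular response curve is compared with a
reference curve averaged from curves over known-hard seabed
(`build_reference_arc()`, at least two training curves on a common angle
grid). Both curves are shifted by their joint minimum, normalized to unit
mass over angle, and accumulated; the two-sample Kolmogorov–Smirnov
statistic $D = \max_\theta |F_{\mathrm{cell}} - F_{\mathrm{ref}}|$ is
converted to *p-hard* via the asymptotic KS survival function at effective
size $n_b/2$ ($n_b$ = number of angle bins). This concrete
curve-to-distribution construction is our own and is isolated in one
function; the underlying ARC methodology does not pin it down, which is a
known caveat. p-hard is 1 for a curve identical to the reference, monotone
non-increasing in $D$, and undefined (an error) for a flat curve with zero
mass. Cut points 10% / 90% (mixed inclusive of both endpoints) classify the
p-hard layer; `idw_interpolate()` (inverse-distance weights, power 2, all
observations as neighbours — sites are small) fills unobserved cells.
Numerically, the KS survival function uses the Jacobi-theta representation,
accurate over the whole range; the suite checks it against the alternating
series to $10^{-10}$.

## Design-based estimation

Per-site class proportions (observed swaths vary, so class areas are
rescaled to the standard 0.04 km² site before estimation) enter the Hájek
ratio form of the Horvitz–Thompson estimator,
$$\hat p_c = 100\cdot\frac{\sum_i y_{ic}/\pi_i}{\sum_i 1/\pi_i},$$
chosen over the raw HT total because the realized site count is random
after effort adjustment and because the three class estimates then sum to
exactly 100 on every input.

**Local neighborhood variance.** With $t_j = z_j/\pi_j$ (residuals
$z_j = y_{jc} - \hat p_c/100$ for the ratio estimator),
$$\hat V = \frac{m}{m-1}\sum_i \sum_{j \in D(i)} w_{ij}\,
  (t_j - \textstyle\sum_k w_{ik} t_k)^2 ,$$
where $D(i)$ is site $i$ plus its four nearest sampled neighbours
($m = 5$), symmetrized so that $j \in D(i) \Rightarrow i \in D(j)$, and the
weights start uniform and are balanced by Sinkhorn row/column normalization
(ending on a row pass) until row sums are exactly 1 and column sums are
within $10^{-7}$ of 1. Three numerical choices deserve explanation:

* *Symmetric support.* A raw nearest-neighbour support need not admit a
  doubly stochastic limit, and the balancing iteration then stalls around
  $10^{-3}$; the symmetric union has total support, so Sinkhorn converges
  geometrically.
* *The $m/(m-1)$ factor.* A local weighted mean over $m$ sites absorbs
  $1/m$ of each squared deviation — the same degree-of-freedom loss as a
  sample variance — so the uncorrected sum is biased low by roughly
  $(m-1)/m$ for spatially unstructured data. With the correction the
  estimator's median ratio to the simple-random-sampling formula on iid
  data is 1.03 in the bundled simulation.
* *Calibration.* Neighborhood size and weight scheme were selected by
  simulating replicate GRTS draws from a fixed synthetic seascape and
  comparing the estimator to the replicate variance of the estimates; the
  shipped configuration tracks it closely for rare and common classes.

Intervals are normal approximation, $\hat p \pm 1.96\,\mathrm{SE}$,
truncated to $[0, 100]$ (or at 0 for areas); the truncated form matches how
such tables are conventionally reported. The interval form was an open
choice; normal approximation is what design-based survey software uses.

In the 1000-replicate validation that `scripts/acceptance.R` and the
acceptance tests run (40-site draws from a 2500-site frame over the default
10 × 10 km seascape), the estimators are unbiased to well under one
percentage point for every class, and interval coverage is near-nominal for
the rare hard class and the mid-frequency mixed class but modestly
conservative (~97–98%) for the dominant, spatially smooth soft class: local
contrasts at the ~1.6 km inter-site spacing include real trend variation
that a balanced sample does not actually suffer. Undercoverage for rare
clustered classes — the sharper failure mode of this estimator family — is
avoided by the calibration above.

**Biota.** Phase-II sites (imagery) get conditional probabilities favouring
mixed reef (class-weighted, default ratio 3:1 — the source design states
the bias but not the weights, so the ratio is exposed as configuration);
overall $\pi^* = \pi_1 \pi_{2|1}$, so a census second phase reduces
two-phase estimates to single-phase bit-identically. Twenty-five scored
points per image give covers in units of 1/25; labels are hierarchical
`/`-separated codes, aggregation to a coarser level truncates codes and
sums hits, so child covers sum exactly to their parent's. Site cover is the
unweighted mean of the site's (GRTS-balanced, hence equally weighted)
images; totals expand by frame area through the same Hájek/variance
machinery. Within-site image subsampling variance is not propagated — site
means are treated as observations, conservative only in so far as the
between-site component dominates, which the zero-inflated covers make the
main term.

## Accuracy assessment

Error matrices are oriented rows = predicted, columns = truth, and both
axes are labelled everywhere (the orientation is a convention; fixing and
labelling it prevents silent transposition). Overall accuracy is
trace/total; producer's accuracy is the column-wise fraction (recall),
user's the row-wise (precision); zero margins give `NA`, never 0. Cohen's
kappa uses $\kappa = (p_o - p_e)/(1 - p_e)$ with bands
$[0, 0.2)$ poor, $[0.2, 0.4)$ fair, $[0.4, 0.6)$ moderate, $[0.6, 0.8)$
good, $[0.8, 1]$ very good, negative values "worse than chance", and is
undefined ($p_e = 1$) when all mass sits in one class on both axes.

## The synthetic seascape

The simulator provides ground truth for everything above. Defaults (all
exposed in `seascape_config()`):

* 400 × 400 cells at 25 m (10 × 10 km); depth 40–160 m linearly along x
  (a ~0.7° regional gradient) plus smooth undulation of 0.4 m sd.
* Substrate from a Gaussian random field smoothed over 24 cells (600 m),
  thresholded at quantiles: the top `reef_fraction` (0.10) of cells form
  hard cores, the band below (`mixed_fraction`, 0.20) forms the
  sand-veneer halo that naturally wraps them. The 600 m correlation length
  produces kilometre-scale semi-continuous reef complexes of the kind
  low-profile shelf reefs form; quantile thresholding makes realized
  fractions match targets up to ties.
* Hard cells rise 1–5 m (scaled by field exceedance); mixed cells up to
  0.9 m. Slope is computed from depth by central differences (one-sided at
  boundaries), in degrees.
* Backscatter: per-class Gaussian, hard $-21 \pm 1$ dB, mixed $-24 \pm 1$,
  soft $-27.5 \pm 1$ (the soft band $-30$ to $-25$ dB and hard $> -25$ dB
  follow the acoustic ranges reported for such seabeds).
* ARCs: per-class exponential decay $b + a e^{-\theta/\tau}$ over 1–60°,
  noise sd 0.5 dB. Hard (offset $-24$, amplitude 8, decay 40) stays above
  soft (offset $-34$, amplitude 10, decay 12) at every angle and decays
  more slowly; mixed ($-26$, 9.5, 36) was placed so its noiseless p-hard
  is mid-band (~0.44) — genuinely intermediate, as the 10–90% mixed band
  presumes. The exponential-plus-offset family is a stand-in: the ARC
  literature this emulates does not print a functional form.
* Biota: per-group, per-class Bernoulli occupancy × Beta cover (shape1
  fixed at 2), reproducing the heavy zero-inflation of benthic point
  scores with two interpretable parameters; macroalgae cover is forced to
  zero beyond 50 m depth. Groups bundled: bryozoa, sponges, cnidaria,
  macroalgae.
* One root seed drives every layer through fixed per-layer sub-streams, so
  a configuration reproduces bit-identically.

What the simulator does **not** emulate — and hence what passing tests do
not demonstrate about real surveys: sonar physics and acquisition artefacts
(beam patterns, nadir stripes, missed returns in rough weather),
sediment-transport dynamics of the ephemeral sand veneer, georeferencing
error between imagery and acoustics, and observer disagreement in image
scoring. Real ARC shapes, in particular, differ from the exponential
stand-in, so the high classification accuracies on synthetic fields
(≥ 90% by both classifiers under well-separated parameters) are an internal
consistency check, not a field-performance claim.

## Problem sizes and degenerate inputs

The test suite simulates at the scales the checks need: full-size
(400 × 400) seascapes for the 1000-replicate coverage and unbiasedness
validation, 120–200-cell grids for classifier recovery, 2 m resolution
grids for the decision rules (whose gradient thresholds only make sense at
fine scale), frames of 50–1000 units and 2000 replicate draws for inclusion
frequencies. Degenerate inputs are errors, not silences: empty angle grids,
flat ARC curves, duplicate site coordinates in balance metrics or
neighborhood weights, prefixes longer than the master sample, images
without exactly 25 points (named in the error), unknown imagery labels
(the vocabulary is echoed), all-zero error matrices, zero-margin classes
(reported `NA`).

## Known limitations

* Finite frames only; no continuous-polygon sampling, stratified panels or
  rotating temporal designs.
* No finite-population correction beyond the design weights (sampling
  fractions in the intended use are small).
* Kappa is unweighted and reported without a variance.
* The conservative interval behaviour for dominant smooth classes, and the
  generic difficulty of variance estimation for very rare clustered
  classes, are properties of the local neighborhood estimator family
  itself; both are quantified by the bundled replicate simulation.
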