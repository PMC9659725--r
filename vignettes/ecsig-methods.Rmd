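---
title: "Methods: emotionality scoring and spectral-count differential analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emotionality scoring and spectral-count differential analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecsig)
```

`ecsig` implements the two analysis arms of a corticosterone /
fluoxetine / ECS mouse study: composite behavioral emotionality scoring
with responder classification, and label-free spectral-counting proteomics
from identification filtering through differential testing and multivariate
summary. This vignette records the models, their assumptions, and the
design decisions made where the methodology left genuine choices open.

## The emotionality score

Each behavioral measure $x$ is standardized against the vehicle control
group: $z = d \cdot (x - \mu)/\sigma$, where $\mu$ and $\sigma$ are the
control group's mean and sample (n−1) standard deviation and
$d \in \{+1, -1\}$ orients the score so that larger $z$ always means more
anxio-depressive behavior. The four default measures
(`measure_specs()`) are open-arm time and open-arm entries in the elevated
plus maze (both $d = -1$), latency to feed in novelty-suppressed feeding
($d = +1$), and grooming duration in the splash test ($d = -1$). Signed
z-scores are averaged *within* each test first, then *across* the three
tests, so each assay carries equal weight regardless of how many measures
it contributes. Home-cage food consumption is an appetite control, not a
score component.

Three choices here were open and are now fixed:

* **Per-session reference.** $\mu, \sigma$ come from the control animals of
  the *same* behavioral session, so every round is internally standardized;
  control composites are exactly zero-mean per session by construction.
  The alternative (reusing baseline-session statistics at follow-up) would
  let control drift leak into treated animals' scores.
* **Control-group $\sigma$.** The reference dispersion is the control
  group's, not the pooled cohort's; a treatment that inflates variance
  should not shrink everyone's z-scores.
* **Censored latencies enter at the cap.** An animal that never feeds
  within the 10-minute window has latency known only to exceed 600 s; its z
  contribution uses 600 s. This understates extreme phenotypes but avoids
  inventing a tail model; the `censored` flag is preserved so the
  Kaplan–Meier analysis can treat the same data correctly.

Missing single measures are dropped from the within-test mean rather than
imputed; an animal missing an entire test is scored over the remaining
tests with a warning. A measure with zero control variance raises an error
naming the measure rather than producing infinite scores.

## Responder classification

Response is an individual percent change between baseline (week 5) and
follow-up (week 10): $100\,(z_5 - z_{10})/z_5 \ge 50\%$. Two conventions
were unstated and are fixed as:

* **Boundary**: a reduction of exactly the threshold counts as response
  (the clinical "≥ 50% improvement" convention).
* **Baseline floor**: percent change of a signed score is unstable near
  zero (and flips sign for negative baselines), so animals with baseline
  $\le$ 0.1 composite-z units are reported `indeterminate` and excluded
  from the response-rate denominator with a note, never silently forced
  into a class. The floor of 0.1 is roughly the resolution at which a
  composite of four unit-variance components can be distinguished from
  zero in cohorts of this size.

`response_rate()` is responders / (responders + non-responders). Applied to
a cohort of 25 treated animals of which 18 clear the threshold, it returns
0.72; with 13 of 20, 0.65.

## Behavioral inference

`gated_location_test()` encodes the analysis policy for non-censored
endpoints: Shapiro–Wilk per group at $\alpha = 0.05$; all groups normal
→ Student t (two groups) or one-way ANOVA with Fisher's-LSD post-hoc;
otherwise Mann–Whitney or Kruskal–Wallis with Dunn's rank post-hoc (with
tie correction). When groups disagree on normality the non-parametric path
is taken — the conservative common practice. Post-hoc p-values are
deliberately unadjusted, matching the per-comparison reporting style of
behavioral pharmacology; the gate decision and per-group normality
p-values travel with every report so a reader can audit the path taken.

Feeding latencies are right-censored, so group comparisons use the
product-limit estimator (`km_estimate()`) and the Mantel–Cox log-rank test
(`logrank_test()`), both via the `survival` package; ties use the standard
hypergeometric variance. The test requires at least one event — an
all-censored comparison is a statistical-precondition error, not a p-value.

## Identification filtering and protein grouping

The filter applies, in order: peptide E-value $< 0.01$ (strict); at least
two distinct retained peptides per protein; protein E-value — the product
of its unique retained peptides' E-values — $< 10^{-4}$ (strict). The
two-peptide exclusion exists once, at this stage. Filtering is idempotent
and row-order independent, and peptide-to-protein mappings that point only
at removed proteins are dropped with them.

Grouping is graph-theoretic: proteins are nodes of the bipartite
protein–peptide graph; two proteins sharing at least one retained peptide
land in the same connected component, so sharing is transitive. A group
member with at least one peptide mapping to it alone is a *subgroup* — one
distinguishable protein. Group identifiers are the lexicographically
smallest member accession, which makes outputs deterministic.

Count assembly rejects razor-style assignment: a shared peptide's spectra
are never attributed to any subgroup (that would double-count spectra or
allocate them arbitrarily) and accumulate instead on a `<group>/shared`
row. Samples with zero total spectra are dropped with a warning.

## Differential abundance

Spectral counts are modelled per protein as Poisson with a log link:
counts ~ group, tested against the intercept-only model by the
likelihood-ratio deviance, $\chi^2_{k-1}$. Three decisions:

* **Fixed effects only.** The study design has three samples per group and
  names no random-effect term; a per-animal random effect is not
  identifiable there, so the "mixed" reading of the model is implemented
  as a fixed-effect GLM.
* **Library-size offset, median-of-ratios by default.** Runs differ in
  depth, so an offset is on by default. Size factors are the median ratio
  of each sample to the geometric-mean reference profile (computed over
  proteins observed in every sample). The simpler log-total offset is
  available (`offset_method = "total"`) but is confounded whenever the
  differential signal is asymmetric: if a quarter of the proteome rises
  4-fold in one group, that group's totals rise too, and total-count
  normalisation makes every null protein appear down-shifted — the
  parameter-recovery tests show FDR collapsing under exactly the planted
  conditions this package is benchmarked on. Median-of-ratios stays
  anchored on the non-differential majority. `offset = FALSE` fits the
  literal unnormalised model.
* **Untestable rows.** All-zero proteins carry no information under this
  model and are reported `untestable` with `NA` p — never $p = 1$ — and are
  excluded from the BH family, so the family size equals the number of
  tested proteins.

Overdispersion is not modelled: with three samples per group a dispersion
parameter is barely estimable, and the Poisson LRT's null calibration is
verified by simulation instead (1,000 null proteins, 2 × 3 design, rate
10; empirical size within Monte-Carlo error of 0.05). Pairwise direction
calls use equal-variance Student t-tests on the raw counts at
$\alpha = 0.05$, with directions reported only for significant proteins;
a square-root variance-stabilising transform is available behind a flag
and off by default. Zero-variance-in-both-groups comparisons are
untestable.

## Multivariate summaries

Biclustering row-centers the matrix (so heat-map colors read as
above/below that protein's average) and runs average-linkage (UPGMA)
agglomeration on Euclidean distances over rows and columns independently;
heights are checked against a brute-force oracle on small instances, and
ties break deterministically at the lowest index. Trees export as Newick
plus merge tables.

The PCA is an ordinary eigendecomposition of the samples in
protein-abundance space (per-protein centering, no unit-variance scaling
by default since spectral counts share a scale; a `scale` flag exists).
The "per-group bivariate-normal densities" of the score plot are read as a
display-layer summary: group mean vector and 2 × 2 covariance of
(PC1, PC2), from which `density_draws()` can simulate points; the scores
themselves are ordinary PCA scores, and both are returned. Component signs
are fixed (largest-magnitude loading positive) so results are reproducible
across linear-algebra backends. Groups of one sample get `NA` covariance;
identical samples give a zero-covariance (point) ellipse.

## What the generators emulate — and what they do not

`simulate_behavior_cohort()` draws Gaussian open-arm times and grooming
durations clamped to the test duration, Poisson entry counts, and
log-normal feeding latencies censored at 600 s. Group effects are planted
in vehicle-SD units with the anxiogenic sign convention; defaults mirror a
four-arm design (vehicle, corticosterone, corticosterone + fluoxetine,
and a fluoxetine-non-responder arm destined for ECS) in which
corticosterone shifts ≈ 1.2–1.5 SD and fluoxetine reverses most of the
shift by follow-up. A per-animal latent susceptibility (SD 0.5 z-units,
shared across measures and sessions) creates the stable individual
differences that make percent-change classification meaningful. The
study's report does not publish per-measure variances, so these defaults
are field-plausible values fixed once, not calibrated estimates.

`simulate_spectral_counts()` draws Poisson counts at
baseline × library factor × fold, with library factors log-uniform in
[0.8, 1.25] (run-to-run depth variation; unreported in the source study)
and planted effects of configurable fraction, direction split, and fold.
`simulate_psm_table()` plants controlled peptide sharing with E-values
log-uniform across the filter thresholds.

Not emulated: raw spectra, retention times, peptide detectability or
length biases, overdispersion beyond Poisson, correlated proteins,
batch structure, body weight, or within-animal correlation between the
behavioral and proteomic arms. Passing tests therefore demonstrate the
statistical machinery on data satisfying its assumptions, not robustness
to every artifact of real acquisitions.

## Problem sizes and determinism

The test suite verifies oracle agreement on hand-computable fixtures,
union-find agreement on 200 random bipartite graphs, UPGMA agreement on
100 random ≤ 6-leaf instances, Poisson-LRT and log-rank null calibration
on 1,000 proteins and 2,000 simulated cohorts respectively, and recovery
of a planted 33-protein signature (7 down / 26 up, 4-fold, counts ≈ 10,
3 samples/group) averaged over 20 seeds — sizes chosen to make
Monte-Carlo error small relative to the tolerances while keeping the
suite quick. All simulators take integer seeds and are byte-reproducible;
`run_pipeline()` writes a manifest (configuration, seed, package version,
file list) sufficient to reproduce a run exactly.

## Known limitations

* The Poisson model understates variance if biological replicates are
  overdispersed; the deviance test will then be anti-conservative. The
  calibration tests cover the Poisson regime only.
* Percent-change response classification is scale-dependent: adding a
  constant to all scores changes the ratios. The baseline floor flags the
  unstable cases but the definition itself is inherited from the clinical
  convention.
* Behavioral post-hoc comparisons are unadjusted by design; users needing
  family-wise control should adjust the reported p-values.
* Shared-peptide spectra are quantified only at group level; proteins
  with no specific peptide are never quantified individually.
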