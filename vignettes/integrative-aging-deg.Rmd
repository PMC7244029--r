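---
title: "Integrative differential expression for physiological aging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative differential expression for physiological aging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degage)
```

## The problem

An isogenic, same-age population of *C. elegans* ages heterogeneously: some
animals retain locomotor capacity while others decline early. Maximum
velocity (MV) — an animal's peak speed over a short recording — is a
physiological-age proxy, and splitting a cohort at an MV of 0.22 mm/sec (the
minimum observed at day 1 of adulthood; the comparison is a strict
"less than", so 0.22 itself is "high") yields a *low* and a *high*
physical-ability group of identical chronological age. `degage` implements
the statistical machinery needed to ask which genes distinguish those groups,
which genes track chronological age in a time course, and how concordant the
two answers are.

## The two-group integrative test

The two-group pipeline (`deg_two_group()`) proceeds in five stages.

**Quantile normalization.** Every sample's log2 intensity distribution is
forced onto the common reference distribution (the rank-wise mean of the
per-sample sorted values). Ties receive the mean of the reference values at
their tied ranks, so the operation is deterministic and idempotent.

**Present calling.** Microarray probes with no expressed target still report
background fluorescence. For each sample a two-component Gaussian mixture is
fitted to the intensity distribution by EM; the low-mean component models
background, the high-mean component signal, and the present/absent cutoff is
the point between the two means where the weighted component densities cross
(the root of $w_1\,\mathcal{N}(x;\mu_1,\sigma_1) =
w_2\,\mathcal{N}(x;\mu_2,\sigma_2)$, a quadratic on the log scale). The EM is
deliberately deterministic — initialized by a median split with
moment-matched halves, converged at a relative log-likelihood change below
1e-8 or 500 iterations — so repeated runs of the pipeline agree exactly
without a seed. Two degenerate cases are handled explicitly rather than
silently: a component collapsing to a point mass is an error, and a fit whose
means are separated by less than two of the larger component's standard
deviations (the minimum for an equal-sd mixture density to be bimodal at
all), or with no crossing between the means, falls back to the midpoint of
the means with a warning and a `fallback` flag. Per-probe aggregation of the
per-sample calls defaults to "present in every sample of at least one group":
a gene reliably detected in one condition is analyzable even if absent in the
other. The mixture is fitted per sample, after normalization.

**Two statistics.** For each probe we compute a pooled-variance Student $t$
statistic and the log2 median ratio (difference of group medians on the log2
scale), both signed so that positive means higher in group A (the low-MV
group in the motivating design). The two statistics respond differently to
outliers and to shift-versus-spread differences; using both is the point of
the integrative test.

**Permutation empirical nulls.** Rather than relying on $t$'s parametric
reference distribution (dubious at $n = 5$ per group after normalization),
each statistic is recomputed for every probe under $B$ group-size-preserving
relabelings of the samples (default $B = 1000$; all distinct relabelings are
enumerated exactly once when there are at most $B$ of them, e.g. all
$\binom{6}{3} = 20$ for a 3+3 design). All probe-by-permutation values are
pooled into one null sample per statistic — a per-data-set null, not a
per-probe null, which is what makes $B$ in the hundreds sufficient — and
smoothed with a Gaussian kernel density estimate (Silverman bandwidth, 2048
grid points covering the null range plus four bandwidths each side). The
two-tailed empirical p-value of an observed value is the KDE tail mass beyond
the null median plus/minus the observed distance from it, by trapezoidal
integration; centering at the null median (rather than zero) was a free
choice and is symmetric for these statistics anyway. P-values are clamped
below at one over the number of pooled draws so the normal-quantile
transform stays finite; infinite statistics (the zero-variance sentinel)
receive the floor.

**Stouffer combination and the three-criterion call.** The two p-values are
combined by Stouffer's method with equal weights: each is mapped to a signed
z score $z = \Phi^{-1}(1 - p/2)\,\mathrm{sign}$, the combined score is
$(z_t + z_{lmr})/\sqrt{2}$, and the combined p is its two-tailed normal
tail. A probe is called differentially expressed when it is (I) present,
(II) has combined $p < 0.05$, and (III) has absolute log2 fold-change
strictly above 0.58 (1.5-fold; the log2 median ratio serves as the
fold-change statistic, since no separate fold-change is defined). "Adjusted"
p-values here means *empirical-null-calibrated*, not multiplicity-adjusted —
no FDR step is applied anywhere in the procedure.

### A known property: the combined p-value is anti-conservative

The $t$ statistic and the log2 median ratio measure the same location shift
on the same samples and correlate at roughly 0.8 under the null. Stouffer's
equal-weight combination assumes independence, so the combined z score has
variance $1+\rho$ rather than 1, and the realized type-I fraction at nominal
0.05 is $2\Phi(-1.96/\sqrt{1+\rho})$ — about 0.14 at $\rho = 0.8$, which the
package's own null simulation in the test suite reproduces. The marginal empirical p-values are individually well
calibrated (KS distance from uniform below 0.05 in the same simulation); the
inflation is purely a property of combining dependent evidence as if
independent. We implement the combination as defined rather than substituting
a dependence-adjusted variant, and flag the consequence: the combined p is an
evidence score, and the practical false-positive control in this procedure
comes from the joint application of all three criteria, not from the nominal
level of criterion II alone.

## The time-series procedure

For a log2-ratio time course over adulthood (`deg_timeseries()`), replicate
values are collapsed to a per-gene median profile per time point, and every
profile is referenced to the baseline day (day 4 of adulthood by default) by
subtraction. A gene is differentially expressed when its maximum absolute
change from baseline strictly exceeds $\log_2 2.5 \approx 1.32$. The 2.5-fold
default is itself a permutation quantity: shuffling each gene's observations
across the time course (destroying trend, preserving the marginal
distribution; with replicates the shuffle acts on observations, which reduces
to shuffling time labels at one replicate per time point) and taking the 95th
percentile of the pooled maximum fold-changes reproduces a cutoff of this
order on background-like data. Both paths are exposed — a fixed cutoff, or
`recompute_cutoff = TRUE` — because a fixed published threshold and a
data-calibrated one serve different reproduction purposes.

DEG trajectories are clustered by k-means with correlation distance,
$k = 40$: each delta profile is standardized across time points, after which
Euclidean distance on standardized rows is a monotone transform of
$1 - r_{\mathrm{Pearson}}$, so ordinary `stats::kmeans` (10 restarts, best
solution kept, fixed seed) applies. The 40 centroids are then clustered
hierarchically (complete linkage, Euclidean), the tree is cut into exactly
three groups — the procedure names exactly three classes — and each group is
labeled `up` or `down` by the sign of its member genes' mean end-minus-
baseline change, with a dead zone: groups moving less than 0.1 log2 units on
average are `others`. The cut height and labeling statistic were genuinely
open choices; sign-of-end-change with a dead zone is the simplest rule that
matches the up/down/others semantics and is testable against planted truth.
Constant delta profiles have undefined correlation and are assigned to
`others` without entering k-means, with a warning.

## Concordance

`overlap_table()` cross-tabulates two directional DEG sets into concordant
(up-up, down-down) and discordant cells. The percentage of overlap is
reported against set A's DEG total by default; the denominator is explicit
and configurable (`"a"`, `"b"`, `"union"`) because no single convention is
canonical.

## The synthetic-data generators

`simulate_two_group()` emulates the statistical structure the two-group
analysis assumes: a bimodal intensity distribution (absent probes drawn
around 4 with sd 0.8, present around 10 with sd 1.2, 30% absent — roughly
six sds of separation, as in well-behaved array data), planted group effects
of configurable size on 10% of present probes with 50/50 randomized sign
(exercising both call directions), and i.i.d. Gaussian measurement noise
(sd 0.3 log2 units) on top of a per-probe baseline. With zero noise each
planted probe realizes its effect exactly, which anchors the calibration
tests. Default sizes (2,000 probes, 5 per group) keep the full pipeline in
seconds; the 20,115-probe scale of a real whole-genome chip is a
configuration choice, not a different code path. The replicate number per MV
group on the real arrays is not recoverable from the study description, so
the 5-per-group default is a free choice of a typical small microarray
design.

`simulate_timeseries()` plants monotone linear log2-ratio trajectories
(rising to +3 or falling to −3 log2 units by day 24, from a day-4 baseline
over six time points) in 10% + 10% of genes, the rest flat, with 0.2 log2
units of observation noise.

What the generators deliberately do **not** emulate: probe-level dye and
scanner artifacts, intensity-dependent variance, correlated gene modules,
and non-monotone age trajectories. Passing recovery tests on this synthetic
data therefore demonstrates that the inference machinery is correct and
calibrated under its own assumptions — not that those assumptions hold for
any particular real data set.

## Numerical and design choices

- **Deterministic EM** (median-split initialization) over random restarts:
  reproducibility without seed bookkeeping; the likelihood surface for
  well-separated two-component mixtures is benign.
- **Pooled nulls** across probes, per statistic: a per-probe null at
  $B = 1000$ would be limited to p-values of 1/1000 resolution and is
  dominated by the pooled KDE.
- **Exhaustive enumeration** of relabelings for small designs removes
  Monte-Carlo error entirely (and makes the sampled path testable against
  exceedance counting).
- **P-value floor** $1/(B \cdot n_{\mathrm{probes}})$: prevents zero
  p-values from breaking the z transform; any probe at the floor is treated
  as maximally significant rather than infinitely so.
- **Strict inequalities** at every published threshold (0.22 mm/sec, 0.05,
  0.58, 2.5-fold): boundary values do not qualify.
- **Problem sizes in the test suite** (2,000 probes, 20 null repeats, 500
  time-series genes) were chosen so the whole suite runs in a few minutes on
  one core while keeping Monte-Carlo error well inside the asserted bands.

## Known limitations

- The combined p-value's anti-conservativeness under statistic dependence,
  discussed above.
- Present calling assumes a genuinely bimodal intensity distribution; arrays
  with few absent probes trigger the midpoint fallback and should be
  inspected.
- The up/down/others labeling reduces 40 trajectory clusters to three
  classes by end-change sign; genes with non-monotone trajectories
  (up-then-down) land in whichever class their end point implies, or
  `others` within the dead zone.
- No multiplicity correction is applied anywhere, by design fidelity to the
  procedure being implemented.
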