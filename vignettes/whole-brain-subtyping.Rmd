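---
title: "Whole-brain oscillator modeling and dynamical subtyping: methods"
author: "BrainHopf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-brain oscillator modeling and dynamical subtyping: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BrainHopf)
```

## The model

Each of N cortical regions (68 by default, a Desikan–Killiany-like
parcellation) is a Stuart–Landau oscillator with an adaptive angular
frequency, coupled through a structural connectome \(C\):

\[
\dot z_j = (A + i\omega_j - |z_j|^2)\,z_j
  + G \sum_i C_{ij}(z_i - z_j) + \beta\,\eta_j,
\qquad
\dot\omega_j = \omega^0_j - F\,\omega_j + M \sum_i C_{ij}\,\arg(z_i).
\]

`Re(z)` is the simulated BOLD signal; `Im(z)` is a hidden state. The four
scalar control parameters are the global bifurcation parameter `A`
(local dynamics cross a supercritical Hopf bifurcation at `A = 0`:
a damped stable focus below, a limit cycle of radius \(\sqrt A\) above),
the global coupling `G`, the frequency feedback `F` (1/s), and the
modulation index `M` tying each region's frequency to its neighbours'
phases. \(\eta_j\) is complex white noise with independent real and
imaginary increments; its SD is fixed at \(\beta = 0.02\). The
frequency equation is deterministic; without modulation it relaxes to
\(\omega^0_j / F\). Intrinsic frequencies \(\omega^0_j\) are the
dominant resting BOLD frequencies, 0.098–0.221 rad/s, either estimated
from data (Welch periodogram peak in 0.008–0.1 Hz, per-region median
across subjects) or drawn uniformly from that range by
`defaultIntrinsicFrequencies()`.

Integration is Euler–Maruyama at `dt = 0.05` s (far below the fastest
intrinsic period of ~28 s), with states sampled every `TR = 2` s after a
60 s burn-in, for a default 420 s (7 min) run matching a typical
resting-state acquisition. Initial amplitudes are drawn uniformly in a
disk of radius 0.1 and \(\omega_j(0) = \omega^0_j\); both are governed
by the configuration seed. With `beta = 0` integration is fully
deterministic. `F = 0` lies on the search grid; it removes the
restoring term of the frequency equation, so a warning is issued and
the run proceeds (it remains finite over the configured duration).
A note on accuracy: the Euler map shifts the limit-cycle radius to
\(\sqrt{A + dt\,\omega^2/2}\); at the default `dt` this bias is ~1e-3
and shrinks linearly in `dt`, which is how the convergence checks in
the test suite use it.

## The connectome

The coupling scaffold is a nonnegative `N x N` matrix with zero
diagonal whose rows are normalized to unit sum, so the coupling term is
a convex combination of neighbour states. Without diffusion data, the
group-consensus construction is emulated: pseudo-subjects contribute
random symmetric edge sets; edges present in strictly more than the
consistency threshold (default 60%) of pseudo-subjects survive;
surviving average weights are mapped by a rank-based inverse-normal
transform onto a Gaussian profile (mean 0.5, SD 0.15, ties averaged,
clipped below at 1e-6 since ~0.04% of that Gaussian's mass is negative)
and then row-normalized — resample first, normalize second.

## Functional connectivity and fitting

Simulated BOLD is band-passed to 0.008–0.1 Hz by discrete cosine
transform windowing (orthonormal DCT-II forward / DCT-III inverse over
the full series length; coefficient `k` maps to frequency
`k/(2 T TR)`; the DC coefficient lies below the band, so means are
removed). FC is the Pearson correlation of regions, Fisher
z-transformed (inputs clipped to |r| ≤ 0.999999, diagonal set to 0).
Similarity between FC matrices is the Pearson correlation of strict
upper triangles — the diagonal is constant and excluded.

The search grid spans A from −0.2 to 0.2 in steps of 0.01, G from
0.005 to 0.05 in steps of 0.005, F from 0 to 1 in steps of 0.1, and M
from 0.10 to 0.50 in steps of 0.03 — axes are inclusive sequences with
a half-step tolerance at the top (M ends at 0.49), giving
41 × 10 × 11 × 14 = 63,140 combinations. Each grid point is simulated
once (`simulateGrid()`), and its per-point noise seed derives from the
master seed and the parameter values, so the bank is independent of
enumeration order, worker count, and of which other points a grid
contains; results are cached on disk by content hash.

Monte-Carlo nonparametric fitting (`monteCarloFit()`) draws, per
iteration, a fraction of subjects (thresholds 30/50/70%,
round-half-up, without replacement, subjects pre-sorted by id so the
result is order-invariant), averages their Fisher-z FCs entrywise, and
records the grid point maximizing upper-triangle similarity (ties go
to the lexicographically smallest point, with a warning). 500
iterations per threshold are pooled into one distribution of 1500
selected parameter sets.

`detectModes()` scales selected points by their axis steps, partitions
them with 2-means seeded by the two most distant distinct selected
points (deterministic farthest-point initialization; a cluster mean is
never reported — each mode's representative is its most frequently
selected grid point, ties to the lexicographically smallest), and
labels the representative with the larger simulated metastability
DEP1. Unimodal record sets raise an error rather than fabricating a
stratification. Subjects are then assigned to the subtype whose
simulated FC their own FC resembles more (exact ties to DEP1, with a
warning).

Synchrony and metastability are the time mean and the temporal
population SD of the Kuramoto order parameter
\(R(t) = |N^{-1}\sum_j e^{i\theta_j(t)}|\), with \(\theta_j = \arg z_j\)
for simulated states and analytic-signal (Hilbert) phases for
BOLD-only input (the returned series is flagged with its phase
source). Mode-level metrics are z-scored against the distribution of
the same metric over all Monte-Carlo-selected grid points, using the
population SD.

## Clinical statistics

The behavioral battery is MADRS-S (9 items, 0–6), BPRS-AFF (5 items,
0–7), CAINS (13 items, 0–4) and TMT A/B on a log-seconds scale; higher
is worse on all of them, so improvement is minus the change score, and
improvement-vs-sham subtracts the sham group's median improvement per
item. The allocation control test is a plain Pearson chi-squared on
the 2 × 2 treatment-by-subtype table without continuity correction
(required to reproduce the statistic 0.09 from the 10/10/10/12
layout). To remove imbalance between subtype cells, `balancedBootstrap()`
tops up the smaller subtype cell within each arm by resampling it with
replacement to the larger cell's size (10/10/10/12 becomes
10/10/12/12). Logistic models of subtype on item scores use IRLS
(≤100 iterations, tolerance 1e-8) with a nonparametric subject
bootstrap on the odds-ratio scale; replicates that fail to converge or
show complete separation are dropped and counted, and more than 50%
drops is an error. Linear models of change scores include treatment,
subtype, their interaction, the baseline score, age and sex; CIs are
percentile bootstrap (95%, 1000 replicates by default) — percentile
rather than BCa, since nothing stronger is warranted at n = 42.
The nested ANOVA fits subtype within treatment (2 nested parameters)
controlling age and sex and reports the F-test of the nested term with
df1 = 2 and df2 equal to the residual degrees of freedom of the data
actually supplied — no fixed df2 is imposed.

## The synthetic cohort: what it emulates and what it does not

`generateCohort()` builds a complete synthetic study: 42 subjects, 20
DEP1 / 22 DEP2, treatment cells 10/10/10/12, ground-truth parameter
sets DEP1 (A = −0.090, G = 0.010, F = 0.7, M = 0.49) and DEP2
(A = 0.020, G = 0.035, F = 0.4, M = 0.46). Ordinal items come from
rounding a latent Gaussian centered at a per-scale typical severity
(3.3 for MADRS-S items, 2.0 for BPRS-AFF, 2.2 for CAINS, chosen so
summed scores land near the trial's baseline means) and clipping to the
item range. Latent effect sizes default to a 0.4 baseline subtype
shift, a −0.5 active-treatment shift and a 0.8 treatment-by-subtype
interaction at follow-up, all in latent (≈ item-point) units with
latent SD 1.0; setting them to 0 gives the null cohorts used for
calibration.

Subject FC maps need a design decision that deserves honesty. At these
parameter magnitudes, with a row-normalized connectome and 7-minute
windows, the model's FC is dominated by realization noise: two runs at
the same parameters with different noise paths produce FC matrices
correlating at only 0.00–0.04. Under fully independent per-subject
simulations there is therefore no subtype signature in single-subject
FC, and subject assignment is at chance — a genuine identifiability
limit of short windows, stated here rather than hidden. The default
generator (`fcSeedMode = "sharedModel"`) instead treats the model's FC
at a parameter point as a canonical object: the simulation seed is
derived from the master seed and the parameter values — the same
derivation the grid bank uses — so all subjects of a subtype share
their subtype's characteristic map and differ by symmetric Fisher-z
noise (SD 0.05, putting within-subtype similarity near 0.85). When
cohort and bank share a master seed this is the classical
well-specified recovery setting: the data-generating process is a
member of the fitted model family, and the end-to-end test verifies
that grid search, Monte-Carlo pooling, mode detection and assignment
recover it. What passing does not show: that 7-minute empirical scans
identify single subjects' dynamical regimes — under
`fcSeedMode = "perSubject"` they demonstrably do not. The two
synthetic subtype maps are also near-orthogonal, unlike empirical
subtype FCs, which share anatomy-driven structure and correlate around
0.95; the generator makes no attempt to emulate that shared component,
BOLD noise spectra, or raw 4-D volumes.

## Numerical choices and problem sizes

Tolerances: row sums within 1e-9; FC symmetry within 1e-9; Fisher-z
clipping at |r| = 0.999999; frequency fixed points verified to 1e-6.
Tie-breaks are deterministic everywhere (average ranks in the
inverse-normal transform, lexicographically smallest grid point,
assignment ties to DEP1) and warn where a tie is scientifically
ambiguous. Degenerate inputs fail loudly: zero-weight connectome rows,
zero-variance regions, double Fisher transforms, unimodal Monte-Carlo
distributions, empty treatment-by-subtype cells.

The packaged analyses run on reduced problem sizes chosen as the
smallest that still exercise every stage at the study's structure: the
demonstration grid (`reducedGrid()`) uses 24 points whose corners
include both ground-truth parameter sets, 3 thresholds × 50 Monte-Carlo
iterations, a 68-region connectome and 7-minute simulations; the full
63,140-point production grid runs through exactly the same code path
with caching and optional forked workers.

## Known limitations

The Fig-like ordering in which the first subtype shows higher
metastability and synchrony than the second is *not* reproduced by
this model at the two fitted parameter sets: across connectomes and
seeds the near-critical, more strongly coupled DEP2 point robustly
yields both higher synchrony and higher metastability, in line with
the standard result that these metrics peak near criticality. The
package reports the measured direction rather than forcing the
expected one; the subtype *labeling rule* (DEP1 = higher
metastability) is retained as a convention. Model-to-empirical fit
values and clinical effect CIs from the original trial require its raw
data and are replaced here by recovery, coverage and power properties
on synthetic cohorts.
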