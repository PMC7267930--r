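---
title: "Temporal stability of modular brain network organization with dynmod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal stability of modular brain network organization with dynmod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynmod)
```

## The analysis in one paragraph

Resting-state functional brain networks are modular: groups of regions
(nodes) are strongly correlated internally and weakly coupled to other
groups. dynmod quantifies how *stable* that modular organization is over the
course of a scan, and relates the stability to a per-subject phenotype such
as an IQ score. The chain is: parcellated BOLD time series → tapered
sliding-window connectivity (Fisher-z weighted Pearson correlations, kept
signed and unthresholded) → multi-restart Louvain modularity maximization
per window at a per-subject resolution γ → the window-wise modularity trace
Q(t). The temporal-stability statistic is SD(Q), the sample standard
deviation of the trace (lower = more stable). Around it the package builds
extreme-modularity-state detection, coclassification (module allegiance)
stability with network-level aggregation, and partial Spearman association
tests against the phenotype with nuisance covariates.

## The model pieces and their parameters

### Windowed connectivity

Windows are `length = 156` time points (≈100 s at TR = 0.645 s, one full
cycle of the slowest band-passed component) shifted by `step = 10`, giving
`floor((T - L)/s) + 1` windows; with an effective scan length of 846 time
points that is 70 windows. Scans of ≈900 acquired volumes minus discarded
initial frames can leave a few more usable time points than that — the
package always derives the window count from the actual series length rather
than forcing a fixed number.

Within each window, edges are weighted Pearson correlations under a taper
(default: a rectangle convolved with a Gaussian of SD 3 time points,
max-normalized), variance-stabilized by the Fisher z-transform
`z = atanh(r)` and clipped at `|r| = 1 - 1e-7`. Negative edges are kept:
anticorrelations carry structure, especially between task-positive and
task-negative systems.

### Signed modularity and Louvain

Community structure per window maximizes a resolution-parameterized
modularity. For a non-negative matrix this is Newman–Girvan weighted
modularity,

\[ Q = \frac{1}{2m}\sum_{ij}\left(w_{ij} - \gamma\,
   \frac{k_i k_j}{2m}\right)\delta(c_i, c_j). \]

Fisher-z matrices contain negative weights, and the standard null model is
not defined for them; the package defaults to the asymmetric signed quality

\[ Q^* = Q^+ - \frac{v^-}{v^+ + v^-}\, Q^-, \]

where \(Q^\pm\) are the Newman terms of the positive/negative parts and
\(v^\pm\) their total weights. This down-weights the negative part by its
share of total weight — negative edges inside a module are penalized, but
can never dominate the positive structure. Because the treatment of
negative weights is a genuine analytic choice, two alternatives are
selectable everywhere (`variant = "positive"` discards negative edges;
`variant = "plain"` applies the Newman formula to the raw matrix), and the
variant used is recorded in every output manifest.

Optimization is two-phase Louvain: greedy local moves to the neighboring
module with maximal quality gain (tolerance `1e-10`), then aggregation of
modules into nodes, repeated until stable (at most 100 passes). The node
sweep order is shuffled by a per-run seed from a platform-independent
Mersenne Twister, so a (matrix, γ, seed) triple always reproduces the same
partition. `best_partition()` runs 100 restarts by default and keeps the
maximum-quality partition, breaking ties toward the lowest seed. On graphs
small enough to enumerate every partition, the restart scheme attains the
exhaustive optimum essentially always (the test suite requires ≥ 99/100
planted graphs of up to 8 nodes at γ ∈ {0.5, 1, 2}).

### Choosing the resolution γ

γ controls module granularity. Rather than fixing it arbitrarily, each
subject's γ is selected from the grid 0.1, 0.2, …, 6.0 (60 levels) as the
value whose *static* (full-scan) partition agrees best with the canonical
17-network reference labeling, measured by mutual information. The package
defaults to *normalized* mutual information (arithmetic-mean-entropy
normalization): raw MI grows mechanically with module count across a
60-level sweep, which would bias selection toward high γ; the raw variant
remains available (`normalized = FALSE`) for the literal reading. Ties go
to the smallest γ.

### States, coclassification, statistics

A window is a high-/low-modularity state when its Q exceeds/falls below
`M · (1 ± fraction)` (strict inequalities; default fraction 0.5) with M
either the subject's own mean Q or a group mean computed by averaging Q
across subjects per window first and across windows second. Because state
counts are threshold-sensitive, `threshold_sweep()` re-runs the detection
across a fraction ladder. Thresholds are always derived from the reference
mean and the fraction at run time; the package never accepts externally
precomputed threshold values, because published threshold numbers are not
always arithmetically consistent with the mean and fraction they accompany.

Coclassification stability is the fraction of windows in which a node pair
shares a module; averaging those scores within and between the seven
canonical networks (VIS, SMN, DAN, VAN, LIM, CON, DMN; hemispheres merged;
self-pairs excluded) yields 28 scores per subject. Excluding the diagonal
is a deliberate choice — self-coclassification is identically 1 and would
inflate within-network scores; `include_diagonal = TRUE` restores the
alternative reading.

Phenotype associations are partial Spearman correlations: both variables
are residualized on the covariates (age, sex, handedness, mean framewise
displacement) by OLS, residuals are ranked (average ranks on ties), and the
Pearson correlation of the ranks is tested with the t approximation at
`df = n - 2 - k`. Residualize-then-rank matches the convention of reporting
standardized residuals of the raw variables; rank-first is available via
`rank_first = TRUE`. The 28 network tests use a Bonferroni threshold
(α/28 = 0.0018 at α = 0.05). Group contrasts (subjects with vs. without
extreme states) use the Mann–Whitney U test: exact enumeration for untied
samples with `n_a · n_b ≤ 400`, otherwise the tie-corrected normal
approximation reported as a z statistic.

## The synthetic cohort generator

No raw imaging data ships with the package; `generate_cohort()` produces
cohorts in which every downstream quantity has a known ground truth. Per
subject, node signals follow a latent factor model: node i of module m at
time t is

\[ y_{it} = \sqrt{b_t}\, g_t + \sqrt{w - b_t}\, f_{mt}
          + \sqrt{1 - w}\,\varepsilon_{it} + \sigma \eta_{it}, \]

with a global factor g, module factors f, within-module correlation
`w = base_within_cov` (default 0.6), and a between-module coupling
\(b_t = b_0 + a\,(1 + \sin(2\pi t/P + \phi))/2\) that oscillates slowly
with subject-specific amplitude a and random phase. The amplitude is the
*planted stability parameter*: larger a ⇒ larger coupling swings ⇒ larger
SD(Q) downstream. White observation noise (`noise_sd`, default 0.5) and
AR(1) smoothing (coefficient 0.3) mimic measurement noise and BOLD temporal
autocorrelation. The phenotype is an IQ-scale score,
`100 + phenotype_slope · (a - midrange) + N(0, phenotype_noise_sd)`,
clipped to [55, 145]; covariates are drawn independently, with an option to
plant a mean-FD/phenotype correlation for confound testing.

Two generator parameters deserve comment. The modulation period defaults to
400 time points: a boxcar of 156 points attenuates a sinusoid of period P by
`sinc(L/P)`, so a period near the window length (e.g. 200) would suppress
the planted fluctuation by ~75% and decouple SD(Q) from the planted
amplitude; at P = 400 the attenuation is mild (~25%) while the default
884-point scan still covers two full cycles. The amplitude range defaults
to (0, 0.4) so that between-module coupling spans from near-independence to
roughly two-thirds of the within-module level; the resulting SD(Q) values
(≈0.02–0.10 at γ = 1) match the scale reported for fast-TR resting-state
cohorts. Both were fixed from pilot simulations of the generator itself,
before any acceptance checks were formulated against them.

What the generator does *not* emulate: hemodynamics, head-motion artifacts,
spatial autocorrelation between neighboring parcels, scanner drift, or
realistic inter-network topology (all between-module pairs share one
coupling process). Passing tests therefore demonstrate that the estimator
chain recovers planted covariance dynamics through windowing, community
detection and rank statistics — not that it is robust to fMRI artifact
structure.

## Numerical choices and degenerate inputs

* Determinism: every stochastic stage takes a seed; a master seed fans out
  to per-subject, per-window, and per-restart seeds through an integer
  mixing function (`derive_seed`), so results do not depend on evaluation
  order. Identical configurations reproduce outputs bit-for-bit.
* Module ids are canonicalized by first appearance in node order; restart
  ties break to the lowest seed; γ-selection ties to the smallest γ.
* Correlations of zero-variance pairs become 0-weight edges with a warning;
  correlations at ±1 are clipped before the Fisher transform.
* SD(Q) uses the sample (n − 1) denominator and refuses traces with fewer
  than two windows; state thresholds are undefined (error) for non-positive
  reference means.
* Mutual information uses natural logarithms; the normalized variant
  defines 0/0 as 1 when both partitions are single-module, else 0.
* Matrices are serialized at 9 significant digits, so written artifacts are
  diff-able and reproducible across runs.
* All-zero connectivity matrices have no defined modularity and raise an
  error rather than returning a value.

## Problem sizes used by the tests

The test suite and acceptance script exercise the full study geometry —
114 nodes, 884 time points, 73 windows, 100-subject cohorts — with 20
Louvain restarts per window, and 20 replicate cohorts for the
parameter-recovery checks; exhaustive-enumeration oracles run on graphs of
up to 8 nodes (4,140 partitions) and the statistical calibration uses 2,000
null simulations. Default analyses of real data should keep the package
default of 100 restarts per window; the recovery simulations use 20 because
the planted block structure is far easier to optimize than empirical
connectivity.

## Known limitations

* Each window is optimized independently; there is no multilayer coupling
  of partitions across windows and no consensus clustering, so module
  labels are not matched through time (coclassification sidesteps this by
  being label-free).
* The signed-quality variant actually used by any given published analysis
  is often unstated; results can differ slightly between variants, which is
  why the variant is configurable and recorded.
* The t approximation for the partial Spearman p-value is asymptotic;
  at very small n an exact permutation approach would be preferable.
* The generator's phenotype link is linear in the planted amplitude;
  nonlinear stability-phenotype relations are out of scope.
* Because the planted coupling oscillates *above* its baseline, a larger
  amplitude also raises the time-averaged coupling and therefore lowers
  mean Q: in synthetic cohorts the time-averaged modularity co-varies with
  the planted stability effect rather than being independent of it, unlike
  what is typically observed empirically.
* Covariates that are constant in a (small) cohort are dropped from the
  association battery with a warning rather than failing the rank check —
  e.g. handedness in a 20-subject draw where everyone is right-handed.

## A minimal run

```{r demo, eval = FALSE}
cfg <- simulation_config(n_subjects = 20, seed = 1)
pipe <- pipeline_config(simulation = cfg, gamma = 1, n_runs = 20, seed = 1)
res <- run_pipeline(pipe, "dynmod-demo")
res$report$correlations      # SD(Q), mean Q and state counts vs phenotype
head(res$measures$measures)  # per-subject measures
```

For real data, point `pipeline_config()` at per-subject TSV time series, a
node labeling table and a phenotype CSV instead of a simulation config, and
leave `gamma = "auto"` to select each subject's resolution against the
17-network reference.
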