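---
title: "Methods: from pupil traces to brain networks in dyadic emotional-contagion experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from pupil traces to brain networks in dyadic emotional-contagion experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vicarious)
```

`vicarious` implements the analysis chain of dyadic emotional-contagion
experiments in head-fixed mice: an observer (OBS) witnesses a demonstrator
(DEM) receiving tail shocks, controls (CTR) witness nothing, and the
analysis asks (i) how strongly each animal reacts to graded shocks of its
own (pupil and locomotion psychometrics), (ii) which brain regions are
recruited (c-Fos density screens), (iii) whether paired animals share
region-level activation beyond chance (dyad coupling against a
shuffled-pairing null), and (iv) how the recruited regions sit in the
anatomical connectome (Leiden communities, HITS hubs/authorities with a
node-resampling bootstrap).

This vignette documents the models, the conventions chosen where the
procedures leave details open, and what the synthetic-data generators do
and do not emulate.

## 1. Trace preprocessing

Pupil area and locomotion are sampled at 20 Hz. The pupil chain is:

1. **Blink removal** (`remove_blinks()`): the absolute first difference of
   the trace is median-filtered (default kernel 5 samples = 0.25 s),
   min-max normalized to [0, 1], and every difference exceeding 0.2 is
   flagged; both endpoint samples of a flagged difference are set to `NA`
   and linearly interpolated between the nearest valid neighbors (edges
   take the nearest valid value).
2. **Savitzky-Golay smoothing** (`smooth_savgol()`): polynomial order 6,
   1.5 s window; in samples, `round(1.5 * 20) = 30` forced odd upward to 31.
3. **Epoching** (`epoch_trials()`): 1 s before to 4 s after each stimulus
   onset. The sample on the onset tick belongs to the post-stimulus
   segment, so an epoch at 20 Hz has 100 samples (20 pre, 80 post).
4. **Baseline normalization** (`normalize_epochs()`): pupil epochs are
   z-scored against the 1 s prestimulus window; locomotion epochs are
   baseline-subtracted only. Epochs with zero prestimulus variance cannot
   be z-scored; they are excluded and logged with a reason in the trial
   matrix's `exclusions` table, never silently zeroed.
5. **Response extraction** (`extract_responses()`): the response is the
   mean over the half-open window [1, 2) s after onset — exactly 20
   samples at 20 Hz.
6. **Zero-condition subtraction** (`subtract_zero_condition()`): per
   animal, the mean response to the 0 uA sham condition is subtracted from
   every intensity, making the 0 uA row exactly zero.

Conventions fixed here because the procedure leaves them open: the median
filter kernel length (5 samples; long enough to kill single-sample noise,
short enough that a 2-sample blink flank survives as three consecutive
large differences); derivative normalization per trace, not per trial;
`endrule = "keep"` in the median filter (no end smoothing — ends carry raw
derivative values); a degenerate min-max normalization (constant filtered
derivative, e.g. a linear ramp) flags nothing; and when a difference is
flagged both of its endpoint samples are removed (conservative removal of
the artifact's rising and falling edge).

Two properties of the 0.2-of-maximum rule are worth knowing. First, it is
*relative*: it presumes blink flanks dominate the derivative track, which
is true of real pupil recordings; on a trace without blinks the maximum is
set by whatever varies most (evoked transients, noise) and the rule will
flag parts of those instead. Second, it is not idempotent in general: a
second pass renormalizes to the new maximum and can flag transient flanks
that the blink-dominated first pass left alone. It is exactly idempotent
on its designed artifact class (blinks on a stationary baseline: the
cleaned trace has degenerate normalization and nothing is flagged), and on
full sessions a second pass moves the extracted 1-2 s responses by well
under 1%; both are asserted in the test suite.

## 2. Psychometrics

Per-intensity responses (replicates averaged) are fitted with the
four-parameter sigmoid

$$f(x) = b + \frac{L}{1 + e^{-k (x - x_0)}}$$

where $b$ is the baseline, $L$ the span of the upper asymptote, $k$ the
slope and $x_0$ the threshold — the intensity at the inflection point,
i.e. the half-maximal response. Before fitting, intensities are max-scaled
to [0, 1] and responses min-max scaled per animal; the threshold is mapped
back to uA for reporting (`fit_psychometric()` via `minpack.lm::nlsLM`).
Goodness of fit is $R^2 = 1 - SS_{res}/SS_{tot}$, negative values allowed
and reported.

Starting values are `b = min(y)`, `L = range(y)`, `x0` at the level
nearest half-maximum, and slope 4 per unit of scaled intensity. Bounds
keep `L >= 0`, the slope in [0, 1] per uA, and `x0` inside the tested
range. The baseline bound deserves a note: min-max scaling pins the
smallest *observation* at 0, but the sigmoid's lower asymptote sits
slightly below it (for the noiseless 5-level ladder the scaled true
baseline is about -0.007), so constraining `b >= 0` makes the exact
solution infeasible and biases the recovered threshold by more than 1 uA.
The lower bound is therefore -0.5 on the scaled axis. Non-convergent fits
are returned with `converged = FALSE` and a diagnostic message, and are
excluded (and counted) from group statistics.

Group comparisons (`compare_groups()`) follow the assumption-driven
selection used for the behavioral statistics: Shapiro-Wilk per group and
Levene (median-centered) across groups at alpha 0.05; when both pass, a
parametric test (one-way ANOVA between subjects, repeated-measures ANOVA
within subjects, t test for two levels with Welch correction under
unequal variances); otherwise Kruskal-Wallis / Friedman / Mann-Whitney /
Wilcoxon signed-rank. Post hoc pairwise tests are Benjamini-Hochberg
adjusted. The branch taken is a pure function of the assumption p-values
and is recorded in the result. Mann-Whitney and signed-rank p-values are
exact by tie-aware enumeration at the small sample sizes of these designs
(enumeration whenever feasible, here up to several thousand arrangements),
with a tie-corrected, continuity-corrected normal approximation beyond.
Threshold correlations across channels use Spearman rank correlation with
an exact permutation p for n <= 8.

## 3. c-Fos activation statistics

Counts become densities (`compute_density()`: cells per mm^3 of atlas
volume). `differential_activation()` runs one two-sided Mann-Whitney U
test per region at alpha 0.05 and deliberately applies **no**
multiple-comparison correction — at 6-7 animals per group the screen is
exploratory and correction would inflate type II errors; the direction of
change is the sign of the median difference. Co-activation
(`coactivation_matrix()`) is the Pearson correlation of regional densities
*across* the animals of one group, for every region pair; zero-variance
regions produce `NA` (undefined) correlations that are excluded and
counted, never imputed as zero. Group co-activation distributions (the
upper matrix triangles) are compared with Kruskal-Wallis
(`compare_coactivation()`). An optional region blacklist keeps the
pipeline atlas-agnostic (hindbrain exclusions are one use).

## 4. Dyad coupling against a shuffled-pairing null

For regions significantly *increased* in both OBS and DEM versus CTR
(`select_shared_regions()`), `dyad_correlation()` computes the Pearson
correlation between paired observers and demonstrators across the true
dyads. Significance uses a surrogate distribution from 42 re-pairings
(`surrogate_null()`), a per-region threshold at the 95th percentile of the
surrogates, and a *strict* exceedance rule in the positive direction only
(`flag_coupled_regions()`).

Two conventions are fixed and one design choice deviates from the obvious
reading:

- **Percentile convention**: linear interpolation between closest ranks at
  position $(n+1)p$ (quantile type 6). For 42 surrogates the threshold
  falls between the 40th and 41st order statistics, and under an
  exchangeable null the strict rule then operates at its nominal 5% level
  ($ (n+1-h)/(n+1) = 0.05 $). Thresholds are per region; a pooled
  threshold across regions is available as an option.
- **Surrogate family**: the natural reading "no observer keeps its true
  demonstrator" (derangements only) turns out to be anti-conservative:
  derangements share pairs with one another but never with the true
  pairing, so the surrogate spread understates the null and the empirical
  false-positive rate roughly doubles (about 9% instead of 5% at 7 dyads,
  measured both with a Gaussian oracle and with the full pipeline). The
  default is therefore `method = "shuffle"` — distinct re-pairings drawn
  without replacement from all permutations except the true one — which is
  calibrated at the nominal level; `method = "derangement"` is retained
  as an option.

Min-max scaling of the per-region density vectors (`minmax_scale()`) is
produced for display only and never enters the statistics.

## 5. Brain-network analysis

`build_network()` assembles the weighted directed connectome from a region
list and an edge list of normalized connection densities; self-loops are
removed (and counted) and isolated regions retained. `partition_leiden()`
maximizes modularity with the Leiden algorithm at a configurable
resolution; igraph's Leiden implementation operates on undirected graphs,
so reciprocal edge weights are summed first. `hits_scores()` computes hub
and authority scores by the mutually reinforcing iteration (a node is a
good hub if it points to good authorities and vice versa); each score
vector is normalized to sum to 1, iterated to a 1e-12 tolerance. When the
dominant eigengap is numerically degenerate (e.g. symmetric disconnected
components) the iteration cannot separate the tied directions; the exact
principal eigenvectors of $W W^\top$ and $W^\top W$ are then used, or an
error is raised with the iteration count if `fallback = FALSE`.

`bootstrap_hits()` asks whether a region's hub/authority score in the
observed network is larger than expected for a random network of the same
size: in each of 1000 iterations the target is kept, the companion nodes
are resampled from the region pool, the subgraph is induced from the full
connectivity table, and the target's scores are recorded; significance is
the z-score of the observed score against the bootstrap distribution with
a one-tailed p from the upper normal tail (two-tailed optional). A zero
bootstrap sd leaves z and p as `NA`, reported explicitly. Edgeless
sampled subgraphs give all-zero scores (no importance without
connections). Note what this null does and does not test: the target's
own edges are present in every iteration, so a node that dominates *any*
company is not significant — significance means the node's score depends
on the specific company it keeps in the observed network (e.g. a hub
whose strong out-edges land on regions that are themselves part of the
activated set). `top_edge_filter()` keeps the `ceiling(f * E)` strongest
edges (stable input-order tie-break) for display only.

## 6. Synthetic data: what it emulates, and what it does not

All generators are pure functions of their seed.

**Sessions** (`simulate_pupil_session()`): an ascending-then-descending
ladder of 0/50/150/300/500 uA repeated 3 times (6 trials per level, 60 s
between stimuli, 20 Hz). Each stimulus evokes a transient with a 0.5 s
raised-cosine rise, a plateau to 2 s and a 2.5 s raised-cosine decay; the
plateau spans the 1-2 s scoring window so the windowed readout of a unit
transient is the trial amplitude itself. Amplitudes follow
`sigmoid(intensity; b = 0.05, L = 0.9, k = 0.02, x0 = 250)` plus Gaussian
jitter (sd `noise_sd`). The baseline is ongoing pupillary unrest modeled
as a 1 Hz phase-wandering oscillation with sd `noise_sd`, plus white
sensor noise of the same sd. The unrest frequency is a deliberate choice
on two measurable grounds: the order-6/31-sample Savitzky-Golay filter
passes 1 Hz at gain 0.978 while attenuating 2 Hz to 0.058, and one full
cycle per 1 s baseline window makes the prestimulus sd phase-independent —
per-epoch z-scoring presupposes a well-defined baseline variance, which
real pupil data has and white noise alone does not provide after
smoothing. Blinks default to 3 per minute as 2-5-sample V-shaped drops of
amplitude 5: real pupil tracks always contain blinks, and the relative
0.2 rule presumes their flanks dominate the derivative. Not emulated:
saccades, eye closures, slow arousal drift, camera dropouts — so passing
tests certify the chain's arithmetic and calibration, not robustness to
every real-world artifact.

**c-Fos studies** (`simulate_cfos_study()`): lognormal regional densities
(baseline log-mean `log(50)`, log-sd 0.5), region volumes lognormal and
constant across animals (atlas volumes), counts rounded so
`density = count / volume` holds exactly. Group activation is a log-scale
shift (`effect_log_fold`, default 1) in the configured region sets; the
default geometry (88 activated regions of which half are shared between
OBS and DEM, groups of 6/7/7) mirrors the dyadic design's structure. Dyad
coupling is one Gaussian latent factor per dyad, shared by both animals
and all coupled regions on the log scale — a dyad-level shared state that
both couples the pair and co-activates the shared regions within a group —
with the loading chosen analytically so the implied Pearson correlation of
the *densities* (not the log densities) equals `dyad_coupling_r`:
$\rho_{\log} = \log(1 + r\,(e^{s^2}-1))/s^2$. The lognormal family is a
modeling choice; nothing here asserts real c-Fos densities are lognormal.

**Connectomes** (`simulate_connectome()`): directed edges with probability
`p_within` inside and `p_between` across planted modules, lognormal
weights, optional planted hubs wired to planted authorities with strong
out-weights, no self-loops. This is a stand-in for an atlas-derived
connectome: it has planted ground truth but none of the spatial or
hierarchical structure of a real one.

**Frame transforms**: `phase_scramble_frames()` randomizes each frame's
2-D Fourier phase while preserving the amplitude spectrum exactly;
conjugate symmetry comes from drawing the phase field from the FFT of a
real white-noise image (one field per frame), and the zero-frequency
component (mean luminance) is copied unchanged. `invert_frames()` flips
rows and is an involution.

## 7. Problem sizes and numerical conventions in the checks

The package's property checks run at the study's own scale: 100 simulated
sessions for threshold recovery (median absolute threshold error about
14 uA at noise sd 0.05, median $R^2$ above 0.99); noiseless chain
fidelity within 0.5% of the generating sigmoid (the check uses the
baseline-subtraction mode, because z-scoring a noiseless trace divides by
a zero prestimulus sd by construction); exhaustive oracle agreement of
the exact tests up to n = 5; 500-1000 null studies of 7 dyads x 44
regions for calibration of the dyad test (flag rate within the binomial
interval around 5%); 300-500 studies for power at planted r = 0.9 (about
90% flagged); 150-200 random graphs for HITS oracle equality (<= 1e-8);
300-500 exchangeable-null replicates for bootstrap p uniformity (KS
distance < 0.1 at 200 bootstrap iterations); 50 seeds for Leiden
planted-partition recovery (mean adjusted Rand index 1.0 at
p_within = 0.6, p_between = 0.05, two 15-node modules); and three frame
sizes up to 128 x 128 for the transform invariants (1e-8 relative
tolerance). `scripts/acceptance.R` recomputes all of these from scratch.

Known limitations: the blink rule's relative threshold (discussed above);
Leiden on the symmetrized graph ignores edge direction; the derangement
surrogate option is anti-conservative by about a factor of two and is not
the default; bootstrap p-values are normal-tail approximations from a
z-score, so their finite-n uniformity is approximate; and the generators'
distributional families (lognormal densities, raised-cosine transients,
sinusoidal unrest) are modeling conveniences, not claims about real data.
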