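---
title: "Dynamic connectivity states: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic connectivity states: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dfncstates)
```

# The analysis in one paragraph

Resting-state fMRI component time courses are not stationary: their
correlation structure drifts between a small set of recurring *connectivity
states* over tens of seconds. This package implements the standard pipeline
for quantifying that drift in a paired-phase clinical cohort (two groups,
each subject scanned drug-OFF and drug-ON): tapered sliding-window covariance,
graphical-LASSO regularization, k-means clustering of windowed connectivity
under city-block distance, per-session temporal metrics (fractional windows,
mean dwell time, number of transitions), and a nonparametric statistical
battery with covariate-adjusted severity correlations. Because no patient
data ship with the package, every claim is exercised against a synthetic
cohort generator whose hidden-state structure is fully known, so recovery can
be scored exactly.

# The generative model behind the synthetic cohort

`simulate_cohort()` draws, for every subject and phase, a hidden state path
and conditionally Gaussian component time courses.

**Hidden state process.** A semi-Markov chain on $k$ states: run lengths are
geometric with state-, group- and phase-specific means $d_{gps}$ (in
timepoints, = windows at step 1), and on leaving state $i$ the next state is
drawn from selection preferences $s \propto \exp(\ell_{gp})$ with the current
state excluded. Geometric runs are the simplest process with a controllable
mean dwell time, which is the pipeline's key metric. The stationary occupancy
has the closed form
$\pi_i \propto s_i (1 - s_i)\, d_i$
(`stationary_occupancy()`), and the initial state is drawn from it, so
finite sessions are sampled from the stationary law. Each subject receives a
normal perturbation (SD 0.25) of the selection logits shared by both phases —
the subject-level random effect that gives paired tests their within-subject
correlation.

**State covariances.** `make_state_covariances()` builds each state's
component correlation matrix from a network factor model: every component
loads $\sqrt{0.25}$ on its network factor and, per state, a signed
network-level loading on one state factor, giving unit-diagonal,
positive-definite matrices without shrinkage adjustments. The five canonical
motifs echo commonly reported state structure qualitatively — a
visual/sensorimotor coupling state, an executive-centred state, a
visual-centred state with basal-ganglia decoupling, an executive/default-mode
state, and a weakly connected state (within-network 0.10, no state factor).
The loading values were fixed at design time so that the five centroids are
roughly equidistant in L1 (pairwise pattern distances ~38–55 in Fisher-z);
equidistance matters because it makes the cluster-validity curve decline
near-linearly up to the true $k$ and then flatten, which is what any elbow
detector needs. They are configuration, not empirical claims.

**Study design defaults.** 41 + 34 subjects, 230 timepoints at TR 2 s after
discarding 10 of 240 volumes. Baseline dwell is 80 timepoints (160 s) for
every state; the drug-ON phase plants the group contrasts: the first group
favours states 1–2 (selection 0.26/0.22, dwell 105) and avoids state 3
(selection 0.10, dwell 55), the second group concentrates in the weak state
(selection 0.48, dwell 100) and also avoids state 3. The drug-OFF phase is
identical for both groups (flat selection), so OFF contrasts are null. The
baseline dwell is at the long end of what sliding-window studies report; it
was chosen once, at design time, because with a 30-TR window a majority-state
label is only meaningful when runs are several window-widths long.

**Severity.** AIMS is linear in the subject's ON-phase occupancy of state 2
plus noise, floored at zero: slope 18, intercept 4.4, noise SD 4. With the
realized occupancy SD (~0.29) this reproduces the target sample moments
(~9.1 ± 6.5) and plants a correlation of ~0.8.

**Motion.** Six-parameter random walks (translation step SD 0.02 mm, rotation
step SD 4e-4 rad). A configurable fraction of subjects has steps scaled by 8,
which pushes mean framewise displacement past the 0.5 mm threshold; the
default fraction is 0 so that the default cohort is the post-QC sample.

**What the generator does *not* emulate** — and hence what passing tests do
not establish about real data: hemodynamic autocorrelation (time courses are
white within a state), scanner drift and physiological noise, spatially
correlated voxel noise, heavy-tailed motion artifacts, and any coupling
between motion and connectivity. Recovery results here are best-case in those
respects.

**Postprocessing and the low-pass.** The postprocessing stage (linear
detrend, MAD despiking, motion regression, zero-phase 0.1 Hz low-pass)
mirrors the standard time-course cleanup. One interaction deserves care: a
low-pass leaves inter-component correlations unbiased but autocorrelates the
series, roughly halving the 30-TR window's effective sample size at TR 2 s.
On real data that trade is favourable because component signals are already
band-limited and the filter removes out-of-band noise; on generator data the
state signal is spectrally flat, so the filter only discards information (in
pilots it collapsed window-state recovery). The pipeline's default for
synthetic cohorts therefore runs detrend/despike/motion regression but skips
the low-pass; real-data users should pass the full `postprocess_config()`.

# Window, taper and window count

Windowed covariance uses a rectangle of `width_tr` = 30 ones convolved with a
unit-mass discrete Gaussian (σ = 3 TR, truncated at 3.5σ), the taper
convention of the dFNC toolbox lineage. The support therefore extends
`pad = ceil(3.5σ)` timepoints beyond the nominal span on each side; weights
sum to the window width. At series boundaries the taper is clipped and the
weighted covariance renormalized. Window positions advance by `step_tr` = 1,
giving the identity `n_windows = floor((T − width)/step) + 1` (201 windows at
T = 230).

# Regularized windowed connectivity

Each window's tapered covariance is regularized by the graphical LASSO
(Friedman-style block coordinate descent, implemented in compiled code;
`rho = 0` returns the sample covariance exactly), converted to correlation,
and Fisher-z transformed with `|r|` clamped at `1 − 1e−7` (so r = ±1 maps to
z ≈ ±8.1). Clustering operates in z-space, matching the static-FC convention;
this is a convention choice, recorded here because the alternative (r-space)
is defensible too.

The penalty is selected per session by held-out Gaussian log-likelihood over
repeated random window splits (default 100 repetitions, 20% held out). Each
repetition fits the model to a *single* train-window covariance — the setting
in which the penalty is actually used — and scores it against the mean
held-out covariance; fitting to a mean train covariance instead would wash
out exactly the sampling noise the penalty exists to control and push the
selection toward zero. The default grid is log-spaced on [0.01, 1]. The
analysis scripts select the penalty once on a pilot session and reuse it
(selected and default value 0.1): the sessions are exchangeable by
construction and a shared penalty keeps centroids comparable.

# State clustering

City-block k-means: windows are assigned to the centroid at minimal L1
distance (ties to the lowest state index) and centroids are updated as
element-wise medians — the exact minimizer of summed L1 distance, which is
why the per-restart cost trace is non-increasing. An emptied cluster is
re-seeded at the point farthest from its centroid. The default is 500 random
restarts with the best total cost kept; at the full desk-scale problem
(30,150 windows × 231 pairs) the analyses and acceptance checks use 8–20
restarts, which pilot runs showed reach the same solutions on this data —
a problem-size choice of this package, stated here so the numbers are
reproducible. States are renumbered by descending total occurrence; state
numbering is therefore stable but data-specific.

# Choosing the number of states

For each candidate $k$ the validity index
$I(k) = \frac{\text{mean within-cluster L1 distance}}
             {\text{mean between-centroid L1 distance}}$
is computed. The elbow is placed at the interior $k$ maximizing the drop
ratio $(I(k{-}1) - I(k)) / \max(I(k) - I(k{+}1), \delta)$ — the point where
the index's improvement collapses — with $\delta$ = 1% of the curve's range
guarding the denominator, and a minimum accepted ratio of 1.5 (a curve with
near-constant drops, e.g. strictly linear, is reported as having no elbow).
An earlier design used the maximum discrete curvature
$I(k{-}1) - 2I(k) + I(k{+}1)$; on pilot generator runs that rule
systematically landed one below the planted $k$, because on a convexly
decaying curve the second difference peaks where the *first* large drop ends,
not where improvement stops. The drop-ratio rule recovered the planted
$k \in \{3, 5\}$ reliably in the same pilots and is scale-invariant, so it is
the package's operationalization of the elbow criterion.

# Temporal metrics and their biases

`temporal_properties()` run-length encodes a session's assignments:
fractional windows (percentage per state), mean dwell time (mean run length,
*terminal runs included* — excluding them biases short sessions), and number
of transitions (runs − 1). Unvisited states report zero with a `visited`
mask, so group-level vectors are complete.

Two biases are inherent and deliberately uncorrected. First, windows smear
state boundaries: a window is labelled by whatever dominates its 30-TR span,
so dwell estimated from window assignments blurs runs shorter than the
window. Second, runs are censored at both session ends; with a 230-timepoint
session and mean dwell 80 the pooled dwell estimate sits ~20% below the
generative mean *for any estimator*, which is why the test suite scores dwell
against a censoring-aware renewal oracle rather than the raw configured mean,
and why generative run lengths are verified separately on long sessions.

# Statistical battery

Between-group comparisons pass each arm through a Lilliefors-type normality
gate (Kolmogorov–Smirnov with estimated parameters, via `nortest`); both
normal → Welch t, otherwise Mann–Whitney U (exact for small untied samples,
normal approximation with tie correction otherwise). Paired OFF/ON contrasts
use the Wilcoxon signed-rank test with zero differences dropped; all-zero
differences are flagged degenerate with p = 1. Categorical tables use the
uncorrected Pearson chi-squared — on the demographic worked example (gender
22/19 vs 21/13) the uncorrected convention gives p = 0.480 against a printed
0.494, inside the band either convention allows; the continuity-corrected
value sits on the other side, and which was used originally is not
determinable.

Severity correlations are partial Spearman: all variables rank-transformed,
covariate ranks (age at onset, LEDD, disease duration) removed by least
squares, residuals correlated, p from the t approximation with
$n - 2 - n_{\mathrm{cov}}$ degrees of freedom. With no covariates this equals
plain Spearman exactly. The FDR family is the $k$ states within one metric
within one contrast (Benjamini–Hochberg, significance at adjusted
p ≤ 0.05); the family definition is not dictated by the battery itself and
other groupings are reasonable — it is exposed through the results table so
users can re-correct.

`run_full_comparison()` emits the four contrast families (between groups at
each phase; within each group across phases) for occupancy and dwell per
state plus transitions, and the severity correlations in the first group's ON
phase. Subjects missing a phase are dropped from paired tests with a warning;
degenerate cells (e.g. a state no one visits) yield flagged NA rows rather
than aborting the battery.

# Simplified group ICA

The voxel-mode stage is a deliberately reduced group spatial ICA: per-session
PCA over time, temporal concatenation, group PCA, then a fixed-point
contrast-maximization rotation (tanh nonlinearity, symmetric decorrelation)
with seeded multi-restart best-run selection. Model-order estimation and
run-stability clustering are configuration, not estimation, and spatial
preprocessing is out of scope. Back-reconstruction projects each session's
data through the group maps by least squares (the dual-regression form of
back-projection). Component selection follows the spectral convention: keep
components whose back-reconstructed time courses have a low-to-high-frequency
power ratio (bands [0, 0.1] / [0.15, 0.25] Hz, Welch spectra) of at least 10
and a dynamic range (peak power minus the minimum above the peak, on the
unit-sum spectrum) of at least 0.05, thresholds calibrated on the generator
where informative and noise components separate by orders of magnitude.
Labels come from the template map with the highest absolute spatial
correlation, ties to the lowest template index.

# Numerical choices

* Fisher-z clamp `1 − 1e−7`; glasso convergence `1e−4` on the mean absolute
  off-diagonal change, inner lasso tolerance `1e−7`, 100 sweeps maximum.
* k-means convergence `1e−6` relative cost change (heavy runs use `1e−5`),
  iteration cap 200 (heavy runs 25); ties in assignment break to the lowest
  state index; empty clusters re-seed at the farthest point.
* Despiking flags `|x − median| / (1.4826·MAD) > 4` and replaces flagged
  samples by natural-spline interpolation through their neighbours.
* The low-pass is an order-5 Butterworth at 0.1 Hz applied forward and
  backward (`signal::filtfilt`), i.e. zero-phase with ≥ 40 dB attenuation at
  0.2 Hz.
* Framewise displacement uses the Power convention: summed absolute backward
  differences with rotations converted on a 50 mm sphere; motion thresholds
  are strict inequalities, translations/rotations compared per axis (a
  convention choice — vector norms are the main alternative).
* One master seed fans out to per-stage and per-session child seeds through a
  deterministic hash (`derive_seed()`), so any stage re-runs bit-identically
  in isolation.

# Problem sizes used in checks

The end-to-end state-recovery check runs the full default cohort (75 subjects
× 2 sessions × 230 timepoints → 30,150 windows) for 5 seeds; elbow recovery
runs 10 seeds per planted k at 20 subjects; statistical calibration uses 1000
null replicates at the design's arm sizes; severity recovery uses the
hidden-path fast mode (no time courses) over 10 seeds. These sizes are the
package's choices for a reproducible desk-scale analysis.

# Known limitations

* The generator's realism limits are listed above; in particular temporal
  whiteness within states makes spectral component selection on generator
  time courses trivial unless signals are explicitly low-passed.
* Dwell estimates are censored and window-smeared (uncorrected, see above).
* The elbow is a heuristic; on data without a clear state structure it
  errors rather than guessing, by design.
* The ICA stage is a minimal reference implementation for testing the
  surrounding pipeline, not a replacement for a production ICA toolbox.
* Dyskinesia duration is not modelled (the underlying study design did not
  collect it) and chronological session order within a morning is ignored.
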