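---
title: "Methods: population analysis of bilateral load responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population analysis of bilateral load responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Primary motor cortex (M1) mainly drives the opposite (contralateral) limb,
yet many M1 neurons also respond when the same-side (ipsilateral) limb is
mechanically perturbed. If both limbs are represented in one population, how
does the ipsilateral signal avoid leaking into contralateral motor output?
One resolution is geometric: the two representations can occupy
near-orthogonal subspaces of population activity, so that a downstream
readout aligned with one context's subspace is blind to the other.

`motorload` implements the full analysis chain for testing this idea in a
postural perturbation task: step torques at the shoulder and/or elbow (eight
combinations, 45 degrees apart in joint-torque space, 0.20 Nm single-joint
and 0.14 Nm per joint multi-joint) applied to either limb while neurons in
one hemisphere are recorded. The pipeline covers per-neuron load tuning,
response onsets, pairwise correlation restructuring, and the subspace
analyses (alignment index, joint orthogonalization), each with its
matched null distribution. A synthetic session generator with controllable
ground truth stands in for recordings, so every stage has a recovery test.

## Preprocessing

**Smoothing.** Spike trains (1 ms resolution) are convolved with a causal
kernel shaped like a post-spike potential,
$k(t) \propto (1 - e^{-t/\tau_r})\, e^{-t/\tau_f}$ with
$\tau_r = 1$ ms rise and $\tau_f = 20$ ms fall, normalized to unit area and
truncated where it falls below $10^{-6}$ of its peak. Causality matters for
onset estimation: a Gaussian kernel would smear response energy backwards in
time. The kernel peaks at $\tau_r \ln(1 + \tau_f/\tau_r) = \ln 21 \approx
3.04$ ms. A Gaussian alternative (SD 20 ms) is provided for variance
comparisons with the PCA literature; swapping kernels changes matrix values
but no shapes or bookkeeping.

**Epochs.** All analyses use three windows relative to load onset: baseline
$[-200, 0)$ ms, perturbation $[0, 300)$ ms, and the last 1000 ms of the
trial (steady state). Windows are half-open; epoch means are arithmetic
means of the smoothed trace.

**Context matrices.** For each context the trial-averaged perturbation
traces are point-sampled every 10 ms (30 samples), each neuron is divided by
its maximum trial-averaged rate across both contexts plus 5 spikes/s (soft
normalization, bounding high-rate neurons' influence), and the mean across
the eight load conditions is subtracted at every time bin. The result is an
$N \times 240$ matrix per context ($8$ conditions $\times$ 30 bins), rows
zero-mean by construction. All recorded neurons enter these matrices,
load-sensitive or not. Two sampling conventions were open: the 10 ms grid
starts at 0 ms (not 5 ms), and sampling is point sampling, not bin
averaging. Note that because the soft-norm divisor depends on a neuron's
maximum rate, adding a constant to one neuron's rates rescales (rather than
leaves identical) its matrix rows; the direction of the rows is unchanged.

## Per-neuron statistics

**Load sensitivity.** A three-way factorial ANOVA (epoch 2 x context 2 x
load 8, Type-II sums of squares) on per-trial epoch means; a neuron is load
sensitive when the epoch main effect or any epoch-involving interaction has
p < 0.05. Per-trial (rather than trial-averaged) observations were chosen so
the test has well-defined degrees of freedom; no multiple-testing
correction is applied, matching the convention for this threshold.

**Preferred loads.** Per neuron, context, and epoch, a plane
$r = b_0 + b_s \tau_s + b_e \tau_e$ is fit by least squares to mean-centred
per-trial epoch means; the preferred load is $\mathrm{atan2}(b_e, b_s)$ and
the magnitude $\sqrt{b_s^2 + b_e^2}$ (Hz/Nm). The p-value is the overall
regression F-test (a single per-fit p, rather than per-coefficient t-tests).
Population structure is summarized by Rayleigh statistics: the unimodal R is
the mean resultant length of unit vectors at the preferred angles, the
bimodal R doubles the angles first (axial structure). Significance comes
from a bootstrap against uniform angles with matched n (1000 draws, seeded);
p is the fraction of uniform draws with an R at least as large.

**Onsets.** Per neuron, the load with the largest absolute change of the
perturbation-epoch mean from baseline is pooled with its two 45-degree
neighbours; the onset is the first millisecond at which the trial-averaged
trace deviates from the baseline mean by more than three baseline SDs and
stays beyond threshold for 20 consecutive ms. The criterion is two-sided by
default (neurons may be suppressed); a one-sided switch exists. The
population onset applies the same rule to the across-neuron average of
best-load traces, each signed so its perturbation-epoch change is positive
(preventing cancellation of excited and suppressed neurons). For the
population trace the best load and the sign are selected on half of the
trials (odd indices) while the averaged trace uses the other half: selecting
on the trace's own trials couples the rectification sign to trace noise and
imprints a spurious population-level step at load onset (we observed onsets
of 0 ms without the split). `selection = "all"` restores the single-sample
rule for comparison.

## Correlation restructuring

Pearson correlations between all neuron pairs' context-matrix rows yield one
coefficient per pair per context; the statistic is the median absolute
difference across pairs. Its null holds tuning fixed and asks what finite
trial counts alone produce: trials of one context are randomly halved within
every load condition, two trial-averaged matrix variants are built (with the
full-data soft-norm divisors), and the median absolute correlation
difference between halves is recorded; 1000 seeded replicates per context,
and the observed value is compared against each context's null separately.
With an odd number of trials the larger half takes the extra trial.

## Subspace analyses

**PCA and the alignment index.** PCA (via SVD) of each context matrix gives
orthonormal neuron-weight components. With top-$k$ components $P_A$ of
context $A$ and the covariance $\Sigma_B$ of context $B$,

$$ A_{A\,\mathrm{on}\,B} \;=\;
   \frac{\mathrm{Tr}(P_A^{\top} \Sigma_B P_A)}{\sum_{i=1}^{k}
   \lambda_i(\Sigma_B)} \in [0, 1], $$

i.e. the variance of $B$ captured by $A$'s components, normalized by the
most any $k$ orthonormal directions could capture. 0 means orthogonal
subspaces, 1 perfectly aligned; $k = 10$ by default. Both directions are
computed and averaged.

**The variance-weighted null.** PCA is run on the column-wise concatenation
of the two context matrices; each replicate samples two sets of $k$
components without replacement, with selection probability proportional to
the variance captured, and scores them against the two covariances exactly
as in the observed computation. The wording of the procedure leaves open
whether the two sets must be disjoint. We draw them independently by
default (`disjoint = FALSE`) because only that variant calibrates: with
forced-disjoint sets every strong shared component is counted in exactly one
of the two sets, so for identical contexts the null concentrates near half
the observed self-alignment and a same-context split is falsely flagged as
orthogonal. Under independent sampling the negative control (two random
halves of one context) lands inside the null's central 95% and truly
orthogonal contexts fall below its 1st percentile. The forced-disjoint
variant remains available behind the flag.

**Joint orthogonalization.** To find bases that capture each context while
being mutually orthogonal, we maximize

$$ \frac{1}{2}\left[
   \frac{\mathrm{Tr}(Q_c^{\top} \Sigma_c Q_c)}{\sum_{i=1}^{d} \lambda_i(\Sigma_c)} +
   \frac{\mathrm{Tr}(Q_i^{\top} \Sigma_i Q_i)}{\sum_{i=1}^{d} \lambda_i(\Sigma_i)}
   \right] $$

over jointly orthonormal $[Q_c \,|\, Q_i]$, an optimization on the Stiefel
manifold of $2d$-frames ($d = 3$). The normalizers are taken as eigenvalues
of the covariances (not singular values of the data matrices), which makes
the objective's maximum exactly 1. The solver is Riemannian gradient ascent
with QR retraction, Barzilai-Borwein step sizes with Armijo backtracking,
convergence at gradient norm $10^{-6}$ (cap 2000 iterations), and
multi-start: the per-context top-$d$ eigenvectors projected to the nearest
jointly orthonormal frame (polar factor) plus four random frames. The
returned objective never falls below the projected-PCA start, and the
orthogonality residual is held to $10^{-8}$.

**Projection differences and weight balance.** Both context matrices are
projected onto a context's orthogonal basis and compared by the
Frobenius-norm relative difference (percent of the reference projection).
Variability comes from resampling the non-reference context's trials with
replacement within each condition (1000 replicates; percentile CI; the p
reported is the fraction of replicates at or below zero difference). To
check that orthogonality does not come from two disjoint neuron groups, each
neuron's absolute weight summed over the top-$k$ components of each context
forms the index $(w_i - w_c)/(w_i + w_c) \in [-1, 1]$; a one-sample
Kolmogorov-Smirnov test compares the standardized indices to normality.

## The synthetic session generator

Ground truth is built backwards from what the analyses must recover. Two
orthonormal neuron bases (one per context, $d = 3$ columns) are constructed
from a random $2d$-frame whose halves are mixed so the mean squared cosine
of their principal angles equals the requested `alignment` exactly. Each
latent dimension carries a preferred direction in joint-torque space drawn
from an axial von Mises distribution (doubled angles are von Mises; major
axis 135 degrees, concentration 2), which makes the neuron-level
preferred-load distribution axially bimodal, as observed. Latent responses
per condition are the planar amplitude (tuning direction dotted with the
torque) times a temporal profile; neuron rates are baseline plus basis times
latents plus a load-independent evoked component, rectified at zero; spikes
are inhomogeneous Poisson at 1 ms.

Defaults are the study conditions: 100 neurons, 10 trials per condition per
context, perturbation onset uniform in 500-1000 ms of hold, 1300 ms of
post-load recording, contralateral median planar magnitude 30 Hz/Nm
(between the two animals' reported 39 and 24) with a 2:1 contra:ipsi gain
ratio, and onsets of 25 ms (contra) and 35 ms (ipsi).

Choices the recordings do not pin down, made once and documented here:

- **Temporal profile.** A 15 ms linear rise to a transient peak of 3x the
  sustained level, a 100 ms linear decay to the plateau, held to trial end.
  Perturbation-evoked M1 responses burst and then settle; a shallow ramp
  without the transient cannot support millisecond-scale onset recovery with
  a threshold detector, because the crossing delay (threshold over slope)
  then differs between contexts by more than the configured lag tolerance.
  Magnitude calibration divides out the profile's perturbation-epoch mean so
  planar-fit magnitudes land on target regardless of profile shape.
- **Untuned component.** Each neuron receives a load-independent evoked
  response of 0.75x its tuned magnitude, mirroring the large
  condition-independent component of cortical perturbation responses; it
  also keeps suppressed lobes away from the zero-rate floor (rectification
  otherwise shaves the stronger contralateral responses and biases the
  recovered gain ratio low). The cross-condition mean subtraction removes
  this component from all context-matrix analyses.
- **Baseline rate 10 Hz**, a typical M1 hold-period rate; Poisson spiking is
  used for its known count statistics.

What the generator does not emulate: non-Poisson dispersion, slow
excitability drift, correlated trial-to-trial noise across neurons
(signal correlations arise only through shared latents), EMG/kinematic
channels (synthetic peripheral traces are generated separately in the
analysis scripts), and any within-session nonstationarity. Passing recovery
tests therefore validates the estimators under idealized variability, not
robustness to those realistic nuisances.

## Numerical conventions

- Spike times are integer milliseconds; bin $t$ covers $[t, t+1)$ ms; all
  windows are half-open.
- Convolution is FFT-based over the full trial with zero padding (baseline
  windows start 500+ ms into the trial, past the kernel's 280 ms support),
  and rates below $10^{-9}$ Hz are floored to zero so silence is exact.
- Best-load ties break to the lower load index; circular differences live in
  $(-180, 180]$; preferred angles in $[0, 360)$.
- Wilcoxon signed-rank statistics use the normal approximation with tie
  correction and drop zero differences.
- Every stochastic routine takes an explicit seed, and reports store the
  seeds, so reruns are bit-for-bit reproducible.

## Problem sizes in the test suite

The recovery tests run at the study scale of 100 neurons and 10 trials per
condition: five alignment levels x 10 seeds for the alignment-recovery
curve, the ten orthogonal-truth sessions reused for the null calibration and
the same-context negative control, and five sessions for onset-lag and
gain-ratio recovery (medians across seeds). Stochastic-calibration checks
use 200-300 replicates (Rayleigh uniformity, onset false positives) and
30-neuron sessions for the trial-count monotonicity of the correlation
null. Unit tests run on toy fixtures built in code.

## Known limitations

- The onset detector's crossing delay depends on response amplitude, so the
  recovered contra-ipsi lag carries a small positive bias (the weaker
  ipsilateral trace crosses threshold relatively later); medians across
  sessions stay within +-5 ms of the configured 10 ms lag.
- The trial-split correlation null assumes exchangeable trials within a
  condition; slow drift would widen the real null.
- The joint orthogonalization is non-convex; multi-start makes the reported
  optimum reliable in practice (it matches brute force on low-dimensional
  toys) but carries no global guarantee.
- With small neuron counts (< ~2k) the alignment null cannot draw two sets
  of k components and fails loudly; choose k accordingly.
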