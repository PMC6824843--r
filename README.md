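# motorload

Population analysis of contralateral and ipsilateral mechanical-load
responses in primary motor cortex (M1).

M1 chiefly drives the opposite limb, yet many of its neurons also respond
when the *same-side* limb is perturbed. `motorload` implements an analysis
pipeline for trial-structured spike recordings from a postural perturbation
task — step torques at the shoulder and/or elbow (eight combinations, 45°
apart in joint-torque space) applied to either limb — that asks how one
population represents both limbs without cross-talk:

- **Preprocessing** — causal post-spike-potential kernel smoothing
  (1 ms rise, 20 ms fall), epoch means (baseline / perturbation / steady
  state), and soft-normalized, mean-subtracted context matrices
  `C, I ∈ R^{N×CT}` (8 conditions × 30 ten-ms samples).
- **Tuning** — three-way load-sensitivity ANOVA (epoch × context × load),
  planar preferred-load fits `r = b₀ + b_s τ_s + b_e τ_e` (preferred angle
  `atan2(b_e, b_s)`, magnitude in Hz/Nm), Rayleigh unimodal/bimodal
  statistics with a uniform bootstrap.
- **Onsets** — best-load population traces with the 3-SD / 20-ms-dwell
  threshold rule and paired context contrasts.
- **Correlations** — pairwise signal-correlation change between contexts
  against a finite-trial split null.
- **Subspaces** — per-context PCA; the alignment index
  `A = Tr(P_Aᵀ Σ_B P_A) / Σᵢ₌₁ᵏ λᵢ(Σ_B)` with a variance-weighted
  random-subspace null; joint orthogonal subspaces `Q_c ⊥ Q_i` by Stiefel
  manifold optimization; relative projection differences
  `‖C_proj − I_proj‖_F / ‖C_proj‖_F × 100`; a neuron-weight balance check.
- **Peripheral** — EMG Butterworth chain (20–200 Hz band-pass,
  rectification, 100 Hz low-pass) with epoch ANOVA, and integrated hand
  speed.
- **Synthetic sessions** — a Poisson-spiking generator with exact
  ground-truth subspace alignment, tuning, gains, and onset lags, so every
  estimator has a recovery test without external data.

## Worked example

The numbered scripts under `analysis/` run the full study on a synthetic
session (100 neurons, 10 trials per condition, ground-truth alignment 0,
2:1 contra:ipsi gain, 10 ms ipsilateral onset lag):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_tuning.R
Rscript analysis/04_onsets.R
Rscript analysis/05_correlations.R
Rscript analysis/06_subspace.R
Rscript analysis/07_peripheral.R
```

Output from a run (`results/` holds the tables):

```
load-sensitive: 96/100 neurons
contra: bimodal R 0.52, axis 122 deg, p 0.000 (n=96)
magnitudes: contra 31.1 vs ipsi 15.6 Hz/Nm (78% larger contra, z 6.4)
population onsets: contra 36 ms, ipsi 48 ms (lag 12 ms, n=96)
median |delta r| over 4950 pairs: 0.318
contra trial-split null: mean 0.101 (sd 0.004), p 0
alignment index 0.17 (null 0.66 +- 0.12, p 0.003)
orthogonal dims: contra 51%/1% (own/other), ipsi 31%/2%
relative difference in contra dims: 100% (95% CI 99-104)
weight balance: KS D 0.081, p 0.53 (n=100)
```

Reading these: nearly every neuron is load sensitive, preferred loads are
axially bimodal, contralateral responses are about twice as large
(31 vs 16 Hz/Nm) and ~12 ms earlier than ipsilateral ones. Pairwise
correlations restructure between contexts far beyond what finite trial
counts explain (0.318 vs a null near 0.10), the two contexts' top-ten
principal components are far less aligned than variance-matched random
subspaces (0.17 vs 0.66), and jointly orthogonalized dimensions capture
half of their own context's variance while seeing ~1–2% of the other's —
ipsilateral activity projected into contralateral dimensions differs from
the contralateral activity by ~100%, i.e. it is essentially invisible
there. The weight-balance index stays normal: orthogonality is not produced
by two disjoint neuron groups.

Equivalently, `run_pipeline(pipeline_config(sim = sim_config(seed = 1)))`
executes every stage in one call and writes `report.json`.

## Package layout

- `R/` — implementation (loads/session IO, simulator, preprocessing,
  tuning, onsets, correlations, subspaces, peripheral, pipeline).
- `analysis/` — the numbered study drivers shown above.
- `tests/testthat/` — unit, property, and acceptance tests (oracles: exact
  trace arithmetic, brute-force grid search for the Stiefel optimum,
  ground-truth recovery, null calibration).
- `vignettes/motorload-methods.Rmd` — the methods notes: model
  assumptions, parameter choices, numerical conventions, limitations.
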