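---
title: "Causal flow, interventional connectivity, and the ground-truth network study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal flow, interventional connectivity, and the ground-truth network study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Targeted stimulation experiments need *efficacious* sites: units whose
perturbation actually moves the rest of the circuit. Finding them by trial
and error is slow and invasive. This package implements and validates a
statistical alternative: infer the **causal flow (CF)** between
simultaneously recorded units from resting activity alone, using convergent
cross-mapping, and test whether CF predicts **interventional connectivity
(IC)** — the measured effect of stimulating each unit.

Both observables are N x N matrices in one orientation convention used by
every function in the package: **rows are targets, columns are sources**.
Column `j` of the CF matrix is the causal-flow vector `f^(j)` of source `j`;
column `j` of the IC matrix is the perturbation vector `s^(j)`.

## Causal flow from convergent cross-mapping

A scalar series `x_i(t)` is lifted to delay vectors
`X_i(t) = (x_i(t), x_i(t - tau), ..., x_i(t - d*tau + tau))`
(`delay_embed()`). If unit `j` drives unit `i`, the attractor reconstructed
from the *target* `i` contains the driver's state, so `x_j` can be predicted
from neighbors in `i`'s delay space; the converse fails when `i` has
dynamics of its own that `j` never sees. `cross_map()` implements simplex
projection: the prediction at time `t` is the weighted average of source
values at the times of the `k = d + 1` nearest library neighbors of the
target's state, with weights `exp(-dist/dist_min)`. Accuracy is the Pearson
correlation between held-out predictions and truth, mapped through the
Fisher z transform (`atanh`, clipped at `|rho| = 1 - 1e-12` so finite
samples cannot produce infinite z). `F[i, j] = z(rho(X_j | X_i))` is the
causal flow from `j` to `i` (`compute_cf_matrix()`).

Cross-validation uses contiguous blocks (default 5) and a Theiler window of
`(d - 1) * tau` samples that excludes temporally adjacent states from every
library: smooth autocorrelated series would otherwise predict themselves
through shared time, not shared dynamics. Neighbor ties are broken toward
the earlier time index, making every result bit-reproducible.

### Hyperparameters

* `tau = 4` samples by default — the delay the monkey-array analyses use at
  1 ms bins, and a small fraction of the simulated driver's orbital period
  after binning.
* `d` is chosen by `select_hyperparameters()`: accuracy grows with `d` until
  the attractor unfolds, then plateaus; the smallest `d` whose median probe
  accuracy is within `plateau_tol = 0.02` z-units of the grid maximum is
  selected (grid default 2..10). When the accuracy is still rising at the
  grid edge the function warns and flags `plateau = FALSE`. We fix `tau` and
  scan `d` — scanning both jointly always favors the largest window and
  defeats the plateau rule.
* `k = d + 1` neighbors, the minimal simplex in d dimensions.

### Significance by twin surrogates

The null hypothesis for each ordered pair is "the target's dynamics carry no
information about the source beyond their own temporal structure".
`find_twins()` computes a recurrence partition of the target's embedded
states: neighbors are states closer than a radius (the 0.1 quantile of
pairwise max-norm distances); states with *identical* neighbor sets are
twins — dynamically interchangeable points of the attractor.
`generate_surrogates()` re-threads the trajectory: at each step the walk
follows the recorded successor with probability `(n - 1)/n` (class size `n`)
or jumps to a twin and continues from the twin's successor. Surrogates
preserve the value set and the attractor geometry while destroying the
temporal alignment with every other series. `cf_significance()` recomputes
`F[i, j]` with the reconstructor replaced by each of 99 surrogates and
reports the add-one empirical p-value `(1 + #{F_surr >= F_emp}) / (1 + n)`;
per-pair significance at `alpha = 0.05` is the default reporting convention,
with an
optional Benjamini-Hochberg flag. On chaotic desk-scale embeddings (~1000
states) typically 1-3% of states have a twin, so many surrogate steps follow
the original trajectory from a random starting phase; the test then behaves
like a trajectory-rethreading/time-shift null, which our calibration tests
show holds its size (false-positive rate ~3% at alpha = 0.05 on independent
noise).

## Interventional connectivity

A stimulation session (`run_perturbation_session()`) repeats a brief pulse
on one unit. For each target, `extract_windows()` sums activity in the
200 ms window before pulse onset and after pulse offset (the pulse interval
itself is excluded — on real arrays it is contaminated by stimulation
artifacts), one scalar per trial per side. `S[i, j]` is the two-sample
Kolmogorov-Smirnov statistic between the pre and post distributions across
trials (`ks_statistic()`, exact sup-difference of the ECDFs over pooled
points, hence invariant under monotone transforms of the activity).
Significance uses within-trial label permutation (default 999 flips) rather
than the asymptotic KS formula, which is anticonservative for the tied,
discrete values binned activity produces.

## The ground-truth simulator

`simulate_network()` integrates a 3 + `n_y` node network: a chaotic Rossler
driver `X` (canonical `alpha = beta = 0.2`, `gamma = 5.7`) feeding `n_y =
100` leaky rate units
`tau0 dy/dt = -lambda y + 10 tanh(J_YX x + J_YY y + I)`, with `J_YX = g *
ones` and `J_YY ~ N(0, g_r^2)`. There is no feedback from Y to X, so ground
truth is known: X is causally upstream, and stimulating Y must never affect
X. Integration is fixed-step RK4 (`dt = 0.01`), deterministic and
bit-reproducible under the seed, with an overflow guard at `1e6` that turns
unstable parameter choices into an explicit "trajectory diverged" error.
Optional dynamical noise (Euler-Maruyama increments on the driven units) and
an additive observational-noise stage (`inject_noise()`, exact per-unit SNR
in dB, private or shared-scalar mode) cover the two noise interpretations; a
softplus-Poisson observation layer (`poissonify()`) emulates spike counts.

### Parameter choices that matter

* **`g_r = 0.02`** (recurrent weight scale). The driven units' effective
  recurrent gain is `10 * g_r * sqrt(n_y)` because the transfer function has
  slope 10 at the origin. The default puts that gain at 2, just past the
  autonomy transition: each driven unit then carries the driver's imprint
  *and* private recurrent fluctuations. Both properties are load-bearing —
  at gain 5 the feed-forward drive (input s.d. ~0.8) drowns under recurrent
  input (s.d. ~4) and nothing about the driver can be reconstructed; at
  gain <= 1 the driven units are fully enslaved functions of the driver and
  cross-mapping becomes symmetric, erasing directionality.
* **Time units.** One model time unit is the leak time constant `tau0`,
  mapped to 50 ms of experimental time (a cortical rate time constant). The
  100 ms stimulation pulse is therefore 2 time units (200 samples) and the
  200 ms comparison windows 400 samples.
* **Pulse port and strength.** The pulse current (`S = 5`) enters driven
  units inside the tanh, where the external drive `I` enters — responses
  saturate naturally at the transfer function's bound — and additively in
  the Rossler rate equations, which have no input port (large currents there
  destabilize the quadratic Rossler term; 5 is strong without divergence).
* **Trials.** 40 jittered, non-overlapping trials per stimulated unit, with
  inter-trial gaps of 10 pulse durations; the KS statistic at n = 40 has a
  noise floor around 0.17, which bounds the resolvable IC.
* **Analysis bin width.** Embedding and the baselines run on series
  thinned by a factor of 10 (`decimate_ensemble()`, one sample per
  0.1 time units, ~60 samples per driver orbit, 2000 samples per resting
  run). Plain decimation preserves the driven units' private fast
  fluctuations, which carry the directional signal; `bin_ensemble()`
  (within-bin averaging, the analog of binned spike counts) is the better
  choice for recordings with per-sample observation noise, which it
  suppresses by sqrt(bin), at the cost of smoothing away exactly those
  fast private components.

## Baselines

Univariate Granger causality (`gc_univariate()`, BIC order selection over
1..10, F-test), conditional/multivariate GC (`gc_multivariate()`), extended
GC (`gc_extended()`, locally linear fits in 10% phase-space neighborhoods),
RBF-nonlinear GC (`gc_nonlinear_rbf()`, k-means centers, median-distance
width), and transfer entropy (`transfer_entropy()`, plug-in over
equal-occupancy bins with circular-shift bias subtraction). All scores
follow the `ln(RSS_restricted / RSS_full)` (or bits) convention and the
shared matrix orientation; time-shift surrogate significance mirrors the
CF testing burden.

## Evaluation

`prediction_tests()` joins a connectivity matrix with an IC matrix over
ordered pairs and reports the Pearson correlation, the IC-on-connectivity
regression, Welch two-group comparisons (IC for significant vs
nonsignificant connectivity and vice versa — Welch because the significant
group is typically much smaller), per-source Gini coefficients, and — given
an electrode geometry — the same statistics after bin-mean distance
detrending (`residualize_distance()`; bin means rather than a parametric
spatial fit because they are assumption-free; an exponential fit can be
emulated by passing custom bins). `gini()` uses the population pairwise
formula: 0 for uniform vectors, 0.5 for exponential samples, large when a
few targets dominate — the signature of hierarchical connectivity.
`cf_hierarchy_pca()` projects CF columns on two principal components and
2-means-clusters them; on the simulator this can recover the X/Y partition,
though not for every network realization at the default coupling (an
occasional weakly coupled unit dominates the first component).

`simulation_study()` packages the full validation protocol — simulate,
subsample 10 units (3 driver + 7 evenly spaced driven), select `d`, compute
CF, stimulate every subsampled unit in its own session, compute IC, and
correlate CF and univariate GC (optionally all baselines) with IC over the
90 ordered pairs. `scripts/acceptance.R` runs five replicate studies at
seeds derived from `--seed` and reports the seed-averaged correlations.

## What the generator does and does not emulate

It reproduces the features the method claims to exploit: deterministic
nonlinear dynamics under sparse subsampling, a known causal hierarchy,
common drive (every driven unit receives the same summed driver input — a
worst-case common-input confound), controlled private/shared noise, and
pulse perturbations with pre/post comparison windows. It does not emulate
spiking biophysics, electrode crosstalk or stimulation artifacts,
nonstationary behavioral states, or the spatial wiring of a real array
(geometry is attached synthetically via `make_grid_geometry()`). Green
tests on this generator therefore validate the statistical machinery and
its directional logic, not performance on any particular recording system.

## Numerical conventions and degenerate inputs

0-based time in tibble output, half-open windows `[t0, t1)`; neighbor and
quantile ties broken deterministically; `rho` clipped before `atanh`;
add-one permutation and surrogate p-values (never exactly zero); constant
units flagged missing with a warning rather than failing the whole matrix;
all-zero vectors are an error for the Gini coefficient; empty distance bins
stay missing, never interpolated; every stochastic step takes an explicit
seed and identical seeds give byte-identical results.

## Known limitations

* Desk-scale series (2000 analysis bins) sit at the short end of what
  convergent cross-mapping needs; weakly coupled pairs are attenuated, and
  the absolute CF-IC correlation under the default conditions is smaller
  than what longer recordings or other network parameterizations could
  yield, although the method ordering (CF above the information-based
  baselines) is stable across seeds.
* In a noiseless deterministic network the driver genuinely predicts the
  shared component of every driven unit, so reverse-direction cross-maps
  carry real information and can reach significance; directionality should
  be read from the forward/reverse asymmetry, not from the reverse test
  alone.
* Pairwise CF cannot resolve triplet or higher-order interactions, and
  significance is per-pair by default (no multiplicity correction), matching
  the reporting convention of per-pair stimulation analyses.
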