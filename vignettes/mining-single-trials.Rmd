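---
title: "Mining representative single trials with proximity graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining representative single trials with proximity graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(trialmine)
```

## The problem

Evoked responses (ERPs) are small relative to ongoing brain activity, so
a condition is recorded over many stimulus-locked epochs ("single
trials") and averaged. The textbook assumptions behind averaging — every
trial carries the same time-locked response plus zero-mean noise — are
both wrong in practice: the response's amplitude and latency drift with
attention, fatigue and habituation, and some epochs are simply atypical.
Averaging everything can smear or bury the component of interest; peak
amplitude and latency read off such an average are unreliable.

trialmine implements a data-driven alternative: **select a representative
subset of trials first, then average only those**. No template is
assumed; the selection comes from the geometry of the trials themselves.

## The pipeline

For one condition at one sensor (`n_trials x n_samples` matrix):

1. **Preprocess.** Zero-phase band-pass filter (FIR or Butterworth IIR,
   forward-backward so the net phase response is zero), applied to the
   trials concatenated end-to-end and re-split, then per-trial baseline
   correction.
2. **Compare trials.** Pairwise **distance correlation** (the sample
   V-statistic: double-centered pairwise-distance matrices, their mean
   elementwise product normalized by the geometric mean of the distance
   variances). dCor lies in [0, 1], detects nonlinear dependence, and is
   invariant to shifting and rescaling either series. The trial distance
   is `1 - dCor`, giving a symmetric matrix with zero diagonal.
3. **Embed.** Classical (Torgerson) multidimensional scaling places the
   trials in the plane: double-center the squared distances, take the two
   leading non-negative eigenpairs, coordinates are eigenvector times
   sqrt(eigenvalue). Deterministic up to axis signs, which are fixed by a
   convention (largest-magnitude coordinate of each axis is positive).
4. **Connect.** The **Gabriel graph** joins trials `p, q` iff no third
   trial lies strictly inside the disk with diameter `pq` — equivalently
   `d(p,q)^2 < d(p,k)^2 + d(q,k)^2` for all other `k`. It sits in the
   containment chain EMST ⊆ RNG ⊆ GG ⊆ DT, so it is always connected;
   all four graphs are available.
5. **Select hubs.** Trials whose Gabriel degree is at least `k`
   (default 4) — nodes in the core of the variability cloud, each
   directly similar to several distinct neighbors — are the
   representatives. Their mean is the evoked estimate.
6. **Estimate.** Peak amplitude and latency are the global extremum of
   the chosen polarity inside a post-onset window; hub scatter is
   summarized by a weighted **global efficiency**, and reliability across
   subjects by a coefficient of variation.

```{r pipeline}
sim <- simulate_trials(sim_config(snr_target = 2, seed = 1))
res <- mine_trials(sim$trials)
glance(res)
```

```{r plot, fig.alt = "Gabriel graph over embedded trials with hubs circled"}
autoplot(res)
```

Every stage is deterministic: the same input and configuration reproduce
the same selection bit for bit, and the core chain (distances, embedding,
graph, hubs) is equivariant under permutation of the trial order. The
concatenated filter stage is the one exception — it deliberately treats
the trials as one continuous recording, so it is applied before any
reordering.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `filter_kind` | FIR | FIR = linear-phase windowed-sinc; IIR = Butterworth band-pass. |
| `filter_order` | 2 | Design order. FIR tap count is `order * 3 * round(fs / low_edge)` (the convention of the common EEG filtering tool, where length is tied to the low cut-off); the forward-backward pass doubles the effective magnitude order. |
| `band` | 0.5–45 Hz | Band edges; must be inside (0, Nyquist). |
| `degree_k` | 4 | Hub degree threshold, 1–8. Larger `k` keeps fewer, more central trials; selection size is non-increasing in `k`. |
| `baseline_window` | first 25 ms | Per-trial mean-subtraction window (half-open, seconds). With no pre-stimulus segment the earliest samples are the least stimulus-driven, hence the default. |
| `polarity` | negative | Peak search direction. The deflection sign depends on the contrast (e.g. deviant-minus-standard components are negative), so it is an explicit input, never inferred. |
| `post_stimulus_window` | [0, 0.4) s | Peak search window. |

The defaults are the combination that maximized SNR in the reference
analysis (FIR, order 2, k = 4, 0.5–45 Hz). `optimize_settings()` rescores
the full 2 x 3 x 4 grid (filter kind x order x degree) on your own
(stimulus x sensor) cells: each combination earns the percentage of cells
in which it attains the cell's maximum SNR; ties break toward FIR, lower
order, higher k.

The SNR itself is `mean(average^2) / mean(residual^2)` over the selected
trials. Identical trials give zero residual power; the ratio is then
capped at `1e12` with a warning. The all-trial variant (select
everything) is the baseline the selection is compared against.

## The synthetic-trial generator

`simulate_trials()` emulates the reference recording geometry: 128 trials
of 205 samples at 512 Hz (a 400 ms post-onset epoch). Each trial is

    a_i * template(t - delta_i) + noise_i(t)

* **Template**: a negative Gaussian deflection, unit depth, centered
  150 ms post-onset, 60 ms FWHM — an MMN-like component. Any sampled
  waveform or function of time can replace it.
* **Amplitude scale** `a_i`: lognormal with natural-scale mean 1 and
  sd 1.2, truncated to (0.2, 5) by rejection. Right-skewed, as empirical
  single-trial amplitudes are.
* **Latency shift** `delta_i`: zero-mean normal, sd 15 ms by default,
  clipped so the shifted peak center stays at least 25 ms inside the
  epoch. The source design lists latency-variation levels that we read as
  15–17 ms: jitter on the order of the component's own width (the
  literal 150–170 ms reading) would leave trials with no shared signal
  support, pile a fifth of the clipped draws onto one boundary value, and
  make every reported recovery result unreachable; at 15–17 ms all of
  them reproduce. The parameter is fully exposed, so the larger values
  can still be run.
* **Scenarios**: `"common"` draws one `(a, delta)` pair shared by every
  trial of a dataset; `"independent"` draws per trial.
* **Noise**: a stationary AR(5) process (default coefficients give the
  low-frequency-weighted spectrum typical of ongoing EEG;
  `fit_ar_noise()` estimates coefficients from your own baseline data by
  Yule-Walker, and `select_order_aic()` picks an order). The noise is
  scaled so that realized SNR — template mean-square over noise
  variance — matches `snr_target` (reference levels 0.5, 1, 2);
  `snr_target = Inf` gives noise-free trials.

Per-trial ground truth (scales, shifts, realized peak of each noiseless
trial, and the dataset's noiseless mean signal) is returned alongside the
data, and everything is reproducible from one seed.

What the generator does **not** emulate: artifact contamination (eye
blinks, muscle), non-stationary noise, multi-sensor correlation,
habituation trends. Tests passing on this generator therefore certify the
pipeline's mechanics and its noise response, not its behavior on messy
recordings.

## Parameter recovery, and what "error" means here

`recovery_experiment()` generates datasets per (SNR x scenario) cell,
mines each, and compares the estimated peak against ground truth. Two
error notions are reported, because they answer different questions:

* `amplitude_mae` / `latency_mae`: error against the peak of the
  **dataset's noiseless mean signal** — the evoked response that trial
  averaging targets. (The mean of per-trial peaks is deliberately not
  used as the reference: with latency jitter, no averaging estimator can
  attain it — the mean of peak values exceeds the peak of the mean.)
* `amplitude_noise_mae` / `latency_noise_mae`: error against the
  estimator applied to the **noiseless signals of the very trials that
  were selected**. This isolates the noise-induced estimation error from
  the selector's systematic preference.

The decomposition matters because of a real property of the method: dCor
is scale-invariant, so hub selection is blind to amplitude and favors
trials of *typical* shape. Under a right-skewed amplitude law the typical
(median-like) trial is shallower than the mean, giving a small,
SNR-independent amplitude offset in the independent scenario. The noise
component of the error shrinks as SNR grows; the offset does not.
Datasets are matched across SNR levels (same signal and noise draws, only
the noise scale changes), the standard paired design for monotonicity
comparisons. Latency has no such offset (the jitter is symmetric) and
stays within about two samples of the truth at every reference SNR. In
the noise-free common-scenario limit the pipeline returns the trial
itself and recovery is exact (run with `filter = FALSE`: with no noise to
remove, the band-pass would only distort the template).

## Known limitations

* **No SNR gain on exchangeable trials.** When every simulated trial has
  identical noise statistics, the hub subset is statistically no better
  than the full set, and its average uses fewer trials: the measured SNR
  of the hub selection is then on par with (slightly below) the all-trial
  average. The selection's value lies in heterogeneous recordings where
  some epochs are atypical — which is what real data look like, and
  exactly what the homogeneous generator does not produce.
* **MDS crowding.** A trial that is near-maximally dissimilar to every
  other trial (pairwise distance ~ 1) does not land on the periphery of
  the 2D classical-MDS embedding — its separation lives in the discarded
  eigendirections, and it is projected into the middle of the cloud. Very
  noisy epochs can therefore still become hubs. A contamination
  experiment (a quarter of trials with 5-25x noise) showed hub
  membership of contaminated trials at chance level. Screening gross
  artifacts before mining remains advisable.
* **Latency resolution** is one sample (about 2 ms at 512 Hz); peak
  estimates are grid extrema with no sub-sample interpolation.
* The hub-count at a given `k` is data-dependent; `select_hubs()` errors
  with a suggestion to lower `k` when no node qualifies, and
  `select_trials()` falls back to the single representative when all
  trials coincide.

## Numerical choices

* **Distances**: `1 - dCor` (the estimator is a similarity; this keeps
  distances in [0, 1] with zero diagonal). A constant trial has zero
  distance variance (the estimator is 0/0); its dCor is defined as 0,
  i.e. distance 1 to everything, with a warning.
* **Gabriel/RNG boundary ties**: a point exactly on the diametral circle
  or lune boundary does not block an edge; the strict predicate carries a
  relative tolerance of 1e-9 on the squared distances so right angles do
  not flip edges on floating-point noise. Coincident embedded points
  (identical trials) are collapsed to one node before graph construction
  and re-expanded afterward, duplicates inheriting the representative's
  hub status.
* **Graph construction**: the Gabriel and lune predicates are evaluated
  by a vectorized per-point sweep over the squared-distance matrix —
  at the a-few-hundred-trials scale this is faster in R than a
  Delaunay-prefiltered scan, and keeps the core method free of the
  triangulation dependency (used only for `delaunay_graph()` itself).
  A brute-force triple-loop oracle in the test suite checks both graphs
  edge-for-edge on random point sets.
* **Hub-scatter global efficiency**: pairwise hub distances are
  normalized by their maximum, inverted into weights `w = 1 - d/dmax`,
  and used as edge lengths `1/w`; the most distant pair gets no direct
  edge. GE is then the mean inverse shortest-path length, with
  disconnected pairs contributing 0. This reading keeps GE in [0, 1]
  (two hubs alone give exactly 0; coincident hubs give 1 by convention)
  and is invariant to uniform scaling of the embedding. The literal
  "reciprocal normalized distance" reading would force GE >= 1 and is
  inconsistent with the reference values (~0.34-0.42).
* **CV conventions**: the reference tables print mean/sd, the reciprocal
  of the textbook CV; both are available (`convention = "paper"` or
  `"conventional"`), reciprocal whenever both are defined.
* **FIR DC null**: the windowed-sinc taps are re-centered
  (`h - mean(h)`) so the DC gain is exactly zero; with kernels thousands
  of taps long the perturbation elsewhere is negligible, and constant
  input is annihilated to machine precision.
* **Filter edge handling**: reflection padding of length
  `3 * order * round(fs / low_edge)`, capped at segment length - 1; FIR
  convolution runs through FFTs, so the long kernels the 0.5 Hz edge
  demands stay cheap.
* **Subsampling** truncates to the first `ceiling(f * n)` trials in
  acquisition order (not random subsets), mirroring how trials accrue
  during a session; preprocessing is applied once to the full recording
  before truncation, since a 6000-tap filter cannot ride on a 20% subset
  and filtering belongs to the recording, not the subset.

## Problem sizes used by the test suite

Unit tests run the generator at 24-128 trials; the Monte-Carlo
properties use 5 datasets per (SNR x scenario) cell for recovery, 50
datasets for the SNR-gain comparison, 100 random point sets (up to 200
points) for the graph oracles, and 100 draws of length-500 series for
the dCor null — sizes at which each property is stable under the fixed
test seeds while the full suite stays comfortably interactive.
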