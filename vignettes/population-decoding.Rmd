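---
title: "Population decoding and synaptic weight heterogeneity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population decoding and synaptic weight heterogeneity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `popdecode`, the
assumptions behind them, the tunable parameters and their defaults, the
design decisions taken where the construction was genuinely open, and what
the synthetic-data tests do and do not establish about real recordings.

## 1. The encoding model

An input population of `N` orientation-tuned neurons responds to a grating
of orientation $\theta$ (always on $[-90^\circ, 90^\circ)$; orientation is
180°-periodic) with

$$ r_i = f_i(\theta) + \varepsilon_i, \qquad
   f_i(\theta) = \alpha_i + \beta_i\, e^{\kappa_i[\cos(2(\theta-\phi_i)) - 1]} $$

* $\alpha_i \ge 0$ — baseline rate; $\beta_i \ge 0$ — tuned amplitude
  (peak response is $\alpha_i + \beta_i$);
* $\kappa_i > 0$ — concentration; the half-width $\gamma$ of the curve
  converts through $\kappa = \log 2 / (1 - \cos 2\gamma)$
  (`bandwidth_to_kappa()`), which is strictly decreasing in $\gamma$ and is
  capped (default 1000) because $\gamma \to 0$ overflows;
* $\phi_i$ — preferred orientation.

The noise $\varepsilon$ is multivariate Gaussian with **limited-range
correlations**: $C_{ij} = c_o e^{-|\delta(\phi_i-\phi_j)|} $ for $i \ne j$,
unit diagonal, where $\delta$ is the circular orientation difference.
$\delta$ is computed on the doubled-angle circle and halved, giving values in
$[0, \pi/2]$ radians; radians are used inside this kernel (the kernel then
spans about a factor $e^{-\pi/2} \approx 0.21$ from co-tuned to orthogonal
pairs, a realistic range for cortical noise correlations). The correlation
matrix is scaled to a covariance by each neuron's **stimulus-averaged** mean
rate, $Q_{ij} = C_{ij}\sqrt{\mu_i\mu_j}$, so each variance equals the mean
rate (Poisson-like) while $Q$ stays stimulus-independent — the assumption
that makes the decoder below exactly linear. Rates below $10^{-3}$ are
floored before scaling; if the Cholesky factorization of $Q$ fails, a
diagonal jitter of $10^{-8}\,\mathrm{tr}(Q)/N$ is added once and reported.

Two population kinds are provided (`population_spec()`):

| parameter | homogeneous | heterogeneous |
|---|---|---|
| $\alpha$ | 0 | Exponential(mean 0.5) |
| $\beta$ | 5 | Lognormal(median 5, log-sd 0.5) |
| bandwidth | $\kappa = 4$ | $\gamma \sim$ Lognormal($\mu=-1$, $\sigma=0.6$), radians |
| $\phi$ | tiled uniformly | Uniform$[-90, 90)$ |

The homogeneous parameters and the bandwidth distribution are the study
conditions; the amplitude and baseline distributions are not constrained by
them, so they are configurable, with defaults chosen to give V1-like spread
of peak rates around the homogeneous value and modest spontaneous activity.

## 2. The decoder

With equal-covariance Gaussian noise, the posterior over $K$ discrete
stimulus classes is a softmax of linear functions of the response vector:

$$ p(\theta_k \mid R) = \frac{e^{R^\top w_k + \beta_k}}
   {\sum_i e^{R^\top w_i + \beta_i}}, \qquad
   w_k = Q^{-1} f(\theta_k), \quad
   \beta_k = -\tfrac12 f(\theta_k)^\top Q^{-1} f(\theta_k) + \log p(\theta_k). $$

`derive_weights()` obtains every $w_k$ by a Cholesky-backed linear solve
(never an explicit inverse) and verifies $\|Q w_k - f(\theta_k)\|$ to a
$10^{-8}$ relative tolerance. The prior is uniform by default. The softmax is
computed with the max-logit subtracted; MAP ties break to the lowest class
index, deterministically. When $Q$ is diagonal the weights reduce to mean
over variance — each input is weighted by its signal-to-noise ratio — and
with correlations present the weights acquire negative flanks and, for
heterogeneous populations, strong neuron-to-neuron variability.

The same readout can be estimated numerically: `fit_weights_logistic()` fits
a ridge-penalized multinomial logistic regression (penalty $10^{-4}$ for
identifiability, since softmax weights are only defined up to per-feature
shifts across classes). On simulated data the numerical and analytic
decoders agree in MAP label on over 95% of held-out trials; this serves as a
cross-check of the closed form, not as the implementation.

### Decoding accuracy

Accuracy is the inverse of the circular mean squared error of the MAP
estimate. Errors wrap on the doubled-angle circle, so an estimate of
$80^\circ$ for a $-80^\circ$ stimulus errs by $20^\circ$; the maximum
squared error is $(\pi/2)^2$. Evaluation is cross-validated in the sense
that weights come from the population parameters while errors are measured
on freshly seeded simulated trials (default 20 per class).

`accuracy_sweep()` uses a **fine stimulus grid by default (K = 120, 1.5°
spacing)**. This is a deliberate design choice: with a coarse grid (e.g.,
22.5° classes) the populations at the default signal-to-noise level decode
essentially without error beyond a hundred neurons or so, the MSE collapses
to exactly zero, and nothing can be compared. On a quasi-continuous grid the
MAP estimate behaves like a continuous estimator, its MSE tracks estimation
precision, and the phenomena of interest are measurable: performance rises
monotonically with $N$ when $c_o = 0$; limited-range correlations saturate
homogeneous populations (performance gain of only ~1.3–1.6x from N = 128 to
512 at $c_o \ge 0.25$) while heterogeneous populations keep improving
(~4x over the same range). K remains an argument; the synapse comparison
below uses K = 8 (22.5°) to match imaging protocols.

### Weight smoothing

To probe whether weight diversity matters, weights can be smoothed over
orientation preference. The smoother is the row-normalized kernel
$S_{ij} = e^{-(\rho_1 + \delta(\phi_i,\phi_j)/\rho_2)}$ applied to each
weight row; $(0, 0)$ is the no-smoothing sentinel. Two choices here were
open and are worth recording:

* **Operator.** A kernel and its pseudoinverse are both candidates for "the
  smoothing matrix". Applying the pseudoinverse of a smooth kernel sharpens
  rather than smooths, so the kernel itself, row-normalized, is used as the
  linear smoother. Row normalization preserves constant weight vectors, and
  it cancels the amplitude factor $e^{-\rho_1}$; since uniform scaling of
  all weight rows cannot change the MAP estimate either, $\rho_2$ is the
  operative parameter.
* **Units.** $\delta/\rho_2$ is computed with $\delta$ in **degrees**, so
  $\rho_2$ is a smoothing range in degrees of orientation preference. With
  radians, even $(\rho_1,\rho_2) = (0.1, 1)$ averages over nearly the whole
  orientation axis and flattens every weight vector to a constant (chance
  decoding); in degrees the canonical sequence $(0.1,1) \to (0.2,2) \to
  (1,10)$ produces strictly decreasing high-frequency content and
  progressively degraded but above-chance decoding, which is the behavior
  the smoothing manipulation is meant to exhibit.

Offsets are recomputed as $-\tfrac12 f(\theta_k)^\top \tilde w_k + \log p$
after smoothing so the readout stays calibrated.

## 3. From weights to synapses

A decoder neuron's excitatory synaptic population is obtained by
`weights_to_frequency()` (negative and zero weights map to probability zero;
positive weights normalize to one) followed by `sample_synapses()`. Two
decisions:

* **Distinct inputs.** By default 100 synapses are drawn **without
  replacement** — they are distinct upstream neurons. Sampling with
  replacement (available via `replace = TRUE`, and used in the
  multinomial-law tests) concentrates most draws on a handful of peak-weight
  neurons; under linear integration a duplicated draw is equivalent to one
  stronger synapse, so the with-replacement population is effectively much
  smaller and less diverse than the stated synapse count suggests.
* **Trial noise.** Synaptic trials are the synapse's tuning curve plus
  Gaussian noise. Three noise models are implemented
  (`simulate_synaptic_trials()`):
  `"shared"` — variance $Q_{ii}$, the source neuron's stimulus-independent
  variance under the population model; `"rate"` — variance equal to the mean
  response at that stimulus (private Poisson-like); and the default
  `"shared_plus_rate"` — their sum. The default is the only one of the three
  that produces both of the qualitative signatures expected of
  calcium-imaging trials of tuned synapses: trial variability that *grows*
  with the mean response (null orientations quieter than preferred), and a
  non-vanishing variability floor at null orientations where the mean
  response of a narrowly tuned synapse is nearly zero. Pure `"shared"` noise
  produces no null/preferred difference at all after peak normalization, and
  pure `"rate"` noise makes null responses almost noiseless. Noise is
  independent across synapses by default; `correlated = TRUE` draws the
  shared component jointly from the corresponding rows of $Q$.

The decoder neuron's own "somatic" tuning is its softmax response to the
noiseless population mean at each grid stimulus (`decoder_output_tuning()`).
At N = 1000 the posterior is saturated, so simulating noisy readout trials
and averaging gives numerically the same curve; the noiseless form is used
for determinism.

## 4. The comparison statistics

`run_synapse_comparison()` ties the pieces together: per run, one population,
analytic weights, and every decoder class treated as one simulated cell with
100 synapses and 10 trials per stimulus on the 22.5° grid (matching the 8–10
trials of the imaging protocol). Statistics:

* **Tuning correlation** — Pearson r between each synapse's trial-averaged
  tuning and the readout tuning (`tuning_correlation()`); zero-variance
  curves are excluded with a count. Pooled medians and per-cell means are
  reported. At the default study conditions (N = 1000, $c_o = 0.2$, 200
  runs) the homogeneous model pools to a median near 0.79 with per-cell
  means near 0.59, the heterogeneous model to ~0.18 / 0.23 — the two models
  are separated by >0.2 in every seeded replicate, and both are positively
  biased.
* **KL model identification** — per-cell histograms of r (bin width 0.05 on
  $[-1,1]$, one pseudocount per bin so divergences are finite) against
  pooled model reference histograms, direction fixed as
  $D_{KL}(\text{cell} \| \text{model})$ throughout. Heterogeneous-model
  cells identify their own model essentially always, and the ranking is
  stable for bin widths 0.001–0.2.
* **Selectivity slope** — the major-axis (first principal component) slope
  of (tuning correlation, vector strength) pairs with bootstrap resampling
  of inputs. Vector strength is the circular resultant on doubled angles,
  $v = |\sum_k r_k e^{2i\theta_k}| / \sum_k r_k$. For the homogeneous model
  the slope is indistinguishable from zero (selectivity is essentially
  constant by construction); for the heterogeneous model the implementation
  finds a clearly positive slope (~0.34) — narrow co-tuned synapses match
  the sharply tuned readout better than broad ones, so selectivity and
  correlation are not independent there. This is a genuine property of this
  model, reported as such by `analysis/03_synapse_comparison.R`.
* **Null/preferred variability** — per synapse, the trial s.d. at its
  preferred grid stimulus and at the stimulus 90° away, after dividing by
  the peak of its trial-averaged curve (`normalize_spine_responses()`, so
  every synapse has equal weight). With the default noise model the null
  median (~0.28) sits reliably below the preferred median (~0.43); a flat
  additive-noise control shows no difference.

## 5. The synthetic spine experiment

`generate_spine_dataset()` emulates the *structure* of a two-photon
spine-imaging session on one cell: 8 orientations at 22.5°, 8–10 trials,
ΔF/F-like responses, a global dendritic signal (soma tuning plus noise)
added to each spine with a per-spine contamination factor, and blank-period
samples of pure baseline noise. Defaults: 159 spines (a typical
visually-responsive count per cell), preferences wrapped-normal around the
somatic preference (sd 35°), lognormal amplitudes, widths uniform on 18–35°,
noise sd 0.15, contamination uniform on 0–0.4. Ground truth is recorded for
every spine so that recovery can be tested.

The preprocessing mirrors the experimental pipeline:

* **bAP subtraction** (`subtract_bap()`): the contamination scale is a
  Theil–Sen slope of spine on dendrite, clipped at zero, estimated on
  *within-stimulus residuals* when the signals are trials x stimuli
  matrices. Estimating on raw values would confound contamination with
  orientation tuning whenever a spine is co-tuned with the soma; the
  trial-by-trial residual coupling is what identifies the bAP leak. The
  rank-based slope resists sparse, spiky events. Recovery is within ±0.1 of
  the true scale at signal-to-noise 3.
* **Inclusion QC** (`spine_inclusion_filter()`): a spine passes if (1) its
  maximum trial-mean response after subtraction exceeds the blank median by
  two *unscaled* median absolute deviations of the blank (no 1.4826
  consistency factor — the criterion is stated directly in MAD units), and
  (2) its Spearman correlation with the dendritic signal, computed after
  dropping samples where the corrected trace is negative, stays below 0.4.
  Fewer than 3 usable samples marks a spine indeterminate (excluded). On
  synthetic data the filter is ≥95% sensitive for strongly responsive
  spines that are genuinely independent of the dendrite and ≥95% specific
  against pure-noise spines. One synthetic-data caveat: because these trials
  have no temporal dynamics, a strongly soma-co-tuned spine's stimulus-driven
  responses alone can push its dendrite correlation past 0.4, so the filter
  also removes co-tuned spines — in real traces the criterion acts mostly on
  trial-by-trial bAP residue.
* **Tuning fits** (`fit_tuning_gaussian()`): wrapped-Gaussian nonlinear
  least squares (baseline + amplitude, width bounded to 4–85°), multi-start
  over all grid orientations and two widths, best residual sum of squares
  wins, honest `converged` flag with a circular-mean fallback. Median
  absolute preference error is under 10° at signal-to-noise 3 with 10
  trials, with no systematic bias.

## 6. Reproducibility and problem sizes

Every stochastic stage takes an explicit seed; multi-stage experiments
derive per-stage seeds from one master seed (`derive_seeds()`), and
`run_experiment()` writes a JSON manifest recording the configuration, all
derived seeds and all artifact paths. Tables are CSV with doubles at 17
significant digits, so write-read round-trips are exact and identical
configurations reproduce identical files.

Problem sizes in the shipped tests and acceptance script are desk-scale
choices: 60 simulation runs per model in the test suite and 200 in
`scripts/acceptance.R` (medians of the comparison statistics are stable to
well under the reporting tolerance at this replication), accuracy sweeps at
N ≤ 512 with 50 replicates per grid cell, and 500-spine recovery
simulations. The original analyses behind these statistics used thousands of
runs and population sizes to N = 2048; the package reproduces their behavior
at reduced scale in minutes on one CPU.

## 7. Known limitations

* The Gaussian equal-covariance assumption is what buys the closed-form
  weights; stimulus-dependent covariance (which would make the optimal
  readout quadratic), spiking noise, rectified responses and nonlinear
  dendritic integration are out of scope.
* The synthetic spine generator reproduces the data *structure* (grids,
  trials, blanks, contamination, noise floors), not calcium-indicator
  biophysics or temporal dynamics; QC behavior on co-tuned spines differs
  from real traces as noted above.
* The homogeneous model's pooled correlation median is dominated by the
  ~half of synapses drawn inside the readout's preferred 22.5° bin, whose
  trial-averaged curves correlate above 0.9 with the sharply tuned readout;
  that quantile is therefore sensitive to exactly how concentrated the
  positive-weight profile is, far more so than the per-cell means or any of
  the heterogeneous-model statistics.
* Selectivity and input–output correlation are not independent in the
  heterogeneous model (positive major-axis slope), unlike in the
  homogeneous model.
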