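---
title: "Point-process GLM functional connectivity: models, choices, limits"
author: "spikeglm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Point-process GLM functional connectivity: models, choices, limits}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`spikeglm` treats an ensemble of `C` simultaneously recorded neurons as a
multivariate point process.  Each cell `c` has a conditional intensity
`lambda_c(t | H_t)` — its instantaneous firing rate given the whole
ensemble's spiking history — modelled log-linearly in lagged spike counts:

```
log lambda_c(t) = a0_c + sum_{i=1..C} sum_{k=1..K} a[i,k]_c * x[i, t-k]
```

where `x[i, t-k]` is the spike count of cell `i` inside the `k`-th history
window (an inclusive millisecond lag range such as 1–3 ms, strictly before
`t`), `exp(a0_c)` is the cell's baseline rate in spikes/s, and
`exp(a[i,k]_c)` is a dimensionless gain: above 1 an excitatory influence of
`i` on `c` at that latency, below 1 an inhibitory one.  With `K` windows the
model for one target cell has `d + 1 = C*K + 1` parameters.

Time is discretized at `Delta` = 1 ms — fine enough that a bin contains at
most one spike in practice (multi-spike bins saturate to 1 and are counted
so the user can shrink `Delta`).  The per-cell log-likelihood is the
discretized point-process likelihood
`sum_t [ y_t log(lambda_t Delta) - lambda_t Delta ]` over unmasked bins.
Conditional on the shared history the cells are independent, so the network
likelihood factorizes and each target cell is fitted separately.

## Estimation

Coefficients maximize the ridge-penalized log-likelihood
`L_p(a) = L(a) - rho * a' Q a` by damped Newton iterations with
step-halving; `-L_p` is convex, so the optimum is global and independent of
the start (a property the test suite checks from random initializations).
Iterations stop when `L_p` changes by less than `1e-4` (config-exposed).
Choices worth knowing:

* **The intercept is not penalized.**  Shrinking `a0` drags every baseline
  toward one spike per bin; standard ridge practice.
* **`Q`** defaults to the identity (plain ridge).  A first-difference
  penalty across adjacent windows of the same source cell
  (`Q_kind = "smooth"`) is available when smooth coefficient traces across
  lags are preferred.
* **`rho` is selected by leave-one-trial-out cross-validation** (the trial
  is the exchangeable unit; `folds = k` gives a k-fold fallback for large
  trial counts), maximizing mean held-out log-likelihood, smaller `rho` on
  ties.  The default grid is 8 log-spaced values in `[1e-4, 1e2]`.
* **Wald machinery.**  The coefficient covariance is the inverse observed
  information of the unpenalized likelihood,
  `Sigma = solve(sum_t lambda_t Delta x_t x_t')` (for a log-linear
  intensity the residual curvature term vanishes); 95% bounds are
  `a_hat ± 1.96 sqrt(diag(Sigma))`.  A singular information matrix falls
  back to a pseudo-inverse with a warning flagging unidentifiable
  coefficients.
* **Early-trial bins are masked, not zero-padded.**  A bin enters the
  likelihood only if its deepest lag lies inside the trial; zero-padding
  would bias counts low at trial onsets.  History for an epoch's first bins
  is drawn from the full trial, so spikes just before the epoch count.

## Window selection

The number and layout of history windows is chosen by BIC,
`-2 L(a) + dim(a) log(l)` with `l` the number of binary samples, ties
toward fewer windows.  One subtlety the implementation handles explicitly:
candidate schemes with different maximal lags mask different numbers of
early-trial bins, so their raw likelihoods are not comparable — the
deeper-history candidate would be scored on fewer bins and its BIC biased
down by roughly twice the per-bin log-likelihood times the bin difference,
which is the same order as the BIC penalty itself.  `select_windows()`
therefore masks every candidate up to the deepest lag in the candidate
list, scoring all models on a common set of bins.

## Goodness of fit

Model adequacy is assessed by the time-rescaling theorem: under a correct
intensity the accumulated intensity between consecutive spikes is i.i.d.
Exp(1), and `u = 1 - exp(-tau)` is uniform, testable by a KS statistic
against the simultaneous bands `1.36/sqrt(n)` (95%) and `1.22/sqrt(n)`
(90%) — note the 90% band is the stricter criterion.  Intervals are pooled
across trials; partial intervals at trial edges are discarded.

Two empirical findings shaped the defaults here:

1. **Discreteness.**  At `Delta` = 1 ms and cortical rates, the naive
   Riemann-sum rescaling (`tau = sum lambda_t Delta`) is anticonservative
   even when the *true* model is supplied: the per-interval mass is
   quantized to the bin grid, and in 200-run calibration pilots only ~89%
   of well-specified samples passed the 95% band.  The default is
   therefore the exact discrete-time construction — each non-spiking bin
   contributes `-log(1 - p_t)` and the spiking bin a randomized residual
   `-log(1 - u p_s)` — which is exactly Exp(1) under the Bernoulli model
   at any bin width.  The naive transform remains available
   (`discrete_correction = "none"`) for closed-form work.
2. **Edge censoring.**  Pooling complete ISIs from short trials
   length-biases the sample: a long interval is more likely to be cut by
   the trial boundary and discarded, so observed intervals skew short.
   The distortion scales like the inverse of the per-trial rescaled length
   (about 4% for 3-s trials at 8.5 spikes/s) and is visible in the KS
   test.  The package's KS calibration study therefore uses long
   control-period-style blocks (16 × 120 s to fit, 4 × 60 s to evaluate,
   at the regular-spiking baseline regime), where censoring is negligible
   and the training set is large enough that plug-in estimation error is
   second-order.  For the short behavioural trials this bias is a known
   caveat of the KS readout, not corrected by default.

## Connectivity readout

A coefficient whose 95% Wald interval excludes zero is a significant
directed connection `i -> c` at that lag, excitatory or inhibitory by its
sign.  Following standard practice for this estimator no multiplicity
correction is applied by default; `bonferroni = TRUE` divides the level
across the K lags of a pair for conservative use.  Two summary conventions
coexist deliberately:

* the **mean (E+I) connectivity ratio** counts significant off-diagonal
  coefficients per lag, normalized by `C^2 - C` ordered pairs and averaged
  over the K lags — self-connections excluded on both sides;
* the **cell-group interaction fractions** (RS-RS, RS-FS, FS-FS) count a
  directed pair once if any lag is significant and divide by `n_RS^2`,
  `2 n_RS n_FS`, `n_FS^2` — self-pairs *included*, so the three
  denominators sum to `C^2`.

The **E:I balance** is the count of excitatory over inhibitory significant
coefficients among distinct-pair edges.  Condition comparisons go through
`stats::wilcox.test` (paired by dataset) and a three-factor
`stats::aov` over cell group, task outcome and period.

## Monte-Carlo controls

`split_half_check()` refits a focal pair's coefficient trace on random
halves of each condition's trials (20 runs by default): if the full-sample
trace reflects structure rather than overfitting, half-sample means
correlate strongly and positively with it.  `shuffle_label_check()`
permutes outcome labels so each shuffled group contains equal numbers of
truly successful and truly unsuccessful trials (100 runs): genuine
outcome-specific coupling is mixed away, and the across-run mean
difference should cover zero per window (the display band is
`mean ± 1.96 SEM`).  With odd group sizes an exact equal mixture is
impossible; the leftover trial is assigned to a random side per run —
a fixed assignment would tilt the null by `(b_u - b_s)/n` per window,
a bias the test suite caught.  By default the refit uses the full
ensemble history; `restrict_to_pair = TRUE` is a faster approximation.
No scalar "trace difference" statistic is exposed: the per-window
confidence bands are the readout.

## The synthetic generator

`make_ground_truth()` + `simulate_ensemble()` provide the oracle for every
stage: a known GLM is forward-sampled bin by bin (Bernoulli draws with
probability `lambda Delta`, clipped at `1 - 1e-6` with clip counts
reported), with empty history at each trial start and independent trials.
Its defaults emulate the recorded preparations: 3-s trials with the
trigger at 1.5 s, background/reaching epochs, baseline rates drawn from
log-normals moment-matched to the RS (8.5 ± 3.6 spikes/s) and FS
(22.7 ± 9.6 spikes/s) regimes, spike durations near 0.9 ms (RS) and 0.4 ms
(FS), a coupled-pair density of 0.15, and excitatory:inhibitory odds of
1.11.  Planted couplings put the same coefficient at every lag window so
recovery can be scored lag by lag; the magnitude (default 0.5, a gain of
about 1.65 per spike) is chosen to keep `lambda Delta` in a stable regime
and is a configuration choice, not a data-derived value — no coupling
magnitudes are published for the recorded pairs.

What the generator does **not** emulate — and hence what passing tests do
not establish about real recordings: within-trial nonstationarity (task
modulation of rates), common input from unrecorded neurons (the classic
confound of functional connectivity), refractoriness and bursting unless a
`self_coupling` is planted, electrode artefacts, and sorting errors.
Recovery results certify the estimator under its own model family, not the
biological identifiability of cortical circuits.

## Validation problem sizes

The shipped test-suite and acceptance script use, as package choices:
2-cell ensembles with 200 trials × 3 s for Wald coverage (200 replicates),
3-cell null ensembles with 60 trials for the false-edge rate (100 runs),
the long-block design above for KS calibration (200 runs), 30-trial
ensembles for BIC selection (20 runs), a 21 + 21-trial sign-reversed pair
for the controls, and 8-cell ensembles for summary-statistic recovery.

## Known limitations

* Dense design matrices: a 15-cell, 10-window condition fit holds an
  `l × 151` double matrix in memory (~150 MB at 50 trials); fine on a
  workstation, wasteful for much longer recordings.
* Piecewise-constant history windows only — no raised-cosine or spline
  bases.
* The KS readout on short trials inherits the censoring bias described
  above.
* Leave-one-trial-out CV refits the model once per trial and candidate
  `rho`; use `folds` for large trial counts.
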