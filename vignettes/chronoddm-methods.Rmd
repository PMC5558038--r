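---
title: "Bounded accumulation models for subjective decision times: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bounded accumulation models for subjective decision times: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronoddm)
```

## The scientific question

In a random-dot motion discrimination task, a participant watches a patch of
stochastically moving dots and decides whether the net motion is leftward or
rightward. In a *controlled-duration* design the experimenter fixes the
viewing time; the participant later reports, by restoring a clock hand, the
moment they *felt* they had decided — the subjective decision time
`t_sd`. The hypothesis under test is that these introspective reports mark
the termination of a bounded evidence-accumulation (drift-diffusion)
process: noisy momentary evidence with mean `kappa * (C - C0)` per second
(`C` the signed motion coherence) and unit variance per second accumulates
until it hits `+B` or `-B`, fixing both the choice and the decision time.

The decisive test is parameter transfer: if `t_sd` marks termination, a fit
of the *mean times alone* yields `(kappa, B, C0)`, which fully determine
the choice function

    P(right | C) = 1 / (1 + exp(-2 kappa (C - C0) B)),

so choice accuracy is *predicted* with no choice data entering the fit. The
package implements that logic end to end on synthetic data it generates
itself, plus the supporting analyses: distributional fits with collapsing
bounds, Jensen-Shannon goodness of fit with bootstrap and permutation
nulls, surrogate sensitivity analyses, and a frequency-domain
motion-energy reverse correlation.

## The flat-bound (parsimonious) model

`mean_decision_time()` implements the chronometric function

    t(C) = B / (kappa (C - C0)) * tanh(kappa (C - C0) B) + t_nd,

with the removable singularity at `C = C0` evaluated as `B^2 + t_nd`
(series expansion below `|kappa (C - C0)| < 1e-9`). `fit_mean_tsd()`
maximizes the Gaussian likelihood of the per-coherence mean `t_sd`, each
condition weighted by its empirical SEM, exactly as one would fit mean
reaction times. Only *congruent-direction* trials enter the means:
rightward choices where the fitted choice function exceeds one half,
leftward otherwise, with the point of subjective equality taken from a
two-parameter ridge-stabilized logistic (`condition_summaries()`). The
ridge (`1e-4` by default) only matters under complete separation, where
plain IRLS diverges; it biases the PSE negligibly otherwise.

Optimization is box-constrained quasi-Newton (L-BFGS-B) with analytic
gradients, from ten deterministic perturbations of a moment-based start
(the time range sets `B^2`; the weak-to-strong contrast sets `kappa`).
The boxes are `B > 0`, `t_nd >= 0`, `|C0| <= 0.512` (the strongest
coherence used), `kappa > 0`. Multi-start matters because the likelihood
has a ridge along `kappa * B`; with a single start the fit occasionally
lands on a `kappa`-inflated, `B`-deflated solution. Standard errors come
from the inverse numerical Hessian at the optimum; on noiseless synthetic
means the fit recovers generating parameters to at least four significant
digits, so the numerical-Hessian shortcut (rather than an analytic one)
costs nothing at the tolerances that matter here.

The significance of the choice prediction is assessed by the shuffle test
(`shuffle_significance()`): permute the (mean, SEM) pairs across signed
coherences, refit, re-predict, and count how many of the shuffled-plus-
original datasets predict at least as well as the original;
`p = (#{LL >= LL_orig}) / (n_shuffles + 1)`. Four hundred shuffles is the
default.

## The collapsing-bound model

To explain full `t_sd` *distributions* (not just means), the bounds
collapse over time:

    A(t) = A0 * (1 - I_{t/2.7}(beta1, beta2)),

where `I` is the regularized incomplete beta function and 2.7 s is the
clock ceiling (one full revolution). The shape is parameterized by
`B_log = log10(beta1 beta2)` (collapse steepness) and
`t_beta = beta1 / (beta1 + beta2)` (normalized time of steepest descent),
which decorrelate better than the raw beta parameters. Non-decision time
is gamma-distributed (mean `mu`, sd `sigma`), keeping latencies positive so
per-trial likelihoods are well defined.

`fpt_density()` propagates the transition density on a space-time grid
with absorption at the moving bounds. The scheme is Crank-Nicolson in
time, centered in space — an *implicit* scheme, because any explicit
centered scheme is unstable at a useful grid (stability would demand
`dt <= dx^2`, i.e. tens of microseconds at `dx = A0/150`). The first two
steps are replaced by pairs of backward-Euler half-steps (Rannacher
smoothing) to damp the oscillations the point-mass initial condition
otherwise induces. Mass is conserved by construction: flux lost through
either absorbing edge per step is attributed to that bound's
choice-conditional density, cells swept by the collapsing bound are
absorbed into the adjacent bound, and the identity
`integral(density) + survival = 1` holds to 1e-6 (it is checked, and a
violation raises an error advising a finer grid). On a near-flat bound the
solver reproduces the classical results `P(upper)` from the logistic
splitting formula to better than 1e-3 and the zero-drift mean
first-passage time `A0^2` to about a millisecond at the default grid
(`dt = 1 ms`, `dx = A0/150`).

Per-trial likelihoods interpolate the gamma-convolved density linearly on
the grid, floored at `1e-10 s^-1` so a stray outlier cannot produce an
infinite penalty. Trials that report no decision contribute the surviving
mass, split evenly between choices. Fitting grids are deliberately coarser
(`dt = 5 ms`, `dx = A0/60` by default in `fit_collapse_mle()`) — the
likelihood surface is smooth and the coarse-grid optimum sits well within
one posterior standard deviation of the fine-grid one, which is what the
runtime trade-off should be judged against.

`metropolis_posterior()` quantifies uncertainty: random-walk Metropolis,
multivariate-normal proposal scaled by `2.38/sqrt(d)`, covariance adapted
every 100 steps from up to 1000 trailing samples *during burn-in only* (so
the kept samples obey detailed balance), 12 chains of 5000 + 5000 by
default, convergence monitored by the split-chain between/within variance
ratio with the conventional 1.1 threshold, and the posterior standard
deviation reported as the parameter standard error. The tests and the
reproduction script run reduced chains (6 × 1500 + 1500 to 8 × 2500 +
2500) on ~1000-4000-trial datasets; at those sizes every parameter's
scale-reduction factor reaches the 1.1 threshold with the longer setting
and the generating parameters fall within three posterior standard
deviations of the posterior mean.

## Synthetic experiments

`simulate_controlled_duration_experiment()` and
`simulate_free_response_experiment()` emulate the two designs: stimulus
durations and delays drawn from {0.2, 0.4, 0.6, 0.8} s with probabilities
{0.125, 0.0625, 0.0625, 0.75}; directions equiprobable; magnitudes uniform
over {0, 3.2, 6.4, 12.8, 25.6, 51.2}%; reports capped by the 2.7 s clock.
Two generator choices were genuinely open:

* **Post-stimulus accumulation.** The chronometric fit treats `t_sd` like a
  reaction time, as if every trial terminates. The generator keeps the
  accumulator running with *zero drift* after stimulus offset until it
  crosses a bound or the clock ceiling. This preserves
  termination-at-a-bound semantics on short-duration trials while leaving
  long-duration (0.8 s) trials — the ones the analyses use — essentially
  unaffected, since the fitted bounds are typically reached within the
  stimulus for realistic parameters.
* **Euler crossing detection.** A naive first-sample-beyond-bound rule
  inflates the effective bound by about `0.58 sqrt(dt)` evidence units
  (~0.013 at the 0.5 ms default), which biases mean decision times by tens
  of milliseconds — an order of magnitude beyond the agreement the rest of
  the package is validated to. The simulators therefore apply a per-step
  Brownian-bridge crossing probability `exp(-2 d0 d1 / dt)` (distances to
  the bound at the step's ends; the locally linearized bound for
  collapsing profiles), which removes the discretization bias to within
  Monte-Carlo error at `n = 1e5`.

Dots leaving the annulus wrap to the opposite edge along the motion axis
(conserving density); the movie grid is 0.05 deg/pixel (about 100 x 100
pixels over the 5-degree field); `correct` at zero coherence is a fair
coin flip. A `decouple_tsd` switch permutes the simulated reports across
trials, preserving their marginal distribution while severing the link to
each trial's own termination — the in-silico analogue of a participant who
uses the clock systematically but not as a termination marker, and the
negative control for the shuffle test.

The generator adds *no* clock-memory noise beyond the gamma non-decision
variability: the reported `t_sd` is crossing time plus one gamma draw.
Real reports surely carry extra perceptual/mnemonic noise; passing tests
on this generator therefore demonstrates the *logic* of the analyses
(prediction, nulls, sensitivity), not robustness to every noise source in
human data.

## Motion energy and leverage

`motion_energy_halves()` computes, for each half of an 800 ms movie
(frames 1-30 and 31-60), the 3-D FFT amplitude integrated over the
spatiotemporal octants corresponding to rightward and leftward drift,
within 2-8 Hz and 0.5-6 cyc/deg (all vertical frequencies summed; cells
with `f_x = 0` or `f_t = 0` belong to neither direction and lie outside
the passband anyway). Which octant pairing means "rightward" under the FFT
sign convention is fixed empirically by a single 100%-coherence
calibration movie, cached per geometry — more robust than reasoning about
DFT conventions. Energies are left unstandardized: both halves share a
construction, so the two leverage coefficients are directly comparable.

`leverage_regression()` fits
`P(right) = logistic(b0 + b1 E_pre + b2 E_post + b3 C)` over weak-coherence
(|C| <= 6.4%), 800 ms trials whose estimated integration endpoint
`t_theta = t_sd - t_nd` lies within a window of the stimulus midpoint.
`bootstrap_leverage_difference()` contrasts `b1 - b2` inside the window
against refits on same-sized resamples of the out-of-window trials
(one-tailed). `simulate_leverage_experiment()` provides the generative
analogue: choices come from a logistic in the stimulus energy accumulated
*up to* each trial's termination time, with each half weighted by the
fraction of it integrated before termination. Its defaults (2766 trials in
the pipeline configuration, matching the pooled weak-coherence trial count
of the experimental design it emulates; energy weight 3 on the
standardized used-energy) produce per-trial stimulus leverage of the same
order as the choice-variance the coherence term leaves unexplained, and a
clearly detectable in-window contrast at that sample size.

## Goodness of fit and sensitivity analyses

The Jensen-Shannon divergence is computed in bits (log base 2, so it is
bounded by 1) between joint histograms over (signed coherence, choice,
10 ms time bin). Fitted cell masses are first rescaled to the observed
cell proportions (`match_proportions()`), so mispredicted error rates do
not masquerade as shape mismatch. The permutation null shuffles the fitted
per-cell distributions across cells, rescales, and shifts each permuted
cell in time (integer bins, edge-truncated and renormalized) to match the
observed cell mean — isolating within-cell *shape* as the only difference
— with `p = (N0 + 1)/(N + 1)`. Whether to pool cells onto one axis or
average per-cell divergences is ambiguous in principle; both are
implemented (`aggregate` argument) and pooled is the default. The
bootstrap CI refits the model to resampled trials (200 draws by default)
and takes percentiles.

The surrogate analyses ask how special the observed means are. Reflected
cumulative-beta surrogates `t = k1 + k2 cbeta(|C - k3|/0.512, alpha,
2 - alpha)` span squashed-semicircle to sharply-peaked shapes as `alpha`
runs over (0, 2) — *small* `alpha` concentrates the beta near zero and
yields the peaked, chronometric-like shape, large `alpha` the squashed
one. The inner linear pair `(k1, k2)` is solved in closed form for each
candidate center `k3` of a one-dimensional search; 31 `alpha` steps from
0.01 to 1.95 by default. The jitter analysis permutes the gaps between
rank-ordered means (ties broken by signed-coherence order), preserving
minimum, maximum and rank order, and regresses the prediction
log-likelihood ratio on the mean absolute distortion; the crossing of the
fitted line with logLR = -10 is reported as a sensitivity scale. The
cross-subject test enumerates all `27^4 = 531441` coordinate-wise
parameter reassignments across four subjects and counts strictly better
combined likelihoods.

## Problem sizes, determinism, limitations

The package's own validation runs at deliberately chosen sizes: `1e5`
paths per parameter set for simulator-versus-closed-form and
simulator-versus-solver agreement (Kolmogorov distance below 0.01), ~4000
trials for collapsing-bound recovery, 2000 trials per synthetic subject
for the shuffle-test replication, 2766 trials for the leverage contrast,
1000 jitter replicates, 400 shuffles, 500 leverage bootstraps. Every
stochastic routine takes an explicit seed and restores the caller's RNG
state; two runs with the same seed are bit-identical.

Known limitations: the collapsing-bound likelihood assumes drift is
stimulus-driven for the whole accumulation (exact for the free-response
design and for the model-generated recovery datasets; an approximation for
controlled-duration tables from the generator, whose drift switches off at
stimulus offset); movie persistence uses a plain-text container rather
than a binary array store; and no eye-movement, lapse, or clock-memory
processes are modeled. The analyses here validate internal consistency of
the method chain, not the neural claims themselves.
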