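---
title: "Cross-map causality with echo state networks: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-map causality with echo state networks: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esnccm)
```

## The method in one paragraph

Convergent cross mapping rests on Takens' observation that in a coupled
dynamical system the *effect* variable's trajectory embeds the history of
its *cause*: if Y causes X, Y's past can be reconstructed from X's time
series. `esnccm` performs that reconstruction with a leaky echo state
network: the candidate *effect* series drives a fixed random reservoir,
and a ridge readout is trained to predict the candidate *cause* series at
every lead/lag τ in a symmetric grid. The Pearson correlation ρ(τ)
between predictions and observations — the cross-map skill — peaks at a
negative lag when the target really is a cause (its *past* is what the
input embeds), at a positive lag in the forward (prediction) direction,
and nowhere in particular when the pair is uncoupled. Comparing the two
directional curves of a pair yields a verdict: one negative peak →
unidirectional cause; two negative peaks → bidirectional; low skill or
an unmatched pattern → no claim.

## The network

State update, for scalar input $X_t$ and $N$-dimensional state $u_t$
(initial state $u_0 = 0$):

$$u_t^* = \tanh(A u_{t-1} + W_{in} X_t), \qquad
  u_t = (1-\psi)\,u_{t-1} + \psi\,u_t^*$$

* $W_{in}$ entries are $\gamma s v$, $A$ entries $\beta s v$, with
  $s \sim \text{Bernoulli}(p_s)$ and $v \sim \text{Uniform}[-1,1]$,
  sampled once per seed ($W_{in}$ first, then $A$, for reproducibility).
* $A$ is then rescaled multiplicatively so its spectral radius (largest
  eigenvalue modulus) equals the configured $\lambda_{max}$ exactly; the
  raw scale $\beta$ is absorbed by this rescale and defaults to 1. A
  spectral radius below 1 is the standard necessary condition for the
  echo state property — states forget their initial condition, which the
  test suite verifies directly (zero input, $\lambda_{max} = 0.5$: state
  norms fall below $10^{-6}$ within 500 steps).
* Only the readout is trained: $\hat Y_{t+\tau} = W_{out} u_t$, with
  $W_{out}$ minimizing $\|\hat Y - Y\|_2^2 + \alpha \|W_{out}\|_2^2$ —
  the standard squared-norm ridge problem, solved by the normal
  equations. ($\alpha$ is a ridge parameter; the squared form is what
  gives it that meaning and a closed-form solution.)

### Tunable parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `N` | reservoir size | 100 | grid: 50–300 |
| `spectral_radius` | $\lambda_{max}$ of $A$, memory depth | 0.5 | grid: 0.1–0.9 |
| `leak` | $\psi$, leaky mixing in $[0,1]$ | 1 | exposed, not a grid axis |
| `connectivity` | $p_s$, sparsity of $A$, $W_{in}$ | 0.1 | grid: 0.1, 0.6 |
| `input_scaling` | $\gamma$, drive into the tanh | 0.5 | grid: 0.1, 0.6 |
| `ridge` | $\alpha$ | 1e-4 | grid: 1e-10…100 |
| `washout` | initial states excluded from fits | 10 | transient removal |

The default tuning grid (`grid_spec()`) enumerates 600 combinations.
$\psi$ is deliberately a configuration value rather than a grid axis:
its tuning status in the source framework is ambiguous, and the grid is
kept to the five axes above. Selected values outside a grid can always
be supplied directly through `reservoir_config()`.

Input and target series are z-standardized around the fit (predictions
are mapped back) by default: daily count features and score features
live on wildly different scales, and $\gamma$ would otherwise be
confounded with the data scale. Set `standardize = FALSE` to disable.

## Lag alignment and skill

For lag $\tau$ the input/target pairing uses the one-sided window
$t = 1+|\tau|-h(\tau), \ldots, T-h(\tau)$ with $h(\tau)=\tau$ for
$\tau \ge 0$ and $0$ otherwise: non-negative lags pair a *prefix* of the
input with targets shifted into the future; negative lags pair a
*suffix* of the input with targets from the past. Both subseries have
length $T-|\tau|$, and the skill is the sample Pearson correlation on
that index set (verified against `stats::cor` to $10^{-10}$).

Two numerical details matter:

* **Prefix reuse.** Reservoir states never depend on future inputs, so
  for $\tau \ge 0$ the states of a single full-series run are
  bit-identical to a fresh run on the prefix; `cross_map_skill()` reuses
  them and only re-runs the reservoir for negative lags.
* **Out-of-sample skill.** The readout is fit on training rows and the
  skill computed on rows the fit never saw: leave-one-unit-out pooling
  when the panel has two or more units, a first-half/second-half
  temporal split for single-unit panels (`evaluation = "insample"` is
  available but discouraged). This choice is load-bearing: an in-sample
  ridge fit with $N = 100$ states reaches spurious peak skill of
  0.2–0.4 on pure white noise — above the default claim threshold —
  whereas the out-of-sample null stays below ≈ 0.15 and true-coupling
  skill remains ≈ 0.99.

Peak ties are broken toward the smallest $|\tau|$, then toward the
negative lag (parsimony first; cross-map causal signals live at negative
lags). $\tau = 0$ counts as the positive domain for the decision rules
(configurable via `zero_positive`).

## Decision rules and threshold

Writing $\rho_x$ for the curve whose *target* is X: a peak of $\rho_x$
at negative $\tau$ (and $\rho_y$ non-negative) means the input series Y
embeds X's history, i.e. **X causes Y**; both peaks negative means
bidirectional coupling; either peak skill below `skill_threshold`
(default 0.2) or both peaks positive yields no claim. Without a minimum
skill, pure noise would always produce a verdict; 0.2 sits well above
the measured out-of-sample null (≤ 0.15 at $T = 1000$) while far below
genuine coupling skill. A coupling delay $d$ shifts the cause-probing
peak to roughly $-(1 + m + d)$, where $m \ge 0$ is the reservoir's own
lag; the shift is monotone in $d$, which is what the delay diagnostics
rely on.

## Tuning

`loocv_nrmse()` implements leave-one-unit-out cross-validation: for each
unit the readout is fit on all other units' stacked post-washout states
and the held-out unit's NRMSE recorded — NRMSE being the RMS error
divided by the *mean* of the observed series, exactly as defined, which
presumes positive-mean series (counts, scores) and is undefined at mean
zero (an error, not an NA). `grid_search()` evaluates the Cartesian
product exhaustively with one shared reservoir seed so combinations
differ only in hyperparameters; ties break toward smaller $N$, then
smaller spectral radius. Tuning happens once per ordered direction at
$\tau = 0$ (the only lag-symmetric choice) and the winning configuration
is frozen across the whole lag grid.

## What the synthetic generators emulate

**Coupled logistic maps** (`gen_coupled_logistic`): the classic CCM
benchmark,
$x_{t+1} = x_t(r_x - r_x x_t - \beta_{xy} y_{t-d})$ and symmetrically
for $y$, with $r_x = 3.8$, $r_y = 3.5$ (chaotic regime, asymmetric so
the two directions are distinguishable), default coupling 0.32, burn-in
200 steps discarded, trajectories clipped to $(10^{-6}, 1-10^{-6})$ and
more than 10 consecutive clips treated as divergence. With zero noise
every generated value equals the update rule applied to its
predecessors, which the tests recompute by hand.

**Tweet panel** (`gen_tweet_panel`): per unit, a latent tanh-squashed
AR(1) sentiment series in $[-1, 1]$ drives four count features through a
log link with a configurable lag (default 7 days), plus optional mutual
cross-excitation among the counts; counts are rounded intensities, hence
nonnegative integers. Defaults — 8 units, $T = 234$ days starting
2020-02-24, intercepts giving daily tweet counts in the tens — mirror
the scale of a multi-city daily study window. What it does *not*
emulate: heavy-tailed bursts, weekday seasonality, shared exogenous
shocks (news events) that confound real panels, or missing days. Passing
tests on these panels demonstrate the pipeline recovers known structure
under its stated assumptions, not that real tweet data satisfy those
assumptions.

## Text preparation

Cleaning removes URLs, strips `#`/`@` while keeping the attached word,
deletes punctuation and junk tokens, lowercases, splits on whitespace
and drops stop-words; it is idempotent, and the stop-word list is an
input, not a constant. The tweet score is the lexicon sum over tokens
divided by the *total* token count (out-of-lexicon tokens count in the
denominator — the literal reading of a mean over the words of the
tweet); emotion frequencies divide per-mood annotation counts by the
same denominator. Tweets that clean to nothing score 0, are flagged
`no_content`, and still count toward daily tweet totals. The denominator
uses post-cleaning tokens (documented choice; pre-cleaning counts are
not recoverable from the token interface). Heuristic sentiment
adjustments (negation, punctuation emphasis, capitalization, boosters,
emoji) belong to external scorers whose output can be ingested as a
column; they are not reimplemented here.

`period_descriptives()` takes the *scored tweet records*, not the daily
panel: the per-period standard deviation is over tweet-wise scores,
which daily aggregates no longer contain.

## Degenerate inputs and numerical choices

* Constant series at some lag → skill is NA (flagged), never a crash;
  a curve with every lag degenerate is an error listing the cause.
* `ridge = 0` with rank-deficient states → error by default,
  minimum-norm SVD solution behind `allow_pinv = TRUE`.
* An all-zero sampled reservoir (possible at tiny $p_s N^2$) cannot be
  rescaled to a spectral radius → explicit error advising larger $p_s$.
* Interior missing days are linearly interpolated before the recursion
  (which needs gap-free input), with the filled positions recorded in an
  attribute; leading/trailing gaps are dropped.
* All randomness flows from user seeds through one internal splitter;
  RNG state of the session is always restored.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run at desk scale, chosen as
the package's own verification conditions: series length 1000 for the
logistic benchmarks (20 replicate seeds for recovery/null rates in the
tests, 10 in the acceptance script), a 72-combination reduced tuning
grid (subset of the 600-point default grid) on a two-unit panel of
length 500, and a four-unit, 234-day synthetic tweet panel for the full
ten-pair study. At these sizes direction recovery is ≈ 90–100%, the
uncoupled false-claim rate 0%, and the white-noise null peak skill
≈ 0.10.

## Known limitations

* Verdicts assume no confounding: a hidden driver of both series can
  produce negative-lag peaks in both directions (read: "bidirectional").
* Skill curves use a single reservoir realization by default;
  `n_seeds > 1` averages curves over reservoirs when sampling noise
  matters (it mostly does not at $N \ge 100$).
* The cross-map is strictly univariate-in/univariate-out; multivariate
  embeddings and surrogate-based significance tests are out of scope.
* Peak "flatness" is reported only as prominence metadata (peak minus
  median skill); no flatness criterion enters the rules.
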