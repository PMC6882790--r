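---
title: "Modeling hierarchical confidence reports: generative model, observers, fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling hierarchical confidence reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hierconf)
```

## The task and its generative model

`hierconf` models confidence reports in a two-level sampling task. On every
trial the observer sees a small sample of `N` items, `N_B` blue and `N_R`
red, drawn from a hidden proportion `mu`, and reports a continuous
confidence `y` in `[0, 1]` that the hidden majority is blue.

Two conditions differ in how `mu` is generated:

* **Flat condition** — each trial's `mu` is an independent draw from
  Beta(4, 4); sample sizes are uniform on {3, 5, ..., 13}. The only route
  to calibrated confidence is the conjugate posterior over `mu`.
* **Blocked condition** — trials come in blocks of five sharing a hidden
  binary *block tendency* `b ~ Bernoulli(0.5)`. Given `b`, each trial's
  proportion is drawn from a skewed Beta: Beta(14, 9) when the block favors
  blue (`b = 1`), Beta(9, 14) otherwise. Sample sizes are uniform on
  {3, ..., 11}. The tendency shapes give a blue-context mean proportion of
  14/23 ≈ 0.609. Blocks are independent, and the observer is assumed to
  know where block boundaries fall.

`sample_exp1_session()` and `sample_exp2_session()` implement exactly this
process. Defaults are the study conditions: 280 flat-condition trials per
session, 114 blocks (570 trials) for the blocked condition, the shape
parameters above. Each block consumes a child random stream whose seed is
drawn up front from the master seed, so enlarging a simulated session never
perturbs the blocks already generated.

```{r generate}
cfg <- generative_config("exp2")
trials <- sample_exp2_session(cfg, n_blocks = 6, seed = 1)
head(trials, 7)
```

## Exact inference by message passing

Because the Beta prior is conjugate to the binomial sample, all of the
ideal observer's integrals have closed forms.

* Flat condition: the posterior over `mu` is
  Beta(`N_B` + 4, `N_R` + 4) and confidence in a blue majority is its mass
  above one half — `exp1_confidence()` evaluates the regularized
  incomplete Beta function.
* Blocked condition: each previous trial contributes a bottom-up *message*
  `m_t(b)`, the normalized Beta-binomial evidence of its counts under the
  two context-conditional mixtures (`trial_message()`). Messages multiply
  into a belief `M_T(b)` over the tendency (`update_context_belief()`),
  which in turn mixes the two context-conditional posteriors of the current
  trial into the reported confidence (`exp2_confidence()`).

All Beta and Beta-binomial masses are computed through `lbeta()` in log
space, so large shape parameters cannot overflow, and normalizers are never
materialized unlogged. Because the hidden proportion is continuous, the
event `mu = 0.5` has no posterior mass and "at least half blue" is simply
the upper regularized incomplete Beta at 0.5.

`exp2_observer_batch()` runs the whole recursion vectorized over a trial
table; `exp2_confidence_numeric()` is a deliberately brute-force trapezoid
integration of the full joint (at least 1e5 grid points per proportion)
kept solely as an independent numerical oracle. The closed form and the
oracle agree to better than 1e-6 across random blocks — this is checked in
the test suite on a thousand freshly sampled blocks.

Two structural properties are worth noting (and are enforced by tests):
swapping all blue/red counts maps every confidence `c` to `1 - c`, and
permuting the order of previous trials leaves the belief and the current
confidence untouched (messages commute).

## Heuristic observers

Four non-probabilistic estimators serve as comparison models:

* `ratio_estimate()` — the sample proportion alone (flat condition);
* `difference_estimate_exp1()` — the count difference `N_B - N_R`;
* `averaging_context()` — mean of previous sample proportions, blind to
  their sample sizes;
* `tally_context()` — pooled blue count over pooled total, size-weighted
  but non-probabilistic;
* `difference_context()` — a logistic of the running mean count
  difference, with sensitivity `omega`.

All context heuristics return 0.5 on a block's first trial and use
strictly previous trials (positions `1..T-1`), with the running mean
divided by `T - 1` exactly as defined. They are running averages, so the
influence of early trials never grows with block position — the key
qualitative contrast to the accumulating probabilistic belief.

## Response model

Internal estimates are mapped to predicted reports and compared to data
through a noise model:

* `sigmoid_map()` — a logistic of an odd cubic polynomial in the
  standardized estimate `c' = 2(c - 0.5)`. With zero intercept the map
  treats blue and red symmetrically; the intercept is retained as a
  global-bias parameter, so symmetry properties are stated conditional on
  `w0 = 0`.
* `flexible_map()` — for the blocked condition, a nine-term odd polynomial
  in `(q', N, M')` passed through a logistic. It integrates *any* context
  estimate `M` (probabilistic or heuristic) with the current sample
  without committing to a combination rule. Each non-constant term is
  divided by its standard deviation over the training inputs
  (`flexible_term_scales()`), computed on the training folds only and
  frozen into the fit, so held-out evaluation never leaks test data. The
  fourth term uses the standardized `M'` (not raw `M`): the two
  conventions define the same model class up to reweighting, and the
  standardized form preserves the odd red/blue symmetry term by term.
  `N` enters raw, as a magnifier of the signed terms.
* `truncated_gauss_logpdf()` / `response_loglik()` — reports follow a
  Gaussian with SD `theta` truncated to `[0, 1]` around the prediction,
  mixed with a constant lapse floor `epsilon`:
  `(1 - eps) * N_[0,1](y | yhat, theta) + eps`. The default
  `epsilon = dnorm(4) ≈ 1.34e-4` keeps far-outlying reports from
  dominating a fit; `theta` is bounded below at 0.01 to avoid the usual
  mixture singularity. The simulator realizes the lapse generatively as a
  uniform-response mixture with weight `epsilon` (the uniform density on
  the unit interval is 1, so the mixture density integrates to one).
* `expected_response()` — the truncated-Gaussian mean, which is pulled
  toward the center relative to the noiseless prediction; useful when
  plotting fitted-model patterns.

## Fitting and model selection

`fit_model()` maximizes the response log-likelihood over mapping weights,
`theta`, and any model-specific parameters. Each training run uses a
seeded differential-evolution global stage under box constraints (weights
in `[-50, 50]`, `theta` in `[0.01, 1]`) followed by bounded L-BFGS-B
refinement. Refinement also starts from a logit-scale least-squares
solution: since every mapping is a logistic link, regressing
`qlogis(y)` on the design lands refinement in the relevant basin, which a
small evolutionary population can miss when the logistic saturates and the
lapse floor flattens the surface. The best refined solution wins, and a
fit that never reports local convergence is flagged on the result rather
than silently returned.

Cross-validation (`cross_validate_folds()`) always splits at the block
level — trials sharing a hidden context never straddle the train/test
boundary — into `k = 10` near-equal folds by default (`k = 3` in the
scaled-down recovery studies below). Per-participant model evidence is the
median held-out log-likelihood across folds (CVLL).

The **mismatched-tendency observer** (`fit_mismatched_tendency()`) refits
the full hierarchical observer with free subjective tendency shapes under
the constraint `nu1' >= nu2'`. It is parameterized by the blue-context
expectation `e = nu1'/(nu1' + nu2')` in `[0.5, 0.95]` and the
concentration `s = nu1' + nu2'` in `[2, 120]`, because the likelihood
forms a curved ridge along which `e` and `s` trade off at roughly constant
separability of the two context distributions,
`(2e - 1) / sqrt(e(1 - e)/(s + 1))`. Refinement is therefore multi-started
from points spaced along that ridge at the separability implied by the
global stage; a single local run can otherwise stall on the ridge's far
end with a materially worse likelihood. The recovered expectation is the scientifically
meaningful readout: values below the generative 0.609 indicate an agent
that behaves as if the context were weaker than it is.

The difference-context sensitivity `omega` is bounded to `[0, 5]` during
fitting: the flexible map's own `M'` weights absorb any sign flip, so
allowing negative `omega` only duplicates solutions.

`bms()` performs random-effects group-level selection on the
participants-by-models CVLL matrix: the standard variational iteration for
a Dirichlet over population model frequencies (uninformative prior count
1), run to `1e-6` stability on the counts — far below any
decision-relevant difference. `exceedance_prob()` evaluates the
probability that each model is the most frequent: the exact Beta tail for
two models, seeded Monte-Carlo over Dirichlet draws otherwise.

## Behavioral pattern analyses

`pattern_suite()` condenses the qualitative signatures of hierarchical
probabilistic inference into six scalar contrasts (each with supporting
binned curves from `bin_equal_count()`, which only serves visualization —
statistics are computed on ungrouped data):

1. higher confidence in blue-tendency blocks at matched sample proportion;
2. aligned confidence rising with the ideal observer's aligned belief
   (computed from strictly previous trials — the belief *before* seeing
   the current sample, which is the quantity a top-down prior should be);
3. a steeper aligned confidence curve for large current samples
   (median split on `N` via `quantile_split()`);
4. a steeper modulation by the previous trial's aligned proportion when
   that sample was large;
5. equal regression weights across previous-trial positions
   (`previous_trial_weights()`, reported as maximum relative deviation
   from the mean weight);
6. aligned confidence rising with within-block position.

The previous-trial regression and the per-sample-size slope regression
(`slope_by_sample_size()`) use the logistic-sigmoid forms with an
*untruncated* Gaussian response likelihood, exactly as specified for these
conditional analyses: responses near the extremes lose density to
spill-over and are thereby down-weighted, stabilizing slope estimates on
scarce conditioned subsets. Both forms are intercept-free (unbiased
judgments are assumed). One consequence worth knowing: because aligned
confidence averages above one half even for a context-blind agent (the
current sample correlates with the tendency), the intercept-free weights
of such an agent settle at small positive values rather than exactly
zero; the diagnostic contrasts — equality across positions, magnitude far
below the hierarchical observer's, and absence of growth in total
influence across block positions — are unaffected.

`evidence_opposing_rate()` counts reports that cross to the opposite side
of 0.5 from the current sample's aligned majority, among trials whose
aligned sample proportion is strictly below one half (ties at exactly 0.5
carry no opposing evidence and are excluded; a continuous report crossing
0.5 coincides with the discrete choice reading for a 0.5 decision
boundary). The comparison rate comes from a context-blind reference agent
reporting the aligned sample proportion plus truncated-Gaussian noise of
SD 0.1, simulated with at least 1e5 draws.

## What the simulator does and does not emulate

The synthetic generator reproduces the stimulus statistics (tendency
mixture, size sets, binomial sampling), the trial counts of the study
sessions, and a response process consisting of a deterministic mapping
plus truncated-Gaussian noise and uniform lapses. It does not emulate
perceptual numerosity noise, learning or drift across a session,
motor-cursor dynamics, or feedback-driven strategy changes — so passing
recovery and pattern tests demonstrates correctness of the pipeline under
its own assumptions, not that human data must follow them. Simulated
agents default to `theta = 0.1`, a mid-range response noise matching the
reference noise level used in the evidence-opposing analysis.

## Problem sizes and numerical choices

The validation studies run at the following sizes, chosen to balance
statistical resolution against a laptop-scale runtime:

* oracle agreement: 1,000 random blocks, 1e5-point grids, tolerance 1e-6;
* pattern suite: 24 simulated agents at 114 blocks (570 trials) each —
  the study's own session sizes;
* tendency recovery: 20 seeded replicates of 570 trials;
* model recovery: 8 simulated agents, 3 block-level folds, a reduced
  differential-evolution budget (population 30, 40 generations), with
  selection expected to recover the generating model at exceedance
  probability at least 0.95.

Ties, degeneracies and edge cases: empty message lists return the prior;
context heuristics return exact 0.5 indifference with no history; constant
binning inputs collapse to a single bin with a warning; degenerate
(constant) polynomial terms keep a unit scale so division is harmless; and
all probability pairs are renormalized in log space.

## Known limitations

* The flexible map is a function approximator; its fitted weights are not
  individually interpretable (collinearity between `q'` and `q'^3` terms
  is substantial), and only held-out likelihood should be compared.
* CVLL with three folds is noisy at single-participant level; group-level
  selection is the supported use.
* The mismatched-observer concentration is weakly identified by design
  (the ridge above); only the expectation should be interpreted.
* Sequential effects across blocks (e.g. carry-over of the previous
  block's belief) are intentionally out of scope: the belief resets to
  the prior at every block boundary.
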