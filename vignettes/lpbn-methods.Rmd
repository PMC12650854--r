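---
title: "Learning probabilistic Boolean networks: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning probabilistic Boolean networks: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpbn)
```

## The model

A learning probabilistic Boolean network (LPBN) operates on a Boolean
substrate `z` of `m` bits. Real-valued features reach the substrate through
a standardize-then-bin map: each feature is centred and scaled with
training-split statistics only, cut into `B` equal-width bins spanning the
standardized training min–max, and one-hot coded, so `m = d * B`
(`fit_binarizer()`). Values outside the training range clamp to the
boundary bins, preserving the one-hot invariant; this clamping convention
is our choice — nothing else keeps the encoding total without rejecting
data. Two optional constant bits (CONST0/CONST1) let a two-input unit
express unary functions: `AND(z, 1) = z`, `XOR(z, 1) = NOT z`.

Each of `N` units holds three categorical distributions parameterized by
logits: input position A (over `m`), input position B (over `m`), and the
operator (over `{AND, OR, XOR, NAND}`). A sampled triple turns the unit
into a concrete gate `h_n = op(z[A], z[B])`; the N-bit feature vector `h`
feeds a linear, logistic, softmax, or policy head. The selector
distributions are *input-independent*: one categorical triple per unit,
which is what the parameter accounting `N (2m + |O|) + head` assumes.
`{NAND}` alone is functionally complete, so the operator library loses no
expressivity by being small; `compile_indicator()` demonstrates the
constructive side by building a multi-layer NAND tree that fires exactly
on one bit pattern (trained models stay single-layer — the compiler
exists to certify expressivity, not to train).

## Estimators

Selector logits cannot be trained by backpropagation through the discrete
sample, so the package uses the score-function (REINFORCE) estimator with
an advantage: per logit, `(F - b)(1{chosen} - pi)`, with feedback `F`
equal to the negative per-example loss (supervised) or the episode return
(RL). The estimator is unbiased for any baseline `b` independent of the
sample; the variance-minimizing constant baseline weights feedback by the
squared score norm (`optimal_constant_baseline()`), and is approximated
online by an exponential moving average with decay 0.95, initialized at
the first observed feedback to avoid a cold-start transient. An entropy
bonus `lambda * H(pi)` with `lambda` annealed linearly from `lambda0` to
zero over the first half of the budget delays premature collapse
(`lambda0 = 1e-3` for supervised tasks, `5e-3` for control tasks).
Advantages are clipped to [-5, 5] and gradients to L2 norm 5 on control
tasks. Exact Rao-Blackwellization over the independent per-unit factors
(`rao_blackwell_grad()`) and Gumbel-Softmax relaxed sampling with common
random numbers (`gumbel_softmax_sample()`, temperature annealed 1.0 to
0.3) are available as estimator variants; the default everywhere is
REINFORCE with the EMA baseline. Learned control variates and the full
relaxation-corrected estimators are out of scope.

## Initialization is where the method lives or dies

With all logits at zero, structures are resampled essentially uniformly at
every step, so the head never sees the same feature twice under one
meaning: its updates scramble, the loss stays flat, and a flat loss gives
the selectors no signal — a mutual deadlock we observed on every task
larger than a toy. The package therefore defaults to an **identity
initialization**: unit `n` starts with its input selectors concentrated
(logit offset 8) on substrate bit `n mod m` and on the AND operator, i.e.
every unit begins as a stable pass-through reader `h_n = z[n mod m]`, the
Boolean analogue of identity-initialized residual blocks. The head then
immediately faces an informative, stable design matrix (the substrate
itself, tiled), and selector learning re-composes units into pairs as the
advantage signal accumulates. The offset is large enough that early
features are stable (about 97% of per-episode draws reproduce the
initialized structure) but finite, so structures remain trainable.

Uniform initialization remains available (`init = "uniform"`) and is the
right choice when the target is *pure interaction* — e.g. two-bit parity,
where no single-bit feature carries signal and learning must bootstrap by
symmetry breaking. That bootstrap works but is slow: parity is solved
reliably with a 600-epoch budget on a 4-bit substrate, not within the
50-epoch benchmark budget. The operator-ablation checks therefore run
parity with uniform initialization and the longer budget.

## Supervised protocol

Classification uses cross-entropy on a logistic head; regression squared
error on a linear head (reported as RMSE, scored as -RMSE so that higher
is better everywhere); representation learning trains a shallow linear
decoder to reconstruct the standardized inputs, with embeddings taken from
the MAP structures at the last epoch (no model selection). Defaults: 50
epochs, batch 64, selector rate 7e-2, head rate 3e-1 (the midpoint of the
stated [2.5, 3.5]e-1 interval), `B = 5`. Evaluation decodes the MAP
structure — argmax per slot, ties to the lowest index — making test
metrics deterministic given the trained logits.

The MLP baseline is one hidden tanh layer trained by minibatch SGD with
the width chosen by `match_mlp_width()` so parameter counts agree within
10%; paired runs share seeds and splits (70/10/20), and the comparison
harness reports mean paired differences with percentile bootstrap CIs
(10,000 resamples; a bias-corrected variant is a switch), exact two-sided
sign tests with Holm correction, Cliff's delta, and TOST equivalence
verdicts. A winner is declared only when the bootstrap CI excludes zero;
with three seeds the exact sign test cannot fall below p = 0.25, so a
p-threshold rule would never declare a winner at such n — the CI rule is
the one consistent with the rest of the reporting conventions. For TOST
with very few seeds the t-tests degenerate, so the verdict additionally
requires the bootstrap CI to sit inside the margin.

## Control tasks

LineWorld is a 9-position chain, start at the center, terminals at both
ends (+1 right, -1 left, 0 otherwise), horizon 40, one-hot states;
training is undiscounted, 500 episodes, selector rate 7e-2, policy-head
rate 1.8e-1, `lambda0 = 5e-3`. Cart-pole uses the canonical constants
(gravity 9.8, cart mass 1.0, pole mass 0.1, half-length 0.5, force 10 N,
Euler step 0.02 s, thresholds 12 degrees and 2.4 m, horizon 280), 8
equal-width bins per state variable over fixed ranges (x within 2.4 m,
velocities within 3 and 3.5, angle within 12 degrees), 300 episodes,
discount 0.99, selector rate 1e-2, head rate 2e-2.

LPBN policies sample one structure per episode (a per-step switch
exists), so the action log-probabilities along the trajectory refer to a
well-defined circuit. The policy head is updated by per-step REINFORCE
with advantages `G_t - V(h_t)` from a linear critic on the Boolean
features; the critic is fitted by normalized least-mean-squares (step
scaled by the mean squared feature norm, three passes per episode), which
keeps the value fit stable regardless of how many feature bits are
active. Selector logits are updated once per episode with the episode
return against the EMA baseline. For cart-pole, `N = 64` units (the unit
count is a free design choice; 64 gives each substrate bit two initial
readers) with identity initialization; reporting uses the trailing
100-episode moving average. For LineWorld, `N = 8` with uniform
initialization suffices — the optimal policy (always right) is
expressible by the head bias alone, and both the LPBN and the
parameter-matched MLP (width 16; 194 parameters each) reach the +1
plateau well before the budget ends.

## Gene-network dynamics

`parse_network()` reads one-gene-per-line rule files (AND/OR/NOT/XOR/NAND
and parentheses; `:=` freezes a gene) under synchronous semantics — all
genes update simultaneously from the current state, which is what the
attractor structure of the shipped cell-cycle model presupposes. The
perturbed chain applies the deterministic update and then flips each bit
independently with probability `p`, giving the closed-form kernel
`P(x -> y) = p^H (1-p)^(n-H)` with `H` the Hamming distance from the
deterministic successor; any `p > 0` makes the chain ergodic.
`stationary_distribution()` offers power iteration (L1 tolerance 1e-12)
and a direct linear solve; the direct method is preferred for small-`p`
chains, whose spectral gap is of order `p` and which therefore mix too
slowly for plain iteration. Non-ergodicity is flagged by disagreement
between two power-iteration starts, since a single converged run cannot
detect non-uniqueness. KL comparisons floor the reference distribution at
1e-12 and renormalize.

The shipped ten-gene mammalian cell-cycle model (CycD, CycE, Rb, E2F,
CycA, p27, Cdc20, UbcH10, Cdh1, CycB; rule provenance documented in the
fixture header) has exactly one quiescent fixed point — Rb, p27, Cdh1
active — and one 7-state oscillatory cycle on the CycD-on half of the
1024-state space, with basins of 512 states each.

`fit_transition_lpbn()` learns these dynamics from data: transitions from
a simulated trajectory (default study condition: 1e5 steps at
`p = 0.001`) are aggregated by unique current state with visitation
counts, and one logistic-head LPBN per gene (substrate = the 10 state
bits plus CONST0/CONST1, `N = 24`) is trained on minibatches of 64 drawn
from the empirical state distribution — so one "epoch" is one pass over
the raw transitions, and heavily revisited attractor states dominate the
objective exactly as they dominate the data. Three such passes per gene
(the default) recover both attractors after MAP extraction
(`lpbn_to_network()`: MAP structure, head thresholded at 0.5) across the
development seeds, with stationary-distribution KL around 0.1–0.2 nats.
An earlier design that trained full-batch on weight-normalized unique
states produced selector gradients an order of magnitude too small to
concentrate the logits within any reasonable budget; the resampling
scheme is equivalent in objective but restores the gradient scale of the
batch-64 protocol.

## What the generators do and do not emulate

The synthetic tasks reproduce the statistical *structure* of the study
conditions: linear-score labels and targets on standard-normal
covariates in 8 dimensions (noise sd 0.1 — the noise scale is not a
published constant, so absolute accuracies are not comparable to any
published table), three isotropic Gaussian blobs in 4 dimensions with
means at pairwise 120 degrees, templated negation sentences over a
closed 24-word vocabulary whose label is polarity XOR negation (8
positive words, 8 negative, 4 label-neutral intensifiers), and the two
control environments. Passing tests on these generators shows the
machinery is correct under the stated generative assumptions; it does not
show robustness to covariate shift, label noise beyond the Gaussian
score model, or real text.

## Numerical choices and degenerate inputs

Softmax is computed with max-subtraction; categorical entropy uses
`0 log 0 = 0`; MAP ties break to the lowest index; logistic outputs are
clamped to [1e-12, 1 - 1e-12] inside cross-entropy; zero-variance
features are rejected at binarizer fit; `B < 2` is rejected; zero-unit
models degrade to the base-rate/bias head; the sign test drops ties and
returns p = 1 when everything ties; the bootstrap of a constant sample
gives a degenerate [c, c] interval.

## Known limitations

Single hidden layer only (multi-layer LPBNs are future work); regression
inherits piecewise-constant discretization bias, so smooth targets are
fit no better than the per-cell conditional mean; REINFORCE structure
search is slow on pure-interaction targets under the benchmark budget
(see the initialization section); dense transition matrices limit exact
chain analysis to about 12 genes, and exhaustive attractor enumeration to
about 20. The uniform-initialization text-negation configuration learns
the interaction rules given budgets several times the benchmark default;
within 50 epochs it typically stays near chance, which is the honest
price of the XOR-shaped label.
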