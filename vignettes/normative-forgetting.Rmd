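---
title: "Forgetting as optimal decision making: the models inside forgetsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forgetting as optimal decision making: the models inside forgetsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forgetsim)
```

## The model

`forgetsim` treats forgetting in classical conditioning as the rational
consequence of acting in a world whose stimulus–reinforcement association
changes over time.  The world is a discrete-time Markov chain on three
hidden states — rewarding (`r`), neutral (`n`), punishing (`p`) — with
per-bin rates `a_rn`, `a_nr`, `a_np`, `a_pn` and no direct `r <-> p`
transitions (a switch of valence always passes through neutral, which keeps
the forgetting trajectory monotone rather than letting the preference
overshoot to the opposite response).  In each bin the agent approaches or
avoids the stimulus.  Avoiding returns the neutral signal with certainty and
reveals nothing.  Approaching returns `+` surely in `r`, `-` surely in `p`,
and `0`, `+`, `-` with probabilities 0.99, 0.005, 0.005 in `n`; the two rare
outcomes stand for reward or punishment unrelated to the stimulus.
Reinforcement magnitudes default to +1 and −1.

Both actions cost something.  The costs `c_ap`, `c_av` are i.i.d.
exponential with scale `lambda` (mean = s.d. = `lambda`), drawn fresh each
bin.  Only their difference `D = c_av − c_ap`, a Laplace(0, `lambda`)
variable, affects the choice; the common level enters expected returns as a
constant.  The costs are the model's stand-in for everything that sways a
single trial but is unrelated to the conditioned stimulus, and they are what
makes behavior probabilistic: a population forgetting curve is just the
Laplace CDF evaluated along a deterministic belief trajectory.

## Belief filtering and the update-order convention

The agent's memory is a belief `b` over the hidden state, updated by
Bayesian filtering.  We use the **correct-then-predict** order: multiply by
the emission likelihood of the observed (action, signal) pair, normalize,
then push through one step of the transition matrix.  Under this convention

* an avoid step is exactly one multiplication by the transition matrix, so
  "no information" and "drift toward the stationary distribution" coincide,
  and
* the stationary distribution is a fixed point of avoiding.

The alternative predict-then-correct order produces different one-step
transients; we document ours prominently because it defines what "delay
`T`" means in every experiment.  A zero-likelihood observation (e.g. `+`
after approaching with the belief entirely on `p`'s complement) raises an
error instead of silently renormalizing: in a simulation such an event is a
bug, not data.

Conditioning is modeled as *belief clamping*: the agent experiences a
defined environmental state, i.e. one `(ap, signal)` update per conditioning
event, without co-simulating the environment during training.  The neutral
event of reversal training is an `(ap, 0)` update.

## Greedy and provident decision making

With belief `b`, the expected immediate reinforcement of approaching is
`R(b) = sum_s b(s) E[signal value | s, ap]`.  The **greedy** policy
approaches iff `R(b) + (c_av − c_ap) >= 0`; it is exactly the discounted-
optimal policy at discount zero, and the package verifies this reduction.

The **provident** policy values the future.  It is the first-step rule of a
horizon-`K` dynamic program in which the expectation over the cost
difference is taken analytically: for action values `A`, `B` and
`D ~ Laplace(0, lambda)`,

```
E[max(A, B + D)] = max(A, B) + (lambda / 2) exp(−|A − B| / lambda),
```

validated against adaptive quadrature to 1e−8 in the test suite.  Each
value node expands over the two actions and the at most three reinforcement
outcomes of approaching, so the tree grows as `4^K`; the package refuses
`K > 7` and ships `K = 5`.  The discount `gamma = 0.95` is the package's
choice (exposed in `dp_config()`): across `gamma` in 0.9–0.97 the policy's
free-run rate changes by well under the Monte-Carlo resolution of 40 runs,
while `gamma -> 0` collapses to greedy.  The decision threshold
`Q_ap(b) − Q_av(b)` is cached per belief, making the per-agent decision a
single comparison with the sampled cost difference.  Ties break toward
approaching everywhere — the information-gathering action.

Because approaching is informative, averaging the posterior over signals
gives exactly the avoided (drifted) belief, and the value function is convex
in the belief; hence the provident threshold is never below the greedy one.
This is the *information bonus*: the provident region of approach strictly
contains the greedy region and includes beliefs with `b_p > b_r`.
Behaviorally it reads as faster forgetting of aversive memories.

## The reward-rate linear program

As an independent route to the reward-rate optimum, the package quantizes
the belief simplex on a square lattice (default pitch 1/20) and the cost
difference into an odd number of equal-probability-mass Laplace intervals
(default 11, so one bin straddles zero).  Updated beliefs that fall off the
lattice are assigned to the vertices of their containing lattice simplex
with barycentric weights — stochastic rounding whose expectation is the
exact belief, so quantization adds variance but no bias.  Per bin, the
conditional mean costs of each action have closed forms: given
`D = c_av − c_ap`, the conditional laws of the two exponential costs yield
`E[c_ap | D] = lambda/2 + max(−D, 0)` and `E[c_av | D] = lambda/2 + max(D, 0)`,
whose truncated-Laplace integrals the tests cross-validate by Monte Carlo.
The cost bin is redrawn independently each step.

On the resulting finite MDP the package solves the standard average-reward
occupation-measure linear program (maximize expected reward subject to flow
balance and normalization) with the HiGHS solver from SciPy, reached through
a small subprocess helper; no R linear-programming backend is required at
runtime beyond that.  The induced deterministic policy is read off the
optimal measure where it has support and completed by a one-step lookahead
with the dual bias values elsewhere (the solver's dual sign convention is
fixed empirically against the support actions, and the agreement is stored
on the returned object).  A Howard policy-iteration oracle in the test suite
reproduces the LP gain to 1e−6 on the same MDP, the zero-reinforcement
world recovers the closed form `−lambda/2`, and refining the lattice from
1/20 to 1/40 moves the rate by about 1%.

At the shipped defaults the three routes agree: the LP rate at 1/20 is
~0.255 per bin, at 1/40 ~0.252, and the simulated rate of the DP(K = 5)
policy sits within a few percent of both.

## The mechanistic approximation

The two-synapse agent replaces filtering with two scalar strengths `w_ap`,
`w_av`.  Without feedback each relaxes toward its baseline,
`w <- w + alpha (w_base − w)`; reward resets `w_ap` to its maximum and
`w_av` to zero, punishment mirrors this.  Decisions compare
`w_ap − w_av + noise` with zero, the noise reusing the Laplace cost-
difference law so both agent families face identical decision
stochasticity.  After a single conditioning event the strengths decay
geometrically, so the model's forgetting curves are available in closed
form, which `fit_mech_params()` exploits: a Nelder-Mead search on
logit/log-transformed parameters (bounds enforced by the transform) from ten
Latin-hypercube-seeded restarts, with a polish phase on the winner.  Greedy
mode ties the two decay rates; provident mode frees them, and fitting the
provident curves yields `alpha_av > alpha_ap` — the avoid channel forgets
faster, mirroring the normative asymmetry.

One identifiability caveat, visible in the tests: when the strength
difference saturates the Laplace CDF (|w_ap − w_av| well above ~3 noise
scales), the two decay rates become interchangeable, and parameter recovery
is only meaningful for generating curves that live in the CDF's sensitive
band.  The recovery test and the acceptance script therefore use such
curves; fits to saturated curves still reproduce the *curves* (small RMSE)
without pinning every parameter.

## Experiments and conventions

`make_protocol()` defines single appetitive/aversive conditioning, spaced
training (six aversive events, nine waiting bins between events), massed
training (six consecutive bins) and reversal (punishing, neutral, punishing
in consecutive bins).  A forgetting curve drifts the post-training belief
through each delay and lets `n_agents` (default 2000) agents decide once
each with fresh costs — one draw per agent, matching the "fraction of agents
choosing the conditioned response" read-out; the exact fraction (Laplace CDF
at the cached threshold) and the stationary-belief asymptote are reported
alongside.  The default delay grid is 0 plus 20 log-spaced points up to 200
bins.  The **half-gap delay** — where the curve first covers half the
distance from its initial value to its asymptote, by linear interpolation —
is computed from the exact fractions, so half-gap comparisons carry no
Monte-Carlo noise.

In the extended model a hidden meta mode (slow/fast) scales all four
transition rates; meta and reward-state transitions factorize within a bin
(the simplest kernel consistent with a rate-setting meta variable).  Ten
extended bins correspond to one basic bin; a conditioning event occupies one
extended bin and a waiting period of `w` basic bins becomes `10 w` drift
steps.  Slow-mode rates are the basic defaults divided by ten — so the slow
world changes per basic bin like the basic model — and fast rates are ten
times slow; meta switches occur at 0.001 per extended bin.  Spaced training
is informative about slowness because punishment evidence that survives a
90-bin gap is much likelier in the slow mode; reversal requires two quick
valence flips and is thus strong fast-mode evidence.  Forgetting curves for
the extended model use the greedy policy on the marginal reward-state
belief.

Free-run comparisons (`compare_policies()`) exploit that the hidden state
evolves independently of the agent's actions: all policies are evaluated on
the same state trajectories, cost draws and emission randomness, an exact
matched design; totals across the 40 runs of 1000 bins remain independent
and each policy's s.e.m. is reported as usual.  The `no_forgetting`
baseline updates its belief on informative observations but never drifts;
`immediate_forgetting` ignores the belief and takes the cheaper action.
Both are package constructions that bracket the belief-based policies.

## Default parameters and why

The shipped defaults are `a_rn = a_pn = 0.04`, `a_nr = a_np = 0.08`,
rewards ±1 and cost scale 0.1.  They were chosen, once, to place the model
in the regime the theory is about, and they are plain config values — every
function takes arbitrary `env_params`:

* symmetric rates and zero average reward, so any forgetting asymmetry is
  attributable to the policy, not the chain;
* a conditioned-state dwell time of 25 bins, long enough that tracking the
  association pays and forgetting curves resolve on a 0–200 bin grid;
* a stimulus that is predictive most of the time (stationary distribution
  0.4/0.2/0.4), making the attainable reward rate clearly positive
  (~0.25 per bin) and the information gathered by approaching economically
  substantial — in this regime the provident policy out-earns the greedy one
  by ~0.06–0.07 per bin, several s.e.m. at the 40 × 1000 design, whereas in
  information-poor regimes (rare conditioned states, large cost scale) the
  two policies are empirically indistinguishable;
* a cost scale small against unit rewards, so fresh memories express almost
  deterministically while the stationary state still shows cost-driven
  variability.

## What the simulation does and does not emulate

The generator produces the model's own world: clamped conditioning, i.i.d.
exponential costs, an agent with exact knowledge of the transition rates.
Passing tests therefore demonstrate internal consistency and the claimed
normative phenomena — they do not show that real animals implement Bayesian
filtering, that real reinforcement schedules are three-state Markov chains,
or anything about the biological substrate of the decay rates.  Delays are
reported in model time bins; mapping bins to hours in any particular
experimental preparation is outside the package's scope, as is fitting to
real behavioral data.

## Numerical notes

* Stationary distributions come from a direct linear solve with a
  reachability check; reducible chains are rejected.
* The reparametrization by (neutral-state probability, average reward,
  timescale) resolves its leftover degree of freedom by the symmetric
  convention `a_rn = a_pn = timescale`, overridable via `leave_p`.
* `half_gap_delay()` returns `NA` when a curve never crosses its midpoint on
  the supplied grid — lengthen the grid rather than extrapolate.
* All Monte-Carlo tolerances in the tests are three standard errors of the
  statistic under test; exact identities are asserted to 1e−10 or tighter.
* Problem sizes used by the tests and the acceptance script — 10^6 emission
  draws, all 5460 observation sequences to length 6 for 20 random parameter
  sets, 40 free runs of 1000 bins, 2000 agents per curve point, lattices
  1/20 and 1/40 — were chosen so the full suite completes in minutes on one
  core while keeping every binomial tolerance meaningfully tight.
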