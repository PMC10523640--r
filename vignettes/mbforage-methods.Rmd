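---
title: "Models and methods: plasticity rules, matching, and rule inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: plasticity rules, matching, and rule inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mbforage` simulates and analyzes a baited two-odor dynamic-foraging task of
the kind used to study operant matching in *Drosophila*, with the agent built
around the circuit logic of the mushroom body: sparse Kenyon-cell (KC) odor
codes, plastic KC→MBON synapses whose modification is gated by a
dopaminergic (DAN) reward signal, and an MBON readout whose activity sets
the probability of *rejecting* an encountered odor. This vignette documents
the models, the tunable parameters and the reasoning behind the numerical
choices, so that results produced by the package can be interpreted — and
doubted — correctly.

## The task

A session is a sequence of blocks. Within a block each odor $o \in \{A,B\}$
has a fixed *baiting* probability $p_o$: at the start of every trial each
currently unbaited odor becomes baited independently with probability
$p_o$, and a bait persists until that odor is next chosen, at which point it
is collected (reward $R=1$) and cleared. Baiting mimics resource depletion
and replenishment and is what makes exclusive preference suboptimal: the
rarely chosen option accumulates a bait and eventually pays off with
certainty. Baits carry across block boundaries unchanged; only the
probabilities change.

Within a trial the fly encounters one odorized arm at a time. The first
encountered odor is drawn uniformly; rejecting an odor leads deterministically
into the other arm (the geometry of a Y-maze), and the first accepted
encounter is the trial's *choice*. A safety cap (100 encounters) forces
acceptance and flags the row; in practice it is reached only in pathological
parameter regimes. For an agent with stationary acceptance probabilities $a$
(odor A) and $b$ (odor B) this encounter process has the closed-form choice
probability

$$P(\text{choice}=A) \;=\; \frac{\tfrac12\,[\,a + (1-b)\,a\,]}{1-(1-a)(1-b)},$$

which the test suite uses as an oracle. Note the two fixed points that
anchor everything else: a naive agent ($a=b=\tfrac12$) chooses each odor
half the time, and a fully learned one ($a \to 1$, $b=\tfrac12$) chooses the
learned odor 75% of the time — acceptance of the *other* odor never changed,
but the encounter loop keeps presenting it.

## The agent

Each odor activates a fixed sparse binary KC pattern ($N = 100$ cells, 10
active per odor by default). Patterns may share a configurable fraction of
active cells (`overlap`, realized exactly by construction) and may be
jittered per encounter by Gaussian noise clipped at zero (`noise_sd`).
The MBON drive for realized activity $S$ is $m = \sum_i W_i S_i$ with
non-negative weights $W$, and the probability of rejecting the encounter is

$$p_{\mathrm{rej}}(m) = \frac{1}{1+e^{-(m-m_0)/s}}.$$

At each choice (and only at choices — no plasticity on rejections or
between trials) the weights of the active KCs are updated by one of four
candidate rules,

$$\Delta W_i \;=\; \eta \; K_i \; D, \qquad
K_i \in \{S_i,\; S_i - E(S_i)\}, \qquad
D \in \{R,\; R - E(R)\},$$

with learning rate $\eta < 0$, reflecting the depression-dominated
plasticity of the KC→MBON synapse: reward *depresses* the chosen odor's
synapses, lowering the MBON's rejection drive and making that odor more
likely to be accepted in future. The four combinations are the
`noncov` rule ($S_i R$), the reward-expectation rule ($S_i\,[R-E(R)]$), the
sensory-expectation rule ($[S_i-E(S_i)]\,R$) and the full covariance rule
(`both`). Expectations are recency-weighted running averages updated once
per choice,

$$E(R) \leftarrow (1-\tfrac1\tau)E(R) + \tfrac1\tau R,$$

and likewise elementwise for $E(S)$, initialized at zero with no warm-up.
Weights are clipped to $[0, 2w_0]$ (saturation above, a floor at zero
below). The theoretical reason the expectation-subtracted rules matter is
that each drives the covariance between choice-conditioned reward and its
subtracted factor to zero at equilibrium, and zero covariance is exactly
Herrnstein's matching condition (choice fractions equal to reward
fractions). The `noncov` rule has no such equilibrium: it is unidirectional,
drives both options' synapses to the floor at slightly different rates, and
produces flat choice-versus-reward behavior.

### Parameter defaults and calibration

| parameter | default | units | rationale |
|---|---|---|---|
| `n_kc`, active fraction | 100, 0.1 | cells | sparse KC coding |
| `overlap`, `noise_sd` | 0, 0 | — | simplest identifiable representation |
| `tau_r`, `tau_s` | 3.5 | trials | the expectation timescale used throughout the analyses |
| `eta` | −0.3 | weight/choice | see below |
| `w0`, `w_max` | 1, 2 | — | saturation at twice the naive weight |
| `m0`, `s` | $w_0 n_{\mathrm{act}}$, $m_0/16$ | drive | see below |

The sigmoid midpoint sits at the naive drive $m_0 = w_0 n_{\mathrm{act}}$ so
that an untrained agent rejects with probability exactly 0.5; together with
the encounter loop this pins the naive choice fraction at 0.5 and the
asymptotic 100:0 preference of the `noncov` rule at 0.75. The slope must be
steep enough that fully depressed weights give near-certain acceptance
($p_{\mathrm{rej}}(0) \le 0.02$); we use $s = m_0/16$, well inside that
requirement, so learned preferences are expressed sharply.

The learning-rate magnitude is calibrated against two timescales at once:
with $|\eta| = 0.3$ a reliably rewarded odor saturates its synapses after
three to four rewarded choices (well within the ~30-choice window one
expects from saturation-limited single-odor learning curves), while the
covariance rules — whose effective step is shrunk by the
expectation-subtracted factors, roughly $|\eta|/8$ per choice — take on the
order of 15–20 trials to re-equilibrate after a block switch, matching the
adaptation timescale reported for real flies. A substantially smaller
$|\eta|$ makes covariance agents too slow to track 80-trial blocks and
produces spurious undermatching: the block-averaged slope then reflects the
transient, not the rule. We verified that at the default calibration the
*steady-state* (late-window) choice-versus-reward slope of the full
covariance rule is within 0.01 of unity, so the residual shortfall of the
full-block slope (~0.93) is the transient contribution that any finite
block length incurs.

## Behavioral analytics

All metrics work on the trial-log schema (one row per encounter; exactly
one choice row per trial) whether the log is simulated or experimental.
"Choice fraction" and "reward fraction" are implemented as proportions
$A/(A+B)$, so the matching law is the identity line and undermatching is a
slope below one. Instantaneous series use a trailing 10-trial window with
masked (not padded) edges; windows containing no reward leave the reward
fraction undefined. The block-level matching summary pools per-fly,
per-block fractions and fits ordinary least squares with a free intercept
(reported, not constrained). Undermatching is additionally summarized per
fly as the mean squared error between the two instantaneous series.
Transition dynamics align instantaneous choice fractions to block changes
with $|\Delta p_A| \ge 0.4$ (the probability menus used here make that the
natural cut between "large" and "small" changes), orienting each curve so
the newly richer odor is positive. The win-stay/lose-switch table is the
joint distribution of the heuristic's prediction and the realized
stay/switch; history-conditional probabilities scan for exact trailing
(odor, outcome) patterns.

## Descriptive choice models

The history logistic regression codes, for each lag, a signed reward
regressor (+1 reward obtained on A, −1 on B, 0 none) and a signed choice
regressor (±1), and predicts the next choice; fit quality is percent
deviance explained against a bias-only null fitted on the same rows. All
logistic fits in the package use a fixed, tiny ridge penalty ($10^{-4}$,
bias unpenalized) solved by IRLS — enough to keep separable designs finite
without biasing large-sample estimates (the suite checks agreement with
`glm` to three decimals on a 5,000-row design). The shuffle control
permutes each fly's (choice, reward) trial sequence, which destroys
trial-to-trial dependence while preserving the marginal choice bias, and
rebuilds the design per shuffle. The leaky-integrator model assigns each
option an exponentially filtered reward history with timescale $\tau$
(both options decay every trial; only the chosen one is incremented) and
fits inverse temperature and bias by profile likelihood over an integer
$\tau$ grid (1–30 by default). At $\tau = 1$ it provably collapses to a
lag-1-reward logistic regression, which the tests verify numerically.

## Inferring the plasticity rule from behavior

Because every candidate rule is *linear* in its four components (constant,
KC, DAN, KC×DAN product) and weights accumulate additively, the MBON drive
at any encounter is exactly a linear combination of four history
regressors: each term's value summed over all prior choices, projected onto
the current odor's pattern (a factor of 1 for the same odor, `overlap`
otherwise). Expectations inside the regressors are recomputed from the
observed log alone (initialized at zero, timescale 3.5 trials by default),
and the KC patterns used are the noiseless binary ones — the analyst does
not observe sensory noise. Logistic regression of encounter-level
accept/reject on these regressors plus a single behavioral bias then
recovers the rule; variants differ only in whether the KC and/or DAN
factors are expectation-subtracted, and are compared by percent deviance
explained. For data generated by the reward-expectation rule the regression
assigns the largest-magnitude coefficient to the product term — the
covariance computation — and the reward-expectation variant beats the
expectation-free one, which is the package's validation of the method.

Two structural notes. First, this linear reduction is exactly why rules
depending on the current weight magnitude or on postsynaptic activity are
out of scope: they break the linearity that lets histories be converted to
regressors. Second, with zero overlap an odor's KC and product regressors
change only after choices of that same odor *for the variants whose KC
factor is the raw input*; sensory-expectation variants intrinsically update
$E(S_i)$ for absent odors at every choice, so that locality property does
not apply to them (and the tests assert it only where it holds).

### Identifiability requires behavioral variability

Rule inference is a regression on accept/reject outcomes, so it is only as
informative as the variability in those outcomes. Noncovariance agents on
the three-block matching task depress both odors' synapses to the floor
within roughly ten trials and thereafter accept essentially every
encounter; such sessions contain a handful of reject rows (sometimes none,
in which case the fit is refused with a diagnostic), and comparing rule
variants on them is noise. The recovery validation for the noncovariance
rule therefore uses the 80:20 two-block protocol, where the lean odor's
acceptance stays at its naive 0.5 throughout and every trial carries
information; there the expectation-free rule wins the pairwise comparison
against the reward-expectation variant in essentially every simulated
session. The same consideration applies to experimental designs: a fly that
never rejects tells you nothing about its learning rule.

## The winner-take-all variant

For comparison with the original two-pathway circuit in which both options
are simultaneously present, `simulate_winner_take_all` activates both
odors' KC populations every trial, lets each drive its own output, and
chooses the pathway with the smaller noisy rejection drive; plasticity is
applied with both sensory inputs active at reward. In this task the
*common-mode* depression cancels in the decision, and what differentiates
the options under the expectation-free rule is the covariance between KC
noise and reward — which is why a small sensory jitter (`noise_sd = 0.05`
by default here) is essential and why the noncovariance rule yields a slope
strictly between flat and unity rather than the flat line seen in the
one-odor-at-a-time task. With the default calibration the covariance rule
reaches a slope of roughly 0.8 in this variant — clearly steeper than the
noncovariance rule but short of unity; we report the ordering, which is the
robust prediction, rather than exact slopes.

## What the synthetic data do and do not emulate

The generator reproduces the statistical structure the analyses assume:
blockwise baiting with persistence, encounter-level accept/reject decisions
from a sigmoidal readout of plastic weights, Bernoulli baited rewards, and
configurable sensory noise and overlap. It does not emulate spatial
trajectories, choice latencies, satiation, off-task plasticity, inter-fly
parameter heterogeneity, or motor-related dopamine signals. Passing tests
therefore certify the *analysis chain* and the *internal consistency of the
model predictions* — e.g. that covariance rules produce matching and the
expectation-free rule produces the 75%/50% saturation plateaus — not that
real flies implement these exact dynamics. Quantities that depend on fly
data (real undermatching slopes, fitted fly timescales, significance tests
against behavior) are outside what desk-scale simulation can reproduce.

## Problem sizes and determinism

Population analyses in the package's reproduction scenarios use 50 agents
for matching slopes and plateaus and 20 agents for rule and timescale
recovery, with three 80-trial blocks (or 60+60 two-block protocols) per
session — the same order as the experimental datasets these analyses are
designed for. Every stochastic routine takes an explicit integer seed; agent
$i$ of a population uses `seed + i - 1`, so single sessions can be
reproduced bit-for-bit in isolation. Fitted quantities are deterministic
given the log.

## Known limitations

* The block-averaged matching slope of covariance agents is intrinsically
  a little below one on 80-trial blocks (transient contamination); use
  longer blocks or late-window fractions to measure the equilibrium slope.
* The sensory-expectation update averages over *all* choices (so $E(S_i)$
  tracks the choice fraction of odor $i$'s odor); a variant that updates
  only on encounters of the odor itself is biologically conceivable and not
  implemented.
* `eta = 0` is accepted as an explicit no-learning control even though the
  depression-based rules require `eta < 0`; positive values are rejected.
* Occasional covariance-rule agents lock onto one odor for a whole session
  (the unchosen odor's synapses potentiate toward saturation); downstream
  fits on such degenerate single-odor logs are refused or flagged rather
  than silently computed.
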