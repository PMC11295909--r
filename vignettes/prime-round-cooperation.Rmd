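---
title: "Methods: testing for cooperation at prime-numbered rounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing for cooperation at prime-numbered rounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(primecoop)
```

`primecoop` implements an end-to-end empirical test of the hypothesis
that cooperation in multi-round one-shot public goods games concentrates
at prime-numbered rounds, as predicted by evolutionary models in which
cooperators act on cyclical schedules with prime period lengths. This
vignette is the package's own account of the models it implements, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the test suite does and does not establish.

## The synthetic panel generator

`generate_panel()` emulates a "strangers"-condition public goods
experiment: `n_participants = 256` players in matching groups of 16,
reshuffled uniformly at random into play groups of 4 within their
matching group every one of `n_rounds = 27` rounds, each choosing an
integer number of tokens in `[0, endowment = 20]`. Payoffs follow the two
framings of the source design — provision,
$\pi_i = 20 - c_i + 0.4\sum_j c_j$, and maintenance,
$\pi_i = w_i + 0.4\sum_j c_j$ with withdrawal $w_i = 20 - c_i$ — which
are monetarily equivalent; all analysis runs on the common
*effective contribution* scale, so the 50/50 matching-group-level
treatment assignment is cosmetic.

Behaviour comes from a mixture of archetypes
(`archetype_mix`, proportions summing to 1):

* **free riders** (0.40) contribute nothing, ever;
* **conditional cooperators** (0.45) adjust toward the mean contribution
  they observed among their *previous* round's group-mates, shrunk by a
  multiplicative `decay` (0.87/round) plus latent Gaussian noise
  (`cc_sd = 1.6` tokens);
* **persistent contributors** (0.15) contribute sporadically throughout
  (probability 0.45/round of a contribution drawn around 7 tokens),
  sustaining the late-round tail of cooperation;
* **prime cyclers** (0 by default) contribute the full endowment exactly
  at prime rounds — a deliberately detectable strategy used in tests of
  the cycle census.

Round-1 decisions of non-free-riders are drawn from the initial
distribution (`initial_mean = 11` latent tokens, sd 6); latent values are
rounded and clipped to `[0, 20]`. These defaults put the round-1 grand
mean near 6.5 tokens, the round-27 mean near 1, and the per-round median
at 0 from about round 3 — the calibration bands the generator is tested
against (round-1 mean in [5.5, 7.5] and round-27 mean in [0.5, 2.0] in at
least 95% of replicate panels).

Two design choices deserve emphasis:

1. **Full peer adjustment.** Conditional cooperators default to
   `adjust_weight = 1`: their latent decision depends on the lagged peer
   mean only, not additionally on their own lagged decision. An own-lag
   component is an omitted variable for the focal regression (which
   conditions on the peer lag, the round trend and stable individual
   intercepts, but not on own history) and would leak systematic
   early-round residual structure into whatever indicator is being
   estimated. With full adjustment the generator satisfies its intended
   null: with `prime_effect_delta = 0` the fitted prime indicator's 95%
   CI excludes zero at close to the nominal 5% rate. Partial weights
   remain available through `decline_params$adjust_weight` for users who
   want a deliberately harder misspecification benchmark.
2. **Two injection modes.** The configuration-driven prime effect
   (`prime_effect_delta` tokens on a `prime_effect_fraction` of
   participants) is applied *during* generation: group-mates observe the
   boosted contributions and conditional cooperators react through their
   ordinary adjustment rule, exactly the feedback path the focal model's
   peer-lag covariate is built to absorb. Parameter-recovery results
   (coverage of $\delta \times f$) refer to this mode.
   `inject_prime_effect()` instead boosts a finished panel post hoc
   (clipping at the endowment, never erroring); it shifts the
   prime-versus-other mean difference by $\delta \times f$ as advertised,
   but peers never react to a post hoc boost while the recomputed peer
   lag includes it, which biases the regression estimate of the boost
   upward by construction. The post hoc mode is therefore a data-editing
   utility, not a recovery benchmark.

What the generator does *not* emulate: framing effects between provision
and maintenance, learning dynamics beyond one-round peer feedback,
participant dropout, and any genuine prime-round behaviour under the
null. Passing tests therefore show that the pipeline recovers what the
generator puts in (and nothing when it puts nothing in) — not that real
participants behave like the archetypes.

## The evolutionary simulator

A genotype pairs a behaviour (cooperator/defector) with a schedule
period $T \in \{2, \dots, 27\}$; an agent is active at intra-generational
time point $t$ iff $T \mid t$, so nothing happens at $t = 1$ and the
model makes no prediction there. Each generation, active agents at each
of 27 time points are paired uniformly at random (an odd one idles) and
play a one-shot prisoner's dilemma with payoffs
temptation 5 > reward 3 > punishment 1 > sucker 0, accumulating totals
(never-active agents keep 0; totals are compared raw, without per-game
averaging). Selection is the classic pairwise comparison process: one
uniformly random focal agent per generation adopts a random distinct
model's genotype with probability
$1/(1 + e^{-s(\pi_m - \pi_f)})$, `selection_intensity` s = 1 by default.
A run starts from a uniform draw over the genotype space and ends at
genotype homogeneity or `max_generations` $= 10^5$.

The exact schedule, pairing and update conventions of the original
simulation are not fully published, so all of them are configuration
values here: the divisibility activity rule (chosen because it makes no
round-1 prediction, matching the comparison figure's convention), one
update event per generation (`events_per_generation` raises it), and
payoff accumulation without averaging. At $s = 0$ the process is neutral
imitation, and the fixation probability of a genotype equals its initial
frequency — the suite verifies this within three binomial standard
errors at $N = 20$ over 2 000 runs, using the compiled (Rcpp) batch
engine that also powers `run_evolution()`. The pure-R
`play_generation()` and `pairwise_comparison_step()` implement the same
contracts one step at a time for inspection and testing.

Fixated strategies become simulated "subjects": a cooperator contributes
the endowment where active and 0 elsewhere, a defector always 0.
`predicted_cooperation_curve()` draws `sample_size = 256` fixated runs
per draw — with replacement by default, so draws remain exchangeable when
fewer than 256 runs are available at reduced scale — and summarises the
per-round full-contribution proportion over `n_draws` draws by its mean
and 2.5th/97.5th percentiles. The observed counterpart uses a Wilson
score 95% interval (well behaved near 0 at $n = 256$; the interval
method was an open choice). `overlap_report()` intersects the two
intervals as *closed* intervals, so curves touching at an endpoint count
as overlapping. Whether the predicted and observed curves overlap in
every round under these defaults is an empirical output of the pipeline,
not an asserted invariant.

## The autocorrelation cycle census

Per participant, the effective-contribution series enters the census only
if it is neither always zero nor weakly monotonic (non-strict, which also
removes constants — their ACF is undefined; nonzero constants are
reported with their own reason code). The sample ACF is the standard
biased estimator
$r_k = \sum_{t \le n-k}(x_t-\bar x)(x_{t+k}-\bar x) / \sum_t (x_t-\bar x)^2$,
computed via `stats::acf()` and cross-checked against an $O(n^2)$
brute-force oracle to 1e-12 in the tests. The maximum lag searched
defaults to 13 ($\lfloor 27/2 \rfloor$): beyond half the series length
each lag rests on very few pairs. The maximum is taken over *signed*
values with ties broken toward the smaller lag, and no positivity is
required for a maximum to "exist"; `require_positive_acf = TRUE`
implements the stricter reading. One caution established by the oracle:
a smooth sinusoid of period 9 has its signed ACF maximum at lag 1 (short
lags inherit smoothness, $r_1 \approx \cos(2\pi/9)$), while a spiky
periodic pulse train peaks at its period outright — maximum-ACF lag
detects spiky cycles, not smooth ones.

## The focal regression and its design table

`build_design()` produces one row per participant per round $t \ge 2$
(round 1 has no lag and never enters), with the effective contribution as
response, the lagged group-mates' mean, a linear round trend, and the
indicator of the active round set. Two peer-lag conventions exist because
the source phrase "the average contribution of the other three group
members from the previous round" is ambiguous under reshuffling;
the default, `previous_round_groupmates`, uses what the participant
actually observed — the mean round-$(t{-}1)$ contribution of their
round-$(t{-}1)$ group — while `current_round_groupmates` averages the
current group-mates' previous decisions. Round exclusions drop
*estimation rows only*; excluded rounds still feed lag construction,
which is what makes a 256-participant panel yield exactly 6 656, 6 400
and 6 144 rows with zero, one and two excluded rounds.

`fit_focal_model()` estimates the mixed model with `lme4::lmer()`
(REML by default, `method = "ml"` available; derivative-free convergence
checks for determinism and speed). Individuals never cross matching
groups, so individual-within-matching-group nesting is expressed as two
crossed intercept terms, which are formally identical here. Inference is
Wald-z throughout — $z$, two-sided normal $p$, CI = estimate ± 1.96 SE —
matching the reporting convention of the analysis this package
implements; no bootstrap or likelihood-ratio inference is provided.
Round 1 is neither prime nor composite: it never enters estimation, and
the rank-sum test pools it with the non-prime group by default
(`include_round_one = FALSE` drops it). Complete ties leave the
tie-corrected rank-sum variance at zero; the package reports $p = 1$.

## The placebo-prime battery

Nine primes occupy $[1, 27]$; the placebo universe is every set of nine
*composite* numbers matching the primes' per-bin counts under three
schemes: one bin ($\binom{17}{9} = 24\,310$ sets — note that 1 is neither
prime nor composite, so the one-bin universe has 17 elements, not 18),
two bins $[1,14]/[15,27]$ with counts (6, 3) ($7 \cdot \binom{10}{3} =
840$), and three bins $[1,9]/[10,18]/[19,27]$ with counts (4, 3, 2)
($1 \cdot 20 \cdot 21 = 420$). Enumeration is exhaustive and
lexicographically deterministic, validated in tests against independent
binomial-coefficient products and subset-nesting relations.

`run_battery()` builds the design once and swaps only the indicator
column between fits, so the battery evaluated at the true prime set is
bit-identical to the focal fit (a tested identity). Summaries count
*strict* exceedance of the focal estimate and "positive significant"
as estimate > 0 with Wald 95% lower bound > 0. The Euclidean distance of
a placebo set from the primes sorts both 9-vectors ascending and takes
the L2 norm — an order-free set embedding. Sets whose estimates are
constant leave the distance–coefficient correlations undefined, flagged
rather than thrown.

## Problem sizes, determinism and degenerate inputs

All stochastic stages take explicit seeds; the pipeline derives
stage-name-keyed child seeds from one master seed so that changing one
stage's parameters does not perturb another's draws. The test suite and
the acceptance script run the stochastic checks at deliberately moderate
scale, chosen to give stable Monte Carlo answers: 200 replicate panels
for the calibration bands, 2 000 neutral-drift runs at $N = 20$,
200 recovery panels of 64 participants (CI coverage of
$\delta f = 1$ token), and 500 null-calibration placebo fits spread over
25 independent 64-participant panels — per-panel significance rates are
strongly correlated across placebo sets, so many small panels estimate
the rate far better than one large one. Full-scale runs ($10^4$
evolutionary runs, all 24 310 one-bin refits on a 256-participant panel)
are supported through the same interfaces.

Degenerate inputs are contracts, not crashes: indivisible group sizes and
invalid archetype mixes raise configuration errors; a constant indicator
or an empty design raises before fitting; non-convergence of a single
battery fit is recorded per set; zero-variance series are rejected by the
ACF (callers filter via eligibility); out-of-range injections clip.

## Limitations

The pipeline's statistical behaviour is established under the
generator's assumptions; real panels bring censoring-at-zero mass,
discreteness and behavioural feedback the linear mixed model only
approximates, and with a supplied real dataset the package reports — but
deliberately does not assert — comparisons against published headline
values. The evolutionary simulator's unpublished details (population
size, payoffs, update counts, schedule phase) are configurable guesses
around stated defaults, so agreement or disagreement of its predicted
cooperation curve with data is an output to inspect, not a calibrated
claim.
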