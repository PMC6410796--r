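---
title: "Modelling and evaluating spaced-repetition schedules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and evaluating spaced-repetition schedules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spacedrep)
```

# The memory model

spacedrep models one learner studying one item as a marked temporal point
process. Recall of the item at time $t$ follows the exponential forgetting
curve

$$m(t) = \Pr(\text{recall}) = e^{-n(t)\,(t - t_r)},$$

where $t_r$ is the time of the last review (time is measured in days from
the first exposure, $t_0 = 0$) and $n(t) \ge 0$ is the *forgetting rate*,
the reciprocal of the familiar memory half-life/strength. Reviews arrive at
random times with *reviewing intensity* $u(t)$ — the expected number of
reviews per day — and each review carries a binary mark $r$: the learner
either recalls the item ($r = 1$, probability $m(t^-)$) or fails. The mark
feeds back into the forgetting rate multiplicatively,

$$n \mapsto (1 - \alpha)\,n \quad\text{on success},\qquad
  n \mapsto (1 + \beta)\,n \quad\text{on failure},$$

with $0 \le \alpha \le 1$ and $\beta \ge 0$ shared across items, while the
initial rate $n(0) = n_0$ carries item difficulty. At each review the
recall probability jumps back to 1 (the decay clock restarts). The pair
$(m, n)$ is a Markov jump process; everything downstream — simulation,
likelihoods, estimation — exploits that structure.

Two degenerate corners are admitted deliberately: $n = 0$ is a valid
"permanently remembered" state with $m \equiv 1$ (reachable when
$\alpha = 1$), and states are immutable values — `apply_review()` returns a
new state — so any trajectory can be replayed exactly from a log, which the
estimators and tests rely on.

A pluggable forgetting-curve variant is provided: `powerlaw_model(omega)`
uses $m = (1 + \omega\,(t - t_r))^{-n(t)}$ with the same jump dynamics, a
heavier-tailed curve preferred by parts of the literature. The exponential
curve is the package default and the one under which the optimal controller
below is derived; the power-law form here is one reasonable
parameterisation of that family, chosen so that $\omega \to 0$ recovers
exponential decay with rate $n\omega$.

# The optimal scheduler

Given the quadratic running loss

$$\ell(m, u) = \tfrac12 (1 - m)^2 + \tfrac12 q\, u^2,$$

which rewards recall while charging for reviewing effort, stochastic
optimal control of the jump dynamics yields a closed-form optimal
reviewing intensity

$$u^*(t) = q^{-1/2}\,\bigl(1 - m(t)\bigr):$$

review intensity is an *affine, decreasing* function of recall probability
— review hard when you are about to forget, not at all when recall is
certain. The trade-off $q > 0$ sets the review budget; the mean number of
reviews in a window decreases monotonically in $q$, so a desired budget can
be dialled in by simulation (`calibrate_q()` does a bisection on $\log q$
with common random numbers). With several items the loss separates and the
optimum is one independent controller per item with its own $q_i$;
multi-item scheduling is therefore just several single-item samplers.

Two baselines span the heuristics used in practice: a *uniform* schedule
with constant rate $\mu$, and a *threshold* schedule that stays silent
until $m$ first falls below $m_{th}$ at time $s$ and then ramps up as
$u(t) = c\, e^{(t - s)/\zeta}$. After each review the recall probability
resets to 1, so the threshold intensity drops back to zero until the next
downward crossing; the package adopts this reset semantics as the only one
consistent with "review just before forgetting".

## Exact sampling

Review times are sampled by Poisson thinning, which is distributionally
exact: propose from a piecewise-constant dominating rate, accept with
probability $u(t)/\text{bound}(t)$. The majorants are:
$q^{-1/2}$ globally for the optimal scheduler (since $1 - m \le 1$), $\mu$
for the uniform one, and — because the threshold ramp is unbounded —
adaptive look-ahead windows of length $\zeta/4$, each bounded by its
window-end intensity $c\,e^{(t_{\text{end}} - s)/\zeta}$. A proposal that
finds the intensity above its claimed bound is a hard error, never a
silently biased sample. Correctness is tested by the time-rescaling
theorem: compensator increments between consecutive events must be i.i.d.
Exp(1), checked with Kolmogorov–Smirnov tests on pooled simulated gaps
(`rescaled_gaps()`).

An optional hourly mode quantises a sampled time to the top of the hour
(`schedule --hourly` in the CLI), for deployments that decide reviews on a
clock tick; the continuous sampler is the default and the tested path.

# The synthetic population

`simulate_population()` generates review logs with the model's exact
statistical structure: item difficulties $n_0$ are log-normal with median
0.04/day and log-sd 1 (a realistic spread from minutes-scale to
months-scale half-lives for language items), $\alpha = 0.3$, $\beta = 0.2$,
one scheduler arm per learner (or any custom assignment), a training window
of tens of days, and one derived RNG stream per (learner, item) — a
deterministic hash of the master seed — so logs are bit-reproducible and
order-independent.

Review sessions can hold several attempts. Two session laws are available
and the distinction matters:

* `"binomial"`: `correct ~ Binomial(attempts, m)`, and the binary mark is
  a perfect session. The mark law is then $m^{\text{attempts}}$. This is
  the natural reading of graded review sessions and is what the estimator
  assumes about binarisation, so it is the default and is used for
  parameter-recovery studies.
* `"mark"`: the model's own mark $r \sim \text{Bernoulli}(m)$ is drawn
  first and the session score is graded conditionally. This preserves
  exactly the mark law under which the controller is optimal, while still
  producing a graded empirical recall $\hat m$; the scheduler-comparison
  experiments use it, because they are about reviewing *timing* under the
  model's own dynamics, not about session grading.

At `attempts = 1` the two laws coincide with the model's Bernoulli mark.

What the generator does *not* emulate — deliberately — includes learner
dropout, circadian and weekday structure, inter-item interference, and any
spacing effect beyond the multiplicative jump rule. Passing tests on these
logs therefore validate the *implementation* of the model, controller,
estimators and evaluation machinery; they do not validate the memory model
against human data. One consequence is discussed at the end of this
vignette.

# Estimation

`fit_memory_model()` is a half-life-regression-style fit: it minimises

$$\sum_{\text{sessions}} \bigl(\hat m - e^{-n\,\Delta t}\bigr)^2
  + \lambda (a^2 + b^2),\qquad
  n = n_{0,i}\,(1-\alpha)^{k_s}\,(1+\beta)^{k_f},$$

over $a = -\log(1-\alpha) \ge 0$, $b = \log(1+\beta) \ge 0$ and one
$\log n_{0,i}$ per item, where $k_s, k_f$ count the successes and failures
before the session and $\hat m$ is the session success fraction clamped to
$[10^{-4}, 1]$ before any logarithm. The objective is squared error on
recall probability only — the simplest regression consistent with the decay
and jump rules — with a small ridge penalty ($\lambda = 0.01$,
configurable) on the two global parameters. Optimisation is L-BFGS-B with
analytic gradients and a fixed deterministic initialisation ($a = b = 0$;
$\log n_{0,i}$ from the closed-form single-review estimate
$-\log\hat m/\Delta t$), capped at 500 iterations; fits are exactly
reproducible and non-convergence is a flag, not an error. The fit is on the
graded $\hat m$, not the binarised mark: the graded fraction carries
strictly more information and the binarised outcome still drives the jump
counts.

Scheduler parameters have closed-form maximum-likelihood estimates given a
replayed memory trajectory: $\hat q = (A/k)^2$ with
$A = \int (1 - m)\,dt$ (piecewise closed form
$\Delta + (e^{-n\Delta} - 1)/n$ per inter-review interval),
$\hat\mu = k/T$, and $\hat c = k / \int e^{(t-s)/\zeta} dt$ over
post-crossing segments. $\zeta$ (per sequence) and $m_{th}$ (per learner)
come from profile-likelihood grid searches over
$\zeta \in \{0.5, 1, 2, 4, 8, 16\}$ d and
$m_{th} \in \{0.3, \dots, 0.9\}$. A sequence containing a review before its
first threshold crossing has likelihood $-\infty$ under that threshold;
thresholds are ranked first by the number of feasible sequences, then by
total log-likelihood, which keeps the argmax deterministic even when every
grid point is infeasible somewhere.

# The natural-experiment evaluation

`evaluation_records()` mirrors the observational evaluation design: each
(learner, item) sequence is split into *training* reviews
$e_1, \dots, e_{n-1}$ and one final *test* review; the training times are
scored by the exact point-process log-likelihood
$LL = \sum_i \log u(t_i) - \int_0^T u\,dt$ under each scheduler (fitted per
learner), with $T = t_{n-1}$ and all compensators in closed form; and the
test review yields the model-free *empirical forgetting rate*
$\hat n = -\log \hat m(t_n) / (t_n - t_{n-1})$, normalised by the item's
average initial empirical rate $\hat n_0$ so difficulty cancels across
items. Lower $\hat n$ means better retention. Group construction follows
the top-25%-by-likelihood rule within cells of equal review count and
similar training period (half-open period bins, configurable edges),
skipping any sequence that qualifies for more than one scheduler; ties
break lexicographically by (likelihood, learner, item) so assignment is
deterministic. Group comparisons use the Mann–Whitney U test — exact by
enumeration for combined sizes up to 12, tie-corrected normal approximation
otherwise — and box summaries use type-7 quantiles. Both the raw and the
normalised rates are reported; plots default to the normalised one.

The per-learner analysis (`learner_correlation()`) takes each learner with
at least 70 sequences (configurable) whose training period lies in a band
(default $8 \pm 3.2$ d), ranks them by log-likelihood under the optimal
scheduler, keeps the top and bottom halves, and reports the Pearson
correlation between log-likelihood and empirical forgetting rate; negative
medians across learners mean retention tracks conformance to the optimal
schedule.

# Numerical choices

* Empirical recall is clamped to $[10^{-4}, 1]$ before logarithms, so a
  fully failed session contributes a large finite rate rather than
  $\infty$.
* Compensators and areas use closed forms throughout; adaptive quadrature
  appears only as an independent oracle in the tests (relative agreement
  $10^{-6}$).
* An event with zero intensity sends a log-likelihood to the $-\infty$
  sentinel rather than erroring; downstream grid searches treat it as
  stated above.
* Degenerate inputs have defined behaviour: $m \equiv 1$ sequences are a
  hard error for $\hat q$ (the likelihood has no maximiser), empty
  sequences give $\hat\mu = 0$ and $\hat c = 0$, and zero-baseline items
  are excluded from normalised comparisons with the raw metric retained.
* The trade-off calibration brackets from $q = 1$ outward geometrically,
  so extreme trade-offs are only simulated when the target budget requires
  them, and a target finer than the Monte-Carlo resolution is an explicit
  error.

# Study sizes used by the tests and acceptance script

The shipped experiments are sized for a desk-scale run: sampler exactness
pools roughly $10^4$ rescaled gaps per scheduler; budget monotonicity uses
2,000 simulated sequences per trade-off value in the test suite (600 in
the acceptance script's summary); parameter recovery uses 5,000 sequences
for the no-jump case and 2,000 for the jump case (1,200 in the script);
the scheduler-comparison population uses three arms of at least 500
evaluated sequences over a 30-day window with a 14-day retention test; and
the per-learner correlation study uses 20 learners with 80 sequences each
over a 12-day window (eligibility threshold configured to 30 sequences in
the band for this population size; the default of 70 reflects the
original eligibility rule at full scale).

# What the synthetic replication can and cannot show

Two of the shipped experiments replicate the direction of the original
scheduler comparison. The optimal scheduler beats the threshold heuristic
on median normalised forgetting rate at matched review budgets, and
within-learner conformance to the optimal schedule correlates negatively
with the forgetting rate when conformance varies by construction.

The comparison against the *uniform* baseline deserves honesty: under this
memory model, at matched budgets, uniform reviewing attains equal or lower
empirical forgetting rates than the optimal controller in our simulations.
The mechanism is visible in the jump rule itself. The expected change of
$\log n$ at a review is $m \log(1-\alpha) + (1-m)\log(1+\beta)$, a
*decreasing* function of the recall probability at the review — so, at a
fixed number of reviews, a schedule that reviews while recall is still
high collects more multiplicative "discounts" on the forgetting rate.
Reviewing early and often is exactly the massed practice whose long-term
inefficacy in humans is well documented, but the exponential model with
state-independent $\alpha, \beta$ does not encode that inefficacy, and the
controller does not optimise the end-of-window forgetting rate — it
optimises the integrated recall/effort loss, for which it is provably
optimal. The original large-scale finding that conformance to the optimal
schedule predicts lower forgetting rates is a statement about human
learners, whose spacing sensitivity the model's loss is designed to
exploit but whose session-level dynamics this generator reproduces only
through the jump rule. The package therefore reports the uniform
comparison as computed, rather than constructing a population tuned to
flip its sign; the threshold comparison and the conformance analysis are
the parts of the headline result that this model can and does reproduce.

# Known limitations

* The multi-attempt session laws are stylised; real platform sessions mix
  item exposures in ways none of them captures.
* The threshold scheduler's fitted $(c, \zeta)$ are weakly identified on
  short sequences; the per-learner pooled profile for $\zeta$ is much
  better behaved and is what the recovery test checks.
* The power-law variant shares the jump rule but its scheduler likelihoods
  are not given closed compensators; it plugs into simulation and recall
  prediction only.
* The evaluation assumes one test review per sequence; multi-test designs
  would need a different record layout.
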