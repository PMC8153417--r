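---
title: "Arbitration between model-based and model-free learning: model, fitting, and synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arbitration between model-based and model-free learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arbrl)
```

## The task

`arbrl` implements a two-stage Markov decision task. From the first-stage
state the agent makes a binary choice (left/right) and transitions to one of
four second-stage states — `S2` or `S3` after a left choice, `S4` or `S5`
after a right choice — with probability `p` for the first successor of the
pair. A second choice leads to an outcome state carrying a coloured coin.
Two manipulations create four block types:

* **Goal condition.** Under a *specific* goal only coins matching the goal
  colour pay out; under the *flexible* goal every coin pays. Goal changes
  re-value the outcomes instantly, which only a planning (model-based)
  system can exploit.
* **Transition uncertainty.** `p = 0.9` (low uncertainty) versus `p = 0.5`
  (high uncertainty). Under high uncertainty the two second-stage actions
  reach the same outcome pair in opposite order, so planning is useless
  there — a regime that favours cached (model-free) values.

Blocks of 3–5 trials (low uncertainty) or 5–7 trials (high uncertainty) are
interleaved pseudo-randomly (no condition type more than twice in a row).
A session plan consists of a 100-trial reward-free pre-training session in
which the agent only learns the state space, followed by four main sessions
of roughly 80 trials. Coin values default to red 40, blue 20, yellow 10
points; values, colours, probabilities, block lengths, and session structure
are all configuration (`task_config()`), never constants in the code.

## The agent

The model has three stages: value learning, arbitration, action selection.

**Model-based (FORWARD) learner.** A transition model `T(s, a, s')` is
updated from the state prediction error, `SPE = 1 − T(s, a, s_observed)`,
with learning rate `α_MB`: the observed successor moves toward 1 by
`α_MB · (1 − T)`, the unobserved one toward 0, keeping rows normalized.
Action values come from backward induction through the two-stage graph
under the *current* goal, so the system re-plans whenever the goal changes.

**Model-free (SARSA) learner.** Cached values `Q_MF(s, a)` are updated from
the reward prediction error `RPE = r + Q_MF(s', a') − Q_MF(s, a)` (terminal
bootstrap 0) with learning rate `α_MF`. The reward entering the update is
the realized goal-conditional reward; the learner itself is blind to goal
changes, which is what makes it habitual.

**Reliability.** Each system's prediction quality is tracked online.
The model-based reliability classifies recent SPEs as "zero"
(≤ 0.2) or non-zero, gives the two event probabilities conjugate Beta
posteriors (prior `(1, 1)`), scores each by its inverse index of dispersion
(posterior mean / posterior variance), and normalizes:
`χ_MB = χ₀ / (χ₀ + χ₁)`. The model-free reliability uses the Pearce–Hall
associability of the unsigned RPE, `ΔΩ = η (|RPE| − Ω)`, normalized as
`χ_MF = (RPE_max − Ω) / RPE_max` with `RPE_max` the maximum coin value.

**Arbitration.** A two-state transition model evolves the model choice
probability, `dP_MB/dt = β (1 − P_MB) − γ P_MB`, integrated by explicit
Euler steps and clipped to `[0, 1]`. The rates are sigmoidal in the rival
system's reliability, `β = A_β / (1 + exp(B χ_MF))` and
`γ = A_γ / (1 + exp(B χ_MB))`: a reliable system retains control. The
amplitudes `A_β`, `A_γ` are free per-subject parameters; the steepness `B`
is a fixed constant (below). `P_MB` weights value integration,
`Q_arb = P_MB Q_MB + (1 − P_MB) Q_MF`.

**Action selection.** Softmax with inverse temperature τ ("degree of
exploitation"), computed with the max-subtraction trick. Five variants
define τ, giving the five fitted models:

| model | exploitation rule | free parameters |
|---|---|---|
| `Arb` | fixed τ, shared learning rate α | α, η, A_β, A_γ, τ (k = 5) |
| `Arb_a` | fixed τ, split α_MB/α_MF | + α split (k = 6) |
| `Arb_a_t1` | logistic: c₁ + (c₂−c₁)/(1+e^(−c₃(P_MB−c₄))) | k = 9 |
| `Arb_a_t2` | linear: τ = P_MB · c | k = 6 |
| `Arb_a_t3` | weighted: τ = P_MB τ_MB + (1−P_MB) τ_MF | k = 7 |

The variants nest: `Arb_a_t3` with `τ_MB = τ_MF` is exactly `Arb_a`, and
`Arb_a` with `α_MB = α_MF` is exactly `Arb` — the test suite asserts both
identities at machine precision.

## Fixed constants and why they have their values

All of these live in `arb_control()` and are configurable.

* **Zero-SPE threshold ε = 0.2.** Once the transition model is graded an
  SPE is almost never exactly 0; with `p = 0.9` learned, the common
  transition yields SPE ≈ 0.1 (a "zero" event) and the rare one ≈ 0.9.
* **SPE window = 6 events (3 trials).** The reliability memory must be
  short enough for `χ_MB` to track the 3–7-trial uncertainty blocks; with a
  long window the estimate averages over block types and the arbitration
  weight barely moves.
* **Rate steepness B = 5.** In simulation `χ_MF` typically occupies
  0.5–0.9 and `χ_MB` 0.05–0.6. `B = 5` maps these ranges onto transition
  rates that differ by an order of magnitude, so the equilibrium
  `β/(β+γ)` spans a wide `P_MB` range across blocks. Much larger `B`
  collapses both rates to near zero (the arbitration weight freezes at its
  starting value and η, A_β, A_γ become unidentifiable); much smaller `B`
  flattens the reliability dependence.
* **Per-decision Euler steps.** `P_MB` takes one Euler step after each
  prediction-error event (twice per trial). With steps only once per trial
  the weight cannot converge within a block, the realized `P_MB` range
  shrinks well below its equilibrium range, and the reliability learning
  rate η becomes practically unrecoverable. A once-per-trial mode is kept
  (`arb_control(p_mb_step = "trial")`).
* **`RPE_max` = max coin value; Ω initialized at `RPE_max/2`.** The
  normalization keeps `χ_MF` in `[0, 1]`; the mid-range start makes
  `χ_MF = 0.5` initially, symmetric with the uninformative-prior
  `χ_MB = 0.5` and `P_MB = 0.5`.
* **Probability floor 1e−12** before logs in the likelihood; softmax uses
  max subtraction. Pre-training trials update the transition model and SPE
  history only and contribute no likelihood terms by default
  (`fit_pretraining = TRUE` includes them).

## Fitting and model comparison

`fit_subject()` minimizes the negative log-likelihood of the logged choices
by multi-start Nelder–Mead (default 128 restarts). Since the simplex method
is unconstrained, each parameter is searched through a scaled-logistic box
transform (learning rates and the logistic midpoint in (0, 1); amplitudes
capped at 5; exploitation parameters at 50; the logistic upper bound fitted
as `c₂ = c₁ + gap` so `c₂ ≥ c₁` holds throughout). Restart points are drawn
on each parameter's natural scale — log-uniform over 0.02–5 for the
exploitation scales, whose plausible values sit far below the box cap.
Two numerical details matter in practice:

* Nelder–Mead needs on the order of a thousand iterations in 6–9
  dimensions; the iteration cap defaults to 1500 (an under-converged
  restart is worse than no restart, because it corrupts best-of-restarts
  selection).
* `compare_models()` fits variants in increasing complexity and gives each
  richer model the embedded optimum of its nested base as an extra warm
  start. This enforces the nesting inequalities in practice, so BIC
  comparisons reflect model structure rather than optimizer luck.

Model comparison uses `BIC = 2·NLL + k·ln(n)` with `n` the number of logged
decisions entering the likelihood (two per main trial), and the group Bayes
factor `BF = exp((ΣBIC_ref − ΣBIC_alt)/2)` summed over subjects — the
aggregation that produces the astronomically large Bayes factors typical of
group-level comparisons.

In recovery experiments the generating parameters are injected as restart 0
(the optimizer can then never return anything worse than the truth), so
reported recovery failures reflect identifiability, not optimization. The
end-to-end depression pipeline does *not* inject the truth — its fits see
only behaviour.

## The synthetic cohort

`cohort_spec()` / `sample_cohort()` generate cohorts with the statistical
structure the analyses assume. CES-D depression scores are uniform integers
on 0–40, populating both sides of the clinical cutoff at 16. Two effect
links tie parameters to the score, each linear on a transformed scale with
Gaussian noise:

* `η` (MF-reliability learning rate), increasing, on the **logit** scale
  (η must stay in (0, 1); intercept `qlogis(0.2)`, slope 0.06 per CES-D
  point, noise SD 0.3);
* `τ_MB` (MB exploitation), decreasing, on the **log** scale (intercept
  `log(0.35)`, slope −0.045, noise SD 0.25).

All other parameters are independent of the score: α ~ Beta(4, 4),
τ_MF ~ lognormal(log 0.1, 0.2), A_β ~ U(1, 2.5), A_γ ~ U(0.3, 1.2). The
asymmetric amplitude ranges offset the structural asymmetry between the two
reliability scales (`χ_MF` sits high because Ω rarely approaches `RPE_max`;
`χ_MB` sits lower), so cohorts contain balanced arbitrators rather than
agents pinned at one extreme. The link magnitudes were calibrated once so
that the cohort's behavioural correlations with CES-D fall in a moderate
negative band (roughly −0.3 to −0.6), and then frozen.

The model-recovery generator (`sample_model_params()`) is deliberately
different: recovery of the weighted-exploitation variant is only
well-posed when its mechanism is active, so the two exploitation parameters
are drawn with a well-separated log-ratio (geometric mean ≈ 0.2,
|log ratio| ≈ 1.2) in a random direction — some agents decisive under
model-based control, some under model-free control — with amplitudes and η
in the range where `P_MB` is mid-range and responsive. Agents with
`τ_MB = τ_MF` realize the nested fixed-τ model exactly, and no method could
(or should) attribute them to the richer variant.

**What the generator does not emulate.** Choices are generated by the model
itself, so fits are well-specified by construction; human data add model
mismatch, lapses, reaction-time structure, and session-level
non-stationarity, none of which are simulated. Passing recovery tests here
demonstrates that the pipeline is correct and the parameters identifiable
under the study design — not that the model is true of any organism.

## Behavioural measures

* **Accumulated reward**: summed points over main sessions.
* **Choice optimality**: the mean likelihood an ideal agent — greedy over
  the *true* transition probabilities and current goal, ties split
  uniformly — assigns to the subject's choices. The tie-splitting is the
  correction for the number of available options; chance is 0.5, and
  high-uncertainty second-stage states are exact ties by design.
* **Choice consistency**: the fraction of first-stage choices repeating the
  previous trial's, computed within sessions.
* **Calibration curves** bin decisions by the model's predicted
  probability of a right choice; **condition breakdowns** report 2×2 cell
  means with standard two-way ANOVA F statistics; score correlations use
  Pearson for behavioural measures and Spearman for fitted parameters
  (right-skewed by their lower bound at 0).

## Problem sizes in the test suite

The automated checks run at desk scale: parameter recovery with 15 agents
and 16 restarts (truth as restart 0), model recovery with 5 repetitions ×
10 agents × 8 restarts, the depression pipeline with 40 subjects and 16
restarts, and null-cohort calibration with 25 reduced-size pipelines
(10 subjects, two 40-trial sessions). The acceptance script
(`scripts/acceptance.R`) re-runs the same analyses from scratch under a
caller-supplied seed.

## Known limitations

* Exploitation parameters other than the two key ones (notably τ_MF and
  A_γ) have narrow generating ranges in the default cohort and recover
  poorly — expected, and irrelevant to the depression contrasts.
* The likelihood surface in η is shallow; η recovery depends on the
  arbitration weight actually moving (see the constants above). Free fits
  shrink η toward small values when the dynamics are frozen.
* BIC-based selection of the weighted-τ variant requires per-subject
  likelihood gains above `ln(n)/2 ≈ 3.3` nats; near the `τ_MB = τ_MF`
  boundary the nested variants are preferred, as parsimony dictates.
* The ideal agent assumes instant knowledge of probability and goal
  changes; it is a normative yardstick, not a model of attainable
  behaviour.
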