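---
title: "A dual-system model of sign- and goal-tracking in autoshaping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dual-system model of sign- and goal-tracking in autoshaping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(stgtsim)
library(dplyr)
```

## The behaviour being modelled

In Pavlovian autoshaping, a lever (the conditioned stimulus, CS) is
presented for about 8 s, after which a food pellet (the unconditioned
stimulus, US) is delivered into a magazine regardless of what the animal
does. Rats split into characteristic phenotypes: *sign-trackers* approach
and engage the lever itself, *goal-trackers* head for the magazine where
the food will arrive. The balance between the two phenotypes is sensitive
to the duration of the inter-trial interval (ITI), and phasic dopamine
activity at CS onset and at reward delivery shows phenotype- and
ITI-dependent patterns.

`stgtsim` simulates this task with a hybrid reinforcement-learning agent
combining two systems that both learn from every observed transition:

* a **Feature-Model-Free (FMF)** temporal-difference learner that attaches
  values not to states or actions but to the *feature* an action is
  directed at — the environment `E`, the lever `L`, the magazine `M` or the
  food `F` — so that, for example, approaching the magazine during the CS
  and engaging it later both read and write the same `V(M)`;
* a **Model-Based (MB)** learner that estimates the task's transition
  function `T(s, a, s')` and reward function `R(s, a)`, solves the Bellman
  action values `Q(s, a) = R(s, a) + γ Σ T(s, a, s') max Q(s', ·)` by value
  iteration, and acts on the *advantage* `A(s, a) = Q(s, a) − max Q(s, ·)`.

Choice blends the two systems with a per-individual weight ω:
`P(s, a) = (1 − ω) A(s, a) + ω V(f(s, a))`, passed through a softmax with
temperature τ. A high-ω individual behaves like a sign-tracker (feature
values favour the lever), a low-ω individual like a goal-tracker (the MB
system prefers the shortest route to the reward, which runs through the
magazine).

## The task graph

A trial is a small deterministic Markov decision process: from the pre-CS
state the agent enters the CS-onset state, chooses to approach the lever,
the magazine or to explore, engages what it approached, experiences US
delivery, and ends the trial by eating (the only rewarded transition,
`r = 1`). Crucially, an agent engaging the magazine is already at the food
cup when the pellet drops, so the goal route is one step shorter than the
sign and explore routes — the structural reason the discounting MB system
prefers `goM`:

```{r}
task <- task_standard("magazine")
task_edges(task)
mb_advantage(mb_solve_q(world_model_ideal(task), gamma = 0.8), "s1")
```

Between trials, the animal visits the magazine and roams the environment
without being rewarded, which is modelled as a multiplicative down-revision
`V(M) ← (1 − u_ITI) V(M)` (and likewise `V(E)`) applied once per completed
trial. ITI *duration* is encoded in the size of the factor: `u_ITI = 0.01`
for short ITIs, `0.1` for long ones. This is the only pathway by which the
ITI affects the model, and it only touches the FMF system.

## The eat-action feature and why the package defaults to the "magazine" variant

The feature function maps every state-action pair to a feature. Two
conventions exist for the final eat action:

* `feature_variant = "food"`: eating is directed at the food `F`, whose
  value is pinned at 1. The eat-transition prediction error is then
  `r − V(F) = 0` identically — a useful analytic identity (and the
  package's acceptance reference), but it means magazine value is never
  updated on sign-tracking trials, and the error at reward consumption
  carries no signal.
* `feature_variant = "magazine"`: eating is directed at the food cup, so
  `V(M)` is replenished toward 1 on *every* trial's eat and the
  consumption error equals `1 − V(M)`, a usable proxy for the dopamine
  burst at reward delivery.

The package implements both, but all experiment presets use the magazine
variant. This is a substantive choice, not a cosmetic one. Under the food
convention the *only* asymmetry between lever and magazine in the FMF
equations is the ITI decay of `V(M)`, which can only ever favour the
lever: the per-trial fixed points under forced single-path training are
`V(L)* = 0.670` versus `V(M)* = 0.523` (at `u_ITI = 0.01`), so a pure-FMF
agent sign-tracks under both ITI conditions. Only with the magazine
eat-feature does the balance tip: the eat update pulls `V(M)` toward 1
(fixed point 0.748 at `u_ITI = 0.01`, but 0.213 at `0.1` where decay wins),
which makes the hallmark reversal — sign-tracking under long ITIs,
goal-tracking under short ones — possible at all in a feature-based
learner. The qualitative ITI phenomena the package is built to reproduce
therefore require this convention.

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `alpha` | learning rate (both systems) | 0.03 | dimensionless, in [0, 1] |
| `gamma` | discount per task step (both systems) | 0.8 | in [0, 1) |
| `tau` | softmax temperature | 0.15 | > 0; larger = more exploration |
| `u_iti` | per-trial ITI down-revision of `V(M)`, `V(E)` | 0.01 / 0.1 | encodes short / long ITI |
| `omega` | FMF weight in choice | per subject | 0 = pure MB, 1 = pure FMF |

The learning rate and discount are deliberately shared between the two
systems, and single parameter values are used for all individuals: the
phenotype continuum is carried by ω alone. ω is fixed within an individual
and stable over training; no MB-to-MF drift is modelled.

Population simulations draw ω from a beta(2, 1) distribution by default —
the simplest density increasing toward 1, reflecting the commonly reported
prevalence of sign-trackers. The shape parameters are exposed in
`sample_omegas()` and a uniform alternative is provided
(`preset("supp_uniform")`); population-level numbers (test statistics,
score magnitudes) shift with this choice, which is why the package's
checks on population results are directional rather than numeric.

## Protocols, pairing and seeds

The canonical protocol is 10 sessions of 50 trials. Sessions are
contiguous training — nothing is reset at session boundaries; the ITI
revision is the only between-trial event. Paired designs
(`run_paired_population()`) run every subject under both `u_ITI` values
with the *same* ω vector, so ITI effects can be tested within subjects;
each subject-condition pair gets a reproducible choice stream derived from
the protocol seed. The single-system presets (`fig3_fmf_only`,
`fig3_mb_only`) additionally reuse the identical choice-noise stream in
both conditions of a subject, so the ITI factor is isolated exactly: for a
pure-MB agent, whose choices never depend on the revised feature values,
the two conditions then produce bit-identical behaviour, which is the
cleanest statement of the MB system's ITI-insensitivity.

```{r}
log <- run_subject(agent_params(omega = 1), protocol(iti = "long",
  feature_variant = "magazine", seed = 1))
count(filter(log, session == 10), cs_choice)
```

## Prediction errors as dopamine proxies

Every transition's temporal-difference error is logged and tagged:

* `delta_cs` — the CS-onset transition, `γ max(V(M), V(L), V(E)) − V(E)`;
  larger after long ITIs because `V(E)` is revised down more strongly
  (reward-predictive signals are more surprising when rewards are sparse);
* `delta_us` — the transition on which food appears (e.g.
  `γ V(F) − V(L)` on a sign-tracking trial);
* `delta_eat` — the consumption transition (`0` under the food variant,
  `1 − V(M)` under the magazine variant).

Analyses compare conditions on per-subject all-session means (Welch test)
and early (sessions 1–3) versus late (4–10) phases within condition
(paired t tests), via `rpe_contrasts()`. The US measure follows the active
feature convention: the delivery-transition error under the food variant,
the consumption error under the magazine variant.

## The split-CS task

`task_split_cs()` divides the 8-s CS period into two decision points. At
CS onset the agent picks lever or magazine (exploration is removed in this
variant); mid-CS it can stay with its stimulus or switch to the other one;
the post-US structure is unchanged, so the goal route keeps its one-step
advantage. The exact node count of this extension is not fixed by the
behaviour being modelled; the package uses the minimal wiring with
bidirectional switching, isolated behind `task_split_cs()` so an
alternative wiring is a one-function change. In short-ITI populations
after acquisition, agents are more likely to be at the magazine in the
second half of the CS than in the first (`split_cs_contrast()`): MB-leaning
agents that started toward the lever switch to the shorter magazine route.

## Numerical choices

* Value iteration runs to a sup-norm tolerance of 1e-9 with a 10,000-sweep
  safety cap; on these acyclic graphs it reaches the exact fixed point in
  at most depth-many sweeps, so recomputing the Bellman solution at every
  decision (warm-started) is cheap, and transient, choice-history-biased
  advantages are faithfully reflected in behaviour.
* `T` is stored per state-action edge: in a deterministic task the
  observed successor is the only triple that can ever leave zero, so the
  general three-index update reduces to one scalar per edge. Rows are not
  renormalized — the observed triple alone approaches 1 exponentially,
  `1 − (1 − α)^n`, which is also the closed form used in tests.
* The trial terminates at eat with zero continuation value in both
  systems, so `Q(s7, eat)` converges to `R(s7, eat)` exactly.
* Softmax probabilities are computed with max-subtraction; they are
  strictly positive at every realized preference gap (probabilities can
  underflow to zero only for preference gaps many orders of magnitude
  beyond the model's [−1, 1] range).
* Decisions use the estimates from before the current transition's
  updates (learn-after-act); within a trial, earlier transitions' updates
  are visible to later decisions.
* The normalized approach score `(p_L − p_M) / (p_L + p_M)` is undefined
  when both inputs are zero; this cannot happen for softmax probabilities
  (strictly positive) and is guarded with an `NA` and a warning for
  frequency-based scores.

## What the generator does and does not emulate

Simulations reproduce the protocol structure (trial counts, paired ITI
conditions, population heterogeneity in ω) and the model's internal
quantities. They do not model response latencies, repeated interactions
with a stimulus within one CS period (outside the two-decision split-CS
variant), forgetting of unused features, within-ITI dynamics beyond the
two-level `u_ITI` factor, or any re-fitting of parameters to empirical
data. Passing checks therefore demonstrate the claimed properties of the
*model* under its stated conditions, not quantitative agreement with any
particular animal dataset.

## Problem sizes used by the test suite

Structural tests run on reduced protocols (2–6 subjects, 10–20 trials per
session); the replication suite and invariant checks run at the canonical
scale (20 subjects per condition, 10 × 50 trials), where the full suite
completes in well under a minute on a single core.

## Known limitations

* Population-level test statistics depend on the unprinted shape of the ω
  distribution; only directions are asserted.
* With ω near 1 the FMF winner-take-all dynamics make individual agents
  lock onto one strategy; population means, not single runs, carry the
  ITI effects.
* The split-CS wiring is one of several reasonable reconstructions of a
  two-decision CS period; conclusions drawn from it are directional.
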