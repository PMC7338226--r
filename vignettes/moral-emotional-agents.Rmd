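---
title: "Moral emotional agents and the reconstruction of emotion-understanding scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moral emotional agents and the reconstruction of emotion-understanding scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meagent)
```

## The agent model

`meagent` simulates story characters as belief–desire–intention agents
with an OCC-style emotional layer. Beliefs are a set of ground
propositions (`name(arg, ...)`); goals carry an importance of success and
of failure in (0, 1] and adoption/success/failure conditions; moral values
carry a priority in (0, 1] and violation conditions. While a violation
condition holds the value is *at stake*, which (a) spawns an active
restoration goal and (b) makes the next action-caused change to the value
morally appraisable. Each cycle runs six phases in a fixed order: Value
Monitoring, Goal Formation, Anticipatory Emotional Appraisal, Execution,
Monitoring, Emotional Appraisal.

Appraisal turns status changes into typed variables: a goal achieved
(failed) yields desirability (undesirability); a value put at stake
(restored) yields blameworthiness (praiseworthiness) with responsibility
*self* when the causing action's actor is the appraising agent and
*other* otherwise; a plan's success probability yields a likelihood
variable. Affect derivation is a closed rule table over these variables:
joy/distress from (un)desirability, pride/shame from self-directed
praise/blame, admiration/reproach from other-directed, hope/fear from
high/low likelihood, and four compound emotions — gratification (joy +
pride), gratitude (joy + admiration), remorse (distress + self-reproach),
anger (distress + reproach) — that fire only when both component
variables are present *with the same cause*.

During deliberation the agent simulates each candidate plan's effects,
derives the anticipated emotions, nets positive against negative
intensities into the expected emotional reward (EER), and commits to the
plan maximizing `p·IoS − (1−p)·IoF + w·EER`. Exact utility ties are broken
by lexicographic plan id so every run is deterministic; execution outcomes
are scripted in the scenario file by default, with an optional seeded
Bernoulli mode.

## Tunable parameters

All quantities the underlying theory leaves numerically open are surfaced
in `affect_config()` rather than hard-coded:

* `theta_hope = 0.7`, `theta_fear = 0.3` — likelihood thresholds for
  hope/fear. The theory says only "high (or low)"; 0.7/0.3 splits the unit
  interval into clearly-high / clearly-low / indifferent thirds.
* `l_ref = 5` — effort is `min(1, length / l_ref)`: intensity grows with
  plan length (more invested effort) and saturates at five steps, a
  generous bound for narrative plans that run one to three steps.
* `w_eer = 1` — the emotional term enters utility at the same scale as the
  goal-achievement term; the deliberation contrasts in the packaged
  scenarios (e.g. the chocolate dilemma) hold over a wide range of `w`.
* `coemit_compounds = TRUE` — a fired compound also emits its components.
  One packaged scenario overrides this: the published prediction for the
  fourth Audience scenario marks the compound alone, and the override is
  part of that scenario's encoding, not a global dial.

Further fixed conventions, documented here because they are choices rather
than consequences: restoration goals inherit both importances from the
value's priority (the only published link between the two scales); the
likelihood variable's intensity is the plan's probability of success and
the derived hope/fear inherit it; realized outcomes are appraised with
probability 1; compound intensity is the mean of its two components;
value-at-stake states present in the *initial* world spawn restoration
goals but generate no emotions — only action-caused deltas are appraised,
so a story can open in medias res without spurious affect.

## Scenario encodings

The seven scenario files under `inst/extdata/scenarios/` encode the
narrative situations with a deliberately minimal condition language:
conjunctions of ground propositions, no negation, no variables — the
smallest language that expresses all seven plots. The published materials
specify the qualitative structure (which values matter to whom, which of
two plans is predicted, which emotions are marked) but not the numeric
importances and priorities; the packaged numbers are authored to satisfy
the ordinal constraints the narratives imply (e.g. the guard's compassion
outweighs his duty) and are validated end-to-end: the test suite re-runs
every scenario and requires the selected plan and the final emotion set to
equal the packaged prediction marks exactly. The other-character
predictions of the Audience test are encoded too but flagged
`provisional` — the source table for them is typographically corrupted —
and they are never used as acceptance references.

## The respondent reconstruction

Per-participant selections were never published, but the printed tables
give, per scenario, group and emotion, the selection percentage to one
decimal. With group sizes 13 (TBI) and 11 (control), `k = round(pct·n/100)`
recovers the integer count uniquely; a residual guard of 0.06 percentage
points (strict one-decimal rounding allows at most 0.05, plus a margin for
the source's inconsistent rounding) rejects any transcription error by
cell name. Audience per-scenario sizes are unprinted (sessions were split)
and are inferred as the smallest n under which every non-zero percentage
is consistent with an integer count; the inferred sizes agree between the
main- and other-character tables of each scenario.

`generate_respondents()` produces synthetic selection matrices consistent
with those counts. In `exact_marginal` mode each emotion column gets
exactly its count of 1s at seeded-random rows, so *every statistic linear
in the column sums* — all score means and all mean SMCs — equals its
closed-form value for any seed; the suite asserts agreement to 1e-12.
What the generator does **not** emulate is the within-participant joint
distribution across emotions and scenarios (unidentifiable from the
published marginals): synthetic standard deviations, and any other
nonlinear statistic, are therefore *not* estimates of the real ones, and
passing tests say nothing about them. This is also why the published
Mann–Whitney U values and Spearman coefficients are out of reach: they
depend on the joint data. The statistics themselves are implemented and
verified against enumeration oracles and the `stats::` reference
implementations instead.

## Scoring conventions

Two conventions are forensic reconstructions, toggleable and verified by
the suite rather than assumed:

* **Moral partition.** The printed score definitions name a few labels
  ("contempt", "blame", "sadness") that are not in the twelve-type answer
  set. The operational partition — moral = {admiration, reproach,
  gratification, gratitude, pride, shame, anger, remorse}, non-moral =
  {joy, distress, fear, hope} — is the unique assignment under which all
  published moral/non-moral score means follow from the emotion-choice
  marginals.
* **Hope rule** (`hope_rule = TRUE`). Selections of hope are not counted
  as error commissions. Only under this rule do the published non-moral
  error means (3.31 TBI, 2.64 control) reproduce; switching it off makes
  exactly those cells fail in `mea_verify()`, which the suite checks as a
  sensitivity control.

Four published cells are *not* reproducible from the source's own
marginals and are excluded from verification, recorded in every report's
`notes`: the control action-score mean (prints 2.00, marginals give
20/11 = 1.82), both all-emotion SMCs of the second Actor scenario, the
all-emotion control SMC of the third (prints 0.65, marginals give 0.67),
and the moral-only control global SMC (prints 0.70, marginals give 0.68).
Printed per-scenario SMCs are otherwise matched at two decimals with a
one-ulp truncation allowance (the source prints 0.76 for 0.769).

## Numerical choices in the statistics

The Mann–Whitney two-tailed p doubles the exact one-tailed permutation
tail (capped at 1), matching the reporting style of standard statistical
packages. The exact distribution is computed by a subset-sum dynamic
program over doubled mid-ranks, so ties are exact too — the reason the
test is implemented in-package; `stats::wilcox.test` declines exact
p-values under ties and serves as the independent cross-check on tie-free
inputs. The exact route is used up to 10^7 group assignments (the study's
13 + 11 split needs 2.5 × 10^6), the tie-corrected normal approximation
beyond. Spearman's rho uses average ranks; its p is an exact permutation p
up to n = 8 (full enumeration, 40,320 permutations — chosen as the point
where interpreted-R enumeration is still instant) and a t-approximation
with n − 2 degrees of freedom above, cross-checked against
`stats::cor.test`.

## Problem sizes and limitations

The whole pipeline is desk-scale: seven scenarios of one reasoning cycle,
groups of 13 and 11 respondents, and score tables linear in 12 × 3 × 2
counts; the test suite's property loops use 30–200 random instances per
invariant and 10^4 Monte-Carlo replicates for the Bernoulli generator
check. Known limitations: no negation or quantification in conditions; no
planner (plans are authored, as the tests' two-alternative design
requires); responsibility attribution is single-actor per action, with no
deeper theory of mind; emotions do not decay across cycles (the packaged
scenarios are single-cycle episodes); and the synthetic respondents carry
no joint structure, as discussed above.
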