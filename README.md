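# meagent

Story characters can be simulated as *moral emotional agents*: BDI
(belief–desire–intention) agents whose deliberation is coupled to an
OCC-style emotional appraisal with explicit moral values. Clinically, such
an agent is useful as a reference standard: its predicted actions and
emotions for narrative scenarios can be compared with the choices of
respondents — here a group of traumatic-brain-injury (TBI) patients and
matched neurologically intact controls — to quantify impairments in moral
emotion understanding. `meagent` implements the agent, machine-readable
encodings of the seven narrative test scenarios (three "Actor Studio",
four "Audience Studio"), and the full scoring battery used to compare
groups.

## The model

Each character carries goals (with an importance of success `IoS` and of
failure `IoF`, both in (0, 1]), moral values (with a priority in (0, 1] and
violation conditions), and an authored plan library. Every reasoning cycle
runs six phases: **Value Monitoring** (a value whose violation condition
holds is *at stake* and spawns a restoration goal), **Goal Formation**,
**Anticipatory Emotional Appraisal**, **Execution**, **Monitoring**, and
**Emotional Appraisal**. Appraisal produces typed variables —
(un)desirability from goal outcomes, praise/blameworthiness from value
changes with a self/other responsibility, likelihood from plan success
probability — and affect-derivation rules map them to the twelve emotion
types (joy, distress, hope, fear, pride, shame, admiration, reproach, and
the compounds gratification, gratitude, remorse, anger, which require both
component variables with a shared cause). Emotion intensity is
multiplicative: `importance × probability × effort`, with effort
`min(1, plan length / L_ref)`. Plans are ranked by

    utility(plan) = p·IoS − (1 − p)·IoF + w·EER,

where the *expected emotional reward* `EER` nets the intensities of
anticipated positive against negative emotions; the agent commits to the
argmax (moral deterrence falls out: raising the priority of a value a plan
violates can only lower that plan's utility).

Respondent agreement with the model is scored per scenario by emotion and
error scores over a moral / non-moral partition (ETS = MES + N-MES,
ERTS = MERS + N-MERS), the action score (Actor scenarios), and the Simple
Matching Coefficient

    SMC = (M00 + M11) / (M00 + M01 + M10 + M11)

over the 12-emotion (or 8 moral-emotion) subset. Per-participant data
behind the published tables are unavailable, but every group mean is
linear in the per-emotion selection counts, which are exactly recoverable
from the printed percentages (`k = round(pct·n/100)`, n = 13 TBI / 11
control); the package reconstructs them and, optionally, generates
exact-marginal synthetic respondent matrices that reproduce every linear
statistic for any seed. Mann–Whitney (exact permutation p, ties via
mid-ranks) and Spearman rank correlation round out the battery.

## Worked example

```r
library(meagent)

sc <- load_scenario(scenario_files("wallace"))
run_scenario(sc)
#> <trace wallace: 1 cycle(s), max_cycles_reached>
#>   wallace: plan=giving_key emotions={shame}
```

The guard hands over the key and feels only shame: giving the key violates
his duty (self-caused blameworthiness → shame) while the prisoner's
freedom — the goal's success condition — lies beyond the episode, so no
joy is generated. Deliberation picks `giving_key` because refusing would
abandon the prisoner, violating his dearer compassion value:

```r
ag <- form_goals(meagent:::refresh_value_flags(sc$characters$wallace, sc$world),
                 sc$world)
sapply(ag$plans, function(p) anticipatory_appraisal(p, ag, sc$world)$utility)
#>   giving_key refusing_key
#>     1.452000     0.910000
```

Rebuilding the group score tables from the packaged marginals:

```r
reproduce_tables("from_marginals")
#> Group means:
#>    group  ats  ets  mes nmes  erts mers nmers
#>      TBI 2.15 3.38 2.15 1.23 11.31 8.00  3.31
#>  control 1.82 2.45 1.36 1.09 10.27 7.64  2.64
#> ...
#>           global    all     0.67         0.71
```

The TBI row reproduces the published means exactly; the control action
score is one of four cells the report flags as internally inconsistent
with the source's own marginals (see the report's `notes`). `mea_verify()`
runs every scenario end-to-end plus all table checks and reports
pass/fail per cell.

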