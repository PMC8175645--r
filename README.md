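# pathrisk

Data-driven risk profiling of intra-hospital patient journeys.

Hospitals plan care as clinical pathways, but the journey a patient actually
experiences — from the condition on admission, through ordered care steps, to
the state at discharge — often deviates from the plan. `pathrisk` is an R
toolkit for clinical-governance and patient-safety analysts who have (or can
simulate) structured journey logs and want to quantify three things:

1. **Outcome risk.** Journeys with similar admission parameters are grouped
   into clusters, and each cluster's journeys are tallied into a directed
   graph: one admission node *I*, one node per care stage *S*, one terminal
   node per outcome *O*. Interrogated as an absorbing Markov chain, the graph
   answers "starting from this patient's current stage, with what probability
   does the journey end in each outcome?" — and the **risk** is
   `1 − P(expected outcome)`.
2. **Next-step probabilities.** The same graph gives the step-ahead
   distribution over possible next stages, e.g. "from Stage A: 65% Stage B,
   25% Stage C, 10% Stage D".
3. **Plan-vs-real deviations.** A realized journey is globally aligned
   against its planned pathway (unit-cost edit distance, deterministic
   traceback) and classified: **A** reroute that still reaches the expected
   outcome, **B** only inserted extra stages, **C** unintended final
   condition, or **NONE**.

## The model in brief

A journey is `P = <I → S1 → … → Sk → O>` with
`I = <a, e, t, d, c, r, o>` (history, examination, medications, diagnosis,
complexity, admission type, expected outcome), steps `Si = <s, p>` and final
state `O = <x, h>`. Per cluster, transition probabilities are estimated from
counts with optional additive smoothing over observed successors:

```
P(u → v) = (count(u, v) + α) / (visits(u) + α · S(u))
```

and outcome probabilities are the absorption probabilities `b_u = Σ_v
P(u → v) · b_v`, solved as a linear system (so cyclic graphs — stage
revisits — are handled exactly). The closed-world default is `α = 0`:
transitions never observed are treated as non-existent. For patients outside
the closed world (unseen admission clusters), a supervised risk predictor
estimates `P(unintended outcome)` from the admission state and the journey
so far through a pluggable learner interface (ridge logistic regression by
default, CART optional).

Everything is testable without real clinical data: a seeded first-order
Markov simulator generates journey logs from known transition tables, with
optional injected deviations, and exposes its exact ground truth for
parameter-recovery checks.

## Worked example

```r
library(pathrisk)

# 100 journeys through Stage A, branching 65/25/10 to Stages B/C/D
log <- extension_example_log()
g   <- build_graph(log, alpha = 0)

next_step_distribution(g, "stage_A")
#> Next step from 'stage_A':
#>   stage_B 65.0%
#>   stage_C 25.0%
#>   stage_D 10.0%

risk_profile(g, "I", "discharged")
#> <risk_profile> from 'I', expected outcome 'discharged'
#>   p(discharged) = 1.0000
#>   risk of missing expected outcome: 0.0000

# the two packaged orthopaedic case studies
fx <- case_study_fixtures()
assess_deviation(fx$case1$pathway, fx$case1$journey)
#> <deviation_report> journey 'case_study_1': type A
#>   edit distance 3 (1 match, 3 sub, 0 ins, 0 del); outcome as expected
assess_deviation(fx$case2$pathway, fx$case2$journey)
#> <deviation_report> journey 'case_study_2': type C
#>   edit distance 3 (1 match, 2 sub, 1 ins, 0 del); outcome 'partial_articular_recovery_ankle' != expected 'full_recovery'
```

The first report says case 1's journey was rerouted (three planned steps
replaced) but still reached full recovery — a type A deviation. Case 2 ends
in partial articular recovery instead of the expected full recovery, an
unintended final condition (type C) regardless of its step-level changes.

Journey logs read and write as JSON Lines (`read_journey_log()`,
`write_journey_log()`; schema in `inst/extdata/journey-log.schema.json`),
graphs export to GraphML/DOT (`export_graph()`), and every result type has
`tidy()`/`glance()`/`autoplot()` methods. A command-line launcher with
`simulate`, `build`, `risk`, `next`, `deviations` and `predict` subcommands
is installed at `system.file("cli", "pathrisk.R", package = "pathrisk")`.

## Package layout

| Area | Functions |
| --- | --- |
| Journey model & I/O | `journey()`, `initial_condition()`, `read_journey_log()`, `write_journey_log()`, `expected_pathway()` |
| Cohorting | `cluster_key()`, `partition_journeys()`, `match_cluster()` |
| Knowledge graph | `build_graph()`, `add_journey()`, `transition_probs()`, `outcome_distribution()`, `risk_profile()`, `next_step_distribution()`, `export_graph()` |
| Deviations | `align_paths()`, `classify_deviation()`, `assess_deviation()`, `deviation_rates()` |
| Prediction | `fit_predictor()`, `predict_risk()`, `risk_delta()`, `learner_logistic()` |
| Simulation | `generator_spec()`, `simulate_log()`, `ground_truth()`, `example_generator_spec()` |

See the methods vignette (`vignettes/journey-risk-model.Rmd`) for the model's
assumptions, parameter choices and limitations.
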