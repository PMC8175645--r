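---
title: "Modelling intra-hospital journey risk with pathrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling intra-hospital journey risk with pathrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathrisk)
```

## The journey model

`pathrisk` treats a hospital stay as an ordered path
`P = <I -> S1 -> ... -> Sk -> O>`. The initial condition `I` collects the
structured admission parameters: history `a`, physical examination `e`,
medications in progress `t`, the admitting diagnosis `d`, case-complexity
factors `c` (comorbidities, allergies, resistances), the admission type `r`
(emergency, elective, day hospital, day surgery) and the clinically expected
outcome `o`. Each step `Si = <s, p>` is a stage label with a parameter
payload, and the final state `O = <x, h>` is the realized outcome with the
discharge health conditions. A journey whose realized outcome `x` equals the
expected `o` followed its intended path; otherwise it realized an unintended
final condition.

Two representational choices matter downstream:

* **Node identity is the stage label `s` alone.** The payload `p` is carried
  as data but does not define graph nodes; keying nodes on the full
  `<s, p>` pair would shatter the graph into near-singleton nodes and
  destroy the frequency estimates. Labels are exact case-sensitive strings —
  the model assumes records are already structured; free-text normalization
  is out of scope (the packaged case studies encode their clinical
  narratives as short canonical labels, keeping the original phrasing in
  each step's `params$narrative`).
* **Time is ordinal.** Step order drives the mathematics; an optional
  ISO-8601 timestamp is carried through serialization but unused. Waiting
  times and length-of-stay are not modelled.

## Cohorting

Risk only makes sense conditional on "patients like this one", so journeys
are clustered by admission parameters before any graph is built. The default
cluster key is `(admission_diagnosis, complexity)` — the diagnosis plus the
comorbidity set — serialized canonically (set-valued fields sorted) so the
key is invariant to storage order. The key fields are configurable because
no universal rule fits every registry; adding `"facility"` to the key
stratifies the knowledge base by hospital, which is how facility covariates
(size, departments, organization type) enter the closed-world model without
any separate machinery.

Cluster lookup at admission time is `"strict"` by default: an unseen key is
an error ("patient outside closed world"), honouring the closed-world
assumption that the knowledge base exhausts the possible journeys. The
`"nearest"` policy is an explicit relaxation for exploratory use: it requires
an exact diagnosis match and maximizes Jaccard similarity over the set-valued
key fields, breaking ties lexicographically so results are reproducible.

## The knowledge graph and its estimates

`build_graph()` tallies a cluster's journeys into a directed graph with one
initial node, one node per stage label and one terminal node per outcome
label. Edge counts are consecutive-pair counts; node visits count
occurrences, so the invariant *outgoing counts sum to visits* holds exactly
for every non-terminal node, and `add_journey()` preserves it while being
field-exactly equivalent to a batch rebuild — the knowledge base can grow
incrementally as journeys are recorded.

Transition probabilities are estimated per node as

$$\hat p(u \to v) = \frac{n_{uv} + \alpha}{n_u + \alpha S_u},$$

where $S_u$ is the number of *observed* successors of $u$. The default
$\alpha = 0$ is the maximum-likelihood estimate demanded by the closed-world
reading: unobserved transitions are non-existent, so smoothing never invents
phantom edges; $\alpha > 0$ only stabilizes estimates among successors that
were actually seen. Probabilities are kept in $[0,1]$ internally — percent
formatting (one decimal) is presentation only, in
`next_step_distribution()`'s print method and the command-line `next`
output.

Outcome probabilities are absorption probabilities of the first-order Markov
chain: for terminal $t$, $b_t(t) = 1$; for every other node,
$b_u = \sum_v \hat p(u \to v)\, b_v$. We solve the linear system
$(I - Q)B = R$ directly (tolerance `1e-12`) rather than enumerating paths,
so cycles — patients revisiting stages — are handled exactly; if the solver
reports singularity the implementation falls back to damped fixed-point
iteration of the same equations. A node from which no terminal is reachable
signals a truncated log and is an error, not a silent zero. The **risk** at
a node is $1 - b(\text{expected outcome})$; an expected outcome never
observed as a terminal yields risk 1 with an explicit warning flag.

The first-order assumption is the minimal faithful reading of a graph whose
nodes are stages: the next stage depends only on the current one. Two
sensitivity handles relax it without changing the machinery:
`build_graph(history_order = 2)` keys each node on the pair
`previous>current`, and `node_params` folds selected step parameters into
node identity (off by default — keying on full payloads would shatter the
graph). Beyond that, the supervised predictor (below) sees the full
multi-hot stage history of the prefix.

## Deviation typology

`align_paths()` computes a global alignment between the planned and realized
stage sequences under unit edit costs (match 0; substitution, insertion,
deletion 1; a substitution-cost hook exists but defaults to uniform because
no step-similarity notion is assumed). The traceback is deterministic,
preferring match > substitution > deletion > insertion on ties, so reports
are reproducible run to run.

Classification formalizes a narrative three-way typology, checked against
both packaged case studies, with precedence **C > NONE > B > A**:

* **C** — the realized outcome differs from the planned one, whatever the
  steps;
* **NONE** — edit distance 0 and matching outcome;
* **B** — only insertions (extra stages slotted into an otherwise intact
  plan), matching outcome;
* **A** — any other reroute (substituted and/or skipped steps) that still
  reaches the expected outcome.

Two rulings were genuinely open and are this package's choices: a journey
mixing insertions with substitutions is classified A (the reroute dominates
the "pure insertion" reading), and a skipped planned step (deletion) is also
A rather than a type of its own, since the typology has no skip class.

## The synthetic-data generator

`simulate_log()` draws journeys as first-order Markov walks over a
per-cluster row-stochastic transition table until absorption, with a
100-step guard against non-absorbing walks and a mandatory seed (identical
spec, identical log, byte for byte). Its `ground_truth()` companion returns
the exact transition rows and absorption probabilities by an independent
direct linear solve over the spec's table, never touching the estimator —
that independence is what makes the parameter-recovery tests meaningful.

Deviation injection post-processes sampled walks: per journey at most one of
an inserted off-plan stage (type B relative to a deterministic backbone
plan), a substituted stage (type A), or a substituted stage with a flipped
outcome (type C), at configured rates. Admission templates can vary history
pools and shuffle the stored order of complexity sets, so cohorting's
canonicalization does real work on simulated logs.

The packaged standard scenario (`example_generator_spec()`) has three
clusters with branching tables — one containing a ward/ICU cycle — two to
three outcomes each, and 100 journeys per cluster by default; deviation
injection is off unless requested. An optional second-order mode was
considered and rejected for the default generator: data violating the
first-order assumption belongs in targeted sensitivity experiments, not in
the standard conditions every test rests on.

What passing these tests shows — and does not. The generator emulates
cluster structure, branching, cycles, outcome mixtures and injected
deviations, so tests demonstrate that the estimators recover known
parameters from data obeying the model's assumptions. Real journey logs add
label noise, non-Markov dependence, censoring and documentation artifacts
that the generator deliberately omits; green tests here are necessary, not
sufficient, evidence for performance on real records.

## Problem sizes and numerical choices

The suite exercises: parameter recovery on a 10-node table (one initial
node, six stages visited by 40–100% of journeys, three outcomes) at
10,000 journeys, where the maximum absolute error of transition estimates is
required to stay within 0.02; exhaustive path enumeration as the absorption
oracle on acyclic graphs up to 8 nodes (agreement to 1e-9); a 200,000-rollout
seeded Monte-Carlo oracle for a cyclic graph with a probability-0.5
self-returning loop (agreement within 3 binomial sigma); incremental-vs-batch
equality over 200 random logs; and recovery of a 0.2 injected insertion rate
at 5,000 journeys within 3 sigma. These sizes were chosen to keep sampling
error well inside each tolerance while running comfortably on a laptop.

Degenerate inputs are defined, not accidental: an empty journey log cannot
build a graph; a step-less journey contributes a direct admission-to-outcome
edge; terminal nodes reject transition queries; querying an outcome node's
absorption returns a point mass on itself.

## The supervised predictor

For patients the closed world cannot answer, `fit_predictor()` learns
$P(\text{unintended outcome})$ from (initial condition, journey prefix,
facility) indicator encodings, expanding each training journey into all of
its step prefixes so risk can be re-estimated step by step. The module's
contribution is the *contract* — deterministic featurization with reserved
unknown slots, a binary target, probability outputs, Brier evaluation
against the constant baseline on a seeded 80/20 by-journey split — while the
learner is pluggable. The shipped default is ridge-penalized logistic
regression (`glmnet`, fixed small penalty: deterministic and well-behaved on
separable toy problems); a CART learner is included, and anything
implementing `fit(x, y)` / `predict(model, x)` drops in. The predictor is
global with cluster information carried in the features; per-cluster fitting
is a filter away (`fit_predictor(parts[[k]])`).

On fully covered closed-world logs, graph risk at the prefix's current node
and the predictor's output agree to within 0.1 mean absolute difference on
the standard scenario — a consistency check between the two routes, not a
theorem; the two estimators answer the same question from different
representations and need not coincide pointwise.

## Limitations

* Frequency estimates presume the cluster's log is large and representative;
  small clusters give high-variance risk numbers with no uncertainty
  quantification attached.
* First-order dynamics; stage payloads do not influence transition
  estimates.
* Deviation alignment treats all stages as equidistant unless a substitution
  cost is supplied.
* No terminology binding: labels are opaque strings, and logs mixing coding
  conventions will fragment both clusters and graphs.
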