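# Seeded synthetic journey generator. Journeys are first-order Markov walks
# over a per-cluster transition table until absorption in an outcome; the
# generator is the testing ground for every estimator in the package
# (parameter recovery, deviation-rate recovery, predictor checks).

validate_transition_table <- function(transitions, stages, outcomes, cluster_id) {
  states <- c("I", stages)
  targets <- c(stages, outcomes)
  if (!setequal(names(transitions), states)) {
    abort(sprintf("cluster '%s': transitions must have one row per state (I + stages)",
                  cluster_id))
  }
  for (st in states) {
    row <- transitions[[st]]
    if (is.null(names(row)) || any(!nzchar(names(row)))) {
      abort(sprintf("cluster '%s': transition row '%s' must be a named vector",
                    cluster_id, st))
    }
    if (!all(names(row) %in% targets)) {
      abort(sprintf("cluster '%s': transition row '%s' targets unknown states: %s",
                    cluster_id, st,
                    paste(setdiff(names(row), targets), collapse = ", ")))
    }
    if (any(row < 0) || abs(sum(row) - 1) > 1e-9) {
      abort(sprintf("cluster '%s': transition row '%s' must be nonnegative and sum to 1",
                    cluster_id, st))
    }
  }
  # every state must be able to reach an outcome along positive-probability edges
  reach <- outcomes
  repeat {
    grown <- FALSE
    for (st in states) {
      if (st %in% reach) next
      if (any(transitions[[st]][names(transitions[[st]]) %in% reach] > 0)) {
        reach <- c(reach, st)
        grown <- TRUE
      }
    }
    if (!grown) break
  }
  missing <- setdiff(states, reach)
  if (length(missing)) {
    abort(sprintf("cluster '%s': no outcome reachable from state(s): %s",
                  cluster_id, paste(missing, collapse = ", ")))
  }
  invisible(transitions)
}

#' Specification for the synthetic-journey generator
#'
#' Defines, per cluster, an initial-condition template, a stage set, a
#' row-stochastic transition table over stages and outcomes, the clinically
#' expected outcome and the number of journeys to draw; plus optional
#' post-hoc deviation injection (extra inserted stages, substituted stages,
#' outcome flips) and a mandatory seed.
#'
#' @param clusters A list of cluster definitions; each a list with fields
#'   `id`, `initial` (an [initial_condition()] template; its
#'   `expected_outcome` must be one of the cluster's outcomes), `stages`
#'   (character), `outcomes` (character), `transitions` (named list mapping
#'   each of `"I"` and the stages to a named probability vector over stages
#'   and outcomes, each row summing to 1), `n_journeys`, and optionally
#'   `history_pool` (list of history-label vectors sampled per journey).
#' @param deviation List with rates `insertion_rate` (an unscheduled extra
#'   stage is inserted: a pure type-B deviation relative to the cluster's
#'   backbone plan), `substitution_rate` (a stage is replaced by an
#'   off-plan variant: type A) and `outcome_flip_rate` (a stage is replaced
#'   and the outcome flipped to another of the cluster's outcomes: type C).
#'   Rates must sum to at most 1; at most one injection is applied per
#'   journey. All default to 0.
#' @param facilities Optional list of [facility_profile()]s; each cluster may
#'   name one via a `facility` field.
#' @param seed Mandatory integer seed; the same spec and seed always produce
#'   a byte-identical log.
#' @return An object of class `generator_spec`.
#' @seealso [simulate_log()], [ground_truth()], [example_generator_spec()]
#' @export
generator_spec <- function(clusters,
                           deviation = list(insertion_rate = 0,
                                            substitution_rate = 0,
                                            outcome_flip_rate = 0),
                           facilities = NULL,
                           seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` is mandatory and must be a single integer")
  }
  deviation <- utils::modifyList(
    list(insertion_rate = 0, substitution_rate = 0, outcome_flip_rate = 0),
    deviation
  )
  rates <- unlist(deviation[c("insertion_rate", "substitution_rate",
                              "outcome_flip_rate")])
  if (any(rates < 0) || sum(rates) > 1 + 1e-12) {
    abort("deviation rates must be nonnegative and sum to at most 1")
  }
  if (!length(clusters)) abort("`clusters` must be nonempty")
  clusters <- purrr::map(clusters, function(cl) {
    for (f in c("id", "initial", "stages", "outcomes", "transitions", "n_journeys")) {
      if (is.null(cl[[f]])) abort(sprintf("cluster definition missing field '%s'", f))
    }
    stopifnot(inherits(cl$initial, "initial_condition"))
    cl$stages <- as.character(cl$stages)
    cl$outcomes <- as.character(cl$outcomes)
    if (!cl$initial$expected_outcome %in% cl$outcomes) {
      abort(sprintf("cluster '%s': expected outcome '%s' is not among its outcomes",
                    cl$id, cl$initial$expected_outcome))
    }
    validate_transition_table(cl$transitions, cl$stages, cl$outcomes, cl$id)
    cl$n_journeys <- as.integer(cl$n_journeys)
    cl
  })
  if (!is.null(facilities)) {
    stopifnot(all(purrr::map_lgl(facilities, inherits, "facility_profile")))
    names(facilities) <- purrr::map_chr(facilities, "facility_id")
  }
  structure(list(clusters = clusters, deviation = deviation,
                 facilities = facilities, seed = as.integer(seed)),
            class = "generator_spec")
}

sample_walk <- function(transitions, outcomes, max_steps = 100L) {
  state <- "I"
  stages <- character()
  for (k in seq_len(max_steps + 1L)) {
    row <- transitions[[state]]
    state <- names(row)[sample.int(length(row), 1L, prob = row)]
    if (state %in% outcomes) return(list(stages = stages, outcome = state))
    stages <- c(stages, state)
  }
  abort(sprintf(
    "walk exceeded %d steps without absorbing in an outcome (last stage '%s')",
    max_steps, state))
}

#' Simulate a synthetic journey log
#'
#' Draws each cluster's journeys as first-order Markov walks from the initial
#' node until absorption in an outcome (a guard aborts any walk exceeding
#' `max_steps`), then applies the spec's deviation injection. Reproducible:
#' the same spec yields an identical log on every run.
#'
#' @param spec A [generator_spec()].
#' @param max_steps Walk-length guard (default 100).
#' @return A journey-log tibble with bookkeeping columns `.cluster_id` (the
#'   generating cluster) and `.injected` (`"none"`, `"B"`, `"A"` or `"C"`);
#'   bookkeeping columns are dropped on serialization.
#' @export
simulate_log <- function(spec, max_steps = 100L) {
  stopifnot(inherits(spec, "generator_spec"))
  local_seed(spec$seed, {
    rows <- purrr::map(spec$clusters, function(cl) {
      fac <- cl$facility %||% NA_character_
      purrr::map(seq_len(cl$n_journeys), function(i) {
        walk <- sample_walk(cl$transitions, cl$outcomes, max_steps)
        ini <- cl$initial
        if (!is.null(cl$history_pool)) {
          ini$history <- as.character(
            cl$history_pool[[sample.int(length(cl$history_pool), 1L)]])
        }
        # shuffle the stored order of the complexity set; the canonical
        # cluster key must be invariant to it
        if (length(ini$complexity) > 1L) {
          ini$complexity <- sample(ini$complexity)
        }
        stages <- walk$stages
        outcome <- walk$outcome
        injected <- "none"
        u <- runif(1)
        dev <- spec$deviation
        if (u < dev$insertion_rate && length(stages)) {
          pos <- sample.int(length(stages), 1L)
          stages <- append(stages, "unscheduled_extra_stage", after = pos)
          injected <- "B"
        } else if (u < dev$insertion_rate + dev$substitution_rate &&
                   length(stages)) {
          pos <- sample.int(length(stages), 1L)
          stages[pos] <- paste0(stages[pos], "_offplan")
          injected <- "A"
        } else if (u < dev$insertion_rate + dev$substitution_rate +
                   dev$outcome_flip_rate && length(stages) &&
                   length(cl$outcomes) > 1L) {
          pos <- sample.int(length(stages), 1L)
          stages[pos] <- paste0(stages[pos], "_offplan")
          others <- setdiff(cl$outcomes, outcome)
          outcome <- others[[sample.int(length(others), 1L)]]
          injected <- "C"
        }
        steps <- if (length(stages)) {
          tibble(action = stages, params = purrr::map(stages, ~ list()),
                 t = seq_along(stages), timestamp = NA_character_)
        } else {
          empty_steps()
        }
        j <- journey(sprintf("%s-%05d", cl$id, i), ini, steps,
                     final_state(outcome), facility = fac)
        j$.cluster_id <- cl$id
        j$.injected <- injected
        j
      })
    })
    dplyr::bind_rows(purrr::flatten(rows))
  })
}

#' Ground-truth probabilities of a generator spec
#'
#' The exact transition row or absorption (outcome) probabilities implied by
#' a cluster's transition table, computed directly from the spec by a linear
#' solve. This is an oracle deliberately independent of the knowledge-graph
#' estimator, for parameter-recovery testing.
#'
#' @param spec A [generator_spec()].
#' @param cluster_id Id of the cluster to interrogate.
#' @param node `"I"` or a stage label.
#' @param query `"transition"` or `"outcome_distribution"`.
#' @return A tibble: `to`/`prob` for transitions, `outcome`/`prob` for the
#'   absorption distribution.
#' @export
ground_truth <- function(spec, cluster_id, node,
                         query = c("transition", "outcome_distribution")) {
  stopifnot(inherits(spec, "generator_spec"))
  query <- match.arg(query)
  ids <- purrr::map_chr(spec$clusters, "id")
  if (!cluster_id %in% ids) abort(sprintf("unknown cluster '%s'", cluster_id))
  cl <- spec$clusters[[match(cluster_id, ids)]]
  states <- c("I", cl$stages)
  if (!node %in% states) {
    abort(sprintf("unknown node '%s' in cluster '%s'", node, cluster_id))
  }
  if (query == "transition") {
    row <- cl$transitions[[node]]
    return(tibble(to = names(row), prob = as.numeric(row)) |>
             dplyr::arrange(dplyr::desc(.data$prob), .data$to))
  }
  # direct linear solve over the spec's table (independent of knowledge_graph)
  Q <- matrix(0, length(states), length(states),
              dimnames = list(states, states))
  R <- matrix(0, length(states), length(cl$outcomes),
              dimnames = list(states, cl$outcomes))
  for (st in states) {
    row <- cl$transitions[[st]]
    for (tg in names(row)) {
      if (tg %in% cl$outcomes) R[st, tg] <- R[st, tg] + row[[tg]]
      else Q[st, tg] <- Q[st, tg] + row[[tg]]
    }
  }
  B <- solve(diag(length(states)) - Q, R)
  tibble(outcome = cl$outcomes, prob = as.numeric(B[node, ])) |>
    dplyr::arrange(.data$outcome)
}

#' A three-cluster example generator specification
#'
#' The package's standard synthetic scenario: three orthopaedic/medical
#' admission clusters with distinct diagnoses and complexity sets, branching
#' transition tables (one containing a cycle: ICU patients can return to the
#' ward), two to three outcomes each, and 100 journeys per cluster. Deviation
#' injection is off; pass rates through `deviation` to turn it on.
#'
#' @param seed Integer seed.
#' @param n_journeys Journeys per cluster (default 100).
#' @param deviation Deviation-injection rates, see [generator_spec()].
#' @return A [generator_spec()].
#' @export
example_generator_spec <- function(seed, n_journeys = 100L,
                                   deviation = list()) {
  hip <- list(
    id = "hip_fracture",
    initial = initial_condition(
      admission_diagnosis = "hip_fracture",
      expected_outcome = "full_recovery",
      complexity = c("osteoporosis", "age_over_75"),
      admission_type = "emergency"
    ),
    history_pool = list(c("fall_at_home"), c("fall_at_home", "prior_fracture"),
                        character()),
    stages = c("imaging", "surgery", "rehabilitation"),
    outcomes = c("full_recovery", "partial_recovery"),
    transitions = list(
      I = c(imaging = 1),
      imaging = c(surgery = 0.9, rehabilitation = 0.1),
      surgery = c(rehabilitation = 0.8, partial_recovery = 0.2),
      rehabilitation = c(full_recovery = 0.85, partial_recovery = 0.15)
    ),
    n_journeys = n_journeys
  )
  pneumonia <- list(
    id = "pneumonia_copd",
    initial = initial_condition(
      admission_diagnosis = "pneumonia",
      expected_outcome = "discharged_home",
      complexity = c("copd"),
      admission_type = "emergency"
    ),
    history_pool = list(c("smoking"), character()),
    stages = c("ward_antibiotics", "icu"),
    outcomes = c("discharged_home", "deceased"),
    transitions = list(
      I = c(ward_antibiotics = 1),
      ward_antibiotics = c(discharged_home = 0.7, icu = 0.3),
      icu = c(ward_antibiotics = 0.6, deceased = 0.4)  # cycle back to the ward
    ),
    n_journeys = n_journeys
  )
  appendectomy <- list(
    id = "appendicitis",
    initial = initial_condition(
      admission_diagnosis = "acute_appendicitis",
      expected_outcome = "discharged_home",
      complexity = character(),
      admission_type = "emergency"
    ),
    stages = c("laparoscopic_appendectomy", "observation"),
    outcomes = c("discharged_home", "readmitted"),
    transitions = list(
      I = c(laparoscopic_appendectomy = 0.95, observation = 0.05),
      laparoscopic_appendectomy = c(observation = 1),
      observation = c(discharged_home = 0.92, readmitted = 0.08)
    ),
    n_journeys = n_journeys
  )
  generator_spec(list(hip, pneumonia, appendectomy), deviation = deviation,
                 seed = seed)
}

#' Read a generator spec from YAML or JSON
#'
#' The on-disk form mirrors [generator_spec()]: top-level `seed`, `deviation`,
#' and `clusters`, each cluster carrying its `initial` template as a plain
#' mapping.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param seed Optional seed overriding the file's.
#' @return A [generator_spec()].
#' @export
read_generator_spec <- function(path, seed = NULL) {
  if (!file.exists(path)) abort_io(sprintf("spec file '%s' does not exist", path))
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  clusters <- purrr::map(doc$clusters, function(cl) {
    ini <- cl$initial
    cl$initial <- initial_condition(
      admission_diagnosis = ini$admission_diagnosis,
      expected_outcome = ini$expected_outcome,
      history = unlist(ini$history) %||% character(),
      exam = ini$exam %||% list(),
      medications = unlist(ini$medications) %||% character(),
      complexity = unlist(ini$complexity) %||% character(),
      admission_type = ini$admission_type %||% "emergency"
    )
    cl$stages <- unlist(cl$stages)
    cl$outcomes <- unlist(cl$outcomes)
    cl$transitions <- purrr::map(cl$transitions, ~ unlist(.x))
    cl
  })
  generator_spec(clusters,
                 deviation = doc$deviation %||% list(),
                 seed = seed %||% doc$seed %||%
                   abort_schema("generator spec must carry a seed"))
}
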