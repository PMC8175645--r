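# Independent oracles and fixture builders used across the suite. These
# deliberately avoid the package's own estimation code paths.

with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Build a journey-log tibble from bare (stages, outcome) paths sharing one
# admission condition.
log_from_paths <- function(paths, outcomes, expected_outcome = "out_good",
                           diagnosis = "dx") {
  if (!length(paths)) {
    return(tibble::tibble(journey_id = character(), initial = list(),
                          steps = list(), final = list(),
                          facility = character()))
  }
  dplyr::bind_rows(purrr::imap(paths, function(st, i) {
    steps <- if (length(st)) {
      dplyr::bind_rows(purrr::imap(st, ~ journey_step(.x, .y)))
    } else {
      NULL
    }
    journey(sprintf("j%04d", i),
            initial_condition(diagnosis, expected_outcome),
            steps,
            final_state(outcomes[[i]]))
  }))
}

# Random valid journey log: same cluster, random stage sequences and
# outcomes.
random_log <- function(n, seed, alphabet = paste0("s", 1:4),
                       outcome_set = c("out_good", "out_bad"),
                       max_len = 5L) {
  with_seed(seed, {
    paths <- purrr::map(seq_len(n), function(i) {
      k <- sample.int(max_len + 1L, 1L) - 1L
      if (k) sample(alphabet, k, replace = TRUE) else character()
    })
    outs <- sample(outcome_set, n, replace = TRUE)
    log_from_paths(paths, outs, expected_outcome = outcome_set[[1]])
  })
}

# Tally per-node successor frequencies straight from the raw step sequences
# (pair-counting oracle, alpha = 0).
tally_transitions <- function(journeys) {
  pairs <- purrr::map_dfr(seq_len(nrow(journeys)), function(i) {
    seqn <- c("I", journeys$steps[[i]]$action,
              paste0("OUT::", journeys$final[[i]]$outcome))
    tibble::tibble(from = seqn[-length(seqn)], to = seqn[-1])
  })
  counts <- table(pairs$from, pairs$to)
  purrr::map(rownames(counts), function(u) {
    row <- counts[u, ]
    row <- row[row > 0]
    row / sum(row)
  }) |> rlang::set_names(rownames(counts))
}

# Exhaustive path-enumeration absorption oracle for acyclic transition
# tables: named list `trans` mapping node -> named probability vector;
# targets prefixed "OUT::" are terminal.
enum_absorption <- function(trans, node) {
  if (startsWith(node, "OUT::")) {
    return(stats::setNames(1, sub("^OUT::", "", node)))
  }
  row <- trans[[node]]
  acc <- list()
  for (nxt in names(row)) {
    sub <- enum_absorption(trans, nxt)
    for (o in names(sub)) {
      acc[[o]] <- (acc[[o]] %||% 0) + row[[nxt]] * sub[[o]]
    }
  }
  unlist(acc)
}

# Monte-Carlo absorption oracle: seeded rollouts over a transition table
# (same representation as enum_absorption), supporting cycles.
mc_absorption <- function(trans, node, n, seed) {
  cum <- purrr::map(trans, cumsum)
  with_seed(seed, {
    hits <- character(n)
    for (i in seq_len(n)) {
      state <- node
      while (!startsWith(state, "OUT::")) {
        row <- cum[[state]]
        state <- names(row)[findInterval(stats::runif(1), row) + 1L]
      }
      hits[i] <- sub("^OUT::", "", state)
    }
    table(hits) / n
  })
}

# Exhaustive minimum alignment cost over all global alignments (unit costs).
brute_align_cost <- function(a, b) {
  if (!length(a)) return(length(b))
  if (!length(b)) return(length(a))
  min(
    brute_align_cost(a[-1], b[-1]) + (a[1] != b[1]),
    brute_align_cost(a[-1], b) + 1,
    brute_align_cost(a, b[-1]) + 1
  )
}

# A deterministic-backbone generator spec: one cluster whose walk is the
# fixed chain s1 -> s2 -> s3 ending in the expected outcome, so any
# deviation relative to that plan comes from injection alone.
backbone_spec <- function(seed, n, deviation = list()) {
  generator_spec(
    clusters = list(list(
      id = "backbone",
      initial = initial_condition("backbone_dx", "recovered",
                                  complexity = "none"),
      stages = c("s1", "s2", "s3"),
      outcomes = "recovered",
      transitions = list(I = c(s1 = 1), s1 = c(s2 = 1), s2 = c(s3 = 1),
                         s3 = c(recovered = 1)),
      n_journeys = n
    )),
    deviation = deviation,
    seed = seed
  )
}

backbone_pathway <- function() {
  expected_pathway("backbone_plan", c("s1", "s2", "s3"), "recovered")
}

# Ten-node recovery spec: diamond-with-remerge structure so every stage is
# visited by a large share of journeys (I, six stages, three outcomes).
recovery_spec <- function(seed, n) {
  generator_spec(
    clusters = list(list(
      id = "recovery",
      initial = initial_condition("recovery_dx", "o1"),
      stages = c("a", "b", "c", "d", "e", "f"),
      outcomes = c("o1", "o2", "o3"),
      transitions = list(
        I = c(a = 1),
        a = c(b = 0.6, c = 0.4),
        b = c(d = 1),
        c = c(d = 1),
        d = c(e = 0.5, f = 0.5),
        e = c(o1 = 0.7, o2 = 0.3),
        f = c(o1 = 0.4, o2 = 0.4, o3 = 0.2)
      ),
      n_journeys = n
    )),
    seed = seed
  )
}
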