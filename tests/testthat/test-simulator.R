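test_that("generator specs validate their transition tables", {
  bad_row <- list(list(
    id = "c", initial = initial_condition("dx", "ok"),
    stages = "s", outcomes = "ok",
    transitions = list(I = c(s = 0.6), s = c(ok = 1)), n_journeys = 1
  ))
  expect_error(generator_spec(bad_row, seed = 1), regexp = "sum to 1")
  trap <- list(list(
    id = "c", initial = initial_condition("dx", "ok"),
    stages = c("s", "trap"), outcomes = "ok",
    transitions = list(I = c(s = 1), s = c(trap = 0.5, ok = 0.5),
                       trap = c(trap = 1)),
    n_journeys = 1
  ))
  expect_error(generator_spec(trap, seed = 1), regexp = "no outcome reachable")
  ok <- list(list(
    id = "c", initial = initial_condition("dx", "ok"),
    stages = "s", outcomes = "ok",
    transitions = list(I = c(s = 1), s = c(ok = 1)), n_journeys = 3
  ))
  expect_error(generator_spec(ok), regexp = "seed")
  expect_error(generator_spec(ok, deviation = list(insertion_rate = 0.8,
                                                   substitution_rate = 0.4),
                              seed = 1))
  expect_s3_class(generator_spec(ok, seed = 1), "generator_spec")
})

test_that("a degenerate deterministic chain yields identical journeys", {
  log <- simulate_log(backbone_spec(seed = 3, n = 5))
  expect_identical(nrow(log), 5L)
  for (i in seq_len(nrow(log))) {
    expect_identical(log$steps[[i]]$action, c("s1", "s2", "s3"))
    expect_identical(log$final[[i]]$outcome, "recovered")
  }
})

test_that("the same seed reproduces a byte-identical journey log", {
  spec <- example_generator_spec(seed = 1234, n_journeys = 40)
  f1 <- withr::local_tempfile(fileext = ".jsonl")
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  write_journey_log(simulate_log(spec), f1)
  write_journey_log(simulate_log(spec), f2)
  expect_identical(readLines(f1), readLines(f2))
  # and a different seed does not
  f3 <- withr::local_tempfile(fileext = ".jsonl")
  write_journey_log(simulate_log(example_generator_spec(seed = 4321,
                                                        n_journeys = 40)), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("empirical successor frequencies match the spec within 3 sigma", {
  spec <- generator_spec(
    clusters = list(list(
      id = "abcd",
      initial = initial_condition("dx", "done"),
      stages = c("A", "B", "C", "D"),
      outcomes = "done",
      transitions = list(
        I = c(A = 1),
        A = c(B = 0.65, C = 0.25, D = 0.10),
        B = c(done = 1), C = c(done = 1), D = c(done = 1)
      ),
      n_journeys = 10000
    )),
    seed = 2024
  )
  log <- simulate_log(spec)
  nxt <- purrr::map_chr(log$steps, ~ .x$action[2])
  n <- nrow(log)
  for (target in c(B = 0.65, C = 0.25, D = 0.10) |> names()) {
    p <- c(B = 0.65, C = 0.25, D = 0.10)[[target]]
    expect_lt(abs(mean(nxt == target) - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("ground truth matches symmetry, enumeration and the estimator loop", {
  # gambler-style symmetric two-outcome chain: 0.5 absorption from the midpoint
  sym <- generator_spec(
    clusters = list(list(
      id = "sym",
      initial = initial_condition("dx", "win"),
      stages = c("L", "M", "R"),
      outcomes = c("lose", "win"),
      transitions = list(
        I = c(M = 1),
        L = c(lose = 0.5, M = 0.5),
        M = c(L = 0.5, R = 0.5),
        R = c(M = 0.5, win = 0.5)
      ),
      n_journeys = 1
    )),
    seed = 6
  )
  gt <- ground_truth(sym, "sym", "M", "outcome_distribution")
  expect_equal(gt$prob[gt$outcome == "win"], 0.5, tolerance = 1e-12)
  expect_error(ground_truth(sym, "sym", "Z"), regexp = "unknown node")
  expect_error(ground_truth(sym, "nope", "M"), regexp = "unknown cluster")

  # deterministic chain: certainty
  gt2 <- ground_truth(backbone_spec(seed = 1, n = 1), "backbone", "I",
                      "outcome_distribution")
  expect_equal(gt2$prob, 1)

  # arbitrary five-node spec against a seeded Monte-Carlo oracle
  spec <- generator_spec(
    clusters = list(list(
      id = "five",
      initial = initial_condition("dx", "ok"),
      stages = c("u", "v", "w"),
      outcomes = c("ok", "ko"),
      transitions = list(
        I = c(u = 0.8, v = 0.2),
        u = c(v = 0.5, w = 0.3, ko = 0.2),
        v = c(u = 0.3, ok = 0.7),
        w = c(w = 0.25, ok = 0.25, ko = 0.5)
      ),
      n_journeys = 1
    )),
    seed = 8
  )
  trans <- list(
    I = c(u = 0.8, v = 0.2),
    u = c(v = 0.5, w = 0.3, `OUT::ko` = 0.2),
    v = c(u = 0.3, `OUT::ok` = 0.7),
    w = c(w = 0.25, `OUT::ok` = 0.25, `OUT::ko` = 0.5)
  )
  n_mc <- 50000
  mc <- mc_absorption(trans, "I", n = n_mc, seed = 55)
  gt3 <- ground_truth(spec, "five", "I", "outcome_distribution")
  for (o in names(mc)) {
    p <- gt3$prob[gt3$outcome == o]
    expect_lt(abs(p - mc[[o]]), 3 * sqrt(p * (1 - p) / n_mc))
  }
  # transition query returns the exact spec row
  tr <- ground_truth(spec, "five", "u", "transition")
  expect_equal(sort(setNames(tr$prob, tr$to)),
               sort(c(v = 0.5, w = 0.3, ko = 0.2)))
})

test_that("the estimation loop closes: graphs recover generator parameters", {
  # scaled-down twin of the acceptance recovery run
  spec <- recovery_spec(seed = 17, n = 4000)
  log <- simulate_log(spec)
  g <- build_graph(log)
  cl <- spec$clusters[[1]]
  for (node in c("I", cl$stages)) {
    est <- transition_probs(g, node)
    want <- cl$transitions[[node]]
    visits <- sum(est$count)
    err <- abs(est$prob[match(names(want), est$to)] - unname(want))
    # per-cell binomial 3-sigma band at the node's realized visit count
    expect_lte(max(err - 3 * sqrt(want * (1 - want) / visits)), 0)
  }
  gt <- ground_truth(spec, "recovery", "I", "outcome_distribution")
  est <- outcome_distribution(g, "I")
  expect_lt(max(abs(est$prob[match(gt$outcome, est$outcome)] - gt$prob)), 0.03)
})

test_that("generator specs load from YAML with the seed overridable", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 5",
    "deviation:",
    "  insertion_rate: 0.1",
    "clusters:",
    "  - id: toy",
    "    initial:",
    "      admission_diagnosis: toy_dx",
    "      expected_outcome: better",
    "      complexity: [frail]",
    "      admission_type: elective",
    "    stages: [triage, treat]",
    "    outcomes: [better, worse]",
    "    transitions:",
    "      I: {triage: 1.0}",
    "      triage: {treat: 1.0}",
    "      treat: {better: 0.9, worse: 0.1}",
    "    n_journeys: 25"
  ), yml)
  spec <- read_generator_spec(yml)
  expect_identical(spec$seed, 5L)
  expect_identical(read_generator_spec(yml, seed = 9)$seed, 9L)
  log <- simulate_log(spec)
  expect_identical(nrow(log), 25L)
  expect_identical(log$initial[[1]]$admission_diagnosis, "toy_dx")
})
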