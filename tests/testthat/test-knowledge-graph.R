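check_count_conservation <- function(graph) {
  out_sums <- tapply(graph$edges$count, graph$edges$from, sum)
  for (i in seq_len(nrow(graph$nodes))) {
    node <- graph$nodes[i, ]
    outgoing <- out_sums[names(out_sums) == node$id]
    if (node$type == "outcome") {
      expect_length(outgoing, 0L)
    } else if (node$visits > 0L) {
      expect_identical(as.integer(outgoing), node$visits, label = node$id)
    }
  }
  expect_identical(graph$nodes$visits[graph$nodes$id == "I"], graph$n_journeys)
}

test_that("a single journey builds the minimal chain graph", {
  log <- log_from_paths(list("s1"), "out_good")
  g <- build_graph(log)
  expect_identical(nrow(g$nodes), 3L)
  expect_identical(nrow(g$edges), 2L)
  expect_true(all(g$edges$count == 1L))
  check_count_conservation(g)
  expect_error(build_graph(log[0, ]))
})

test_that("edge counts equal brute-force pair tallies over a simulated log", {
  spec <- generator_spec(
    clusters = list(list(
      id = "chain6",
      initial = initial_condition("chain_dx", "ok"),
      stages = c("u", "v", "w", "x"),
      outcomes = c("ok", "ko"),
      transitions = list(
        I = c(u = 0.7, v = 0.3),
        u = c(v = 0.5, w = 0.5),
        v = c(w = 0.6, x = 0.4),
        w = c(x = 0.5, ok = 0.5),
        x = c(ok = 0.7, ko = 0.3)
      ),
      n_journeys = 500
    )),
    seed = 99
  )
  log <- simulate_log(spec)
  g <- build_graph(log)
  oracle <- tally_transitions(log)
  for (node in names(oracle)) {
    if (startsWith(node, "OUT::")) next
    user_node <- if (node == "I") "I" else node
    got <- transition_probs(g, user_node)
    want <- oracle[[node]]
    names(want) <- sub("^OUT::", "", names(want))
    expect_setequal(got$to, names(want))
    expect_equal(got$prob[match(names(want), got$to)], unname(want),
                 tolerance = 1e-12)
  }
  check_count_conservation(g)
})

test_that("transition smoothing follows (count + alpha) / (visits + alpha * S)", {
  # counts B:3, C:1 out of a node visited 4 times
  log <- log_from_paths(c(rep(list(c("a", "B")), 3), list(c("a", "C"))),
                        rep("out_good", 4))
  g0 <- build_graph(log, alpha = 0)
  p0 <- transition_probs(g0, "a")
  expect_equal(p0$prob[p0$to == "B"], 0.75)
  g1 <- build_graph(log, alpha = 1)
  p1 <- transition_probs(g1, "a")
  expect_equal(p1$prob[p1$to == "B"], 4 / 6)
  expect_equal(p1$prob[p1$to == "C"], 2 / 6)
  expect_equal(sum(p1$prob), 1, tolerance = 1e-12)
  # a single-successor node has probability 1 under any alpha
  for (alpha in c(0, 0.5, 3)) {
    p <- transition_probs(build_graph(log, alpha = alpha), "B")
    expect_equal(p$prob, 1)
  }
  # terminal nodes have no successors
  expect_error(transition_probs(g0, "out_good"), regexp = "terminal")
  expect_error(transition_probs(g0, "nowhere"))
})

test_that("incremental updates are field-exactly the batch rebuild", {
  # 20 random logs here; the acceptance suite scales this property to 200
  for (seed in 1:20) {
    log <- random_log(1 + (seed %% 10), seed = seed)
    batch <- build_graph(log)
    inc <- empty_graph(cluster = batch$cluster)
    for (i in seq_len(nrow(log))) inc <- add_journey(inc, log[i, ])
    expect_identical(inc$nodes, batch$nodes)
    expect_identical(inc$edges, batch$edges)
    expect_identical(inc$n_journeys, batch$n_journeys)
    check_count_conservation(inc)
  }
})

test_that("add_journey grows the graph consistently", {
  log <- log_from_paths(list("s1"), "out_good")
  g <- build_graph(log)
  # novel stage label creates a node and keeps invariants
  extra <- log_from_paths(list(c("s1", "brand_new_stage")), "out_bad")
  g2 <- add_journey(g, extra)
  expect_true("brand_new_stage" %in% g2$nodes$label)
  expect_identical(g2$n_journeys, 2L)
  check_count_conservation(g2)
  # cluster mismatch is refused
  alien <- log_from_paths(list("s1"), "out_good", diagnosis = "other_dx")
  expect_error(add_journey(g, alien), regexp = "cluster")
})

test_that("outcome distributions match the exhaustive path-enumeration oracle", {
  # linear chain: certainty from every node
  chain <- build_graph(log_from_paths(list(c("s1", "s2")), "out_good"))
  for (node in c("I", "s1", "s2")) {
    d <- outcome_distribution(chain, node)
    expect_equal(d$prob, 1)
    expect_identical(d$outcome, "out_good")
  }
  # acyclic branching graphs against enumeration, several random logs
  for (seed in c(3, 4, 5)) {
    log <- with_seed(seed, {
      paths <- purrr::map(1:40, function(i) {
        # strictly increasing stage indices keep the graph acyclic
        idx <- sort(sample.int(4, sample.int(4, 1)))
        paste0("s", idx)
      })
      log_from_paths(paths, sample(c("out_good", "out_bad"), 40, TRUE))
    })
    g <- build_graph(log)
    trans <- tally_transitions(log)
    for (node in names(trans)) {
      user_node <- if (node == "I") "I" else node
      want <- enum_absorption(trans, node)
      got <- outcome_distribution(g, user_node)
      expect_equal(sum(got$prob), 1, tolerance = 1e-9)
      expect_equal(got$prob[match(names(want), got$outcome)], unname(want),
                   tolerance = 1e-9)
    }
  }
})

test_that("cyclic absorption equals the linear-solve value and Monte-Carlo", {
  # wandering between ward and icu before discharge or death: the
  # icu -> ward edge makes the chain cyclic
  paths <- c(
    rep(list(c("ward")), 5),
    rep(list(c("ward", "icu")), 2),
    rep(list(c("ward", "icu", "ward")), 2),
    list(c("ward", "icu", "ward", "icu"))
  )
  outs <- c(rep("discharged", 5), rep("deceased", 2), rep("discharged", 2),
            "deceased")
  log <- log_from_paths(paths, outs, expected_outcome = "discharged")
  g <- build_graph(log)
  got <- outcome_distribution(g, "I")
  emp <- tally_transitions(log)
  mc <- mc_absorption(emp, "I", n = 20000, seed = 77)
  for (o in names(mc)) {
    p <- got$prob[got$outcome == o]
    expect_lt(abs(p - mc[[o]]), 3 * sqrt(p * (1 - p) / 20000))
  }
  expect_equal(sum(got$prob), 1, tolerance = 1e-9)
})

test_that("risk is one minus the absorption probability of the expected outcome", {
  # two-outcome graph, counts 9 expected / 1 other straight from admission
  log <- log_from_paths(rep(list(character()), 10),
                        c(rep("out_good", 9), "out_bad"))
  g <- build_graph(log)
  rp <- risk_profile(g, "I", "out_good")
  expect_equal(rp$risk, 0.1)
  expect_true(rp$expected_outcome_seen)
  # all journeys as expected: zero risk
  g0 <- build_graph(log_from_paths(rep(list("s1"), 4), rep("out_good", 4)))
  expect_equal(risk_profile(g0, "I", "out_good")$risk, 0)
  # expected outcome never observed: risk 1 plus a warning
  expect_warning(rp1 <- risk_profile(g0, "I", "never_seen"),
                 regexp = "never observed")
  expect_equal(rp1$risk, 1)
  expect_false(rp1$expected_outcome_seen)
})

test_that("adding an expected-outcome journey never increases initial risk", {
  for (seed in 1:25) {
    log <- random_log(3 + (seed %% 10), seed = 100 + seed)
    g <- build_graph(log)
    risk0 <- suppressWarnings(risk_profile(g, "I", "out_good")$risk)
    new_j <- with_seed(seed, {
      k <- sample.int(4, 1) - 1L
      st <- if (k) sample(paste0("s", 1:4), k, TRUE) else character()
      log_from_paths(list(st), "out_good")
    })
    new_j$journey_id <- "appended"
    risk1 <- risk_profile(add_journey(g, new_j), "I", "out_good")$risk
    expect_lte(risk1, risk0 + 1e-12)
  }
})

test_that("next_step_distribution is the percent view of transition_probs", {
  g <- build_graph(extension_example_log())
  nxt <- next_step_distribution(g, "stage_A")
  tp <- transition_probs(g, "stage_A")
  expect_equal(nxt$prob, tp$prob)
  expect_equal(nxt$percent, 100 * tp$prob)
  expect_error(next_step_distribution(g, "discharged"), regexp = "terminal")
  # uniform four-way split
  ulog <- log_from_paths(purrr::map(1:4, ~ c("hub", paste0("spoke", .x))),
                         rep("out_good", 4))
  un <- next_step_distribution(build_graph(ulog), "hub")
  expect_equal(un$percent, rep(25, 4))
  out <- capture.output(print(nxt))
  expect_match(out, "stage_B 65.0%", all = FALSE, fixed = TRUE)
})

test_that("graph export round-trips counts and marks one terminal per outcome", {
  log <- simulate_log(example_generator_spec(seed = 5, n_journeys = 40))
  g <- build_graph(partition_journeys(log)[[1]])
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, gml, "graphml")
  ig <- igraph::read_graph(gml, format = "graphml")
  expect_identical(sort(igraph::E(ig)$count),
                   sort(as.numeric(g$edges$count)))
  n_out <- sum(igraph::V(ig)$type == "outcome")
  expect_identical(n_out, sum(g$nodes$type == "outcome"))

  dot <- withr::local_tempfile(fileext = ".dot")
  chain <- build_graph(log_from_paths(list("s1"), "out_good"))
  export_graph(chain, dot, "dot")
  txt <- readLines(dot)
  expect_true(any(grepl("prob", txt)))  # edges carry probability annotations
  expect_error(export_graph(chain, dot, "gexf"))
})

test_that("knowledge bases serialize counts-only and round-trip", {
  log <- simulate_log(example_generator_spec(seed = 8, n_journeys = 30))
  graphs <- purrr::map(partition_journeys(log), build_graph)
  path <- withr::local_tempfile(fileext = ".json")
  write_knowledge_base(graphs, path)
  back <- read_knowledge_base(path)
  expect_identical(names(back), names(graphs))
  for (k in names(graphs)) {
    expect_identical(back[[k]]$nodes, graphs[[k]]$nodes)
    expect_identical(back[[k]]$edges, graphs[[k]]$edges)
    expect_identical(back[[k]]$n_journeys, graphs[[k]]$n_journeys)
  }
  # probabilities are derived, not stored
  expect_false(any(grepl('"prob"', readLines(path))))
})

test_that("tidiers and autoplot cover the graph result types", {
  g <- build_graph(extension_example_log())
  td <- tidy(g)
  expect_identical(nrow(td), nrow(g$edges))
  expect_equal(sum(td$prob[td$from == "stage_A"]), 1)
  gl <- glance(g)
  expect_identical(gl$n_journeys, 100L)
  expect_s3_class(autoplot(g), "ggplot")
  rp <- risk_profile(g, "I", "discharged")
  expect_s3_class(autoplot(rp), "ggplot")
  expect_identical(glance(rp)$risk, 0)
})

test_that("order-2 history and step-param keying refine node identity", {
  # order matters: (a,b) always recovers, (c,b) never does
  log <- log_from_paths(
    c(rep(list(c("a", "b")), 3), rep(list(c("c", "b")), 3)),
    c(rep("out_good", 3), rep("out_bad", 3))
  )
  g1 <- build_graph(log)
  d1 <- outcome_distribution(g1, "b")
  expect_equal(d1$prob[d1$outcome == "out_good"], 0.5)
  g2 <- build_graph(log, history_order = 2)
  d2 <- outcome_distribution(g2, "a>b")
  expect_equal(d2$prob, 1)
  expect_identical(d2$outcome, "out_good")
  # incremental updates respect the graph's history order
  inc <- empty_graph(cluster = g2$cluster, history_order = 2)
  for (i in seq_len(nrow(log))) inc <- add_journey(inc, log[i, ])
  expect_identical(inc$nodes, g2$nodes)
  expect_identical(inc$edges, g2$edges)

  # folding a step parameter into node identity splits the stage node
  plog <- dplyr::bind_rows(
    journey("p1", initial_condition("dx", "out_good"),
            journey_step("surgery", 1, params = list(grade = "minor")),
            final_state("out_good")),
    journey("p2", initial_condition("dx", "out_good"),
            journey_step("surgery", 1, params = list(grade = "major")),
            final_state("out_bad"))
  )
  gp <- build_graph(plog, node_params = "grade")
  expect_true(all(c("surgery[grade:minor]", "surgery[grade:major]") %in%
                    gp$nodes$label))
  dmaj <- outcome_distribution(gp, "surgery[grade:major]")
  expect_identical(dmaj$outcome, "out_bad")
})
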