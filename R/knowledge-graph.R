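# Internal node-id scheme: the single initial node is "I"; stage nodes are
# "s:<label>"; terminal outcome nodes are "o:<label>". Stage and outcome
# labels therefore never collide even if equal as strings. User-facing
# functions accept "I" or a bare stage label and return bare labels.

node_id_stage <- function(label) paste0("s:", label)
node_id_outcome <- function(label) paste0("o:", label)

node_label <- function(id) sub("^[so]:", "", id)

node_type <- function(id) {
  dplyr::case_when(
    id == "I" ~ "initial",
    startsWith(id, "s:") ~ "stage",
    startsWith(id, "o:") ~ "outcome"
  )
}

stage_node_labels <- function(steps, history_order, node_params) {
  labels <- steps$action
  if (length(node_params) && nrow(steps)) {
    extra <- purrr::map_chr(steps$params, function(p) {
      vals <- p[intersect(node_params, names(p))]
      if (!length(vals)) return("")
      paste0("[", paste(names(vals), purrr::map_chr(vals, as.character),
                        sep = ":", collapse = ";"), "]")
    })
    labels <- paste0(labels, extra)
  }
  if (history_order >= 2L && length(labels)) {
    labels <- paste(c("I", head(labels, -1)), labels, sep = ">")
  }
  labels
}

journey_node_path <- function(journeys, i, history_order = 1L,
                              node_params = character()) {
  c("I",
    node_id_stage(stage_node_labels(journeys$steps[[i]], history_order,
                                    node_params)),
    node_id_outcome(journeys$final[[i]]$outcome))
}

# Canonical ordering makes incremental updates field-exactly equal to batch
# rebuilds.
normalize_graph <- function(graph) {
  type_rank <- c(initial = 1L, stage = 2L, outcome = 3L)
  graph$nodes <- dplyr::arrange(graph$nodes, type_rank[.data$type], .data$label)
  graph$edges <- dplyr::arrange(graph$edges, .data$from, .data$to)
  graph
}

#' Build the knowledge graph of a journey cluster
#'
#' Tallies a cohort of journeys into a directed multigraph: one initial node,
#' one node per distinct stage label, one terminal node per distinct outcome
#' label. Edge counts are the number of observed consecutive transitions
#' (admission to first step, step to step, last step to outcome; admission
#' directly to outcome for step-less journeys). Node visits count occurrences,
#' so for every non-terminal node the outgoing edge counts sum exactly to its
#' visits. The graph, interrogated as a first-order absorbing Markov chain, is
#' the cluster's knowledge base.
#'
#' @param journeys A journey-log tibble; all journeys must share one cluster
#'   key (partition first with [partition_journeys()]).
#' @param alpha Nonnegative additive-smoothing pseudo-count applied, at query
#'   time, over a node's *observed* successors only. The default `0` is the
#'   pure maximum-likelihood estimate of the closed world; no phantom edges
#'   are ever created.
#' @param key_fields Cluster-key fields used to check homogeneity and label
#'   the graph; `NULL` skips the check (useful for ad-hoc logs).
#' @param history_order `1` (default) keys nodes on the stage label alone —
#'   the first-order Markov reading. `2` augments node identity with the
#'   previous stage label (`"prev>curr"`), a sensitivity handle for data with
#'   longer memory; queries then address the compound labels.
#' @param node_params Optional character vector of step-parameter names to
#'   fold into node identity (e.g. distinguishing a stage by severity grade).
#'   Off by default: keying on full payloads would shatter the graph.
#' @return An object of class `knowledge_graph` with tibble fields `nodes`
#'   (`id`, `label`, `type`, `visits`) and `edges` (`from`, `to`, `count`).
#' @examples
#' g <- build_graph(extension_example_log())
#' transition_probs(g, "stage_A")
#' @export
build_graph <- function(journeys, alpha = 0,
                        key_fields = c("admission_diagnosis", "complexity"),
                        history_order = 1L, node_params = character()) {
  validate_journeys(journeys)
  if (!nrow(journeys)) abort("cannot build a knowledge graph from an empty journey log")
  if (alpha < 0) abort("`alpha` must be nonnegative")
  cluster <- NA_character_
  if (!is.null(key_fields)) {
    keys <- unique(purrr::map2_chr(journeys$initial, journeys$facility,
                                   cluster_key, key_fields = key_fields))
    if (length(keys) > 1L) {
      abort(sprintf(
        "journeys span %d clusters; partition the log before building a graph",
        length(keys)))
    }
    cluster <- keys
  }
  paths <- purrr::map(seq_len(nrow(journeys)), journey_node_path,
                      journeys = journeys, history_order = history_order,
                      node_params = node_params)
  edge_df <- dplyr::bind_rows(purrr::map(paths, function(p) {
    tibble(from = p[-length(p)], to = p[-1])
  }))
  edges <- dplyr::count(edge_df, .data$from, .data$to, name = "count")
  ids <- unique(c(unlist(paths, use.names = FALSE)))
  arrivals <- dplyr::count(edge_df, .data$to, name = "visits")
  nodes <- tibble(id = ids) |>
    dplyr::left_join(arrivals, by = c(id = "to")) |>
    dplyr::mutate(
      visits = dplyr::if_else(.data$id == "I", nrow(journeys),
                              dplyr::coalesce(.data$visits, 0L)),
      label = node_label(.data$id),
      type = node_type(.data$id)
    ) |>
    dplyr::select("id", "label", "type", "visits")
  graph <- structure(
    list(cluster = cluster, key_fields = key_fields, nodes = nodes,
         edges = edges, n_journeys = nrow(journeys), alpha = alpha,
         history_order = as.integer(history_order),
         node_params = as.character(node_params)),
    class = "knowledge_graph"
  )
  normalize_graph(graph)
}

#' Add a journey to an existing knowledge graph
#'
#' Increments node and edge counts in place, so a knowledge base can grow as
#' new journeys are recorded without rebuilding. The result is field-exactly
#' identical to [build_graph()] on the extended log.
#'
#' @param graph A `knowledge_graph`.
#' @param journey A one-row journey-log tibble whose cluster key equals the
#'   graph's cluster.
#' @return The updated `knowledge_graph`.
#' @export
add_journey <- function(graph, journey) {
  stopifnot(inherits(graph, "knowledge_graph"))
  validate_journeys(journey)
  if (nrow(journey) != 1L) abort("`journey` must be a one-row journey log")
  if (!is.null(graph$key_fields)) {
    key <- cluster_key(journey$initial[[1]], graph$key_fields,
                       journey$facility[[1]])
    if (!identical(key, graph$cluster)) {
      abort(sprintf("journey belongs to cluster '%s', not the graph's '%s'",
                    key, graph$cluster))
    }
  }
  path <- journey_node_path(journey, 1L, graph$history_order %||% 1L,
                            graph$node_params %||% character())
  new_edges <- dplyr::count(tibble(from = path[-length(path)], to = path[-1]),
                            .data$from, .data$to, name = "add")
  graph$edges <- dplyr::full_join(graph$edges, new_edges, by = c("from", "to")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L) +
                    dplyr::coalesce(.data$add, 0L)) |>
    dplyr::select("from", "to", "count")
  new_visits <- dplyr::count(tibble(id = path[-1]), .data$id, name = "add")
  graph$nodes <- dplyr::full_join(graph$nodes, new_visits, by = "id") |>
    dplyr::mutate(
      visits = dplyr::coalesce(.data$visits, 0L) +
        dplyr::if_else(.data$id == "I", 1L, dplyr::coalesce(.data$add, 0L)),
      label = node_label(.data$id),
      type = node_type(.data$id)
    ) |>
    dplyr::select("id", "label", "type", "visits")
  if (!"I" %in% graph$nodes$id) {
    graph$nodes <- dplyr::bind_rows(
      tibble(id = "I", label = "I", type = "initial", visits = 1L),
      graph$nodes
    )
  }
  graph$n_journeys <- graph$n_journeys + 1L
  normalize_graph(graph)
}

#' An empty knowledge graph for incremental construction
#'
#' @param cluster Cluster-key string the graph will accumulate (or `NA`).
#' @inheritParams build_graph
#' @return A `knowledge_graph` with zero journeys.
#' @export
empty_graph <- function(cluster = NA_character_, alpha = 0,
                        key_fields = c("admission_diagnosis", "complexity"),
                        history_order = 1L, node_params = character()) {
  structure(
    list(cluster = cluster, key_fields = if (is.na(cluster)) NULL else key_fields,
         nodes = tibble(id = character(), label = character(),
                        type = character(), visits = integer()),
         edges = tibble(from = character(), to = character(), count = integer()),
         n_journeys = 0L, alpha = alpha,
         history_order = as.integer(history_order),
         node_params = as.character(node_params)),
    class = "knowledge_graph"
  )
}

resolve_node <- function(graph, node) {
  if (!is_string(node)) abort("`node` must be a single node label")
  if (node %in% graph$nodes$id) return(node)
  sid <- node_id_stage(node)
  if (sid %in% graph$nodes$id) return(sid)
  oid <- node_id_outcome(node)
  if (oid %in% graph$nodes$id) return(oid)
  abort(sprintf("node '%s' is not in the knowledge graph", node))
}

smoothed_probs <- function(graph, id) {
  out <- dplyr::filter(graph$edges, .data$from == id)
  if (!nrow(out)) {
    if (node_type(id) == "outcome") {
      abort(sprintf("'%s' is a terminal outcome node and has no successors",
                    node_label(id)))
    }
    abort(sprintf("node '%s' has no observed successors", node_label(id)))
  }
  visits <- graph$nodes$visits[match(id, graph$nodes$id)]
  if (visits == 0L && graph$alpha == 0) {
    abort(sprintf("node '%s' is unvisited and alpha = 0", node_label(id)))
  }
  s <- nrow(out)
  dplyr::mutate(out, prob = (.data$count + graph$alpha) /
                  (visits + graph$alpha * s))
}

#' Transition probabilities out of a node
#'
#' The probability of each observed successor of a node, estimated as
#' `(count + alpha) / (visits + alpha * S)` where `S` is the number of
#' observed successors of the node. With the default `alpha = 0` this is the
#' maximum-likelihood estimate; probabilities always sum to one.
#'
#' @param graph A `knowledge_graph`.
#' @param node `"I"` for the initial node, or a stage label.
#' @return A tibble with columns `to` (successor label), `type` (`"stage"` or
#'   `"outcome"`), `count` and `prob`, ordered by decreasing probability.
#' @export
transition_probs <- function(graph, node) {
  stopifnot(inherits(graph, "knowledge_graph"))
  id <- resolve_node(graph, node)
  if (node_type(id) == "outcome") {
    abort(sprintf("'%s' is a terminal outcome node and has no successors", node))
  }
  smoothed_probs(graph, id) |>
    dplyr::transmute(to = node_label(.data$to), type = node_type(.data$to),
                     count = .data$count, prob = .data$prob) |>
    dplyr::arrange(dplyr::desc(.data$prob), .data$to)
}

#' Next-step probability distribution
#'
#' The step-ahead view of [transition_probs()]: from the patient's current
#' stage, with what probability does the journey move to each possible next
#' stage or outcome? Identical estimates, presented with a percentage column
#' and a percent-formatted print method.
#'
#' @inheritParams transition_probs
#' @return A tibble with columns `to`, `type`, `count`, `prob`, `percent`, of
#'   class `next_step_distribution`.
#' @examples
#' g <- build_graph(extension_example_log())
#' next_step_distribution(g, "stage_A")
#' @export
next_step_distribution <- function(graph, node) {
  out <- transition_probs(graph, node)
  out <- dplyr::mutate(out, percent = 100 * .data$prob)
  class(out) <- c("next_step_distribution", class(out))
  attr(out, "from_node") <- node
  out
}

#' @export
print.next_step_distribution <- function(x, ...) {
  cat(sprintf("Next step from '%s':\n", attr(x, "from_node")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %s %.1f%%\n", x$to[[i]], x$percent[[i]]))
  }
  invisible(x)
}

# Transition matrix of the reachable sub-chain from `id`, with smoothing.
reachable_chain <- function(graph, id) {
  succ <- split(graph$edges$to, graph$edges$from)
  seen <- character()
  frontier <- id
  while (length(frontier)) {
    seen <- c(seen, frontier)
    nxt <- unique(unlist(succ[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
  }
  nodes <- graph$nodes[graph$nodes$id %in% seen, ]
  transient <- nodes$id[nodes$type != "outcome"]
  terminal <- nodes$id[nodes$type == "outcome"]
  if (!length(terminal)) {
    abort(sprintf(
      "no terminal outcome is reachable from node '%s'; the log looks truncated",
      node_label(id)))
  }
  P <- matrix(0, nrow = length(transient), ncol = length(c(transient, terminal)),
              dimnames = list(transient, c(transient, terminal)))
  for (u in transient) {
    pr <- smoothed_probs(graph, u)
    P[u, pr$to] <- pr$prob
  }
  list(transient = transient, terminal = terminal,
       Q = P[, transient, drop = FALSE], R = P[, terminal, drop = FALSE])
}

# Absorption probabilities B solve (I - Q) B = R. Falls back to damped
# fixed-point iteration if the direct solve reports singularity.
solve_absorption <- function(Q, R, tol = 1e-12) {
  A <- diag(nrow(Q)) - Q
  B <- tryCatch(solve(A, R, tol = tol), error = function(e) NULL)
  if (is.null(B)) {
    B <- matrix(0, nrow = nrow(R), ncol = ncol(R), dimnames = dimnames(R))
    damp <- 0.5
    for (iter in seq_len(100000L)) {
      Bn <- damp * (Q %*% B + R) + (1 - damp) * B
      if (max(abs(Bn - B)) < tol) return(Bn)
      B <- Bn
    }
    warn("absorption fixed-point iteration did not fully converge")
  }
  B
}

#' Outcome (absorption) probability distribution from a node
#'
#' The probability that a journey currently at `node` terminates in each
#' outcome, under the first-order Markov chain whose transition probabilities
#' are the graph's (smoothed) estimates. For a terminal node `t` the
#' distribution is a point mass on `t`; for every other node `u` the
#' probabilities satisfy `b_u = sum_v P(u -> v) b_v` and are obtained by a
#' linear solve, so cyclic graphs (stage revisits) are supported exactly.
#'
#' @inheritParams transition_probs
#' @return A tibble with columns `outcome` and `prob`, summing to one, sorted
#'   by outcome label.
#' @export
outcome_distribution <- function(graph, node) {
  stopifnot(inherits(graph, "knowledge_graph"))
  id <- resolve_node(graph, node)
  if (node_type(id) == "outcome") {
    return(tibble(outcome = node_label(id), prob = 1))
  }
  chain <- reachable_chain(graph, id)
  # every reachable transient node must itself reach a terminal: detect by
  # checking that absorption rows sum to 1
  B <- solve_absorption(chain$Q, chain$R)
  if (any(abs(rowSums(B) - 1) > 1e-6)) {
    abort(sprintf(
      "some stages reachable from '%s' cannot reach any outcome; the log looks truncated",
      node_label(id)))
  }
  tibble(outcome = node_label(chain$terminal), prob = as.numeric(B[id, ])) |>
    dplyr::arrange(.data$outcome)
}

#' Risk profile of a patient at a node
#'
#' The health risk at a node is the probability of ending the journey in any
#' final condition other than the expected one:
#' `risk = 1 - P(absorb in expected outcome | current node)`. If the expected
#' outcome has never been observed as a terminal of this cluster's graph the
#' risk is 1 and a warning flag is raised.
#'
#' @inheritParams transition_probs
#' @param expected_outcome The outcome label expected on admission (recorded
#'   in the patient's initial condition).
#' @return An object of class `risk_profile`: a list with `from_node`,
#'   `outcome_probs` (tibble), `expected_outcome`, `risk` and
#'   `expected_outcome_seen`.
#' @examples
#' g <- build_graph(extension_example_log())
#' risk_profile(g, "I", "discharged")
#' @export
risk_profile <- function(graph, node, expected_outcome) {
  if (!is_string(expected_outcome)) {
    abort("`expected_outcome` must be a single non-empty string")
  }
  probs <- outcome_distribution(graph, node)
  seen <- expected_outcome %in% probs$outcome
  risk <- if (seen) 1 - probs$prob[probs$outcome == expected_outcome] else 1
  if (!seen) {
    warn(sprintf(
      "expected outcome '%s' was never observed in this cluster; risk set to 1",
      expected_outcome))
  }
  structure(
    list(from_node = node, outcome_probs = probs,
         expected_outcome = expected_outcome, risk = as.numeric(risk),
         expected_outcome_seen = seen),
    class = "risk_profile"
  )
}

#' @export
print.risk_profile <- function(x, ...) {
  cat(sprintf("<risk_profile> from '%s', expected outcome '%s'\n",
              x$from_node, x$expected_outcome))
  for (i in seq_len(nrow(x$outcome_probs))) {
    cat(sprintf("  p(%s) = %.4f\n", x$outcome_probs$outcome[[i]],
                x$outcome_probs$prob[[i]]))
  }
  cat(sprintf("  risk of missing expected outcome: %.4f%s\n", x$risk,
              if (x$expected_outcome_seen) "" else " (expected outcome unobserved)"))
  invisible(x)
}

#' @export
print.knowledge_graph <- function(x, ...) {
  n_stage <- sum(x$nodes$type == "stage")
  n_out <- sum(x$nodes$type == "outcome")
  cat(sprintf("<knowledge_graph> cluster: %s\n", x$cluster))
  cat(sprintf("  %d journeys | %d stage nodes | %d outcomes | %d edges | alpha = %g\n",
              x$n_journeys, n_stage, n_out, nrow(x$edges), x$alpha))
  invisible(x)
}

as_igraph <- function(graph) {
  edges <- graph$edges
  probs <- dplyr::bind_rows(purrr::map(unique(edges$from),
                                       function(u) smoothed_probs(graph, u)))
  edges <- dplyr::left_join(edges, dplyr::select(probs, "from", "to", "prob"),
                            by = c("from", "to"))
  igraph::graph_from_data_frame(
    d = edges,
    vertices = dplyr::transmute(graph$nodes, name = .data$id,
                                label = .data$label, type = .data$type,
                                visits = .data$visits)
  )
}

#' Export a knowledge graph for external tooling
#'
#' Writes the graph with node annotations (`label`, `type`, `visits`) and edge
#' annotations (`count`, `prob`) in GraphML or DOT, for rendering or
#' interchange with standard graph tools.
#'
#' @param graph A `knowledge_graph`.
#' @param path Output file.
#' @param format `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "dot")) {
  stopifnot(inherits(graph, "knowledge_graph"))
  format <- match.arg(format)
  if (!nrow(graph$edges)) abort("cannot export an empty knowledge graph")
  ig <- as_igraph(graph)
  igraph::write_graph(ig, path, format = format)
  invisible(path)
}

# ---- knowledge-base serialization (counts only; probabilities derived) ------

kb_schema_version <- "1"

#' Write / read a serialized knowledge base
#'
#' A knowledge base is a set of per-cluster knowledge graphs. It is stored as
#' a versioned JSON document carrying counts only — transition probabilities
#' are always derived at query time, so the smoothing `alpha` can change
#' without rebuilding.
#'
#' @param graphs A named list of `knowledge_graph` objects (names are cluster
#'   keys), e.g. `purrr::map(partition_journeys(log), build_graph)`.
#' @param path File path for the JSON document.
#' @return `write_knowledge_base()` returns `path` invisibly;
#'   `read_knowledge_base()` returns the named list of graphs.
#' @export
write_knowledge_base <- function(graphs, path) {
  stopifnot(is.list(graphs), all(purrr::map_lgl(graphs, inherits, "knowledge_graph")))
  doc <- list(
    schema_version = kb_schema_version,
    graphs = purrr::map(graphs, function(g) {
      list(
        cluster = if (is.na(g$cluster)) NULL else g$cluster,
        key_fields = as.list(g$key_fields %||% list()),
        alpha = g$alpha,
        history_order = g$history_order %||% 1L,
        node_params = as.list(g$node_params %||% character()),
        n_journeys = g$n_journeys,
        nodes = purrr::pmap(g$nodes, function(id, label, type, visits) {
          list(id = id, label = label, type = type, visits = visits)
        }),
        edges = purrr::pmap(g$edges, function(from, to, count) {
          list(from = from, to = to, count = count)
        })
      )
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_knowledge_base
#' @export
read_knowledge_base <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("knowledge base '%s' does not exist", path))
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(as.character(doc$schema_version), kb_schema_version)) {
    abort_schema(sprintf("unknown knowledge-base schema_version '%s'",
                         doc$schema_version))
  }
  purrr::map(doc$graphs, function(g) {
    key_fields <- unlist(g$key_fields) %||% NULL
    graph <- structure(
      list(
        cluster = g$cluster %||% NA_character_,
        key_fields = if (length(key_fields)) as.character(key_fields) else NULL,
        nodes = dplyr::bind_rows(purrr::map(g$nodes, function(n) {
          tibble(id = n$id, label = n$label, type = n$type,
                 visits = as.integer(n$visits))
        })),
        edges = dplyr::bind_rows(purrr::map(g$edges, function(e) {
          tibble(from = e$from, to = e$to, count = as.integer(e$count))
        })),
        n_journeys = as.integer(g$n_journeys),
        alpha = as.numeric(g$alpha),
        history_order = as.integer(g$history_order %||% 1L),
        node_params = as.character(unlist(g$node_params) %||% character())
      ),
      class = "knowledge_graph"
    )
    normalize_graph(graph)
  })
}
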