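# broom-style tidiers and ggplot2 autoplot methods for the package's result
# types.

#' Tidy a knowledge graph into its edge table
#'
#' @param x A `knowledge_graph`.
#' @param ... Unused.
#' @return A tibble with one row per edge: `from`, `from_type`, `to`,
#'   `to_type`, `count`, `prob` (smoothed with the graph's alpha).
#' @exportS3Method generics::tidy
tidy.knowledge_graph <- function(x, ...) {
  probs <- dplyr::bind_rows(purrr::map(unique(x$edges$from),
                                       function(u) smoothed_probs(x, u)))
  dplyr::transmute(
    probs,
    from = node_label(.data$from), from_type = node_type(.data$from),
    to = node_label(.data$to), to_type = node_type(.data$to),
    count = .data$count, prob = .data$prob
  ) |>
    dplyr::arrange(.data$from_type != "initial", .data$from, .data$to)
}

#' @rdname tidy.knowledge_graph
#' @exportS3Method generics::glance
glance.knowledge_graph <- function(x, ...) {
  tibble(
    cluster = x$cluster,
    n_journeys = x$n_journeys,
    n_stages = sum(x$nodes$type == "stage"),
    n_outcomes = sum(x$nodes$type == "outcome"),
    n_edges = nrow(x$edges),
    alpha = x$alpha
  )
}

#' Tidy a risk profile
#'
#' @param x A `risk_profile`.
#' @param ... Unused.
#' @return The outcome-probability tibble with an `expected` flag column.
#' @exportS3Method generics::tidy
tidy.risk_profile <- function(x, ...) {
  dplyr::mutate(x$outcome_probs, expected = .data$outcome == x$expected_outcome)
}

#' @rdname tidy.risk_profile
#' @exportS3Method generics::glance
glance.risk_profile <- function(x, ...) {
  tibble(from_node = x$from_node, expected_outcome = x$expected_outcome,
         risk = x$risk, n_outcomes = nrow(x$outcome_probs),
         expected_outcome_seen = x$expected_outcome_seen)
}

#' Tidy a deviation alignment or report
#'
#' @param x A `deviation_alignment` or `deviation_report`.
#' @param ... Unused.
#' @return The alignment tibble with a `position` column.
#' @exportS3Method generics::tidy
tidy.deviation_alignment <- function(x, ...) {
  dplyr::mutate(x$alignment, position = dplyr::row_number(),
                .before = "planned")
}

#' @rdname tidy.deviation_alignment
#' @exportS3Method generics::glance
glance.deviation_alignment <- function(x, ...) {
  out <- tibble(n_match = x$n_match, n_sub = x$n_sub, n_ins = x$n_ins,
                n_del = x$n_del, edit_distance = x$edit_distance)
  if (inherits(x, "deviation_report")) {
    out <- dplyr::mutate(out, journey_id = x$journey_id,
                         outcome_match = x$outcome_match,
                         deviation_type = x$deviation_type,
                         .before = "n_match")
  }
  out
}

#' Tidy a fitted risk predictor
#'
#' @param x A `risk_predictor`.
#' @param ... Unused.
#' @return For the default ridge-logistic learner, a tibble of feature
#'   coefficients; otherwise an empty tibble.
#' @exportS3Method generics::tidy
tidy.risk_predictor <- function(x, ...) {
  if (inherits(x$model, "glmnet")) {
    co <- as.matrix(stats::coef(x$model))
    tibble(term = rownames(co), estimate = as.numeric(co[, 1]))
  } else {
    tibble(term = character(), estimate = numeric())
  }
}

#' @rdname tidy.risk_predictor
#' @exportS3Method generics::glance
glance.risk_predictor <- function(x, ...) {
  dplyr::mutate(x$metrics, learner = x$learner$name, base_rate = x$base_rate)
}

#' Plot a knowledge graph
#'
#' Draws the cluster's journey graph left-to-right from admission to
#' outcomes, edge width proportional to transition probability.
#'
#' @param object A `knowledge_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.knowledge_graph <- function(object, ...) {
  ig <- as_igraph(object)
  lay <- igraph::layout_with_sugiyama(ig)$layout
  nodes <- dplyr::mutate(object$nodes, x = lay[, 2], y = lay[, 1])
  edges <- tidy.knowledge_graph(object) |>
    dplyr::mutate(
      from_id = ifelse(.data$from_type == "initial", "I",
                       ifelse(.data$from_type == "stage",
                              node_id_stage(.data$from), node_id_outcome(.data$from))),
      to_id = ifelse(.data$to_type == "stage", node_id_stage(.data$to),
                     node_id_outcome(.data$to))
    ) |>
    dplyr::left_join(dplyr::select(nodes, "id", x0 = "x", y0 = "y"),
                     by = c(from_id = "id")) |>
    dplyr::left_join(dplyr::select(nodes, "id", x1 = "x", y1 = "y"),
                     by = c(to_id = "id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
                   linewidth = .data$prob),
      colour = "grey55",
      arrow = ggplot2::arrow(length = ggplot2::unit(2.5, "mm"), type = "closed")
    ) +
    ggplot2::geom_label(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label,
                   fill = .data$type),
      size = 3
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 1.6), guide = "none") +
    ggplot2::scale_fill_manual(values = c(initial = "#cde7f0", stage = "#f0e6cd",
                                          outcome = "#d8f0cd")) +
    ggplot2::labs(title = object$cluster, x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Plot a risk profile
#'
#' Bar chart of the outcome-absorption probabilities from the profiled node,
#' the expected outcome highlighted.
#'
#' @param object A `risk_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.risk_profile <- function(object, ...) {
  df <- tidy.risk_profile(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$outcome, y = .data$prob,
                                   fill = .data$expected)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#4c9f70", `FALSE` = "#c26d5c"),
                               name = "expected") +
    ggplot2::labs(
      x = NULL, y = "absorption probability",
      title = sprintf("Outcome risk from '%s' (risk = %.3f)",
                      object$from_node, object$risk)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a deviation alignment
#'
#' Tile view of the aligned planned and realized step sequences, coloured by
#' alignment operation.
#'
#' @param object A `deviation_alignment` or `deviation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.deviation_alignment <- function(object, ...) {
  df <- tidy.deviation_alignment(object) |>
    tidyr::pivot_longer(c("planned", "realized"), names_to = "track",
                        values_to = "label")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$track,
                                   fill = .data$op)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 2.8, na.rm = TRUE) +
    ggplot2::scale_fill_manual(values = c(match = "#b6d7a8", substitution = "#f9cb9c",
                                          insertion = "#a4c2f4", deletion = "#ea9999")) +
    ggplot2::labs(x = "alignment position", y = NULL) +
    ggplot2::theme_minimal()
}
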