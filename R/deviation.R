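#' Globally align a realized journey against its planned pathway
#'
#' Global alignment of two stage-label sequences minimizing unit-cost edit
#' distance (match 0; substitution, insertion and deletion 1 each, unless a
#' substitution cost hook is supplied). Traceback is deterministic: on ties it
#' prefers match over substitution over deletion (planned step skipped) over
#' insertion (extra realized step), so identical inputs always yield the same
#' alignment.
#'
#' @param planned Non-empty character vector of planned stage labels.
#' @param realized Character vector of realized stage labels (may be empty).
#' @param sub_cost Either a single number (default 1) or a function
#'   `f(planned_label, realized_label)` returning the substitution cost for a
#'   mismatching pair; matches always cost 0.
#' @return An object of class `deviation_alignment`: a list with the
#'   `alignment` tibble (`planned`, `realized`, `op`), the counts `n_match`,
#'   `n_sub`, `n_ins`, `n_del`, the unit-cost `edit_distance`
#'   (`n_sub + n_ins + n_del`) and the (possibly weighted) `cost`.
#' @examples
#' fx <- case_study_fixtures()
#' align_paths(fx$case1$pathway$planned_steps, fx$case1$journey$steps[[1]]$action)
#' @export
align_paths <- function(planned, realized, sub_cost = 1) {
  planned <- as.character(planned)
  realized <- as.character(realized)
  if (!length(planned)) abort("`planned` must be a non-empty sequence of stage labels")
  subc <- if (is.function(sub_cost)) sub_cost else function(a, b) sub_cost
  n <- length(planned)
  m <- length(realized)
  D <- matrix(0, n + 1L, m + 1L)
  D[, 1L] <- 0:n
  D[1L, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      diag_cost <- if (planned[i] == realized[j]) 0 else subc(planned[i], realized[j])
      D[i + 1L, j + 1L] <- min(D[i, j] + diag_cost,   # match / substitution
                               D[i, j + 1L] + 1,      # deletion of planned[i]
                               D[i + 1L, j] + 1)      # insertion of realized[j]
    }
  }
  # deterministic traceback, preference: match > substitution > deletion > insertion
  ops <- character(0)
  pl <- character(0)
  re <- character(0)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L) {
      diag_cost <- if (planned[i] == realized[j]) 0 else subc(planned[i], realized[j])
      if (D[i + 1L, j + 1L] == D[i, j] + diag_cost) {
        ops <- c(if (planned[i] == realized[j]) "match" else "substitution", ops)
        pl <- c(planned[i], pl); re <- c(realized[j], re)
        i <- i - 1L; j <- j - 1L
        next
      }
    }
    if (i > 0L && D[i + 1L, j + 1L] == D[i, j + 1L] + 1) {
      ops <- c("deletion", ops)
      pl <- c(planned[i], pl); re <- c(NA_character_, re)
      i <- i - 1L
    } else {
      ops <- c("insertion", ops)
      pl <- c(NA_character_, pl); re <- c(realized[j], re)
      j <- j - 1L
    }
  }
  counts <- c(match = sum(ops == "match"), substitution = sum(ops == "substitution"),
              insertion = sum(ops == "insertion"), deletion = sum(ops == "deletion"))
  structure(
    list(
      alignment = tibble(planned = pl, realized = re, op = ops),
      n_match = unname(counts["match"]),
      n_sub = unname(counts["substitution"]),
      n_ins = unname(counts["insertion"]),
      n_del = unname(counts["deletion"]),
      edit_distance = unname(counts["substitution"] + counts["insertion"] +
                               counts["deletion"]),
      cost = D[n + 1L, m + 1L]
    ),
    class = "deviation_alignment"
  )
}

#' Classify a journey deviation
#'
#' The three-way typology of how a realized journey can deviate from its plan:
#' type `"C"` — the journey ends in an unintended final condition (realized
#' outcome differs from the planned one), regardless of the steps; `"NONE"` —
#' steps and outcome both match the plan; `"B"` — the only step changes are
#' inserted additional stages, and the expected outcome is still reached;
#' `"A"` — the journey was rerouted (substituted and/or skipped stages) but
#' still arrives at the expected outcome. Precedence: C, then NONE, then B,
#' then A; a journey mixing insertions with substitutions is a reroute (A).
#'
#' @param report A `deviation_alignment` from [align_paths()].
#' @param planned_outcome Outcome label of the expected pathway.
#' @param realized_outcome Outcome label the journey actually reached.
#' @return One of `"NONE"`, `"A"`, `"B"`, `"C"`.
#' @export
classify_deviation <- function(report, planned_outcome, realized_outcome) {
  stopifnot(inherits(report, "deviation_alignment"))
  if (!identical(planned_outcome, realized_outcome)) return("C")
  if (report$edit_distance == 0L) return("NONE")
  if (report$n_sub == 0L && report$n_del == 0L) return("B")
  "A"
}

#' Assess one journey against an expected pathway
#'
#' Aligns the realized step sequence against the planned one and classifies
#' the deviation.
#'
#' @param pathway An [expected_pathway()].
#' @param journey A one-row journey-log tibble.
#' @inheritParams align_paths
#' @return An object of class `deviation_report`: the alignment fields plus
#'   `journey_id`, `planned_outcome`, `realized_outcome`, `outcome_match` and
#'   `deviation_type`.
#' @export
assess_deviation <- function(pathway, journey, sub_cost = 1) {
  stopifnot(inherits(pathway, "expected_pathway"))
  validate_journeys(journey)
  if (nrow(journey) != 1L) abort("`journey` must be a one-row journey log")
  aln <- align_paths(pathway$planned_steps, journey$steps[[1]]$action, sub_cost)
  realized_outcome <- journey$final[[1]]$outcome
  out <- c(
    aln,
    list(journey_id = journey$journey_id[[1]],
         planned_outcome = pathway$expected_outcome,
         realized_outcome = realized_outcome,
         outcome_match = identical(pathway$expected_outcome, realized_outcome),
         deviation_type = classify_deviation(aln, pathway$expected_outcome,
                                             realized_outcome))
  )
  class(out) <- c("deviation_report", "deviation_alignment")
  out
}

#' @export
print.deviation_report <- function(x, ...) {
  cat(sprintf("<deviation_report> journey '%s': type %s\n", x$journey_id,
              x$deviation_type))
  cat(sprintf("  edit distance %d (%d match, %d sub, %d ins, %d del); outcome %s\n",
              x$edit_distance, x$n_match, x$n_sub, x$n_ins, x$n_del,
              if (x$outcome_match) "as expected" else
                sprintf("'%s' != expected '%s'", x$realized_outcome, x$planned_outcome)))
  invisible(x)
}

#' Per-journey conformance table
#'
#' One row per journey: alignment counts, outcome match and deviation type.
#' This is the table the command-line `deviations` report writes as CSV.
#'
#' @param pathway An [expected_pathway()].
#' @param journeys A journey-log tibble.
#' @return A tibble with columns `journey_id`, `edit_distance`, `n_match`,
#'   `n_sub`, `n_ins`, `n_del`, `outcome_match`, `deviation_type`.
#' @export
deviation_table <- function(pathway, journeys) {
  validate_journeys(journeys)
  if (!nrow(journeys)) abort("`journeys` must be nonempty")
  purrr::map_dfr(seq_len(nrow(journeys)), function(i) {
    rep <- assess_deviation(pathway, journeys[i, ])
    tibble(journey_id = rep$journey_id, edit_distance = rep$edit_distance,
           n_match = rep$n_match, n_sub = rep$n_sub, n_ins = rep$n_ins,
           n_del = rep$n_del, outcome_match = rep$outcome_match,
           deviation_type = rep$deviation_type)
  })
}

#' Deviation-type rates over a journey log
#'
#' Classifies every journey against the pathway and reports counts and
#' fractions per deviation type; fractions sum to one.
#'
#' @inheritParams deviation_table
#' @return A tibble with one row per type (`NONE`, `A`, `B`, `C`) and columns
#'   `deviation_type`, `n`, `fraction`.
#' @export
deviation_rates <- function(pathway, journeys) {
  tab <- deviation_table(pathway, journeys)
  types <- factor(tab$deviation_type, levels = c("NONE", "A", "B", "C"))
  counts <- table(types)
  tibble(deviation_type = names(counts), n = as.integer(counts),
         fraction = as.integer(counts) / nrow(tab))
}
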