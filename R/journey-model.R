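#' Initial condition of a patient on admission
#'
#' The structured admission state of a patient: history, physical examination,
#' medications in progress, the admitting diagnosis, case-complexity factors
#' (comorbidity, allergy, resistance), the hospitalization type, and the
#' clinically expected outcome. Together with the ordered care steps and the
#' discharge state it makes up one intra-hospital journey.
#'
#' @param admission_diagnosis Single non-empty label for the diagnosis that
#'   makes hospitalization necessary (e.g. `"distal_femur_fracture_right"`).
#' @param expected_outcome Single non-empty label for the outcome expected on
#'   admission (e.g. `"full_recovery"`).
#' @param history Character vector of coded history labels (set-valued).
#' @param exam Named list mapping examination labels to values.
#' @param medications Character vector of coded medication labels, dose
#'   annotations included in the label.
#' @param complexity Character vector of coded complexity factors
#'   (comorbidities, allergies, resistances); set-valued.
#' @param admission_type One of `"emergency"`, `"elective"`, `"day_hospital"`,
#'   `"day_surgery"`.
#'
#' @return An object of class `initial_condition`.
#' @seealso [journey()], [cluster_key()]
#' @export
initial_condition <- function(admission_diagnosis,
                              expected_outcome,
                              history = character(),
                              exam = list(),
                              medications = character(),
                              complexity = character(),
                              admission_type = c("emergency", "elective",
                                                 "day_hospital", "day_surgery")) {
  if (!is_string(admission_diagnosis)) {
    abort_schema("`admission_diagnosis` must be a single non-empty string")
  }
  if (!is_string(expected_outcome)) {
    abort_schema("`expected_outcome` must be a single non-empty string")
  }
  admission_type <- match.arg(admission_type)
  history <- as.character(history)
  medications <- as.character(medications)
  complexity <- as.character(complexity)
  check_label(c(admission_diagnosis, expected_outcome, history, medications,
                complexity), "initial-condition label")
  if (length(exam) && (is.null(names(exam)) || any(!nzchar(names(exam))))) {
    abort_schema("`exam` must be a fully named list")
  }
  structure(
    list(
      history = history,
      exam = exam,
      medications = medications,
      admission_diagnosis = admission_diagnosis,
      complexity = complexity,
      admission_type = admission_type,
      expected_outcome = expected_outcome
    ),
    class = "initial_condition"
  )
}

#' Final (discharge) state of a journey
#'
#' @param outcome Single non-empty outcome label observed at discharge. When it
#'   differs from the expected outcome recorded on admission the journey
#'   realizes an unintended final condition.
#' @param health_conditions Named list of discharge health-condition values,
#'   complications included.
#'
#' @return An object of class `final_state`.
#' @export
final_state <- function(outcome, health_conditions = list()) {
  if (!is_string(outcome)) abort_schema("`outcome` must be a single non-empty string")
  check_label(outcome, "outcome label")
  if (length(health_conditions) &&
      (is.null(names(health_conditions)) || any(!nzchar(names(health_conditions))))) {
    abort_schema("`health_conditions` must be a fully named list")
  }
  structure(list(outcome = outcome, health_conditions = health_conditions),
            class = "final_state")
}

#' One intermediate step of a journey
#'
#' @param action Non-empty stage label: the action performed or situation
#'   experienced, defining the transition to the next step.
#' @param t Ordinal time index; strictly increasing within a journey. The
#'   model is order-based, so `t` is step order, not wall-clock time.
#' @param params Named list of structured parameters attached to the step.
#' @param timestamp Optional ISO-8601 string, carried through serialization but
#'   unused by the model.
#'
#' @return A one-row tibble with columns `action`, `params`, `t`, `timestamp`.
#' @export
journey_step <- function(action, t, params = list(), timestamp = NA_character_) {
  if (!is_string(action)) abort_schema("`action` must be a single non-empty string")
  check_label(action, "stage label")
  tibble(
    action = action,
    params = list(params),
    t = as.integer(t),
    timestamp = as.character(timestamp)
  )
}

#' Facility profile
#'
#' Structural covariates of a healthcare facility, shared by all journeys that
#' take place in it: size, departments, organization type, caseload statistics
#' and personnel roles.
#'
#' @param facility_id Single non-empty identifier.
#' @param beds Nonnegative number of beds.
#' @param n_departments Nonnegative number of specialist departments.
#' @param organization_type Free label, e.g. `"university_hospital"`.
#' @param caseload_stats Named list mapping case labels to counts.
#' @param personnel Character vector of role labels.
#'
#' @return An object of class `facility_profile`.
#' @export
facility_profile <- function(facility_id, beds = 0L, n_departments = 0L,
                             organization_type = "unspecified",
                             caseload_stats = list(), personnel = character()) {
  if (!is_string(facility_id)) abort_schema("`facility_id` must be a single non-empty string")
  beds <- as.integer(beds)
  n_departments <- as.integer(n_departments)
  if (is.na(beds) || beds < 0L) abort_schema("`beds` must be a nonnegative integer")
  if (is.na(n_departments) || n_departments < 0L) {
    abort_schema("`n_departments` must be a nonnegative integer")
  }
  structure(
    list(facility_id = facility_id, beds = beds, n_departments = n_departments,
         organization_type = organization_type,
         caseload_stats = caseload_stats,
         personnel = as.character(personnel)),
    class = "facility_profile"
  )
}

#' Construct a one-journey log
#'
#' A journey is the complete intra-hospital path of one patient: the initial
#' condition on admission, `k >= 0` ordered intermediate steps, and the final
#' state at discharge. Journey logs are tibbles with one row per journey;
#' `journey()` builds a one-row log and logs are combined with
#' [dplyr::bind_rows()].
#'
#' @param journey_id Single non-empty identifier.
#' @param initial An [initial_condition()].
#' @param steps A tibble of steps as produced by [journey_step()] (bind rows
#'   for multi-step journeys), or `NULL` for a direct admission-to-discharge
#'   journey.
#' @param final A [final_state()].
#' @param facility Optional facility identifier (string) or `NA`.
#'
#' @return A one-row journey-log tibble with columns `journey_id`, `initial`,
#'   `steps`, `final`, `facility`.
#' @examples
#' j <- journey(
#'   "j1",
#'   initial_condition("pneumonia", "discharged_home"),
#'   dplyr::bind_rows(journey_step("antibiotics", 1), journey_step("imaging", 2)),
#'   final_state("discharged_home")
#' )
#' @export
journey <- function(journey_id, initial, steps = NULL, final, facility = NA_character_) {
  if (!is_string(journey_id)) abort_schema("`journey_id` must be a single non-empty string")
  if (!inherits(initial, "initial_condition")) {
    abort_schema("`initial` must be an initial_condition")
  }
  if (!inherits(final, "final_state")) abort_schema("`final` must be a final_state")
  steps <- steps %||% empty_steps()
  steps <- as_tibble(steps)
  validate_steps(steps, journey_id)
  tibble(
    journey_id = journey_id,
    initial = list(initial),
    steps = list(steps),
    final = list(final),
    facility = as.character(facility)
  )
}

empty_steps <- function() {
  tibble(action = character(), params = list(), t = integer(),
         timestamp = character())
}

validate_steps <- function(steps, journey_id = "?") {
  required <- c("action", "params", "t", "timestamp")
  if (!all(required %in% names(steps))) {
    abort_schema(sprintf("journey '%s': steps must have columns %s",
                         journey_id, paste(required, collapse = ", ")))
  }
  if (nrow(steps) > 1L && any(diff(steps$t) <= 0L)) {
    abort_schema(sprintf("journey '%s': step time indices must be strictly increasing",
                         journey_id))
  }
  invisible(steps)
}

#' Validate a journey log
#'
#' Checks every invariant of the journey model on each row: non-empty
#' diagnosis, admission type in its enumeration, non-empty expected and
#' realized outcomes, non-empty stage labels and strictly increasing step
#' order. Errors on the first violation, naming the offending journey.
#'
#' @param journeys A journey-log tibble.
#' @return The input, invisibly, if valid.
#' @export
validate_journeys <- function(journeys) {
  required <- c("journey_id", "initial", "steps", "final", "facility")
  if (!is.data.frame(journeys) || !all(required %in% names(journeys))) {
    abort_schema(sprintf("a journey log needs columns %s",
                         paste(required, collapse = ", ")))
  }
  for (i in seq_len(nrow(journeys))) {
    id <- journeys$journey_id[[i]]
    if (!is_string(id)) abort_schema(sprintf("row %d: empty journey_id", i))
    ini <- journeys$initial[[i]]
    if (!inherits(ini, "initial_condition")) {
      abort_schema(sprintf("journey '%s': `initial` is not an initial_condition", id))
    }
    fin <- journeys$final[[i]]
    if (!inherits(fin, "final_state")) {
      abort_schema(sprintf("journey '%s': `final` is not a final_state", id))
    }
    validate_steps(journeys$steps[[i]], id)
  }
  invisible(journeys)
}

#' Does each journey realize its expected path?
#'
#' A journey whose realized outcome equals the outcome expected on admission
#' realizes the planned path; otherwise it realizes a varied path with an
#' unintended final condition.
#'
#' @param journeys A journey-log tibble.
#' @return The log with a logical `unintended` column appended.
#' @export
flag_unintended <- function(journeys) {
  validate_journeys(journeys)
  dplyr::mutate(
    journeys,
    unintended = purrr::map2_lgl(.data$final, .data$initial,
                                 ~ .x$outcome != .y$expected_outcome)
  )
}

#' Expected clinical pathway
#'
#' The journey a clinician outlines on admission: an ordered sequence of
#' planned stage labels and the outcome the plan should reach.
#'
#' @param name Pathway identifier.
#' @param planned_steps Non-empty character vector of stage labels in order.
#' @param expected_outcome Outcome label the plan leads to.
#' @return An object of class `expected_pathway`.
#' @export
expected_pathway <- function(name, planned_steps, expected_outcome) {
  if (!is_string(name)) abort_schema("`name` must be a single non-empty string")
  planned_steps <- as.character(planned_steps)
  if (!length(planned_steps) || any(!nzchar(planned_steps))) {
    abort_schema("`planned_steps` must be a non-empty vector of non-empty labels")
  }
  if (!is_string(expected_outcome)) {
    abort_schema("`expected_outcome` must be a single non-empty string")
  }
  structure(list(name = name, planned_steps = planned_steps,
                 expected_outcome = expected_outcome),
            class = "expected_pathway")
}

# ---- JSON-Lines serialization -----------------------------------------------

journey_schema_version <- "1"

as_json_record <- function(journeys, i) {
  ini <- journeys$initial[[i]]
  fin <- journeys$final[[i]]
  steps <- journeys$steps[[i]]
  step_list <- purrr::pmap(
    list(steps$action, steps$params, steps$t, steps$timestamp),
    function(action, params, t, timestamp) {
      rec <- list(action = action, params = as_json_map(params), t = t)
      if (!is.na(timestamp)) rec$timestamp <- timestamp
      rec
    }
  )
  fac <- journeys$facility[[i]]
  list(
    schema_version = journey_schema_version,
    journey_id = journeys$journey_id[[i]],
    initial = list(
      history = as_json_array(ini$history),
      exam = as_json_map(ini$exam),
      medications = as_json_array(ini$medications),
      admission_diagnosis = ini$admission_diagnosis,
      complexity = as_json_array(ini$complexity),
      admission_type = ini$admission_type,
      expected_outcome = ini$expected_outcome
    ),
    steps = step_list,
    final = list(outcome = fin$outcome,
                 health_conditions = as_json_map(fin$health_conditions)),
    facility = if (is.na(fac)) NULL else fac
  )
}

# Empty named collections must serialize as {} / [] and scalars must stay
# scalars, so shape them explicitly before toJSON(auto_unbox = TRUE).
as_json_map <- function(x) {
  if (!length(x)) return(structure(list(), names = character()))
  x
}

as_json_array <- function(x) {
  if (!length(x)) return(list())
  as.list(x)
}

#' Write a journey log as JSON Lines
#'
#' One journey per line, stable key order, UTF-8. Bookkeeping columns whose
#' names start with `.` (added e.g. by the simulator) are not serialized.
#' `write_journey_log()` and [read_journey_log()] round-trip a valid log
#' field-exactly.
#'
#' @param journeys A journey-log tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_journey_log <- function(journeys, path) {
  validate_journeys(journeys)
  lines <- purrr::map_chr(seq_len(nrow(journeys)), function(i) {
    jsonlite::toJSON(as_json_record(journeys, i), auto_unbox = TRUE,
                     null = "null", digits = NA)
  })
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) abort_io(sprintf("cannot open '%s' for writing", path)))
  on.exit(close(con), add = TRUE)
  if (length(lines)) writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

from_json_map <- function(x, where, line) {
  # jsonlite parses {} as a zero-length *named* list; normalize to list() so
  # write/read round-trips are field-exact
  if (is.null(x) || !length(x)) return(list())
  if (!is.list(x)) abort_schema(sprintf("line %d: %s must be an object", line, where))
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    abort_schema(sprintf("line %d: %s must have named fields", line, where))
  }
  x
}

from_json_array <- function(x, where, line) {
  if (is.null(x)) return(character())
  if (!is.list(x) && !is.character(x)) {
    abort_schema(sprintf("line %d: %s must be an array of strings", line, where))
  }
  out <- unlist(x, use.names = FALSE)
  if (is.null(out)) character() else as.character(out)
}

json_string <- function(x, where, line) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    abort_schema(sprintf("line %d: field '%s' must be a non-empty string", line, where))
  }
  x
}

parse_journey_line <- function(txt, line) {
  rec <- tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = FALSE),
    error = function(e) abort_schema(sprintf("line %d: invalid JSON (%s)",
                                             line, conditionMessage(e)))
  )
  ver <- rec$schema_version
  if (is.null(ver)) abort_schema(sprintf("line %d: missing schema_version", line))
  if (!identical(as.character(ver), journey_schema_version)) {
    abort_schema(sprintf("line %d: unknown schema_version '%s'", line, ver))
  }
  ini_rec <- from_json_map(rec$initial, "initial", line)
  ini <- tryCatch(
    initial_condition(
      admission_diagnosis = json_string(ini_rec$admission_diagnosis,
                                        "initial.admission_diagnosis", line),
      expected_outcome = json_string(ini_rec$expected_outcome,
                                     "initial.expected_outcome", line),
      history = from_json_array(ini_rec$history, "initial.history", line),
      exam = from_json_map(ini_rec$exam, "initial.exam", line),
      medications = from_json_array(ini_rec$medications, "initial.medications", line),
      complexity = from_json_array(ini_rec$complexity, "initial.complexity", line),
      admission_type = json_string(ini_rec$admission_type,
                                   "initial.admission_type", line)
    ),
    error = function(e) {
      abort_schema(sprintf("line %d: initial: %s", line, conditionMessage(e)))
    }
  )
  steps_rec <- rec$steps
  if (is.null(steps_rec)) steps_rec <- list()
  steps <- if (length(steps_rec)) {
    dplyr::bind_rows(Map(function(st, k) {
      st <- from_json_map(st, sprintf("steps[%d]", k), line)
      journey_step(
        action = json_string(st$action, sprintf("steps[%d].action", k), line),
        t = st$t %||% abort_schema(sprintf("line %d: steps[%d].t missing", line, k)),
        params = from_json_map(st$params, sprintf("steps[%d].params", k), line),
        timestamp = st$timestamp %||% NA_character_
      )
    }, steps_rec, seq_along(steps_rec)))
  } else {
    empty_steps()
  }
  fin_rec <- from_json_map(rec$final, "final", line)
  fin <- final_state(
    outcome = json_string(fin_rec$outcome, "final.outcome", line),
    health_conditions = from_json_map(fin_rec$health_conditions,
                                      "final.health_conditions", line)
  )
  fac <- rec$facility
  out <- tryCatch(
    journey(json_string(rec$journey_id, "journey_id", line), ini, steps, fin,
            facility = if (is.null(fac)) NA_character_ else as.character(fac)),
    error = function(e) abort_schema(sprintf("line %d: %s", line, conditionMessage(e)))
  )
  out
}

#' Read a JSON-Lines journey log
#'
#' Parses and validates a journey log written by [write_journey_log()] (or any
#' producer of the published schema, see
#' `system.file("extdata", "journey-log.schema.json", package = "pathrisk")`).
#' The whole file is rejected on the first malformed line; the error names the
#' line number and the offending field.
#'
#' @param path Path to a `.jsonl` file, one JSON journey object per line.
#' @return A journey-log tibble, journeys in file order.
#' @export
read_journey_log <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("journey log '%s' does not exist", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(tibble(journey_id = character(), initial = list(), steps = list(),
                  final = list(), facility = character()))
  }
  # plain loop, not purrr: parse errors must surface with their own condition
  # class (purrr would wrap them)
  rows <- lapply(seq_along(lines), function(i) parse_journey_line(lines[[i]], i))
  out <- dplyr::bind_rows(rows)
  validate_journeys(out)
  out
}

#' Read / write an expected-pathway definition
#'
#' Expected pathways are stored as small JSON documents with keys `name`,
#' `planned_steps` and `expected_outcome`.
#'
#' @param path File path.
#' @return `read_expected_pathway()` returns an [expected_pathway()].
#' @export
read_expected_pathway <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("pathway file '%s' does not exist", path))
  rec <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) abort_schema(conditionMessage(e)))
  expected_pathway(
    name = json_string(rec$name, "name", 1L),
    planned_steps = from_json_array(rec$planned_steps, "planned_steps", 1L),
    expected_outcome = json_string(rec$expected_outcome, "expected_outcome", 1L)
  )
}

#' @rdname read_expected_pathway
#' @param pathway An [expected_pathway()].
#' @export
write_expected_pathway <- function(pathway, path) {
  stopifnot(inherits(pathway, "expected_pathway"))
  jsonlite::write_json(
    list(name = pathway$name,
         planned_steps = as.list(pathway$planned_steps),
         expected_outcome = pathway$expected_outcome),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' @export
print.initial_condition <- function(x, ...) {
  cat("<initial_condition>", x$admission_diagnosis,
      sprintf("[%s]", x$admission_type),
      "-> expected:", x$expected_outcome, "\n")
  if (length(x$complexity)) {
    cat("  complexity:", paste(sort(x$complexity), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.expected_pathway <- function(x, ...) {
  cat("<expected_pathway>", x$name, "\n")
  cat(" ", paste(x$planned_steps, collapse = " -> "), "->", x$expected_outcome, "\n")
  invisible(x)
}
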