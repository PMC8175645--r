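#' Canonical cluster key of an initial condition
#'
#' Journeys are grouped into cohorts by admission parameters so that each
#' cohort gets its own knowledge graph. The default key is the admitting
#' diagnosis together with the complexity (comorbidity) set. Keys are
#' canonical strings: set-valued fields are sorted before serialization, so
#' two admissions with the same complexity factors in different order receive
#' the same key. `"facility"` may be included among the key fields to
#' stratify the knowledge base by facility.
#'
#' @param initial An [initial_condition()].
#' @param key_fields Character vector of initial-condition field names
#'   (`admission_diagnosis`, `complexity`, `history`, `medications`, `exam`,
#'   `admission_type`, `expected_outcome`), optionally plus `"facility"`.
#' @param facility Facility id, consulted only when `"facility"` is among
#'   `key_fields`.
#' @return A single string; equal initial conditions map to equal strings.
#' @export
cluster_key <- function(initial,
                        key_fields = c("admission_diagnosis", "complexity"),
                        facility = NA_character_) {
  stopifnot(inherits(initial, "initial_condition"))
  if (!length(key_fields)) abort("`key_fields` must be nonempty")
  set_fields <- c("complexity", "history", "medications")
  scalar_fields <- c("admission_diagnosis", "admission_type", "expected_outcome")
  parts <- purrr::map_chr(key_fields, function(f) {
    if (f %in% scalar_fields) {
      paste0(f, "=", initial[[f]])
    } else if (f %in% set_fields) {
      paste0(f, "={", paste(sort(unique(initial[[f]])), collapse = ","), "}")
    } else if (f == "exam") {
      kv <- initial$exam[order(names(initial$exam))]
      paste0("exam={", paste(names(kv), unname(purrr::map_chr(kv, as.character)),
                             sep = ":", collapse = ","), "}")
    } else if (f == "facility") {
      paste0("facility=", if (is.na(facility)) "" else facility)
    } else {
      abort(sprintf("unknown cluster key field '%s'", f))
    }
  })
  paste(parts, collapse = "|")
}

parse_cluster_key <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)[[1]]
  fields <- sub("=.*$", "", parts)
  values <- sub("^[^=]*=", "", parts)
  out <- purrr::map2(values, fields, function(v, f) {
    if (grepl("^\\{.*\\}$", v)) {
      inner <- substr(v, 2L, nchar(v) - 1L)
      if (nzchar(inner)) strsplit(inner, ",", fixed = TRUE)[[1]] else character()
    } else {
      v
    }
  })
  setNames(out, fields)
}

#' Attach cluster keys to a journey log
#'
#' @param journeys A journey-log tibble.
#' @inheritParams cluster_key
#' @return The log with a `.cluster` character column appended.
#' @export
add_cluster_key <- function(journeys,
                            key_fields = c("admission_diagnosis", "complexity")) {
  validate_journeys(journeys)
  dplyr::mutate(
    journeys,
    .cluster = purrr::map2_chr(.data$initial, .data$facility, cluster_key,
                               key_fields = key_fields)
  )
}

#' Partition a journey log into clusters
#'
#' Splits a log into cohorts by canonical cluster key. The result is a true
#' partition: every journey appears in exactly one cluster and cluster sizes
#' sum to the input size.
#'
#' @inheritParams add_cluster_key
#' @return A named list of journey-log tibbles, names sorted lexicographically.
#' @export
partition_journeys <- function(journeys,
                               key_fields = c("admission_diagnosis", "complexity")) {
  keyed <- add_cluster_key(journeys, key_fields)
  parts <- split(dplyr::select(keyed, -".cluster"), keyed$.cluster)
  parts[order(names(parts))]
}

#' Match a new admission to a known cluster
#'
#' At admission time the patient's cluster is looked up in the knowledge base.
#' Under the `"strict"` policy (the closed-world default) an unseen key is an
#' error: the patient falls outside the closed world and must be handled by
#' the supervised risk predictor instead. Under `"nearest"`, the key with an
#' exactly matching admission diagnosis and maximal Jaccard similarity over
#' the set-valued key fields is returned, ties broken by lexicographic key
#' order.
#'
#' @inheritParams cluster_key
#' @param known_keys Character vector of cluster-key strings in the knowledge
#'   base (all built with the same `key_fields`).
#' @param policy `"strict"` or `"nearest"`.
#' @return A single key from `known_keys`.
#' @export
match_cluster <- function(initial, known_keys,
                          policy = c("strict", "nearest"),
                          key_fields = c("admission_diagnosis", "complexity"),
                          facility = NA_character_) {
  policy <- match.arg(policy)
  if (!length(known_keys)) abort("`known_keys` must be nonempty")
  key <- cluster_key(initial, key_fields, facility)
  if (key %in% known_keys) return(key)
  if (policy == "strict") {
    abort_closed_world(sprintf(
      "patient outside closed world: cluster key '%s' has no knowledge graph", key))
  }
  target <- parse_cluster_key(key)
  set_fields <- intersect(names(target), c("complexity", "history", "medications"))
  scalar_fields <- setdiff(names(target), set_fields)
  candidates <- sort(known_keys)
  scores <- purrr::map_dbl(candidates, function(k) {
    cand <- parse_cluster_key(k)
    # exact match required on every scalar key field (the diagnosis above all)
    for (f in scalar_fields) {
      if (!identical(cand[[f]], target[[f]])) return(-Inf)
    }
    if (!length(set_fields)) return(1)
    a <- unlist(purrr::imap(target[set_fields], ~ paste0(.y, ":", .x)))
    b <- unlist(purrr::imap(cand[set_fields], ~ paste0(.y, ":", .x)))
    u <- length(union(a, b))
    if (u == 0L) 1 else length(intersect(a, b)) / u
  })
  if (all(scores == -Inf)) {
    abort_closed_world(sprintf(
      "patient outside closed world: no known cluster shares diagnosis of key '%s'", key))
  }
  candidates[[which.max(scores)]]
}
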