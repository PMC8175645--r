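# Supervised risk prediction for patients the closed-world knowledge base
# cannot answer: encode (initial condition, partial journey, facility) as a
# fixed-length indicator vector and learn P(unintended outcome) with a
# pluggable binary-probability learner.

#' Fit a feature vocabulary on a training log
#'
#' Collects the label sets (diagnoses, complexity factors, stage labels,
#' organization types) that define the feature-vector dimensionality. Labels
#' unseen at prediction time map to a reserved "unknown" slot.
#'
#' @param journeys A journey-log tibble.
#' @param facilities Optional named list of [facility_profile()]s referenced
#'   by the log.
#' @return An object of class `feature_vocab`.
#' @export
fit_vocab <- function(journeys, facilities = NULL) {
  validate_journeys(journeys)
  inis <- journeys$initial
  structure(
    list(
      diagnoses = sort(unique(purrr::map_chr(inis, "admission_diagnosis"))),
      complexity = sort(unique(unlist(purrr::map(inis, "complexity")))),
      admission_types = c("emergency", "elective", "day_hospital", "day_surgery"),
      stages = sort(unique(unlist(purrr::map(journeys$steps, "action")))),
      org_types = sort(unique(purrr::map_chr(facilities %||% list(),
                                             "organization_type"))),
      facilities = facilities
    ),
    class = "feature_vocab"
  )
}

slot_names <- function(levels, prefix) {
  # paste0() maps zero-length input to "", so guard explicitly
  named <- if (length(levels)) paste0(prefix, "=", levels) else character()
  c(named, paste0(prefix, "=<unknown>"))
}

one_hot <- function(value, levels, prefix) {
  v <- setNames(numeric(length(levels) + 1L), slot_names(levels, prefix))
  hit <- match(value, levels)
  if (length(value)) {
    if (is.na(hit)) v[length(v)] <- 1 else v[hit] <- 1
  }
  v
}

multi_hot <- function(values, levels, prefix) {
  v <- setNames(numeric(length(levels) + 1L), slot_names(levels, prefix))
  hits <- match(values, levels)
  v[hits[!is.na(hits)]] <- 1
  if (any(is.na(hits))) v[length(v)] <- 1
  v
}

#' Encode a journey prefix as a feature vector
#'
#' Deterministic encoding of the admission state plus the journey so far:
#' diagnosis and admission type one-of-K, complexity and visited stages
#' multi-hot, journey length so far, and facility covariates (beds,
#' departments, organization type). The encoding is a pure function of its
#' inputs given the vocabulary.
#'
#' @param initial An [initial_condition()].
#' @param steps Character vector of stage labels traversed so far (possibly
#'   empty).
#' @param vocab A [fit_vocab()] vocabulary.
#' @param facility Facility id (looked up in the vocabulary's profiles) or
#'   `NA`.
#' @return A named numeric vector of fixed length.
#' @export
featurize <- function(initial, steps = character(), vocab, facility = NA_character_) {
  stopifnot(inherits(initial, "initial_condition"),
            inherits(vocab, "feature_vocab"))
  steps <- as.character(steps)
  fac <- if (!is.na(facility) && !is.null(vocab$facilities) &&
             facility %in% names(vocab$facilities)) {
    vocab$facilities[[facility]]
  } else {
    NULL
  }
  c(
    one_hot(initial$admission_diagnosis, vocab$diagnoses, "dx"),
    multi_hot(initial$complexity, vocab$complexity, "cx"),
    one_hot(initial$admission_type, vocab$admission_types, "adm"),
    multi_hot(steps, vocab$stages, "stage"),
    n_steps = length(steps),
    fac_beds = if (is.null(fac)) 0 else fac$beds,
    fac_departments = if (is.null(fac)) 0 else fac$n_departments,
    one_hot(if (is.null(fac)) character() else fac$organization_type,
            vocab$org_types, "org")
  )
}

# Feature matrix over all step prefixes (length 0..k) of each journey, with
# the journey-level "unintended outcome" label attached.
prefix_matrix <- function(journeys, vocab) {
  labelled <- flag_unintended(journeys)
  rows <- purrr::map(seq_len(nrow(labelled)), function(i) {
    actions <- labelled$steps[[i]]$action
    purrr::map(0:length(actions), function(k) {
      list(journey_id = labelled$journey_id[[i]],
           x = featurize(labelled$initial[[i]], head(actions, k), vocab,
                         labelled$facility[[i]]),
           y = labelled$unintended[[i]])
    })
  })
  rows <- purrr::flatten(rows)
  list(
    journey_id = purrr::map_chr(rows, "journey_id"),
    x = do.call(rbind, purrr::map(rows, "x")),
    y = purrr::map_lgl(rows, "y")
  )
}

#' Binary-probability learners
#'
#' The risk predictor is learner-agnostic: a learner is a list with a `name`,
#' a `fit(x, y)` function returning a model, and a `predict(model, x)`
#' function returning probabilities in `[0, 1]`. `learner_logistic()` — the
#' shipped default — is ridge-penalized logistic regression (deterministic,
#' robust to separable toy problems); `learner_tree()` is a CART decision
#' tree (requires the rpart package).
#'
#' @param lambda Ridge penalty of the default learner.
#' @return A learner object usable with [fit_predictor()].
#' @export
learner_logistic <- function(lambda = 1e-2) {
  list(
    name = "ridge_logistic",
    fit = function(x, y) {
      glmnet::glmnet(x, factor(y, levels = c(FALSE, TRUE)), family = "binomial",
                     alpha = 0, lambda = lambda, standardize = FALSE)
    },
    predict = function(model, x) {
      as.numeric(predict(model, x, type = "response"))
    }
  )
}

#' @rdname learner_logistic
#' @param ... Passed to [rpart::rpart()].
#' @export
learner_tree <- function(...) {
  if (!requireNamespace("rpart", quietly = TRUE)) {
    abort("learner_tree() requires the rpart package")
  }
  dots <- list(...)
  list(
    name = "cart",
    fit = function(x, y) {
      df <- as.data.frame(x)
      names(df) <- make.names(names(df))
      df$.y <- factor(y, levels = c(FALSE, TRUE))
      do.call(rpart::rpart,
              c(list(.y ~ ., data = df, method = "class"), dots))
    },
    predict = function(model, x) {
      df <- as.data.frame(x)
      names(df) <- make.names(names(df))
      as.numeric(predict(model, df, type = "prob")[, "TRUE"])
    }
  )
}

brier_score <- function(p, y) mean((p - as.numeric(y))^2)

#' Fit a supervised risk predictor on a journey log
#'
#' Labels each journey as unintended (realized outcome differs from the
#' expected one), expands journeys into step prefixes so risk can be
#' re-estimated as the patient advances, fits the learner on a seeded
#' 80/20 by-journey split, and reports held-out Brier scores against the
#' constant-rate baseline.
#'
#' @param journeys A training journey-log tibble with at least one intended
#'   and one unintended journey.
#' @param learner A learner object, see [learner_logistic()].
#' @param seed Integer seed for the train/evaluation split.
#' @param train_fraction Fraction of journeys used for fitting (default 0.8).
#' @param facilities Optional named list of [facility_profile()]s.
#' @return An object of class `risk_predictor`.
#' @examples
#' log <- simulate_log(example_generator_spec(seed = 7))
#' pred <- fit_predictor(log, seed = 7)
#' glance(pred)
#' @export
fit_predictor <- function(journeys, learner = learner_logistic(), seed = 1L,
                          train_fraction = 0.8, facilities = NULL) {
  labelled <- flag_unintended(journeys)
  if (length(unique(labelled$unintended)) < 2L) {
    abort("training log must contain both intended and unintended outcomes")
  }
  vocab <- fit_vocab(journeys, facilities)
  mat <- prefix_matrix(journeys, vocab)
  ids <- unique(mat$journey_id)
  n_train <- max(2L, floor(train_fraction * length(ids)))
  train_ids <- local_seed(seed, sample(ids, n_train))
  in_train <- mat$journey_id %in% train_ids
  # both classes must appear in the training half
  if (length(unique(mat$y[in_train])) < 2L) {
    in_train <- rep(TRUE, length(mat$y))
  }
  model <- learner$fit(mat$x[in_train, , drop = FALSE], mat$y[in_train])
  eval_x <- mat$x[!in_train, , drop = FALSE]
  eval_y <- mat$y[!in_train]
  metrics <- if (nrow(eval_x)) {
    p <- pmin(pmax(learner$predict(model, eval_x), 0), 1)
    base <- mean(mat$y[in_train])
    tibble(n_train = sum(in_train), n_eval = length(eval_y),
           brier = brier_score(p, eval_y),
           brier_baseline = brier_score(rep(base, length(eval_y)), eval_y))
  } else {
    tibble(n_train = sum(in_train), n_eval = 0L,
           brier = NA_real_, brier_baseline = NA_real_)
  }
  structure(
    list(learner = learner, model = model, vocab = vocab, metrics = metrics,
         base_rate = mean(labelled$unintended)),
    class = "risk_predictor"
  )
}

#' Predict the unintended-outcome risk of a journey prefix
#'
#' @param predictor A fitted [fit_predictor()] model.
#' @param initial An [initial_condition()].
#' @param steps Character vector of stage labels traversed so far.
#' @param facility Facility id or `NA`.
#' @return A probability in `[0, 1]`.
#' @export
predict_risk <- function(predictor, initial, steps = character(),
                         facility = NA_character_) {
  stopifnot(inherits(predictor, "risk_predictor"))
  x <- matrix(featurize(initial, steps, predictor$vocab, facility), nrow = 1)
  colnames(x) <- names(featurize(initial, steps, predictor$vocab, facility))
  pmin(pmax(predictor$learner$predict(predictor$model, x), 0), 1)
}

#' Risk variation from taking one more step
#'
#' The change in predicted unintended-outcome risk when the patient passes
#' from the current prefix to the prefix extended by `new_step`.
#'
#' @inheritParams predict_risk
#' @param new_step Stage label of the candidate next step.
#' @return A number in `[-1, 1]`.
#' @export
risk_delta <- function(predictor, initial, steps = character(), new_step,
                       facility = NA_character_) {
  predict_risk(predictor, initial, c(steps, new_step), facility) -
    predict_risk(predictor, initial, steps, facility)
}

#' @export
print.risk_predictor <- function(x, ...) {
  cat(sprintf("<risk_predictor> learner: %s\n", x$learner$name))
  cat(sprintf("  base unintended rate: %.3f | held-out Brier %.4f (baseline %.4f)\n",
              x$base_rate, x$metrics$brier, x$metrics$brier_baseline))
  invisible(x)
}
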