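#' Clinical score threshold rules
#'
#' Step-function baselines used throughout perioperative risk work: a
#' PPOSSUM predicted risk of at least 30% flags high risk, ASA grade >= 2
#' flags high risk (boundary inclusive by default, configurable), DASI below
#' 34 flags high risk (lower functional capacity = worse), and an anaerobic
#' threshold below 11 ml O2/kg/min flags high risk.
#'
#' @param name one of `"PPOSSUM"`, `"ASA"`, `"DASI"`, `"AT"`.
#' @param threshold decision threshold; defaults to the established value
#'   for the named score.
#' @param direction `"higher-is-risk"` or `"lower-is-risk"`; defaults to the
#'   clinically forced direction for the named score.
#' @param inclusive whether a value exactly at the threshold is classed high
#'   risk (default `TRUE`).
#' @return A `clinical_score_rule`.
#' @export
clinical_score_rule <- function(name = c("PPOSSUM", "ASA", "DASI", "AT"),
                                threshold = NULL, direction = NULL,
                                inclusive = TRUE) {
  name <- match.arg(name)
  defaults <- list(
    PPOSSUM = list(threshold = 0.30, direction = "higher-is-risk"),
    ASA = list(threshold = 2, direction = "higher-is-risk"),
    DASI = list(threshold = 34, direction = "lower-is-risk"),
    AT = list(threshold = 11, direction = "lower-is-risk"))
  d <- defaults[[name]]
  if (is.null(threshold)) threshold <- d$threshold
  if (is.null(direction)) direction <- d$direction
  direction <- match.arg(direction, c("higher-is-risk", "lower-is-risk"))
  stopifnot(is.finite(threshold))
  structure(list(name = name, threshold = threshold, direction = direction,
                 inclusive = inclusive),
            class = "clinical_score_rule")
}

#' Predict with a threshold rule
#'
#' For `"lower-is-risk"` scores the comparison flips: values strictly below
#' the threshold (at or below when `inclusive = FALSE` flips the boundary)
#' are classed 1. `DASI < 34` and `AT < 11` are high risk; `PPOSSUM >= 0.30`
#' and `ASA >= 2` are high risk.
#'
#' @param rule a [clinical_score_rule()].
#' @param value numeric score values (finite).
#' @return Integer 0/1 predictions.
#' @export
score_predict <- function(rule, value) {
  stopifnot(inherits(rule, "clinical_score_rule"), all(is.finite(value)))
  if (rule$direction == "higher-is-risk") {
    as.integer(if (rule$inclusive) value >= rule$threshold
               else value > rule$threshold)
  } else {
    as.integer(if (rule$inclusive) value < rule$threshold
               else value <= rule$threshold)
  }
}

#' Single-covariate anaerobic-threshold logistic baseline
#'
#' Maximum-likelihood logistic regression of the outcome on one CPET-derived
#' feature (canonically the anaerobic threshold in ml O2/kg/min), fit on the
#' training partition only.
#'
#' @param train,test data frames.
#' @param at_feature covariate column name.
#' @param outcome outcome column name.
#' @return List: `probabilities` (per test row), `coefficients`
#'   (intercept, slope), `model` (the `glm` fit).
#' @export
at_logistic_baseline <- function(train, test, at_feature = "vo2_kg_at",
                                 outcome = "poms_class_d3") {
  stopifnot(at_feature %in% names(train), at_feature %in% names(test))
  fml <- stats::reformulate(at_feature, response = outcome)
  fit <- stats::glm(fml, data = train, family = stats::binomial())
  list(probabilities = as.numeric(stats::predict(fit, newdata = test,
                                                 type = "response")),
       coefficients = stats::coef(fit),
       model = fit)
}

.feature_matrix <- function(data, outcome) {
  drop <- c(outcome, "patient_id", "poms_count_d3", "poms_class_d3")
  as.matrix(data[setdiff(names(data), drop)])
}

#' Reference classifier learners
#'
#' Thin adapters over established implementations, each exposing the
#' `fit(data, outcome, params)` / `predict(model, newdata)` interface
#' consumed by [grid_search_cv()] and the experiment pipeline:
#'
#' * `"lr"` — logistic regression (`stats::glm`), no tuning parameters;
#' * `"dt"` — decision tree (`rpart`), tunable `cp`, `maxdepth`;
#' * `"rf"` — random forest (`randomForest`), tunable `ntree`, `mtry_frac`;
#' * `"gbt"` — gradient-boosted trees (`xgboost`), tunable `nrounds`,
#'   `max_depth`, `eta`.
#'
#' @param name learner name.
#' @return A learner list with `fit`, `predict`, `name` and `default_grid`
#'   (ordered simple to complex, as the tie-break expects).
#' @export
reference_learner <- function(name = c("lr", "dt", "rf", "gbt")) {
  name <- match.arg(name)
  switch(name,
    lr = list(
      name = "lr",
      default_grid = data.frame(dummy = 1),
      fit = function(data, outcome, params) {
        x <- .feature_matrix(data, outcome)
        suppressWarnings(stats::glm.fit(cbind(1, x), data[[outcome]],
                                        family = stats::binomial()))
      },
      predict = function(model, newdata) {
        x <- .feature_matrix(newdata, "poms_class_d3")
        beta <- model$coefficients
        beta[is.na(beta)] <- 0  # aliased (collinear/constant) columns drop out
        as.numeric(stats::plogis(cbind(1, x) %*% beta))
      }),
    dt = list(
      name = "dt",
      default_grid = data.frame(cp = c(0.05, 0.01, 0.002),
                                maxdepth = c(3, 5, 8)),
      fit = function(data, outcome, params) {
        d <- data[setdiff(names(data), c("patient_id", "poms_count_d3"))]
        d[[outcome]] <- factor(d[[outcome]], levels = c(0, 1))
        rpart::rpart(stats::reformulate(".", response = outcome), data = d,
                     method = "class",
                     control = rpart::rpart.control(
                       cp = params$cp %||% 0.01,
                       maxdepth = params$maxdepth %||% 5))
      },
      predict = function(model, newdata)
        as.numeric(predict(model, newdata = newdata, type = "prob")[, "1"])),
    rf = list(
      name = "rf",
      default_grid = data.frame(ntree = c(100, 300), mtry_frac = c(0.2, 0.33)),
      fit = function(data, outcome, params) {
        x <- .feature_matrix(data, outcome)
        randomForest::randomForest(
          x, factor(data[[outcome]], levels = c(0, 1)),
          ntree = params$ntree %||% 300,
          mtry = max(1L, floor((params$mtry_frac %||% 0.33) * ncol(x))))
      },
      predict = function(model, newdata) {
        x <- .feature_matrix(newdata, "poms_class_d3")
        as.numeric(predict(model, newdata = x, type = "prob")[, "1"])
      }),
    gbt = list(
      name = "gbt",
      default_grid = data.frame(nrounds = c(50, 100, 200),
                                max_depth = c(2, 3, 4),
                                eta = c(0.3, 0.1, 0.1)),
      fit = function(data, outcome, params) {
        x <- .feature_matrix(data, outcome)
        xgboost::xgboost(x, factor(data[[outcome]], levels = c(0, 1)),
                         nrounds = params$nrounds %||% 100,
                         max_depth = params$max_depth %||% 3,
                         learning_rate = params$eta %||% 0.1,
                         nthreads = 1, verbosity = 0)
      },
      predict = function(model, newdata) {
        x <- .feature_matrix(newdata, "poms_class_d3")
        as.numeric(predict(model, x, type = "response"))
      }))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[[1]])) b else a

#' Fit the reference classifiers under the shared harness
#'
#' Tunes each requested learner by [grid_search_cv()] on the training
#' partition and returns frozen probability predictors for the test rows.
#'
#' @param train,test preprocessed data frames.
#' @param learners character vector of [reference_learner()] names.
#' @param folds CV folds for the grid search.
#' @param seed integer seed.
#' @param outcome outcome column name.
#' @return Named list per learner: `probabilities`, `best_params`,
#'   `cv_table`, `predict_fun`.
#' @export
reference_classifiers <- function(train, test,
                                  learners = c("lr", "dt", "rf", "gbt"),
                                  folds = 10L, seed = 1L,
                                  outcome = "poms_class_d3") {
  out <- lapply(learners, function(nm) {
    lrn <- reference_learner(nm)
    set.seed(seed)
    gs <- grid_search_cv(lrn, train, lrn$default_grid, folds = folds,
                         seed = seed, outcome = outcome)
    predict_fun <- function(newdata) lrn$predict(gs$model, newdata)
    list(probabilities = predict_fun(test),
         best_params = gs$best_params,
         cv_table = gs$cv_table,
         predict_fun = predict_fun)
  })
  stats::setNames(out, learners)
}
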