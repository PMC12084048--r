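#' Experiment specification
#'
#' Describes one end-to-end study: which dataset arms to run (tabular
#' clinical-only, CRF-only, combined; waveform-derived `crf_ts`; and the
#' scalar `crf_subset` restricted to exactly the waveform patients), which
#' model arms, the split/evaluation plan, and the generator and evolution
#' settings. All stage seeds derive deterministically from `seed`.
#'
#' @param dataset_arms subset of `c("clinical", "crf", "combined", "crf_ts",
#'   "crf_subset")`.
#' @param model_arms subset of `c("mosr", "lr", "dt", "rf", "gbt")`.
#' @param generator a [cohort_config()] (used when no user data is given).
#' @param evolution an [evolution_config()] for the MOSR arm.
#' @param split_ratio outer train fraction (default 0.8).
#' @param val_ratio train-side fraction kept for champion validation
#'   (default 0.9 train / 0.1 validation).
#' @param cv_folds grid-search folds for the reference arms (default 10).
#' @param n_test_runs,test_fraction repeated-evaluation plan (default 10
#'   runs on 90% subsamples).
#' @param ts_target_len downsampled length per waveform channel.
#' @param waveform_noise_sd noise multiplier for generated waveforms.
#' @param seed master seed.
#' @return An `experiment_spec` list.
#' @export
experiment_spec <- function(dataset_arms = c("clinical", "crf", "combined"),
                            model_arms = c("mosr", "lr"),
                            generator = cohort_config(),
                            evolution = evolution_config(),
                            split_ratio = 0.8, val_ratio = 0.9,
                            cv_folds = 10L, n_test_runs = 10L,
                            test_fraction = 0.9, ts_target_len = 100L,
                            waveform_noise_sd = 0.5, seed = 1L) {
  dataset_arms <- match.arg(dataset_arms,
                            c("clinical", "crf", "combined", "crf_ts",
                              "crf_subset"), several.ok = TRUE)
  model_arms <- match.arg(model_arms, c("mosr", "lr", "dt", "rf", "gbt"),
                          several.ok = TRUE)
  stopifnot(length(dataset_arms) >= 1L, length(model_arms) >= 1L)
  structure(list(dataset_arms = dataset_arms, model_arms = model_arms,
                 generator = generator, evolution = evolution,
                 split_ratio = split_ratio, val_ratio = val_ratio,
                 cv_folds = as.integer(cv_folds),
                 n_test_runs = as.integer(n_test_runs),
                 test_fraction = test_fraction,
                 ts_target_len = as.integer(ts_target_len),
                 waveform_noise_sd = waveform_noise_sd,
                 seed = as.integer(seed)),
            class = "experiment_spec")
}

# deterministic per-stage seed derivation, kept inside 32-bit integer range
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h) %% 2147483629)
}

.arm_dataset <- function(arm, cohort, waveforms, ts_target_len) {
  keep_meta <- c("patient_id", "poms_class_d3")
  if (arm == "crf_ts") {
    outcome <- stats::setNames(cohort$poms_class_d3, cohort$patient_id)
    return(build_ts_feature_matrix(waveforms, ts_target_len, outcome = outcome))
  }
  cols <- switch(arm,
    clinical = cohort_features(cohort, "clinical"),
    crf = cohort_features(cohort, "crf"),
    combined = cohort_features(cohort, "all"),
    crf_subset = cohort_features(cohort, "crf"))
  d <- as.data.frame(cohort)[c(keep_meta[1], cols, keep_meta[2])]
  if (arm == "crf_subset")
    d <- d[d$patient_id %in% names(waveforms), , drop = FALSE]
  d
}

.fit_mosr_arm <- function(train, evolution, val_ratio, seed,
                          outcome = "poms_class_d3") {
  inner <- stratified_split(train, val_ratio, seed = seed, outcome = outcome)
  cfg <- evolution
  cfg$seed <- seed
  drop <- intersect(c("patient_id", "poms_count_d3"), names(train))
  fit <- mosr_evolve(inner$a[setdiff(names(inner$a), drop)], outcome,
                     config = cfg,
                     validation = inner$b[setdiff(names(inner$b), drop)])
  list(fit = fit,
       predict_fun = function(newdata) predict(fit, newdata, type = "prob"))
}

#' Run a full experiment
#'
#' For each dataset arm: generate (or take) the cohort, split 80:20
#' stratified, fit the train-only preprocessing transform, fit every model
#' arm (MOSR by evolution with a 90:10 train/validation champion split;
#' reference learners by cross-validated grid search), then evaluate each
#' frozen model by repeated test subsampling. No stage ever touches the test
#' partition before the final evaluation.
#'
#' @param spec an [experiment_spec()].
#' @param cohort optional pre-built `cohort_table`; generated from
#'   `spec$generator` when `NULL`.
#' @param waveforms optional named list of `cpet_series`; generated when
#'   `NULL` and a waveform arm is requested.
#' @return An `experiment_report`: nested list `results[[arm]][[model]]`
#'   with `report` (a `metric_report`), plus per-arm split sizes, MOSR
#'   champion formulae, the experiment specification, and a manifest of
#'   derived seeds.
#' @export
run_experiment <- function(spec, cohort = NULL, waveforms = NULL) {
  stopifnot(inherits(spec, "experiment_spec"))
  if (is.null(cohort)) cohort <- generate_cohort(spec$generator)
  if (is.null(waveforms) &&
      any(spec$dataset_arms %in% c("crf_ts", "crf_subset"))) {
    set.seed(stage_seed(spec$seed, "waveforms"))
    waveforms <- generate_cohort_waveforms(cohort,
                                           noise_sd = spec$waveform_noise_sd)
  }

  results <- list()
  formulas <- list()
  manifest <- list(master_seed = spec$seed, stages = list())
  for (arm in spec$dataset_arms) {
    d <- .arm_dataset(arm, cohort, waveforms, spec$ts_target_len)
    # the two waveform arms share one split so they are compared on the same
    # patients (the scalar-subset arm is evaluated against the identical
    # test subset as the time-series arm)
    split_stage <- if (arm %in% c("crf_ts", "crf_subset")) "waveform_cohort"
                   else arm
    split_seed <- stage_seed(spec$seed, paste0("split_", split_stage))
    sp <- stratified_split(d, spec$split_ratio, seed = split_seed)
    tf <- preprocess_fit(sp$a)
    train <- preprocess_apply(tf, sp$a)
    test <- preprocess_apply(tf, sp$b)
    arm_results <- list()
    for (model in spec$model_arms) {
      fit_seed <- stage_seed(spec$seed, paste0("fit_", arm, "_", model))
      eval_seed <- stage_seed(spec$seed, paste0("eval_", arm, "_", model))
      if (model == "mosr") {
        fitted <- .fit_mosr_arm(train, spec$evolution, spec$val_ratio,
                                fit_seed)
        formulas[[paste(arm, "mosr", sep = "_")]] <-
          to_formula_text(fitted$fit$champion$tree)
        predict_fun <- fitted$predict_fun
        extra <- list(fit = fitted$fit)
      } else {
        lrn <- reference_learner(model)
        drop <- intersect(c("patient_id", "poms_count_d3"), names(train))
        tr <- train[setdiff(names(train), drop)]
        set.seed(fit_seed)
        gs <- grid_search_cv(lrn, tr, lrn$default_grid,
                             folds = spec$cv_folds, seed = fit_seed)
        predict_fun <- function(newdata) lrn$predict(gs$model, newdata)
        extra <- list(best_params = gs$best_params)
      }
      report <- repeated_test_evaluation(predict_fun, test,
                                         n_runs = spec$n_test_runs,
                                         fraction = spec$test_fraction,
                                         seed = eval_seed)
      arm_results[[model]] <- c(list(report = report), extra)
      manifest$stages[[paste(arm, model, sep = "/")]] <-
        list(fit_seed = fit_seed, eval_seed = eval_seed)
    }
    results[[arm]] <- arm_results
    manifest$stages[[paste0("split/", arm)]] <-
      list(seed = split_seed, n_train = nrow(sp$a), n_test = nrow(sp$b))
  }
  structure(list(results = results, champion_formulas = formulas,
                 spec = spec, manifest = manifest),
            class = "experiment_report")
}

#' Summarise an experiment report as a metric table
#'
#' One row per dataset arm x model arm x metric, mirroring the standard
#' mean-and-95%-CI presentation.
#'
#' @param report an `experiment_report`.
#' @return Data frame with `arm`, `model`, `metric`, `mean`, `ci_half`.
#' @export
report_table <- function(report) {
  rows <- list()
  for (arm in names(report$results))
    for (model in names(report$results[[arm]])) {
      r <- report$results[[arm]][[model]]$report
      rows[[paste(arm, model)]] <-
        cbind(data.frame(arm = arm, model = model),
              as.data.frame(r)[c("metric", "mean", "ci_half")])
    }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
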