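#' Study evaluation protocol
#'
#' Data handling and measurement: train-only preprocessing (binary coding,
#' one-hot expansion, 0-1 min-max scaling), stratified splitting with
#' largest-remainder class allocation, 10-fold cross-validated grid search,
#' repeated test-subsample evaluation with t-based confidence intervals, and
#' ROC/PR computation.
#'
#' @name evaluation
NULL

round_half_up <- function(x) floor(x + 0.5)

#' Fit a preprocessing transform on the training partition
#'
#' Learns, from `data` only: min/max for continuous columns (rescaled to
#' 0-1), the level sets of non-ordinal categorical columns (one-hot
#' expanded as `<name>_<level>` indicators), and passes already-binary 0/1
#' columns through unchanged. Apply the frozen transform to any partition
#' with [preprocess_apply()]; continuous values outside the training range
#' map outside \[0, 1\] (no clipping) and raise a warning, and categories
#' unseen in training map to all-zero indicators with a warning.
#'
#' @param data training data frame.
#' @param categorical character vector of non-ordinal categorical columns to
#'   one-hot encode.
#' @param exclude columns (ids, outcomes) copied through untouched.
#' @return A `preprocess_transform` object.
#' @export
preprocess_fit <- function(data, categorical = character(0),
                           exclude = c("patient_id", "poms_count_d3",
                                       "poms_class_d3")) {
  cols <- setdiff(names(data), exclude)
  spec <- lapply(cols, function(cn) {
    v <- data[[cn]]
    if (cn %in% categorical)
      return(list(type = "onehot", levels = sort(unique(as.character(v)))))
    if (is.numeric(v) && all(v %in% c(0, 1)))
      return(list(type = "binary"))
    if (!is.numeric(v))
      stop("column '", cn, "' is non-numeric; list it in `categorical`")
    list(type = "minmax", min = min(v), max = max(v))
  })
  structure(list(spec = stats::setNames(spec, cols), exclude = exclude),
            class = "preprocess_transform")
}

#' Apply a frozen preprocessing transform
#'
#' @param transform a `preprocess_transform` from [preprocess_fit()].
#' @param data data frame to transform (any partition).
#' @return Transformed data frame; excluded columns present in `data` are
#'   carried through unchanged.
#' @export
preprocess_apply <- function(transform, data) {
  out <- list()
  for (cn in intersect(transform$exclude, names(data))) out[[cn]] <- data[[cn]]
  for (cn in names(transform$spec)) {
    s <- transform$spec[[cn]]
    v <- data[[cn]]
    if (is.null(v)) stop("column '", cn, "' missing at apply time")
    if (s$type == "binary") {
      out[[cn]] <- as.numeric(v)
    } else if (s$type == "minmax") {
      rng <- s$max - s$min
      scaled <- if (rng > 0) (v - s$min) / rng else rep(0, length(v))
      if (any(scaled < 0 | scaled > 1))
        warning("column '", cn, "': ", sum(scaled < 0 | scaled > 1),
                " value(s) outside the training range (not clipped)")
      out[[cn]] <- scaled
    } else {
      chr <- as.character(v)
      unseen <- setdiff(unique(chr), s$levels)
      if (length(unseen) > 0L)
        warning("column '", cn, "': unseen categor",
                if (length(unseen) > 1) "ies " else "y ",
                paste(unseen, collapse = ", "), " mapped to all-zero")
      for (lv in s$levels)
        out[[paste0(cn, "_", lv)]] <- as.numeric(chr == lv)
    }
  }
  as.data.frame(out, check.names = FALSE)
}

#' Stratified two-way split
#'
#' Partition sizes follow round-half-up on `ratio * n`; the size of the
#' first partition is allocated across outcome classes by largest remainder
#' so class prevalence matches within one sample. Partitions are disjoint
#' and exhaustive.
#'
#' @param data data frame with a binary outcome column.
#' @param ratio fraction assigned to the first partition.
#' @param seed integer seed for the within-class shuffles.
#' @param outcome outcome column name.
#' @return List with data frames `a` and `b` and the index vectors
#'   `idx_a`, `idx_b`.
#' @export
stratified_split <- function(data, ratio, seed = 1L,
                             outcome = "poms_class_d3") {
  y <- data[[outcome]]
  if (is.null(y)) stop("outcome column '", outcome, "' not found")
  classes <- sort(unique(y))
  if (any(table(y) < 2L)) stop("every class needs at least 2 members")
  n <- nrow(data)
  size_a <- round_half_up(ratio * n)

  per_class_n <- vapply(classes, function(cl) sum(y == cl), numeric(1))
  ideal <- ratio * per_class_n
  alloc <- floor(ideal)
  short <- size_a - sum(alloc)
  if (short > 0) {
    order_rem <- order(ideal - alloc, decreasing = TRUE)
    alloc[order_rem[seq_len(short)]] <- alloc[order_rem[seq_len(short)]] + 1
  } else if (short < 0) {
    order_rem <- order(ideal - alloc)
    alloc[order_rem[seq_len(-short)]] <- alloc[order_rem[seq_len(-short)]] - 1
  }

  set.seed(seed)
  idx_a <- integer(0)
  for (k in seq_along(classes)) {
    members <- which(y == classes[k])
    idx_a <- c(idx_a, sample(members, alloc[k]))
  }
  idx_a <- sort(idx_a)
  idx_b <- setdiff(seq_len(n), idx_a)
  list(a = data[idx_a, , drop = FALSE], b = data[idx_b, , drop = FALSE],
       idx_a = idx_a, idx_b = idx_b)
}

# stratified fold assignment; every fold sees both classes whenever each
# class has at least `folds` members
.stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  fold_of <- integer(length(y))
  for (cl in unique(y)) {
    members <- sample(which(y == cl))
    fold_of[members] <- rep_len(seq_len(folds), length(members))
  }
  for (f in seq_len(folds))
    if (length(unique(y[fold_of == f])) < 2L)
      stop("fold ", f, " has a single class; too few samples for ", folds,
           " stratified folds")
  fold_of
}

#' Cross-validated grid search
#'
#' Scores every configuration of a learner by the mean validation metric
#' over stratified folds, picks the best (ties resolve to the earliest grid
#' row — order grids simple to complex), and refits it on the full training
#' set.
#'
#' @param learner a list with `fit(data, outcome, params)` returning a model
#'   and `predict(model, newdata)` returning probabilities.
#' @param data training data frame.
#' @param grid data frame of parameter configurations (one row each).
#' @param folds number of CV folds (default 10).
#' @param seed integer seed for fold assignment.
#' @param outcome outcome column name.
#' @param metric `"auc"` (maximised) or `"bce"` (minimised).
#' @return List: `model` (refit on all of `data`), `best_params` (one-row
#'   data frame), `cv_table` (per-configuration mean and SD of the metric).
#' @export
grid_search_cv <- function(learner, data, grid, folds = 10L, seed = 1L,
                           outcome = "poms_class_d3", metric = c("auc", "bce")) {
  metric <- match.arg(metric)
  if (nrow(grid) == 0L) stop("empty grid")
  y <- data[[outcome]]
  fold_of <- .stratified_folds(y, folds, seed)
  scores <- matrix(NA_real_, nrow(grid), folds)
  for (g in seq_len(nrow(grid))) {
    params <- as.list(grid[g, , drop = FALSE])
    for (f in seq_len(folds)) {
      tr <- data[fold_of != f, , drop = FALSE]
      va <- data[fold_of == f, , drop = FALSE]
      model <- learner$fit(tr, outcome, params)
      p <- learner$predict(model, va)
      scores[g, f] <- if (metric == "auc") roc_auc(p, va[[outcome]])
                      else binary_cross_entropy(p, va[[outcome]])
    }
  }
  mean_score <- rowMeans(scores)
  best <- if (metric == "auc") which.max(mean_score) else which.min(mean_score)
  cv_table <- cbind(grid,
                    data.frame(mean_metric = mean_score,
                               sd_metric = apply(scores, 1L, stats::sd)))
  list(model = learner$fit(data, outcome, as.list(grid[best, , drop = FALSE])),
       best_params = grid[best, , drop = FALSE],
       cv_table = cv_table)
}

#' Confusion-matrix metric panel
#'
#' Computes accuracy, AUC, F1, sensitivity, specificity, PPV and NPV from
#' probabilities and binary labels at decision threshold 0.5. Metrics with a
#' zero denominator (e.g. specificity on an all-positive sample) come back
#' `NA` and are counted in the `undefined` attribute.
#'
#' @param probabilities predicted probabilities.
#' @param labels binary 0/1 labels.
#' @param threshold decision threshold (default 0.5).
#' @return Named list with the seven metrics plus confusion counts
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
metric_panel <- function(probabilities, labels, threshold = 0.5) {
  pred <- as.integer(probabilities >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  ppv <- safe_div(tp, tp + fp)
  npv <- safe_div(tn, tn + fn)
  f1 <- if (is.na(ppv) || is.na(sens) || (ppv + sens) == 0) NA_real_
        else 2 * ppv * sens / (ppv + sens)
  auc <- if (length(unique(labels)) < 2L) NA_real_
         else roc_auc(probabilities, labels)
  list(accuracy = (tp + tn) / length(labels), auc = auc, f1 = f1,
       sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Repeated test-subsample evaluation
#'
#' Evaluates a frozen model over `n_runs` random subsamples of the held-out
#' test partition: each run draws `floor(fraction * n)` rows without
#' replacement, computes the full [metric_panel()], and the report gives the
#' mean and 95% Student-t confidence half-width (df = `n_runs - 1`) per
#' metric, excluding runs where a metric was undefined (exclusions are
#' counted).
#'
#' @param predict_fun function mapping a data frame to probabilities (the
#'   frozen model; no refitting happens here).
#' @param test held-out test data frame.
#' @param n_runs number of subsample runs (default 10).
#' @param fraction subsample fraction (default 0.9; `fraction = 1` disables
#'   subsampling and yields zero-width intervals).
#' @param seed integer seed for the subsample draws.
#' @param outcome outcome column name.
#' @return A `metric_report`: data frame with columns `metric`, `mean`,
#'   `ci_half`, `n_used`, `n_excluded`; per-run panels in attribute `runs`.
#' @export
repeated_test_evaluation <- function(predict_fun, test, n_runs = 10L,
                                     fraction = 0.9, seed = 1L,
                                     outcome = "poms_class_d3") {
  stopifnot(fraction > 0, fraction <= 1)
  n <- nrow(test)
  m <- as.integer(floor(fraction * n))
  set.seed(seed)
  runs <- lapply(seq_len(n_runs), function(r) {
    idx <- if (fraction < 1) sample.int(n, m) else seq_len(n)
    sub <- test[idx, , drop = FALSE]
    metric_panel(predict_fun(sub), sub[[outcome]])
  })
  metrics <- c("accuracy", "auc", "f1", "sensitivity", "specificity",
               "ppv", "npv")
  report <- do.call(rbind, lapply(metrics, function(mname) {
    vals <- vapply(runs, function(r) r[[mname]], numeric(1))
    ok <- vals[!is.na(vals)]
    k <- length(ok)
    ci <- if (k >= 2L && stats::sd(ok) > 0)
      stats::qt(0.975, df = k - 1L) * stats::sd(ok) / sqrt(k) else 0
    data.frame(metric = mname, mean = if (k > 0) mean(ok) else NA_real_,
               ci_half = ci, n_used = k, n_excluded = n_runs - k)
  }))
  attr(report, "runs") <- runs
  attr(report, "subsample_size") <- m
  class(report) <- c("metric_report", "data.frame")
  report
}

#' Area under the ROC curve
#'
#' Tie-corrected pairwise concordance computed from mid-ranks: tied
#' positive/negative score pairs count one half.
#'
#' @param probabilities scores (any monotone scale).
#' @param labels binary 0/1 labels with both classes present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(probabilities, labels) {
  if (length(probabilities) != length(labels)) stop("length mismatch")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(probabilities)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * n0)
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return Data frame with `threshold`, `fpr`, `tpr`, one row per distinct
#'   score plus the endpoints.
#' @export
roc_curve <- function(probabilities, labels) {
  ord <- order(probabilities, decreasing = TRUE)
  p <- probabilities[ord]; y <- labels[ord]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  keep <- c(which(diff(p) != 0), length(p))
  tpr <- cumsum(y == 1)[keep] / n1
  fpr <- cumsum(y == 0)[keep] / n0
  data.frame(threshold = c(Inf, p[keep]), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Precision-recall curve points
#'
#' Rows are sorted by decreasing score; ties are processed as one block.
#'
#' @inheritParams roc_auc
#' @return Data frame with `threshold`, `recall`, `precision`.
#' @export
pr_curve <- function(probabilities, labels) {
  ord <- order(probabilities, decreasing = TRUE)
  p <- probabilities[ord]; y <- labels[ord]
  n1 <- sum(y == 1)
  if (n1 == 0L) stop("no positive labels")
  keep <- c(which(diff(p) != 0), length(p))
  tp <- cumsum(y == 1)[keep]
  pred_pos <- keep
  data.frame(threshold = p[keep], recall = tp / n1,
             precision = tp / pred_pos)
}
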