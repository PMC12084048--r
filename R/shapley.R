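#' Model-agnostic Shapley feature attribution
#'
#' Per-row, per-feature Shapley values for any model exposing a probability
#' output, with absent features marginalised by substituting values from a
#' background sample (the marginal, KernelSHAP-style assumption). Feature
#' sets of at most `exact_limit` features are attributed by exact coalition
#' enumeration; larger sets use the permutation-sampling estimator.
#' Attributions live on the probability scale, so per row the feature values
#' plus the baseline (mean model output over the background) reconstruct the
#' model output — exactly on the enumeration path, within Monte-Carlo
#' tolerance on the sampling path.
#'
#' @param predict_fun function mapping a feature data frame to
#'   probabilities.
#' @param rows data frame of rows to explain.
#' @param background non-empty data frame of background rows (canonically a
#'   ~100-row stratified sample of the training partition).
#' @param n_permutations permutations per explained row for the sampling
#'   estimator (default 100).
#' @param seed integer seed for the sampling path.
#' @param features columns to attribute (default: all shared columns of
#'   `rows` and `background`).
#' @param exact_limit feature-count threshold for exact enumeration
#'   (default 12).
#' @return An `attribution_result`: list with `values` (rows x features
#'   matrix of Shapley values), `baseline`, `prediction` (model output per
#'   row), `features`, `method` (`"exact"` or `"sampling"`).
#' @export
shapley_values <- function(predict_fun, rows, background,
                           n_permutations = 100L, seed = 1L,
                           features = NULL, exact_limit = 12L) {
  if (nrow(background) == 0L) stop("background must be non-empty")
  if (is.null(features))
    features <- intersect(names(rows), names(background))
  p <- length(features)
  stopifnot(p >= 1L)
  baseline <- mean(predict_fun(background))
  method <- if (p <= exact_limit) "exact" else "sampling"
  set.seed(seed)
  values <- if (method == "exact")
    .shapley_exact(predict_fun, rows, background, features)
  else
    .shapley_sampling(predict_fun, rows, background, features, n_permutations)
  structure(list(values = values, baseline = baseline,
                 prediction = predict_fun(rows), features = features,
                 method = method),
            class = "attribution_result")
}

# value function v(S): mean over the background of the model output with
# features in S taken from the explained row, the rest from the background row
.coalition_value <- function(predict_fun, row, background, features, S) {
  data <- background
  for (f in features[S]) data[[f]] <- row[[f]]
  mean(predict_fun(data))
}

.shapley_exact <- function(predict_fun, rows, background, features) {
  p <- length(features)
  n_subsets <- 2^p
  # subset membership matrix and cached values per explained row
  membership <- matrix(FALSE, n_subsets, p)
  for (j in seq_len(p))
    membership[, j] <- bitwAnd(seq_len(n_subsets) - 1L, bitwShiftL(1L, j - 1L)) > 0L
  sizes <- rowSums(membership)
  # weight of coalition S for a feature j not in S; the full set never plays
  # that role, so its (undefined) weight is pinned to zero
  w <- ifelse(sizes < p,
              factorial(sizes) * factorial(pmax(p - sizes - 1, 0)) / factorial(p),
              0)

  out <- matrix(0, nrow(rows), p, dimnames = list(NULL, features))
  for (r in seq_len(nrow(rows))) {
    row <- rows[r, , drop = FALSE]
    vals <- vapply(seq_len(n_subsets), function(s)
      .coalition_value(predict_fun, row, background, features, membership[s, ]),
      numeric(1))
    for (j in seq_len(p)) {
      without <- which(!membership[, j])
      with_j <- without + bitwShiftL(1L, j - 1L)
      out[r, j] <- sum(w[without] * (vals[with_j] - vals[without]))
    }
  }
  out
}

.shapley_sampling <- function(predict_fun, rows, background, features,
                              n_permutations) {
  p <- length(features)
  nb <- nrow(background)
  out <- matrix(0, nrow(rows), p, dimnames = list(NULL, features))
  for (r in seq_len(nrow(rows))) {
    row <- rows[r, , drop = FALSE]
    acc <- numeric(p)
    for (m in seq_len(n_permutations)) {
      perm <- sample.int(p)
      b <- background[sample.int(nb, 1L), , drop = FALSE]
      current <- b
      prev <- predict_fun(current)
      for (j in perm) {
        current[[features[j]]] <- row[[features[j]]]
        cur <- predict_fun(current)
        acc[j] <- acc[j] + (cur - prev)
        prev <- cur
      }
    }
    out[r, ] <- acc / n_permutations
  }
  out
}

#' Global feature ranking from attributions
#'
#' Orders features by descending mean absolute Shapley value; ties keep
#' alphabetical (name) order for stability.
#'
#' @param result an `attribution_result` from [shapley_values()].
#' @return Data frame with `feature` and `mean_abs_value`, most important
#'   first.
#' @export
rank_features <- function(result) {
  stopifnot(inherits(result, "attribution_result"))
  mav <- colMeans(abs(result$values))
  ord <- order(-mav, result$features)
  data.frame(feature = result$features[ord], mean_abs_value = mav[ord],
             row.names = NULL)
}

#' Long-format attribution table
#'
#' @param result an `attribution_result`.
#' @param row_ids optional row identifiers.
#' @return Data frame `row_id, feature, shap_value` (beeswarm-ready).
#' @export
attribution_long <- function(result, row_ids = NULL) {
  n <- nrow(result$values)
  if (is.null(row_ids)) row_ids <- seq_len(n)
  data.frame(row_id = rep(row_ids, times = length(result$features)),
             feature = rep(result$features, each = n),
             shap_value = as.vector(result$values))
}
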