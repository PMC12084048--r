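#' Binary cross-entropy
#'
#' Mean negative Bernoulli log-likelihood,
#' `-mean(y * log(p) + (1 - y) * log(1 - p))`. Probabilities are clipped into
#' `[1e-12, 1 - 1e-12]` first so the loss is finite for degenerate
#' predictions.
#'
#' @param probabilities numeric vector of predicted probabilities.
#' @param labels binary (0/1) vector of the same length.
#' @return Non-negative scalar loss.
#' @export
binary_cross_entropy <- function(probabilities, labels) {
  if (length(probabilities) != length(labels))
    stop("probabilities and labels must have equal length")
  if (length(labels) == 0L) stop("empty input")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  p <- clip_probability(probabilities)
  -mean(labels * log(p) + (1 - labels) * log1p(-p))
}

#' Complexity-penalised AIC objective
#'
#' The parsimony objective of the evolutionary engine:
#' `2 * k + 2 * n * bce`, i.e. `2k - 2 log L` under the Bernoulli likelihood,
#' with model complexity `k` taken as the formula's node count. Strictly
#' increasing in `k` at fixed loss, so among equally accurate formulae the
#' smaller one always wins.
#'
#' @param bce mean binary cross-entropy on the training rows.
#' @param n number of training rows.
#' @param k complexity (node count), `>= 1`.
#' @return Scalar criterion value (smaller is better).
#' @export
partial_aic <- function(bce, n, k) {
  stopifnot(n >= 1, k >= 1, is.finite(bce), bce >= 0)
  2 * k + 2 * n * bce
}
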