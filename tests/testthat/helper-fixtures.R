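# Shared fixtures and independent oracles used across test files.

# planted-logit classification problem: y = 1[sigmoid(3 x1 - 3 x2) > u]
make_planted_data <- function(n, n_noise = 0, seed = 1, sd = 2) {
  set.seed(seed)
  p <- 2 + n_noise
  d <- as.data.frame(matrix(rnorm(n * p, sd = sd), n, p))
  names(d) <- paste0("x", seq_len(p))
  d$y <- as.integer(runif(n) < plogis(3 * d$x1 - 3 * d$x2))
  d
}

# brute-force sliding median with shrinking symmetric edge windows
oracle_median_filter <- function(x, k) {
  h <- (k - 1) / 2
  n <- length(x)
  sapply(seq_len(n), function(i) {
    hh <- min(h, i - 1, n - i)
    median(x[(i - hh):(i + hh)])
  })
}

# O(n^2) pairwise-dominance front peeling (minimisation)
oracle_fronts <- function(obj) {
  n <- nrow(obj)
  remaining <- seq_len(n)
  fronts <- list()
  dominates <- function(i, j)
    all(obj[i, ] <= obj[j, ]) && any(obj[i, ] < obj[j, ])
  while (length(remaining) > 0) {
    nd <- remaining[sapply(remaining, function(j)
      !any(sapply(remaining, function(i) i != j && dominates(i, j))))]
    fronts[[length(fronts) + 1]] <- sort(nd)
    remaining <- setdiff(remaining, nd)
  }
  fronts
}

# naive per-breakpoint two-segment least squares via lm refits
oracle_breakpoint <- function(x, y, min_segment) {
  m <- length(x)
  best <- NULL
  for (b in min_segment:(m - min_segment + 1)) {
    f1 <- lm(y[1:b] ~ x[1:b])
    f2 <- lm(y[b:m] ~ x[b:m])
    if (coef(f2)[2] <= coef(f1)[2]) next
    rss <- sum(resid(f1)^2) + sum(resid(f2)^2)
    if (is.null(best) || rss < best$rss) best <- list(b = b, rss = rss)
  }
  best
}

# O(n^2) concordance AUC with half-credit ties
oracle_auc <- function(s, y) {
  pos <- s[y == 1]; neg <- s[y == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# exact Shapley values by enumerating all feature orderings (independent of
# the package's subset-enumeration path)
oracle_shapley <- function(predict_fun, row, background, features) {
  p <- length(features)
  perms <- .permutations(p)
  vals <- numeric(p)
  v <- function(S) {
    d <- background
    for (f in features[S]) d[[f]] <- row[[f]]
    mean(predict_fun(d))
  }
  for (k in seq_len(nrow(perms))) {
    S <- logical(p)
    prev <- v(S)
    for (j in perms[k, ]) {
      S[j] <- TRUE
      cur <- v(S)
      vals[j] <- vals[j] + (cur - prev)
      prev <- cur
    }
  }
  vals / nrow(perms)
}

.permutations <- function(p) {
  if (p == 1) return(matrix(1))
  sub <- .permutations(p - 1)
  do.call(rbind, lapply(seq_len(p), function(i)
    cbind(i, matrix(setdiff(seq_len(p), i)[sub], nrow(sub)))))
}
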