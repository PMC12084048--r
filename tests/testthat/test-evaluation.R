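test_that("min-max scaling learns on train only and flags out-of-range values", {
  train <- data.frame(v = c(10, 12, 20), poms_class_d3 = c(0, 1, 1))
  tf <- preprocess_fit(train)
  test <- data.frame(v = c(15, 25), poms_class_d3 = c(0, 1))
  expect_warning(out <- preprocess_apply(tf, test), "outside the training range")
  expect_equal(out$v, c(0.5, 1.5))  # no clipping
})

test_that("one-hot expansion sums to one per row and unseen levels map to zero", {
  train <- data.frame(surgery = c("a", "b", "c", "a"),
                      poms_class_d3 = c(0, 1, 0, 1))
  tf <- preprocess_fit(train, categorical = "surgery")
  out <- preprocess_apply(tf, train)
  oh <- out[paste0("surgery_", c("a", "b", "c"))]
  expect_true(all(rowSums(oh) == 1))
  test <- data.frame(surgery = "zz", poms_class_d3 = 0)
  expect_warning(o2 <- preprocess_apply(tf, test), "unseen")
  expect_equal(sum(o2[paste0("surgery_", c("a", "b", "c"))]), 0)
})

test_that("binary 0/1 columns pass through unchanged", {
  train <- data.frame(flag = c(0, 1, 0), v = c(1, 2, 3),
                      poms_class_d3 = c(0, 1, 1))
  out <- preprocess_apply(preprocess_fit(train), train)
  expect_equal(out$flag, c(0, 1, 0))
  expect_equal(out$v, c(0, 0.5, 1))
})

test_that("stratified split reproduces the protocol partition sizes", {
  mk <- function(n, npos) data.frame(poms_class_d3 = c(rep(1, npos), rep(0, n - npos)))
  s1 <- stratified_split(mk(1190, 633), 0.8, seed = 1)
  expect_equal(nrow(s1$a), 952)
  expect_equal(nrow(s1$b), 238)
  s2 <- stratified_split(mk(952, 506), 0.9, seed = 1)
  expect_equal(nrow(s2$a), 857)
  expect_equal(nrow(s2$b), 95)
})

test_that("split prevalence matches within one sample and partitions are exact", {
  set.seed(19)
  for (i in 1:25) {
    n <- sample(20:400, 1)
    npos <- sample(5:(n - 5), 1)
    ratio <- runif(1, 0.3, 0.9)
    d <- data.frame(poms_class_d3 = sample(c(rep(1, npos), rep(0, n - npos))))
    sp <- stratified_split(d, ratio, seed = i)
    expect_equal(nrow(sp$a) + nrow(sp$b), n)
    expect_equal(nrow(sp$a), floor(ratio * n + 0.5))
    expect_setequal(c(sp$idx_a, sp$idx_b), seq_len(n))
    # class allocation off by at most one sample from the ideal quota
    expect_lte(abs(sum(sp$a$poms_class_d3) - ratio * npos), 1)
  }
  d10 <- data.frame(poms_class_d3 = rep(c(0, 1), 5))
  sp <- stratified_split(d10, 0.5, seed = 2)
  expect_equal(nrow(sp$a), 5)
  expect_lte(abs(sum(sp$a$poms_class_d3) - 2.5), 0.5)
})

test_that("grid search returns the single point, prefers dominators, matches refits", {
  d <- make_planted_data(120, seed = 22)
  names(d)[names(d) == "y"] <- "poms_class_d3"
  lrn <- reference_learner("dt")
  one <- data.frame(cp = 0.01, maxdepth = 4)
  gs <- grid_search_cv(lrn, d, one, folds = 5, seed = 3)
  expect_equal(gs$best_params$cp, 0.01)

  # a configuration strictly better on every fold must win: compare a depth-1
  # stump against a reasonable tree on strongly non-linear-in-one-split data
  grid <- data.frame(cp = c(0.0, 0.5), maxdepth = c(6, 1))
  gs2 <- grid_search_cv(lrn, d, grid, folds = 5, seed = 3)
  expect_equal(gs2$best_params$maxdepth, 6)

  # CV table equals an exhaustive manual refit with the same folds
  grid3 <- data.frame(cp = c(0.05, 0.01, 0.002), maxdepth = c(3, 5, 8))
  gs3 <- grid_search_cv(lrn, d, grid3, folds = 4, seed = 9)
  fold_of <- mosr:::.stratified_folds(d$poms_class_d3, 4, 9)
  for (g in 1:3) {
    scores <- sapply(1:4, function(f) {
      fit <- lrn$fit(d[fold_of != f, ], "poms_class_d3", as.list(grid3[g, ]))
      roc_auc(lrn$predict(fit, d[fold_of == f, ]),
              d$poms_class_d3[fold_of == f])
    })
    expect_equal(gs3$cv_table$mean_metric[g], mean(scores), tolerance = 1e-12)
  }
})

test_that("repeated evaluation draws the protocol subsample size and handles degeneracy", {
  set.seed(29)
  test <- data.frame(x = rnorm(238), poms_class_d3 = rbinom(238, 1, 0.5))
  rep1 <- repeated_test_evaluation(function(d) plogis(d$x), test, seed = 4)
  expect_equal(attr(rep1, "subsample_size"), 214)

  # all-positive subsample: sensitivity defined, specificity flagged missing
  allpos <- data.frame(x = rnorm(30), poms_class_d3 = rep(1, 30))
  r <- repeated_test_evaluation(function(d) rep(0.99, nrow(d)), allpos,
                                n_runs = 3, seed = 1)
  expect_equal(r$mean[r$metric == "sensitivity"], 1)
  expect_equal(r$n_excluded[r$metric == "specificity"], 3)

  # deterministic model without subsampling: all CI widths are exactly zero
  r0 <- repeated_test_evaluation(function(d) plogis(d$x), test,
                                 fraction = 1, seed = 2)
  expect_true(all(r0$ci_half == 0))
})

test_that("per-run confusion identities hold to machine precision", {
  set.seed(39)
  test <- data.frame(x = rnorm(200), poms_class_d3 = rbinom(200, 1, 0.4))
  rep1 <- repeated_test_evaluation(function(d) plogis(2 * d$x), test, seed = 6)
  for (run in attr(rep1, "runs")) {
    expect_equal(run$f1,
                 2 * run$ppv * run$sensitivity / (run$ppv + run$sensitivity),
                 tolerance = 1e-12)
    expect_equal(run$ppv, run$tp / (run$tp + run$fp), tolerance = 1e-12)
    expect_equal(run$npv, run$tn / (run$tn + run$fn), tolerance = 1e-12)
    n <- run$tp + run$fp + run$tn + run$fn
    expect_equal(run$accuracy * n, run$tp + run$tn, tolerance = 1e-9)
  }
})

test_that("AUC: separation, pure ties, oracle agreement, monotone invariance", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  hand_s <- c(0.1, 0.4, 0.35, 0.8, 0.8, 0.5, 0.5, 0.5, 0.9, 0.2, 0.6, 0.6)
  hand_y <- c(0, 0, 1, 1, 0, 1, 0, 1, 1, 0, 1, 0)
  expect_equal(roc_auc(hand_s, hand_y), oracle_auc(hand_s, hand_y))
  set.seed(49)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # force ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    a <- roc_auc(s, y)
    expect_equal(a, oracle_auc(s, y), tolerance = 1e-12)
    expect_equal(roc_auc(qlogis(clip_probability(s, 1e-6)), y), a)
  }
  expect_error(roc_auc(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("ROC trapezoid integration agrees with concordance AUC", {
  set.seed(59)
  for (i in 1:20) {
    s <- sample(seq(0, 1, 0.05), 40, replace = TRUE)
    y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    curve <- roc_curve(s, y)
    trap <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
    expect_equal(trap, roc_auc(s, y), tolerance = 1e-10)
  }
})

test_that("PR curve ends at full recall with prevalence precision", {
  set.seed(69)
  s <- runif(50); y <- rbinom(50, 1, 0.4)
  pr <- pr_curve(s, y)
  expect_equal(pr$recall[nrow(pr)], 1)
  expect_equal(pr$precision[nrow(pr)], mean(y))
  expect_true(all(pr$precision >= 0 & pr$precision <= 1))
})
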