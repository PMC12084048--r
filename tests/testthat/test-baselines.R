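test_that("clinical score thresholds classify at the established cut-points", {
  expect_equal(score_predict(clinical_score_rule("PPOSSUM"), 0.31), 1L)
  expect_equal(score_predict(clinical_score_rule("PPOSSUM"), 0.29), 0L)
  expect_equal(score_predict(clinical_score_rule("PPOSSUM"), 0.30), 1L)
  expect_equal(score_predict(clinical_score_rule("ASA"), 2), 1L)
  expect_equal(score_predict(clinical_score_rule("ASA", inclusive = FALSE), 2), 0L)
  expect_equal(score_predict(clinical_score_rule("AT"), 10.9), 1L)
  expect_equal(score_predict(clinical_score_rule("AT"), 11), 0L)
  expect_equal(score_predict(clinical_score_rule("DASI"), 58), 0L)
  expect_equal(score_predict(clinical_score_rule("DASI"), 20), 1L)
})

test_that("threshold rules are step functions of the score value", {
  rule <- clinical_score_rule("PPOSSUM")
  v <- seq(0, 1, by = 0.01)
  pred <- score_predict(rule, v)
  expect_equal(sum(diff(pred) != 0), 1)  # exactly one jump
  expect_equal(v[which(diff(pred) != 0) + 1], 0.30)
})

test_that("AT logistic baseline recovers coefficients like an independent IRLS solver", {
  # hand-rolled Newton-Raphson for the 6-point dataset
  x <- c(8, 9, 10, 12, 14, 16)
  y <- c(1, 1, 1, 0, 0, 1)
  irls <- function(x, y, iters = 50) {
    X <- cbind(1, x)
    beta <- c(0, 0)
    for (i in seq_len(iters)) {
      eta <- X %*% beta
      mu <- plogis(eta)
      W <- as.numeric(mu * (1 - mu))
      beta <- beta + solve(t(X) %*% (X * W), t(X) %*% (y - mu))
    }
    as.numeric(beta)
  }
  train <- data.frame(vo2_kg_at = x, poms_class_d3 = y)
  fit <- at_logistic_baseline(train, train)
  expect_equal(unname(fit$coefficients), irls(x, y), tolerance = 1e-6)

  # separable toy data: monotone probabilities, training AUC 1
  sep <- data.frame(vo2_kg_at = 1:20,
                    poms_class_d3 = as.integer(1:20 <= 10))
  f2 <- suppressWarnings(at_logistic_baseline(sep, sep))
  expect_true(all(diff(f2$probabilities) <= 0))
  expect_equal(roc_auc(f2$probabilities, sep$poms_class_d3), 1)

  # zero-information feature: slope within 2 SE of zero
  set.seed(77)
  null <- data.frame(vo2_kg_at = rnorm(1000),
                     poms_class_d3 = rbinom(1000, 1, 0.5))
  f3 <- at_logistic_baseline(null, null)
  se <- sqrt(diag(vcov(f3$model)))[2]
  expect_lt(abs(unname(f3$coefficients[2])), 2 * se)
})

test_that("all reference classifiers separate linearly separable toy data", {
  set.seed(87)
  n <- 300
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$poms_class_d3 <- as.integer(d$x1 > 0)
  sp <- stratified_split(d, 0.7, seed = 1)
  res <- reference_classifiers(sp$a, sp$b, learners = c("lr", "dt", "rf", "gbt"),
                               folds = 5, seed = 2)
  for (nm in names(res))
    expect_gte(roc_auc(res[[nm]]$probabilities, sp$b$poms_class_d3), 0.95)
})

test_that("seeded reference runs repeat identically", {
  d <- make_planted_data(150, seed = 31)
  names(d)[names(d) == "y"] <- "poms_class_d3"
  sp <- stratified_split(d, 0.8, seed = 3)
  r1 <- reference_classifiers(sp$a, sp$b, learners = c("rf", "gbt"),
                              folds = 4, seed = 11)
  r2 <- reference_classifiers(sp$a, sp$b, learners = c("rf", "gbt"),
                              folds = 4, seed = 11)
  for (nm in names(r1))
    expect_identical(r1[[nm]]$probabilities, r2[[nm]]$probabilities)
})

test_that("a single-point grid equals a direct fit with those parameters", {
  d <- make_planted_data(120, seed = 41)
  names(d)[names(d) == "y"] <- "poms_class_d3"
  lrn <- reference_learner("gbt")
  gs <- grid_search_cv(lrn, d, data.frame(nrounds = 30, max_depth = 2, eta = 0.3),
                       folds = 4, seed = 5)
  direct <- lrn$fit(d, "poms_class_d3",
                    list(nrounds = 30, max_depth = 2, eta = 0.3))
  expect_equal(lrn$predict(gs$model, d), lrn$predict(direct, d),
               tolerance = 1e-10)
})
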