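test_that("dummy features get zero attribution and active ones carry the deviation", {
  f <- function(d) 0.3 + 0.2 * d$x1
  set.seed(1)
  bg <- data.frame(x1 = rnorm(40), x2 = rnorm(40))
  row <- data.frame(x1 = 1.5, x2 = -2)
  res <- shapley_values(f, row, bg)   # 2 features -> exact enumeration
  expect_equal(res$method, "exact")
  expect_equal(unname(res$values[1, "x2"]), 0, tolerance = 1e-12)
  expect_equal(unname(res$values[1, "x1"]),
               0.2 * (1.5 - mean(bg$x1)), tolerance = 1e-12)
  # efficiency: baseline + attributions reconstruct the model output
  expect_equal(res$baseline + sum(res$values[1, ]), res$prediction[1],
               tolerance = 1e-12)
})

test_that("interchangeable duplicated features share attribution equally", {
  f <- function(d) plogis(d$a + d$b)
  set.seed(2)
  v <- rnorm(30)
  bg <- data.frame(a = v, b = v)
  row <- data.frame(a = 2, b = 2)
  res <- shapley_values(f, row, bg)
  expect_equal(unname(res$values[1, "a"]), unname(res$values[1, "b"]),
               tolerance = 1e-12)
})

test_that("exact enumeration matches the independent all-orderings oracle", {
  f <- function(d) plogis(0.8 * d$x1 - 1.2 * d$x2 + 0.5 * d$x1 * d$x3)
  set.seed(3)
  bg <- data.frame(x1 = rnorm(25), x2 = rnorm(25), x3 = rnorm(25))
  for (i in 1:5) {
    row <- data.frame(x1 = rnorm(1), x2 = rnorm(1), x3 = rnorm(1))
    res <- shapley_values(f, row, bg)
    ora <- oracle_shapley(f, row, bg, c("x1", "x2", "x3"))
    expect_equal(unname(res$values[1, ]), ora, tolerance = 1e-10)
  }
})

test_that("sampling estimator converges to the exact values within Monte-Carlo error", {
  f <- function(d) plogis(0.8 * d$x1 - 1.2 * d$x2 + 0.3 * d$x3)
  set.seed(4)
  bg <- data.frame(x1 = rnorm(20), x2 = rnorm(20), x3 = rnorm(20))
  row <- data.frame(x1 = 1, x2 = -1, x3 = 0.5)
  exact <- shapley_values(f, row, bg)
  # force the sampling path with many permutations
  reps <- sapply(1:10, function(s) {
    r <- shapley_values(f, row, bg, n_permutations = 200, seed = s,
                        exact_limit = 0)
    r$values[1, ]
  })
  se <- apply(reps, 1, sd) / sqrt(10)
  est <- rowMeans(reps)
  for (j in 1:3)
    expect_lt(abs(est[j] - exact$values[1, j]), 4 * max(se[j], 1e-4))
})

test_that("efficiency holds on the sampling path within tolerance", {
  f <- function(d) plogis(d$x1 - d$x2 + 0.2 * d$x3)
  set.seed(5)
  bg <- data.frame(x1 = rnorm(20), x2 = rnorm(20), x3 = rnorm(20))
  row <- data.frame(x1 = 1, x2 = 0, x3 = -1)
  res <- shapley_values(f, row, bg, n_permutations = 300, seed = 6,
                        exact_limit = 0)
  expect_lt(abs(res$baseline + sum(res$values[1, ]) - res$prediction[1]), 0.05)
})

test_that("feature ranking orders by mean absolute value with stable ties", {
  vals <- rbind(c(0.1, -0.5, 0.1), c(-0.3, 0.4, -0.1))
  res <- structure(list(values = `colnames<-`(vals, c("b", "a", "c")),
                        features = c("b", "a", "c"),
                        baseline = 0, prediction = c(0, 0), method = "exact"),
                   class = "attribution_result")
  rk <- rank_features(res)
  expect_equal(rk$feature, c("a", "b", "c"))
  expect_equal(rk$mean_abs_value, c(0.45, 0.2, 0.1))
})

test_that("attribution ranks the planted dominant feature first on a fitted model", {
  d <- make_planted_data(400, n_noise = 2, seed = 51)
  fit <- suppressWarnings(glm(y ~ ., data = d, family = binomial()))
  pf <- function(nd) as.numeric(predict(fit, newdata = nd, type = "response"))
  set.seed(52)
  bg <- d[sample(nrow(d), 50), 1:4]
  rows <- d[1:30, 1:4]
  res <- shapley_values(pf, rows, bg)
  rk <- rank_features(res)
  expect_setequal(rk$feature[1:2], c("x1", "x2"))
})
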