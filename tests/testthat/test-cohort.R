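test_that("identical config and seed reproduce the table bit for bit", {
  cfg <- cohort_config(n_patients = 200, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  # serialization round-trip is byte-identical too
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(a, f1); write_cohort(b, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("null effects give target prevalence and no feature-outcome association", {
  cfg <- cohort_config(n_patients = 2000, crf_effect = 0, clinical_effect = 0,
                       prevalence_target = 0.5, seed = 3)
  co <- generate_cohort(cfg)
  prev <- mean(co$poms_class_d3)
  se <- sqrt(0.5 * 0.5 / 2000)
  expect_lt(abs(prev - 0.5), 3 * se)
  for (f in c("vo2_kg_at", "age", "crf_10"))
    expect_lt(abs(cor(co[[f]], co$poms_class_d3)), 0.1)
})

test_that("empirical prevalence tracks the target over seeds", {
  prevs <- sapply(1:20, function(s)
    mean(generate_cohort(cohort_config(n_patients = 2000, seed = s))$poms_class_d3))
  expect_lt(abs(mean(prevs) - 633 / 1190), 0.02)
})

test_that("AT-fitness feature carries the planted inverse correlation", {
  co <- generate_cohort(cohort_config(seed = 12))
  r <- cor(co$vo2_kg_at, co$poms_count_d3)
  expect_lt(r, 0)
  expect_gte(abs(r), 0.59)
  expect_lte(abs(r), 0.79)
})

test_that("outcome probability is monotone decreasing in latent fitness", {
  # increasing fitness lowers latent risk, which must never raise P(POMS >= 2)
  risk <- seq(-6, 6, by = 0.1)
  p <- cohort_outcome_probability(risk)
  expect_true(all(diff(p) >= 0))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("POMS morbidity classification follows the two-domain threshold", {
  # far-negative risk: no positive domains, class 0
  set.seed(1)
  a <- generate_poms(-50)
  expect_equal(a$positive_count, 0)
  expect_equal(a$morbidity_class, 0L)
  # exactly two positive non-excluded domains -> class 1
  b <- poms_assessment(c(TRUE, TRUE, rep(FALSE, 7)))
  expect_equal(b$positive_count, 2)
  expect_equal(b$morbidity_class, 1L)
  # a routine-care excluded domain alone never counts
  c1 <- poms_assessment(c(TRUE, rep(FALSE, 8)), excluded_domains = 1L)
  expect_equal(c1$positive_count, 0)
  expect_equal(c1$morbidity_class, 0L)
  # deterministic class from count, threshold 2, across random assessments
  set.seed(2)
  for (i in 1:50) {
    dom <- runif(9) < 0.4
    excl <- sample(0:2, 1)
    ex <- if (excl > 0) sample(1:9, excl) else integer(0)
    a <- poms_assessment(dom, excluded_domains = ex)
    expect_equal(a$positive_count, sum(dom[setdiff(1:9, ex)]))
    expect_identical(a$morbidity_class, as.integer(a$positive_count >= 2))
  }
  expect_error(generate_poms(0.5, day = 4), "day")
  expect_error(generate_poms(Inf), "finite")
})

test_that("day-5/7 counts correlate positively with day 3 through shared risk", {
  set.seed(9)
  risk <- rnorm(400)
  c3 <- sapply(risk, function(r) generate_poms(r, 3)$positive_count)
  c5 <- sapply(risk, function(r) generate_poms(r, 5)$positive_count)
  c7 <- sapply(risk, function(r) generate_poms(r, 7)$positive_count)
  expect_gt(cor(c3, c5), 0.3)
  expect_gt(cor(c3, c7), 0.3)
  expect_lt(mean(c5), mean(c3))
})

test_that("invalid generator configurations are rejected", {
  expect_error(cohort_config(prevalence_target = 0), "prevalence")
  expect_error(cohort_config(prevalence_target = 1), "prevalence")
  expect_error(cohort_config(crf_effect = Inf))
  expect_error(cohort_config(n_patients = 0))
})

test_that("cohort CSV + sidecar round-trips with feature metadata", {
  co <- generate_cohort(cohort_config(n_patients = 50, seed = 5))
  f <- tempfile(fileext = ".csv")
  write_cohort(co, f)
  back <- read_cohort(f)
  expect_equal(as.data.frame(back)$vo2_kg_at, co$vo2_kg_at)
  expect_identical(attr(back, "feature_group"), attr(co, "feature_group"))
  expect_identical(cohort_features(back, "crf"), cohort_features(co, "crf"))
})
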