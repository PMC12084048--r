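test_that("median filter basics: constants, impulse rejection, edges", {
  expect_equal(median_filter(rep(3, 10), 5), rep(3, 10))
  expect_equal(median_filter(c(0, 0, 10, 0, 0), 3), rep(0, 5))
  expect_error(median_filter(1:10, 4), "odd")
  expect_error(median_filter(1:3, 5), "exceeds")
})

test_that("median filter matches the sliding sort-and-middle oracle", {
  set.seed(15)
  for (i in 1:100) {
    x <- rnorm(50)
    k <- sample(c(3, 5, 7, 9), 1)
    expect_equal(median_filter(x, k), oracle_median_filter(x, k))
  }
})

test_that("filter and downsample are idempotent on constants and commute with affine maps", {
  x <- rnorm(200)
  for (op in list(function(v) median_filter(v, 5),
                  function(v) downsample(v, 50))) {
    expect_equal(op(rep(2.5, 200)), rep(2.5, length(op(rep(2.5, 200)))))
    expect_equal(op(3 * x + 1), 3 * op(x) + 1, tolerance = 1e-12)
  }
})

test_that("downsampling preserves endpoints, lines and monotonicity", {
  const <- rep(1.5, 3600)
  expect_equal(downsample(const, 100), rep(1.5, 100))
  ramp <- seq(0, 1, length.out = 1000)
  got <- downsample(ramp, 100)
  expect_length(got, 100)
  expect_lt(max(abs(got - seq(0, 1, length.out = 100))), 1e-9)
  set.seed(8)
  mono <- cumsum(abs(rnorm(500)))
  ds <- downsample(mono, 120)
  expect_true(all(diff(ds) >= 0))
  expect_equal(ds[c(1, 120)], mono[c(1, 500)])
  expect_error(downsample(1:10, 11), "exceeds")
  expect_error(downsample(1:10, 1), "at least 2")
})

test_that("V-slope detection finds noiseless planted breakpoints exactly", {
  x <- seq(200, 2000, length.out = 600)
  kink <- x[300]
  y <- ifelse(x <= kink, 0.85 * x, 0.85 * kink + 1.15 * (x - kink))
  at <- detect_at_vslope(x, y, c(1, 600))
  expect_true(at$determinate)
  expect_equal(at$index, 300L)
  expect_equal(at$value, x[300])
  # a single straight line is indeterminate
  at2 <- detect_at_vslope(x, 0.9 * x + 3, c(1, 600))
  expect_false(at2$determinate)
  expect_error(detect_at_vslope(x, y, c(1, 100)), "minimum segment")
})

test_that("V-slope detection equals the exhaustive lm-refit oracle", {
  set.seed(25)
  for (i in 1:20) {
    m <- sample(150:300, 1)
    x <- seq(300, 1500, length.out = m)
    b_true <- sample(60:(m - 60), 1)
    y <- ifelse(seq_len(m) <= b_true,
                0.85 * x, 0.85 * x[b_true] + 1.15 * (x - x[b_true])) +
      rnorm(m, sd = 5)
    got <- detect_at_vslope(x, y, c(1, m), min_segment = 60)
    ora <- oracle_breakpoint(x, y, 60)
    if (got$determinate) {
      expect_equal(got$index, ora$b)
      expect_equal(got$rss_two, ora$rss, tolerance = 1e-6)
    }
  }
})

test_that("noisy planted breaks are recovered within ten samples almost always", {
  set.seed(35)
  hits <- 0
  for (trial in 1:100) {
    m <- 400
    x <- seq(300, 1500, length.out = m)
    b_true <- 200
    y <- ifelse(seq_len(m) <= b_true,
                0.85 * x, 0.85 * x[b_true] + 1.15 * (x - x[b_true])) +
      rnorm(m, sd = 3)
    got <- detect_at_vslope(x, y, c(1, m))
    if (got$determinate && abs(got$index - b_true) <= 10) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("breakpoint location survives downsampling to 1000, 500 and 100", {
  m <- 3000
  x <- seq(300, 1500, length.out = m)
  b_true <- 1800
  y <- ifelse(seq_len(m) <= b_true,
              0.85 * x, 0.85 * x[b_true] + 1.15 * (x - x[b_true]))
  full <- detect_at_vslope(x, y, c(1, m))
  frac_full <- full$index / m
  for (len in c(1000, 500, 100)) {
    at <- detect_at_vslope(downsample(x, len), downsample(y, len), c(1, len),
                           min_segment = max(5, round(60 * len / m)))
    expect_true(at$determinate)
    expect_lt(abs(at$index / len - frac_full), 0.02)
  }
})

test_that("30-second peak uptake: constants, closed-form ramp, and bound", {
  expect_equal(vo2_peak(rep(10, 100), 100), 10)
  # linear ramp ending at v with slope s: mean of the last 30 samples
  s <- 0.02
  ramp <- seq(by = s, length.out = 200, from = 1)
  v <- ramp[200]
  expect_equal(vo2_peak(ramp, 200, mode = "last30"), v - 14.5 * s,
               tolerance = 1e-12)
  expect_equal(vo2_peak(ramp, 200, mode = "rolling"), v - 14.5 * s,
               tolerance = 1e-12)
  expect_error(vo2_peak(rep(1, 20), 20), "fewer than")
  set.seed(45)
  x <- abs(rnorm(300, 15))
  xf <- median_filter(x, 5)
  expect_lte(vo2_peak(xf, 300), max(xf))
})

test_that("time-series feature matrix obeys the channel-major ordering contract", {
  set.seed(55)
  wf <- list(
    generate_cpet_waveforms(10, 16, patient_id = "A", noise_sd = 0.1),
    generate_cpet_waveforms(12, 18, patient_id = "B", noise_sd = 0.1))
  names(wf) <- c("A", "B")
  m <- build_ts_feature_matrix(wf, 100, outcome = c(A = 1, B = 0))
  expect_equal(nrow(m), 2)
  expect_equal(ncol(m), 2 + 15 * 100)   # id + features + outcome
  # feature j of channel c equals downsample(channel c)[j]
  for (ch in c("vo2", "hr", "rer")) {
    ds <- downsample(wf[["A"]]$channels[[ch]], 100)
    for (j in c(1, 50, 100))
      expect_equal(m[1, sprintf("%s_%03d", ch, j)], ds[j])
  }
  # identical waveforms give identical rows
  m2 <- build_ts_feature_matrix(list(A = wf[["A"]], B = wf[["A"]]), 50)
  expect_equal(unname(as.numeric(m2[1, -1])), unname(as.numeric(m2[2, -1])))
  # missing channel errors
  broken <- wf
  broken[["B"]]$channels$hr <- NULL
  expect_error(build_ts_feature_matrix(broken, 50), "missing channel")
})
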