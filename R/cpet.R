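#' CPET signal processing
#'
#' Filtering, fixed-length rescaling, and derivation of the headline
#' cardiorespiratory-fitness features (anaerobic threshold by the V-slope
#' method, 30-second peak oxygen uptake) from 1-Hz recordings.
#'
#' @name cpet_signals
NULL

#' Sliding median filter
#'
#' Odd-window running median with shrinking symmetric windows at the edges:
#' sample `i` is the median over `[i - h, i + h]` with
#' `h = min((window-1)/2, i-1, n-i)`, so the output has the input's length
#' and the first/last samples pass through unchanged.
#'
#' @param series numeric vector.
#' @param window odd positive window width, at most `length(series)`.
#' @return Filtered numeric vector of the same length.
#' @export
median_filter <- function(series, window = 5L) {
  n <- length(series)
  if (window %% 2L != 1L || window < 1L) stop("window must be odd and positive")
  if (window > n) stop("window exceeds series length")
  h <- (window - 1L) %/% 2L
  if (h == 0L) return(series)
  vapply(seq_len(n), function(i) {
    hh <- min(h, i - 1L, n - i)
    stats::median(series[(i - hh):(i + hh)])
  }, numeric(1))
}

#' Shape-preserving downsampling
#'
#' Linear interpolation at `target_len` equally spaced time points spanning
#' the full series, so the first and last samples are preserved exactly,
#' lines are reproduced exactly, and monotone input stays monotone.
#'
#' @param series numeric vector.
#' @param target_len desired output length, between 2 and `length(series)`.
#' @return Numeric vector of length `target_len`.
#' @export
downsample <- function(series, target_len) {
  n <- length(series)
  if (target_len < 2L) stop("target_len must be at least 2")
  if (target_len > n) stop("target_len exceeds input length")
  stats::approx(seq_len(n), series, xout = seq(1, n, length.out = target_len))$y
}

# O(1)-per-range simple linear regression RSS via cumulative sums
.make_rss <- function(x, y) {
  cx <- cumsum(x); cy <- cumsum(y)
  cxx <- cumsum(x * x); cxy <- cumsum(x * y); cyy <- cumsum(y * y)
  at <- function(cs, i) if (i == 0L) 0 else cs[i]
  function(i, j) {
    m <- j - i + 1L
    sx <- at(cx, j) - at(cx, i - 1L)
    sy <- at(cy, j) - at(cy, i - 1L)
    sxx <- at(cxx, j) - at(cxx, i - 1L)
    sxy <- at(cxy, j) - at(cxy, i - 1L)
    syy <- at(cyy, j) - at(cyy, i - 1L)
    vxx <- sxx - sx * sx / m
    vxy <- sxy - sx * sy / m
    vyy <- syy - sy * sy / m
    slope <- if (vxx > 0) vxy / vxx else 0
    rss <- vyy - if (vxx > 0) vxy * vxy / vxx else 0
    list(rss = max(rss, 0), slope = slope)
  }
}

#' V-slope anaerobic threshold detection
#'
#' Fits a two-segment least-squares line to CO2 output against oxygen uptake
#' over the ramp window, choosing the breakpoint that minimises the total
#' residual sum of squares subject to the second slope exceeding the first
#' (the V-slope geometry: CO2 output accelerates past the threshold). Both
#' segments must span at least `min_segment` samples, and the best
#' two-segment fit must improve on the single-line fit by at least
#' `improvement` (relative RSS reduction); otherwise the result is flagged
#' indeterminate.
#'
#' @param vo2,vco2 aligned numeric sequences (any consistent units).
#' @param ramp_window integer pair `c(start, end)` of 1-based sample indices
#'   delimiting the ramp.
#' @param min_segment minimum samples per segment (default 60).
#' @param improvement required relative RSS improvement over a single line
#'   (default 0.05).
#' @return A list of class `at_estimate`: `index` (breakpoint sample, `NA`
#'   when indeterminate), `value` (`vo2[index]`), `determinate` (logical),
#'   `slope1`, `slope2`, `rss_two`, `rss_one`.
#' @export
detect_at_vslope <- function(vo2, vco2, ramp_window, min_segment = 60L,
                             improvement = 0.05) {
  stopifnot(length(vo2) == length(vco2), length(ramp_window) == 2L)
  start <- as.integer(ramp_window[1L]); end <- as.integer(ramp_window[2L])
  if (start < 1L || end > length(vo2) || start >= end)
    stop("ramp_window out of bounds")
  if (end - start + 1L < 2L * min_segment)
    stop("ramp_window shorter than twice the minimum segment length")

  x <- vo2[start:end]; y <- vco2[start:end]
  fit <- .make_rss(x, y)
  m <- length(x)
  one <- fit(1L, m)
  indeterminate <- list(index = NA_integer_, value = NA_real_,
                        determinate = FALSE, slope1 = one$slope,
                        slope2 = one$slope, rss_two = one$rss,
                        rss_one = one$rss)

  best <- NULL
  for (b in min_segment:(m - min_segment + 1L)) {
    f1 <- fit(1L, b); f2 <- fit(b, m)
    if (f2$slope <= f1$slope) next
    total <- f1$rss + f2$rss
    if (is.null(best) || total < best$rss_two)
      best <- list(b = b, slope1 = f1$slope, slope2 = f2$slope,
                   rss_two = total)
  }
  if (is.null(best))
    return(structure(indeterminate, class = "at_estimate"))
  improved <- if (one$rss > 0) (one$rss - best$rss_two) / one$rss else 0
  if (improved < improvement)
    return(structure(indeterminate, class = "at_estimate"))
  idx <- start + best$b - 1L
  structure(list(index = idx, value = vo2[idx], determinate = TRUE,
                 slope1 = best$slope1, slope2 = best$slope2,
                 rss_two = best$rss_two, rss_one = one$rss),
            class = "at_estimate")
}

#' Peak oxygen uptake over 30 seconds
#'
#' `mode = "rolling"` (default) returns the highest 30-sample rolling mean
#' among windows ending within the final `search_s` seconds of ramped
#' exercise; `mode = "last30"` returns the literal mean of the 30 samples
#' ending at `ramp_end`. The rolling form dominates the literal one on any
#' input.
#'
#' @param vo2_per_kg numeric sequence (ml/kg/min).
#' @param ramp_end 1-based index of the last ramped-exercise sample; must be
#'   at least 30.
#' @param mode `"rolling"` or `"last30"`.
#' @param window averaging window in samples (default 30).
#' @param search_s terminal search span in samples for the rolling mode
#'   (default 60).
#' @return Scalar peak value (ml/kg/min).
#' @export
vo2_peak <- function(vo2_per_kg, ramp_end = length(vo2_per_kg),
                     mode = c("rolling", "last30"), window = 30L,
                     search_s = 60L) {
  mode <- match.arg(mode)
  ramp_end <- as.integer(ramp_end)
  if (ramp_end < window) stop("fewer than ", window, " ramp samples")
  if (ramp_end > length(vo2_per_kg)) stop("ramp_end out of bounds")
  if (mode == "last30")
    return(mean(vo2_per_kg[(ramp_end - window + 1L):ramp_end]))
  ends <- max(window, ramp_end - search_s + window):ramp_end
  means <- vapply(ends, function(e)
    mean(vo2_per_kg[(e - window + 1L):e]), numeric(1))
  max(means)
}

#' Extract the headline CRF feature row from a recording
#'
#' Median-filters each channel, then reads rest/AT/peak values of heart
#' rate, per-kg oxygen uptake, RER and the CO2 ventilatory equivalent, the
#' V-slope anaerobic threshold and the 30-second peak.
#'
#' @param series a [cpet_series()].
#' @param filter_window median filter width (default 5 s).
#' @return One-row data frame of derived features (`at_*`, `peak_*`,
#'   `rest_*`, plus `at_determinate`).
#' @export
extract_crf_features <- function(series, filter_window = 5L) {
  ch <- lapply(series$channels, median_filter, window = filter_window)
  pm <- series$phase_marks
  rest_idx <- seq_len(max(1L, pm[["ramp_start"]] - 1L))
  at <- detect_at_vslope(ch$vo2_kg, ch$vco2_kg,
                         c(pm[["ramp_start"]], pm[["peak"]]))
  peak <- vo2_peak(ch$vo2_kg, ramp_end = pm[["peak"]])
  at_i <- if (at$determinate) at$index else pm[["peak"]]
  data.frame(
    rest_hr = mean(ch$hr[rest_idx]),
    rest_vo2_kg = mean(ch$vo2_kg[rest_idx]),
    rest_rer = mean(ch$rer[rest_idx]),
    at_vo2_kg = if (at$determinate) at$value else NA_real_,
    at_hr = ch$hr[at_i],
    at_rer = ch$rer[at_i],
    at_ve_vco2 = ch$ve[at_i] * 1000 / ch$vco2[at_i],
    peak_vo2_kg = peak,
    peak_hr = max(ch$hr[seq_len(pm[["peak"]])]),
    peak_rer = ch$rer[pm[["peak"]]],
    at_determinate = at$determinate)
}

#' Build a time-series feature matrix
#'
#' Downsamples every channel of every patient to `target_len` samples and
#' concatenates them channel-major (all positions of channel 1, then channel
#' 2, ...) into one row per patient. Column names are
#' `<channel>_<position>` with zero-padded 1-based positions, so feature `j`
#' of channel `c` equals `downsample(channel c)[j]`.
#'
#' @param waveforms named list of `cpet_series` with identical channel sets.
#' @param target_len downsampled length per channel (e.g. 1000, 500, 100).
#' @param outcome optional named vector (by patient id) appended as column
#'   `poms_class_d3`.
#' @return Data frame with `patient_id`, the stacked features and optionally
#'   the outcome.
#' @export
build_ts_feature_matrix <- function(waveforms, target_len, outcome = NULL) {
  stopifnot(length(waveforms) >= 1L)
  channels <- names(waveforms[[1L]]$channels)
  rows <- lapply(waveforms, function(s) {
    missing <- setdiff(channels, names(s$channels))
    if (length(missing) > 0L)
      stop("patient ", s$patient_id, " is missing channel(s): ",
           paste(missing, collapse = ", "))
    unlist(lapply(channels, function(cn)
      downsample(s$channels[[cn]], target_len)), use.names = FALSE)
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- unlist(lapply(channels, function(cn)
    sprintf("%s_%0*d", cn, nchar(as.character(target_len)), seq_len(target_len))))
  out <- data.frame(patient_id = vapply(waveforms, `[[`, character(1), "patient_id"),
                    mat, check.names = FALSE, row.names = NULL)
  if (!is.null(outcome))
    out$poms_class_d3 <- as.integer(outcome[out$patient_id])
  out
}
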