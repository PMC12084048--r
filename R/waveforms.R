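#' 1-Hz CPET waveform container
#'
#' A `cpet_series` holds one patient's incremental exercise recording: time
#' in seconds at 1-s spacing, a named list of equal-length channels, the
#' phase marks (ramp start, anaerobic threshold if known, peak, recovery
#' start; 1-based sample indices) and body mass.
#'
#' @param patient_id identifier.
#' @param t seconds from test start, strictly increasing at 1-s spacing.
#' @param channels named list of numeric vectors, all the same length as `t`.
#' @param phase_marks named integer vector with entries among `ramp_start`,
#'   `at`, `peak`, `recovery_start`.
#' @param body_mass_kg positive scalar.
#' @return An object of class `cpet_series`.
#' @export
cpet_series <- function(patient_id, t, channels, phase_marks, body_mass_kg) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)), body_mass_kg > 0)
  len <- vapply(channels, length, integer(1))
  if (any(len != length(t))) stop("all channels must match the time axis length")
  if (length(t) > 1L && any(diff(t) != 1)) stop("time axis must advance at 1-s spacing")
  structure(list(patient_id = patient_id, t = t, channels = channels,
                 phase_marks = phase_marks, body_mass_kg = body_mass_kg),
            class = "cpet_series")
}

#' @export
print.cpet_series <- function(x, ...) {
  cat("<cpet_series> ", x$patient_id, ": ", length(x$t), " s, ",
      length(x$channels), " channels (",
      paste(utils::head(names(x$channels), 5), collapse = ", "),
      if (length(x$channels) > 5) ", ..." else "", ")\n", sep = "")
  invisible(x)
}

.CPET_CHANNELS <- c("vo2", "vco2", "vo2_kg", "vco2_kg", "ve", "hr", "rer",
                    "peto2", "petco2", "vo2_hr", "work_rate", "rr", "vt",
                    "spo2", "met")

# per-channel noise scale multipliers (channels live on very different units)
.CPET_NOISE_SCALE <- c(vo2 = 30, vco2 = 30, vo2_kg = 0.4, vco2_kg = 0.4,
                       ve = 1.5, hr = 2, rer = 0.02, peto2 = 0.2,
                       petco2 = 0.15, vo2_hr = 0.4, work_rate = 1.5,
                       rr = 1, vt = 30, spo2 = 0.3, met = 0.1)

#' Simulate a 1-Hz CPET recording
#'
#' Builds a 15-channel exercise test around a patient's planted anaerobic
#' threshold and peak oxygen uptake: a rest plateau, a linear ramp, a
#' 30-second sustained peak, and an exponential-like recovery. CO2 output
#' follows the V-slope geometry — linear in oxygen uptake with slope 0.85
#' below the planted AT and 1.15 above it — so the threshold is recoverable
#' from the `vco2`-vs-`vo2` relationship. Gaussian noise of SD
#' `noise_sd * channel scale` is added per channel; `noise_sd = 0` yields
#' exact geometric round-trips with the signal-processing extractors.
#'
#' @param vo2_kg_at planted AT oxygen uptake (ml/kg/min), positive.
#' @param vo2_kg_peak planted peak oxygen uptake (ml/kg/min), `> vo2_kg_at`.
#' @param body_mass_kg body mass.
#' @param patient_id identifier stored on the series.
#' @param rest_s,ramp_s,peak_s,recovery_s phase durations in seconds.
#' @param vo2_kg_rest resting oxygen uptake (ml/kg/min).
#' @param recovery_tau time constant (s) of the post-exercise oxygen-uptake
#'   decay; faster recovery (smaller tau) reflects better dynamic exercise
#'   response.
#' @param noise_sd noise multiplier (0 disables noise).
#' @return A [cpet_series()] with `ramp_start`, `at`, `peak` and
#'   `recovery_start` phase marks.
#' @export
generate_cpet_waveforms <- function(vo2_kg_at, vo2_kg_peak,
                                    body_mass_kg = 75,
                                    patient_id = "P0000",
                                    rest_s = 120L, ramp_s = 480L,
                                    peak_s = 30L, recovery_s = 120L,
                                    vo2_kg_rest = 3.8, recovery_tau = 40,
                                    noise_sd = 0.5) {
  if (!is.finite(vo2_kg_at) || vo2_kg_at <= 0) stop("AT target must be positive")
  if (!is.finite(vo2_kg_peak) || vo2_kg_peak <= 0) stop("peak target must be positive")
  if (vo2_kg_peak <= vo2_kg_at) stop("peak target must exceed the AT target")
  if (vo2_kg_at <= vo2_kg_rest) stop("AT target must exceed the resting value")

  n <- rest_s + ramp_s + peak_s + recovery_s
  ramp_start <- rest_s + 1L
  peak_start <- rest_s + ramp_s + 1L
  recovery_start <- rest_s + ramp_s + peak_s + 1L

  # AT planted on an exact ramp sample; slope in ml/kg/min per second
  slope <- (vo2_kg_peak - vo2_kg_rest) / (ramp_s - 1L)
  at_idx <- ramp_start +
    as.integer(round((vo2_kg_at - vo2_kg_rest) / slope))
  at_idx <- min(max(at_idx, ramp_start), peak_start - 1L)
  at_value <- vo2_kg_rest + slope * (at_idx - ramp_start)

  vo2_kg <- numeric(n)
  vo2_kg[1:rest_s] <- vo2_kg_rest
  vo2_kg[ramp_start:(peak_start - 1L)] <- vo2_kg_rest + slope * (0:(ramp_s - 1L))
  vo2_kg[peak_start:(recovery_start - 1L)] <- vo2_kg_peak
  rec <- seq_len(recovery_s)
  vo2_kg[recovery_start:n] <- vo2_kg_rest +
    (vo2_kg_peak - vo2_kg_rest) * exp(-rec / recovery_tau)

  vo2 <- vo2_kg * body_mass_kg
  # V-slope geometry: vco2 piecewise-linear in vo2 with the break at the AT
  at_vo2 <- at_value * body_mass_kg
  vco2 <- ifelse(vo2 <= at_vo2, 0.85 * vo2, 0.85 * at_vo2 + 1.15 * (vo2 - at_vo2))
  hr <- 82 + (136 - 82) * (vo2_kg - vo2_kg_rest) / (vo2_kg_peak - vo2_kg_rest)
  ve <- 0.028 * vco2 + 6
  rr <- 12 + 18 * (vo2_kg - vo2_kg_rest) / (vo2_kg_peak - vo2_kg_rest)
  frac <- (vo2_kg - vo2_kg_rest) / (vo2_kg_peak - vo2_kg_rest)
  channels <- list(
    vo2 = vo2, vco2 = vco2, vo2_kg = vo2_kg, vco2_kg = vco2 / body_mass_kg,
    ve = ve, hr = hr, rer = vco2 / vo2,
    peto2 = 13.2 - 1.2 * frac + 1.6 * pmax(0, frac - (at_idx - ramp_start) / ramp_s),
    petco2 = 5.1 + 0.5 * frac - 0.9 * pmax(0, frac - (at_idx - ramp_start) / ramp_s),
    vo2_hr = vo2 / hr,
    work_rate = pmax(0, (vo2 - vo2_kg_rest * body_mass_kg) / 10),
    rr = rr, vt = 1000 * ve / rr, spo2 = 96 - 1.5 * frac,
    met = vo2_kg / 3.5)

  if (noise_sd > 0) {
    for (nm in names(channels))
      channels[[nm]] <- channels[[nm]] +
        stats::rnorm(n, sd = noise_sd * .CPET_NOISE_SCALE[[nm]])
  }

  cpet_series(patient_id, t = seq_len(n) - 1L, channels = channels,
              phase_marks = c(ramp_start = ramp_start, at = at_idx,
                              peak = recovery_start - 1L,
                              recovery_start = recovery_start),
              body_mass_kg = body_mass_kg)
}

#' Generate waveforms for a cohort's CPET subset
#'
#' Selects the first `ts_fraction` share of patients (deterministic given the
#' generator seed) and simulates one [generate_cpet_waveforms()] recording
#' per patient from the planted tabular AT/peak features.
#'
#' @param cohort a `cohort_table` from [generate_cohort()].
#' @param noise_sd waveform noise multiplier.
#' @return Named list of `cpet_series`, one per selected patient.
#' @export
generate_cohort_waveforms <- function(cohort, noise_sd = 0.5) {
  config <- attr(cohort, "config")
  n_ts <- as.integer(round(config$ts_fraction * nrow(cohort)))
  if (n_ts == 0L) return(list())
  idx <- seq_len(n_ts)
  mass <- if ("bmi" %in% names(cohort)) 1.7^2 * cohort$bmi else rep(75, nrow(cohort))
  lat <- attr(cohort, "latent")
  out <- lapply(idx, function(i)
    generate_cpet_waveforms(
      vo2_kg_at = lat$at_target[i],
      vo2_kg_peak = lat$peak_target[i],
      body_mass_kg = mass[i],
      patient_id = cohort$patient_id[i],
      vo2_kg_rest = lat$rest_target[i],
      recovery_tau = lat$recovery_tau[i],
      noise_sd = noise_sd))
  stats::setNames(out, cohort$patient_id[idx])
}

#' Write / read waveforms as long-format CSV
#'
#' Long format: `patient_id, t_sec, channel, value`, one row per sample per
#' channel.
#'
#' @param waveforms named list of `cpet_series`.
#' @param path CSV path.
#' @return `write_waveforms()` returns `path` invisibly; `read_waveforms()`
#'   a named list of `cpet_series` (phase marks and body mass are stored in a
#'   `<path>.meta.json` sidecar).
#' @export
write_waveforms <- function(waveforms, path) {
  long <- do.call(rbind, lapply(waveforms, function(s) {
    do.call(rbind, lapply(names(s$channels), function(ch)
      data.frame(patient_id = s$patient_id, t_sec = s$t, channel = ch,
                 value = s$channels[[ch]])))
  }))
  utils::write.csv(long, path, row.names = FALSE)
  meta <- lapply(waveforms, function(s)
    list(phase_marks = as.list(s$phase_marks), body_mass_kg = s$body_mass_kg))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_waveforms
#' @export
read_waveforms <- function(path) {
  long <- utils::read.csv(path)
  meta <- jsonlite::fromJSON(paste0(path, ".meta.json"), simplifyVector = FALSE)
  ids <- unique(long$patient_id)
  out <- lapply(ids, function(id) {
    sub <- long[long$patient_id == id, ]
    channels <- lapply(split(sub, sub$channel), function(d)
      d$value[order(d$t_sec)])
    m <- meta[[id]]
    cpet_series(id, t = sort(unique(sub$t_sec)),
                channels = channels[unique(sub$channel)],
                phase_marks = unlist(m$phase_marks),
                body_mass_kg = m$body_mass_kg)
  })
  stats::setNames(out, ids)
}
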