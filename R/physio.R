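# Physiological preprocessing: PPG beats and inter-beat intervals, HR / RV /
# end-tidal CO2 timecourses locked to the fMRI volume grid, and HRV summaries.

#' Construct a physiological recording
#'
#' A uniformly sampled waveform from one of the supported modalities.
#'
#' @param samples numeric amplitude vector (arbitrary units; mmHg for
#'   capnograph traces).
#' @param fs sampling rate in Hz.
#' @param modality one of `"ppg"`, `"respiration"`, `"capnograph"`.
#' @param start_time_s recording start relative to the first BOLD volume (s).
#' @return object of class `physio_recording`.
#' @export
physio_recording <- function(samples, fs,
                             modality = c("ppg", "respiration", "capnograph"),
                             start_time_s = 0) {
  modality <- match.arg(modality)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) cfg_error("fs must be a positive scalar")
  if (!all(is.finite(samples))) stop("non-finite samples in physio recording")
  structure(list(samples = as.numeric(samples), fs = fs, modality = modality,
                 start_time_s = start_time_s),
            class = "physio_recording")
}

#' @export
print.physio_recording <- function(x, ...) {
  cat(sprintf("<physio_recording> %s: %d samples @ %g Hz (%.1f s), start %.2f s\n",
              x$modality, length(x$samples), x$fs,
              length(x$samples) / x$fs, x$start_time_s))
  invisible(x)
}

# Sample times of a recording, on the BOLD clock.
rec_times <- function(rec) rec$start_time_s + (seq_along(rec$samples) - 1L) / rec$fs

#' Construct a beat series
#'
#' @param beat_times_s strictly increasing beat times (s).
#' @param artifact_mask optional logical flag per inter-beat interval.
#' @return object of class `beat_series` with elements `beat_times_s`,
#'   `ibi_s` and `artifact_mask`.
#' @export
beat_series <- function(beat_times_s, artifact_mask = NULL) {
  if (is.unsorted(beat_times_s, strictly = TRUE)) stop("beat times must be strictly increasing")
  ibi <- diff(beat_times_s)
  if (any(ibi <= 0)) stop("inter-beat intervals must be positive")
  if (is.null(artifact_mask)) artifact_mask <- rep(FALSE, length(ibi))
  structure(list(beat_times_s = beat_times_s, ibi_s = ibi,
                 artifact_mask = artifact_mask),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beats over %.1f s, mean IBI %.3f s, %d flagged\n",
              length(x$beat_times_s), diff(range(x$beat_times_s)),
              mean(x$ibi_s), sum(x$artifact_mask)))
  invisible(x)
}

#' Construct a TR-locked physiological timecourse
#'
#' @param values one value per BOLD volume.
#' @param tr_s repetition time (s).
#' @param kind one of `"hr_bpm"`, `"rv_norm"`, `"rv_raw"`, `"petco2_mmHg"`,
#'   `"breathing_rate_bpm"`.
#' @return object of class `physio_timecourse`.
#' @export
physio_timecourse <- function(values, tr_s, kind) {
  structure(list(values = as.numeric(values), tr_s = tr_s,
                 n_vols = length(values), kind = kind),
            class = "physio_timecourse")
}

#' @export
print.physio_timecourse <- function(x, ...) {
  cat(sprintf("<physio_timecourse> %s: %d volumes, TR %g s, mean %.3f\n",
              x$kind, x$n_vols, x$tr_s, mean(x$values)))
  invisible(x)
}

# Volume acquisition times (first volume at t = 0).
vol_times <- function(tr_s, n_vols) (seq_len(n_vols) - 1L) * tr_s

#' Detect cardiac beats in a PPG recording
#'
#' The waveform is band-pass filtered 0.5-2 Hz with a zero-phase
#' (forward-backward) second-order Butterworth filter; local maxima with
#' height at least 5% of the filtered signal's interquartile range and at
#' least 0.25 s apart are taken as beats.
#'
#' @param ppg a `physio_recording` with modality `"ppg"`, at least 10 s long.
#' @return a [beat_series()].
#' @export
detect_beats <- function(ppg) {
  stopifnot(inherits(ppg, "physio_recording"))
  if (ppg$modality != "ppg") cfg_error("detect_beats expects a PPG recording")
  if (length(ppg$samples) / ppg$fs < 10) cfg_error("PPG recording shorter than 10 s")
  bf <- signal::butter(2, c(0.5, 2) / (ppg$fs / 2), type = "pass")
  filt <- signal::filtfilt(bf, ppg$samples)
  thr <- 0.05 * stats::IQR(filt)
  idx <- find_peaks(filt, ppg$fs, min_height = thr, min_sep_s = 0.25)
  if (length(idx) < 2L) stop("no cardiac rhythm detected")
  beat_series(ppg$start_time_s + (idx - 1L) / ppg$fs)
}

#' Flag and interpolate artifactual inter-beat intervals
#'
#' Intervals outside the physiological range 0.33-2.0 s, or deviating more
#' than 3 scaled median absolute deviations from a 15-beat running median,
#' are flagged and replaced by linear interpolation between neighbouring
#' valid intervals; beat times are rebuilt cumulatively from the first beat.
#'
#' @param beats a [beat_series()] with at least 4 intervals.
#' @return a cleaned `beat_series`; flagged intervals are marked in
#'   `artifact_mask` and, if more than half were flagged, the result carries
#'   attribute `quality = "poor"` and a warning is raised.
#' @export
clean_ibi <- function(beats) {
  stopifnot(inherits(beats, "beat_series"))
  ibi <- beats$ibi_s
  n <- length(ibi)
  if (n < 4L) cfg_error("need at least 4 inter-beat intervals")
  k <- min(15L, if (n %% 2L == 0L) n - 1L else n)
  if (k %% 2L == 0L) k <- k - 1L
  med <- stats::runmed(ibi, k, endrule = "median")
  dev <- ibi - med
  s <- stats::mad(dev)
  flag <- ibi < 0.33 | ibi > 2.0
  if (s > 0) flag <- flag | abs(dev) > 3 * s
  if (!any(flag)) {
    return(beat_series(beats$beat_times_s, artifact_mask = flag))
  }
  if (all(flag)) stop("all inter-beat intervals flagged as artifacts")
  good <- which(!flag)
  ibi_clean <- ibi
  ibi_clean[flag] <- stats::approx(good, ibi[good], xout = which(flag), rule = 2)$y
  out <- beat_series(beats$beat_times_s[1L] + c(0, cumsum(ibi_clean)),
                     artifact_mask = flag)
  if (mean(flag) > 0.5) {
    warning("more than 50% of inter-beat intervals flagged as artifacts")
    attr(out, "quality") <- "poor"
  }
  out
}

#' Heart-rate timecourse on the volume grid
#'
#' For each BOLD volume, HR (bpm) is 60 divided by the median of the
#' inter-beat intervals whose midpoints fall in the 6-second window centred
#' at that volume's acquisition time; edge windows are clipped to the
#' recorded data. Empty windows are filled by linear interpolation from
#' neighbouring volumes, with a warning.
#'
#' @param beats a cleaned [beat_series()].
#' @param tr_s repetition time (s).
#' @param n_vols number of BOLD volumes.
#' @param window_s sliding-window length (s).
#' @return a [physio_timecourse()] of kind `"hr_bpm"`.
#' @export
hr_timecourse <- function(beats, tr_s, n_vols, window_s = 6) {
  stopifnot(inherits(beats, "beat_series"))
  mid <- (utils::head(beats$beat_times_s, -1) + utils::tail(beats$beat_times_s, -1)) / 2
  tv <- vol_times(tr_s, n_vols)
  half <- window_s / 2
  hr <- vapply(tv, function(t0) {
    sel <- mid >= t0 - half & mid <= t0 + half
    if (!any(sel)) return(NA_real_)
    60 / stats::median(beats$ibi_s[sel])
  }, numeric(1))
  if (anyNA(hr)) {
    warning("volumes with no inter-beat intervals in window; interpolated")
    ok <- which(!is.na(hr))
    if (!length(ok)) stop("no inter-beat intervals overlap the scan")
    hr <- stats::approx(ok, hr[ok], xout = seq_len(n_vols), rule = 2)$y
  }
  physio_timecourse(hr, tr_s, "hr_bpm")
}

#' Respiratory-variation timecourse
#'
#' RV at each volume is the standard deviation of the raw respiration
#' waveform within the 6-second window centred at that volume's time;
#' edge windows are clipped to the recorded data.
#'
#' @param resp a `physio_recording` with modality `"respiration"`.
#' @inheritParams hr_timecourse
#' @return a [physio_timecourse()] of kind `"rv_raw"`.
#' @export
rv_timecourse <- function(resp, tr_s, n_vols, window_s = 6) {
  stopifnot(inherits(resp, "physio_recording"))
  if (resp$modality != "respiration") cfg_error("rv_timecourse expects a respiration recording")
  tt <- rec_times(resp)
  half <- window_s / 2
  rv <- vapply(vol_times(tr_s, n_vols), function(t0) {
    sel <- tt >= t0 - half & tt <= t0 + half
    if (sum(sel) < 2L) return(0)
    stats::sd(resp$samples[sel])
  }, numeric(1))
  if (all(rv == 0)) warning("constant respiration waveform; RV is zero everywhere")
  physio_timecourse(rv, tr_s, "rv_raw")
}

#' Normalize a respiratory-variation series to approximately [-1, 1]
#'
#' Bounds are the empirical 1.45th and 98.55th percentiles; the mean of the
#' in-bounds values is subtracted from the data and from both bounds, then
#' positive values are divided by the adjusted upper bound and negative
#' values by the magnitude of the adjusted lower bound. This absorbs
#' between-subject differences in belt gain and torso size.
#'
#' @param rv a [physio_timecourse()] of raw RV values.
#' @return a `physio_timecourse` of kind `"rv_norm"`.
#' @export
normalize_rv <- function(rv) {
  stopifnot(inherits(rv, "physio_timecourse"))
  v <- rv$values
  b <- stats::quantile(v, c(0.0145, 0.9855), names = FALSE, type = 7)
  inb <- v >= b[1] & v <= b[2]
  m <- mean(v[inb])
  v <- v - m
  lo <- b[1] - m
  hi <- b[2] - m
  if (hi <= 0 || lo >= 0) stop("degenerate RV distribution")
  out <- ifelse(v >= 0, v / hi, v / abs(lo))
  physio_timecourse(out, rv$tr_s, "rv_norm")
}

#' Heart-rate-variability summary metrics
#'
#' RMSSD is the root mean square of successive inter-beat-interval
#' differences (ms). LF and HF power are band integrals (0.04-0.15 Hz and
#' 0.15-0.4 Hz) of the power spectral density of the IBI series, cubically
#' interpolated onto a uniform 4 Hz grid and estimated by a Welch
#' periodogram (120 s Hann segments, 50% overlap); units ms^2. RMSSD, LF
#' and HF are reported on the natural-log scale, alongside average HR, the
#' standard deviation of the raw RV series, breathing rate and mean CO2
#' when supplied.
#'
#' @param beats a cleaned [beat_series()] spanning at least 2 minutes.
#' @param rv optional raw RV [physio_timecourse()] (for `sd_rv`).
#' @param breathing_rate_bpm optional scalar breathing rate.
#' @param avg_co2_mmHg optional scalar mean end-tidal CO2.
#' @param resample_hz uniform grid rate for spectral estimation.
#' @return object of class `hrv_summary`: `ln_rmssd`, `ln_lf`, `ln_hf`,
#'   `rmssd_ms`, `lf_ms2`, `hf_ms2`, `avg_hr_bpm`, `sd_rv`,
#'   `breathing_rate_bpm`, `avg_co2_mmHg`. Non-positive band powers give
#'   `NA` logs and attribute `power_flag = TRUE`.
#' @export
hrv_metrics <- function(beats, rv = NULL, breathing_rate_bpm = NA_real_,
                        avg_co2_mmHg = NA_real_, resample_hz = 4) {
  stopifnot(inherits(beats, "beat_series"))
  span <- diff(range(beats$beat_times_s))
  ibi_ms <- beats$ibi_s * 1000
  rmssd <- sqrt(mean(diff(ibi_ms)^2))
  if (span >= 120) {
    mid <- (utils::head(beats$beat_times_s, -1) + utils::tail(beats$beat_times_s, -1)) / 2
    tg <- seq(mid[1], mid[length(mid)], by = 1 / resample_hz)
    ibi_u <- stats::spline(mid, ibi_ms, xout = tg, method = "natural")$y
    ps <- welch_psd(ibi_u, resample_hz)
    band_power <- function(lo, hi) {
      sel <- ps$freq >= lo & ps$freq <= hi
      if (sum(sel) < 2L) return(0)
      trapz(ps$freq[sel], ps$psd[sel])
    }
    lf <- band_power(0.04, 0.15)
    hf <- band_power(0.15, 0.40)
  } else {
    warning("fewer than 2 minutes of beats: LF/HF power not estimated")
    lf <- hf <- NA_real_
  }
  out <- structure(list(
    ln_rmssd = if (rmssd > 0) log(rmssd) else NA_real_,
    ln_lf = if (isTRUE(lf > 0)) log(lf) else NA_real_,
    ln_hf = if (isTRUE(hf > 0)) log(hf) else NA_real_,
    rmssd_ms = rmssd, lf_ms2 = lf, hf_ms2 = hf,
    avg_hr_bpm = 60 / mean(beats$ibi_s),
    sd_rv = if (is.null(rv)) NA_real_ else stats::sd(rv$values),
    breathing_rate_bpm = breathing_rate_bpm,
    avg_co2_mmHg = avg_co2_mmHg), class = "hrv_summary")
  if (!isTRUE(lf > 0) || !isTRUE(hf > 0)) attr(out, "power_flag") <- TRUE
  out
}

#' @export
print.hrv_summary <- function(x, ...) {
  cat(sprintf(paste0("<hrv_summary> RMSSD %.1f ms (ln %.2f), LF %.0f ms^2 (ln %.2f), ",
                     "HF %.0f ms^2 (ln %.2f), HR %.1f bpm\n"),
              x$rmssd_ms, x$ln_rmssd, x$lf_ms2, x$ln_lf, x$hf_ms2, x$ln_hf,
              x$avg_hr_bpm))
  invisible(x)
}

#' Breathing rate from a respiration waveform
#'
#' The waveform is lightly smoothed (0.5 s moving average) and breath peaks
#' with a minimum separation of 1.5 s are counted; the rate is peaks per
#' second times 60.
#'
#' @param resp a `physio_recording` with modality `"respiration"`,
#'   at least 30 s long.
#' @return breathing rate in breaths per minute.
#' @export
breathing_rate <- function(resp) {
  stopifnot(inherits(resp, "physio_recording"))
  if (resp$modality != "respiration") cfg_error("breathing_rate expects a respiration recording")
  dur <- length(resp$samples) / resp$fs
  if (dur < 30) cfg_error("need at least 30 s of respiration signal")
  k <- max(1L, round(0.5 * resp$fs))
  sm <- stats::filter(resp$samples, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- resp$samples[is.na(sm)]
  pk <- find_peaks(as.numeric(sm), resp$fs, min_sep_s = 1.5)
  if (length(pk) < 2L) stop("fewer than 2 respiration peaks detected")
  length(pk) / dur * 60
}

#' Align a capnograph trace to the respiration waveform
#'
#' Capnograph tubing introduces a measurement delay. The shift (in whole
#' sample steps, within `max_shift_s`) that makes the Pearson correlation
#' between the advanced capnograph and the respiration waveform most
#' negative is returned, exploiting the expected inverse relation between
#' the two signals. Positive shift means the capnograph lags respiration.
#'
#' @param co2 capnograph `physio_recording`.
#' @param resp respiration `physio_recording` at the same sampling rate.
#' @param max_shift_s maximum shift searched, in seconds.
#' @return the optimal shift in seconds; if the correlation is never
#'   negative a warning is raised and the best shift is still returned.
#' @export
align_capnograph <- function(co2, resp, max_shift_s = 10) {
  stopifnot(inherits(co2, "physio_recording"), inherits(resp, "physio_recording"))
  if (max_shift_s <= 0) cfg_error("max_shift_s must be positive")
  if (abs(co2$fs - resp$fs) > 1e-9) cfg_error("recordings must share a sampling rate")
  x <- co2$samples; y <- resp$samples
  n <- min(length(x), length(y))
  x <- x[seq_len(n)]; y <- y[seq_len(n)]
  dmax <- floor(max_shift_s * co2$fs)
  shifts <- -dmax:dmax
  r <- vapply(shifts, function(d) {
    if (d >= 0) {
      xs <- x[(1 + d):n]; ys <- y[1:(n - d)]
    } else {
      xs <- x[1:(n + d)]; ys <- y[(1 - d):n]
    }
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
    stats::cor(xs, ys)
  }, numeric(1))
  if (all(is.na(r))) stop("degenerate signals: correlation undefined at every shift")
  best <- which.min(r)
  if (min(r, na.rm = TRUE) >= 0)
    warning("capnograph-respiration correlation never negative; alignment unreliable")
  shifts[best] / co2$fs
}

#' End-tidal CO2 timecourse on the volume grid
#'
#' After advancing the capnograph by the alignment shift, breath-wise
#' maxima (peaks at least 1.5 s apart) are taken as end-tidal values and
#' linearly interpolated onto the volume acquisition times.
#'
#' @param co2 capnograph `physio_recording`.
#' @param shift_s alignment shift from [align_capnograph()] (s).
#' @inheritParams hr_timecourse
#' @return a [physio_timecourse()] of kind `"petco2_mmHg"`.
#' @export
petco2_timecourse <- function(co2, shift_s, tr_s, n_vols) {
  stopifnot(inherits(co2, "physio_recording"))
  if (co2$modality != "capnograph") cfg_error("petco2_timecourse expects a capnograph recording")
  pk <- find_peaks(co2$samples, co2$fs, min_sep_s = 1.5)
  if (length(pk) < 2L) stop("fewer than 2 breaths detected in capnograph trace")
  pk_t <- rec_times(co2)[pk] - shift_s
  vals <- stats::approx(pk_t, co2$samples[pk], xout = vol_times(tr_s, n_vols),
                        rule = 2)$y
  physio_timecourse(vals, tr_s, "petco2_mmHg")
}

#' Interquartile-range outlier screen
#'
#' Marks values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` for exclusion;
#' quartiles use linear interpolation of order statistics.
#'
#' @param values numeric vector of per-subject metric values (>= 4).
#' @return logical inclusion mask, `TRUE` for retained values.
#' @export
iqr_screen <- function(values) {
  if (length(values) < 4L) cfg_error("need at least 4 values for IQR screening")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7, na.rm = TRUE)
  iqr <- q[2] - q[1]
  values >= q[1] - 1.5 * iqr & values <= q[2] + 1.5 * iqr
}
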