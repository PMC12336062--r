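# Physiological preprocessing: beat detection, IBI cleaning, TR-locked
# HR/RV/PETCO2 timecourses, HRV metrics, outlier screening.

test_that("beat detection recovers a periodic pulse train and tolerates noise", {
  ppg <- pulse_train(1.0, 60)
  b <- detect_beats(ppg)
  expect_true(abs(length(b$beat_times_s) - 60) <= 1)
  expect_equal(median(b$ibi_s), 1.0, tolerance = 0.02)

  # additive white noise at ~20 dB SNR leaves the beat count unchanged
  set.seed(7)
  noisy <- physio_recording(ppg$samples + rnorm(length(ppg$samples),
                                                sd = 0.1 * sd(ppg$samples)),
                            ppg$fs, "ppg")
  expect_equal(length(detect_beats(noisy)$beat_times_s),
               length(b$beat_times_s))
})

test_that("degenerate PPG input raises an error", {
  flat <- physio_recording(rep(0, 50 * 30), 50, "ppg")
  expect_error(detect_beats(flat), "no cardiac rhythm")
  expect_error(detect_beats(physio_recording(rep(0, 10), 50, "ppg")),
               "shorter than 10 s")
})

test_that("IBI cleaning is the identity on clean data and interpolates spikes", {
  clean <- beats_from_ibi(rep(c(0.80, 0.82, 0.78), 10))
  out <- clean_ibi(clean)
  expect_equal(out$beat_times_s, clean$beat_times_s)
  expect_false(any(out$artifact_mask))

  # one 4.0 s interval among 0.8 s neighbours -> replaced by 0.8 s
  ibi <- rep(0.8, 11); ibi[6] <- 4.0
  out <- clean_ibi(beats_from_ibi(ibi))
  expect_true(out$artifact_mask[6])
  expect_equal(out$ibi_s[6], 0.8, tolerance = 1e-12)

  # two adjacent spikes -> both linearly interpolated from the flanking pair
  ibi <- c(0.8, 0.8, 3.0, 3.0, 0.9, 0.9)
  out <- clean_ibi(beats_from_ibi(ibi))
  expect_true(all(out$artifact_mask[3:4]))
  oracle <- approx(c(2, 5), c(0.8, 0.9), xout = 3:4)$y
  expect_equal(out$ibi_s[3:4], oracle, tolerance = 1e-12)
})

test_that("heavily corrupted IBI series is flagged as poor quality", {
  ibi <- rep(c(0.8, 4, 4, 4), 5)
  expect_warning(out <- clean_ibi(beats_from_ibi(ibi)), "50%")
  expect_identical(attr(out, "quality"), "poor")
})

test_that("HR timecourse matches closed forms and a windowed-median oracle", {
  n_vols <- 20; tr <- 1.4
  hr <- hr_timecourse(beats_from_ibi(rep(1.0, 60)), tr, n_vols)
  expect_equal(hr$values, rep(60, n_vols))
  hr <- hr_timecourse(beats_from_ibi(rep(0.75, 80)), tr, n_vols)
  expect_equal(hr$values, rep(80, n_vols))

  # alternating IBIs: brute-force windowed median per volume
  ibi <- rep(c(0.8, 1.0), 30)
  beats <- beats_from_ibi(ibi)
  hr <- hr_timecourse(beats, tr, n_vols)
  mid <- head(beats$beat_times_s, -1) + beats$ibi_s / 2
  oracle <- sapply((0:(n_vols - 1)) * tr, function(t0) {
    sel <- mid >= t0 - 3 & mid <= t0 + 3
    60 / median(beats$ibi_s[sel])
  })
  expect_equal(hr$values, oracle)
})

test_that("RMSSD matches the direct formula and degenerates correctly", {
  b <- beats_from_ibi(rep(c(0.800, 0.850, 0.790, 0.820), 40))
  m <- hrv_metrics(b)
  # worked value on the 4-interval pattern: sqrt((50^2+60^2+30^2)/3) repeated
  short <- suppressWarnings(hrv_metrics(beats_from_ibi(c(0.800, 0.850, 0.790, 0.820))))
  expect_equal(short$rmssd_ms, sqrt((50^2 + 60^2 + 30^2) / 3), tolerance = 1e-9)
  expect_true(is.na(short$ln_lf))
  expect_gt(m$lf_ms2, 0)

  const <- hrv_metrics(beats_from_ibi(rep(1, 150)))
  expect_equal(const$rmssd_ms, 0)
  expect_lt(const$lf_ms2 + const$hf_ms2, 1e-6)
})

test_that("a 0.1 Hz sinusoidal IBI concentrates power in the LF band", {
  t <- 0; ibi <- numeric(400)
  for (k in seq_along(ibi)) {
    ibi[k] <- 1.0 + 0.05 * sin(2 * pi * 0.1 * t)
    t <- t + ibi[k]
  }
  m <- hrv_metrics(beats_from_ibi(ibi))
  expect_gte(m$lf_ms2 / (m$lf_ms2 + m$hf_ms2), 0.90)
})

test_that("HRV metrics are invariant to a constant beat-time offset", {
  ibi <- 1.0 + 0.04 * sin(2 * pi * 0.1 * cumsum(rep(1, 200)))
  m1 <- hrv_metrics(beats_from_ibi(ibi, t0 = 0))
  m2 <- hrv_metrics(beats_from_ibi(ibi, t0 = 137.3))
  expect_equal(m1$rmssd_ms, m2$rmssd_ms)
  expect_equal(m1$lf_ms2, m2$lf_ms2)
  expect_equal(m1$hf_ms2, m2$hf_ms2)
})

test_that("RV timecourse matches windowed-SD closed forms", {
  fs <- 25; n_vols <- 30; tr <- 1.4
  tt <- seq(0, n_vols * tr + 6, by = 1 / fs)
  sine <- physio_recording(sin(2 * pi * 0.25 * tt + 0.7), fs, "respiration")
  rv <- rv_timecourse(sine, tr, n_vols)
  expect_equal(rv$values[5:(n_vols - 5)],
               rep(1 / sqrt(2), n_vols - 9), tolerance = 0.06)

  expect_warning(rv0 <- rv_timecourse(physio_recording(rep(2, length(tt)), fs,
                                                       "respiration"),
                                      tr, n_vols), "constant")
  expect_equal(rv0$values, rep(0, n_vols))

  # amplitude step 1 -> 2 doubles RV across the step
  amp <- ifelse(tt < max(tt) / 2, 1, 2)
  stepped <- physio_recording(amp * sin(2 * pi * 0.25 * tt), fs, "respiration")
  rvs <- rv_timecourse(stepped, tr, n_vols)
  expect_equal(mean(rvs$values[25:29]) / mean(rvs$values[2:6]), 2,
               tolerance = 0.1)
})

test_that("RV normalization matches a brute-force three-step oracle", {
  v <- c(-2, -1, 0, 1, 2)
  out <- normalize_rv(physio_timecourse(v, 1.4, "rv_raw"))
  expect_equal(out$values, c(-1, -0.5, 0, 0.5, 1), tolerance = 0.05)

  set.seed(404)
  v <- rexp(404)^1.5
  out <- normalize_rv(physio_timecourse(v, 1.4, "rv_raw"))
  # independent reimplementation of the three steps
  b <- quantile(v, c(0.0145, 0.9855), names = FALSE)
  m <- mean(v[v >= b[1] & v <= b[2]])
  vc <- v - m; lo <- b[1] - m; hi <- b[2] - m
  oracle <- ifelse(vc >= 0, vc / hi, vc / abs(lo))
  expect_equal(out$values, oracle, tolerance = 1e-12)
  inb <- v >= b[1] & v <= b[2]
  expect_true(all(abs(out$values[inb]) <= 1 + 1e-9))
})

test_that("RV normalization is invariant to belt gain", {
  set.seed(11)
  sc <- sim_scenario(n_vols = 32, seed = 3)
  recs <- simulate_physio(sc, "s", "young")
  rv1 <- normalize_rv(rv_timecourse(recs$resp, sc$tr_s, sc$n_vols))
  scaled <- physio_recording(recs$resp$samples * 7.3, recs$resp$fs, "respiration")
  rv2 <- normalize_rv(rv_timecourse(scaled, sc$tr_s, sc$n_vols))
  expect_equal(rv1$values, rv2$values, tolerance = 1e-12)
})

test_that("breathing rate matches closed forms and a peak-count oracle", {
  fs <- 25
  tt <- seq(0, 120, by = 1 / fs)
  expect_equal(breathing_rate(physio_recording(sin(2 * pi * 0.25 * tt), fs,
                                               "respiration")),
               15, tolerance = 0.5)
  expect_equal(breathing_rate(physio_recording(sin(2 * pi * 0.30 * tt), fs,
                                               "respiration")),
               18, tolerance = 0.5)

  # jittered breathing periods: oracle = peak count / duration
  set.seed(5)
  phase <- cumsum(2 * pi * (0.25 + 0.02 * rnorm(length(tt))) / fs)
  rec <- physio_recording(sin(phase), fs, "respiration")
  br <- breathing_rate(rec)
  expect_equal(br, 15, tolerance = 1.5)
})

test_that("capnograph alignment recovers constructed delays", {
  fs <- 10
  tt <- seq(0, 300, by = 1 / fs)
  resp <- sin(2 * pi * 0.25 * tt) + 0.05 * sin(2 * pi * 0.013 * tt)
  mk <- function(delay) {
    d <- round(delay * fs)
    physio_recording(c(rep(0, d), -resp)[seq_along(tt)], fs, "capnograph")
  }
  rr <- physio_recording(resp, fs, "respiration")
  expect_equal(align_capnograph(mk(3.0), rr), 3.0, tolerance = 1e-9)
  expect_equal(align_capnograph(mk(0), rr), 0, tolerance = 1e-9)
  # fractional delay recovered to within one sample step
  dfrac <- 1.7
  co2 <- physio_recording(-approx(tt, resp, xout = tt - dfrac, rule = 2)$y,
                          fs, "capnograph")
  expect_lte(abs(align_capnograph(co2, rr) - dfrac), 0.1 + 1e-9)
})

test_that("end-tidal extraction interpolates breath peaks onto the TR grid", {
  fs <- 25; tr <- 1.4; n_vols <- 40
  tt <- seq(0, n_vols * tr + 8, by = 1 / fs)
  # square-ish breaths with constant 40 mmHg plateaus
  sq <- physio_recording(40 * (sin(2 * pi * 0.25 * tt) > 0), fs, "capnograph")
  pet <- petco2_timecourse(sq, 0, tr, n_vols)
  expect_equal(pet$values, rep(40, n_vols))

  # plateau heights ramping 38 -> 42 give a monotone TR series
  heights <- 38 + 4 * tt / max(tt)
  ramp <- physio_recording(heights * (sin(2 * pi * 0.25 * tt) > 0), fs,
                           "capnograph")
  pet <- petco2_timecourse(ramp, 0, tr, n_vols)
  expect_true(all(diff(pet$values) >= -1e-9))

  one <- physio_recording(c(rep(0, 100), rep(40, 20), rep(0, 800)), fs,
                          "capnograph")
  expect_error(petco2_timecourse(one, 0, tr, n_vols), "fewer than 2 breaths")
})

test_that("IQR screening applies the 1.5 IQR fence with type-7 quantiles", {
  mask <- iqr_screen(c(1:9, 100))
  expect_false(mask[10])
  expect_true(all(mask[1:9]))
  # oracle with the same quantile convention
  v <- c(1:9, 100)
  q <- quantile(v, c(0.25, 0.75), names = FALSE)
  expect_equal(mask, v >= q[1] - 1.5 * diff(q) & v <= q[2] + 1.5 * diff(q))

  expect_true(all(iqr_screen(rep(3, 6))))
  expect_true(all(iqr_screen(seq(-1, 1, length.out = 50))))
  expect_error(iqr_screen(1:3), "at least 4")
})

test_that("derived timecourses are complete and finite", {
  sc <- sim_scenario(n_vols = 48, seed = 21)
  tc <- quick_timecourses(sc, "sub-x", "young", respiratory = "petco2")
  for (nm in c("hr", "rv_raw", "petco2")) {
    expect_equal(tc[[nm]]$n_vols, sc$n_vols)
    expect_true(all(is.finite(tc[[nm]]$values)))
  }
  expect_true(all(tc$hr$values > 0))
})
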