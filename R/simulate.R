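# Synthetic physiological waveforms and coupled BOLD data with known
# ground truth. Everything is a deterministic function of scenario + seed
# + subject id, so downstream stages can be tested by parameter recovery.

# Per-subject/session deterministic seed.
subject_seed <- function(scenario, subject, what, session = "pre") {
  derive_seed(scenario$seed, subject, what, session)
}

#' Simulate physiological recordings for one subject
#'
#' Generates a PPG pulse train whose inter-beat intervals follow the
#' group's mean heart rate with sinusoidal low-frequency (0.1 Hz) and
#' high-frequency (at the breathing frequency) modulation; a
#' quasi-sinusoidal respiration waveform at the group breathing rate with
#' slow amplitude jitter; and a capnograph trace with breath-synchronous
#' plateaus around the group CO2 level, delayed by the scenario's
#' capnograph measurement delay. PPG pulses are raised cosines (one per
#' beat). Output is bit-identical for identical scenario + subject id.
#'
#' @param scenario a [sim_scenario()].
#' @param subject subject identifier (string).
#' @param group name of the group in `scenario$group_params`.
#' @param session `"pre"` or `"post"` (enters the seed only).
#' @param duration_s recording length; defaults to scan duration + 10 s.
#' @return list of [physio_recording()]s: `ppg`, `resp`, `co2`.
#' @export
simulate_physio <- function(scenario, subject, group = names(scenario$group_params)[1],
                            session = "pre", duration_s = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  p <- scenario$group_params[[group]]
  if (is.null(p)) cfg_error(sprintf("unknown group '%s'", group))
  if (is.null(duration_s)) duration_s <- scenario$n_vols * scenario$tr_s + 10
  fs <- scenario$physio_fs_hz
  tt <- seq(0, duration_s, by = 1 / fs)
  f_b <- p$breathing_rate_bpm / 60

  # --- cardiac beat train (deterministic given parameters) ---
  ibi0 <- 60 / p$mean_hr_bpm
  beats <- numeric(ceiling(duration_s / ibi0 * 2) + 4L)
  beats[1] <- 0.3
  k <- 1L
  while (beats[k] < duration_s) {
    t0 <- beats[k]
    ibi <- ibi0 + p$hrv_lf_amp_s * sin(2 * pi * 0.1 * t0) +
      p$hrv_hf_amp_s * sin(2 * pi * f_b * t0)
    k <- k + 1L
    beats[k] <- t0 + max(ibi, 0.33)
  }
  beats <- beats[1:k]

  # raised-cosine pulse per beat, width 0.30 s
  ppg <- numeric(length(tt))
  width <- 0.30
  for (b in beats) {
    i0 <- floor(b * fs) + 1L
    i1 <- min(length(tt), i0 + ceiling(width * fs))
    if (i0 > length(tt)) break
    seg <- tt[i0:i1] - b
    ppg[i0:i1] <- ppg[i0:i1] + 0.5 * (1 - cos(2 * pi * pmin(seg, width) / width))
  }

  # --- respiration: quasi-sinusoid with slow amplitude jitter ---
  set.seed(subject_seed(scenario, subject, "resp", session))
  knot_t <- seq(0, duration_s + 10, by = 10)
  amp <- stats::spline(knot_t, 1 + 0.15 * stats::rnorm(length(knot_t)),
                       xout = tt, method = "natural")$y
  resp <- amp * sin(2 * pi * f_b * tt)

  # --- capnograph: breath-synchronous plateaus, inverse to respiration ---
  set.seed(subject_seed(scenario, subject, "co2", session))
  exhale <- pmax(-resp / pmax(abs(amp), 1e-6), 0)        # in [0, 1]
  plateau <- pmin(1, exhale / 0.4)^0.5                   # flat-topped
  n_breaths <- ceiling(duration_s * f_b) + 2L
  breath_var <- rep(1 + 0.01 * stats::rnorm(n_breaths),
                    each = ceiling(length(tt) / n_breaths))[seq_along(tt)]
  co2_raw <- p$co2_mean_mmHg * plateau * breath_var
  # measurement delay: the trace reports gas sampled co2_delay_s earlier
  dshift <- round(scenario$co2_delay_s * fs)
  co2 <- c(rep(co2_raw[1], dshift), co2_raw)[seq_along(tt)]

  list(ppg = physio_recording(ppg, fs, "ppg"),
       resp = physio_recording(resp, fs, "respiration"),
       co2 = physio_recording(co2, fs, "capnograph"))
}

# Convolve a TR-locked series with a response function on a fine grid,
# delay by lag_s, and sample back at volume times (z-scored).
coupled_regressor <- function(values, tr_s, n_vols, rf, lag_s, dt = 0.1) {
  tv <- vol_times(tr_s, n_vols)
  tfine <- seq(0, tv[n_vols], by = dt)
  xf <- interp_to(tv, zscore(detrend_linear(values)), tfine)
  kern <- rf(seq(0, 60, by = dt))
  cf <- conv_causal(xf, kern, dt)
  zscore(interp_to(tfine, cf, tv - lag_s))
}

#' Simulate coupled BOLD data for one subject
#'
#' Each in-brain voxel is the sum of response-function-convolved
#' physiological regressors (CRF for heart rate; RRF or the CO2 response
#' for the respiratory measure), delayed by the group latency on the fine
#' convolution grid before TR sampling, weighted by per-voxel betas, plus
#' Legendre polynomial drift and AR(1) noise around a baseline of 100.
#' The signal amplitude at every voxel is solved (a quadratic in the
#' scale) so that `var(signal) / var(signal + noise)` equals the voxel's
#' target variance fraction exactly on the realized series; drift is
#' deterministic and excluded from the accounting, matching a PVE analysis
#' that projects drift out first.
#'
#' @param scenario a [sim_scenario()].
#' @param physio named list of TR-locked [physio_timecourse()]s: `hr`
#'   plus `rv` and/or `petco2`.
#' @param subject subject identifier.
#' @param group group name.
#' @param session `"pre"` or `"post"`.
#' @param true_pve optional per-voxel target variance-fraction vector (one
#'   value per in-brain voxel, recycled); defaults to
#'   `pve_base * coupling_gain`. Must lie in `[0, 1)`.
#' @param respiratory which respiratory measure couples into BOLD:
#'   `"rv"` or `"petco2"` (defaults to whichever is present).
#' @param return_components also return the realized `signal`, `noise`
#'   and `drift` component matrices (volumes x voxels).
#' @return list with `bold` (a [bold_volume()] with tissue masks) and
#'   `ground_truth` (data frame: voxel index, betas, realized `true_pve`,
#'   `true_lag_s`); plus `components` if requested.
#' @export
simulate_bold <- function(scenario, physio, subject,
                          group = names(scenario$group_params)[1],
                          session = "pre", true_pve = NULL,
                          respiratory = NULL, return_components = FALSE) {
  stopifnot(inherits(scenario, "sim_scenario"))
  p <- scenario$group_params[[group]]
  if (is.null(p)) cfg_error(sprintf("unknown group '%s'", group))
  n <- scenario$n_vols
  tr <- scenario$tr_s
  for (tc in physio) stopifnot(inherits(tc, "physio_timecourse"), tc$n_vols == n)
  if (is.null(respiratory))
    respiratory <- if (!is.null(physio[["rv"]])) "rv" else "petco2"

  lag <- p$latency_shift_s
  regs <- list(cardiac = coupled_regressor(physio[["hr"]]$values, tr, n, crf, lag))
  if (respiratory == "rv" && !is.null(physio[["rv"]])) {
    regs$resp <- coupled_regressor(physio[["rv"]]$values, tr, n, rrf, lag)
  } else if (respiratory == "petco2" && !is.null(physio[["petco2"]])) {
    regs$resp <- coupled_regressor(physio[["petco2"]]$values, tr, n,
                                   function(t) co2_rf(t), lag)
  }

  sp <- scenario$grid_shape
  nvox <- prod(sp)
  if (is.null(true_pve)) true_pve <- scenario$pve_base * p$coupling_gain
  true_pve <- rep(true_pve, length.out = nvox)
  if (any(true_pve < 0 | true_pve >= 1)) cfg_error("true_pve must be in [0, 1)")

  set.seed(subject_seed(scenario, subject, "bold", session))
  beta_c <- stats::runif(nvox, 0.5, 1.5)
  beta_r <- if (length(regs) > 1L) stats::runif(nvox, 0.5, 1.5) else rep(0, nvox)

  S <- regs$cardiac %*% t(beta_c)
  if (length(regs) > 1L) S <- S + regs$resp %*% t(beta_r)
  S <- sweep(S, 2, colMeans(S))

  ar1 <- scenario$noise$ar1_coef
  sig <- scenario$noise$sigma
  E <- matrix(stats::rnorm(n * nvox, sd = sig), n, nvox)
  if (ar1 > 0) E <- apply(E, 2, function(e) as.numeric(stats::filter(e, ar1, "recursive")))
  E <- sweep(E, 2, colMeans(E))

  # exact per-voxel scaling: var(a s) / var(a s + e) = p
  vs <- colSums(S^2)
  ve <- colSums(E^2)
  cse <- colSums(S * E)
  a <- numeric(nvox)
  realized <- true_pve
  for (v in seq_len(nvox)) {
    pv <- true_pve[v]
    if (pv == 0 || vs[v] == 0) { a[v] <- 0; realized[v] <- 0; next }
    if (ve[v] == 0) { a[v] <- 1; realized[v] <- 1; next }
    disc <- pv^2 * cse[v]^2 + pv * (1 - pv) * vs[v] * ve[v]
    a[v] <- (pv * cse[v] + sqrt(disc)) / ((1 - pv) * vs[v])
  }
  Ssc <- sweep(S, 2, a, `*`)

  D <- legendre_basis(n, length(scenario$drift) - 1L) %*% scenario$drift
  bold_mat <- 100 + as.numeric(D) + Ssc + E
  arr <- aperm(array(bold_mat, c(n, sp)), c(2, 3, 4, 1))

  gt <- data.frame(voxel = seq_len(nvox),
                   beta_cardiac = a * beta_c, beta_resp = a * beta_r,
                   true_pve = realized, true_lag_s = lag)
  out <- list(bold = bold_volume(arr, tr, scenario_masks(sp)), ground_truth = gt)
  if (return_components)
    out$components <- list(signal = Ssc, noise = E,
                           drift = matrix(D, n, nvox))
  out
}
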