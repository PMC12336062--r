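# Simulation scenarios: cohort structure, per-group physiological and
# coupling parameters, acquisition geometry, noise and drift.

#' Default per-group simulation parameters
#'
#' The built-in groups emulate the qualitative age contrasts reported for
#' resting-state cohorts: the older group couples physiology into BOLD at
#' half the gain, with a 2 s later vascular latency, halved
#' high-frequency heart-rate modulation and a slightly lower breathing
#' rate. Magnitudes are free modelling choices.
#'
#' @return named list of per-group parameter lists (`young`, `old`), each
#'   with `coupling_gain`, `latency_shift_s`, `mean_hr_bpm`,
#'   `hrv_lf_amp_s`, `hrv_hf_amp_s`, `breathing_rate_bpm`,
#'   `co2_mean_mmHg`.
#' @export
default_group_params <- function() {
  list(
    young = list(coupling_gain = 1.0, latency_shift_s = 0.0, mean_hr_bpm = 70,
                 hrv_lf_amp_s = 0.05, hrv_hf_amp_s = 0.05,
                 breathing_rate_bpm = 16, co2_mean_mmHg = 39),
    old   = list(coupling_gain = 0.5, latency_shift_s = 2.0, mean_hr_bpm = 67,
                 hrv_lf_amp_s = 0.05, hrv_hf_amp_s = 0.025,
                 breathing_rate_bpm = 14, co2_mean_mmHg = 40)
  )
}

#' Construct a simulation scenario
#'
#' Bundles everything the generator needs: cohort size, per-group
#' physiology and coupling, acquisition grid, fine-grid sampling rate,
#' AR(1) noise, polynomial drift and the master seed. All downstream
#' outputs are deterministic functions of the scenario.
#'
#' @param n_subjects_per_group subjects per group.
#' @param group_params per-group parameter lists, see
#'   [default_group_params()].
#' @param grid_shape 3-vector of voxels per axis.
#' @param n_vols number of BOLD volumes (>= 16).
#' @param tr_s repetition time (s).
#' @param physio_fs_hz physiological sampling rate (Hz, >= 10).
#' @param noise list with `ar1_coef` in `[0, 1)` and innovation `sigma`.
#' @param drift Legendre drift coefficients (order = length - 1), in
#'   signal units.
#' @param pve_base target variance fraction at `coupling_gain = 1`; the
#'   per-voxel target is `pve_base * coupling_gain`.
#' @param co2_delay_s capnograph measurement delay baked into simulated
#'   traces (s).
#' @param seed master RNG seed.
#' @return object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_subjects_per_group = 2,
                         group_params = default_group_params(),
                         grid_shape = c(6, 6, 6), n_vols = 64, tr_s = 1.4,
                         physio_fs_hz = 25,
                         noise = list(ar1_coef = 0.3, sigma = 1),
                         drift = c(0, 2, -1, 0.5, 0.25),
                         pve_base = 0.3, co2_delay_s = 2.0, seed = 1) {
  if (tr_s <= 0) cfg_error("tr_s must be positive")
  if (physio_fs_hz < 10) cfg_error("physio_fs_hz must be at least 10")
  if (n_vols < 16) cfg_error("n_vols must be at least 16")
  if (noise$ar1_coef < 0 || noise$ar1_coef >= 1) cfg_error("ar1_coef must be in [0, 1)")
  req <- c("coupling_gain", "latency_shift_s", "mean_hr_bpm", "hrv_lf_amp_s",
           "hrv_hf_amp_s", "breathing_rate_bpm", "co2_mean_mmHg")
  for (g in names(group_params)) {
    miss <- setdiff(req, names(group_params[[g]]))
    if (length(miss))
      cfg_error(sprintf("group '%s' missing parameter(s): %s", g,
                        paste(miss, collapse = ", ")))
    if (group_params[[g]]$coupling_gain < 0) cfg_error("coupling_gain must be >= 0")
    if (group_params[[g]]$mean_hr_bpm <= 0) cfg_error("mean_hr_bpm must be positive")
  }
  if (pve_base < 0 || pve_base >= 1) cfg_error("pve_base must be in [0, 1)")
  structure(list(n_subjects_per_group = n_subjects_per_group,
                 group_params = group_params,
                 grid_shape = as.integer(grid_shape), n_vols = as.integer(n_vols),
                 tr_s = tr_s, physio_fs_hz = physio_fs_hz, noise = noise,
                 drift = drift, pve_base = pve_base, co2_delay_s = co2_delay_s,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("<sim_scenario> %d/group x %d groups, grid %s, %d vols @ TR %g s, fs %g Hz, seed %d\n",
              x$n_subjects_per_group, length(x$group_params),
              paste(x$grid_shape, collapse = "x"), x$n_vols, x$tr_s,
              x$physio_fs_hz, x$seed))
  for (g in names(x$group_params)) {
    p <- x$group_params[[g]]
    cat(sprintf("  %s: gain %.2f, latency %+.1f s, HR %g bpm, breathing %g bpm\n",
                g, p$coupling_gain, p$latency_shift_s, p$mean_hr_bpm,
                p$breathing_rate_bpm))
  }
  invisible(x)
}

# Geometric tissue partition of the simulation grid: a central ventricle
# core, a white-matter shell around it, gray matter outside; brain = all.
scenario_masks <- function(grid_shape) {
  sp <- grid_shape
  ctr <- (sp + 1) / 2
  idx <- expand.grid(x = seq_len(sp[1]), y = seq_len(sp[2]), z = seq_len(sp[3]))
  d <- pmax(abs(idx$x - ctr[1]), pmax(abs(idx$y - ctr[2]), abs(idx$z - ctr[3])))
  lim <- max(ctr - 1)
  vent <- array(d <= lim / 3, sp)
  white <- array(d > lim / 3 & d <= 2 * lim / 3, sp)
  gray <- array(d > 2 * lim / 3, sp)
  list(brain = array(TRUE, sp), gray = gray, white = white, ventricles = vent)
}
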