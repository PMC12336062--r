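# Shared fixture builders. Everything is generated in code at test time.

# Ideal PPG pulse train: raised-cosine pulses at exactly the given rate.
pulse_train <- function(rate_hz, duration_s, fs = 50) {
  tt <- seq(0, duration_s, by = 1 / fs)
  x <- numeric(length(tt))
  beats <- seq(0.2, duration_s, by = 1 / rate_hz)
  for (b in beats) {
    sel <- tt >= b & tt <= b + 0.3
    x[sel] <- x[sel] + 0.5 * (1 - cos(2 * pi * (tt[sel] - b) / 0.3))
  }
  physio_recording(x, fs, "ppg")
}

# Beat series with prescribed inter-beat intervals.
beats_from_ibi <- function(ibi_s, t0 = 0) beat_series(t0 + c(0, cumsum(ibi_s)))

# One subject's TR-locked timecourses straight from the generator chain.
quick_timecourses <- function(scenario, subject = "sub-a", group = "young",
                              respiratory = "rv") {
  recs <- simulate_physio(scenario, subject, group)
  derive_timecourses(recs, scenario$tr_s, scenario$n_vols,
                     respiratory = respiratory)
}

# Per-subject joint-model PVE maps for a simulated two-group cohort
# (in memory; no disk I/O).
cohort_pve_maps <- function(scenario, respiratory = "rv") {
  maps <- list(); labs <- character(0)
  for (grp in names(scenario$group_params)) {
    for (j in seq_len(scenario$n_subjects_per_group)) {
      sub <- sprintf("sub-%s%02d", grp, j)
      tc <- quick_timecourses(scenario, sub, grp, respiratory)
      sim <- simulate_bold(scenario, tc, sub, grp, respiratory = respiratory)
      maps[[length(maps) + 1L]] <- pve(sim$bold, build_regressors(tc, "joint"))
      labs <- c(labs, grp)
    }
  }
  list(maps = maps, labels = factor(labs, levels = names(scenario$group_params)))
}
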