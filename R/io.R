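# File interfaces: NIfTI volumes, BIDS-style physio TSV + JSON sidecar,
# cohort manifest and ground-truth tables, subject loading with validation.

#' Write a 3D/4D array as gzipped NIfTI
#'
#' @param arr numeric array.
#' @param path output path (`.nii.gz`).
#' @param pixdim voxel sizes; time step in the 4th slot for 4D data.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(arr, path, pixdim = NULL) {
  img <- RNifti::asNifti(arr * 1.0)
  if (!is.null(pixdim)) RNifti::pixdim(img) <- pixdim
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file as a plain array
#'
#' @param path file path.
#' @return numeric array with attribute `pixdim`.
#' @export
read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  out <- as.array(img)
  attr(out, "pixdim") <- RNifti::pixdim(img)
  out
}

#' Write physiological recordings as BIDS-style TSV + JSON sidecar
#'
#' All recordings must share a sampling rate and start time; columns are
#' named by modality. The sidecar carries `SamplingFrequency`, `StartTime`
#' and `Columns`.
#'
#' @param recs named list of [physio_recording()]s.
#' @param stem output stem; writes `<stem>.tsv` and `<stem>.json`.
#' @return the TSV path, invisibly.
#' @export
write_physio <- function(recs, stem) {
  fs <- unique(vapply(recs, function(r) r$fs, numeric(1)))
  st <- unique(vapply(recs, function(r) r$start_time_s, numeric(1)))
  if (length(fs) != 1L || length(st) != 1L)
    cfg_error("recordings disagree in sampling rate or start time")
  n <- min(vapply(recs, function(r) length(r$samples), integer(1)))
  df <- as.data.frame(lapply(recs, function(r) r$samples[seq_len(n)]))
  names(df) <- names(recs)
  tsv <- paste0(stem, ".tsv")
  utils::write.table(format(df, digits = 10, trim = TRUE), tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sidecar <- list(SamplingFrequency = fs, StartTime = st, Columns = names(df))
  writeLines(jsonlite::toJSON(sidecar, auto_unbox = TRUE, pretty = TRUE),
             paste0(stem, ".json"))
  invisible(tsv)
}

#' Read BIDS-style physio TSV + JSON sidecar
#'
#' @param stem path stem (without extension).
#' @param modalities mapping from column name to recording modality;
#'   defaults assume columns named `ppg`, `resp`, `co2`.
#' @return named list of [physio_recording()]s.
#' @export
read_physio <- function(stem,
                        modalities = c(ppg = "ppg", resp = "respiration",
                                       co2 = "capnograph")) {
  meta <- jsonlite::fromJSON(paste0(stem, ".json"))
  df <- utils::read.delim(paste0(stem, ".tsv"), check.names = FALSE)
  missing_cols <- setdiff(meta$Columns, names(df))
  if (length(missing_cols))
    stop(sprintf("physio TSV missing column(s): %s", paste(missing_cols, collapse = ", ")))
  out <- list()
  for (cn in meta$Columns) {
    if (!cn %in% names(modalities)) next
    out[[cn]] <- physio_recording(df[[cn]], meta$SamplingFrequency,
                                  modalities[[cn]], meta$StartTime)
  }
  out
}

#' Simulate a cohort and write it to disk
#'
#' One BOLD + physio file set per subject per session, with tissue masks,
#' a cohort manifest (CSV) and a ground-truth table (TSV). Group
#' differences follow the scenario's per-group parameters; subjects
#' alternate between the `osc_plus` and `osc_minus` conditions. An
#' optional `session_effect` modifies group parameters for post-session
#' data of matching group x condition cells.
#'
#' @param scenario a [sim_scenario()].
#' @param out_dir output directory (created if absent).
#' @param sessions `"pre"` or `c("pre", "post")`.
#' @param conditions condition labels cycled over subjects within a group.
#' @param respiratory `"rv"` or `"petco2"`: which respiratory measure is
#'   coupled into BOLD and recorded in ground truth.
#' @param session_effect optional named list, e.g.
#'   `list(old.osc_plus = list(latency_shift_s = 1))`, overriding group
#'   parameters for post-session simulation.
#' @param overwrite refuse to touch an existing manifest unless `TRUE`.
#' @return the manifest data frame, invisibly; files under `out_dir`.
#' @export
simulate_cohort <- function(scenario, out_dir, sessions = "pre",
                            conditions = c("osc_plus", "osc_minus"),
                            respiratory = "rv", session_effect = NULL,
                            overwrite = FALSE) {
  stopifnot(inherits(scenario, "sim_scenario"))
  man_path <- file.path(out_dir, "manifest.csv")
  if (file.exists(man_path) && !overwrite)
    stop(sprintf("refusing to overwrite existing dataset at %s (set overwrite = TRUE)", out_dir))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  rows <- list()
  gt_rows <- list()
  for (grp in names(scenario$group_params)) {
    for (j in seq_len(scenario$n_subjects_per_group)) {
      sub <- sprintf("sub-%s%02d", grp, j)
      cond <- conditions[(j - 1L) %% length(conditions) + 1L]
      for (ses in sessions) {
        sc <- scenario
        eff_key <- paste(grp, cond, sep = ".")
        if (ses == "post" && !is.null(session_effect[[eff_key]]))
          sc$group_params[[grp]] <- utils::modifyList(sc$group_params[[grp]],
                                                      session_effect[[eff_key]])
        recs <- simulate_physio(sc, sub, group = grp, session = ses)
        tc <- derive_timecourses(recs, sc$tr_s, sc$n_vols,
                                 respiratory = respiratory)
        sim <- simulate_bold(sc, tc, sub, group = grp, session = ses,
                             respiratory = respiratory)
        stem <- file.path(out_dir, paste0(sub, "_ses-", ses))
        write_nifti(sim$bold$data, paste0(stem, "_bold.nii.gz"),
                    pixdim = c(2, 2, 2, sc$tr_s))
        for (mk in c("gray", "white", "ventricles"))
          write_nifti(sim$bold$masks[[mk]] * 1L,
                      file.path(out_dir, paste0(sub, "_mask-", mk, ".nii.gz")))
        write_physio(recs, paste0(stem, "_physio"))
        rows[[length(rows) + 1L]] <- data.frame(
          subject = sub, age_group = grp, condition = cond, session = ses,
          bold = paste0(basename(stem), "_bold.nii.gz"),
          physio = paste0(basename(stem), "_physio"),
          stringsAsFactors = FALSE)
        gt <- sim$ground_truth
        gt$subject <- sub; gt$session <- ses
        gt_rows[[length(gt_rows) + 1L]] <- gt
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, man_path, row.names = FALSE, quote = FALSE)
  gt_all <- do.call(rbind, gt_rows)
  utils::write.table(format(gt_all, digits = 10, trim = TRUE),
                     file.path(out_dir, "ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Derive TR-locked timecourses from raw recordings
#'
#' Runs the full physiological preprocessing chain: beat detection and
#' interval cleaning, windowed-median HR, windowed-SD RV with
#' normalization, and (for capnograph input) alignment and end-tidal CO2
#' extraction.
#'
#' @param recs named list of recordings (`ppg`, `resp`, optionally `co2`).
#' @param tr_s,n_vols volume grid.
#' @param respiratory `"rv"` or `"petco2"`.
#' @return named list of [physio_timecourse()]s (`hr`, `rv` and/or
#'   `petco2`, plus `rv_raw`).
#' @export
derive_timecourses <- function(recs, tr_s, n_vols, respiratory = "rv") {
  beats <- clean_ibi(detect_beats(recs$ppg))
  out <- list(hr = hr_timecourse(beats, tr_s, n_vols))
  if (!is.null(recs$resp)) {
    rv_raw <- rv_timecourse(recs$resp, tr_s, n_vols)
    out$rv_raw <- rv_raw
    if (respiratory == "rv") out$rv <- normalize_rv(rv_raw)
  }
  if (respiratory == "petco2") {
    if (is.null(recs$co2)) cfg_error("petco2 requested but no capnograph recording")
    shift <- align_capnograph(recs$co2, recs$resp)
    out$petco2 <- petco2_timecourse(recs$co2, shift, tr_s, n_vols)
    attr(out$petco2, "shift_s") <- shift
  }
  out
}

#' Load one subject's data from a cohort directory
#'
#' Reads the BOLD volume, tissue masks and physiological recordings named
#' by a manifest row, validating grid agreement and that the recordings
#' cover the scan.
#'
#' @param row one row of the cohort manifest (data frame).
#' @param dir dataset directory.
#' @param tr_s repetition time (s).
#' @return list with `bold` (a [bold_volume()]) and `physio` (recordings).
#' @export
load_subject <- function(row, dir, tr_s) {
  bold_path <- file.path(dir, row$bold)
  if (!file.exists(bold_path)) stop(sprintf("missing BOLD file: %s", bold_path))
  arr <- read_nifti(bold_path)
  sp <- dim(arr)[1:3]
  masks <- list(brain = array(TRUE, sp))
  for (mk in c("gray", "white", "ventricles")) {
    mp <- file.path(dir, paste0(row$subject, "_mask-", mk, ".nii.gz"))
    if (file.exists(mp)) {
      m <- read_nifti(mp)
      if (!identical(dim(m)[1:3], sp))
        stop(sprintf("mask '%s' grid %s does not match BOLD grid %s", mk,
                     paste(dim(m), collapse = "x"), paste(sp, collapse = "x")))
      masks[[mk]] <- array(m > 0.5, sp)
    }
  }
  recs <- read_physio(file.path(dir, row$physio))
  scan_dur <- dim(arr)[4] * tr_s
  for (nm in names(recs)) {
    dur <- length(recs[[nm]]$samples) / recs[[nm]]$fs
    if (dur < scan_dur - tr_s)
      stop(sprintf("physio '%s' covers %.1f s but scan lasts %.1f s", nm, dur, scan_dur))
  }
  list(bold = bold_volume(arr, tr_s, masks), physio = recs)
}
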