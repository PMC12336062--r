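# Pipeline orchestration: dataset profiles and the staged run directory.

#' Built-in dataset profiles
#'
#' `"nki-like"`: TR 1.4 s, 404 volumes, respiratory measure RV, lag grid
#' -2..+15 TRs, no tissue upsampling. `"hrver-like"`: TR 2.4 s, 175
#' volumes, respiratory measure end-tidal CO2, lag grid -1..+9 TRs,
#' tissue-level upsampling to 0.2 s.
#'
#' @param name profile name.
#' @param ... overrides for individual fields.
#' @return object of class `pipeline_config`: `tr_s`, `n_vols`,
#'   `respiratory`, `lag_grid`, `upsample_dt_s`, `drift_order`, `n_perm`,
#'   `alpha`, `seed`.
#' @export
pipeline_config <- function(name = c("nki-like", "hrver-like"), ...) {
  name <- match.arg(name)
  base <- if (name == "nki-like") {
    list(profile = name, tr_s = 1.4, n_vols = 404L, respiratory = "rv",
         lag_grid = default_lag_grid("nki-like"), upsample_dt_s = NULL,
         drift_order = 4L, n_perm = 500L, alpha = 0.05, seed = 1L)
  } else {
    list(profile = name, tr_s = 2.4, n_vols = 175L, respiratory = "petco2",
         lag_grid = default_lag_grid("hrver-like"), upsample_dt_s = 0.2,
         drift_order = 4L, n_perm = 500L, alpha = 0.05, seed = 1L)
  }
  cfg <- utils::modifyList(base, list(...))
  if (cfg$tr_s <= 0 || cfg$n_vols <= 0 || cfg$n_perm <= 0 || cfg$alpha <= 0)
    cfg_error("pipeline config fields must be positive")
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline_config> %s: TR %g s, %d vols, respiratory = %s, %d perms, seed %d\n",
              x$profile, x$tr_s, x$n_vols, x$respiratory, x$n_perm, x$seed))
  invisible(x)
}

stage_done <- function(run_dir, stage) file.exists(file.path(run_dir, paste0(".", stage, ".done")))
mark_done <- function(run_dir, stage) {
  writeLines(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
             file.path(run_dir, paste0(".", stage, ".done")))
}
plog <- function(run_dir, ...) {
  msg <- sprintf(...)
  cat(msg, "\n", sep = "", file = file.path(run_dir, "pipeline.log"), append = TRUE)
  message(msg)
}

#' Run the physiological-coupling pipeline on a cohort directory
#'
#' Stages run in dependency order: `physio` (TR-locked timecourses per
#' subject), `pve` (three-model percent-variance-explained maps and a
#' cohort mask-average table), `xcorr` (voxelwise HR lag maps and tissue
#' cross-correlations), `group` (TFCE-permutation age contrast on the
#' joint PVE maps). Completed stages are skipped unless `force = TRUE`;
#' every run logs its configuration and seed.
#'
#' @param dataset_dir cohort directory from [simulate_cohort()] (or the
#'   same layout for real data).
#' @param run_dir output directory for this run.
#' @param config a [pipeline_config()].
#' @param stages subset of `c("physio", "pve", "xcorr", "group")`.
#' @param session which session's scans to analyse.
#' @param force recompute completed stages.
#' @return `run_dir`, invisibly.
#' @export
run_pipeline <- function(dataset_dir, run_dir, config,
                         stages = c("physio", "pve", "xcorr", "group"),
                         session = "pre", force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, c("physio", "pve", "xcorr", "group"),
                      several.ok = TRUE)
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- utils::read.csv(file.path(dataset_dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  manifest <- manifest[manifest$session == session, , drop = FALSE]
  writeLines(jsonlite::toJSON(list(profile = config$profile, tr_s = config$tr_s,
                                   respiratory = config$respiratory,
                                   n_perm = config$n_perm, alpha = config$alpha,
                                   seed = config$seed, session = session,
                                   package_version = as.character(utils::packageVersion("physbold"))),
                              auto_unbox = TRUE, pretty = TRUE),
             file.path(run_dir, "provenance.json"))

  subjects <- manifest$subject
  load1 <- function(i) load_subject(manifest[i, ], dataset_dir, config$tr_s)

  if ("physio" %in% stages) {
    if (stage_done(run_dir, "physio") && !force) {
      plog(run_dir, "physio stage up to date")
    } else {
      for (i in seq_len(nrow(manifest))) {
        sub <- load1(i)
        tc <- derive_timecourses(sub$physio, config$tr_s, sub$bold$n_vols,
                                 respiratory = config$respiratory)
        df <- data.frame(volume = seq_len(sub$bold$n_vols))
        for (nm in names(tc)) df[[nm]] <- tc[[nm]]$values
        utils::write.table(format(df, digits = 10, trim = TRUE),
                           file.path(run_dir, paste0(subjects[i], "_timecourses.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      mark_done(run_dir, "physio")
      plog(run_dir, "physio stage complete (%d subjects)", nrow(manifest))
    }
  }

  read_tc <- function(i, nvols) {
    df <- utils::read.delim(file.path(run_dir, paste0(subjects[i], "_timecourses.tsv")))
    out <- list(hr = physio_timecourse(df[["hr"]], config$tr_s, "hr_bpm"))
    if (!is.null(df[["rv"]])) out$rv <- physio_timecourse(df[["rv"]], config$tr_s, "rv_norm")
    if (!is.null(df[["petco2"]])) out$petco2 <- physio_timecourse(df[["petco2"]], config$tr_s, "petco2_mmHg")
    out
  }

  if ("pve" %in% stages) {
    if (!stage_done(run_dir, "physio")) stop("pve stage requires the physio stage outputs")
    if (stage_done(run_dir, "pve") && !force) {
      plog(run_dir, "pve stage up to date")
    } else {
      summ <- list()
      for (i in seq_len(nrow(manifest))) {
        sub <- load1(i)
        tc <- read_tc(i, sub$bold$n_vols)
        maps <- run_three_models(sub$bold, tc, drift_order = config$drift_order)
        for (tag in names(maps)) {
          v <- maps[[tag]]$values
          v[is.na(v)] <- 0
          write_nifti(v, file.path(run_dir, paste0(subjects[i], "_pve-", tag, ".nii.gz")))
          for (mk in c("gray", "white", "ventricles")) {
            if (is.null(sub$bold$masks[[mk]])) next
            summ[[length(summ) + 1L]] <- data.frame(
              subject = subjects[i], model = tag, tissue = mk,
              mean_pve = mean(maps[[tag]]$values[sub$bold$masks[[mk]]], na.rm = TRUE))
          }
        }
      }
      utils::write.table(format(do.call(rbind, summ), digits = 10, trim = TRUE),
                         file.path(run_dir, "pve_summary.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      mark_done(run_dir, "pve")
      plog(run_dir, "pve stage complete")
    }
  }

  if ("xcorr" %in% stages) {
    if (!stage_done(run_dir, "physio")) stop("xcorr stage requires the physio stage outputs")
    if (stage_done(run_dir, "xcorr") && !force) {
      plog(run_dir, "xcorr stage up to date")
    } else {
      for (i in seq_len(nrow(manifest))) {
        sub <- load1(i)
        tc <- read_tc(i, sub$bold$n_vols)
        lcm <- voxelwise_xcorr(sub$bold, tc$hr, config$lag_grid)
        v <- lcm$values
        v[is.na(v)] <- 0
        write_nifti(v, file.path(run_dir, paste0(subjects[i], "_xcorr-hr.nii.gz")))
        xc <- tissue_xcorr(sub$bold, tc$hr, config$lag_grid,
                           upsample_dt_s = config$upsample_dt_s)
        write_tissue_xcorr(xc, file.path(run_dir, paste0(subjects[i], "_tissue-xcorr-hr.tsv")))
      }
      mark_done(run_dir, "xcorr")
      plog(run_dir, "xcorr stage complete")
    }
  }

  if ("group" %in% stages) {
    if (!stage_done(run_dir, "pve")) stop("group stage requires the pve stage outputs")
    if (stage_done(run_dir, "group") && !force) {
      plog(run_dir, "group stage up to date")
    } else {
      groups <- unique(manifest$age_group)
      if (length(groups) == 2L &&
          all(table(manifest$age_group) >= 3L)) {
        maps <- lapply(seq_len(nrow(manifest)), function(i)
          read_nifti(file.path(run_dir, paste0(subjects[i], "_pve-joint.nii.gz"))))
        gs <- permutation_test(maps, manifest$age_group,
                               n_perm = config$n_perm, seed = config$seed)
        write_nifti(gs$t_map, file.path(run_dir, "group_tmap.nii.gz"))
        write_nifti(gs$tfce_map, file.path(run_dir, "group_tfce.nii.gz"))
        write_nifti(gs$p_corr_pos, file.path(run_dir, "group_pcorr_pos.nii.gz"))
        write_nifti(gs$p_corr_neg, file.path(run_dir, "group_pcorr_neg.nii.gz"))
        plog(run_dir, "group stage complete (%s vs %s, %d perms)",
             gs$levels[1], gs$levels[2], gs$n_perm)
      } else {
        plog(run_dir, "group stage skipped: need two groups with >= 3 subjects each")
      }
      mark_done(run_dir, "group")
    }
  }
  invisible(run_dir)
}
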