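# Voxelwise linear modelling of BOLD against physiological regressors and
# percent-variance-explained (PVE) maps.

#' Construct a 4D BOLD volume with tissue masks
#'
#' @param data 4D numeric array `(x, y, z, t)`.
#' @param tr_s repetition time (s).
#' @param masks named list of 3D logical arrays on the same spatial grid;
#'   must include `brain`, optionally `gray`, `white`, `ventricles`.
#' @return object of class `bold_volume`.
#' @export
bold_volume <- function(data, tr_s, masks) {
  stopifnot(length(dim(data)) == 4L, is.list(masks), !is.null(masks$brain))
  sp <- dim(data)[1:3]
  for (nm in names(masks)) {
    if (!identical(dim(masks[[nm]]), sp))
      stop(sprintf("mask '%s' grid %s does not match BOLD grid %s", nm,
                   paste(dim(masks[[nm]]), collapse = "x"),
                   paste(sp, collapse = "x")))
    masks[[nm]] <- array(as.logical(masks[[nm]]), sp)
  }
  structure(list(data = data, tr_s = tr_s, masks = masks,
                 n_vols = dim(data)[4]), class = "bold_volume")
}

#' @export
print.bold_volume <- function(x, ...) {
  cat(sprintf("<bold_volume> %s voxels x %d volumes, TR %g s; masks: %s\n",
              paste(dim(x$data)[1:3], collapse = "x"), x$n_vols,
              x$tr_s, paste(names(x$masks), collapse = ", ")))
  invisible(x)
}

# In-mask voxel series as an n_vols x V matrix, plus the voxel indices.
mask_matrix <- function(bold, mask = bold$masks$brain) {
  idx <- which(mask)
  d <- dim(bold$data)
  Y <- matrix(aperm(bold$data, c(4, 1, 2, 3)), nrow = d[4])[, idx, drop = FALSE]
  list(Y = Y, idx = idx, sp = d[1:3])
}

# Scatter per-voxel values back into a 3D map (NA outside mask).
unmask_map <- function(values, idx, sp) {
  m <- array(NA_real_, sp)
  m[idx] <- values
  m
}

#' Fit the voxelwise physiological GLM
#'
#' Ordinary least squares of every in-mask voxel timecourse on the design
#' matrix. Rank-deficient designs are rejected with the offending columns
#' named.
#'
#' @param bold a [bold_volume()].
#' @param design a [build_regressors()] result.
#' @return object of class `coupling_fit` with per-voxel coefficients
#'   (`betas`, k x V), the design, mask indices and dimensions. Methods:
#'   `print`, `summary`, `coef`, `fitted`, `residuals`.
#' @export
fit_voxelwise <- function(bold, design) {
  stopifnot(inherits(bold, "bold_volume"), inherits(design, "regressor_set"))
  X <- design$X
  if (nrow(X) != bold$n_vols)
    stop(sprintf("design has %d rows but BOLD has %d volumes", nrow(X), bold$n_vols))
  mm <- mask_matrix(bold)
  if (!ncol(mm$Y)) stop("brain mask is empty")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- design$labels[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop(sprintf("rank-deficient design; collinear column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  betas <- qr.coef(qx, mm$Y)
  rownames(betas) <- design$labels
  structure(list(betas = betas, design = design, idx = mm$idx, sp = mm$sp,
                 tr_s = bold$tr_s, n_vols = bold$n_vols, qr = qx, Y = mm$Y),
            class = "coupling_fit")
}

#' @export
print.coupling_fit <- function(x, ...) {
  cat(sprintf("<coupling_fit> %s model: %d voxels, %d volumes, %d regressors\n",
              x$design$model_tag, ncol(x$betas), x$n_vols, nrow(x$betas)))
  invisible(x)
}

#' @export
coef.coupling_fit <- function(object, ...) object$betas

#' @export
fitted.coupling_fit <- function(object, ...) object$design$X %*% object$betas

#' @export
residuals.coupling_fit <- function(object, ...) object$Y - fitted(object)

#' @export
summary.coupling_fit <- function(object, ...) {
  res <- residuals(object)
  ydet <- drift_residualize(object$Y, object$design)
  r2 <- 1 - colSums(res^2) / pmax(colSums(ydet^2), .Machine$double.eps)
  out <- list(model_tag = object$design$model_tag,
              n_voxels = ncol(object$betas), n_vols = object$n_vols,
              labels = object$design$labels,
              beta_mean = rowMeans(object$betas),
              pve_summary = stats::quantile(pmin(pmax(r2, 0), 1),
                                            c(0, .25, .5, .75, 1)))
  class(out) <- "summary.coupling_fit"
  out
}

#' @export
print.summary.coupling_fit <- function(x, ...) {
  cat(sprintf("Voxelwise physiological GLM (%s model)\n", x$model_tag))
  cat(sprintf("  %d voxels x %d volumes, %d regressors\n",
              x$n_voxels, x$n_vols, length(x$labels)))
  cat("  PVE quantiles (drift-adjusted):\n")
  print(round(x$pve_summary, 4))
  invisible(x)
}

# Residualize the columns of M against the drift block of the design.
drift_residualize <- function(M, design) {
  D <- design$X[, design$drift_idx, drop = FALSE]
  qd <- qr(D)
  M - D %*% qr.coef(qd, M)
}

#' Percent-variance-explained map
#'
#' PVE at a voxel is the fraction of the drift-adjusted BOLD variance
#' captured by the physiological regressors: both the voxel series and the
#' physiological columns are residualized against the polynomial drift
#' block, and PVE = 1 - RSS/TSS of the resulting regression (a partial
#' R^2). Values are clipped to [0, 1]; zero-variance voxels are `NA`.
#'
#' @inheritParams fit_voxelwise
#' @return object of class `pve_map`: 3D `values` array (fractions, `NA`
#'   outside mask), `model_tag`, and the in-mask voxel indices.
#' @export
pve <- function(bold, design) {
  stopifnot(inherits(bold, "bold_volume"), inherits(design, "regressor_set"))
  if (nrow(design$X) != bold$n_vols)
    stop("design rows do not match BOLD volumes")
  mm <- mask_matrix(bold)
  if (!ncol(mm$Y)) stop("brain mask is empty")
  Yd <- drift_residualize(mm$Y, design)
  Xp <- drift_residualize(design$X[, design$phys_idx, drop = FALSE], design)
  qp <- qr(Xp)
  rss <- colSums((Yd - Xp %*% qr.coef(qp, Yd))^2)
  tss <- colSums(Yd^2)
  v <- ifelse(tss < .Machine$double.eps * bold$n_vols, NA_real_,
              pmin(pmax(1 - rss / tss, 0), 1))
  structure(list(values = unmask_map(v, mm$idx, mm$sp),
                 model_tag = design$model_tag, idx = mm$idx),
            class = "pve_map")
}

#' @export
print.pve_map <- function(x, ...) {
  v <- x$values[x$idx]
  cat(sprintf("<pve_map> %s model: %d voxels, median PVE %.4f (IQR %.4f-%.4f)\n",
              x$model_tag, length(v), stats::median(v, na.rm = TRUE),
              stats::quantile(v, .25, na.rm = TRUE),
              stats::quantile(v, .75, na.rm = TRUE)))
  invisible(x)
}

#' Fit the joint, cardiac-only and respiratory-only models
#'
#' Builds the three designs from the available physiological timecourses
#' and returns one PVE map per model. Cardiac and respiratory columns are
#' not orthogonalized, so variance shared between the two signal families
#' appears in both single-signal models.
#'
#' @param bold a [bold_volume()].
#' @param physio named list of [physio_timecourse()] objects (`hr`, and
#'   `rv` or `petco2`).
#' @param drift_order,dt_s,co2_params passed to [build_regressors()].
#' @return named list of [pve()] maps: `joint`, `cardiac`, `respiratory`.
#'   Models whose physiological inputs are missing are skipped with a
#'   warning.
#' @export
run_three_models <- function(bold, physio, drift_order = 4, dt_s = 0.5,
                             co2_params = NULL) {
  out <- list()
  have_hr <- !is.null(physio[["hr"]])
  have_resp <- !is.null(physio[["rv"]]) || !is.null(physio[["petco2"]])
  for (tag in c("joint", "cardiac", "respiratory")) {
    need_hr <- tag %in% c("joint", "cardiac")
    need_resp <- tag %in% c("joint", "respiratory")
    if ((need_hr && !have_hr) || (need_resp && !have_resp)) {
      warning(sprintf("skipping %s model: required physiological timecourse missing", tag))
      next
    }
    rs <- build_regressors(physio, model_tag = tag, drift_order = drift_order,
                           dt_s = dt_s, co2_params = co2_params)
    out[[tag]] <- pve(bold, rs)
  }
  out
}
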