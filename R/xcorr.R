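# Model-free lagged cross-correlation of BOLD with physiological series,
# voxelwise and averaged within tissue compartments.

#' Construct a lag grid
#'
#' Lags must be uniformly spaced at an integer multiple of the sampling
#' step in use. Positive lag means the physiological signal leads BOLD.
#'
#' @param lags_s ordered numeric vector of lags (s).
#' @param step_s the sampling step the lags refer to (s).
#' @return object of class `lag_grid`.
#' @export
lag_grid <- function(lags_s, step_s) {
  if (length(lags_s) < 1L) cfg_error("empty lag grid")
  d <- diff(lags_s)
  if (length(d) && (any(d <= 0) || diff(range(d)) > 1e-9))
    cfg_error("lags must be increasing and uniformly spaced")
  steps <- lags_s / step_s
  if (any(abs(steps - round(steps)) > 1e-6))
    cfg_error("each lag must be an integer multiple of the sampling step")
  structure(list(lags_s = lags_s, step_s = step_s), class = "lag_grid")
}

#' Built-in lag grids for the two acquisition profiles
#'
#' The `"nki-like"` profile (TR 1.4 s) spans -2 to +15 TRs
#' (-2.8 ... 21.0 s); the `"hrver-like"` profile (TR 2.4 s) spans
#' -2.4 ... 21.6 s in TR steps.
#'
#' @param profile `"nki-like"` or `"hrver-like"`.
#' @return a [lag_grid()].
#' @export
default_lag_grid <- function(profile = c("nki-like", "hrver-like")) {
  profile <- match.arg(profile)
  if (profile == "nki-like") lag_grid(seq(-2, 15) * 1.4, 1.4)
  else lag_grid(seq(-1, 9) * 2.4, 2.4)
}

#' Cross-correlation of two series at a set of lags
#'
#' At lag `L = d * step_s` the physiological series `x` is shifted forward
#' by `d` samples, so `y[i]` is paired with `x[i - d]`; the overlapping
#' segments are linearly detrended and their Pearson correlation returned.
#' Overlap shrinks with `|lag|` (no padding). Lags with fewer than
#' `min_overlap` overlapping samples give `NA` with a warning.
#'
#' @param x physiological series.
#' @param y BOLD (or other) series of the same length, same uniform grid.
#' @param step_s sampling step (s).
#' @param grid a [lag_grid()].
#' @param min_overlap minimum number of overlapping samples.
#' @return named numeric vector of Pearson r, one per lag.
#' @export
xcorr_at_lags <- function(x, y, step_s, grid, min_overlap = 30) {
  stopifnot(inherits(grid, "lag_grid"), length(x) == length(y))
  n <- length(x)
  r <- vapply(grid$lags_s, function(L) {
    d <- round(L / step_s)
    if (abs(d) >= n - 2L || n - abs(d) < min_overlap) return(NA_real_)
    if (d >= 0) {
      xs <- x[1:(n - d)]; ys <- y[(1 + d):n]
    } else {
      xs <- x[(1 - d):n]; ys <- y[1:(n + d)]
    }
    xs <- detrend_linear(xs); ys <- detrend_linear(ys)
    sx <- sqrt(sum(xs^2)); sy <- sqrt(sum(ys^2))
    if (sx == 0 || sy == 0) return(NA_real_)
    sum(xs * ys) / (sx * sy)
  }, numeric(1))
  if (anyNA(r)) warning("lags with insufficient overlap returned NA")
  names(r) <- sprintf("%.3f", grid$lags_s)
  r
}

#' Voxelwise lagged cross-correlation map
#'
#' [xcorr_at_lags()] applied to every in-mask voxel, vectorized per lag.
#' The physiological series must be on the volume grid and all lags must
#' be TR multiples (no voxel-level upsampling).
#'
#' @param bold a [bold_volume()].
#' @param physio a [physio_timecourse()] on the same volume grid.
#' @param grid a [lag_grid()] with `step_s` equal to the TR.
#' @param mask 3D logical array; defaults to the brain mask.
#' @return object of class `lag_corr_map`: 4D `values` array
#'   `(x, y, z, lag)` of Pearson r (`NA` outside mask), `grid`, `kind`.
#' @export
voxelwise_xcorr <- function(bold, physio, grid, mask = NULL) {
  stopifnot(inherits(bold, "bold_volume"), inherits(physio, "physio_timecourse"),
            inherits(grid, "lag_grid"))
  if (physio$n_vols != bold$n_vols) stop("physio timecourse does not match BOLD volumes")
  if (abs(grid$step_s - bold$tr_s) > 1e-9)
    cfg_error("voxelwise lag grid step must equal the TR")
  if (is.null(mask)) mask <- bold$masks$brain
  mm <- mask_matrix(bold, mask)
  n <- bold$n_vols
  x <- physio$values
  out <- array(NA_real_, c(mm$sp, length(grid$lags_s)))
  det_mat <- function(M) {   # column-wise linear detrend
    t <- seq_len(nrow(M))
    Q <- qr(cbind(1, t))
    M - cbind(1, t) %*% qr.coef(Q, M)
  }
  for (j in seq_along(grid$lags_s)) {
    d <- round(grid$lags_s[j] / grid$step_s)
    if (abs(d) >= n - 2L || n - abs(d) < 30) next
    if (d >= 0) {
      xs <- x[1:(n - d)]; rows <- (1 + d):n
    } else {
      xs <- x[(1 - d):n]; rows <- 1:(n + d)
    }
    Ys <- det_mat(mm$Y[rows, , drop = FALSE])
    xs <- detrend_linear(xs)
    sx <- sqrt(sum(xs^2))
    sy <- sqrt(colSums(Ys^2))
    r <- as.numeric(crossprod(Ys, xs)) / (sx * sy)
    r[!is.finite(r)] <- NA_real_
    slab <- array(NA_real_, mm$sp)
    slab[mm$idx] <- r
    out[, , , j] <- slab
  }
  structure(list(values = out, grid = grid, kind = physio$kind),
            class = "lag_corr_map")
}

#' @export
print.lag_corr_map <- function(x, ...) {
  cat(sprintf("<lag_corr_map> %s vs BOLD: %s voxels x %d lags (%.1f to %.1f s)\n",
              x$kind, paste(dim(x$values)[1:3], collapse = "x"),
              length(x$grid$lags_s), min(x$grid$lags_s), max(x$grid$lags_s)))
  invisible(x)
}

#' Tissue-averaged lagged cross-correlation
#'
#' BOLD is averaged within each tissue mask; optionally both the averaged
#' BOLD series and the physiological series are linearly interpolated to a
#' finer step (e.g. 0.2 s) and the lag grid refined accordingly before
#' correlation.
#'
#' @param bold a [bold_volume()].
#' @param physio a [physio_timecourse()] on the volume grid.
#' @param grid a [lag_grid()] in TR steps.
#' @param masks named list of tissue masks; defaults to the volume's
#'   `gray`, `white`, `ventricles`.
#' @param upsample_dt_s optional target step (s) for upsampling.
#' @return object of class `tissue_xcorr`: matrix `r` (tissue x lag),
#'   `grid` (possibly refined), `kind`, `upsample_dt_s`. Empty masks are
#'   dropped with a warning.
#' @export
tissue_xcorr <- function(bold, physio, grid, masks = NULL, upsample_dt_s = NULL) {
  stopifnot(inherits(bold, "bold_volume"), inherits(physio, "physio_timecourse"),
            inherits(grid, "lag_grid"))
  if (is.null(masks))
    masks <- bold$masks[intersect(c("gray", "white", "ventricles"), names(bold$masks))]
  keep <- vapply(masks, function(m) sum(m) > 0, logical(1))
  if (!all(keep)) {
    warning(sprintf("dropping empty tissue mask(s): %s",
                    paste(names(masks)[!keep], collapse = ", ")))
    masks <- masks[keep]
  }
  if (!length(masks)) stop("no non-empty tissue masks")
  tv <- vol_times(bold$tr_s, bold$n_vols)
  x <- physio$values
  step <- bold$tr_s
  out_grid <- grid
  if (!is.null(upsample_dt_s)) {
    ratio <- bold$tr_s / upsample_dt_s
    if (abs(ratio - round(ratio)) > 1e-6)
      cfg_error("upsample_dt_s must divide the TR")
    tu <- seq(tv[1], tv[length(tv)], by = upsample_dt_s)
    x <- interp_to(tv, x, tu)
    step <- upsample_dt_s
    out_grid <- lag_grid(seq(min(grid$lags_s), max(grid$lags_s), by = upsample_dt_s),
                         upsample_dt_s)
  }
  r <- t(vapply(masks, function(m) {
    mm <- mask_matrix(bold, m)
    series <- rowMeans(mm$Y)
    if (!is.null(upsample_dt_s)) series <- interp_to(tv, series, seq(tv[1], tv[length(tv)], by = upsample_dt_s))
    suppressWarnings(xcorr_at_lags(x, series, step, out_grid))
  }, numeric(length(out_grid$lags_s))))
  rownames(r) <- names(masks)
  structure(list(r = r, grid = out_grid, kind = physio$kind,
                 upsample_dt_s = upsample_dt_s),
            class = "tissue_xcorr")
}

#' @export
print.tissue_xcorr <- function(x, ...) {
  cat(sprintf("<tissue_xcorr> %s vs BOLD: tissues %s, %d lags%s\n",
              x$kind, paste(rownames(x$r), collapse = "/"),
              ncol(x$r),
              if (is.null(x$upsample_dt_s)) ""
              else sprintf(", upsampled to %g s", x$upsample_dt_s)))
  invisible(x)
}

#' Write tissue cross-correlations as TSV
#'
#' @param xc a `tissue_xcorr`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tissue_xcorr <- function(xc, path) {
  stopifnot(inherits(xc, "tissue_xcorr"))
  df <- data.frame(tissue = rep(rownames(xc$r), each = ncol(xc$r)),
                   lag_s = rep(xc$grid$lags_s, times = nrow(xc$r)),
                   r = as.vector(t(xc$r)))
  utils::write.table(format(df, digits = 10, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
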