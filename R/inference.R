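# Group-level statistics: voxelwise two-sample t maps, post-minus-pre
# difference stacks, TFCE enhancement, label-shuffling permutation
# inference, lag-wise tissue tests and cohort summary tests.

# Stack coercion: accepts a 4D array (x, y, z, subject) or a list of 3D
# maps / pve_map objects; returns voxels-x-subjects matrix + geometry.
as_stack <- function(maps, mask = NULL) {
  if (is.list(maps) && !is.array(maps)) {
    maps <- lapply(maps, function(m) if (inherits(m, "pve_map")) m$values else m)
    arr <- array(unlist(maps), c(dim(maps[[1]]), length(maps)))
  } else arr <- maps
  stopifnot(length(dim(arr)) == 4L)
  sp <- dim(arr)[1:3]
  M <- matrix(arr, prod(sp), dim(arr)[4])
  if (is.null(mask)) mask <- rowSums(!is.finite(M)) == 0
  list(M = M[mask, , drop = FALSE], idx = which(mask), sp = sp)
}

# Vectorized per-voxel linear model t-statistic for one coefficient.
# M: voxels x subjects; X: subjects x p design; j: tested column.
lm_tvec <- function(M, X, j) {
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("design rank-deficient: a covariate is collinear with the group indicator")
  XtXinv <- chol2inv(qr.R(qx))
  B <- t(qr.coef(qx, t(M)))                       # voxels x p
  res <- M - B %*% t(X)
  dfree <- ncol(M) - ncol(X)
  s2 <- rowSums(res^2) / dfree
  se <- sqrt(s2 * XtXinv[j, j])
  t <- B[, j] / se
  t[se == 0] <- NA_real_
  list(t = t, df = dfree)
}

#' Voxelwise two-sample t map
#'
#' Pooled-variance two-sample t statistic (group A minus group B) at every
#' voxel, computed as the group-indicator coefficient test in a per-voxel
#' linear model; optional covariate columns are added to the model. The
#' pooled form keeps the statistic exchangeable under label permutation.
#'
#' @param maps_A,maps_B 4D arrays `(x, y, z, subject)` or lists of 3D maps
#'   (or [pve()] maps), at least 3 subjects per group, co-registered.
#' @param covariates optional numeric matrix (`nA + nB` rows, A first).
#' @return list with 3D `t` map (`NA` at voxels with zero residual
#'   variance or outside the common mask), `df`, and `n = c(nA, nB)`.
#' @export
two_sample_tmap <- function(maps_A, maps_B, covariates = NULL) {
  sa <- as_stack(maps_A)
  sb <- as_stack(maps_B)
  stopifnot(identical(sa$sp, sb$sp))
  nA <- ncol(sa$M); nB <- ncol(sb$M)
  if (nA < 3L || nB < 3L) cfg_error("need at least 3 subjects per group")
  idx <- intersect(sa$idx, sb$idx)
  M <- cbind(sa$M[match(idx, sa$idx), , drop = FALSE],
             sb$M[match(idx, sb$idx), , drop = FALSE])
  g <- c(rep(1, nA), rep(0, nB))
  X <- cbind(1, g)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  ft <- lm_tvec(M, X, 2L)
  list(t = unmask_map(ft$t, idx, sa$sp), df = ft$df, n = c(nA, nB))
}

#' Post-minus-pre difference maps
#'
#' Subject-matched post minus pre maps; group comparisons of intervention
#' effects operate on these difference stacks.
#'
#' @param pre,post 4D arrays or lists of 3D maps, one entry per subject.
#' @param ids optional subject identifiers; `pre` and `post` must contain
#'   the same ids (order in `post` may differ).
#' @return 4D array of per-subject post - pre maps, ordered as `pre`.
#' @export
paired_diff_maps <- function(pre, post, ids = NULL) {
  sp <- as_stack(pre, mask = TRUE)
  ss <- as_stack(post, mask = TRUE)
  stopifnot(identical(sp$sp, ss$sp))
  if (ncol(sp$M) != ncol(ss$M))
    stop("pre and post stacks have different numbers of subjects")
  ord <- seq_len(ncol(sp$M))
  if (!is.null(ids)) {
    stopifnot(length(ids$pre) == ncol(sp$M), length(ids$post) == ncol(ss$M))
    miss <- c(setdiff(ids$pre, ids$post), setdiff(ids$post, ids$pre))
    if (length(miss))
      stop(sprintf("unmatched subject id(s): %s", paste(unique(miss), collapse = ", ")))
    ord <- match(ids$pre, ids$post)
  }
  D <- ss$M[, ord, drop = FALSE] - sp$M
  array(D, c(sp$sp, ncol(D)))
}

#' Threshold-free cluster enhancement
#'
#' Integrates cluster extent and height over all thresholds:
#' \deqn{TFCE(v) = \sum_h e(h, v)^E h^H \, dh,}
#' where `e(h, v)` is the size of the supra-threshold connected component
#' containing voxel `v` at height `h` (26-connectivity by default,
#' midpoint-rule thresholds). Negative values are enhanced separately on
#' the sign-flipped map and returned with negative sign, so the output is
#' a signed enhanced map.
#'
#' @param stat_map 3D statistic map (`NA` allowed outside the mask).
#' @param E extent exponent.
#' @param H height exponent.
#' @param dh threshold step; default `max(|map|)/100`.
#' @param connectivity 6, 18 or 26.
#' @return 3D enhanced map, same shape; 0 where the input is `NA`.
#' @export
tfce_enhance <- function(stat_map, E = 0.5, H = 2.0, dh = NULL,
                         connectivity = 26) {
  stopifnot(length(dim(stat_map)) == 3L)
  if (!connectivity %in% c(6, 18, 26)) cfg_error("connectivity must be 6, 18 or 26")
  v <- stat_map
  v[is.na(v)] <- 0
  if (any(!is.finite(v))) stop("non-finite values inside mask")
  amax <- max(abs(v))
  if (amax == 0) return(array(0, dim(stat_map)))
  if (is.null(dh)) dh <- amax / 100
  if (dh <= 0) cfg_error("dh must be positive")
  dims <- as.integer(dim(stat_map))
  pos <- tfce_cpp(as.numeric(pmax(v, 0)), dims, E, H, dh, as.integer(connectivity))
  neg <- tfce_cpp(as.numeric(pmax(-v, 0)), dims, E, H, dh, as.integer(connectivity))
  array(pos - neg, dim(stat_map))
}

#' TFCE permutation test for a group difference
#'
#' The observed statistic is the TFCE-enhanced pooled two-sample t map.
#' The null distribution of the map-wise maximum is built by shuffling
#' group labels (group sizes preserved exactly); familywise-corrected
#' p-values are
#' \deqn{p(v) = \frac{1 + \#\{perm : \max_u TFCE_{perm}(u) \ge TFCE_{obs}(v)\}}{n_{perm} + 1}}
#' per direction (A > B and B > A).
#'
#' @param maps 4D array or list of 3D maps, all subjects.
#' @param group_labels vector with two levels; first level is group "A".
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed, recorded in the result.
#' @param covariates optional covariate matrix (subjects x q).
#' @param E,H,dh,connectivity TFCE parameters, see [tfce_enhance()].
#' @return object of class `group_stat`: `t_map`, `tfce_map` (signed),
#'   `p_corr_pos` (A > B), `p_corr_neg` (B > A), `n_perm`, `seed`,
#'   `null_max_pos`, `null_max_neg`.
#' @export
permutation_test <- function(maps, group_labels, n_perm = 500, seed = 1,
                             covariates = NULL, E = 0.5, H = 2.0, dh = NULL,
                             connectivity = 26) {
  if (n_perm < 100) cfg_error("n_perm must be at least 100")
  st <- as_stack(maps)
  labs <- as.factor(group_labels)
  stopifnot(nlevels(labs) == 2L, length(labs) == ncol(st$M))
  g_obs <- as.numeric(labs == levels(labs)[1])

  tvec_for <- function(g) {
    X <- cbind(1, g)
    if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
    t <- lm_tvec(st$M, X, 2L)$t
    t[!is.finite(t)] <- 0
    t
  }
  enh <- function(t) {
    m <- unmask_map(t, st$idx, st$sp)
    m[is.na(m)] <- 0
    tfce_enhance(m, E = E, H = H, dh = dh, connectivity = connectivity)
  }

  t_obs <- tvec_for(g_obs)
  tf_obs <- enh(t_obs)
  tf_vec <- tf_obs[st$idx]

  set.seed(seed)
  null_pos <- numeric(n_perm)
  null_neg <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    g <- sample(g_obs)
    stopifnot(sum(g) == sum(g_obs))   # group sizes preserved
    tf <- enh(tvec_for(g))
    null_pos[p] <- max(tf, 0)
    null_neg[p] <- max(-tf, 0)
  }
  p_of <- function(obs, null) {
    vapply(obs, function(o) (1 + sum(null >= o)) / (n_perm + 1), numeric(1))
  }
  p_pos <- unmask_map(p_of(pmax(tf_vec, 0), null_pos), st$idx, st$sp)
  p_neg <- unmask_map(p_of(pmax(-tf_vec, 0), null_neg), st$idx, st$sp)
  structure(list(t_map = unmask_map(t_obs, st$idx, st$sp),
                 tfce_map = tf_obs, p_corr_pos = p_pos, p_corr_neg = p_neg,
                 n_perm = n_perm, seed = seed,
                 null_max_pos = null_pos, null_max_neg = null_neg,
                 levels = levels(labs)),
            class = "group_stat")
}

#' @export
print.group_stat <- function(x, ...) {
  cat(sprintf("<group_stat> %s vs %s: %d permutations (seed %d)\n",
              x$levels[1], x$levels[2], x$n_perm, x$seed))
  cat(sprintf("  min corrected p: %s>%s %.4f, %s>%s %.4f\n",
              x$levels[1], x$levels[2], min(x$p_corr_pos, na.rm = TRUE),
              x$levels[2], x$levels[1], min(x$p_corr_neg, na.rm = TRUE)))
  invisible(x)
}

#' Lag-wise tissue cross-correlation tests
#'
#' A t test at every lag for every tissue between two stacks of
#' [tissue_xcorr()] results (two-sample, or paired for pre/post designs),
#' with Bonferroni correction over lags within each tissue. Significance
#' is reported both at the corrected threshold `alpha / n_lags` and at the
#' uncorrected `alpha`.
#'
#' @param xc_A,xc_B lists of `tissue_xcorr` objects on a common lag grid.
#' @param alpha familywise significance level.
#' @param paired if `TRUE`, subjects are matched across `xc_A`/`xc_B`.
#' @return object of class `tissue_group_test`: data frame with `tissue`,
#'   `lag_s`, `t`, `p`, `sig_corrected`, `sig_uncorrected`; and
#'   `bonferroni_alpha = alpha / n_lags`.
#' @export
lagwise_tissue_test <- function(xc_A, xc_B, alpha = 0.05, paired = FALSE) {
  grids <- lapply(c(xc_A, xc_B), function(x) x$grid$lags_s)
  if (!all(vapply(grids, function(g) isTRUE(all.equal(g, grids[[1]])), logical(1))))
    stop("tissue cross-correlation stacks are on different lag grids")
  tissues <- rownames(xc_A[[1]]$r)
  lags <- grids[[1]]
  thr <- alpha / length(lags)
  rows <- list()
  for (ti in tissues) {
    A <- t(vapply(xc_A, function(x) x$r[ti, ], numeric(length(lags))))
    B <- t(vapply(xc_B, function(x) x$r[ti, ], numeric(length(lags))))
    for (j in seq_along(lags)) {
      tt <- tryCatch(stats::t.test(A[, j], B[, j], paired = paired),
                     error = function(e) list(statistic = c(t = NA_real_),
                                              p.value = NaN))
      pj <- if (is.finite(tt$p.value)) tt$p.value else 1  # degenerate: no evidence
      rows[[length(rows) + 1L]] <- data.frame(
        tissue = ti, lag_s = lags[j],
        t = unname(tt$statistic), p = pj,
        sig_corrected = pj < thr,
        sig_uncorrected = pj < alpha)
    }
  }
  structure(list(table = do.call(rbind, rows), bonferroni_alpha = thr,
                 alpha = alpha, n_lags = length(lags), paired = paired),
            class = "tissue_group_test")
}

#' @export
print.tissue_group_test <- function(x, ...) {
  cat(sprintf("<tissue_group_test> %d lags, Bonferroni threshold %.6f%s\n",
              x$n_lags, x$bonferroni_alpha, if (x$paired) " (paired)" else ""))
  sig <- x$table[x$table$sig_corrected, c("tissue", "lag_s", "t", "p")]
  if (nrow(sig)) {
    cat("  significant after correction:\n")
    print(sig, row.names = FALSE)
  } else cat("  no lag significant after correction\n")
  invisible(x)
}

#' Cohort summary-metric tests
#'
#' Between-group (Welch two-sample) and optional within-group pre/post
#' (paired) t tests on HRV summary metrics. RMSSD, LF and HF enter on
#' their natural-log scale; average HR, CO2, breathing rate and SD RV stay
#' raw. Apply [iqr_screen()] per metric beforehand; metrics with fewer
#' than 4 valid values in a group are skipped with a note.
#'
#' @param hrv data frame with one row per subject (ln-scale HRV columns
#'   `ln_rmssd`, `ln_lf`, `ln_hf` and raw `avg_hr_bpm`, `sd_rv`,
#'   `breathing_rate_bpm`, `avg_co2_mmHg` as available), plus a grouping
#'   column.
#' @param group name of the grouping column (two levels).
#' @param metrics metric columns to test; defaults to all recognised ones
#'   present.
#' @return data frame with `metric`, group means/variances, `t`, `df`,
#'   `p`, and `skipped` flags.
#' @export
cohort_summary_tests <- function(hrv, group = "age_group", metrics = NULL) {
  known <- c("ln_rmssd", "ln_lf", "ln_hf", "avg_hr_bpm", "sd_rv",
             "breathing_rate_bpm", "avg_co2_mmHg")
  if (is.null(metrics)) metrics <- intersect(known, names(hrv))
  g <- as.factor(hrv[[group]])
  stopifnot(nlevels(g) == 2L)
  lv <- levels(g)
  rows <- lapply(metrics, function(m) {
    a <- hrv[[m]][g == lv[1]]; b <- hrv[[m]][g == lv[2]]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 4L || length(b) < 4L) {
      message(sprintf("metric '%s' skipped: fewer than 4 valid values in a group", m))
      return(data.frame(metric = m, mean_A = NA, var_A = NA, mean_B = NA,
                        var_B = NA, t = NA, df = NA, p = NA, skipped = TRUE))
    }
    tt <- stats::t.test(a, b)
    data.frame(metric = m, mean_A = mean(a), var_A = stats::var(a),
               mean_B = mean(b), var_B = stats::var(b),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, skipped = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- lv
  out
}
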