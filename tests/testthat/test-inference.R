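# Group inference: t maps, difference stacks, TFCE, permutations,
# lag-wise tissue tests, cohort summary tests.

rand_stack <- function(n, sp = c(4, 4, 3), mean = 0, sd = 1, seed = 1) {
  set.seed(seed)
  array(rnorm(prod(sp) * n, mean, sd), c(sp, n))
}

test_that("two-sample t maps match a closed-form pooled oracle", {
  sp <- c(1, 1, 1)
  A <- array(c(1, 2, 3), c(sp, 3))
  B <- array(c(4, 5, 6), c(sp, 3))
  res <- two_sample_tmap(A, B)
  # pooled: means 2 and 5, s_p^2 = 1, t = -3 / sqrt(2/3)
  expect_equal(res$t[1, 1, 1], -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$df, 4)

  # identical groups give t = 0
  S <- rand_stack(5, seed = 3)
  res0 <- two_sample_tmap(S, S)
  expect_true(all(abs(res0$t) < 1e-10, na.rm = TRUE))
})

test_that("covariates enter the voxelwise model and collinearity is an error", {
  A <- rand_stack(6, seed = 4); B <- rand_stack(6, seed = 5, mean = 1)
  cov_ok <- matrix(rnorm(12), 12, 1)
  res <- two_sample_tmap(A, B, covariates = cov_ok)
  expect_true(all(is.finite(res$t)))
  g <- c(rep(1, 6), rep(0, 6))
  expect_error(two_sample_tmap(A, B, covariates = cbind(2 * g + 1)),
               "collinear")
})

test_that("paired difference maps are exact and validate subject matching", {
  pre <- rand_stack(4, seed = 6)
  post <- pre + 2
  D <- paired_diff_maps(pre, post)
  expect_equal(as.numeric(D), rep(2, length(D)))
  D0 <- paired_diff_maps(pre, pre)
  expect_equal(max(abs(D0)), 0)
  expect_error(paired_diff_maps(pre, post,
                                ids = list(pre = c("a", "b", "c", "d"),
                                           post = c("a", "b", "c", "e"))),
               "unmatched subject id")
})

test_that("TFCE matches the single-voxel closed form and handles signs", {
  z <- array(0, c(5, 5, 5))
  expect_equal(tfce_enhance(z), z)

  m <- z; m[3, 3, 3] <- 3
  # integral of h^2 dh from 0 to 3 = 9 for an isolated voxel (E=.5, H=2)
  expect_equal(tfce_enhance(m, dh = 3 / 2000)[3, 3, 3], 9, tolerance = 1e-3)

  # negative tail enhanced separately with sign preserved
  expect_equal(tfce_enhance(-m, dh = 3 / 2000)[3, 3, 3], -9, tolerance = 1e-3)

  expect_error(tfce_enhance(array(Inf, c(2, 2, 2))), "non-finite")
})

test_that("TFCE agrees with a fine-step brute-force oracle on random maps", {
  set.seed(9)
  m <- array(pmax(rnorm(8^3), 0), c(8, 8, 8))
  dh <- max(m) / 1000
  fast <- tfce_enhance(m, dh = dh)
  # brute force: explicit connected components at each threshold
  oracle <- array(0, dim(m))
  nbr <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nbr <- nbr[rowSums(abs(nbr)) > 0, ]
  label_components <- function(mask) {
    lab <- array(0L, dim(mask)); cur <- 0L
    idx <- which(mask, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      v <- idx[r, ]
      if (lab[v[1], v[2], v[3]] > 0) next
      cur <- cur + 1L
      queue <- list(v)
      lab[v[1], v[2], v[3]] <- cur
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (k in seq_len(nrow(nbr))) {
          q <- p + nbr[k, ]
          if (any(q < 1) || any(q > dim(mask))) next
          if (mask[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0L) {
            lab[q[1], q[2], q[3]] <- cur
            queue[[length(queue) + 1L]] <- q
          }
        }
      }
    }
    lab
  }
  for (s in seq_len(1000)) {
    h <- (s - 0.5) * dh
    mask <- m >= h
    if (!any(mask)) break
    lab <- label_components(mask)
    sizes <- tabulate(lab[mask])
    oracle[mask] <- oracle[mask] + sizes[lab[mask]]^0.5 * h^2 * dh
  }
  i_max <- which.max(m)
  expect_lt(abs(fast[i_max] - oracle[i_max]) / oracle[i_max], 0.01)
  expect_lt(max(abs(fast - oracle)) / max(oracle), 0.02)
})

test_that("TFCE is monotone under pointwise increases of the statistic map", {
  set.seed(10)
  for (i in 1:100) {
    m1 <- array(pmax(rnorm(6^3), 0), c(6, 6, 6))
    m2 <- m1 + array(runif(6^3, 0, 0.5), c(6, 6, 6))
    dh <- max(m2) / 50
    expect_true(all(tfce_enhance(m2, dh = dh) >= tfce_enhance(m1, dh = dh) - 1e-9))
  }
})

test_that("permutation p-values follow the permutation definition", {
  # gigantic group effect: observed TFCE beats every permutation
  A <- rand_stack(6, sp = c(3, 3, 2), mean = 50, sd = 0.5, seed = 11)
  B <- rand_stack(6, sp = c(3, 3, 2), mean = 0, sd = 0.5, seed = 12)
  maps <- array(c(A, B), c(3, 3, 2, 12))
  gs <- permutation_test(maps, factor(rep(c("A", "B"), each = 6),
                                      levels = c("A", "B")),
                         n_perm = 100, seed = 2)
  expect_equal(min(gs$p_corr_pos, na.rm = TRUE), 1 / 101, tolerance = 1e-12)
  expect_true(all(gs$p_corr_pos >= 1 / 101 & gs$p_corr_pos <= 1, na.rm = TRUE))
  expect_equal(gs$n_perm, 100)
  expect_error(permutation_test(maps, rep(c("A", "B"), each = 6), n_perm = 10),
               "at least 100")
})

test_that("lag-wise tissue tests apply Bonferroni over lags", {
  g <- lag_grid(seq(0, 17) * 1.4, 1.4)   # 18 lags
  mk <- function(offset, seed) {
    set.seed(seed)
    r <- matrix(rnorm(2 * 18, sd = 0.1), 2, 18,
                dimnames = list(c("gray", "white"), NULL))
    r[1, 5] <- r[1, 5] + offset
    structure(list(r = r, grid = g, kind = "hr_bpm", upsample_dt_s = NULL),
              class = "tissue_xcorr")
  }
  A <- lapply(1:20, function(i) mk(0.3, i))
  B <- lapply(1:20, function(i) mk(0.0, 100 + i))
  res <- lagwise_tissue_test(A, B)
  expect_equal(res$bonferroni_alpha, 0.05 / 18, tolerance = 1e-12)
  expect_equal(res$bonferroni_alpha, 0.002778, tolerance = 1e-3)
  tab <- res$table
  hit <- tab[tab$tissue == "gray" & tab$lag_s == g$lags_s[5], ]
  expect_true(hit$sig_corrected)

  # identical stacks: nothing significant (paired differences all zero)
  res0 <- lagwise_tissue_test(A, A, paired = TRUE)
  expect_false(any(res0$table$sig_uncorrected))

  # mismatched lag grids are a hard error
  g2 <- lag_grid(seq(0, 17) * 2.4, 2.4)
  C <- lapply(A, function(x) { x$grid <- g2; x })
  expect_error(lagwise_tissue_test(A, C), "different lag grids")
})

test_that("cohort summary tests match t.test and handle degenerate inputs", {
  df <- data.frame(age_group = rep(c("young", "old"), each = 4),
                   ln_rmssd = c(1, 2, 3, 4, 2, 3, 4, 5),
                   avg_hr_bpm = c(70, 71, 69, 70, 70, 71, 69, 70))
  res <- cohort_summary_tests(df)
  oracle <- t.test(c(2, 3, 4, 5), c(1, 2, 3, 4))  # levels: old first
  expect_equal(res$t[res$metric == "ln_rmssd"], unname(oracle$statistic),
               tolerance = 1e-12)
  expect_equal(abs(res$t[res$metric == "avg_hr_bpm"]), 0, tolerance = 1e-12)

  df$ln_lf <- c(NA, NA, NA, NA, 1, 2, 3, 4)
  expect_message(res2 <- cohort_summary_tests(df), "skipped")
  expect_true(res2$skipped[res2$metric == "ln_lf"])
})
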