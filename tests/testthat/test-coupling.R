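# Voxelwise GLM fitting and percent-variance-explained maps.

make_toy_bold <- function(X, betas, noise_sd = 0, sp = NULL, seed = 1) {
  n <- nrow(X); V <- ncol(betas)
  if (is.null(sp)) sp <- c(V, 1, 1)
  set.seed(seed)
  Y <- X %*% betas + matrix(rnorm(n * V, sd = noise_sd), n, V)
  arr <- aperm(array(Y, c(n, sp)), c(2, 3, 4, 1))
  bold_volume(arr, 1.4, list(brain = array(TRUE, sp)))
}

test_that("OLS reproduces exact representations and a normal-equations oracle", {
  sc <- sim_scenario(n_vols = 64, seed = 4)
  tc <- quick_timecourses(sc)
  rs <- build_regressors(tc, "joint")
  k <- ncol(rs$X)

  # voxel equal to one design column: that beta 1, others 0, residual 0
  B <- matrix(0, k, 1); B[2, 1] <- 1
  bold <- make_toy_bold(rs$X, B)
  fit <- fit_voxelwise(bold, rs)
  expect_equal(as.numeric(coef(fit)), as.numeric(B), tolerance = 1e-10)
  expect_lt(max(abs(residuals(fit))), 1e-10)

  # noise orthogonalized against the design has zero betas
  set.seed(9)
  e <- rnorm(sc$n_vols)
  e <- e - rs$X %*% qr.coef(qr(rs$X), e)
  bold <- make_toy_bold(rs$X, matrix(0, k, 1))
  bold$data[1, 1, 1, ] <- e
  fit <- fit_voxelwise(bold, rs)
  expect_lt(max(abs(coef(fit))), 1e-10)

  # 10-voxel toy volume vs naive normal equations
  set.seed(10)
  B <- matrix(rnorm(k * 10), k, 10)
  bold <- make_toy_bold(rs$X, B, noise_sd = 0.5, sp = c(5, 2, 1))
  fit <- fit_voxelwise(bold, rs)
  mmY <- matrix(aperm(bold$data, c(4, 1, 2, 3)), nrow = sc$n_vols)
  oracle <- solve(t(rs$X) %*% rs$X) %*% t(rs$X) %*% mmY
  expect_lt(max(abs(coef(fit) - oracle)), 1e-8)
})

test_that("rank-deficient designs are rejected with the offending column named", {
  sc <- sim_scenario(n_vols = 64, seed = 4)
  tc <- quick_timecourses(sc)
  rs <- build_regressors(tc, "joint")
  rs$X <- cbind(rs$X, dup = rs$X[, 1])
  rs$labels <- c(rs$labels, "dup")
  bold <- make_toy_bold(rs$X[, -ncol(rs$X)], matrix(0, ncol(rs$X) - 1, 1))
  expect_error(fit_voxelwise(bold, rs), "collinear")
})

test_that("PVE is exact in the noiseless limit and near null for pure noise", {
  sc <- sim_scenario(n_vols = 404, tr_s = 1.4, grid_shape = c(4, 4, 2),
                     noise = list(ar1_coef = 0, sigma = 0), seed = 6)
  tc <- quick_timecourses(sc)
  sim <- simulate_bold(sc, tc, "s", "young", true_pve = 0.5)
  maps <- run_three_models(sim$bold, tc)
  expect_true(all(maps$joint$values >= 0.99))

  # pure noise: mean PVE ~ k_phys/(n-1), below 0.02
  scn <- sim_scenario(n_vols = 404, grid_shape = c(5, 5, 4),
                      noise = list(ar1_coef = 0, sigma = 1), seed = 6)
  simn <- simulate_bold(scn, tc, "s", "young", true_pve = 0)
  rs <- build_regressors(tc, "joint")
  pm <- pve(simn$bold, rs)
  expect_lt(mean(pm$values), 0.02)
  expect_gt(mean(pm$values), 0)   # null R^2 inflation is positive
})

test_that("PVE is invariant to affine rescaling of the voxel series", {
  sc <- sim_scenario(n_vols = 64, grid_shape = c(3, 3, 2), seed = 8)
  tc <- quick_timecourses(sc)
  sim <- simulate_bold(sc, tc, "s", "young")
  rs <- build_regressors(tc, "joint")
  p1 <- pve(sim$bold, rs)
  sim$bold$data <- sim$bold$data * 3.7 + 42
  p2 <- pve(sim$bold, rs)
  expect_equal(p1$values, p2$values, tolerance = 1e-9)
})

test_that("nested-model monotonicity holds at every voxel", {
  sc <- sim_scenario(n_vols = 96, grid_shape = c(4, 4, 3), seed = 12)
  tc <- quick_timecourses(sc)
  sim <- simulate_bold(sc, tc, "s", "young")
  maps <- run_three_models(sim$bold, tc)
  expect_named(maps, c("joint", "cardiac", "respiratory"))
  expect_true(all(maps$joint$values >=
                  pmax(maps$cardiac$values, maps$respiratory$values) - 1e-12))
  expect_true(all(maps$joint$values >= 0 & maps$joint$values <= 1))
})

test_that("cardiac-only coupling is recovered by the right single model", {
  sc <- sim_scenario(n_vols = 404, grid_shape = c(4, 4, 2), seed = 14)
  tc <- quick_timecourses(sc)
  tc_cardiac_only <- list(hr = tc$hr)        # respiratory betas zero
  sim <- simulate_bold(sc, tc_cardiac_only, "s", "young", true_pve = 0.4)
  maps <- run_three_models(sim$bold, tc)
  expect_equal(mean(maps$cardiac$values), mean(maps$joint$values),
               tolerance = 0.05)
  expect_lt(mean(maps$respiratory$values), 0.05)
  expect_gt(mean(maps$cardiac$values), 0.3)
})

test_that("uncorrelated drivers make single-model PVEs approximately additive", {
  n <- 404; tr <- 1.4
  set.seed(33)
  tc <- list(hr = physio_timecourse(rnorm(n), tr, "hr_bpm"),
             rv = physio_timecourse(rnorm(n), tr, "rv_norm"))
  rs <- build_regressors(tc, "joint")
  Xp <- rs$X[, rs$phys_idx]
  y <- Xp %*% c(1, 0.3, 0.3, 1, 0.3, 0.3) + rnorm(n, sd = 3)
  arr <- array(y, c(1, 1, 1, n))
  bold <- bold_volume(arr, tr, list(brain = array(TRUE, c(1, 1, 1))))
  maps <- run_three_models(bold, tc)
  expect_lt(abs(maps$cardiac$values[1] + maps$respiratory$values[1] -
                  maps$joint$values[1]), 0.05)
})

test_that("missing physiological inputs skip the affected model with a warning", {
  sc <- sim_scenario(n_vols = 64, grid_shape = c(3, 3, 2), seed = 15)
  tc <- quick_timecourses(sc)
  sim <- simulate_bold(sc, tc, "s", "young")
  w <- capture_warnings(maps <- run_three_models(sim$bold, list(hr = tc$hr)))
  expect_true(any(grepl("skipping joint", w)))
  expect_true(any(grepl("skipping respiratory", w)))
  expect_named(maps, "cardiac")
})

test_that("coupling_fit methods are coherent", {
  sc <- sim_scenario(n_vols = 64, grid_shape = c(3, 3, 2), seed = 16)
  tc <- quick_timecourses(sc)
  sim <- simulate_bold(sc, tc, "s", "young")
  rs <- build_regressors(tc, "joint")
  fit <- fit_voxelwise(sim$bold, rs)
  expect_s3_class(fit, "coupling_fit")
  expect_equal(dim(coef(fit)), c(ncol(rs$X), 18))
  expect_equal(fitted(fit) + residuals(fit), fit$Y, tolerance = 1e-9)
  s <- summary(fit)
  expect_output(print(s), "Voxelwise physiological GLM")
  expect_true(all(s$pve_summary >= 0 & s$pve_summary <= 1))
})
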