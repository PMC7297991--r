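null_design <- function(n = 12) {
  tibble::tibble(scan_id = sprintf("J%02d_T1", 1:n),
                 subject_id = sprintf("J%02d", 1:n),
                 sex = rep(c("F", "M"), each = n / 2),
                 gest_week = rep(seq(19, 36, length.out = n / 2), 2))
}

test_that("gaussian smoothing preserves constants and total mass", {
  v <- volume_map(array(3.7, c(12, 12, 12)), voxel_size = 2)
  sm <- smooth_volume(v, fwhm_mm = 4)
  expect_lt(max(abs(sm$values - 3.7)), 1e-10)

  set.seed(4)
  v2 <- volume_map(array(runif(12^3), c(12, 12, 12)), voxel_size = 2)
  sm2 <- smooth_volume(v2, fwhm_mm = 6)
  expect_equal(sum(sm2$values), sum(v2$values), tolerance = 1e-6)
  expect_error(smooth_volume(v2, -1), "non-negative")
})

test_that("the impulse response is a discrete gaussian at sigma = fwhm/2.355", {
  n <- 21
  a <- array(0, c(n, n, n)); a[11, 11, 11] <- 1
  sm <- smooth_volume(volume_map(a, voxel_size = 1), fwhm_mm = 4)
  sigma <- 4 / (2 * sqrt(2 * log(2)))
  prof <- sm$values[, 11, 11]
  # log-ratio of successive samples of exp(-x^2/2s^2): (2k-1)/(2s^2)
  for (k in c(1, 2, 3)) {
    lr <- log(prof[11] / prof[11 + k])
    expect_equal(lr, k^2 / (2 * sigma^2), tolerance = 0.02)
  }
  expect_equal(sum(sm$values), 1, tolerance = 1e-10)
})

test_that("jacobian phantoms honour identity and uniform-scale configurations", {
  d <- null_design(4)
  d$icv <- rep(1, 4)
  maps <- generate_jacobian_maps(d, list(grid = 12L, noise_sd = 0, global_scale_sd = 0), seed = 1)
  expect_equal(length(maps), 4)
  for (m in maps) expect_lt(max(abs(m$values[m$mask] - 1)), 1e-12)

  d$icv <- c(1, 1, 1, 1.1^3)
  maps2 <- generate_jacobian_maps(d, list(grid = 12L, noise_sd = 0, global_scale_sd = 0), seed = 1)
  expect_equal(unique(as.vector(maps2[[4]]$values)), 1.331, tolerance = 1e-12)
  expect_error(
    generate_jacobian_maps(d, list(grid = 12L,
                                   focal = list(list(centre = c(50, 1, 1),
                                                     radius_mm = 2,
                                                     log_offset_F = 0.1,
                                                     log_offset_M = 0))),
                           seed = 1),
    "outside grid")
})

test_that("finite-difference jacobian matches the analytic determinant", {
  # polynomial mapping phi(x) = (x + a x^2 / 2, y + b y^2 / 2, z + c z^2 / 2):
  # J = diag(1 + a x, 1 + b y, 1 + c z), det = product
  n <- 16
  ax <- seq(0, 1.5, length.out = n)
  g <- expand.grid(x = ax, y = ax, z = ax)
  a <- 0.08; b <- -0.05; cc <- 0.03
  phi_x <- array(g$x + a * g$x^2 / 2, c(n, n, n))
  phi_y <- array(g$y + b * g$y^2 / 2, c(n, n, n))
  phi_z <- array(g$z + cc * g$z^2 / 2, c(n, n, n))
  h <- ax[2] - ax[1]
  fd <- jacobian_fd(phi_x, phi_y, phi_z, voxel_size = h)
  analytic <- array((1 + a * g$x) * (1 + b * g$y) * (1 + cc * g$z), c(n, n, n))
  interior <- 2:(n - 1)
  expect_lt(max(abs(fd[interior, interior, interior] -
                      analytic[interior, interior, interior])), 1e-3)
})

test_that("voxelwise OLS matches a scalar per-voxel oracle", {
  d <- null_design(14)
  maps <- generate_jacobian_maps(d, list(grid = 8L, mask_radius_frac = 0.45,
                                         noise_sd = 0.05), seed = 5)
  fit <- voxelwise_fit(maps, d, fwhm_mm = 0, degree = 2)
  # oracle: lm() looped over in-mask voxels
  mask <- maps[[1]]$mask
  Y <- do.call(rbind, lapply(maps, function(m) log(m$values[mask])))
  b <- build_poly_basis(d$gest_week, 2)
  wb <- eval_basis(b, d$gest_week)
  male <- as.numeric(d$sex == "M")
  gbar <- vapply(maps, function(m) mean(m$values[mask]), numeric(1))
  t_or <- vapply(seq_len(ncol(Y)), function(v) {
    df <- data.frame(y = Y[, v], male = male, w1 = wb[, 1], w2 = wb[, 2],
                     lg = log(gbar))
    summary(lm(y ~ male + w1 + w2 + male:w1 + lg, data = df))$coefficients["male", "t value"]
  }, numeric(1))
  expect_equal(unname(fit$t_sex$values[mask]), unname(t_or), tolerance = 1e-8)
})

test_that("identical maps give zero effect and zero T everywhere", {
  d <- null_design(8)
  one <- generate_jacobian_maps(d[1, ], list(grid = 8L, noise_sd = 0.03),
                                seed = 2)[[1]]
  maps <- setNames(rep(list(one), 8), d$scan_id)
  fit <- voxelwise_fit(maps, d, fwhm_mm = 0, degree = 2)
  expect_true(all(fit$t_sex$values == 0))
  expect_lt(max(abs(fit$effect_sex$values[fit$mask])), 1e-10)
  expect_gt(fit$n_zero_variance, 0)
})

test_that("a female-larger focal sphere yields a negative male-effect cluster", {
  d <- null_design(20)
  fs <- list(grid = 16L, noise_sd = 0.01,
             focal = list(list(centre = c(8, 8, 8), radius_mm = 4,
                               log_offset_F = 0.25, log_offset_M = 0)))
  maps <- generate_jacobian_maps(d, fs, seed = 6)
  fit <- voxelwise_fit(maps, d, fwhm_mm = 0, degree = 2)
  expect_lt(fit$effect_sex$values[8, 8, 8], -0.15)
  expect_lt(fit$t_sex$values[8, 8, 8], -2)
})

test_that("maxT permutation is deterministic, conservative and mask-restricted", {
  d <- null_design(16)
  fs <- list(grid = 10L, noise_sd = 0.05,
             focal = list(list(centre = c(5, 5, 5), radius_mm = 3,
                               log_offset_F = 0, log_offset_M = 0.6)))
  maps <- generate_jacobian_maps(d, fs, seed = 7)
  fit <- voxelwise_fit(maps, d, fwhm_mm = 0, degree = 2)
  r1 <- maxt_permutation(fit, n_perm = 60, seed = 9)
  r2 <- maxt_permutation(fit, n_perm = 60, seed = 9)
  expect_identical(r1$threshold_sex, r2$threshold_sex)
  expect_identical(r1$sig_sex, r2$sig_sex)
  # maxT threshold dominates the uncorrected two-sided t quantile
  expect_gte(r1$threshold_sex, qt(0.975, fit$df))
  expect_true(all(!(r1$sig_sex & !fit$mask)))
  expect_true(all(abs(fit$t_sex$values[r1$sig_sex]) >= r1$threshold_sex))
  # thresholds non-increasing in alpha
  r3 <- maxt_permutation(fit, n_perm = 60, seed = 9, alpha = 0.2)
  expect_lte(r3$threshold_sex, r1$threshold_sex)
  expect_error(maxt_permutation(fit, n_perm = 10, seed = 1), ">= 20")
})

test_that("a strong focal effect is localised (dice overlap with the truth)", {
  d <- null_design(20)
  centre <- c(8, 8, 8); radius <- 4
  fs <- list(grid = 16L, noise_sd = 0.02,
             focal = list(list(centre = centre, radius_mm = radius,
                               log_offset_F = 0, log_offset_M = 0.5)))
  maps <- generate_jacobian_maps(d, fs, seed = 8)
  fit <- voxelwise_fit(maps, d, fwhm_mm = 0, degree = 2)
  res <- maxt_permutation(fit, n_perm = 99, seed = 10)
  ax <- seq_len(16)
  d2 <- outer(outer((ax - centre[1])^2, (ax - centre[2])^2, "+"),
              (ax - centre[3])^2, "+")
  truth <- d2 <= radius^2 & fit$mask
  dice <- 2 * sum(res$sig_sex & truth) / (sum(res$sig_sex) + sum(truth))
  expect_gt(dice, 0.5)
})

test_that("volumes round-trip through NIfTI with voxel size", {
  v <- volume_map(array(rnorm(6 * 5 * 4), c(6, 5, 4)), voxel_size = c(2, 2, 3))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume_nifti(v, path)
  back <- read_volume_nifti(path)
  expect_equal(back$values, v$values, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$voxel_size, v$voxel_size)
})
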