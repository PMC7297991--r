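# Voxelwise tensor-based morphometry of Jacobian-determinant maps:
# Gaussian smoothing, per-voxel OLS of log|J| on sex, age polynomial and
# the log mean Jacobian, and maxT permutation FWER control with
# subject-level label exchange.

#' 3D scalar volume container
#'
#' @param values 3D numeric array (e.g. Jacobian determinants `|J(x)|`).
#' @param voxel_size Voxel spacing in mm, length 1 or 3.
#' @param mask Logical/0-1 array of the same dimensions (analysis region);
#'   defaults to everything.
#' @return A `volume_map` object.
#' @export
volume_map <- function(values, voxel_size = 1, mask = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  if (any(voxel_size <= 0)) stop("voxel_size must be positive.", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, dim(values))
  if (!identical(dim(mask), dim(values))) {
    stop("mask and values dimensions differ.", call. = FALSE)
  }
  structure(list(values = values, voxel_size = as.numeric(voxel_size),
                 mask = array(as.logical(mask), dim(values))),
            class = "volume_map")
}

#' @export
print.volume_map <- function(x, ...) {
  cat("<volume_map>", paste(dim(x$values), collapse = "x"), "voxels,",
      paste(x$voxel_size, collapse = "x"), "mm,",
      sum(x$mask), "in mask\n")
  invisible(x)
}

#' Read/write a volume as NIfTI
#'
#' Voxel size is carried in the NIfTI header. The mask is not stored;
#' supply or rebuild it on read.
#'
#' @param vol A [volume_map()].
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param mask Optional mask array for the volume read back.
#' @export
write_volume_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "volume_map"))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path, mask = NULL) {
  img <- RNifti::readNifti(path)
  volume_map(array(as.numeric(img), dim(img)[1:3]),
             voxel_size = RNifti::pixdim(img)[1:3], mask = mask)
}

# 1D Gaussian kernel, sigma in voxels, truncated at 4 sigma, normalised.
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Symmetric (edge-repeating) reflection of out-of-range indices; valid for
# kernel radii larger than the grid.
reflect_index <- function(i, n) {
  j <- (i - 1) %% (2 * n)
  ifelse(j >= n, 2 * n - 1 - j, j) + 1
}

# Separable convolution along one array dimension with reflect padding.
convolve_dim <- function(a, k, dim_idx) {
  if (length(k) == 1) return(a)
  r <- (length(k) - 1) / 2
  n <- dim(a)[dim_idx]
  idx <- reflect_index(seq(1 - r, n + r), n)
  perm <- c(dim_idx, setdiff(1:3, dim_idx))
  ap <- aperm(a, perm)
  d <- dim(ap)
  m <- matrix(ap, nrow = d[1])
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, nrow = d[1], ncol = ncol(m))
  for (j in seq_along(k)) {
    out <- out + k[j] * mp[(j - 1) + seq_len(d[1]), , drop = FALSE]
  }
  aperm(array(out, d), order(perm))
}

#' Gaussian-smooth a volume
#'
#' Smooths with per-axis sigma `fwhm / sqrt(8 log 2)` in mm (the standard
#' FWHM-to-sigma conversion), using a normalised kernel (a constant map is
#' unchanged) and reflect padding at the boundary (the map's total sum is
#' conserved).
#'
#' @param vol A [volume_map()].
#' @param fwhm_mm Full width at half maximum in mm (default 4).
#' @return Smoothed `volume_map` (same mask).
#' @export
smooth_volume <- function(vol, fwhm_mm = 4) {
  stopifnot(inherits(vol, "volume_map"))
  if (fwhm_mm < 0) stop("fwhm must be non-negative.", call. = FALSE)
  if (fwhm_mm == 0) return(vol)
  sigma_mm <- fwhm_mm / sqrt(8 * log(2))
  a <- vol$values
  for (d in 1:3) {
    a <- convolve_dim(a, gauss_kernel(sigma_mm / vol$voxel_size[d]), d)
  }
  volume_map(a, vol$voxel_size, vol$mask)
}

#' Generate synthetic Jacobian-determinant phantom maps
#'
#' Produces one analytic `|J|` map per scan:
#' `|J(x)| = scale^3 * exp(sum of focal log-offsets at x) * exp(noise)`,
#' where `scale` is a per-scan global linear scale (tied to the scan's ICV
#' when supplied, else to a gestational-age growth curve), focal effects
#' are smooth spherical blobs with sex-specific log-volume offsets, and the
#' noise field is Gaussian, smoothed to the requested correlation length.
#' The mask is a central spherical "intracranial" region.
#'
#' @param design Tibble with scan_id, subject_id, sex, gest_week and
#'   optionally icv.
#' @param field_spec List: `grid` (edge length, default 32), `voxel_mm`
#'   (default 1), `mask_radius_frac` (default 0.42), `noise_sd` (log units,
#'   default 0.05), `noise_corr_mm` (default 3), `global_scale_sd`
#'   (per-scan log-volume jitter of the global scale, default 0.05,
#'   emulating between-subject head-size variability — without it the mean
#'   Jacobian covariate would be collinear with any focal sex effect),
#'   `focal` — list of focal regions, each `list(centre (voxel coords),
#'   radius_mm, log_offset_F, log_offset_M)`.
#' @param seed Integer seed.
#' @return Named list of [volume_map()]s, one per scan (names = scan_id).
#' @export
generate_jacobian_maps <- function(design, field_spec = list(), seed) {
  fs <- list(grid = 32L, voxel_mm = 1, mask_radius_frac = 0.42,
             noise_sd = 0.05, noise_corr_mm = 3, global_scale_sd = 0.05,
             focal = list())
  fs[names(field_spec)] <- field_spec
  n <- fs$grid
  centre <- (n + 1) / 2
  ax <- seq_len(n)
  dist2 <- outer(outer((ax - centre)^2, (ax - centre)^2, "+"),
                 (ax - centre)^2, "+")
  mask <- dist2 <= (fs$mask_radius_frac * n)^2
  for (f in fs$focal) {
    if (any(f$centre < 1 | f$centre > n)) {
      stop("focal region centre outside grid.", call. = FALSE)
    }
  }
  focal_field <- function(sex) {
    fld <- array(0, dim = c(n, n, n))
    for (f in fs$focal) {
      off <- if (sex == "M") f$log_offset_M else f$log_offset_F
      if (off == 0) next
      r_vox <- f$radius_mm / fs$voxel_mm
      d2 <- outer(outer((ax - f$centre[1])^2, (ax - f$centre[2])^2, "+"),
                  (ax - f$centre[3])^2, "+")
      fld <- fld + off * exp(-d2 / (2 * (r_vox / 2)^2))
    }
    fld
  }
  ff <- list(F = focal_field("F"), M = focal_field("M"))

  if ("icv" %in% names(design)) {
    scale3 <- design$icv / median(design$icv)
  } else {
    # volume doubling roughly every 5 weeks mid-gestation
    scale3 <- exp(0.14 * (design$gest_week - 27))
  }

  with_seed(seed, {
    scale3 <- scale3 * exp(rnorm(nrow(design), 0, fs$global_scale_sd))
    maps <- purrr::map(seq_len(nrow(design)), function(i) {
      noise <- array(rnorm(n^3), dim = c(n, n, n))
      if (fs$noise_sd > 0 && fs$noise_corr_mm > 0) {
        sm <- smooth_volume(volume_map(noise, fs$voxel_mm),
                            fwhm_mm = fs$noise_corr_mm * 2.355)
        noise <- sm$values
        s <- sd(noise)
        noise <- if (s > 0) noise / s * fs$noise_sd else noise * 0
      } else {
        noise <- noise * fs$noise_sd
      }
      vals <- scale3[i] * exp(ff[[as.character(design$sex[i])]] + noise)
      volume_map(vals, fs$voxel_mm, mask)
    })
    setNames(maps, design$scan_id)
  })
}

#' Finite-difference Jacobian determinant of a sampled mapping
#'
#' Given the three coordinate components of a spatial mapping sampled on a
#' regular grid, computes the determinant of the central-difference
#' Jacobian at interior voxels (one-sided at the boundary). Useful as an
#' independent check of analytic determinant fields.
#'
#' @param phi_x,phi_y,phi_z 3D arrays: mapped coordinates, mm.
#' @param voxel_size Grid spacing in mm (length 1 or 3).
#' @return 3D array of `|J|` values.
#' @export
jacobian_fd <- function(phi_x, phi_y, phi_z, voxel_size = 1) {
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  grad_dim <- function(a, d) {
    n <- dim(a)[d]
    ip <- pmin(seq_len(n) + 1, n)
    im <- pmax(seq_len(n) - 1, 1)
    denom <- (ip - im) * voxel_size[d]
    idx <- function(i) switch(d, a[i, , , drop = FALSE],
                              a[, i, , drop = FALSE], a[, , i, drop = FALSE])
    out <- (idx(ip) - idx(im))
    sweep_dim <- array(rep(denom, each = if (d == 1) 1 else prod(dim(a)[seq_len(d - 1)])),
                       dim(a))
    out / sweep_dim
  }
  g <- list(x = lapply(1:3, grad_dim, a = phi_x),
            y = lapply(1:3, grad_dim, a = phi_y),
            z = lapply(1:3, grad_dim, a = phi_z))
  g$x[[1]] * (g$y[[2]] * g$z[[3]] - g$y[[3]] * g$z[[2]]) -
    g$x[[2]] * (g$y[[1]] * g$z[[3]] - g$y[[3]] * g$z[[1]]) +
    g$x[[3]] * (g$y[[1]] * g$z[[2]] - g$y[[2]] * g$z[[1]])
}

#' Build the TBM design from a scan table and Jacobian maps
#'
#' Computes per-scan `G = mean |J|` over the mask and assembles the design
#' columns: male indicator, orthonormal age basis to degree 4, and log G.
#'
#' @param design Tibble with scan_id, subject_id, sex, gest_week (rows in
#'   the order of `maps`).
#' @param maps Named list of [volume_map()]s.
#' @param degree Age polynomial degree (default 4).
#' @return List with `X` (design matrix), `design` (augmented tibble),
#'   `basis`, and term indices for sex and sex-age columns.
#' @export
tbm_design <- function(design, maps, degree = 4) {
  stopifnot(nrow(design) == length(maps))
  mask <- maps[[1]]$mask
  gbar <- purrr::map_dbl(maps, ~ mean(.x$values[mask]))
  if (any(gbar <= 0)) stop("mean Jacobian must be positive.", call. = FALSE)
  basis <- build_poly_basis(design$gest_week, degree)
  wb <- eval_basis(basis, design$gest_week)
  male <- as.numeric(sex_factor(design$sex) == "M")
  X <- cbind(intercept = 1, male = male, wb,
             male_w1 = male * wb[, 1], log_G = log(gbar))
  if (sd(log(gbar)) < 1e-12) {
    # a constant mean Jacobian carries no information and is collinear
    # with the intercept; drop it rather than fail
    X <- X[, colnames(X) != "log_G", drop = FALSE]
  }
  if (qr(X)$rank < ncol(X)) stop("rank-deficient TBM design.", call. = FALSE)
  list(X = X, design = dplyr::mutate(design, mean_jacobian = unname(gbar)),
       basis = basis, sex_col = "male", sexage_col = "male_w1")
}

# Matrix OLS of Y (n x V) on X; returns T statistics for selected columns.
ols_tmaps <- function(X, Y, cols) {
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Y)
  res <- Y - X %*% B
  df <- nrow(X) - ncol(X)
  s2 <- colSums(res^2) / df
  out <- lapply(cols, function(j) {
    se <- sqrt(pmax(s2 * XtXi[j, j], 0))
    t <- B[j, ] / se
    t[se < 1e-14] <- 0
    list(beta = B[j, ], t = t, n_zero = sum(se < 1e-14))
  })
  names(out) <- colnames(X)[cols]
  out
}

#' Voxelwise OLS fit of log Jacobian maps
#'
#' Per in-mask voxel, ordinary least squares of `log |J(x)|` on
#' [male, age basis (to degree 4), male x age, log mean-Jacobian], with
#' T statistics for the sex and sex-age terms. Voxels with zero residual
#' variance get T = 0 (count reported).
#'
#' @param maps Named list of [volume_map()]s sharing one grid and mask.
#' @param design Scan tibble (see [tbm_design()]).
#' @param fwhm_mm Smoothing FWHM applied to each map before the log
#'   transform (0 to skip).
#' @param degree Age polynomial degree.
#' @return A `tbm_fit` list: effect and T maps ([volume_map()]s), design,
#'   mask, and the voxel matrix used (for permutation).
#' @export
voxelwise_fit <- function(maps, design, fwhm_mm = 4, degree = 4) {
  stopifnot(length(maps) >= 3)
  dims <- dim(maps[[1]]$values)
  mask <- maps[[1]]$mask
  for (m in maps) {
    if (!identical(dim(m$values), dims) || !identical(m$mask, mask)) {
      stop("all maps must share one grid and mask.", call. = FALSE)
    }
  }
  if (fwhm_mm > 0) maps <- purrr::map(maps, smooth_volume, fwhm_mm = fwhm_mm)
  Y <- do.call(rbind, purrr::map(maps, ~ log(.x$values[mask])))
  dz <- tbm_design(design, maps, degree)
  sex_j <- match(dz$sex_col, colnames(dz$X))
  int_j <- match(dz$sexage_col, colnames(dz$X))
  fits <- ols_tmaps(dz$X, Y, c(sex_j, int_j))
  to_vol <- function(v) {
    a <- array(0, dims)
    a[mask] <- v
    volume_map(a, maps[[1]]$voxel_size, mask)
  }
  n_zero <- fits[[1]]$n_zero
  structure(list(effect_sex = to_vol(fits[[1]]$beta),
                 t_sex = to_vol(fits[[1]]$t),
                 t_sexage = to_vol(fits[[2]]$t),
                 X = dz$X, Y = Y, mask = mask, dims = dims,
                 voxel_size = maps[[1]]$voxel_size,
                 design = dz$design, df = nrow(dz$X) - ncol(dz$X),
                 n_zero_variance = n_zero),
            class = "tbm_fit")
}

#' maxT permutation FWER correction for TBM T-maps
#'
#' Permutes sex labels at the subject level (all scans of a subject move
#' together, preserving the repeated-measures structure), rebuilds the sex
#' and sex-age design columns, refits, and records the maximum `|T|` over
#' in-mask voxels per permutation. The corrected two-sided threshold is the
#' `ceiling((1 - alpha) * (n_perm + 1))`-th order statistic of the maxT
#' distribution; voxels with observed `|T|` at or above it are flagged.
#'
#' @param fit A `tbm_fit` from [voxelwise_fit()].
#' @param n_perm Number of permutations (>= 20; the full-scale analysis
#'   uses 20000, desk-scale suites 500).
#' @param seed Integer seed.
#' @param alpha Family-wise level.
#' @return A `tbm_result` list: thresholds, significance masks, maxT
#'   distributions, n_perm, seed.
#' @export
maxt_permutation <- function(fit, n_perm = 500, seed, alpha = 0.05) {
  stopifnot(inherits(fit, "tbm_fit"))
  if (n_perm < 20) stop("n_perm must be >= 20.", call. = FALSE)
  des <- fit$design
  subj <- unique(des$subject_id)
  subj_sex <- des$sex[match(subj, des$subject_id)]
  if (min(table(sex_factor(subj_sex))) < 6) {
    warning("fewer than 6 subjects per sex: permutation p-values are coarse.")
  }
  X <- fit$X
  sex_j <- match("male", colnames(X))
  int_j <- match("male_w1", colnames(X))
  w1 <- X[, "w1"]
  maxt <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      perm_sex <- sample(as.character(subj_sex))
      male <- as.numeric(perm_sex[match(des$subject_id, subj)] == "M")
      Xp <- X
      Xp[, sex_j] <- male
      Xp[, int_j] <- male * w1
      f <- ols_tmaps(Xp, fit$Y, c(sex_j, int_j))
      c(max(abs(f[[1]]$t)), max(abs(f[[2]]$t)))
    }, numeric(2))
  })
  k <- ceiling((1 - alpha) * (n_perm + 1))
  thr <- function(v) if (k <= length(v)) sort(v)[k] else Inf
  thr_sex <- thr(maxt[1, ])
  thr_int <- thr(maxt[2, ])
  flag <- function(tvol, thr) {
    a <- array(FALSE, fit$dims)
    a[fit$mask] <- abs(tvol$values[fit$mask]) >= thr
    a
  }
  structure(list(threshold_sex = thr_sex, threshold_sexage = thr_int,
                 sig_sex = flag(fit$t_sex, thr_sex),
                 sig_sexage = flag(fit$t_sexage, thr_int),
                 maxt_sex = maxt[1, ], maxt_sexage = maxt[2, ],
                 n_perm = n_perm, seed = seed, alpha = alpha,
                 fit = fit),
            class = "tbm_result")
}

#' @export
print.tbm_result <- function(x, ...) {
  cat("<tbm_result>", x$n_perm, "permutations, alpha", x$alpha, "\n",
      "corrected |T| thresholds: sex", round(x$threshold_sex, 3),
      "| sex-age", round(x$threshold_sexage, 3), "\n",
      "flagged voxels: sex", sum(x$sig_sex),
      "| sex-age", sum(x$sig_sexage), "\n")
  invisible(x)
}
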