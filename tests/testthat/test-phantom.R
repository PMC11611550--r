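# Digital phantom construction and counting statistics.

test_that("symmetric phantom is mirror-symmetric with exact tissue contrast", {
  fx <- small_phantom()
  a <- fx$activity$voxels
  expect_equal(max(abs(a - petgan:::mirror_x(a))), 0)
  gm <- fx$labels == phantom_labels[["gm"]]
  wm <- fx$labels == phantom_labels[["wm"]]
  csf <- fx$labels == phantom_labels[["csf"]]
  expect_equal(mean(a[gm]) / mean(a[wm]), 4)
  expect_equal(mean(a[csf]) / mean(a[wm]), 0.3)
  # all named regions and tissue classes are populated and connected brain
  for (nm in names(phantom_labels)[-1])
    expect_gt(sum(fx$labels == phantom_labels[[nm]]), 0)
  lab <- petgan:::cpp_label3d(fx$labels > 0L)
  expect_equal(max(lab), 1L)
})

test_that("phantom build is deterministic and validates lesions", {
  spec <- phantom_spec(grid_shape = c(32, 32, 32), seed = 5L)
  a1 <- build_phantom(spec)$activity$voxels
  a2 <- build_phantom(spec)$activity$voxels
  expect_identical(a1, a2)
  bad <- phantom_spec(grid_shape = c(32, 32, 32),
                      lesions = list(list(center = c(2, 2, 2),
                                          radius_mm = 3, multiplier = 0.6)))
  expect_error(build_phantom(bad), "lesion 1")
  expect_error(phantom_spec(thinning_fraction = 0), "thinning_fraction")
  expect_error(phantom_spec(thinning_fraction = 1.2), "thinning_fraction")
  expect_error(phantom_spec(activity_ratio_gm_wm_csf = c(4, -1, 0.3)),
               "ratio")
})

test_that("standard-dose counts follow Poisson statistics around the target", {
  fx <- small_phantom()
  counts <- attr(fx$sd, "counts")
  tot <- fx$spec$total_counts_standard
  expect_lt(abs(sum(counts) - tot), 5 * sqrt(tot))
  # identity limit: no PSF means raw counts are returned
  spec0 <- phantom_spec(grid_shape = c(16, 16, 16), psf_fwhm_mm = 0,
                        total_counts_standard = 1e5, seed = 9L)
  ph0 <- build_phantom(spec0)
  sd0 <- simulate_standard_dose(ph0$activity, spec0)
  expect_identical(sd0$voxels, attr(sd0, "counts"))
  # reproducibility
  sd0b <- simulate_standard_dose(ph0$activity, spec0)
  expect_identical(sd0$voxels, sd0b$voxels)
  expect_error(simulate_standard_dose(
    pet_volume(array(0, c(16, 16, 16))), spec0), "zero")
})

test_that("binomial thinning conserves expected counts and is degenerate at p=1", {
  fx <- small_phantom()
  counts <- attr(fx$sd, "counts")
  n_tot <- sum(counts)
  p <- 0.10
  # Monte-Carlo over replicates: each replicate sum within 5 binomial sd,
  # and the pooled mean much tighter
  reps <- 120
  sums <- numeric(reps)
  for (r in seq_len(reps)) {
    set.seed(1000 + r)
    sums[r] <- sum(stats::rbinom(length(counts), as.integer(counts), p))
  }
  sd_bin <- sqrt(n_tot * p * (1 - p))
  expect_true(all(abs(sums - p * n_tot) < 5 * sd_bin))
  expect_lt(abs(mean(sums) - p * n_tot), 5 * sd_bin / sqrt(reps))
  # p = 1 reproduces the standard-dose volume exactly
  spec1 <- phantom_spec(grid_shape = c(32, 32, 32),
                        voxel_size_mm = c(4, 4, 4),
                        total_counts_standard = 2e6,
                        thinning_fraction = 1, seed = 42L)
  ld1 <- simulate_low_dose(fx$sd, spec1)
  expect_equal(ld1$voxels, fx$sd$voxels)
  bad_spec <- fx$spec
  bad_spec$thinning_fraction <- 0
  expect_error(simulate_low_dose(fx$sd, bad_spec), "thinning_fraction")
})

test_that("per-voxel relative noise variance scales like 1/p", {
  lambda <- 60
  nvox <- 1500
  reps <- 80
  rel_var <- function(p) {
    m <- matrix(0, reps, nvox)
    for (r in seq_len(reps)) {
      set.seed(2000 + r)
      n <- stats::rpois(nvox, lambda)
      x <- stats::rbinom(nvox, n, p)
      m[r, ] <- (x - lambda * p) / (lambda * p)
    }
    mean(apply(m, 2, stats::var))
  }
  v_full <- rel_var(1)
  v_thin <- rel_var(0.1)
  expect_equal(v_thin / v_full, 10, tolerance = 0.15)
})

test_that("cohorts are reproducible with valid metadata and manifest", {
  spec <- phantom_spec(grid_shape = c(16, 16, 16), voxel_size_mm = c(6, 6, 6),
                       total_counts_standard = 2e5, seed = 3L)
  dir <- withr::local_tempdir()
  co <- make_cohort(5, spec, dir = dir, seed = 21L)
  expect_equal(nrow(co$manifest), 5)
  expect_true(all(co$manifest$dose_MBq >= 150 & co$manifest$dose_MBq <= 370))
  expect_true(all(co$manifest$weight_kg >= 50 & co$manifest$weight_kg <= 90))
  expect_true(all(file.exists(co$manifest$path_ld)))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  # distinct subjects, deterministic regeneration
  s1 <- co$subjects[[1]]$pair$sd$voxels
  s2 <- co$subjects[[2]]$pair$sd$voxels
  expect_gt(max(abs(s1 - s2)), 0)
  co2 <- make_cohort(5, spec, seed = 21L)
  expect_identical(co2$subjects[[3]]$pair$ld$voxels,
                   co$subjects[[3]]$pair$ld$voxels)
  # zero jitter: identical geometry up to noise realization
  co3 <- make_cohort(2, spec, jitter = list(size_sd = 0, ratio_sd = 0),
                     seed = 4L)
  expect_equal(dim(co3$subjects[[1]]$pair$sd),
               dim(co3$subjects[[2]]$pair$sd))
})
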