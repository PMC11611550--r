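# The six image-quality metrics.

test_that("metric identities hold on identical inputs", {
  set.seed(71)
  v <- array(runif(16^3), c(16, 16, 16))
  expect_equal(ssim(v, v), 1)
  expect_equal(nrmse(v, v), 0)
  expect_equal(psnr(v, v), Inf)
  expect_lt(fid(v, v), 1e-6)
  lab <- array(2L, dim(v)); lab[5:12, 5:12, 5:12] <- 3L
  sc <- snr_cnr_metrics(v, v, lab)
  expect_equal(sc$snr_metric, 0)
  expect_equal(sc$cnr_metric, 0)
})

test_that("ssim is symmetric and matches a nested-loop oracle", {
  set.seed(72)
  a <- array(runif(16^3), c(16, 16, 16))
  b <- a + array(rnorm(16^3, 0, 0.1), dim(a))
  expect_equal(ssim(a, b, data_range = 1), ssim(b, a, data_range = 1),
               tolerance = 1e-12)
  # brute-force oracle: per-voxel Gaussian-weighted local statistics with
  # explicit loops and mirror-reflected indices
  sigma <- 1.5; win <- 5L; r <- (win - 1L) %/% 2L
  k1d <- exp(-0.5 * (-r:r)^2 / sigma^2); k1d <- k1d / sum(k1d)
  refl <- function(i, n) {
    per <- 2 * (n - 1)
    i <- ((i - 1) %% per + per) %% per
    ifelse(i < n, i + 1, per - i + 1)
  }
  n <- 16L
  L <- diff(range(b)); c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  oracle_map <- array(0, dim(a))
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    wa <- 0; wb <- 0; waa <- 0; wbb <- 0; wab <- 0
    for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
      wgt <- k1d[dx + r + 1] * k1d[dy + r + 1] * k1d[dz + r + 1]
      ii <- refl(i + dx, n); jj <- refl(j + dy, n); kk <- refl(k + dz, n)
      av <- a[ii, jj, kk]; bv <- b[ii, jj, kk]
      wa <- wa + wgt * av; wb <- wb + wgt * bv
      waa <- waa + wgt * av * av; wbb <- wbb + wgt * bv * bv
      wab <- wab + wgt * av * bv
    }
    va <- waa - wa^2; vb <- wbb - wb^2; cab <- wab - wa * wb
    oracle_map[i, j, k] <- ((2 * wa * wb + c1) * (2 * cab + c2)) /
      ((wa^2 + wb^2 + c1) * (va + vb + c2))
  }
  expect_equal(ssim(a, b, sigma = sigma, win = win), mean(oracle_map),
               tolerance = 1e-6)
})

test_that("psnr and nrmse follow their closed forms and invariances", {
  set.seed(73)
  b <- array(runif(12^3), c(12, 12, 12))
  rng <- diff(range(b))
  a <- b + 0.1 * rng
  # uniform shift of 10% of the range: MSE = (0.1 range)^2, PSNR = 20 dB
  expect_equal(psnr(a, b), 20, tolerance = 1e-9)
  # nrmse scale invariance
  a2 <- b + array(rnorm(12^3, 0, 0.05), dim(b))
  expect_equal(nrmse(3.7 * a2, 3.7 * b), nrmse(a2, b), tolerance = 1e-12)
  expect_error(nrmse(a2, b * 0), "zero-energy")
})

test_that("feature distance matches the 1-D closed form and Gaussian limit", {
  set.seed(74)
  # closed form for 1-D features: (mu_a - mu_b)^2 + (sd_a - sd_b)^2
  fa <- matrix(rnorm(400, 1, 2)); fb <- matrix(rnorm(400, -0.5, 3))
  want <- (mean(fa) - mean(fb))^2 + (stats::sd(fa) - stats::sd(fb))^2
  expect_equal(fid_from_features(fa, fb), want, tolerance = 1e-9)
  # equal-mean, equal-covariance Gaussians: distance near 0 at n = 500
  fa2 <- matrix(rnorm(500 * 4), 500, 4)
  fb2 <- matrix(rnorm(500 * 4), 500, 4)
  expect_lt(fid_from_features(fa2, fb2), 0.1)
  expect_equal(fid_from_features(fa2, fa2), 0)
  expect_error(fid_from_features(fa2[1, , drop = FALSE], fb2), ">= 2")
})

test_that("snr/cnr deviation reacts predictably to extra noise", {
  set.seed(75)
  lab <- array(0L, c(20, 20, 20))
  lab[3:18, 3:18, 3:18] <- 2L
  lab[8:13, 8:13, 8:13] <- 3L
  sdv <- array(1, dim(lab))
  sdv[lab == 3L] <- 4
  sdv <- sdv + array(rnorm(length(sdv), 0, 0.2), dim(lab))
  # doubling the WM noise in the test volume halves its SNR:
  # |SNR_dn - SNR_sd| / SNR_sd ~ 0.5 (and CNR likewise)
  dn <- sdv
  wm <- lab == 2L
  mu_wm <- mean(sdv[wm])
  dn[wm] <- mu_wm + 2 * (sdv[wm] - mu_wm)
  sc <- snr_cnr_metrics(dn, sdv, lab)
  expect_equal(sc$snr_metric, 0.5, tolerance = 0.06)
  expect_true(sc$snr_metric >= 0 && sc$cnr_metric >= 0)
  expect_error(snr_cnr_metrics(dn, sdv, array(0L, dim(lab))), "empty")
})

test_that("all six metrics degrade monotonically with added noise", {
  set.seed(76)
  fx <- small_phantom()
  ref <- fx$sd$voxels / max(fx$sd$voxels)
  lab <- fx$labels
  sigmas <- c(0.02, 0.06, 0.15)
  res <- lapply(sigmas, function(s) {
    set.seed(77)
    noisy <- ref + array(rnorm(length(ref), 0, s), dim(ref))
    sc <- snr_cnr_metrics(noisy, ref, lab)
    c(ssim = ssim(noisy, ref, data_range = 1), psnr = psnr(noisy, ref),
      nrmse = nrmse(noisy, ref), fid = fid(noisy, ref),
      snr = sc$snr_metric)
  })
  m <- do.call(rbind, res)
  expect_true(all(diff(m[, "ssim"]) < 0))
  expect_true(all(diff(m[, "psnr"]) < 0))
  expect_true(all(diff(m[, "nrmse"]) > 0))
  expect_true(all(diff(m[, "fid"]) > 0))
})

test_that("cohort metric report aggregates per-pair rows", {
  set.seed(78)
  fx <- small_phantom()
  ref <- fx$sd$voxels / max(fx$sd$voxels)
  dn1 <- ref + array(rnorm(length(ref), 0, 0.05), dim(ref))
  dn2 <- ref + array(rnorm(length(ref), 0, 0.1), dim(ref))
  rep <- metric_report(list(dn1, dn2), list(ref, ref), fx$labels)
  expect_equal(nrow(rep$per_pair), 2)
  expect_equal(nrow(rep$summary), 6)
  expect_true(all(c("ssim", "psnr_db", "nrmse", "fid", "snr_metric",
                    "cnr_metric") %in% rep$summary$metric))
  expect_gt(rep$per_pair$ssim[1], rep$per_pair$ssim[2])
})
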