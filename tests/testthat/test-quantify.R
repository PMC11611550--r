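# SUV, SUVr, asymmetry mapping and cohort statistics.

test_that("SUV map follows the C x BW / Dose arithmetic", {
  v <- pet_volume(array(5, c(8, 8, 8)))             # 5 kBq/mL everywhere
  meta <- scan_meta(body_weight_kg = 70, injected_dose_MBq = 200)
  s <- suv_map(v, meta)
  expect_equal(unique(as.vector(s$voxels)), 5 * 70 / 200)
  expect_equal(unique(as.vector(s$voxels)), 1.75)
  # zero activity and linearity
  expect_true(all(suv_map(pet_volume(array(0, c(4, 4, 4))), meta)$voxels == 0))
  s3 <- suv_map(pet_volume(array(15, c(4, 4, 4))), meta)
  expect_equal(unique(as.vector(s3$voxels)), 3 * 1.75)
  expect_error(scan_meta(-1, 200), "weight")
  expect_error(scan_meta(70, 0), "dose")
})

test_that("SUVr normalizes by the reference region and is scale-invariant", {
  fx <- lesion_phantom()
  meta <- scan_meta(70, 200)
  suv <- suv_map(fx$activity, meta)
  tab <- suvr(suv, fx$labels, "cerebellum")
  expect_equal(tab$suvr[tab$region == "cerebellum"], 1)
  # planted 0.6x lesion: its mean SUV ~ 0.6 x the homologous mirrored
  # (unlesioned) tissue, which spans the same GM/WM mixture
  les_mask <- fx$labels == lesion_label_base
  hom_mask <- petgan:::mirror_x(les_mask)
  expect_equal(mean(suv$voxels[les_mask]) / mean(suv$voxels[hom_mask]),
               0.6, tolerance = 0.02)
  # invariant to global intensity scaling
  tab2 <- suvr(pet_volume(suv$voxels * 17, suv$spacing), fx$labels,
               "cerebellum")
  expect_equal(tab2$suvr, tab$suvr, tolerance = 1e-12)
  expect_error(suvr(suv, array(0L, dim(fx$labels)), "cerebellum"), "empty")
})

test_that("zAI is zero on symmetric input and localizes a planted lesion", {
  fx <- small_phantom()
  meta <- scan_meta(70, 200)
  sym <- quantify_volume(fx$activity, meta, fx$labels, "cerebellum")
  expect_true(all(sym$zai$voxels == 0))
  expect_equal(nrow(sym$roi$components), 0)
  lf <- lesion_phantom()
  q <- quantify_volume(lf$activity, meta, lf$labels, "cerebellum")
  les_mask <- lf$labels == lesion_label_base
  # the global zAI minimum falls inside the lesion label
  wmin <- which.min(q$zai$voxels)
  expect_true(les_mask[wmin])
  # hypometabolic ROI recovers the lesion with Dice > 0.5
  roi_mask <- q$roi$labels > 0L
  dice <- 2 * sum(roi_mask & les_mask) / (sum(roi_mask) + sum(les_mask))
  expect_gt(dice, 0.5)
  expect_equal(q$roi$components$volume_mm3,
               q$roi$components$n_vox * prod(lf$spec$voxel_size_mm))
})

test_that("zAI map is antisymmetric under mirroring", {
  set.seed(81)
  fx <- small_phantom()
  v <- fx$activity$voxels * (1 + array(rnorm(length(fx$activity$voxels),
                                             0, 0.05),
                                       dim(fx$activity$voxels)))
  vol <- pet_volume(v, fx$activity$spacing)
  z <- zai_map(vol, fx$labels > 0L)
  ai <- attr(z, "ai")
  expect_equal(ai, -petgan:::mirror_x(ai), tolerance = 1e-10)
})

test_that("noisier input can only add false-positive components", {
  meta <- scan_meta(70, 200)
  fx <- small_phantom()
  spec <- fx$spec
  counts_fp <- function(thin_seed, p) {
    spec_p <- spec
    spec_p$thinning_fraction <- p
    ld <- simulate_low_dose(fx$sd, spec_p, seed = thin_seed)
    pvol <- pet_volume(ld$voxels, spec$voxel_size_mm)
    q <- quantify_volume(pvol, meta, fx$labels, "cerebellum")
    nrow(q$roi$components)
  }
  # the noise-free symmetric activity yields no components at all; any
  # component under count noise is a false positive
  q0 <- quantify_volume(fx$activity, meta, fx$labels, "cerebellum")
  n_clean <- nrow(q0$roi$components)
  expect_equal(n_clean, 0)
  n_thin <- mean(vapply(101:103, counts_fp, numeric(1), p = 0.1))
  expect_gte(n_thin, n_clean)
})

test_that("Mann-Whitney U matches exhaustive rank enumeration at n = 4 vs 4", {
  x <- c(1.2, 3.4, 2.2, 5.0)
  y <- c(0.7, 2.9, 1.9, 4.1)
  got <- mann_whitney_u(x, y)
  # oracle: U from first principles; p by enumerating all C(8,4) group
  # assignments of the pooled ranks
  pooled <- c(x, y)
  rk <- rank(pooled)
  u_stat <- sum(rk[1:4]) - 4 * 5 / 2
  expect_equal(got$U, u_stat)
  combs <- utils::combn(8, 4)
  u_all <- apply(combs, 2, function(ix) sum(rk[ix]) - 10)
  # exact two-sided p: doubled smaller tail over all rank assignments
  p_exact <- min(1, 2 * min(mean(u_all <= u_stat), mean(u_all >= u_stat)))
  expect_equal(got$p, p_exact, tolerance = 1e-12)
})

test_that("cohort comparison flags nothing on identical arms", {
  set.seed(82)
  tab <- expand.grid(subject_id = sprintf("s%02d", 1:6),
                     region = c("gm", "wm", "cerebellum"),
                     stringsAsFactors = FALSE)
  tab$suvr <- runif(nrow(tab), 0.5, 1.5)
  cmp <- compare_cohort(tab, tab)
  expect_true(all(cmp$pct_dev_mean == 0))
  expect_true(all(!cmp$significant))
  expect_true(all(cmp$p >= 0.65))
  # shifted arm becomes significant
  tab2 <- tab
  tab2$suvr <- tab2$suvr + 10
  cmp2 <- compare_cohort(tab2, tab)
  expect_true(all(cmp2$significant))
  two <- tab[tab$subject_id %in% c("s01", "s02"), ]
  expect_error(compare_cohort(two, two), ">= 3")
})
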