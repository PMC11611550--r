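# Objectives, schedule, splits and the training loop.

test_that("generator loss components have their closed forms", {
  dn <- array(0.5, c(4, 4, 4)); sdv <- array(0.5, c(4, 4, 4))
  # identical volumes: L1 component exactly 0
  gl <- generator_loss(array(0, c(2, 2, 2)), dn, sdv)
  expect_equal(gl$l1, 0)
  # logit-0 fake scores: BCE adversarial component = ln 2
  expect_equal(gl$adversarial, log(2), tolerance = 1e-12)
  # arithmetic with the default weights: 1 * ln2 + 100 * 0.01 = 1.6931...
  sdv2 <- dn + 0.01
  gl2 <- generator_loss(array(0, c(2, 2, 2)), dn, sdv2,
                        weights = loss_weights(1, 100))
  expect_equal(gl2$total, 1 * log(2) + 100 * 0.01, tolerance = 1e-9)
  # MSE form at score 0 against label 1
  gl3 <- generator_loss(array(0, c(2, 2, 2)), dn, sdv,
                        adversarial_form = "MSE")
  expect_equal(gl3$adversarial, 1)
  expect_error(generator_loss(NaN, dn, sdv), "non-finite")
})

test_that("discriminator loss matches limits, closed forms and symmetry", {
  z <- array(0, c(3, 3, 3))
  expect_equal(discriminator_loss(z, z), 2 * log(2), tolerance = 1e-12)
  # perfect discrimination drives the loss to zero
  expect_lt(discriminator_loss(z + 40, z - 40), 1e-10)
  # exchanging real/fake with a label flip leaves the loss unchanged
  set.seed(61)
  r <- array(rnorm(27), c(3, 3, 3)); f <- array(rnorm(27), c(3, 3, 3))
  expect_equal(discriminator_loss(r, f), discriminator_loss(-f, -r),
               tolerance = 1e-12)
  expect_equal(discriminator_loss(r, f, "MSE"),
               mean((r - 1)^2) + mean(f^2))
})

test_that("learning rate is constant then decays linearly to zero", {
  cfg <- train_config("paper")
  expect_equal(cfg$lr, 1e-4)
  expect_equal(lr_schedule(0, cfg), 1e-4)
  expect_equal(lr_schedule(99, cfg), 1e-4)
  expect_equal(lr_schedule(250, cfg), 1e-4 * (400 - 250) / (400 - 100))
  expect_equal(lr_schedule(250, cfg), 5e-5)
  expect_equal(lr_schedule(400, cfg), 0)
  expect_error(lr_schedule(401, cfg), "epoch")
  expect_error(lr_schedule(-1, cfg), "epoch")
})

test_that("splits are disjoint, exhaustive, subject-level and seeded", {
  sp <- split_dataset(20, c(0.7, 0.15, 0.15), seed = 8)
  expect_length(sp$train, 14)
  expect_length(sp$val, 3)
  expect_length(sp$test, 3)
  expect_setequal(c(sp$train, sp$val, sp$test), 1:20)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_length(intersect(sp$train, sp$test), 0)
  sp2 <- split_dataset(20, c(0.7, 0.15, 0.15), seed = 8)
  expect_identical(sp, sp2)
  expect_error(split_dataset(3, c(0.9, 0.05, 0.05)), "empty")
  expect_error(split_dataset(10, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("feature-distance loss is zero at identity, nonnegative and noise-monotone", {
  set.seed(62)
  ex <- feature_extractor()
  v <- array(runif(16 * 16 * 8), c(16, 16, 8))
  expect_lt(fid_loss_term(v, v, ex), 1e-6)
  vals <- vapply(c(0.05, 0.1, 0.2), function(s) {
    set.seed(63)
    fid_loss_term(v + array(rnorm(length(v), 0, s), dim(v)), v, ex)
  }, numeric(1))
  expect_true(all(vals >= 0))
  expect_true(all(diff(vals) > 0))
  expect_error(fid_loss_term(array(1, c(4, 4, 1)), array(1, c(4, 4, 1))),
               "2 feature")
})

test_that("pure L1 training decreases the loss on a 2-pair overfit", {
  set.seed(64)
  mk <- function() {
    s <- array(runif(16^3, -0.8, 0.8), c(16, 16, 16))
    list(sd = s, ld = pmin(pmax(s + array(rnorm(16^3, 0, 0.15),
                                          dim(s)), -1), 1))
  }
  pairs <- list(mk(), mk())
  cfg <- train_config("smoke", epochs = 20L,
                      weights = loss_weights(lambda1 = 0, lambda2 = 100),
                      gen_spec = generator_spec(levels = 2L,
                                                base_channels = 4L,
                                                ssab_positions = integer(0)),
                      disc_spec = discriminator_spec(enabled = FALSE),
                      seed = 2)
  res <- train(pairs, cfg, split = list(train = 1:2, val = integer(0),
                                        test = integer(0)))
  g <- res$history$g_loss
  expect_length(g, 20)
  # non-increasing across the 20-epoch window (start vs end)
  expect_lt(mean(tail(g, 5)), mean(head(g, 5)))
  # with the discriminator disabled the loss is exactly lambda2 * L1
  expect_equal(res$steps$g_total, 100 * res$steps$l1, tolerance = 1e-12)
  expect_true(all(res$steps$adversarial == 0))
})

test_that("logged totals conserve the weighted component sum at every step", {
  set.seed(65)
  mk <- function() {
    s <- array(runif(16^3, -0.8, 0.8), c(16, 16, 16))
    list(sd = s, ld = pmin(pmax(s + array(rnorm(16^3, 0, 0.15),
                                          dim(s)), -1), 1))
  }
  pairs <- list(mk(), mk(), mk())
  w <- loss_weights(lambda1 = 1, lambda2 = 100, fid_weight = 0.5)
  cfg <- train_config("smoke", epochs = 2L, weights = w,
                      gen_spec = generator_spec(levels = 2L,
                                                base_channels = 4L,
                                                ssab_positions = integer(0)),
                      disc_spec = discriminator_spec(layers = 2L,
                                                     base_channels = 4L),
                      seed = 3)
  res <- train(pairs, cfg, split = list(train = 1:2, val = 3L,
                                        test = integer(0)))
  with(res$steps, expect_equal(
    g_total, w$lambda1 * adversarial + w$lambda2 * l1 + w$fid_weight * fid,
    tolerance = 1e-12))
  expect_equal(nrow(res$history), 2)
  expect_true(all(is.finite(res$history$val_ssim)))
  # best-validation checkpoint bookkeeping
  expect_true(res$checkpoint$val_ssim >= max(res$history$val_ssim) - 1e-12)
})

test_that("training is reproducible given a seed", {
  set.seed(66)
  mk <- function() {
    s <- array(runif(8^3, -0.8, 0.8), c(8, 8, 8))
    list(sd = s, ld = pmin(pmax(s + array(rnorm(8^3, 0, 0.2), dim(s)),
                                -1), 1))
  }
  pairs <- list(mk(), mk(), mk())
  cfg <- train_config("smoke", epochs = 2L,
                      gen_spec = generator_spec(levels = 1L,
                                                base_channels = 4L,
                                                ssab_positions = integer(0)),
                      disc_spec = discriminator_spec(layers = 1L,
                                                     base_channels = 4L),
                      seed = 9)
  sp <- list(train = 1:2, val = 3L, test = integer(0))
  r1 <- train(pairs, cfg, split = sp)
  r2 <- train(pairs, cfg, split = sp)
  expect_identical(r1$history$g_loss, r2$history$g_loss)
  expect_identical(r1$params, r2$params)
})
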