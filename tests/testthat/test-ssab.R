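# The self-similarity-aware attention block and its three units.

test_that("similarity score has its closed form on constant maps", {
  cfg <- ssab_config(window_size = 3L, dynamic_range_policy = "fixed",
                     dynamic_range_fixed = 2)
  c2 <- (0.03 * 2)^2
  expect_equal(c2, 0.0036)
  for (v in c(0, 0.5, -0.7, 2)) {
    f <- array(v, c(8, 8, 8, 2))
    s <- self_similarity_map(f, cfg)
    expect_equal(dim(s), dim(f))
    want <- (2 * v + c2) / (2 * v^2 + c2)
    expect_lt(max(abs(s - want)), 1e-12)
  }
  # zero map scores exactly 1 (c2 / c2)
  expect_equal(unique(as.vector(
    self_similarity_map(array(0, c(8, 8, 8, 1)), cfg))), 1)
  expect_error(self_similarity_map(array(0, c(2, 2, 2, 1)),
                                   ssab_config(window_size = 5L)), "window")
})

test_that("similarity score matches a nested-loop sliding-window oracle", {
  set.seed(51)
  w <- 3L
  f <- array(rnorm(7 * 7 * 7 * 2), c(7, 7, 7, 2))
  cfg <- ssab_config(window_size = w, dynamic_range_policy = "per_channel")
  got <- self_similarity_map(f, cfg)
  # independent oracle: per-voxel box mean by explicit loops (zero padding,
  # constant 1/w^3 weight), then the printed score formula
  r <- (w - 1L) %/% 2L
  for (ch in 1:2) {
    L <- max(f[, , , ch]) - min(f[, , , ch])
    c2 <- (0.03 * max(L, 1e-3))^2
    for (probe in list(c(1, 1, 1), c(4, 4, 4), c(7, 2, 5))) {
      acc <- 0; n_valid <- 0
      for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
        i <- probe[1] + dx; j <- probe[2] + dy; k <- probe[3] + dz
        if (i >= 1 && i <= 7 && j >= 1 && j <= 7 && k >= 1 && k <= 7) {
          acc <- acc + f[i, j, k, ch]
          n_valid <- n_valid + 1
        }
      }
      m <- acc / n_valid
      want <- (2 * m + c2) / (2 * m^2 + c2)
      expect_equal(got[probe[1], probe[2], probe[3], ch], want,
                   tolerance = 1e-6)
    }
  }
})

test_that("attention multipliers lie strictly in (0,1) and preserve shape", {
  set.seed(52)
  cfg <- tiny_ssab_cfg()
  f <- array(rnorm(6 * 6 * 6 * 4), c(6, 6, 6, 4))
  params <- petgan:::ssab_init(4L, cfg, seed = 1)
  for (fun in list(similarity_attention, cbam_attention, self_attention,
                   ssab_block)) {
    out <- fun(f, cfg, params = params)
    expect_equal(dim(out), dim(f))
  }
  # the sigmoid gates themselves, probed over many random maps
  for (rep in 1:25) {
    ff <- array(rnorm(5^3 * 4) * 3, c(5, 5, 5, 4))
    tape <- petgan:::tg_tape()
    pn <- petgan:::nn_lift(tape, params)
    s <- petgan:::ssab_similarity_map_node(petgan:::tg_const(tape, ff), cfg)
    a <- petgan:::tg_sigmoid(petgan:::tg_add(
      petgan:::tg_conv3d(s, pn$sim_ws, pn$sim_bs),
      petgan:::tg_conv3d(petgan:::tg_const(tape, ff), pn$sim_wf,
                         pn$sim_bf)))
    expect_true(all(a$value > 0 & a$value < 1))
  }
  # saturated negative logits drive the gated output toward zero
  sat <- params
  sat$sim_bs <- -50; sat$sim_bf <- -50
  sat$sim_ws <- sat$sim_ws * 0; sat$sim_wf <- sat$sim_wf * 0
  out0 <- similarity_attention(f, cfg, params = sat)
  expect_lt(max(abs(out0)), 1e-10)
})

test_that("self-attention is the identity at gamma 0 and permutation-equivariant", {
  set.seed(53)
  cfg <- tiny_ssab_cfg()
  f <- array(rnorm(4 * 4 * 4 * 4), c(4, 4, 4, 4))
  params <- petgan:::ssab_init(4L, cfg, seed = 2)
  expect_equal(params$sa_gamma, 0)
  expect_equal(self_attention(f, cfg, params = params), f)
  # softmax rows sum to 1 inside the unit
  tape <- petgan:::tg_tape()
  pn <- petgan:::nn_lift(tape, params)
  fn <- petgan:::tg_const(tape, f)
  q <- petgan:::tg_conv3d(fn, pn$sa_wq, pn$sa_bq)
  k <- petgan:::tg_conv3d(fn, pn$sa_wk, pn$sa_bk)
  attn <- petgan:::tg_softmax_rows(petgan:::tg_matmul(
    petgan:::tg_reshape(q, c(64L, 2L)),
    petgan:::tg_transpose(petgan:::tg_reshape(k, c(64L, 2L)))))
  expect_equal(rowSums(attn$value), rep(1, 64), tolerance = 1e-6)
  # permutation equivariance with gamma active: permuting spatial
  # positions permutes the output identically (1x1x1 projections carry no
  # spatial context)
  params$sa_gamma <- 0.7
  perm <- sample(64)
  fm <- matrix(f, 64, 4)
  fp <- array(fm[perm, ], c(4, 4, 4, 4))
  o1 <- self_attention(f, cfg, params = params)
  o2 <- self_attention(fp, cfg, params = params)
  o1m <- matrix(o1, 64, 4)
  expect_equal(matrix(o2, 64, 4), o1m[perm, ], tolerance = 1e-10)
})

test_that("channel attention branches coincide on constant-per-channel input", {
  cfg <- tiny_ssab_cfg()
  f <- array(rep(c(1.5, -2, 0.3, 4), each = 4^3), c(4, 4, 4, 4))
  tape <- petgan:::tg_tape()
  fn <- petgan:::tg_const(tape, f)
  gap <- petgan:::tg_gap(fn)$value
  gmp <- petgan:::tg_gmp(fn)$value
  expect_equal(gap, gmp)
  out <- cbam_attention(f, cfg, seed = 3)
  expect_equal(dim(out), dim(f))
})

test_that("full block is deterministic, fusible and trainable end to end", {
  set.seed(54)
  cfg <- tiny_ssab_cfg()
  f <- array(rnorm(6^3 * 4) * 0.5, c(6, 6, 6, 4))
  params <- petgan:::ssab_init(4L, cfg, seed = 7)
  o1 <- ssab_block(f, cfg, params = params)
  o2 <- ssab_block(f, cfg, params = params)
  expect_identical(o1, o2)
  expect_equal(dim(o1), dim(f))
  # gradient flows to every unit's parameters once the residual gate is
  # open (gamma = 0 blocks q/k/v by construction)
  params$sa_gamma <- 0.5
  fun <- function(tape, pn) {
    ff <- pn$f; pn$f <- NULL
    out <- petgan:::ssab_block_node(pn, ff, cfg)
    petgan:::tg_mean(petgan:::tg_mul(out, out))
  }
  pall <- c(params, list(f = f))
  tape <- petgan:::tg_tape()
  pn <- lapply(pall, function(p) petgan:::tg_param(tape, p))
  loss <- fun(tape, pn)
  petgan:::tg_backward(loss)
  for (nm in names(params)) {
    g <- pn[[nm]]$grad
    expect_false(is.null(g), label = paste("gradient reaches", nm))
    expect_true(all(is.finite(g)))
    expect_gt(sum(abs(g)), 0, label = paste("nonzero grad for", nm))
  }
  # the finite-difference agreement of the same graph
  worst <- fd_gradient_check(fun, pall, n_probe = 2L)
  expect_lt(worst, 2e-4)
})

test_that("window-size policy follows the feature-map size", {
  expect_equal(petgan:::ssab_window(ssab_config(), c(64, 64, 64)), 9L)
  expect_equal(petgan:::ssab_window(ssab_config(), c(16, 16, 16)), 3L)
  expect_equal(petgan:::ssab_window(ssab_config(window_size = 5),
                                    c(64, 64, 64)), 5L)
})
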