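# The autodiff core: analytic gradients must agree with central finite
# differences through representative composite graphs.

test_that("convolution gradients match finite differences on both paths", {
  set.seed(11)
  x0 <- array(rnorm(6 * 6 * 6 * 2) * 0.5, c(6, 6, 6, 2))
  w0 <- array(rnorm(27 * 2 * 3) * 0.3, c(3, 3, 3, 2, 3))
  b0 <- rnorm(3) * 0.1
  for (stride in 1:2) {
    fun <- function(tape, pn) {
      out <- petgan:::tg_conv3d(pn$x, pn$w, pn$b, stride)
      petgan:::tg_mean(petgan:::tg_mul(out, out))
    }
    worst <- fd_gradient_check(fun, list(x = x0, w = w0, b = b0),
                               n_probe = 4L)
    expect_lt(worst, 1e-4)
  }
  # large-patch path (cache budget exceeded) agrees with the cached path
  old <- petgan:::.conv_cache_budget
  out1 <- petgan:::cpp_conv3d_forward(x0, w0, b0, 1L, 1L)
  K <- petgan:::cpp_im2col(x0, dim(w0)[1:3], 1L, 1L)
  out2 <- K %*% matrix(w0, ncol = 3)
  out2 <- sweep(out2, 2, b0, "+")
  expect_equal(as.vector(out1), as.vector(out2), tolerance = 1e-12)
})

test_that("elementwise, pooling and attention ops backpropagate correctly", {
  set.seed(12)
  f0 <- array(rnorm(4 * 4 * 4 * 3) * 0.5, c(4, 4, 4, 3))
  a0 <- array(rnorm(4 * 4 * 4 * 1) * 0.5, c(4, 4, 4, 1))
  m0 <- matrix(rnorm(6 * 3) * 0.5, 6, 3)
  funs <- list(
    sigmoid_tanh = function(tape, pn)
      petgan:::tg_mean(petgan:::tg_sigmoid(petgan:::tg_tanh(pn$f))),
    lrelu = function(tape, pn)
      petgan:::tg_mean(petgan:::tg_mul(petgan:::tg_lrelu(pn$f), pn$f)),
    bcast = function(tape, pn)
      petgan:::tg_mean(petgan:::tg_bcast_mul(pn$f, petgan:::tg_sigmoid(pn$a))),
    pools = function(tape, pn) {
      g1 <- petgan:::tg_gap(pn$f); g2 <- petgan:::tg_gmp(pn$f)
      petgan:::tg_sum(petgan:::tg_mul(g1, g2))
    },
    chan = function(tape, pn)
      petgan:::tg_mean(petgan:::tg_concat_c(petgan:::tg_chan_mean(pn$f),
                                            petgan:::tg_chan_max(pn$f))),
    softmax = function(tape, pn)
      petgan:::tg_mean(petgan:::tg_softmax_rows(pn$m)),
    matmul = function(tape, pn)
      petgan:::tg_mean(petgan:::tg_matmul(petgan:::tg_transpose(pn$m),
                                          pn$m)),
    upsample = function(tape, pn)
      petgan:::tg_mean(petgan:::tg_mul(petgan:::tg_upsample2(pn$f),
                                       petgan:::tg_upsample2(pn$f))),
    avgpool = function(tape, pn)
      petgan:::tg_mean(petgan:::tg_mul(petgan:::tg_avgpool2(pn$f),
                                       petgan:::tg_avgpool2(pn$f))),
    boxmean = function(tape, pn)
      petgan:::tg_mean(petgan:::tg_mul(petgan:::tg_box_mean(pn$f, 3L),
                                       pn$f)),
    div_sqrt = function(tape, pn)
      petgan:::tg_mean(petgan:::tg_div(petgan:::tg_sqrt(
        petgan:::tg_mul(pn$f, pn$f)), petgan:::tg_sigmoid(pn$f)))
  )
  for (nm in names(funs)) {
    worst <- fd_gradient_check(funs[[nm]], list(f = f0, a = a0, m = m0),
                               n_probe = 3L)
    expect_lt(worst, 2e-4, label = paste("fd error for", nm))
  }
})

test_that("loss ops have closed-form values and correct gradients", {
  set.seed(13)
  x0 <- array(rnorm(24), c(2, 3, 4, 1))
  t0 <- array(rnorm(24), c(2, 3, 4, 1))
  # BCE with logits at 0 equals log 2
  tape <- petgan:::tg_tape()
  z <- petgan:::tg_const(tape, array(0, c(2, 2, 2, 1)))
  expect_equal(petgan:::tg_bce_logits(z, 1)$value, log(2))
  expect_equal(petgan:::tg_bce_logits(z, 0)$value, log(2))
  for (fn in list(
    function(tape, pn) petgan:::tg_l1(pn$x, petgan:::tg_const(tape, t0)),
    function(tape, pn) petgan:::tg_mse(pn$x, t0),
    function(tape, pn) petgan:::tg_bce_logits(pn$x, 1))) {
    worst <- fd_gradient_check(fn, list(x = x0), n_probe = 5L)
    expect_lt(worst, 1e-4)
  }
})

test_that("softmax rows sum to one and backward sweep is reverse-ordered", {
  set.seed(14)
  m <- matrix(rnorm(40) * 3, 8, 5)
  tape <- petgan:::tg_tape()
  s <- petgan:::tg_softmax_rows(petgan:::tg_const(tape, m))
  expect_equal(rowSums(s$value), rep(1, 8), tolerance = 1e-12)
  expect_true(all(s$value > 0 & s$value < 1))
})
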