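#' @useDynLib petgan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Reverse-mode autodiff tape.
#
# A tape records operations in execution order; each node is an environment
# holding its value, accumulated gradient, parent nodes and a backward
# closure. Because the graph is built define-by-run, creation order is a
# topological order and the backward pass is a single reverse sweep.
# Feature maps are dense arrays dim (X, Y, Z, C); matrices are plain R
# matrices. Only leaves created with tg_param() report gradients upward.
# ---------------------------------------------------------------------------

tg_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  class(tp) <- "tg_tape"
  tp
}

tg_node <- function(tape, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  nd$tape <- tape
  if (!is.null(tape)) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes))
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    tape$nodes[[tape$n]] <- nd
  }
  nd
}

tg_const <- function(tape, x) tg_node(tape, x)

tg_param <- function(tape, x) {
  nd <- tg_node(tape, x)
  nd$is_param <- TRUE
  nd
}

tg_acc <- function(nd, g) {
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
  invisible(NULL)
}

#' @title Run the backward sweep of an autodiff tape
#' @description Seeds the scalar loss node with gradient 1 and propagates
#'   gradients through every recorded operation in reverse order.
#' @param loss a scalar tape node
#' @return invisibly, the tape
#' @keywords internal
tg_backward <- function(loss) {
  stopifnot(length(loss$value) == 1L)
  tape <- loss$tape
  loss$grad <- 1
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
  }
  invisible(tape)
}

# -- elementwise arithmetic --------------------------------------------------

tg_add <- function(a, b) {
  tg_node(a$tape, a$value + b$value, list(a, b), function(nd) {
    tg_acc(nd$parents[[1]], nd$grad)
    g <- nd$grad
    if (length(nd$parents[[2]]$value) == 1L) g <- sum(g)
    tg_acc(nd$parents[[2]], g)
  })
}

tg_sub <- function(a, b) {
  tg_node(a$tape, a$value - b$value, list(a, b), function(nd) {
    tg_acc(nd$parents[[1]], nd$grad)
    tg_acc(nd$parents[[2]], -nd$grad)
  })
}

tg_mul <- function(a, b) {
  tg_node(a$tape, a$value * b$value, list(a, b), function(nd) {
    tg_acc(nd$parents[[1]], nd$grad * nd$parents[[2]]$value)
    tg_acc(nd$parents[[2]], nd$grad * nd$parents[[1]]$value)
  })
}

# multiply by a plain numeric constant
tg_smul <- function(a, s) {
  tg_node(a$tape, a$value * s, list(a), function(nd) {
    tg_acc(nd$parents[[1]], nd$grad * s)
  })
}

# multiply a tensor by a scalar parameter node (SAGAN gamma)
tg_gmul <- function(a, g) {
  tg_node(a$tape, a$value * as.numeric(g$value), list(a, g), function(nd) {
    tg_acc(nd$parents[[1]], nd$grad * as.numeric(nd$parents[[2]]$value))
    tg_acc(nd$parents[[2]], sum(nd$grad * nd$parents[[1]]$value))
  })
}

# broadcast a single-channel map A (X,Y,Z,1) across the channels of F
tg_bcast_mul <- function(f, a) {
  df <- dim(f$value)
  av <- array(a$value, df[1:3])
  val <- f$value * as.vector(av)  # recycles over the channel dimension
  tg_node(f$tape, val, list(f, a), function(nd) {
    fv <- nd$parents[[1]]$value
    d <- dim(fv)
    am <- array(nd$parents[[2]]$value, d[1:3])
    tg_acc(nd$parents[[1]], nd$grad * as.vector(am))
    ga <- array(rowSums(matrix(nd$grad * fv, ncol = d[4])), c(d[1:3], 1L))
    tg_acc(nd$parents[[2]], ga)
  })
}

# -- nonlinearities ----------------------------------------------------------

tg_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  tg_node(a$tape, s, list(a), function(nd) {
    tg_acc(nd$parents[[1]], nd$grad * nd$value * (1 - nd$value))
  })
}

tg_tanh <- function(a) {
  tv <- tanh(a$value)
  tg_node(a$tape, tv, list(a), function(nd) {
    tg_acc(nd$parents[[1]], nd$grad * (1 - nd$value^2))
  })
}

tg_lrelu <- function(a, alpha = 0.2) {
  v <- a$value
  slope <- alpha + (1 - alpha) * (v > 0)
  out <- v * slope
  dim(out) <- dim(v)
  tg_node(a$tape, out, list(a), function(nd) {
    tg_acc(nd$parents[[1]], nd$grad * slope)
  })
}

tg_relu <- function(a) tg_lrelu(a, alpha = 0)

tg_sqrt <- function(a, eps = 1e-8) {
  s <- sqrt(a$value + eps)
  tg_node(a$tape, s, list(a), function(nd) {
    tg_acc(nd$parents[[1]], nd$grad * 0.5 / nd$value)
  })
}

tg_square <- function(a) tg_mul(a, a)

# -- convolution and resampling ---------------------------------------------

# patch matrices up to this many doubles are cached in the node and reused
# by the backward pass (memory/time trade-off)
.conv_cache_budget <- 3.2e7

tg_conv3d <- function(x, w, b, stride = 1L, pad = NULL) {
  kd <- dim(w$value)
  if (is.null(pad)) pad <- (kd[1] - 1L) %/% 2L
  stride <- as.integer(stride); pad <- as.integer(pad)
  xd <- dim(x$value)
  kr <- prod(kd[1:4])
  nout <- prod((xd[1:3] + 2L * pad - kd[1:3]) %/% stride + 1L)
  if (kr * nout <= .conv_cache_budget) {
    K <- cpp_im2col(x$value, kd[1:3], stride, pad)
    od <- attr(K, "outdim")
    wm <- matrix(w$value, kr, kd[5])
    val <- K %*% wm
    val <- sweep(val, 2L, b$value, "+")
    dim(val) <- c(od, kd[5])
    nd <- tg_node(x$tape, val, list(x, w, b), function(nd) {
      g <- matrix(nd$grad, ncol = kd[5])
      tg_acc(nd$parents[[2]], array(crossprod(nd$K, g), kd))
      tg_acc(nd$parents[[3]], colSums(g))
      gc <- g %*% t(matrix(nd$parents[[2]]$value, kr, kd[5]))
      tg_acc(nd$parents[[1]], cpp_col2im(gc, dim(nd$parents[[1]]$value),
                                         kd[1:3], stride, pad))
      nd$K <- NULL
    })
    nd$K <- K
    nd
  } else {
    val <- cpp_conv3d_forward(x$value, w$value, b$value, stride, pad)
    tg_node(x$tape, val, list(x, w, b), function(nd) {
      gr <- cpp_conv3d_backward(nd$parents[[1]]$value, nd$parents[[2]]$value,
                                nd$grad, stride, pad)
      tg_acc(nd$parents[[1]], gr$gx)
      tg_acc(nd$parents[[2]], gr$gw)
      tg_acc(nd$parents[[3]], gr$gb)
    })
  }
}

tg_upsample2 <- function(x) {
  d <- dim(x$value)
  ix <- rep(seq_len(d[1]), each = 2L)
  iy <- rep(seq_len(d[2]), each = 2L)
  iz <- rep(seq_len(d[3]), each = 2L)
  val <- x$value[ix, iy, iz, , drop = FALSE]
  tg_node(x$tape, val, list(x), function(nd) {
    g <- nd$grad
    dg <- dim(g)
    # fold each 2x2x2 block back onto its source voxel
    dim(g) <- c(2L, dg[1] %/% 2L, 2L, dg[2] %/% 2L, 2L, dg[3] %/% 2L, dg[4])
    g <- aperm(g, c(1L, 3L, 5L, 2L, 4L, 6L, 7L))
    gi <- colSums(matrix(g, nrow = 8L))
    dim(gi) <- c(dg[1] %/% 2L, dg[2] %/% 2L, dg[3] %/% 2L, dg[4])
    tg_acc(nd$parents[[1]], gi)
  })
}

tg_concat_c <- function(a, b) {
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(all(da[1:3] == db[1:3]))
  val <- array(c(a$value, b$value), c(da[1:3], da[4] + db[4]))
  tg_node(a$tape, val, list(a, b), function(nd) {
    da <- dim(nd$parents[[1]]$value)
    g <- nd$grad
    n1 <- prod(da)
    g1 <- array(g[seq_len(n1)], da)
    g2 <- array(g[-seq_len(n1)], dim(nd$parents[[2]]$value))
    tg_acc(nd$parents[[1]], g1)
    tg_acc(nd$parents[[2]], g2)
  })
}

tg_avgpool2 <- function(x) {  # stride-2 average pooling, shape halves
  d <- dim(x$value)
  v <- x$value
  dim(v) <- c(2L, d[1] %/% 2L, 2L, d[2] %/% 2L, 2L, d[3] %/% 2L, d[4])
  v <- aperm(v, c(1L, 3L, 5L, 2L, 4L, 6L, 7L))
  val <- colSums(matrix(v, nrow = 8L)) / 8
  dim(val) <- c(d[1] %/% 2L, d[2] %/% 2L, d[3] %/% 2L, d[4])
  tg_node(x$tape, val, list(x), function(nd) {
    d <- dim(nd$parents[[1]]$value)
    g <- nd$grad / 8
    ix <- rep(seq_len(d[1] %/% 2L), each = 2L)
    iy <- rep(seq_len(d[2] %/% 2L), each = 2L)
    iz <- rep(seq_len(d[3] %/% 2L), each = 2L)
    tg_acc(nd$parents[[1]], g[ix, iy, iz, , drop = FALSE])
  })
}

# scale each channel of F by the matching entry of a 1 x C matrix node
tg_chan_scale <- function(f, s) {
  d <- dim(f$value)
  val <- f$value * rep(as.vector(s$value), each = prod(d[1:3]))
  tg_node(f$tape, val, list(f, s), function(nd) {
    d <- dim(nd$parents[[1]]$value)
    nv <- prod(d[1:3])
    sv <- as.vector(nd$parents[[2]]$value)
    tg_acc(nd$parents[[1]], nd$grad * rep(sv, each = nv))
    gs <- colSums(matrix(nd$grad * nd$parents[[1]]$value, nrow = nv))
    tg_acc(nd$parents[[2]], matrix(gs, nrow = 1L))
  })
}

tg_div <- function(a, b) {
  tg_node(a$tape, a$value / b$value, list(a, b), function(nd) {
    bv <- nd$parents[[2]]$value
    tg_acc(nd$parents[[1]], nd$grad / bv)
    tg_acc(nd$parents[[2]], -nd$grad * nd$parents[[1]]$value / bv^2)
  })
}

# -- matrix ops (self-attention) --------------------------------------------

tg_reshape <- function(x, d) {
  orig <- dim(x$value)
  v <- x$value
  dim(v) <- d
  tg_node(x$tape, v, list(x), function(nd) {
    g <- nd$grad
    dim(g) <- orig
    tg_acc(nd$parents[[1]], g)
  })
}

tg_matmul <- function(a, b) {
  tg_node(a$tape, a$value %*% b$value, list(a, b), function(nd) {
    tg_acc(nd$parents[[1]], nd$grad %*% t(nd$parents[[2]]$value))
    tg_acc(nd$parents[[2]], t(nd$parents[[1]]$value) %*% nd$grad)
  })
}

tg_transpose <- function(a) {
  tg_node(a$tape, t(a$value), list(a), function(nd) {
    tg_acc(nd$parents[[1]], t(nd$grad))
  })
}

tg_softmax_rows <- function(a) {
  v <- a$value
  v <- v - apply(v, 1L, max)
  e <- exp(v)
  s <- e / rowSums(e)
  tg_node(a$tape, s, list(a), function(nd) {
    sv <- nd$value
    g <- nd$grad
    tg_acc(nd$parents[[1]], (g - rowSums(g * sv)) * sv)
  })
}

# -- pooling / reductions ----------------------------------------------------

tg_gap <- function(x) {  # global average pool -> 1 x C matrix
  d <- dim(x$value)
  nv <- prod(d[1:3])
  val <- matrix(colMeans(matrix(x$value, nrow = nv)), nrow = 1L)
  tg_node(x$tape, val, list(x), function(nd) {
    d <- dim(nd$parents[[1]]$value)
    nv <- prod(d[1:3])
    g <- array(rep(as.vector(nd$grad) / nv, each = nv), d)
    tg_acc(nd$parents[[1]], g)
  })
}

tg_gmp <- function(x) {  # global max pool -> 1 x C matrix
  d <- dim(x$value)
  nv <- prod(d[1:3])
  m <- matrix(x$value, nrow = nv)
  idx <- max.col(t(m), ties.method = "first")
  val <- matrix(m[cbind(idx, seq_len(d[4]))], nrow = 1L)
  tg_node(x$tape, val, list(x), function(nd) {
    d <- dim(nd$parents[[1]]$value)
    nv <- prod(d[1:3])
    g <- matrix(0, nv, d[4])
    g[cbind(idx, seq_len(d[4]))] <- as.vector(nd$grad)
    dim(g) <- d
    tg_acc(nd$parents[[1]], g)
  })
}

tg_chan_mean <- function(x) {  # mean over channels -> (X,Y,Z,1)
  d <- dim(x$value)
  val <- array(rowMeans(matrix(x$value, ncol = d[4])), c(d[1:3], 1L))
  tg_node(x$tape, val, list(x), function(nd) {
    d <- dim(nd$parents[[1]]$value)
    g <- array(rep(as.vector(nd$grad) / d[4], d[4]), d)
    tg_acc(nd$parents[[1]], g)
  })
}

tg_chan_max <- function(x) {  # max over channels -> (X,Y,Z,1)
  d <- dim(x$value)
  m <- matrix(x$value, ncol = d[4])
  idx <- max.col(m, ties.method = "first")
  val <- array(m[cbind(seq_len(nrow(m)), idx)], c(d[1:3], 1L))
  tg_node(x$tape, val, list(x), function(nd) {
    d <- dim(nd$parents[[1]]$value)
    g <- matrix(0, prod(d[1:3]), d[4])
    g[cbind(seq_len(nrow(g)), idx)] <- as.vector(nd$grad)
    dim(g) <- d
    tg_acc(nd$parents[[1]], g)
  })
}

# sliding-window local mean, normalized by the number of in-volume window
# positions: m = S(x) / n with S the (self-adjoint) zero-padded box sum and
# n = S(1); the adjoint is g -> S(g / n)
tg_box_mean <- function(x, w) {
  w <- as.integer(w)
  d <- dim(x$value)
  n <- cpp_box_sum3d(array(1, c(d[1:3], 1L)), w)
  n <- as.vector(n)  # recycled across channels below
  val <- cpp_box_sum3d(x$value, w) / n
  tg_node(x$tape, val, list(x), function(nd) {
    tg_acc(nd$parents[[1]], cpp_box_sum3d(nd$grad / n, w))
  })
}

# similarity score s = (2m + c2) / (2 m^2 + c2), c2 a per-channel constant
tg_sssim_score <- function(m, c2) {
  d <- dim(m$value)
  c2a <- array(rep(c2, each = prod(d[1:3])), d)
  den <- 2 * m$value^2 + c2a
  val <- (2 * m$value + c2a) / den
  tg_node(m$tape, val, list(m), function(nd) {
    mv <- nd$parents[[1]]$value
    den <- 2 * mv^2 + c2a
    dsdm <- (2 * den - (2 * mv + c2a) * 4 * mv) / den^2
    tg_acc(nd$parents[[1]], nd$grad * dsdm)
  })
}

# -- scalar losses -----------------------------------------------------------

tg_mean <- function(x) {
  n <- length(x$value)
  tg_node(x$tape, mean(x$value), list(x), function(nd) {
    p <- nd$parents[[1]]
    g <- array(nd$grad / n, dim(p$value) %||% length(p$value))
    tg_acc(p, g)
  })
}

tg_sum <- function(x) {
  tg_node(x$tape, sum(x$value), list(x), function(nd) {
    p <- nd$parents[[1]]
    g <- array(nd$grad, dim(p$value) %||% length(p$value))
    tg_acc(p, g)
  })
}

# mean absolute error between two tensors
tg_l1 <- function(a, b) {
  n <- length(a$value)
  tg_node(a$tape, mean(abs(a$value - b$value)), list(a, b), function(nd) {
    s <- sign(nd$parents[[1]]$value - nd$parents[[2]]$value)
    tg_acc(nd$parents[[1]], nd$grad * s / n)
    tg_acc(nd$parents[[2]], -nd$grad * s / n)
  })
}

# mean squared error against a constant target array or scalar
tg_mse <- function(a, target) {
  n <- length(a$value)
  diff <- a$value - target
  tg_node(a$tape, mean(diff^2), list(a), function(nd) {
    d <- nd$parents[[1]]$value - target
    tg_acc(nd$parents[[1]], nd$grad * 2 * d / n)
  })
}

# numerically stable mean BCE-with-logits against constant target in {0,1}
tg_bce_logits <- function(x, target) {
  v <- x$value
  loss <- mean(pmax(v, 0) - v * target + log1p(exp(-abs(v))))
  n <- length(v)
  tg_node(x$tape, loss, list(x), function(nd) {
    v <- nd$parents[[1]]$value
    sg <- 1 / (1 + exp(-v))
    tg_acc(nd$parents[[1]], nd$grad * (sg - target) / n)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
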