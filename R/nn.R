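# Parameter containers, initialization and the Adam optimizer for the
# tape-based network core. A "param set" is a named list of numeric arrays;
# at each training step it is lifted onto a tape with nn_lift(), and after
# the backward sweep nn_grads() collects gradients by name.

# He-style normal init for a conv kernel (k, k, k, cin, cout)
nn_conv_w <- function(k, cin, cout, gain = 2) {
  fan_in <- k^3 * cin
  array(stats::rnorm(k^3 * cin * cout, 0, sqrt(gain / fan_in)),
        c(k, k, k, cin, cout))
}

nn_dense_w <- function(cin, cout, gain = 2) {
  matrix(stats::rnorm(cin * cout, 0, sqrt(gain / cin)), cin, cout)
}

nn_lift <- function(tape, params) {
  lapply(params, function(p) tg_param(tape, p))
}

nn_grads <- function(pnodes) {
  lapply(pnodes, function(nd) {
    if (is.null(nd$grad)) array(0, dim(nd$value) %||% length(nd$value))
    else nd$grad
  })
}

nn_count_params <- function(params) sum(vapply(params, length, numeric(1)))

# -- Adam --------------------------------------------------------------------

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, betas = c(0.5, 0.999),
                      eps = 1e-8) {
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mh <- state$m[[nm]] / corr1
    vh <- state$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}
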