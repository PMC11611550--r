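#' Configuration of the self-similarity-aware attention block
#'
#' @param window_size odd sliding-window width for the local-mean
#'   convolution of the similarity score; `NULL` selects
#'   `max(3, nearest odd to min(spatial)/8)` from the feature-map size
#' @param k2 stabilization constant of the similarity score (default 0.03)
#' @param dynamic_range_policy `"per_channel"` (max - min of each channel,
#'   clamped below at 1e-3) or `"fixed"` (use `dynamic_range_fixed`)
#' @param dynamic_range_fixed dynamic range L when the policy is fixed
#'   (default 2, the range of data rescaled to [-1, 1])
#' @param form `"literal"` evaluates the printed score
#'   (2 m + c2) / (2 m^2 + c2) with m the windowed local mean;
#'   `"canonical"` replaces the squared mean by the windowed second moment
#' @param fusion_kernel kernel width of the channel-preserving fusion
#'   convolution (default 1)
#' @param sa_reduction channel reduction of the self-attention query/key
#'   projections (default 8)
#' @param ca_reduction channel reduction of the channel-attention MLP
#'   (default 16)
#' @param spatial_kernel kernel width of the spatial/similarity attention
#'   convolutions (default 7, applied as 7x7x7)
#' @param sa_pool_threshold self-attention pools key/value maps by 2x when
#'   the number of spatial positions exceeds this (default 4096)
#' @param max_attn_elements hard budget on the attention matrix size;
#'   exceeding it raises an error advising a downsampled placement
#' @return an object of class `ssab_config`
#' @export
ssab_config <- function(window_size = NULL, k2 = 0.03,
                        dynamic_range_policy = c("per_channel", "fixed"),
                        dynamic_range_fixed = 2,
                        form = c("literal", "canonical"),
                        fusion_kernel = 1L, sa_reduction = 8L,
                        ca_reduction = 16L, spatial_kernel = 7L,
                        sa_pool_threshold = 4096,
                        max_attn_elements = 3.4e7) {
  dynamic_range_policy <- match.arg(dynamic_range_policy)
  form <- match.arg(form)
  if (!is.null(window_size) &&
      (window_size < 3L || window_size %% 2L == 0L))
    stop("window_size must be an odd integer >= 3")
  if (fusion_kernel %% 2L == 0L || spatial_kernel %% 2L == 0L)
    stop("kernels must be odd")
  if (sa_reduction < 1L || ca_reduction < 1L)
    stop("reductions must be >= 1")
  structure(list(window_size = window_size, k2 = k2,
                 dynamic_range_policy = dynamic_range_policy,
                 dynamic_range_fixed = dynamic_range_fixed, form = form,
                 fusion_kernel = as.integer(fusion_kernel),
                 sa_reduction = as.integer(sa_reduction),
                 ca_reduction = as.integer(ca_reduction),
                 spatial_kernel = as.integer(spatial_kernel),
                 sa_pool_threshold = sa_pool_threshold,
                 max_attn_elements = max_attn_elements),
            class = "ssab_config")
}

ssab_window <- function(cfg, spatial) {
  if (!is.null(cfg$window_size)) return(as.integer(cfg$window_size))
  w <- round(min(spatial) / 8)
  w <- as.integer(ifelse(w %% 2 == 0, w + 1, w))
  max(3L, w)
}

ssab_c2 <- function(cfg, f_value) {
  k2 <- cfg$k2
  if (cfg$dynamic_range_policy == "fixed") {
    L <- rep(cfg$dynamic_range_fixed, dim(f_value)[4])
  } else {
    m <- matrix(f_value, ncol = dim(f_value)[4])
    L <- pmax(apply(m, 2, max) - apply(m, 2, min), 1e-3)
  }
  (k2 * L)^2
}

# ---------------------------------------------------------------------------
# Parameter initialization per attention unit. `channels` is the feature
# width C the block operates on.
# ---------------------------------------------------------------------------

ssab_init <- function(channels, cfg = ssab_config(), seed = 1L) {
  set.seed(as.integer(seed))
  C <- as.integer(channels)
  if (C < cfg$sa_reduction)
    stop("channels (", C, ") must be >= sa_reduction (", cfg$sa_reduction, ")")
  if (C < cfg$ca_reduction)
    stop("channels (", C, ") must be >= ca_reduction (", cfg$ca_reduction, ")")
  k7 <- cfg$spatial_kernel
  ck <- max(1L, C %/% cfg$sa_reduction)
  cr <- max(1L, C %/% cfg$ca_reduction)
  list(
    # similarity attention: Conv7 over the score map and over F, one output
    # channel each (a spatial attention map broadcast over channels)
    sim_ws = nn_conv_w(k7, C, 1L), sim_bs = numeric(1),
    sim_wf = nn_conv_w(k7, C, 1L), sim_bf = numeric(1),
    # self-attention: 1x1x1 query/key/value projections + residual gamma
    sa_wq = nn_conv_w(1L, C, ck), sa_bq = numeric(ck),
    sa_wk = nn_conv_w(1L, C, ck), sa_bk = numeric(ck),
    sa_wv = nn_conv_w(1L, C, C),  sa_bv = numeric(C),
    sa_gamma = 0,
    # channel -> spatial convolutional attention
    ca_w1 = nn_dense_w(C, cr), ca_b1 = numeric(cr),
    ca_w2 = nn_dense_w(cr, C), ca_b2 = numeric(C),
    sp_w = nn_conv_w(k7, 2L, 1L), sp_b = numeric(1),
    # fusion convolution, channel-preserving
    fu_w = nn_conv_w(cfg$fusion_kernel, C, C), fu_b = numeric(C))
}

# ---------------------------------------------------------------------------
# Tape-level unit forwards (pn: lifted parameter nodes; f: feature node)
# ---------------------------------------------------------------------------

ssab_similarity_map_node <- function(f, cfg) {
  d <- dim(f$value)
  w <- ssab_window(cfg, d[1:3])
  if (any(d[1:3] < w))
    stop("similarity window (", w, ") larger than the feature grid")
  c2 <- ssab_c2(cfg, f$value)
  m <- tg_box_mean(f, w)
  if (cfg$form == "literal") {
    tg_sssim_score(m, c2)
  } else {
    m2 <- tg_box_mean(tg_square(f), w)
    c2n <- tg_const(f$tape, array(rep(c2, each = prod(d[1:3])), d))
    tg_div(tg_add(tg_smul(m, 2), c2n), tg_add(tg_smul(m2, 2), c2n))
  }
}

ssab_similarity_attention_node <- function(pn, f, cfg) {
  s <- ssab_similarity_map_node(f, cfg)
  logits <- tg_add(tg_conv3d(s, pn$sim_ws, pn$sim_bs),
                   tg_conv3d(f, pn$sim_wf, pn$sim_bf))
  a <- tg_sigmoid(logits)
  tg_bcast_mul(f, a)
}

ssab_self_attention_node <- function(pn, f, cfg) {
  d <- dim(f$value)
  n <- prod(d[1:3])
  q <- tg_conv3d(f, pn$sa_wq, pn$sa_bq)
  k <- tg_conv3d(f, pn$sa_wk, pn$sa_bk)
  v <- tg_conv3d(f, pn$sa_wv, pn$sa_bv)
  pooled <- FALSE
  while (n * prod(dim(k$value)[1:3]) > cfg$max_attn_elements &&
         all(dim(k$value)[1:3] %% 2 == 0)) {
    if (n <= cfg$sa_pool_threshold) break
    k <- tg_avgpool2(k); v <- tg_avgpool2(v); pooled <- TRUE
    if (prod(dim(k$value)[1:3]) <= 64) break
  }
  m <- prod(dim(k$value)[1:3])
  if (n * m > cfg$max_attn_elements)
    stop("self-attention over ", n, " positions exceeds the attention ",
         "budget even after key/value pooling; place the block at a ",
         "deeper (downsampled) encoder level")
  ck <- dim(q$value)[4]
  qm <- tg_reshape(q, c(n, ck))
  km <- tg_reshape(k, c(m, ck))
  vm <- tg_reshape(v, c(m, d[4]))
  attn <- tg_softmax_rows(tg_matmul(qm, tg_transpose(km)))
  att <- tg_reshape(tg_matmul(attn, vm), d)
  tg_add(tg_gmul(att, pn$sa_gamma), f)
}

ssab_cbam_attention_node <- function(pn, f, cfg) {
  mlp <- function(x) {
    h <- tg_relu(tg_add(tg_matmul(x, pn$ca_w1),
                        tg_reshape(pn$ca_b1, c(1L, length(pn$ca_b1$value)))))
    tg_add(tg_matmul(h, pn$ca_w2),
           tg_reshape(pn$ca_b2, c(1L, length(pn$ca_b2$value))))
  }
  ca <- tg_sigmoid(tg_add(mlp(tg_gap(f)), mlp(tg_gmp(f))))
  fc <- tg_chan_scale(f, ca)
  sp_in <- tg_concat_c(tg_chan_mean(fc), tg_chan_max(fc))
  sa <- tg_sigmoid(tg_conv3d(sp_in, pn$sp_w, pn$sp_b))
  tg_bcast_mul(fc, sa)
}

ssab_block_node <- function(pn, f, cfg) {
  s1 <- ssab_self_attention_node(pn, f, cfg)
  s2 <- ssab_similarity_attention_node(pn, f, cfg)
  s3 <- ssab_cbam_attention_node(pn, f, cfg)
  tg_conv3d(tg_add(tg_add(s1, s2), s3), pn$fu_w, pn$fu_b)
}

# ---------------------------------------------------------------------------
# User-facing functional wrappers operating on plain (X, Y, Z, C) arrays.
# Parameters default to a fresh seeded initialization so the operations are
# deterministic and inspectable outside a training loop.
# ---------------------------------------------------------------------------

ssab_wrap <- function(f, cfg, params, seed, fun) {
  f <- ssab_as_feature(f)
  C <- dim(f)[4]
  if (is.null(params)) params <- ssab_init(C, cfg, seed)
  tape <- tg_tape()
  pn <- nn_lift(tape, params)
  fn <- tg_const(tape, f)
  out <- fun(pn, fn, cfg)
  out$value
}

ssab_as_feature <- function(f) {
  if (inherits(f, "pet_volume")) f <- f$voxels
  f <- as.array(f)
  if (length(dim(f)) == 3L) dim(f) <- c(dim(f), 1L)
  if (length(dim(f)) != 4L) stop("feature maps must be (X, Y, Z, C) arrays")
  f
}

#' Pixel-wise self-similarity score map
#'
#' Computes, per channel, the windowed local mean m of the feature map and
#' the score (2 m + c2) / (2 m^2 + c2) with c2 = (k2 L)^2, L taken from the
#' configured dynamic-range policy. The score is finite everywhere (c2 > 0
#' stabilizes the weak denominator) and equals 1 on a zero map.
#'
#' @param f feature map: array (X, Y, Z, C), 3D array or [pet_volume]
#' @param cfg an [ssab_config]
#' @return array of the same shape as `f`
#' @export
self_similarity_map <- function(f, cfg = ssab_config()) {
  f <- ssab_as_feature(f)
  tape <- tg_tape()
  ssab_similarity_map_node(tg_const(tape, f), cfg)$value
}

#' Similarity attention unit
#'
#' Applies a sigmoid attention map sigma(Conv7(score) + Conv7(F)),
#' broadcast over channels, to the feature map: out = A (x) F. Attention
#' values are strictly inside (0, 1).
#'
#' @inheritParams self_similarity_map
#' @param params optional parameter list from [ssab_init()]
#' @param seed seed for the default parameter initialization
#' @return array of the same shape as `f`
#' @export
similarity_attention <- function(f, cfg = ssab_config(), params = NULL,
                                 seed = 1L) {
  ssab_wrap(f, cfg, params, seed, ssab_similarity_attention_node)
}

#' Self-attention unit
#'
#' Query/key/value 1x1x1 projections (query/key width C / `sa_reduction`),
#' row-softmax attention over flattened spatial positions, and a residual
#' connection scaled by a learnable gamma initialized at zero — so an
#' untrained unit is the identity.
#'
#' @inheritParams similarity_attention
#' @return array of the same shape as `f`
#' @export
self_attention <- function(f, cfg = ssab_config(), params = NULL, seed = 1L) {
  ssab_wrap(f, cfg, params, seed, ssab_self_attention_node)
}

#' Channel-then-spatial convolutional attention
#'
#' Channel attention (shared MLP over global average and max pools, sigmoid
#' gate) followed by spatial attention (7x7x7 convolution over the
#' channel-mean and channel-max maps, sigmoid gate), applied sequentially.
#'
#' @inheritParams similarity_attention
#' @return array of the same shape as `f`
#' @export
cbam_attention <- function(f, cfg = ssab_config(), params = NULL, seed = 1L) {
  ssab_wrap(f, cfg, params, seed, ssab_cbam_attention_node)
}

#' Full self-similarity-aware attention block
#'
#' Sums the outputs of the self-attention, similarity attention and
#' channel/spatial attention units and fuses them with a channel-preserving
#' convolution. Shape-preserving and deterministic given parameters.
#'
#' @inheritParams similarity_attention
#' @return array of the same shape as `f`
#' @export
ssab_block <- function(f, cfg = ssab_config(), params = NULL, seed = 1L) {
  ssab_wrap(f, cfg, params, seed, ssab_block_node)
}
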