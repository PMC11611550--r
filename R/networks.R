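#' Generator architecture specification
#'
#' A U-shaped encoder-decoder with skip connections in the image-to-image
#' translation lineage: a large-kernel input convolution, stride-2 encoder
#' blocks with the self-similarity-aware attention block applied at chosen
#' encoder levels, nearest-neighbour upsampling decoder blocks with skip
#' concatenation, and a tanh-bounded single-channel output.
#'
#' @param levels number of 2x downsamplings (default 4)
#' @param base_channels channel width after the input convolution
#'   (default 32; doubles per level)
#' @param input_kernel width of the input convolution (default 7; set 3 for
#'   the ablation that removes the large input kernel)
#' @param ssab_positions encoder level indices (1-based, after each
#'   downsampling) where the attention block is applied; default `c(2, 3)`;
#'   use `integer(0)` for the attention-free ablation baseline
#' @param attention_type `"ssab"` (full block), `"self"`, `"similarity"`,
#'   `"cbam"` (single units, for the attention-type ablation) or `"none"`
#' @param ssab_cfg an [ssab_config]
#' @param final_activation `"tanh"` (output bounded in [-1, 1])
#' @param global_residual learn the denoising correction in logit space:
#'   the network output enters the final tanh added to artanh of the
#'   (slightly shrunk) input, so an untrained generator is the identity on
#'   the low-count volume and training only has to remove noise. `FALSE`
#'   gives the plain encoder-decoder output
#' @return an object of class `generator_spec`
#' @export
generator_spec <- function(levels = 4L, base_channels = 32L,
                           input_kernel = 7L, ssab_positions = c(2L, 3L),
                           attention_type = c("ssab", "self", "similarity",
                                              "cbam", "none"),
                           ssab_cfg = ssab_config(),
                           final_activation = "tanh",
                           global_residual = TRUE) {
  attention_type <- match.arg(attention_type)
  levels <- as.integer(levels)
  ssab_positions <- as.integer(ssab_positions)
  if (any(ssab_positions < 1L | ssab_positions > levels))
    stop("ssab_positions must lie in 1..levels")
  if (attention_type == "none") ssab_positions <- integer(0)
  structure(list(levels = levels, base_channels = as.integer(base_channels),
                 input_kernel = as.integer(input_kernel),
                 ssab_positions = ssab_positions,
                 attention_type = attention_type, ssab_cfg = ssab_cfg,
                 final_activation = final_activation,
                 global_residual = isTRUE(global_residual)),
            class = "generator_spec")
}

gen_channels <- function(spec) spec$base_channels * 2^(0:spec$levels)

#' Initialize generator parameters
#'
#' @param spec a [generator_spec]
#' @param seed RNG seed for the weight initialization
#' @return named list of parameter arrays (prefix `g_`)
#' @export
generator_init <- function(spec, seed = 1L) {
  set.seed(as.integer(seed))
  ch <- gen_channels(spec)
  p <- list()
  p$g_in_w <- nn_conv_w(spec$input_kernel, 1L, ch[1]); p$g_in_b <- numeric(ch[1])
  for (l in seq_len(spec$levels)) {
    p[[sprintf("g_enc%d_w", l)]] <- nn_conv_w(3L, ch[l], ch[l + 1])
    p[[sprintf("g_enc%d_b", l)]] <- numeric(ch[l + 1])
  }
  p$g_bot_w <- nn_conv_w(3L, ch[spec$levels + 1], ch[spec$levels + 1])
  p$g_bot_b <- numeric(ch[spec$levels + 1])
  for (l in seq_len(spec$levels)) {
    p[[sprintf("g_up%d_w", l)]] <- nn_conv_w(3L, ch[l + 1], ch[l])
    p[[sprintf("g_up%d_b", l)]] <- numeric(ch[l])
    # 1x1x1 skip-merge: the preceding 3x3x3 up-convolution does the local
    # mixing; the merge only recombines channels
    p[[sprintf("g_mrg%d_w", l)]] <- nn_conv_w(1L, 2L * ch[l], ch[l])
    p[[sprintf("g_mrg%d_b", l)]] <- numeric(ch[l])
  }
  # with the global residual the correction branch starts closed (exact
  # identity at initialization), as usual for residual denoisers
  p$g_out_w <- if (spec$global_residual) array(0, c(3, 3, 3, ch[1], 1L))
               else nn_conv_w(3L, ch[1], 1L)
  p$g_out_b <- numeric(1)
  if (spec$attention_type != "none") {
    for (l in spec$ssab_positions) {
      sp <- ssab_init(ch[l + 1], spec$ssab_cfg,
                      seed = as.integer(seed) + 1000L + l)
      names(sp) <- sprintf("g_att%d_%s", l, names(sp))
      p <- c(p, sp)
    }
  }
  p
}

att_subset <- function(pn, l) {
  pre <- sprintf("g_att%d_", l)
  sel <- pn[startsWith(names(pn), pre)]
  names(sel) <- substring(names(sel), nchar(pre) + 1L)
  sel
}

attention_node <- function(spec, pn, l, f) {
  sel <- att_subset(pn, l)
  cfg <- spec$ssab_cfg
  switch(spec$attention_type,
         ssab = ssab_block_node(sel, f, cfg),
         self = ssab_self_attention_node(sel, f, cfg),
         similarity = ssab_similarity_attention_node(sel, f, cfg),
         cbam = ssab_cbam_attention_node(sel, f, cfg),
         none = f)
}

# tape-level generator forward: x node (X,Y,Z,1) -> output node (X,Y,Z,1)
generator_forward_node <- function(pn, x, spec) {
  f <- tg_lrelu(tg_conv3d(x, pn$g_in_w, pn$g_in_b))
  skips <- list(f)
  for (l in seq_len(spec$levels)) {
    f <- tg_lrelu(tg_conv3d(f, pn[[sprintf("g_enc%d_w", l)]],
                            pn[[sprintf("g_enc%d_b", l)]], stride = 2L))
    if (l %in% spec$ssab_positions && spec$attention_type != "none")
      f <- attention_node(spec, pn, l, f)
    skips[[l + 1L]] <- f
  }
  f <- tg_relu(tg_conv3d(f, pn$g_bot_w, pn$g_bot_b))
  for (l in seq.int(spec$levels, 1L)) {
    # channel-reducing 3x3x3 convolution at the coarse grid, then nearest
    # upsampling (the cheap ordering; the merge and output convolutions
    # smooth the block structure)
    f <- tg_upsample2(tg_relu(tg_conv3d(f, pn[[sprintf("g_up%d_w", l)]],
                                        pn[[sprintf("g_up%d_b", l)]])))
    f <- tg_concat_c(f, skips[[l]])
    f <- tg_relu(tg_conv3d(f, pn[[sprintf("g_mrg%d_w", l)]],
                           pn[[sprintf("g_mrg%d_b", l)]]))
  }
  z <- tg_conv3d(f, pn$g_out_w, pn$g_out_b)
  if (spec$global_residual) {
    # residual-in-logit-space: tanh(z + artanh(0.999 x)) is ~x when z = 0,
    # so the network learns the noise correction, not the whole image
    xr <- atanh(pmin(pmax(x$value, -1), 1) * 0.999)
    z <- tg_add(z, tg_const(x$tape, xr))
  }
  tg_tanh(z)
}

#' Run the generator on a preprocessed low-count volume
#'
#' @param ld_volume a [pet_volume] (or 3D array) with values in [-1, 1]
#' @param spec a [generator_spec]
#' @param params parameter list from [generator_init()]; a fresh seeded
#'   initialization is used when `NULL`
#' @param seed seed for the default initialization
#' @return denoised volume of the same shape, values in [-1, 1]; a
#'   [pet_volume] when the input was one
#' @export
generator_forward <- function(ld_volume, spec = generator_spec(),
                              params = NULL, seed = 1L) {
  vol_in <- inherits(ld_volume, "pet_volume")
  x <- if (vol_in) ld_volume$voxels else as.array(ld_volume)
  d3 <- dim(x)[1:3]
  div <- 2^spec$levels
  if (any(d3 %% div != 0)) {
    need <- (div - d3 %% div) %% div
    stop("input shape ", paste(d3, collapse = "x"), " is not divisible by 2^",
         spec$levels, "; pad by (", paste(need, collapse = ", "),
         ") voxels")
  }
  if (is.null(params)) params <- generator_init(spec, seed)
  dim(x) <- c(d3, 1L)
  tape <- tg_tape()
  out <- generator_forward_node(nn_lift(tape, params), tg_const(tape, x),
                                spec)
  o <- out$value
  dim(o) <- d3
  if (vol_in) pet_volume(o, ld_volume$spacing, ld_volume$origin,
                         ld_volume$orientation)
  else o
}

#' Discriminator architecture specification
#'
#' A 3D patch discriminator: stacked stride-2 convolutions over the
#' (conditioning, candidate) channel concatenation, emitting a spatial map
#' of per-patch logits (no final sigmoid; the losses apply it).
#'
#' @param layers number of stride-2 convolution blocks (default 3)
#' @param base_channels first-layer width (default 32; doubles per layer)
#' @param conditional condition on the low-count input (default TRUE)
#' @param enabled ablation switch; when FALSE, training skips the
#'   adversarial game entirely
#' @return an object of class `discriminator_spec`
#' @export
discriminator_spec <- function(layers = 3L, base_channels = 32L,
                               conditional = TRUE, enabled = TRUE) {
  structure(list(layers = as.integer(layers),
                 base_channels = as.integer(base_channels),
                 conditional = isTRUE(conditional), enabled = isTRUE(enabled)),
            class = "discriminator_spec")
}

#' Initialize discriminator parameters
#' @param spec a [discriminator_spec]
#' @param seed RNG seed
#' @return named list of parameter arrays (prefix `d_`)
#' @export
discriminator_init <- function(spec, seed = 1L) {
  set.seed(as.integer(seed))
  cin <- if (spec$conditional) 2L else 1L
  ch <- c(cin, spec$base_channels * 2^(0:(spec$layers - 1L)))
  p <- list()
  for (l in seq_len(spec$layers)) {
    p[[sprintf("d_c%d_w", l)]] <- nn_conv_w(3L, ch[l], ch[l + 1])
    p[[sprintf("d_c%d_b", l)]] <- numeric(ch[l + 1])
  }
  p$d_out_w <- nn_conv_w(3L, ch[spec$layers + 1L], 1L)
  p$d_out_b <- numeric(1)
  p
}

discriminator_forward_node <- function(pn, ld, cand, spec) {
  f <- if (spec$conditional) tg_concat_c(ld, cand) else cand
  for (l in seq_len(spec$layers))
    f <- tg_lrelu(tg_conv3d(f, pn[[sprintf("d_c%d_w", l)]],
                            pn[[sprintf("d_c%d_b", l)]], stride = 2L))
  tg_conv3d(f, pn$d_out_w, pn$d_out_b)
}

#' Run the discriminator on a (conditioning, candidate) pair
#'
#' @param ld_volume conditioning low-count volume ([pet_volume] or array)
#' @param candidate_volume candidate (standard-dose or denoised) volume
#' @param spec a [discriminator_spec]
#' @param params parameters from [discriminator_init()]; seeded default
#'   when `NULL`
#' @param seed seed for the default initialization
#' @return 3D array of per-patch logits (spatial extent input / 2^layers)
#' @export
discriminator_forward <- function(ld_volume, candidate_volume,
                                  spec = discriminator_spec(),
                                  params = NULL, seed = 1L) {
  ld <- ssab_as_feature(ld_volume)
  cd <- ssab_as_feature(candidate_volume)
  if (!all(dim(ld) == dim(cd)))
    stop("conditioning and candidate volumes must have the same shape")
  if (is.null(params)) params <- discriminator_init(spec, seed)
  tape <- tg_tape()
  pn <- nn_lift(tape, params)
  out <- discriminator_forward_node(pn, tg_const(tape, ld),
                                    tg_const(tape, cd), spec)
  o <- out$value
  dim(o) <- dim(o)[1:3]
  o
}

#' Count the parameters of a parameter set
#' @param params named list of arrays
#' @return total number of scalar parameters
#' @export
n_params <- function(params) nn_count_params(params)
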