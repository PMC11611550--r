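#' Loss weights of the combined objective
#'
#' The total generator objective is
#' `lambda1 * adversarial + lambda2 * L1 + fid_weight * FID`.
#'
#' @param lambda1 weight of the adversarial term (default 1)
#' @param lambda2 weight of the L1 reconstruction regularizer (default 100)
#' @param fid_weight weight of the optional feature-distance term
#'   (default 0; enabled by one training-loss ablation)
#' @return a `loss_weights` list
#' @export
loss_weights <- function(lambda1 = 1, lambda2 = 100, fid_weight = 0) {
  if (lambda1 < 0 || lambda2 < 0 || fid_weight < 0)
    stop("loss weights must be nonnegative")
  structure(list(lambda1 = lambda1, lambda2 = lambda2,
                 fid_weight = fid_weight), class = "loss_weights")
}

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' Generator loss and its components
#'
#' Adversarial term on the discriminator's fake scores (non-saturating
#' binary cross-entropy against the real label by default, least-squares
#' form for the MSE ablation, or the saturating log(1 - D) form behind a
#' flag) plus the L1 reconstruction regularizer between the denoised and
#' standard-dose volumes.
#'
#' @param d_scores_fake patch logits of the discriminator on the denoised
#'   volume
#' @param dn denoised volume (array or [pet_volume])
#' @param sd standard-dose reference of the same shape
#' @param weights a [loss_weights]
#' @param adversarial_form `"BCE"` or `"MSE"`
#' @param saturating use the saturating generator objective
#' @param fid_value optional precomputed feature-distance component
#' @return list with `total`, `adversarial`, `l1`, `fid`
#' @export
generator_loss <- function(d_scores_fake, dn, sd, weights = loss_weights(),
                           adversarial_form = c("BCE", "MSE"),
                           saturating = FALSE, fid_value = 0) {
  adversarial_form <- match.arg(adversarial_form)
  dn <- ssab_as_feature(dn); sd <- ssab_as_feature(sd)
  if (!all(dim(dn) == dim(sd))) stop("dn and sd must have the same shape")
  x <- as.numeric(d_scores_fake)
  adv <- if (adversarial_form == "MSE") mean((x - 1)^2)
         else if (saturating) mean(log1p(-1 / (1 + exp(-x)) + 1e-12))
         else mean(softplus(-x))
  l1 <- mean(abs(sd - dn))
  total <- weights$lambda1 * adv + weights$lambda2 * l1 +
    weights$fid_weight * fid_value
  if (!is.finite(total))
    stop("non-finite generator loss (adv = ", adv, ", l1 = ", l1, ")")
  list(total = total, adversarial = adv, l1 = l1, fid = fid_value)
}

#' Discriminator loss
#'
#' Binary cross-entropy of real patches against 1 and fake patches against
#' 0 (sigmoid applied to logits), or the least-squares form.
#'
#' @param d_scores_real patch logits on the (conditioning, standard-dose)
#'   pair
#' @param d_scores_fake patch logits on the (conditioning, denoised) pair
#' @param adversarial_form `"BCE"` or `"MSE"`
#' @return scalar loss
#' @export
discriminator_loss <- function(d_scores_real, d_scores_fake,
                               adversarial_form = c("BCE", "MSE")) {
  adversarial_form <- match.arg(adversarial_form)
  r <- as.numeric(d_scores_real); f <- as.numeric(d_scores_fake)
  loss <- if (adversarial_form == "MSE") mean((r - 1)^2) + mean(f^2)
          else mean(softplus(-r)) + mean(softplus(f))
  if (!is.finite(loss)) stop("non-finite discriminator loss")
  loss
}

#' Learning-rate schedule
#'
#' Constant for the first `lr_constant_epochs` epochs, then linear decay to
#' zero at `epochs`.
#'
#' @param epoch 0-based epoch index in `[0, epochs]`
#' @param cfg a [train_config] (fields `lr`, `lr_constant_epochs`, `epochs`)
#' @return learning rate for that epoch
#' @export
lr_schedule <- function(epoch, cfg) {
  if (epoch < 0 || epoch > cfg$epochs)
    stop("epoch must lie in [0, ", cfg$epochs, "]")
  if (epoch < cfg$lr_constant_epochs) return(cfg$lr)
  cfg$lr * (cfg$epochs - epoch) / (cfg$epochs - cfg$lr_constant_epochs)
}

#' Training configuration
#'
#' Defaults reproduce the full-scale training recipe: Adam with momenta
#' (0.5, 0.999), learning rate 1e-4 constant for 100 epochs then linear to
#' zero at 400, batch size 1, loss weights (1, 100), 70/15/15 splits. The
#' `"smoke"` profile scales the same recipe to desk size: 2-level / base-8
#' generator on 32^3 volumes, 30 epochs with decay from epoch 10.
#'
#' @param profile `"paper"` or `"smoke"`
#' @param adversarial_form `"BCE"` or `"MSE"`
#' @param epochs,lr,lr_constant_epochs,betas,batch_size,split,seed training
#'   knobs; see details
#' @param weights a [loss_weights]
#' @param gen_spec a [generator_spec]
#' @param disc_spec a [discriminator_spec]
#' @param saturating_adv use the saturating generator objective
#' @param fid_extractor feature extractor for the FID loss variant (see
#'   [feature_extractor()]); required when `weights$fid_weight > 0`
#' @return a `train_config`
#' @export
train_config <- function(profile = c("smoke", "paper"),
                         adversarial_form = c("BCE", "MSE"),
                         epochs = NULL, lr = NULL,
                         lr_constant_epochs = NULL,
                         betas = c(0.5, 0.999), batch_size = 1L,
                         split = c(0.70, 0.15, 0.15), seed = 1L,
                         weights = loss_weights(),
                         gen_spec = NULL, disc_spec = NULL,
                         saturating_adv = FALSE, fid_extractor = NULL) {
  profile <- match.arg(profile)
  adversarial_form <- match.arg(adversarial_form)
  if (is.null(epochs)) epochs <- if (profile == "paper") 400L else 30L
  # the smoke profile runs two orders of magnitude fewer optimizer steps
  # than the full recipe; it uses a proportionally larger step size
  if (is.null(lr)) lr <- if (profile == "paper") 1e-4 else 1e-3
  if (is.null(lr_constant_epochs))
    lr_constant_epochs <- min(if (profile == "paper") 100L else 10L, epochs)
  if (epochs < lr_constant_epochs)
    stop("epochs must be >= lr_constant_epochs")
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  if (is.null(gen_spec)) {
    gen_spec <- if (profile == "paper") generator_spec()
      else generator_spec(levels = 2L, base_channels = 8L,
                          ssab_positions = 2L,
                          ssab_cfg = ssab_config(sa_reduction = 8L,
                                                 ca_reduction = 8L))
  }
  if (is.null(disc_spec)) {
    disc_spec <- if (profile == "paper") discriminator_spec()
      else discriminator_spec(layers = 2L, base_channels = 8L)
  }
  if (weights$fid_weight > 0 && is.null(fid_extractor))
    fid_extractor <- feature_extractor()
  structure(list(profile = profile, adversarial_form = adversarial_form,
                 epochs = as.integer(epochs), lr = lr,
                 lr_constant_epochs = as.integer(lr_constant_epochs),
                 betas = betas, batch_size = as.integer(batch_size),
                 split = split, seed = as.integer(seed), weights = weights,
                 gen_spec = gen_spec, disc_spec = disc_spec,
                 saturating_adv = saturating_adv,
                 fid_extractor = fid_extractor),
            class = "train_config")
}

#' Subject-level train/validation/test split
#'
#' @param n_pairs number of subject pairs, or a list of pairs
#' @param fractions length-3 fractions summing to 1
#' @param seed RNG seed
#' @return list of disjoint, exhaustive index vectors `train`, `val`,
#'   `test`
#' @export
split_dataset <- function(n_pairs, fractions = c(0.70, 0.15, 0.15),
                          seed = 1L) {
  n <- if (is.list(n_pairs)) length(n_pairs) else as.integer(n_pairs)
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  n_train <- round(n * fractions[1])
  n_val <- round(n * fractions[2])
  n_test <- n - n_train - n_val
  if (n_train < 1 || n_val < 1 || n_test < 1)
    stop("split produces an empty subset at n = ", n)
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  list(train = sort(perm[seq_len(n_train)]),
       val = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[n_train + n_val + seq_len(n_test)]))
}

as_net_input <- function(v) {
  x <- if (inherits(v, "pet_volume")) v$voxels else as.array(v)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

# differentiable feature-distance term between two single-volume "batches"
# of axial slices (diagonal-covariance Frechet form); see feature_extractor()
fid_loss_node <- function(dn_node, sd_value, extractor) {
  tape <- dn_node$tape
  d <- dim(dn_node$value)
  nz <- d[3]
  if (nz < 2) stop("need >= 2 feature vectors for a covariance fit")
  p <- d[1] * d[2]
  W <- tg_const(tape, extractor$projection(p))
  feats <- function(x_node) {
    sl <- tg_reshape(x_node, c(p, nz))
    tg_tanh(tg_matmul(tg_transpose(sl), W))
  }
  moments <- function(fm) {
    ones <- tg_const(tape, matrix(1 / nz, 1L, nz))
    mu <- tg_matmul(ones, fm)                       # 1 x d
    mu2 <- tg_matmul(ones, tg_mul(fm, fm))
    va <- tg_sub(mu2, tg_mul(mu, mu))
    list(mu = mu, va = va)
  }
  a <- moments(feats(dn_node))
  sdn <- tg_const(tape, array(sd_value, c(d[1], d[2], d[3], 1L)))
  b <- moments(feats(sdn))
  dmu <- tg_sub(a$mu, b$mu)
  dsd <- tg_sub(tg_sqrt(a$va), tg_sqrt(b$va))
  tg_add(tg_sum(tg_mul(dmu, dmu)), tg_sum(tg_mul(dsd, dsd)))
}

#' Differentiable feature-distance loss term
#'
#' Fréchet distance between diagonal-Gaussian fits of slice features of the
#' denoised and standard-dose volumes, using the fixed seeded projection
#' extractor. Zero when the batches coincide, nonnegative, and
#' differentiable with respect to the denoised volume.
#'
#' @param dn_batch denoised volume (array or [pet_volume])
#' @param sd_batch standard-dose volume of the same shape
#' @param extractor a [feature_extractor()]
#' @return scalar loss value
#' @export
fid_loss_term <- function(dn_batch, sd_batch,
                          extractor = feature_extractor()) {
  dn <- as_net_input(dn_batch); sdv <- as_net_input(sd_batch)
  if (!all(dim(dn) == dim(sdv))) stop("batch shapes differ")
  tape <- tg_tape()
  fid_loss_node(tg_const(tape, dn), sdv, extractor)$value
}

#' Train the denoising GAN
#'
#' Alternating discriminator/generator updates with Adam, per-epoch
#' validation SSIM, best-validation checkpointing and a full per-step loss
#' history. With the discriminator disabled the loop reduces to supervised
#' L1 regression (the component ablation); with `lambda1 = 0` the
#' adversarial term is skipped even if the discriminator trains.
#'
#' @param pairs list of subjects, each `list(ld = , sd = )` of preprocessed
#'   volumes in [-1, 1] (arrays or [pet_volume]s)
#' @param cfg a [train_config]
#' @param split optional precomputed split from [split_dataset()]; by
#'   default the configured fractions are applied (all pairs train when
#'   there are too few for a 3-way split and `split = NULL` fails)
#' @param verbose print per-epoch progress
#' @return list with `checkpoint` (best-validation parameters + spec),
#'   `params` (final), `history` (per-epoch data.frame), `steps` (per-step
#'   loss components), `split`
#' @export
train <- function(pairs, cfg = train_config(), split = NULL,
                  verbose = FALSE) {
  if (length(pairs) < 2L) stop("need at least 2 training pairs")
  if (is.null(split)) split <- split_dataset(length(pairs), cfg$split,
                                             cfg$seed)
  gp <- generator_init(cfg$gen_spec, seed = cfg$seed)
  use_d <- cfg$disc_spec$enabled
  if (use_d) dp <- discriminator_init(cfg$disc_spec, seed = cfg$seed + 1L)
  g_state <- adam_state(gp)
  if (use_d) d_state <- adam_state(dp)
  w <- cfg$weights
  hist_rows <- vector("list", cfg$epochs)
  step_rows <- list()
  best <- list(val = -Inf, params = gp, epoch = 0L)
  step_i <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    lr <- lr_schedule(epoch - 1L, cfg)
    set.seed(cfg$seed * 1000L + epoch)
    order_i <- sample(split$train)
    ep_g <- c(); ep_d <- c()
    for (i in order_i) {
      ld <- as_net_input(pairs[[i]]$ld)
      sdv <- as_net_input(pairs[[i]]$sd)
      # ---- generator step ----
      tape <- tg_tape()
      pn <- nn_lift(tape, gp)
      dn <- generator_forward_node(pn, tg_const(tape, ld), cfg$gen_spec)
      l1_node <- tg_l1(dn, tg_const(tape, sdv))
      adv_val <- 0
      if (use_d && w$lambda1 > 0) {
        # discriminator parameters enter as constants: no D grads in G step
        dpc <- lapply(dp, function(x) tg_const(tape, x))
        scores <- discriminator_forward_node(dpc, tg_const(tape, ld), dn,
                                             cfg$disc_spec)
        adv_node <- if (cfg$adversarial_form == "MSE") tg_mse(scores, 1)
          else tg_bce_logits(scores, 1)
        adv_val <- adv_node$value
        loss <- tg_add(tg_smul(adv_node, w$lambda1),
                       tg_smul(l1_node, w$lambda2))
      } else {
        loss <- tg_smul(l1_node, w$lambda2)
      }
      fid_val <- 0
      if (w$fid_weight > 0) {
        fid_node <- fid_loss_node(dn, sdv[, , , 1], cfg$fid_extractor)
        fid_val <- fid_node$value
        loss <- tg_add(loss, tg_smul(fid_node, w$fid_weight))
      }
      if (!is.finite(loss$value))
        stop("generator loss diverged (NaN) at epoch ", epoch)
      tg_backward(loss)
      upd <- adam_step(gp, nn_grads(pn), g_state, lr, cfg$betas)
      gp <- upd$params; g_state <- upd$state
      ep_g <- c(ep_g, loss$value)
      d_val <- NA_real_
      # ---- discriminator step ----
      if (use_d) {
        dn_det <- dn$value
        tape2 <- tg_tape()
        dnn <- nn_lift(tape2, dp)
        ldn <- tg_const(tape2, ld)
        s_real <- discriminator_forward_node(dnn, ldn, tg_const(tape2, sdv),
                                             cfg$disc_spec)
        s_fake <- discriminator_forward_node(dnn, ldn,
                                             tg_const(tape2, dn_det),
                                             cfg$disc_spec)
        d_loss <- if (cfg$adversarial_form == "MSE")
          tg_add(tg_mse(s_real, 1), tg_mse(s_fake, 0))
          else tg_add(tg_bce_logits(s_real, 1), tg_bce_logits(s_fake, 0))
        if (!is.finite(d_loss$value))
          stop("discriminator loss diverged (NaN) at epoch ", epoch)
        tg_backward(d_loss)
        updd <- adam_step(dp, nn_grads(dnn), d_state, lr, cfg$betas)
        dp <- updd$params; d_state <- updd$state
        d_val <- d_loss$value
        ep_d <- c(ep_d, d_val)
      }
      step_i <- step_i + 1L
      step_rows[[step_i]] <- data.frame(
        step = step_i, epoch = epoch, pair = i,
        adversarial = adv_val, l1 = l1_node$value, fid = fid_val,
        g_total = loss$value, d_loss = d_val)
    }
    # ---- validation ----
    val_ssim <- NA_real_
    if (length(split$val)) {
      vs <- vapply(split$val, function(i) {
        dn <- predict_generator(gp, pairs[[i]]$ld, cfg$gen_spec)
        ssim(dn, pairs[[i]]$sd)
      }, numeric(1))
      val_ssim <- mean(vs)
      if (is.finite(val_ssim) && val_ssim > best$val)
        best <- list(val = val_ssim, params = gp, epoch = epoch)
    }
    hist_rows[[epoch]] <- data.frame(
      epoch = epoch, lr = lr, g_loss = mean(ep_g),
      d_loss = if (length(ep_d)) mean(ep_d) else NA_real_,
      val_ssim = val_ssim)
    if (verbose)
      message(sprintf("epoch %3d lr %.2e G %.4f D %s val SSIM %s", epoch,
                      lr, mean(ep_g),
                      if (length(ep_d)) sprintf("%.4f", mean(ep_d)) else "-",
                      if (is.na(val_ssim)) "-" else sprintf("%.4f",
                                                            val_ssim)))
  }
  if (!is.finite(best$val)) best <- list(val = NA_real_, params = gp,
                                         epoch = cfg$epochs)
  checkpoint <- list(gen_spec = cfg$gen_spec, params = best$params,
                     seed = cfg$seed, epoch = best$epoch,
                     val_ssim = best$val, n_params = nn_count_params(gp))
  class(checkpoint) <- "petgan_checkpoint"
  list(checkpoint = checkpoint, params = gp,
       history = do.call(rbind, hist_rows),
       steps = do.call(rbind, step_rows), split = split)
}

# value-only generator forward for inference
predict_generator <- function(params, ld, spec) {
  x <- as_net_input(ld)
  tape <- tg_tape()
  out <- generator_forward_node(nn_lift(tape, params), tg_const(tape, x),
                                spec)
  o <- out$value
  dim(o) <- dim(o)[1:3]
  if (inherits(ld, "pet_volume"))
    pet_volume(o, ld$spacing, ld$origin, ld$orientation)
  else o
}

#' Denoise a preprocessed volume with a trained checkpoint
#'
#' @param volume a [pet_volume] or array in [-1, 1]
#' @param checkpoint a `petgan_checkpoint` from [train()] (or a path to an
#'   RDS file holding one)
#' @return denoised volume of the same type
#' @export
denoise <- function(volume, checkpoint) {
  if (is.character(checkpoint)) checkpoint <- readRDS(checkpoint)
  stopifnot(inherits(checkpoint, "petgan_checkpoint"))
  predict_generator(checkpoint$params, volume, checkpoint$gen_spec)
}

#' Save a checkpoint to disk
#' @param checkpoint a `petgan_checkpoint`
#' @param path RDS output path
#' @return the path, invisibly
#' @export
save_checkpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path)
  invisible(path)
}
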