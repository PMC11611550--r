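#' Structural similarity between two volumes
#'
#' Mean local SSIM with a 3D Gaussian window (default sigma 1.5, 11 voxels
#' wide), stabilizers `k1 = 0.01`, `k2 = 0.03`, reflective boundary
#' handling. The data range defaults to the intensity range of the
#' reference `b`.
#'
#' @param a test volume (array or [pet_volume])
#' @param b reference volume of the same shape
#' @param sigma Gaussian window standard deviation in voxels
#' @param win window width in voxels (odd)
#' @param k1,k2 stabilization constants
#' @param data_range dynamic range L; default `max(b) - min(b)`
#' @return scalar mean SSIM in [-1, 1]
#' @export
ssim <- function(a, b, sigma = 1.5, win = 11L, k1 = 0.01, k2 = 0.03,
                 data_range = NULL) {
  a <- vol_array(a); b <- vol_array(b)
  if (!all(dim(a) == dim(b))) stop("volumes must have the same shape")
  if (is.null(data_range)) data_range <- diff(range(b))
  if (data_range <= 0) data_range <- 1
  r <- (win - 1L) %/% 2L
  g <- function(x) cpp_gauss3d(x, rep(sigma, 3), as.integer(r))
  c1 <- (k1 * data_range)^2; c2 <- (k2 * data_range)^2
  mu_a <- g(a); mu_b <- g(b)
  va <- g(a * a) - mu_a^2
  vb <- g(b * b) - mu_b^2
  cab <- g(a * b) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + c1) * (2 * cab + c2)
  den <- (mu_a^2 + mu_b^2 + c1) * (va + vb + c2)
  mean(num / den)
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 log10(range(b)^2 / MSE)`; identical volumes return `Inf`.
#'
#' @inheritParams ssim
#' @return PSNR in dB
#' @export
psnr <- function(a, b) {
  a <- vol_array(a); b <- vol_array(b)
  if (!all(dim(a) == dim(b))) stop("volumes must have the same shape")
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  rng <- diff(range(b))
  10 * log10(rng^2 / mse)
}

#' Normalized root mean square error
#'
#' RMSE divided by the root mean square of the reference.
#'
#' @inheritParams ssim
#' @return nonnegative NRMSE
#' @export
nrmse <- function(a, b) {
  a <- vol_array(a); b <- vol_array(b)
  if (!all(dim(a) == dim(b))) stop("volumes must have the same shape")
  denom <- sqrt(mean(b^2))
  if (denom == 0) stop("zero-energy reference volume")
  sqrt(mean((a - b)^2)) / denom
}

vol_array <- function(v) if (inherits(v, "pet_volume")) v$voxels else
  as.array(v)

#' Fixed seeded slice-feature extractor
#'
#' Maps each axial slice of a volume to a feature vector through a fixed
#' random projection (seeded, cached per slice size) followed by tanh.
#' Feature-distance values computed with it are internally comparable
#' across runs of this package; they are not on the scale of
#' Inception-based implementations.
#'
#' @param seed projection seed
#' @param n_features feature dimension per slice
#' @return a `feature_extractor` object
#' @export
feature_extractor <- function(seed = 20240101L, n_features = 16L) {
  cache <- new.env(parent = emptyenv())
  projection <- function(p) {
    key <- as.character(p)
    if (is.null(cache[[key]])) {
      set.seed(as.integer(seed) + p %% 1000003L)
      cache[[key]] <- matrix(stats::rnorm(p * n_features, 0, 1 / sqrt(p)),
                             p, n_features)
    }
    cache[[key]]
  }
  structure(list(seed = as.integer(seed),
                 n_features = as.integer(n_features),
                 projection = projection),
            class = "feature_extractor")
}

#' Slice features of a set of volumes
#' @param vols list of volumes (equal shapes)
#' @param extractor a [feature_extractor()]
#' @return matrix with one row per axial slice
#' @export
extract_features <- function(vols, extractor = feature_extractor()) {
  if (!is.list(vols) || inherits(vols, "pet_volume")) vols <- list(vols)
  do.call(rbind, lapply(vols, function(v) {
    x <- vol_array(v)
    d <- dim(x)
    sl <- t(matrix(x, nrow = d[1] * d[2]))        # slices x pixels
    tanh(sl %*% extractor$projection(d[1] * d[2]))
  }))
}

sqrtm_psd <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Fréchet distance between Gaussian fits of two feature sets
#'
#' `||mu_a - mu_b||^2 + Tr(Sa + Sb - 2 (Sa^1/2 Sb Sa^1/2)^1/2)` with a
#' symmetric matrix square root; small negative rounding is clamped to 0.
#'
#' @param fa,fb feature matrices (rows = observations)
#' @return nonnegative distance
#' @export
fid_from_features <- function(fa, fb) {
  fa <- as.matrix(fa); fb <- as.matrix(fb)
  if (nrow(fa) < 2 || nrow(fb) < 2)
    stop("need >= 2 feature vectors per set for a covariance fit")
  mua <- colMeans(fa); mub <- colMeans(fb)
  sa <- stats::cov(fa); sb <- stats::cov(fb)
  if (any(!is.finite(sa)) || any(!is.finite(sb)))
    stop("non-finite feature covariance")
  ra <- sqrtm_psd(sa)
  cross <- sqrtm_psd(ra %*% sb %*% ra)
  val <- sum((mua - mub)^2) + sum(diag(sa)) + sum(diag(sb)) -
    2 * sum(diag(cross))
  max(val, 0)
}

#' Fréchet feature distance between two sets of volumes
#'
#' @param set_a,set_b lists of volumes (or single volumes) of equal shape
#' @param extractor a [feature_extractor()]
#' @return nonnegative distance
#' @export
fid <- function(set_a, set_b, extractor = feature_extractor()) {
  fid_from_features(extract_features(set_a, extractor),
                    extract_features(set_b, extractor))
}

#' Region-based SNR and CNR agreement metrics
#'
#' Per volume, SNR = mean(GM) / sd(WM) and CNR = (mean(GM) - mean(WM)) /
#' sd(WM). The reported metrics are relative absolute deviations of the
#' denoised volume's SNR and CNR from the reference's, so 0 means perfect
#' agreement and lower is better.
#'
#' @param dn denoised volume
#' @param sd reference standard-dose volume
#' @param labels integer label map providing GM (3) and WM (2) regions
#' @return list with `snr_metric`, `cnr_metric` and the raw per-volume
#'   `snr_dn`, `snr_sd`, `cnr_dn`, `cnr_sd`
#' @export
snr_cnr_metrics <- function(dn, sd, labels) {
  dn <- vol_array(dn); sd <- vol_array(sd)
  gm <- labels == phantom_labels[["gm"]]
  wm <- labels == phantom_labels[["wm"]]
  if (!any(gm) || !any(wm)) stop("GM or WM region is empty in the label map")
  reg <- function(v) {
    s <- stats::sd(v[wm])
    if (s == 0) stop("zero WM standard deviation")
    c(snr = mean(v[gm]) / s, cnr = (mean(v[gm]) - mean(v[wm])) / s)
  }
  a <- reg(dn); b <- reg(sd)
  list(snr_metric = abs(a[["snr"]] - b[["snr"]]) / abs(b[["snr"]]),
       cnr_metric = abs(a[["cnr"]] - b[["cnr"]]) / abs(b[["cnr"]]),
       snr_dn = a[["snr"]], snr_sd = b[["snr"]],
       cnr_dn = a[["cnr"]], cnr_sd = b[["cnr"]])
}

#' Image-quality report for a cohort of volume pairs
#'
#' Computes the six quality metrics per pair (SSIM, PSNR, NRMSE, feature
#' distance, SNR and CNR agreement) plus a cohort mean and standard
#' deviation row for each.
#'
#' @param dn_list list of denoised volumes
#' @param sd_list list of matching standard-dose volumes
#' @param labels_list list of label maps (or one shared map) for SNR/CNR
#' @param extractor a [feature_extractor()]
#' @return list with `per_pair` (data.frame) and `summary` (data.frame of
#'   mean and sd per metric)
#' @export
metric_report <- function(dn_list, sd_list, labels_list = NULL,
                          extractor = feature_extractor()) {
  n <- length(dn_list)
  stopifnot(length(sd_list) == n)
  rows <- lapply(seq_len(n), function(i) {
    dn <- dn_list[[i]]; sdv <- sd_list[[i]]
    row <- data.frame(pair = i,
                      ssim = ssim(dn, sdv),
                      psnr_db = psnr(dn, sdv),
                      nrmse = nrmse(dn, sdv),
                      fid = fid(dn, sdv, extractor),
                      snr_metric = NA_real_, cnr_metric = NA_real_)
    if (!is.null(labels_list)) {
      lab <- if (is.list(labels_list)) labels_list[[i]] else labels_list
      sc <- snr_cnr_metrics(dn, sdv, lab)
      row$snr_metric <- sc$snr_metric
      row$cnr_metric <- sc$cnr_metric
    }
    row
  })
  per_pair <- do.call(rbind, rows)
  metrics <- setdiff(names(per_pair), "pair")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_pair[[m]]), numeric(1)),
    sd = vapply(metrics, function(m) stats::sd(per_pair[[m]]), numeric(1)),
    row.names = NULL)
  list(per_pair = per_pair, summary = summary)
}
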