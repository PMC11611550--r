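#' Otsu threshold of a numeric vector
#'
#' Maximizes between-class variance over a 256-bin histogram; used as the
#' automated surrogate for manual background removal.
#'
#' @param x numeric values
#' @param nbins histogram bins
#' @return threshold value
#' @keywords internal
otsu_threshold <- function(x, nbins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- graphics::hist(x, breaks = seq(rng[1], rng[2], length.out = nbins + 1L),
                      plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, length(p))
  bcv[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  mids[which.max(bcv)]
}

#' Strip non-brain background from a volume
#'
#' Thresholds the volume (Otsu by default), keeps the largest connected
#' component, fills interior holes (low-uptake CSF must stay inside the
#' mask), zeroes everything outside, and returns the mask for audit.
#'
#' @param volume a [pet_volume] with nonnegative intensities
#' @param threshold_policy `"otsu"` or a numeric threshold
#' @return list with `volume` (masked) and `mask` (logical array)
#' @export
strip_background <- function(volume, threshold_policy = "otsu") {
  stopifnot(inherits(volume, "pet_volume"))
  v <- volume$voxels
  thr <- if (is.numeric(threshold_policy)) threshold_policy
         else otsu_threshold(as.vector(v))
  fg <- v > thr
  if (!any(fg)) {
    if (all(v > 0) && stats::sd(v) == 0) {
      # uniform positive volume: everything is foreground
      fg <- array(TRUE, dim(v))
    } else {
      stop("background stripping produced an empty mask")
    }
  }
  lab <- cpp_label3d(fg)
  tab <- tabulate(lab[lab > 0L])
  mask <- array(lab == which.max(tab), dim(v))
  # fill holes: background components not touching the grid boundary
  bg <- cpp_label3d(!mask)
  d <- dim(v)
  border_labels <- unique(c(bg[c(1, d[1]), , ], bg[, c(1, d[2]), ],
                            bg[, , c(1, d[3])]))
  hole <- !mask & !(bg %in% border_labels)
  mask <- mask | array(hole, d)
  out <- v
  out[!mask] <- 0
  list(volume = pet_volume(out, volume$spacing, volume$origin,
                           volume$orientation),
       mask = mask)
}

#' Normalize and rescale a volume to [-1, 1]
#'
#' Z-scores intensities by the in-mask mean and standard deviation (voxels
#' outside the mask stay at zero before rescaling), then maps the volume's
#' [min, max] affinely onto [-1, 1]. Every constant needed to invert the
#' chain exactly is stored in the returned record.
#'
#' @param volume a [pet_volume]
#' @param mask logical array of brain voxels; default: nonzero voxels
#' @return list with `volume` (rescaled) and `record` (a `preproc_record`)
#' @export
normalize_and_rescale <- function(volume, mask = NULL) {
  stopifnot(inherits(volume, "pet_volume"))
  v <- volume$voxels
  if (is.null(mask)) mask <- v != 0
  if (!any(mask)) stop("empty mask: nothing to normalize")
  mu <- mean(v[mask])
  sdv <- stats::sd(v[mask])
  if (!is.finite(sdv) || sdv == 0)
    stop("constant volume: standard deviation is zero")
  z <- array(0, dim(v))
  z[mask] <- (v[mask] - mu) / sdv
  zmin <- min(z); zmax <- max(z)
  if (zmax == zmin) stop("degenerate intensity range after normalization")
  y <- 2 * (z - zmin) / (zmax - zmin) - 1
  record <- structure(list(brain_mask = mask,
                           resample_shape = dim(v),
                           norm_mean = mu, norm_sd = sdv,
                           rescale_min = zmin, rescale_max = zmax,
                           study_scale_constant = max(v[mask])),
                      class = "preproc_record")
  list(volume = pet_volume(y, volume$spacing, volume$origin,
                           volume$orientation),
       record = record)
}

#' Invert the intensity rescaling
#'
#' Two modes. `"paper"` applies the approximate inversion used before SUV
#' computation on denoised outputs: add 1, halve, multiply by the study
#' scale constant (by default the volume's pre-normalization maximum, or a
#' cohort-average maximum when supplied). `"exact"` inverts the recorded
#' affine + z-score chain exactly (background voxels return to zero).
#'
#' @param volume a [pet_volume] with values in [-1, 1]
#' @param record the `preproc_record` from [normalize_and_rescale()]
#' @param mode `"paper"` or `"exact"`
#' @return a [pet_volume] on the original intensity scale
#' @export
invert_rescale <- function(volume, record, mode = c("paper", "exact")) {
  mode <- match.arg(mode)
  stopifnot(inherits(volume, "pet_volume"), inherits(record, "preproc_record"))
  y <- volume$voxels
  if (mode == "paper") {
    if (is.null(record$study_scale_constant))
      stop("record lacks study_scale_constant required for paper mode")
    out <- (y + 1) / 2 * record$study_scale_constant
  } else {
    need <- c("rescale_min", "rescale_max", "norm_mean", "norm_sd",
              "brain_mask")
    miss <- need[vapply(record[need], is.null, logical(1))]
    if (length(miss)) stop("record lacks fields for exact mode: ",
                           paste(miss, collapse = ", "))
    z <- (y + 1) / 2 * (record$rescale_max - record$rescale_min) +
      record$rescale_min
    out <- array(0, dim(y))
    out[record$brain_mask] <- z[record$brain_mask] * record$norm_sd +
      record$norm_mean
  }
  pet_volume(out, volume$spacing, volume$origin, volume$orientation)
}

#' Full preprocessing chain for one volume
#'
#' Applies, in this fixed order: background stripping, resampling to the
#' network grid, in-mask z-score normalization and [-1, 1] rescaling. The
#' record carries every constant needed for exact inversion; the mask is
#' re-derived on the resampled grid.
#'
#' @param volume a [pet_volume]
#' @param target_shape network input grid, default 128^3
#' @param threshold_policy passed to [strip_background()]
#' @return list with `volume`, `record`, `steps` (character log of the
#'   applied order)
#' @export
preprocess_volume <- function(volume, target_shape = c(128L, 128L, 128L),
                              threshold_policy = "otsu") {
  st <- strip_background(volume, threshold_policy)
  rs <- resample(st$volume, target_shape)
  # support of the resampled stripped volume (interpolation spreads the
  # brain edge; those voxels carry genuine signal and stay in-mask)
  nr <- normalize_and_rescale(rs, mask = rs$voxels != 0)
  nr$record$resample_shape <- as.integer(target_shape)
  list(volume = nr$volume, record = nr$record,
       steps = c("strip_background", "resample", "normalize", "rescale"))
}

#' Serialize a preprocessing record to JSON
#'
#' The brain mask is stored as run-length encoded indices so the sidecar
#' stays compact and exactly invertible.
#'
#' @param record a `preproc_record`
#' @param path output JSON path
#' @return the path, invisibly
#' @export
write_preproc_record <- function(record, path) {
  rl <- rle(as.vector(record$brain_mask))
  payload <- list(resample_shape = record$resample_shape,
                  norm_mean = record$norm_mean, norm_sd = record$norm_sd,
                  rescale_min = record$rescale_min,
                  rescale_max = record$rescale_max,
                  study_scale_constant = record$study_scale_constant,
                  mask_rle_lengths = rl$lengths, mask_rle_values = rl$values,
                  mask_dim = dim(record$brain_mask))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a preprocessing record written by [write_preproc_record()]
#' @param path JSON path
#' @return a `preproc_record`
#' @export
read_preproc_record <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  mask <- array(inverse.rle(structure(list(lengths = p$mask_rle_lengths,
                                           values = p$mask_rle_values),
                                      class = "rle")), p$mask_dim)
  structure(list(brain_mask = mask, resample_shape = p$resample_shape,
                 norm_mean = p$norm_mean, norm_sd = p$norm_sd,
                 rescale_min = p$rescale_min, rescale_max = p$rescale_max,
                 study_scale_constant = p$study_scale_constant),
            class = "preproc_record")
}
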