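#' Scan metadata for SUV computation
#'
#' @param body_weight_kg patient body weight in kg
#' @param injected_dose_MBq net injected tracer dose in MBq
#' @return a `scan_meta` list
#' @export
scan_meta <- function(body_weight_kg, injected_dose_MBq) {
  if (!is.numeric(body_weight_kg) || body_weight_kg <= 0)
    stop("body weight must be positive")
  if (!is.numeric(injected_dose_MBq) || injected_dose_MBq <= 0)
    stop("injected dose must be positive")
  structure(list(body_weight_kg = body_weight_kg,
                 injected_dose_MBq = injected_dose_MBq),
            class = "scan_meta")
}

#' Voxel-wise standardized uptake value map
#'
#' SUV = C x BW / Dose in the standard g/mL convention: activity
#' concentration in kBq/mL, body weight in kg, dose in MBq (the kBq -> MBq
#' and kg -> g factors cancel).
#'
#' @param volume_activity a [pet_volume] of activity concentration (kBq/mL)
#' @param meta a [scan_meta]
#' @return a [pet_volume] of unitless SUV
#' @export
suv_map <- function(volume_activity, meta) {
  stopifnot(inherits(volume_activity, "pet_volume"),
            inherits(meta, "scan_meta"))
  pet_volume(volume_activity$voxels * meta$body_weight_kg /
               meta$injected_dose_MBq,
             volume_activity$spacing, volume_activity$origin,
             volume_activity$orientation)
}

#' Per-region relative SUV (SUVr) table
#'
#' Region mean SUV divided by the reference region's mean; the reference
#' row has SUVr exactly 1. The reference is the cerebellum for epilepsy
#' analyses and the occipital lobe for dementia / healthy-volunteer
#' analyses.
#'
#' @param suv a [pet_volume] of SUV values
#' @param labels integer label map on the same grid
#' @param reference region name (see [phantom_labels]) or integer label
#' @return data.frame with columns `region`, `label`, `n_vox`, `mean_suv`,
#'   `suvr`
#' @export
suvr <- function(suv, labels, reference = "cerebellum") {
  stopifnot(inherits(suv, "pet_volume"))
  v <- suv$voxels
  ref_label <- if (is.character(reference)) {
    if (!reference %in% names(phantom_labels))
      stop("unknown reference region: ", reference)
    phantom_labels[[reference]]
  } else as.integer(reference)
  present <- sort(unique(as.vector(labels)))
  present <- present[present > 0L]
  if (!ref_label %in% present || !any(labels == ref_label))
    stop("reference region (label ", ref_label, ") is empty")
  ref_mean <- mean(v[labels == ref_label])
  if (ref_mean == 0) stop("reference region has zero mean SUV")
  name_of <- function(l) {
    nm <- names(phantom_labels)[match(l, phantom_labels)]
    ifelse(is.na(nm), sprintf("lesion_%d", l - lesion_label_base + 1L), nm)
  }
  rows <- lapply(present, function(l) {
    sel <- labels == l
    data.frame(region = name_of(l), label = l, n_vox = sum(sel),
               mean_suv = mean(v[sel]), suvr = mean(v[sel]) / ref_mean,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Standardized asymmetry-index (zAI) map
#'
#' For each in-mask voxel with a positive left+right intensity sum,
#' AI = 200 (I - I_mirror) / (I + I_mirror), where the mirror reflects
#' about the midsagittal plane (first-axis index reflection; inputs are
#' assumed to sit in a left-right-symmetric frame). The AI map is then
#' z-scored against its own in-mask mean and standard deviation. A
#' perfectly symmetric volume (zero AI variance) returns an all-zero map.
#'
#' @param suv a [pet_volume] (typically a smoothed SUV map)
#' @param brain_mask logical array of brain voxels; default: positive
#'   voxels
#' @return a [pet_volume] of zAI values with attribute `ai` (the raw
#'   asymmetry index map)
#' @export
zai_map <- function(suv, brain_mask = NULL) {
  stopifnot(inherits(suv, "pet_volume"))
  v <- suv$voxels
  if (is.null(brain_mask)) brain_mask <- v > 0
  m <- mirror_x(v)
  mask_m <- brain_mask & mirror_x(brain_mask)
  denom <- v + m
  valid <- mask_m & denom > 0
  ai <- array(0, dim(v))
  ai[valid] <- 200 * (v[valid] - m[valid]) / denom[valid]
  mu <- mean(ai[valid])
  s <- stats::sd(ai[valid])
  z <- array(0, dim(v))
  # an (effectively) symmetric volume has zero AI variance up to float
  # noise; z-scoring would amplify rounding error, so return the zero map
  if (is.finite(s) && s > 1e-6) z[valid] <- (ai[valid] - mu) / s
  out <- pet_volume(z, suv$spacing, suv$origin, suv$orientation)
  attr(out, "ai") <- ai
  out
}

#' Hypometabolic regions of a zAI map
#'
#' Connected components (6-connectivity) of voxels below the z threshold,
#' with their volumes in mm^3. An empty result is allowed.
#'
#' @param zai a [pet_volume] of zAI values
#' @param threshold z cutoff, default -2 (the conventional two-sigma rule)
#' @return list with `labels` (integer component map) and `components`
#'   (data.frame: `component`, `n_vox`, `volume_mm3`)
#' @export
hypometabolic_roi <- function(zai, threshold = -2) {
  stopifnot(inherits(zai, "pet_volume"))
  sel <- zai$voxels < threshold
  if (!any(sel)) {
    return(list(labels = array(0L, dim(zai$voxels)),
                components = data.frame(component = integer(0),
                                        n_vox = integer(0),
                                        volume_mm3 = numeric(0))))
  }
  lab <- cpp_label3d(sel)
  ids <- seq_len(max(lab))
  nv <- tabulate(lab[lab > 0L], nbins = max(lab))
  vox_mm3 <- prod(zai$spacing)
  list(labels = lab,
       components = data.frame(component = ids, n_vox = nv,
                               volume_mm3 = nv * vox_mm3))
}

#' Full quantification of one volume
#'
#' Optionally inverts the [-1, 1] rescaling (the approximate
#' inversion), computes the SUV map, smooths it with a 2 mm FWHM Gaussian,
#' and derives the per-region SUVr table, the zAI map and the hypometabolic
#' components.
#'
#' @param volume a [pet_volume]; if `record` is supplied the volume is
#'   assumed rescaled to [-1, 1] and is inverted first
#' @param meta a [scan_meta]
#' @param labels integer label map on the volume's grid
#' @param reference SUVr reference region
#' @param record optional `preproc_record` for inversion
#' @param smooth_fwhm_mm Gaussian FWHM for SUV smoothing (default 2)
#' @param zai_threshold hypometabolism cutoff (default -2)
#' @return list with `suv`, `suvr` (data.frame), `zai`, `roi`
#' @export
quantify_volume <- function(volume, meta, labels, reference = "cerebellum",
                            record = NULL, smooth_fwhm_mm = 2,
                            zai_threshold = -2) {
  if (!is.null(record)) volume <- invert_rescale(volume, record, "paper")
  suv <- suv_map(volume, meta)
  suv_s <- smooth_volume(suv, smooth_fwhm_mm)
  tab <- suvr(suv_s, labels, reference)
  zai <- zai_map(suv_s, brain_mask = labels > 0L)
  roi <- hypometabolic_roi(zai, zai_threshold)
  list(suv = suv_s, suvr = tab, zai = zai, roi = roi)
}

#' Cohort comparison of denoised against standard-dose quantification
#'
#' For each region, compares the denoised and standard-dose SUVr values
#' across subjects with the two-sided Mann-Whitney U test (significance at
#' p < 0.05) and reports the per-region absolute percent SUVr deviation
#' (cohort mean and sd).
#'
#' @param dn_reports data.frame with columns `subject_id`, `region`,
#'   `suvr` for the denoised arm
#' @param sd_reports same for the standard-dose arm
#' @return data.frame with one row per region: `region`, `n`, `U`, `p`,
#'   `significant`, `pct_dev_mean`, `pct_dev_sd`
#' @export
compare_cohort <- function(dn_reports, sd_reports) {
  need <- c("subject_id", "region", "suvr")
  if (!all(need %in% names(dn_reports)) || !all(need %in% names(sd_reports)))
    stop("reports need columns subject_id, region, suvr")
  regions <- intersect(unique(dn_reports$region), unique(sd_reports$region))
  rows <- lapply(regions, function(r) {
    dnv <- dn_reports[dn_reports$region == r, ]
    sdv <- sd_reports[sd_reports$region == r, ]
    m <- merge(dnv[, c("subject_id", "suvr")],
               sdv[, c("subject_id", "suvr")], by = "subject_id",
               suffixes = c("_dn", "_sd"))
    if (nrow(m) < 3) stop("need >= 3 subjects per arm (region ", r, ")")
    wt <- suppressWarnings(stats::wilcox.test(m$suvr_dn, m$suvr_sd,
                                              alternative = "two.sided"))
    pd <- 100 * abs(m$suvr_dn - m$suvr_sd) / abs(m$suvr_sd)
    data.frame(region = r, n = nrow(m), U = unname(wt$statistic),
               p = wt$p.value, significant = wt$p.value < 0.05,
               pct_dev_mean = mean(pd), pct_dev_sd = stats::sd(pd),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mann-Whitney U statistic and exact two-sided p value
#'
#' Thin, explicit wrapper used for rank-statistic checks: returns the U
#' statistic of x against y and the two-sided p value.
#'
#' @param x,y numeric samples
#' @return list with `U` and `p`
#' @export
mann_whitney_u <- function(x, y) {
  wt <- suppressWarnings(stats::wilcox.test(x, y,
                                            alternative = "two.sided"))
  list(U = unname(wt$statistic), p = wt$p.value)
}
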