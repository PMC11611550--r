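#' Digital brain phantom specification
#'
#' Describes a nested-ellipsoid brain phantom: a CSF core, a WM shell and a
#' GM rim with textbook FDG contrast (GM:WM:CSF = 4:1:0.3 by default),
#' named cortical/subcortical sub-regions, optional focal lesions and
#' left/right asymmetry, plus the counting statistics of a standard-dose
#' acquisition and the binomial thinning fraction of the low-dose arm.
#'
#' @param grid_shape integer triple of voxels (default 64^3)
#' @param voxel_size_mm positive triple, mm (default 2)
#' @param activity_ratio_gm_wm_csf positive triple of unitless activity
#'   ratios for gray matter, white matter and CSF
#' @param total_counts_standard expected total detected events at standard
#'   dose
#' @param thinning_fraction probability that a detected event is retained in
#'   the low-dose arm, in (0, 1]; 0.10 emulates reconstructing 10% of the
#'   acquisition
#' @param lesions list of lesions, each `list(center = voxel triple,
#'   radius_mm = r, multiplier = m)`
#' @param psf_fwhm_mm Gaussian point-spread FWHM applied as a reconstruction
#'   proxy (mm)
#' @param asymmetry optional activity multiplier applied to the left
#'   hemisphere (x below the midsagittal plane); `NULL` for none
#' @param brain_scale overall size factor of the brain ellipsoids (cohort
#'   jitter)
#' @param seed integer seed driving all randomness derived from this spec
#' @return an object of class `phantom_spec`
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         voxel_size_mm = c(2, 2, 2),
                         activity_ratio_gm_wm_csf = c(4, 1, 0.3),
                         total_counts_standard = 5e6,
                         thinning_fraction = 0.10,
                         lesions = list(),
                         psf_fwhm_mm = 4,
                         asymmetry = NULL,
                         brain_scale = 1,
                         seed = 1L) {
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  voxel_size_mm <- as.numeric(rep_len(voxel_size_mm, 3L))
  if (any(grid_shape < 8L)) stop("grid_shape must be at least 8 voxels per axis")
  if (any(voxel_size_mm <= 0)) stop("voxel sizes must be strictly positive")
  if (any(activity_ratio_gm_wm_csf <= 0))
    stop("activity ratios must be strictly positive")
  if (!is.numeric(thinning_fraction) || thinning_fraction <= 0 ||
      thinning_fraction > 1)
    stop("thinning_fraction must lie in (0, 1]")
  if (total_counts_standard <= 0) stop("total_counts_standard must be positive")
  if (psf_fwhm_mm < 0) stop("psf_fwhm_mm must be nonnegative")
  half_extent <- min(grid_shape * voxel_size_mm) / 2
  for (i in seq_along(lesions)) {
    le <- lesions[[i]]
    if (!all(c("center", "radius_mm", "multiplier") %in% names(le)))
      stop("lesion ", i, " needs fields center, radius_mm, multiplier")
    if (le$radius_mm >= half_extent)
      stop("lesion ", i, " radius exceeds half the grid extent")
    if (le$multiplier <= 0) stop("lesion ", i, " multiplier must be positive")
  }
  if (!is.null(asymmetry) && (!is.numeric(asymmetry) || asymmetry <= 0))
    stop("asymmetry must be a positive multiplier or NULL")
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 activity_ratio_gm_wm_csf = activity_ratio_gm_wm_csf,
                 total_counts_standard = total_counts_standard,
                 thinning_fraction = thinning_fraction, lesions = lesions,
                 psf_fwhm_mm = psf_fwhm_mm, asymmetry = asymmetry,
                 brain_scale = brain_scale, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Integer label codes used by phantom label maps
#' @export
phantom_labels <- c(background = 0L, csf = 1L, wm = 2L, gm = 3L,
                    cerebellum = 4L, occipital = 5L, hippocampus = 6L,
                    temporal = 7L, frontal = 8L, parietal = 9L, insula = 10L,
                    caudate = 11L, putamen = 12L, thalamus = 13L)

#' First integer label assigned to lesions
#' @export
lesion_label_base <- 100L

#' Build the phantom activity volume and label map
#'
#' Constructs the nested-ellipsoid brain, carves named sub-regions out of
#' the gray-matter rim and white matter, applies lesion multipliers and the
#' hemispheric asymmetry factor, and returns the noise-free activity
#' distribution with its label map. Deterministic (no randomness is used at
#' this stage).
#'
#' @param spec a [phantom_spec]
#' @return list with elements `activity` (a [pet_volume]) and `labels`
#'   (integer array of the same shape, with attributes `region_table` and
#'   `mid_plane`)
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  sp <- spec$voxel_size_mm
  ctr <- (d + 1) / 2
  # voxel-centre coordinates in mm relative to the grid centre
  cx <- (seq_len(d[1]) - ctr[1]) * sp[1]
  cy <- (seq_len(d[2]) - ctr[2]) * sp[2]
  cz <- (seq_len(d[3]) - ctr[3]) * sp[3]
  X <- array(cx, d)
  Y <- array(rep(cy, each = d[1]), d)
  Z <- array(rep(cz, each = d[1] * d[2]), d)

  semi <- 0.42 * d * sp / 2 * spec$brain_scale     # outer brain semi-axes, mm
  r <- sqrt((X / semi[1])^2 + (Y / semi[2])^2 + (Z / semi[3])^2)

  lab <- array(phantom_labels[["background"]], d)
  lab[r <= 1] <- phantom_labels[["gm"]]            # cortical rim by default
  lab[r <= 0.82] <- phantom_labels[["wm"]]
  lab[r <= 0.30] <- phantom_labels[["csf"]]        # ventricular core

  rim <- lab == phantom_labels[["gm"]]
  zr <- Z / semi[3]; yr <- Y / semi[2]; xr <- X / semi[1]
  # named cortical territories carved out of the rim (symmetric in x)
  cereb <- rim & zr < -0.55 & yr < -0.15
  occip <- rim & !cereb & yr < -0.55
  front <- rim & yr > 0.45
  pari  <- rim & !front & zr > 0.55
  temp  <- rim & !cereb & !occip & !front & !pari & abs(xr) > 0.55 & zr < 0.1
  insu  <- rim & !cereb & !occip & !front & !pari & !temp &
           abs(xr) > 0.6 & abs(zr) <= 0.35 & abs(yr) <= 0.35
  lab[cereb] <- phantom_labels[["cerebellum"]]
  lab[occip] <- phantom_labels[["occipital"]]
  lab[front] <- phantom_labels[["frontal"]]
  lab[pari]  <- phantom_labels[["parietal"]]
  lab[temp]  <- phantom_labels[["temporal"]]
  lab[insu]  <- phantom_labels[["insula"]]

  # paired deep structures inside white matter (gray-matter activity)
  deep <- function(center_frac, semi_mm, code) {
    for (s in c(-1, 1)) {
      cc <- center_frac * semi; cc[1] <- s * abs(cc[1])
      rr <- sqrt(((X - cc[1]) / semi_mm[1])^2 + ((Y - cc[2]) / semi_mm[2])^2 +
                 ((Z - cc[3]) / semi_mm[3])^2)
      sel <- rr <= 1 & lab == phantom_labels[["wm"]]
      lab[sel] <<- code
    }
  }
  deep(c(0.28, 0.25, 0.10), c(5, 9, 6),  phantom_labels[["caudate"]])
  deep(c(0.50, 0.05, 0.00), c(6, 10, 7), phantom_labels[["putamen"]])
  deep(c(0.22, -0.18, 0.00), c(7, 8, 6), phantom_labels[["thalamus"]])
  deep(c(0.55, -0.30, -0.35), c(6, 10, 5), phantom_labels[["hippocampus"]])

  ratios <- spec$activity_ratio_gm_wm_csf
  gm_like <- phantom_labels[c("gm", "cerebellum", "occipital", "hippocampus",
                              "temporal", "frontal", "parietal", "insula",
                              "caudate", "putamen", "thalamus")]
  act <- array(0, d)
  act[lab %in% gm_like] <- ratios[1]
  act[lab == phantom_labels[["wm"]]] <- ratios[2]
  act[lab == phantom_labels[["csf"]]] <- ratios[3]

  brain <- lab > 0L
  # lesions: spherical activity multipliers, must lie inside the brain
  for (i in seq_along(spec$lesions)) {
    le <- spec$lesions[[i]]
    cc <- (as.numeric(le$center) - ctr) * sp
    rr <- sqrt((X - cc[1])^2 + (Y - cc[2])^2 + (Z - cc[3])^2)
    sel <- rr <= le$radius_mm
    if (!any(sel & brain))
      stop("lesion ", i, " (center ", paste(le$center, collapse = ","),
           ") lies outside the brain mask")
    sel <- sel & brain
    act[sel] <- act[sel] * le$multiplier
    lab[sel] <- lesion_label_base + i - 1L
  }

  if (!is.null(spec$asymmetry)) {
    left <- X < 0
    act[left & brain] <- act[left & brain] * spec$asymmetry
  }

  attr(lab, "region_table") <- data.frame(
    label = unname(phantom_labels), name = names(phantom_labels),
    stringsAsFactors = FALSE)
  attr(lab, "mid_plane") <- (d[1] + 1) / 2
  list(activity = pet_volume(act, spacing = sp), labels = lab)
}

#' Simulate the standard-dose acquisition
#'
#' Normalizes the activity map to an expected-count map with total
#' `total_counts_standard`, draws independent Poisson counts per voxel, and
#' applies a Gaussian point-spread blur as a reconstruction proxy. The
#' pre-blur integer counts are retained in the `counts` attribute so the
#' low-dose arm can thin the same detected events.
#'
#' @param activity a [pet_volume] of nonnegative activity
#' @param spec a [phantom_spec]
#' @param seed RNG seed (defaults to `spec$seed`)
#' @return a [pet_volume] of blurred counts with attribute `counts`
#' @export
simulate_standard_dose <- function(activity, spec, seed = spec$seed) {
  stopifnot(inherits(activity, "pet_volume"))
  a <- activity$voxels
  if (any(a < 0)) stop("activity must be nonnegative")
  tot <- sum(a)
  if (tot <= 0) stop("activity is identically zero; nothing to simulate")
  lambda <- a / tot * spec$total_counts_standard
  set.seed(as.integer(seed))
  counts <- array(stats::rpois(length(lambda), lambda), dim(a))
  out <- pet_volume(counts, activity$spacing, activity$origin,
                    activity$orientation)
  if (spec$psf_fwhm_mm > 0) out <- smooth_volume(out, spec$psf_fwhm_mm)
  attr(out, "counts") <- counts
  out
}

#' Simulate the low-dose acquisition by binomial count thinning
#'
#' Each detected event of the standard-dose scan is independently retained
#' with probability `thinning_fraction` — the count-statistics analogue of
#' reconstructing a 10% subset of the acquisition frames. The same PSF blur
#' is then applied.
#'
#' @param standard_counts output of [simulate_standard_dose()] (its `counts`
#'   attribute holds the pre-blur events)
#' @param spec a [phantom_spec]
#' @param seed RNG seed (defaults to `spec$seed + 1`)
#' @return a [pet_volume] of blurred thinned counts with attribute `counts`
#' @export
simulate_low_dose <- function(standard_counts, spec, seed = spec$seed + 1L) {
  stopifnot(inherits(standard_counts, "pet_volume"))
  p <- spec$thinning_fraction
  if (p <= 0 || p > 1) stop("thinning_fraction must lie in (0, 1]")
  counts <- attr(standard_counts, "counts")
  if (is.null(counts)) counts <- standard_counts$voxels
  if (any(counts < 0) || any(counts != round(counts)))
    stop("standard counts must be nonnegative integers (pre-blur counts)")
  if (p == 1) {
    thin <- counts
  } else {
    set.seed(as.integer(seed))
    thin <- array(stats::rbinom(length(counts), size = as.integer(counts),
                                prob = p), dim(counts))
  }
  out <- pet_volume(thin, standard_counts$spacing, standard_counts$origin,
                    standard_counts$orientation)
  if (spec$psf_fwhm_mm > 0) out <- smooth_volume(out, spec$psf_fwhm_mm)
  attr(out, "counts") <- thin
  out
}

#' Generate a cohort of paired low-/standard-dose phantom scans
#'
#' Draws per-subject variation in brain size, tissue contrast and lesion
#' presence, simulates both dose arms, assigns injected dose and body
#' weight from the configured ranges, and (optionally) writes NIfTI volumes
#' plus a CSV manifest.
#'
#' @param n_subjects number of subjects (>= 1)
#' @param base_spec a [phantom_spec] giving the cohort's nominal conditions
#' @param jitter list of variation knobs: `size_sd` (relative sd of brain
#'   scale), `ratio_sd` (relative sd of the GM activity ratio),
#'   `lesion_prob` (probability of one 0.6x temporal lesion),
#'   `dose_range_MBq`, `weight_range_kg`
#' @param dir output directory for NIfTI + manifest, or `NULL` to keep the
#'   cohort in memory only
#' @param seed cohort seed
#' @return list with `subjects` (each `list(pair, labels, meta)` where
#'   `pair` is `list(ld, sd)`) and `manifest` (data.frame)
#' @export
make_cohort <- function(n_subjects, base_spec,
                        jitter = list(size_sd = 0.04, ratio_sd = 0.05,
                                      lesion_prob = 0,
                                      dose_range_MBq = c(150, 370),
                                      weight_range_kg = c(50, 90)),
                        dir = NULL, seed = base_spec$seed) {
  stopifnot(n_subjects >= 1, inherits(base_spec, "phantom_spec"))
  jd <- list(size_sd = 0.04, ratio_sd = 0.05, lesion_prob = 0,
             dose_range_MBq = c(150, 370), weight_range_kg = c(50, 90))
  jd[names(jitter)] <- jitter
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(2^20, n_subjects)
  subjects <- vector("list", n_subjects)
  rows <- vector("list", n_subjects)
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n_subjects)) {
    set.seed(sub_seeds[i])
    scale_i <- base_spec$brain_scale * (1 + stats::rnorm(1, 0, jd$size_sd))
    ratios <- base_spec$activity_ratio_gm_wm_csf
    ratios[1] <- ratios[1] * (1 + stats::rnorm(1, 0, jd$ratio_sd))
    lesions <- base_spec$lesions
    if (stats::runif(1) < jd$lesion_prob) {
      ctr <- (base_spec$grid_shape + 1) / 2
      off <- 0.55 * 0.42 * base_spec$grid_shape[1] / 2
      lesions <- c(lesions, list(list(
        center = c(ctr[1] - off, ctr[2] - 0.2 * ctr[2], ctr[3] - 0.3 * ctr[3]),
        radius_mm = 8, multiplier = 0.6)))
    }
    dose <- stats::runif(1, jd$dose_range_MBq[1], jd$dose_range_MBq[2])
    weight <- stats::runif(1, jd$weight_range_kg[1], jd$weight_range_kg[2])
    spec_i <- phantom_spec(
      grid_shape = base_spec$grid_shape,
      voxel_size_mm = base_spec$voxel_size_mm,
      activity_ratio_gm_wm_csf = ratios,
      total_counts_standard = base_spec$total_counts_standard,
      thinning_fraction = base_spec$thinning_fraction,
      lesions = lesions, psf_fwhm_mm = base_spec$psf_fwhm_mm,
      asymmetry = base_spec$asymmetry, brain_scale = scale_i,
      seed = sub_seeds[i])
    ph <- build_phantom(spec_i)
    sd_vol <- simulate_standard_dose(ph$activity, spec_i)
    ld_vol <- simulate_low_dose(sd_vol, spec_i)
    meta <- list(subject_id = sprintf("sub-%03d", i), dose_MBq = dose,
                 weight_kg = weight, seed = sub_seeds[i])
    paths <- list(ld = NA_character_, sd = NA_character_,
                  labels = NA_character_)
    if (!is.null(dir)) {
      paths$ld <- file.path(dir, sprintf("%s_ld.nii.gz", meta$subject_id))
      paths$sd <- file.path(dir, sprintf("%s_sd.nii.gz", meta$subject_id))
      paths$labels <- file.path(dir, sprintf("%s_labels.nii.gz",
                                             meta$subject_id))
      write_volume(ld_vol, paths$ld)
      write_volume(sd_vol, paths$sd)
      write_volume(pet_volume(array(as.numeric(ph$labels),
                                    dim(ph$labels)),
                              spacing = spec_i$voxel_size_mm), paths$labels)
    }
    subjects[[i]] <- list(pair = list(ld = ld_vol, sd = sd_vol),
                          labels = ph$labels, meta = meta, spec = spec_i)
    rows[[i]] <- data.frame(subject_id = meta$subject_id,
                            dose_MBq = dose, weight_kg = weight,
                            seed = sub_seeds[i], path_ld = paths$ld,
                            path_sd = paths$sd, path_labels = paths$labels,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  list(subjects = subjects, manifest = manifest)
}
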