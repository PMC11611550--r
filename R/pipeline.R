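#' Default pipeline configuration
#'
#' Flat key/value configuration for the end-to-end pipeline. The `"paper"`
#' profile uses the full-scale training recipe (128^3 grids, 400 epochs);
#' the `"smoke"` profile is the scaled-down desk recipe (32^3, 30 epochs).
#'
#' @param profile `"smoke"` or `"paper"`
#' @return named list of configuration values
#' @export
pipeline_config <- function(profile = c("smoke", "paper")) {
  profile <- match.arg(profile)
  smoke <- profile == "smoke"
  list(profile = profile,
       seed = 1L,
       n_subjects = if (smoke) 10L else 114L,
       grid_shape = if (smoke) 32L else 64L,
       voxel_size_mm = if (smoke) 4 else 2,
       total_counts_standard = if (smoke) 2e6 else 5e7,
       thinning_fraction = 0.10,
       psf_fwhm_mm = 4,
       lesion_prob = 0,
       target_shape = if (smoke) 32L else 128L,
       epochs = if (smoke) 30L else 400L,
       lr = if (smoke) 1e-3 else 1e-4,
       adversarial_form = "BCE",
       lambda1 = 1, lambda2 = 100, fid_weight = 0,
       discriminator_enabled = TRUE,
       attention_type = "ssab",
       reference_region = "cerebellum",
       stages = c("simulate", "preprocess", "train", "denoise", "evaluate",
                  "quantify"))
}

#' Read a pipeline configuration file
#'
#' YAML (flat keys); missing keys fall back to the profile defaults.
#'
#' @param path YAML file
#' @return configuration list
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- pipeline_config(profile = user$profile %||% "smoke")
  base[names(user)] <- user
  base
}

pipeline_train_config <- function(cfg) {
  if (cfg$profile == "paper") {
    gen <- generator_spec(attention_type = cfg$attention_type)
    disc <- discriminator_spec(enabled = isTRUE(cfg$discriminator_enabled))
  } else {
    gen <- generator_spec(levels = 2L, base_channels = 8L,
                          ssab_positions = 2L,
                          attention_type = cfg$attention_type,
                          ssab_cfg = ssab_config(sa_reduction = 8L,
                                                 ca_reduction = 8L))
    disc <- discriminator_spec(layers = 2L, base_channels = 8L,
                               enabled = isTRUE(cfg$discriminator_enabled))
  }
  train_config(profile = cfg$profile,
               adversarial_form = cfg$adversarial_form,
               epochs = as.integer(cfg$epochs), lr = cfg$lr,
               seed = as.integer(cfg$seed),
               weights = loss_weights(cfg$lambda1, cfg$lambda2,
                                      cfg$fid_weight),
               gen_spec = gen, disc_spec = disc)
}

#' Run the full pipeline
#'
#' Executes, in order, the requested stages: phantom cohort simulation,
#' preprocessing, training, denoising of the held-out test subjects,
#' image-quality evaluation and SUV/SUVr/zAI quantification with the
#' cohort comparison. Each stage writes its outputs under `out_dir` and the
#' run manifest records configuration, seeds, stage timestamps and paths.
#'
#' @param config_path path to a YAML configuration (see
#'   [pipeline_config()]), or a configuration list
#' @param out_dir output directory
#' @param verbose print stage progress
#' @return the run manifest (list), invisibly; written to
#'   `out_dir/manifest.json`
#' @export
run_pipeline <- function(config_path, out_dir = tempfile("petgan_run_"),
                         verbose = TRUE) {
  cfg <- if (is.character(config_path)) read_pipeline_config(config_path)
         else config_path
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = cfg[setdiff(names(cfg), "stages")],
                   stages = list(),
                   version = as.character(utils::packageVersion("petgan")))
  say <- function(...) if (verbose) message(...)
  stamp <- function(stage, paths = list()) {
    manifest$stages[[stage]] <<- list(time = format(Sys.time(),
                                                    "%Y-%m-%dT%H:%M:%S"),
                                      paths = paths)
  }
  stages <- cfg$stages

  say("stage: simulate")
  base_spec <- phantom_spec(grid_shape = rep(cfg$grid_shape, 3L),
                            voxel_size_mm = rep(cfg$voxel_size_mm, 3L),
                            total_counts_standard = cfg$total_counts_standard,
                            thinning_fraction = cfg$thinning_fraction,
                            psf_fwhm_mm = cfg$psf_fwhm_mm,
                            seed = as.integer(cfg$seed))
  sim_dir <- file.path(out_dir, "simulated")
  cohort <- make_cohort(cfg$n_subjects, base_spec,
                        jitter = list(lesion_prob = cfg$lesion_prob),
                        dir = if ("simulate" %in% stages) sim_dir else NULL,
                        seed = as.integer(cfg$seed))
  stamp("simulate", list(dir = sim_dir))

  say("stage: preprocess")
  shape <- rep(as.integer(cfg$target_shape), 3L)
  prep <- lapply(cohort$subjects, function(s) {
    ld <- preprocess_volume(s$pair$ld, shape)
    sd <- preprocess_volume(s$pair$sd, shape)
    list(ld = ld$volume, sd = sd$volume, ld_record = ld$record,
         sd_record = sd$record)
  })
  stamp("preprocess")

  tc <- pipeline_train_config(cfg)
  split <- split_dataset(length(prep), tc$split, tc$seed)
  result <- NULL
  if ("train" %in% stages) {
    say("stage: train")
    result <- train(prep, tc, split = split, verbose = verbose)
    ckpt_path <- file.path(out_dir, "checkpoint.rds")
    save_checkpoint(result$checkpoint, ckpt_path)
    utils::write.csv(result$history, file.path(out_dir, "history.csv"),
                     row.names = FALSE)
    stamp("train", list(checkpoint = ckpt_path,
                        history = file.path(out_dir, "history.csv")))
  }

  report <- NULL
  quant <- NULL
  if (!is.null(result) && "denoise" %in% stages) {
    say("stage: denoise")
    dn_dir <- file.path(out_dir, "denoised")
    dir.create(dn_dir, showWarnings = FALSE)
    # all held-out subjects (validation + test) are denoised so the cohort
    # comparison has enough arms at smoke scale
    test_idx <- sort(c(split$val, split$test))
    dn <- lapply(test_idx, function(i)
      denoise(prep[[i]]$ld, result$checkpoint))
    for (k in seq_along(test_idx))
      write_volume(dn[[k]], file.path(dn_dir,
        sprintf("%s_dn.nii.gz", cohort$subjects[[test_idx[k]]]$meta$subject_id)))
    stamp("denoise", list(dir = dn_dir))

    if ("evaluate" %in% stages) {
      say("stage: evaluate")
      labels_rs <- lapply(test_idx, function(i)
        resample_labels(cohort$subjects[[i]]$labels,
                        cohort$subjects[[i]]$spec$voxel_size_mm, shape))
      report <- metric_report(dn, lapply(test_idx, function(i) prep[[i]]$sd),
                              labels_rs)
      utils::write.csv(report$per_pair,
                       file.path(out_dir, "metrics_per_pair.csv"),
                       row.names = FALSE)
      utils::write.csv(report$summary,
                       file.path(out_dir, "metrics_summary.csv"),
                       row.names = FALSE)
      stamp("evaluate", list(per_pair = file.path(out_dir,
                                                  "metrics_per_pair.csv")))
    }

    if ("quantify" %in% stages) {
      say("stage: quantify")
      qrows <- function(vol_list, which_arm) {
        do.call(rbind, lapply(seq_along(test_idx), function(k) {
          i <- test_idx[k]
          s <- cohort$subjects[[i]]
          meta <- scan_meta(s$meta$weight_kg, s$meta$dose_MBq)
          rec <- prep[[i]]$sd_record
          lab <- resample_labels(s$labels, s$spec$voxel_size_mm, shape)
          q <- quantify_volume(vol_list[[k]], meta, lab,
                               cfg$reference_region, record = rec)
          cbind(subject_id = s$meta$subject_id, q$suvr)
        }))
      }
      sd_tab <- qrows(lapply(test_idx, function(i) prep[[i]]$sd), "sd")
      dn_tab <- qrows(dn, "dn")
      quant <- compare_cohort(dn_tab, sd_tab)
      utils::write.csv(quant, file.path(out_dir, "quantification.csv"),
                       row.names = FALSE)
      stamp("quantify", list(table = file.path(out_dir,
                                               "quantification.csv")))
    }
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, cohort = cohort, prep = prep,
                 train = result, metrics = report, quant = quant,
                 split = split, out_dir = out_dir))
}

#' Resample an integer label map to a target grid
#'
#' Nearest-neighbour resampling (labels must not be interpolated).
#'
#' @param labels integer 3D array
#' @param spacing voxel spacing of the label grid
#' @param target_shape integer triple
#' @return integer array on the target grid
#' @export
resample_labels <- function(labels, spacing, target_shape) {
  d <- dim(labels)
  target_shape <- as.integer(target_shape)
  idx <- function(n, t) pmin(pmax(round((seq_len(t) - 0.5) * n / t + 0.5),
                                  1L), n)
  labels[idx(d[1], target_shape[1]), idx(d[2], target_shape[2]),
         idx(d[3], target_shape[3])]
}
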