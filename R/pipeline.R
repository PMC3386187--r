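# End-to-end orchestration: simulate -> ROIs -> GLCM + DTCWT texture ->
# PCA discriminant -> SVM staging, with manifests and a run log.

#' Pipeline configuration
#'
#' Collects the sub-configurations of every pipeline stage. The master
#' seed deterministically derives all scene, ROI and classifier seeds.
#'
#' @param stages stage labels.
#' @param n_per_stage images per stage.
#' @param grid_shape detector grid.
#' @param pixel_size pixel pitch in meters.
#' @param energy photon energy in keV.
#' @param distance propagation distance in meters.
#' @param psf_sigma,photons_per_pixel,bit_depth,noise detector model.
#' @param n_rois ROIs per region per image (default 20).
#' @param roi_size ROI side in pixels (default 60).
#' @param ng gray levels for co-occurrence quantization.
#' @param dtcwt_levels wavelet decomposition levels.
#' @param cr_threshold contribution-rate threshold.
#' @param svm an [svm_config()].
#' @param master_seed master seed.
#' @param phantom phantom parameters.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(stages = tumor_stages(), n_per_stage = 1L,
                            grid_shape = c(1024L, 1024L), pixel_size = 9e-6,
                            energy = 15, distance = 0.5, psf_sigma = 1,
                            photons_per_pixel = 1e5, bit_depth = 16L,
                            noise = TRUE, n_rois = 20L, roi_size = 60L,
                            ng = 16L, dtcwt_levels = 2L, cr_threshold = 0.80,
                            svm = svm_config(), master_seed = 1L,
                            phantom = phantom_params()) {
  if (is.null(stages)) stop_config("pipeline config is missing `stages`")
  sim <- simulate_config(stages = stages, n_per_stage = n_per_stage,
                         grid_shape = grid_shape, pixel_size = pixel_size,
                         energy = energy, distance = distance,
                         psf_sigma = psf_sigma,
                         photons_per_pixel = photons_per_pixel,
                         bit_depth = bit_depth, noise = noise,
                         master_seed = master_seed, phantom = phantom)
  if (!is_count(n_rois) || !is_count(roi_size))
    stop_config("`n_rois` and `roi_size` must be positive integers")
  structure(list(sim = sim, n_rois = as.integer(n_rois),
                 roi_size = as.integer(roi_size), ng = as.integer(ng),
                 dtcwt_levels = as.integer(dtcwt_levels),
                 cr_threshold = cr_threshold, svm = svm,
                 master_seed = as.integer(master_seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat keys matching the arguments of [pipeline_config()]; unknown keys
#' are rejected by name. The `svm` entry may be a mapping with `cost`,
#' `gamma`, `folds`, `seed`.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_config("config file does not exist: %s", path)
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop_config("unknown pipeline config key(s): %s",
                paste(bad, collapse = ", "))
  if (!is.null(raw$svm)) raw$svm <- do.call(svm_config, raw$svm)
  if (!is.null(raw$phantom)) raw$phantom <- do.call(phantom_params, raw$phantom)
  do.call(pipeline_config, raw)
}

config_hash <- function(config) {
  derive_seed(0L, paste(deparse(unclass(config)), collapse = ""))
}

# Sample per-image ROIs (both regions) and compute both feature tables.
extract_image_features <- function(img, mask, stage, source_id, config,
                                   seed) {
  rois <- c(
    sample_rois(img, mask, "normal", n = config$n_rois,
                size = config$roi_size, seed = derive_seed(seed, "roi-n"),
                stage = stage, source_id = source_id),
    sample_rois(img, mask, "tumor", n = config$n_rois,
                size = config$roi_size, seed = derive_seed(seed, "roi-t"),
                stage = stage, source_id = source_id)
  )
  list(glcm = texture_features(rois, Ng = config$ng),
       dtcwt = subband_texture_features(rois, Ng = config$ng,
                                        levels = config$dtcwt_levels))
}

#' Run the full analysis pipeline
#'
#' Simulates the dataset, extracts ROIs and both texture feature tables,
#' runs the per-stage GLCM sign discriminant, the LF1 stage-trend
#' analysis, and the SVM staging, writing `features.csv`,
#' `features_dtcwt.csv`, `discriminant_report.json`, `svm_report.json`
#' and `run.log` into `out_dir`. Deterministic under a fixed master seed;
#' a stage failure is recorded in the log and re-raised with the stage
#' name.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return list with the feature tables and reports, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop_config("cannot create output directory: %s", out_dir)
  log_path <- file.path(out_dir, "run.log")
  logln <- function(...) cat(sprintf(...), "\n", sep = "",
                             file = log_path, append = TRUE)
  cat(sprintf("ilpcitex %s | R %s.%s\nconfig hash %d | master seed %d\n",
              as.character(utils::packageVersion("ilpcitex")),
              R.version$major, R.version$minor,
              config_hash(config), config$master_seed),
      file = log_path)

  run_stage <- function(name, expr) {
    logln("stage %s: start", name)
    res <- tryCatch(expr, error = function(e) {
      logln("stage %s: FAILED: %s", name, conditionMessage(e))
      stop_config("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e))
    })
    logln("stage %s: done", name)
    res
  }

  manifest <- run_stage("simulate", simulate_dataset(config$sim, out_dir))

  feats <- run_stage("texture", {
    gl <- list(); dt <- list()
    for (r in seq_len(nrow(manifest))) {
      img <- read_image(file.path(out_dir, manifest$file[r]))
      msk <- read_mask(file.path(out_dir, manifest$mask[r]))
      fe <- extract_image_features(img, msk, manifest$stage[r],
                                   manifest$file[r], config,
                                   seed = manifest$seed[r])
      gl[[r]] <- fe$glcm; dt[[r]] <- fe$dtcwt
    }
    list(glcm = do.call(rbind, gl), dtcwt = do.call(rbind, dt))
  })
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.12g", x))
    df
  }
  utils::write.csv(fmt(feats$glcm), file.path(out_dir, "features.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(fmt(feats$dtcwt), file.path(out_dir, "features_dtcwt.csv"),
                   row.names = FALSE, quote = FALSE)

  disc <- run_stage("discriminate",
                    glcm_discriminant(feats$glcm, config$cr_threshold))
  trend <- if (length(config$sim$stages) >= 3L) {
    run_stage("stage-trend", lf_stage_trend(feats$dtcwt, "LF1"))
  } else NULL
  disc_json <- list(
    per_stage = lapply(disc, function(d) list(
      normal = unname(d$group_stats$normal[c("mean", "sd")]),
      tumor = unname(d$group_stats$tumor[c("mean", "sd")]),
      cr1 = d$cr1, agreement = d$agreement,
      components = d$selected_components)))
  if (!is.null(trend))
    disc_json$lf1_trend <- list(stage_means = as.list(trend$stage_means),
                                rho = trend$rho, cr1 = trend$cr1)
  jsonlite::write_json(disc_json, file.path(out_dir, "discriminant_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  svm_rep <- if (length(config$sim$stages) >= 2L) {
    run_stage("stage-classify", {
      ds <- build_stage_features(feats$dtcwt, "LF1", config$cr_threshold)
      crossval_svm(ds, config$svm)
    })
  } else NULL
  if (!is.null(svm_rep)) {
    jsonlite::write_json(
      list(accuracy = svm_rep$accuracy, per_fold = svm_rep$per_fold,
           confusion = as.data.frame.matrix(unclass(svm_rep$confusion)),
           best_cost = svm_rep$best_cost, best_gamma = svm_rep$best_gamma,
           permutation_baseline = svm_rep$permutation_baseline,
           folds = svm_rep$folds, multiclass = svm_rep$multiclass),
      file.path(out_dir, "svm_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  logln("pipeline complete")
  invisible(list(manifest = manifest, features = feats$glcm,
                 features_dtcwt = feats$dtcwt, discriminant = disc,
                 lf1_trend = trend, svm = svm_rep))
}
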