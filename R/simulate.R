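# Dataset simulation: staged phantoms -> Fresnel projections -> detector
# images + label masks + manifest.

#' Simulation configuration
#'
#' @param stages stage labels to simulate.
#' @param n_per_stage images per stage (default 6, one per animal in a
#'   group).
#' @param grid_shape detector grid `c(rows, cols)` (even).
#' @param pixel_size pixel pitch in meters (default 9 um).
#' @param energy photon energy in keV (default 15).
#' @param distance sample-detector distance in meters (default 0.5).
#' @param psf_sigma detector blur sd in pixels.
#' @param photons_per_pixel expected photons at unit intensity.
#' @param bit_depth detector bit depth.
#' @param noise logical; Poisson shot noise on/off.
#' @param master_seed master seed; all per-image seeds derive from it.
#' @param phantom phantom generator parameters ([phantom_params()]).
#' @param materials material optical constants ([liver_materials()]).
#' @return a validated `sim_config` list.
#' @export
simulate_config <- function(stages = tumor_stages(), n_per_stage = 6L,
                            grid_shape = c(1024L, 1024L), pixel_size = 9e-6,
                            energy = 15, distance = 0.5, psf_sigma = 1,
                            photons_per_pixel = 1e5, bit_depth = 16L,
                            noise = TRUE, master_seed = 1L,
                            phantom = phantom_params(),
                            materials = liver_materials()) {
  if (!length(stages) || !all(stages %in% tumor_stages()))
    stop_config("`stages` must be a subset of {%s}",
                paste(tumor_stages(), collapse = ", "))
  if (!is_count(n_per_stage)) stop_config("`n_per_stage` must be >= 1")
  structure(list(stages = stages, n_per_stage = as.integer(n_per_stage),
                 grid_shape = as.integer(grid_shape),
                 pixel_size = pixel_size, energy = energy,
                 distance = distance, psf_sigma = psf_sigma,
                 photons_per_pixel = photons_per_pixel,
                 bit_depth = as.integer(bit_depth), noise = isTRUE(noise),
                 master_seed = as.integer(master_seed), phantom = phantom,
                 materials = materials),
            class = "sim_config")
}

#' Simulate one detector image of a staged phantom
#'
#' Chains phantom construction, plane-wave projection, paraxial Fresnel
#' propagation to the detector plane, and the detector model.
#'
#' @param config a [simulate_config()].
#' @param stage stage label.
#' @param seed scene seed (detector noise uses a seed derived from it).
#' @return list with `image` (a `projection_image`), `scene`.
#' @export
simulate_image <- function(config, stage, seed) {
  optics <- optical_constants(config$energy, config$materials)
  geom <- propagation_geometry(config$distance, config$pixel_size,
                               config$grid_shape)
  scene <- build_liver_phantom(stage, config$grid_shape, config$pixel_size,
                               seed, config$phantom)
  proj <- project_scene(scene, optics)
  field <- fresnel_propagate(projection_to_field(proj), geom, optics)
  det <- detector_model(config$psf_sigma, config$photons_per_pixel,
                        config$bit_depth,
                        seed = derive_seed(seed, "detector"),
                        noise = config$noise)
  img <- detect(field_intensity(field), det, pixel_size = config$pixel_size)
  list(image = img, scene = scene)
}

#' Simulate a dataset of staged projection images
#'
#' Writes one 16-bit grayscale TIFF and one 8-bit label-mask TIFF per
#' phantom plus a `manifest.csv` (`file,mask,stage,seed`). Per-image seeds
#' are derived from the master seed, the stage name and the image index,
#' so the output is deterministic and adding images never perturbs
#' earlier ones.
#'
#' @param config a [simulate_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest data.frame, invisibly.
#' @export
simulate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop_config("cannot create output directory: %s", out_dir)
  rows <- list()
  for (stage in config$stages) {
    for (i in seq_len(config$n_per_stage)) {
      seed <- derive_seed(config$master_seed, stage, i)
      sim <- simulate_image(config, stage, seed)
      fimg <- sprintf("img_%s_%02d.tif", stage, i)
      fmsk <- sprintf("mask_%s_%02d.tif", stage, i)
      write_image(sim$image, file.path(out_dir, fimg))
      write_mask(sim$scene$region_mask, file.path(out_dir, fmsk))
      rows[[length(rows) + 1L]] <-
        data.frame(file = fimg, mask = fmsk, stage = stage, seed = seed,
                   stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
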