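# Synthetic liver phantom: staged tumor morphology with ground truth.

#' Default parameters of the liver phantom generator
#'
#' The defaults define the study conditions emulated by the generator:
#' a smooth correlated parenchyma texture, a diffuse fine-grained tumor
#' texture at the earliest stage (6 days), and necrotic lumps whose count
#' and mean radius grow with stage at 9/12/15 days, with curvilinear
#' vessels adjacent to the tumor from 9 days on. Lengths are in meters,
#' correlation lengths and radii in pixels (9 um default pitch).
#'
#' @param ... named overrides of any default listed below.
#' @return a named list of generator parameters.
#' @export
phantom_params <- function(...) {
  p <- list(
    base_thickness = 3e-3,    # mean projected liver thickness (m)
    liver_frac     = c(0.46, 0.44), # liver ellipse semi-axes / grid size
    macro_amp      = 1.0e-4,  # large-scale thickness modulation (m)
    macro_len      = 48,      # its correlation length (px)
    normal_amp     = 1.5e-4,  # parenchyma texture amplitude (m)
    normal_len     = 12,      # parenchyma correlation length (px)
    tumor_fraction = 0.35,    # tumor radius / half grid
    tumor_dome     = 4e-4,    # extra projected thickness of the tumor (m)
    dome_edge_sigma = 8,      # taper of the tumor boundary (px)
    # diffuse fine viable-tumor grain; amplitude and scale drift up with
    # stage (progressive tissue disorganization), and the necrotic lump
    # coverage grows with stage, so later stages are coarser throughout
    fine_amp  = c("6d" = 2.0e-4, "9d" = 2.8e-4, "12d" = 3.6e-4, "15d" = 4.4e-4),
    fine_len  = c("6d" = 2.3, "9d" = 2.7, "12d" = 3.1, "15d" = 3.5),
    # necrotic lumps per 1e4 tumor pixels, so the necrotic fraction is
    # independent of the grid size
    lump_density = c("6d" = 0, "9d" = 8, "12d" = 10, "15d" = 12),
    lump_radius = c("6d" = 0, "9d" = 11, "12d" = 14, "15d" = 17), # mean (px)
    lump_radius_sd = 0.12,    # sdlog of the lognormal lump radii
    lump_thickness = 6e-4,    # lump projected thickness (m)
    lump_sharpness = 6,       # super-Gaussian exponent of the lump profile
    lump_texture = 0.4,       # relative debris texture inside lumps
    lump_texture_len = 4,     # its correlation length (px)
    vessel_count = c("6d" = 0, "9d" = 2, "12d" = 3, "15d" = 4),
    vessel_width = 3,         # Gaussian cross-section sd (px)
    vessel_thickness = 0.8e-4 # vessel projected thickness (m)
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop_config("unknown phantom parameter(s): %s",
                               paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  if (!is.numeric(p$tumor_fraction) || p$tumor_fraction <= 0 ||
      p$tumor_fraction >= 1)
    stop_config("`tumor_fraction` must lie in (0, 1)")
  p
}

tumor_stages <- function() c("6d", "9d", "12d", "15d")

#' Build a staged synthetic liver phantom scene
#'
#' Produces per-material projected-thickness maps (parenchyma, tumor,
#' necrosis, vessel), a region label mask (0 background, 1 normal, 2 tumor)
#' and a ground-truth record of the necrotic-lump statistics. Identical
#' `(stage, grid_shape, seed, params)` reproduce the scene bit for bit.
#'
#' @param stage one of `"6d"`, `"9d"`, `"12d"`, `"15d"` (days after
#'   tumor-cell inoculation).
#' @param grid_shape even integers `c(rows, cols)`, at least 256 each.
#' @param pixel_size detector pixel pitch in meters.
#' @param seed integer seed of the scene.
#' @param params generator parameters from [phantom_params()].
#' @return a `phantom_scene` object.
#' @export
build_liver_phantom <- function(stage = c("6d", "9d", "12d", "15d"),
                                grid_shape = c(1024L, 1024L),
                                pixel_size = 9e-6, seed = 1L,
                                params = phantom_params()) {
  stage <- match.arg(stage)
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape %% 2L != 0L) || any(grid_shape < 256L))
    stop_config("`grid_shape` must be even and at least 256 x 256")
  nr <- grid_shape[1]; nc <- grid_shape[2]
  p <- params

  with_seed(seed, {
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)

    # liver outline: slightly irregular ellipse
    cy <- nr / 2; cx <- nc / 2
    th <- atan2(rows - cy, cols - cx)
    wob <- 1 + 0.05 * cos(2 * th + stats::runif(1, 0, 2 * pi)) +
      0.03 * cos(3 * th + stats::runif(1, 0, 2 * pi))
    er <- ((rows - cy) / (p$liver_frac[1] * nr))^2 +
      ((cols - cx) / (p$liver_frac[2] * nc))^2
    liver <- er <= wob^2

    # tumor blob: harmonically modulated disk near the center
    tc <- c(cy, cx) + stats::runif(2, -0.08, 0.08) * c(nr, nc)
    R <- p$tumor_fraction * min(nr, nc) / 2
    tth <- atan2(rows - tc[1], cols - tc[2])
    mod <- 1
    for (k in 2:5)
      mod <- mod + 0.06 * stats::rnorm(1) * cos(k * tth + stats::runif(1, 0, 2 * pi))
    dist <- sqrt((rows - tc[1])^2 + (cols - tc[2])^2)
    tumor <- liver & (dist <= R * mod)

    region <- matrix(0L, nr, nc)
    region[liver] <- 1L
    region[tumor] <- 2L

    # parenchyma: base slab + macro modulation + fine correlated texture
    parenchyma <- (p$base_thickness +
                     p$macro_amp * gauss_field(nr, nc, p$macro_len) +
                     p$normal_amp * gauss_field(nr, nc, p$normal_len)) * liver

    # tumor: soft-edged dome + stage-dependent fine grain inside the mask
    soft <- fft_gauss_blur(tumor + 0, p$dome_edge_sigma)
    tum_thk <- p$tumor_dome * soft +
      p$fine_amp[[stage]] * gauss_field(nr, nc, p$fine_len[[stage]]) * tumor

    # necrotic lumps (9d and later): super-Gaussian disks inside the tumor
    necro <- matrix(0, nr, nc)
    radii <- numeric(0)
    n_lumps <- round(p$lump_density[[stage]] * sum(tumor) / 1e4 *
                       stats::runif(1, 0.95, 1.05))
    if (n_lumps > 0) {
      idx <- which(tumor)
      probe <- seq(0, 2 * pi, length.out = 17)[-17]
      for (i in seq_len(n_lumps)) {
        # lognormal radii: polydisperse necrosis, mean growing with stage
        r_i <- max(2.5, stats::rlnorm(1,
                                      log(p$lump_radius[[stage]]) -
                                        p$lump_radius_sd^2 / 2,
                                      p$lump_radius_sd))
        placed <- FALSE
        for (try in 1:200) {
          at <- idx[sample.int(length(idx), 1L)]
          ar <- (at - 1L) %% nr + 1L
          ac <- (at - 1L) %/% nr + 1L
          pr <- pmin(pmax(round(ar + r_i * sin(probe)), 1L), nr)
          pc <- pmin(pmax(round(ac + r_i * cos(probe)), 1L), nc)
          if (all(tumor[cbind(pr, pc)])) {
            necro <- stamp_bump(necro, ar, ac, r_i, p$lump_thickness,
                                p$lump_sharpness)
            radii <- c(radii, r_i)
            placed <- TRUE
            break
          }
        }
        if (!placed) next
      }
      # necrotic debris: lump interiors carry their own correlated texture
      if (p$lump_texture > 0 && length(radii))
        necro <- necro * pmax(1 + p$lump_texture *
                                gauss_field(nr, nc, p$lump_texture_len), 0)
    }

    # vessels: curvilinear tubes skirting the tumor boundary (9d and later)
    vessel <- matrix(0, nr, nc)
    n_ves <- p$vessel_count[[stage]]
    if (n_ves > 0) {
      for (v in seq_len(n_ves)) {
        a0 <- stats::runif(1, 0, 2 * pi)
        r0 <- tc[1] + 1.08 * R * sin(a0)
        c0 <- tc[2] + 1.08 * R * cos(a0)
        # heading roughly tangential to the tumor boundary
        th0 <- a0 + pi / 2 + stats::rnorm(1, 0, 0.3)
        path <- walk_path(r0, c0, th0, n_steps = round(0.5 * min(nr, nc)))
        vessel <- stamp_tube(vessel, path, p$vessel_width, p$vessel_thickness)
      }
      vessel <- vessel * liver
    }

    structure(
      list(
        thickness = list(parenchyma = pmax(parenchyma, 0),
                         tumor = pmax(tum_thk, 0),
                         necrosis = pmax(necro, 0),
                         vessel = pmax(vessel, 0)),
        region_mask = region,
        stage = stage,
        seed = as.integer(seed),
        pixel_size = pixel_size,
        grid_shape = grid_shape,
        truth = list(lump_count = length(radii),
                     lump_radii = radii,
                     mean_lump_radius = if (length(radii)) mean(radii) else 0,
                     vessel_count = n_ves),
        params = p
      ),
      class = "phantom_scene"
    )
  })
}

#' Project a phantom scene to phase and contact intensity
#'
#' Under plane-wave, monochromatic illumination the object transmission is
#' `q = sqrt(I0) * exp(i * phi)` with phase `phi = -k * sum_m delta_m t_m`
#' and contact intensity `I0 = exp(-2 k * sum_m beta_m t_m)`, where `t_m`
#' is the projected thickness of material `m`.
#'
#' @param scene a `phantom_scene`.
#' @param optics an [optical_constants()] object providing `(delta, beta)`
#'   for every material in the scene.
#' @return a `phantom_projection` with fields `phi` (radians) and `I0`.
#' @export
project_scene <- function(scene, optics) {
  stopifnot(inherits(scene, "phantom_scene"),
            inherits(optics, "optical_constants"))
  dsum <- 0; bsum <- 0
  for (nm in names(scene$thickness)) {
    mat <- optics$materials[[nm]]
    if (is.null(mat))
      stop_config("no optical constants for material '%s'", nm)
    dsum <- dsum + mat[["delta"]] * scene$thickness[[nm]]
    bsum <- bsum + mat[["beta"]] * scene$thickness[[nm]]
  }
  structure(
    list(phi = -optics$k * dsum,
         I0 = exp(-2 * optics$k * bsum),
         pixel_size = scene$pixel_size),
    class = "phantom_projection"
  )
}
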