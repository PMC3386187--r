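# Phantom simulation: optics, projection, Fresnel/TIE forward models,
# detector and dataset writer.

test_that("photon energy converts to wavelength by the hc/E closed form", {
  expect_equal(energy_to_wavelength(15), 8.2656e-11, tolerance = 1e-4)
  expect_equal(energy_to_wavelength(12.398), 1.00005e-10, tolerance = 1e-4)
  # inverse proportionality: E * lambda is constant
  e <- c(8, 15, 30, 72.5)
  expect_equal(diff(range(e * energy_to_wavelength(e))), 0)
  expect_error(energy_to_wavelength(0), "positive")
  expect_error(energy_to_wavelength(-3), "positive")
})

test_that("optical constants and geometry satisfy their invariants", {
  opt <- optical_constants(15)
  expect_equal(opt$k * opt$wavelength, 2 * pi, tolerance = 1e-12)
  for (m in opt$materials) expect_true(all(m >= 0))
  expect_error(optical_constants(15, list(bad = c(delta = -1, beta = 0))),
               "delta")
  expect_error(propagation_geometry(pixel_size = 0), "pixel_size")
  expect_error(propagation_geometry(grid_shape = c(255, 256)), "even")
  expect_error(propagation_geometry(distance = -1), ">= 0")
})

test_that("liver phantom follows the stage morphology model", {
  s6 <- build_liver_phantom("6d", c(256L, 256L), seed = 0L)
  expect_identical(s6$truth$lump_count, 0L)
  expect_gt(sum(s6$region_mask == 2L), 0)
  expect_true(all(vapply(s6$thickness, function(t) all(t >= 0), logical(1))))

  # lump radii grow strictly across 9d -> 12d -> 15d under one seed
  r <- vapply(c("9d", "12d", "15d"), function(sg)
    build_liver_phantom(sg, c(256L, 256L), seed = 3L)$truth$mean_lump_radius,
    numeric(1))
  expect_true(all(diff(r) > 0))

  # seeded determinism, bit for bit
  a <- build_liver_phantom("12d", c(256L, 256L), seed = 7L)
  b <- build_liver_phantom("12d", c(256L, 256L), seed = 7L)
  expect_identical(a$thickness, b$thickness)
  expect_identical(a$region_mask, b$region_mask)

  expect_error(phantom_params(tumor_fraction = 1.2), "tumor_fraction")
  expect_error(build_liver_phantom("6d", c(128L, 128L)), "256")
})

test_that("generator truth statistics are stage-ordered for every seed", {
  for (seed in 1:20) {
    tr <- lapply(tumor_stages(), function(sg)
      build_liver_phantom(sg, c(256L, 256L), seed = seed)$truth)
    counts <- vapply(tr, `[[`, numeric(1), "lump_count")
    radii <- vapply(tr, `[[`, numeric(1), "mean_lump_radius")
    expect_true(all(diff(counts) >= 0))
    expect_true(all(diff(radii) >= 0))
  }
})

test_that("scene projection obeys the thin-object phase/absorption model", {
  opt <- optical_constants(15)
  sc <- build_liver_phantom("6d", c(256L, 256L), seed = 1L)

  # empty object
  sc0 <- sc
  sc0$thickness <- lapply(sc$thickness, function(t) t * 0)
  p0 <- project_scene(sc0, opt)
  expect_true(all(p0$phi == 0))
  expect_true(all(p0$I0 == 1))

  # uniform slab of one material: constant phase -k delta t
  t0 <- 1e-4
  scs <- sc0
  scs$thickness$parenchyma <- matrix(t0, 256, 256)
  ps <- project_scene(scs, opt)
  delta <- opt$materials$parenchyma[["delta"]]
  beta <- opt$materials$parenchyma[["beta"]]
  expect_equal(max(abs(ps$phi + opt$k * delta * t0)), 0, tolerance = 1e-6)
  expect_equal(ps$I0[1, 1], exp(-2 * opt$k * beta * t0), tolerance = 1e-12)

  # doubling thickness doubles phi and squares I0
  scd <- scs
  scd$thickness$parenchyma <- 2 * scs$thickness$parenchyma
  pd <- project_scene(scd, opt)
  expect_equal(pd$phi, 2 * ps$phi, tolerance = 1e-12)
  expect_equal(pd$I0, ps$I0^2, tolerance = 1e-12)

  # missing material constants
  opt2 <- optical_constants(15, list(parenchyma = c(delta = 1e-6, beta = 1e-9)))
  expect_error(project_scene(sc, opt2), "tumor")
})

test_that("Fresnel propagator is the paraxial transfer function", {
  n <- 256
  opt <- optical_constants(15)
  geom <- propagation_geometry(0.5, 9e-6, c(n, n))
  proj <- gauss_bump_projection(n, phi0 = 0.05, sigma_px = 40)
  fld <- projection_to_field(proj)

  # z = 0 identity
  g0 <- propagation_geometry(0, 9e-6, c(n, n))
  expect_lt(max(Mod(fresnel_propagate(fld, g0, opt)$amplitude -
                      fld$amplitude)), 1e-12)

  # unitarity: pure-phase total intensity conserved
  for (z in c(0.1, 0.5, 1.0)) {
    gz <- propagation_geometry(z, 9e-6, c(n, n))
    out <- fresnel_propagate(fld, gz, opt)
    expect_equal(sum(field_intensity(out)), sum(field_intensity(fld)),
                 tolerance = 1e-9)
  }

  # weak Gaussian bump: center intensity matches the TIE closed form
  out <- fresnel_propagate(fld, geom, opt)
  icen <- field_intensity(out)[n / 2, n / 2]
  pred <- 1 + opt$wavelength * 0.5 / pi * 0.05 / (40 * 9e-6)^2
  expect_equal(icen - 1, pred - 1, tolerance = 0.01)

  # aliasing guard warns with the maximum safe distance
  gfar <- propagation_geometry(5000, 9e-6, c(n, n))
  expect_warning(fresnel_propagate(fld, gfar, opt), "alias-safe")

  expect_error(
    fresnel_propagate(fld, propagation_geometry(0.5, 9e-6, c(128, 128)), opt),
    "does not match")
})

test_that("TIE intensity is the linearized Laplacian model", {
  n <- 256
  opt <- optical_constants(15)
  geom <- propagation_geometry(0.5, 9e-6, c(n, n))

  # linear phase ramp has zero Laplacian almost everywhere; use a constant
  # (the periodic stencil sees the wrap of a ramp) plus the Gaussian case
  flat <- structure(list(phi = matrix(1.23, n, n),
                         I0 = matrix(0.9, n, n), pixel_size = 9e-6),
                    class = "phantom_projection")
  expect_equal(tie_intensity(flat, geom, opt), flat$I0,
               ignore_attr = TRUE, tolerance = 1e-12)

  proj <- gauss_bump_projection(n, phi0 = 0.05, sigma_px = 40)
  It <- tie_intensity(proj, geom, opt)
  pred <- 1 + opt$wavelength * 0.5 / pi * 0.05 / (40 * 9e-6)^2
  expect_equal(It[n / 2, n / 2] - 1, pred - 1, tolerance = 0.01)

  # agreement with the Fresnel propagator in the weak-object limit
  If <- field_intensity(fresnel_propagate(projection_to_field(proj), geom, opt))
  expect_lt(sqrt(mean((It - If)^2)) / mean(If), 0.02)
})

test_that("Fresnel and TIE intensities converge as the phase weakens", {
  n <- 256
  opt <- optical_constants(15)
  geom <- propagation_geometry(0.5, 9e-6, c(n, n))
  rms <- vapply(c(0.2, 0.1, 0.05, 0.025), function(phi0) {
    proj <- gauss_bump_projection(n, phi0, sigma_px = 10)
    It <- tie_intensity(proj, geom, opt)
    If <- field_intensity(fresnel_propagate(projection_to_field(proj),
                                            geom, opt))
    sqrt(mean((It - If)^2)) / mean(If)
  }, numeric(1))
  expect_true(all(diff(rms) < 0))
})

test_that("propagation produces edge enhancement across a material step", {
  n <- 256
  opt <- optical_constants(15)
  phi <- matrix(0, n, n); phi[, (n / 4):(3 * n / 4)] <- 0.3
  phi <- ilpcitex:::fft_gauss_blur(phi, 1)
  proj <- structure(list(phi = phi, I0 = matrix(1, n, n), pixel_size = 9e-6),
                    class = "phantom_projection")
  contrast <- function(z) {
    gz <- propagation_geometry(z, 9e-6, c(n, n))
    I <- field_intensity(fresnel_propagate(projection_to_field(proj), gz, opt))
    max(I) - min(I)
  }
  expect_gt(contrast(0.5), contrast(0))
})

test_that("detector chain blurs, counts and rescales as configured", {
  # identity chain on constant input
  det0 <- detector_model(psf_sigma = 0, noise = FALSE)
  img <- detect(matrix(0.5, 32, 32), det0)
  expect_true(all(img$pixels == img$pixels[1, 1]))

  # normalized PSF conserves the total
  x <- matrix(runif(64 * 64), 64, 64)
  blurred <- ilpcitex:::fft_gauss_blur(x, 2.5)
  expect_equal(sum(blurred), sum(x), tolerance = 1e-9)

  # Poisson mean recovers the intensity within 3 standard errors
  lam <- 50
  det <- detector_model(psf_sigma = 0, photons_per_pixel = lam, seed = NULL)
  tot <- 0; nrep <- 1000; npix <- 8 * 8
  set.seed(99)
  for (i in seq_len(nrep)) tot <- tot + mean(detect(matrix(1, 8, 8), det)$counts)
  se <- sqrt(lam / (nrep * npix))
  expect_lt(abs(tot / nrep - lam), 3 * se)

  expect_error(detect(matrix(-1, 4, 4), det0), "non-negative")
  expect_error(detector_model(psf_sigma = -1), "psf_sigma")
})

test_that("simulate_dataset writes a deterministic image/mask/manifest set", {
  cfg <- simulate_config(stages = "6d", n_per_stage = 1L,
                         grid_shape = c(256L, 256L), master_seed = 4L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- simulate_dataset(cfg, d1)
  m2 <- simulate_dataset(cfg, d2)
  expect_identical(nrow(m1), 1L)
  expect_setequal(list.files(d1), c("img_6d_01.tif", "mask_6d_01.tif",
                                    "manifest.csv"))
  expect_identical(readBin(file.path(d1, "img_6d_01.tif"), "raw", 1e7),
                   readBin(file.path(d2, "img_6d_01.tif"), "raw", 1e7))
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))

  # 4 stages x 6 images -> 24 manifest rows (one animal group per stage)
  cfg24 <- simulate_config(n_per_stage = 6L)
  expect_identical(length(cfg24$stages) * cfg24$n_per_stage, 24L)
})
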