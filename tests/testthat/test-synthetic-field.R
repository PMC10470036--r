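test_that("empty canopy gives a pure ridge profile and zero truth", {
  tr <- scene_truth(n_plots = 1, canopy_scale = 0, dsm_noise_sd = 0,
                    grid_offset = "none")
  sc <- make_scene(tr, 0.01)
  expect_true(all(sc$mask$values == 0))
  expect_identical(tr$plot_truth$true_volume, 0)
  expect_identical(tr$plot_truth$true_coverage, 0)
  expect_equal(max(sc$dsm$values), tr$base_altitude + tr$ridge_height)
  expect_equal(min(sc$dsm$values), tr$base_altitude)
  # flat crest occupies its nominal fraction of the profile
  frac_top <- mean(sc$dsm$values == tr$base_altitude + tr$ridge_height)
  expect_equal(frac_top, tr$ridge_top_width / tr$ridge_spacing,
               tolerance = 0.05)
})

test_that("grid-aligned cuboid canopy samples its exact footprint and truth", {
  tr <- one_plant_truth(shape = "cuboid", a = 0.5, b = 0.3, height = 0.4,
                        x = 1.5, y = 1.05)
  expect_equal(tr$plot_truth$true_volume, 0.24)
  expect_equal(tr$plot_truth$true_mean_height, 0.4)
  for (g in gsd_pair()) {
    sc <- make_scene(tr, g)
    area <- sum(sc$mask$values) * pixel_area(sc$mask)
    expect_equal(area, 0.6, tolerance = 1e-12)
  }
})

test_that("hemiellipsoid truth is (2/3) pi a b c and sampling converges to it", {
  a <- 0.15; b <- 0.12; h <- 0.35
  tr <- one_plant_truth(a = a, b = b, height = h, grid_offset = c(0.3, 0.7))
  expect_equal(tr$plot_truth$true_volume, 2 / 3 * pi * a * b * h)
  errs <- vapply(c(1 / 30, 1 / 60, 1 / 120), function(g) {
    sc <- make_scene(tr, g)
    # sampled canopy volume straight from the surface (no estimation stage)
    plane <- structure(list(plot_id = "P01",
                            zplane = tr$base_altitude + tr$ridge_height,
                            n_pixels = 1L, percentile = 0.9,
                            source_date = NA), class = "base_plane")
    hm <- height_map(sc$dsm, plane, sc$mask, sc$plots[[1]])
    abs(plot_volume(hm) - tr$plot_truth$true_volume)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))  # error shrinks monotonically with gsd
  expect_lt(errs[3] / tr$plot_truth$true_volume, 0.01)
})

test_that("sampled footprint area converges to the true footprint", {
  tr <- one_plant_truth(a = 0.15, b = 0.15, height = 0.4,
                        grid_offset = c(0.25, 0.6))
  true_area <- pi * 0.15^2
  errs <- vapply(c(1 / 30, 1 / 60, 1 / 120), function(g) {
    sc <- make_scene(tr, g)
    abs(sum(sc$mask$values) * pixel_area(sc$mask) - true_area)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("identical seeds give bit-identical scenes", {
  tr <- scene_truth(n_plots = 1, dsm_noise_sd = 0.02, seed = 99)
  a <- make_scene(tr, 0.02); b <- make_scene(tr, 0.02)
  expect_identical(a$dsm$values, b$dsm$values)
  expect_identical(a$mask$values, b$mask$values)
  expect_identical(a$bands$nir$values, b$bands$nir$values)
  tr2 <- scene_truth(n_plots = 1, dsm_noise_sd = 0.02, seed = 100)
  expect_false(identical(make_scene(tr2, 0.02)$dsm$values, a$dsm$values))
})

test_that("the altitude pair samples one field at the two survey GSDs", {
  tr <- scene_truth(n_plots = 1, dsm_noise_sd = 0.005)
  pair <- make_height_pair(tr)
  expect_equal(pair$fine$gsd, 0.00833, tolerance = 1e-3)
  expect_equal(pair$coarse$gsd, 0.01667, tolerance = 1e-3)
  expect_identical(pair$fine$gsd * 2, pair$coarse$gsd)
  df <- dim(pair$fine$dsm$values); dc <- dim(pair$coarse$dsm$values)
  expect_true(all(abs(df - 2 * dc) <= 2))
  # same continuous surface: noise-free bare DSMs agree up to the soil
  # slope (max 2 m/m on the flanks) times one fine-pixel offset
  tr0 <- scene_truth(n_plots = 1, canopy_scale = 0, dsm_noise_sd = 0,
                     grid_offset = "none")
  p0 <- make_height_pair(tr0)
  fine_at_coarse <- resample_to(p0$fine$dsm, p0$coarse$dsm, "nearest")
  expect_lt(max(abs(fine_at_coarse$values - p0$coarse$dsm$values),
                na.rm = TRUE), 2 * sqrt(2) * p0$fine$gsd / 2 + 1e-12)
})

test_that("aligned cuboids give identical volumes at both GSDs", {
  tr <- one_plant_truth(shape = "cuboid", a = 0.5, b = 0.3, height = 0.4,
                        x = 1.5, y = 1.05)
  pair <- make_height_pair(tr)
  vols <- vapply(pair, function(sc) {
    plane <- structure(list(plot_id = "P01",
                            zplane = tr$base_altitude + tr$ridge_height,
                            n_pixels = 1L, percentile = 0.9,
                            source_date = NA), class = "base_plane")
    as.numeric(plot_volume(height_map(sc$dsm, plane, sc$mask,
                                      sc$plots[[1]])))
  }, numeric(1))
  expect_identical(vols[["fine"]], vols[["coarse"]])
  expect_equal(vols[["fine"]], 0.24, tolerance = 1e-12)
})

test_that("bare-ground scenes expose the ridge top through noise", {
  # noisy flat-soil plot: the 90% selection estimates the Gaussian
  # 90th percentile, soil + 1.2816 sd
  tr <- scene_truth(n_plots = 1, canopy_scale = 0, ridge_height = 0,
                    dsm_noise_sd = 0.01, seed = 7)
  bare <- make_bareground_scene(tr, 0.006)   # ~ 1.4e5 pixels in plot
  bp <- estimate_base_plane(bare$dsm, bare$plots[[1]])
  expect_equal(bp$zplane, tr$base_altitude + qnorm(0.9) * 0.01,
               tolerance = 0.002)
  expect_true(all(bare$mask$values == 0))
})

test_that("generator rejects invalid layouts", {
  expect_error(make_scene(scene_truth(n_plots = 1), gsd = 3),
               "plot unresolvable")
  expect_error(one_plant_truth(a = 0.2, x = 0.1), "outside its plot")
  expect_error(
    scene_truth(n_plots = 1, plants = data.frame(
      plot = 1, x = c(1, 1.1), y = c(1, 1), a = 0.15, b = 0.15,
      height = 0.3, shape = "hemiellipsoid")),
    "overlapping canopy")
  expect_error(scene_truth(plot_width = 2), "integer multiple")
  expect_error(scene_truth(grid_offset = c(1.5, 0)), "grid_offset")
})

test_that("band rasters carry pure spectra, mixed only on request", {
  tr <- one_plant_truth()
  sc <- make_scene(tr, 1 / 120)
  vals <- unique(as.vector(sc$bands$nir$values))
  expect_setequal(vals, c(tr$soil_reflectance[["nir"]],
                          tr$leaf_reflectance[["nir"]]))
  # leaf spectrum exactly where the mask is 1
  expect_true(all((sc$bands$nir$values == tr$leaf_reflectance[["nir"]]) ==
                    (sc$mask$values == 1)))
  trm <- one_plant_truth(); trm$mixed_pixels <- TRUE
  scm <- make_scene(trm, 1 / 120)
  mixed <- scm$bands$nir$values
  expect_true(any(mixed > tr$soil_reflectance[["nir"]] &
                    mixed < tr$leaf_reflectance[["nir"]]))
  expect_true(all(mixed >= 0 & mixed <= 1))
})
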