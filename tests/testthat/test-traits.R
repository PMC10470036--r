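plane_at <- function(z, id = "A") {
  structure(list(plot_id = id, zplane = z, n_pixels = 1L, percentile = 0.9,
                 source_date = NA), class = "base_plane")
}

test_that("height is DSM minus base plane, clipped at zero", {
  d <- raster_grid(matrix(c(10.45, 10.0, 9.8, 10.2), 2, 2),
                   origin = c(0, 2), gsd = 1)
  m <- raster_grid(matrix(1, 2, 2), origin = c(0, 2), gsd = 1)
  hm <- height_map(d, plane_at(10), m, rect_plot("A", 0, 0, 2, 2))
  expect_equal(sort(as.vector(hm$values)), c(0, 0, 0.2, 0.45))
  hm2 <- height_map(d, plane_at(10), m, rect_plot("A", 0, 0, 2, 2),
                    clip_negative = FALSE)
  expect_equal(min(hm2$values), -0.2)
  # unmasked and out-of-plot pixels are nodata
  m0 <- raster_grid(matrix(c(1, 0, 1, 1), 2, 2), origin = c(0, 2), gsd = 1)
  hm3 <- height_map(d, plane_at(10), m0, rect_plot("A", 0, 0, 1, 2))
  expect_identical(sum(!is.na(hm3$values)), 1L)
})

test_that("height mapping enforces alignment and plot/plane identity", {
  d <- raster_grid(matrix(10, 2, 2), origin = c(0, 2), gsd = 1)
  m_off <- raster_grid(matrix(1, 2, 2), origin = c(0, 2), gsd = 0.5)
  expect_error(height_map(d, plane_at(10), m_off, rect_plot("A", 0, 0, 2, 2)),
               "not aligned")
  m <- raster_grid(matrix(1, 2, 2), origin = c(0, 2), gsd = 1)
  expect_error(height_map(d, plane_at(10, id = "B"), m,
                          rect_plot("A", 0, 0, 2, 2)), "belongs to")
})

test_that("noise-free canopy heights reproduce the analytic surface exactly", {
  a <- 0.15; b <- 0.15; h <- 0.4
  tr <- one_plant_truth(a = a, b = b, height = h)
  sc <- make_scene(tr, 1 / 120)
  plane <- plane_at(tr$base_altitude + tr$ridge_height, "P01")
  hm <- height_map(sc$dsm, plane, sc$mask, sc$plots[[1]])
  sel <- which(!is.na(hm$values), arr.ind = TRUE)
  px <- x_centers(hm)[sel[, 2]] - (tr$plot_x0[1] + 2.25)
  py <- y_centers(hm)[sel[, 1]] - (tr$plot_y0[1] + 1.125)
  analytic <- h * sqrt(pmax(0, 1 - (px / a)^2 - (py / b)^2))
  expect_equal(max(abs(hm$values[sel] - analytic)), 0)
})

test_that("plot aggregates follow their definitions", {
  hm <- raster_grid(matrix(c(0.2, 0.6, NA, NA), 2, 2), origin = c(0, 2),
                    gsd = 0.01)
  expect_equal(as.numeric(plot_mean_height(hm)), 0.4)
  expect_equal(as.numeric(plot_volume(hm)), 1e-4 * 0.8)
  one <- raster_grid(matrix(1), origin = c(0, 0.01), gsd = 0.01)
  expect_equal(as.numeric(plot_volume(one)), 1e-4)
  uniform <- raster_grid(matrix(0.4, 3, 3), origin = c(0, 3), gsd = 1)
  expect_equal(as.numeric(plot_mean_height(uniform)), 0.4)
})

test_that("a canopy-free height map flags no_canopy instead of failing", {
  empty <- raster_grid(matrix(NA_real_, 2, 2), origin = c(0, 2), gsd = 1)
  mh <- plot_mean_height(empty); v <- plot_volume(empty)
  expect_identical(as.numeric(mh), 0)
  expect_identical(as.numeric(v), 0)
  expect_true(attr(mh, "no_canopy"))
  expect_true(attr(v, "no_canopy"))
})

test_that("volume equals pixel area x count x mean height identically", {
  set.seed(12)
  for (i in 1:5) {
    v <- matrix(runif(400, 0, 0.6), 20, 20)
    v[sample(400, 150)] <- NA
    hm <- raster_grid(v, origin = c(0, 20 * 0.0125), gsd = 0.0125)
    mh <- plot_mean_height(hm); vol <- plot_volume(hm)
    expect_equal(as.numeric(vol),
                 pixel_area(hm) * attr(mh, "n_pixels") * as.numeric(mh),
                 tolerance = 1e-14)
  }
})

test_that("coverage is masked area over polygon area", {
  m1 <- raster_grid(matrix(1, 10, 10), origin = c(0, 1), gsd = 0.1)
  p <- rect_plot("A", 0, 0, 1, 1)
  expect_equal(as.numeric(plot_coverage(m1, p)), 1)
  m0 <- raster_grid(matrix(0, 10, 10), origin = c(0, 1), gsd = 0.1)
  expect_identical(as.numeric(plot_coverage(m0, p)), 0)
  expect_error(plot_coverage(m1, rect_plot("B", 50, 50, 1, 1)), "plot 'B'")
  # synthetic scene: within one boundary-pixel layer of the true fraction
  tr <- scene_truth(n_plots = 1, dsm_noise_sd = 0)
  sc <- make_scene(tr, 1 / 120)
  cov <- as.numeric(plot_coverage(sc$mask, sc$plots[[1]]))
  n_plants <- nrow(tr$plants)
  boundary_area <- n_plants * 2 * pi * 0.15 * (1 / 120)
  expect_lt(abs(cov - tr$plot_truth$true_coverage),
            boundary_area / (tr$plot_length * tr$plot_width))
})

test_that("index formulas match a scalar per-pixel oracle", {
  set.seed(13)
  nr <- 6; nc <- 7
  mk <- function() raster_grid(matrix(runif(nr * nc, 0.01, 1), nr, nc),
                               origin = c(0, nr), gsd = 1)
  bands <- list(blue = mk(), green = mk(), red = mk(), rededge = mk(),
                nir = mk())
  oracle <- list(
    ndvi  = function(p) (p["nir"] - p["red"]) / (p["nir"] + p["red"]),
    gndvi = function(p) (p["nir"] - p["green"]) / (p["nir"] + p["green"]),
    ndre  = function(p) (p["nir"] - p["rededge"]) / (p["nir"] + p["rededge"]),
    cire  = function(p) p["nir"] / p["rededge"] - 1,
    lci   = function(p) (p["nir"] - p["rededge"]) / (p["nir"] + p["red"]))
  for (ix in names(oracle)) {
    got <- index_map(bands, ix)$values
    want <- matrix(0, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      p <- vapply(bands, function(b) b$values[i, j], numeric(1))
      want[i, j] <- unname(oracle[[ix]](p))
    }
    expect_equal(got, want, info = ix)
  }
})

test_that("index symmetry zeros and worked values hold", {
  g <- function(v) raster_grid(matrix(v, 2, 2), origin = c(0, 2), gsd = 1)
  b <- list(nir = g(0.8), red = g(0.8), rededge = g(0.8), green = g(0.3))
  expect_true(all(index_map(b, "ndvi")$values == 0))
  expect_true(all(index_map(b, "ndre")$values == 0))
  expect_true(all(index_map(b, "cire")$values == 0))
  b2 <- list(nir = g(0.8), rededge = g(0.4), red = g(0.1))
  expect_equal(index_map(b2, "cire")$values[1, 1], 1.0)
  expect_equal(index_map(b2, "ndvi")$values[1, 1], (0.8 - 0.1) / (0.8 + 0.1))
  # red and green NDVI variants are genuinely different quantities
  b3 <- list(nir = g(0.8), red = g(0.1), green = g(0.2))
  expect_false(isTRUE(all.equal(index_map(b3, "ndvi")$values,
                                index_map(b3, "gndvi")$values)))
})

test_that("zero denominators become nodata, with a count attached", {
  g <- function(v) raster_grid(matrix(v, 1, 2), origin = c(0, 1), gsd = 1)
  b <- list(nir = g(c(0, 0.5)), red = g(c(0, 0.5)))
  im <- index_map(b, "ndvi")
  expect_true(is.na(im$values[1, 1]))
  expect_identical(im$values[1, 2], 0)
  b2 <- list(nir = g(c(0.5, 0.5)), rededge = g(c(0, 0.2)))
  im2 <- index_map(b2, "cire")
  expect_true(is.na(im2$values[1, 1]))
  expect_identical(attr(im2, "n_zero_denom"), 1L)
  expect_error(index_map(list(nir = g(1)), "ndvi"), "missing band\\(s\\): red")
  expect_error(index_map(list(nir = g(1)), "nope"), "unknown index")
})

test_that("plot index means honour the mask mode", {
  nr <- 10
  ndvi <- raster_grid(matrix(0.1, nr, nr), origin = c(0, 1), gsd = 0.1)
  ndvi$values[, 1:5] <- 0.8
  mask <- raster_grid((ndvi$values == 0.8) + 0, origin = c(0, 1), gsd = 0.1)
  p <- rect_plot("A", 0, 0, 1, 1)
  expect_equal(as.numeric(plot_index_mean(ndvi, mask, p)), 0.8)
  expect_equal(as.numeric(plot_index_mean(ndvi, mask, p, mask_mode = "plot")),
               mean(c(0.8, 0.1)))
  none <- raster_grid(matrix(0, nr, nr), origin = c(0, 1), gsd = 0.1)
  res <- plot_index_mean(ndvi, none, p)
  expect_true(is.na(res))
  expect_true(attr(res, "no_canopy"))
})

test_that("the full trait table matches generator truth on a 3-plot scene", {
  tr <- scene_truth(n_plots = 3, canopy_scale = c(0.6, 0.8, 1),
                    dsm_noise_sd = 0, grid_offset = "none")
  rec <- run_pipeline(tr, gsd_pair()[["fine"]])
  expect_identical(nrow(rec), 3L)
  expect_identical(rec$plot_id, tr$plot_truth$plot_id)
  expect_rel_error_lt(rec$volume, tr$plot_truth$true_volume, 0.01)
  expect_rel_error_lt(rec$mean_height, tr$plot_truth$true_mean_height, 0.03)
  expect_true(all(abs(rec$coverage - tr$plot_truth$true_coverage) < 0.01))
  leaf_ndvi <- unname((tr$leaf_reflectance["nir"] - tr$leaf_reflectance["red"]) /
                        (tr$leaf_reflectance["nir"] + tr$leaf_reflectance["red"]))
  expect_equal(rec$ndvi, rep(leaf_ndvi, 3))
  expect_true(all(rec$ndvi >= -1 & rec$ndvi <= 1))
  expect_true(all(rec$ndre >= -1 & rec$ndre <= 1))
  expect_true(all(rec$cire >= -1))
})

test_that("an all-zero mask yields flagged zero-volume records", {
  tr <- scene_truth(n_plots = 2, dsm_noise_sd = 0)
  sc <- make_scene(tr, 1 / 60)
  bare <- make_bareground_scene(tr, 1 / 60)
  planes <- estimate_base_planes(bare$dsm, bare$plots)
  zero <- raster_grid(matrix(0, nrow(sc$dsm$values), ncol(sc$dsm$values)),
                      origin = c(sc$dsm$origin_x, sc$dsm$origin_y),
                      gsd = c(sc$dsm$gsd_x, sc$dsm$gsd_y), crs = sc$dsm$crs)
  rec <- extract_traits(sc$dsm, sc$bands, zero, sc$plots, planes)
  expect_true(all(rec$no_canopy))
  expect_true(all(rec$volume == 0))
  expect_true(all(rec$coverage == 0))
  expect_true(all(is.na(rec$ndvi)))
})

test_that("failed plots are reported while others still process", {
  tr <- scene_truth(n_plots = 2, dsm_noise_sd = 0)
  sc <- make_scene(tr, 1 / 60)
  bare <- make_bareground_scene(tr, 1 / 60)
  planes <- estimate_base_planes(bare$dsm, bare$plots)
  plots <- as_plot_collection(c(unclass(sc$plots)[1:2],
                                list(rect_plot("OFF", 900, 900, 1, 1))))
  expect_warning(rec <- extract_traits(sc$dsm, sc$bands, sc$mask, plots,
                                       planes), "OFF")
  expect_identical(nrow(rec), 2L)
  expect_match(attr(rec, "errors"), "OFF")
})

test_that("reruns on identical inputs write byte-identical CSVs", {
  tr <- scene_truth(n_plots = 1, dsm_noise_sd = 0.01, seed = 5)
  dir <- withr::local_tempdir()
  f <- function(path) {
    rec <- run_pipeline(tr, 1 / 60)
    write_traits(rec, path)
    path
  }
  a <- f(file.path(dir, "a.csv")); b <- f(file.path(dir, "b.csv"))
  expect_identical(readLines(a), readLines(b))
})

test_that("heights and volumes are invariant to a DSM translation", {
  tr <- scene_truth(n_plots = 1, dsm_noise_sd = 0.005, seed = 21)
  sc <- make_scene(tr, 1 / 60)
  bare <- make_bareground_scene(tr, 1 / 60)
  shift <- 3.7
  rec0 <- extract_traits(sc$dsm, sc$bands, sc$mask, sc$plots,
                         estimate_base_planes(bare$dsm, bare$plots))
  dsm_s <- sc$dsm; dsm_s$values <- dsm_s$values + shift
  bare_s <- bare$dsm; bare_s$values <- bare_s$values + shift
  rec1 <- extract_traits(dsm_s, sc$bands, sc$mask, sc$plots,
                         estimate_base_planes(bare_s, bare$plots))
  expect_equal(rec1$mean_height, rec0$mean_height, tolerance = 1e-12)
  expect_equal(rec1$volume, rec0$volume, tolerance = 1e-12)
})
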