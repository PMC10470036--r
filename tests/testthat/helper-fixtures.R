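# shared fixture builders; everything is generated in code at test time

# small grid with sequential values for transform-sensitive checks
seq_grid <- function(nr = 4, nc = 5, gsd = 1, origin = c(0, nr * gsd),
                     crs = NA_character_) {
  raster_grid(matrix(seq_len(nr * nc), nr, nc), origin = origin, gsd = gsd,
              crs = crs)
}

# single-plot truth wrapping one explicit canopy, aligned grid, no noise
one_plant_truth <- function(shape = "hemiellipsoid", a = 0.15, b = 0.15,
                            height = 0.4, x = 2.25, y = 1.125,
                            noise = 0, margin = 0.45, seed = 1,
                            grid_offset = "none") {
  scene_truth(n_plots = 1, margin = margin, dsm_noise_sd = noise,
              seed = seed, grid_offset = grid_offset,
              plants = data.frame(plot = 1, x = x, y = y, a = a, b = b,
                                  height = height, shape = shape))
}

# run the full per-date pipeline on a scene pair (bare planes + traits)
run_pipeline <- function(truth, gsd) {
  sc <- make_scene(truth, gsd)
  bare <- make_bareground_scene(truth, gsd)
  planes <- estimate_base_planes(bare$dsm, bare$plots,
                                 source_date = "bare-soil")
  extract_traits(sc$dsm, sc$bands, sc$mask, sc$plots, planes,
                 date_label = "test")
}

expect_rel_error_lt <- function(est, truth, bound) {
  expect_true(all(abs(est - truth) / abs(truth) < bound),
              label = sprintf("relative error %s < %g",
                              paste(signif(abs(est - truth) / abs(truth), 3),
                                    collapse = ", "), bound))
}
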