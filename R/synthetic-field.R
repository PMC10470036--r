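#' Parameters and ground truth of a synthetic potato field
#'
#' Defines an analytic field scene: ridged bare soil, a regular stand of
#' parametric plant canopies on the ridge tops, and pure soil/leaf
#' reflectance spectra for the five camera bands. Every derived trait the
#' pipeline estimates (mean canopy height, canopy volume, ground coverage)
#' has a closed form here, so pipeline output can be compared against
#' exact truth at any ground sampling distance.
#'
#' The defaults reproduce a typical hilled potato trial: plots of
#' 4.5 m x 2.25 m, ridges 0.30 m high at 0.75 m spacing, plants at 0.30 m
#' spacing along each ridge. The ridge cross-section is a trapezoid wave
#' (flat crest of width `ridge_top_width`, flat furrow bottom of width
#' `furrow_width`, linear flanks); the flat crest gives an unambiguous
#' "top of the ridge" altitude for base-plane estimation.
#'
#' Canopies are placed on ridge crests. A `"hemiellipsoid"` canopy with
#' semi-axes (a, b) and apex height h has volume (2/3)*pi*a*b*h and mean
#' height (2/3)*h over its footprint; a `"cuboid"` canopy (half-widths a,
#' b) has volume 4*a*b*h and mean height h. Canopies must not overlap and
#' must lie inside their plot, which keeps the per-plot truth a plain sum.
#'
#' @param n_plots Number of plots (laid out in one row along x).
#' @param plot_length,plot_width Plot dimensions in metres (x resp. y).
#' @param plot_gap Gap between neighbouring plots, metres.
#' @param margin Bare margin around the plot block, metres.
#' @param ridge_height Ridge crest height above the furrow bottom, metres.
#' @param ridge_spacing Centre-to-centre ridge spacing, metres;
#'   `plot_width` must be an integer multiple of it.
#' @param ridge_top_width Width of the flat ridge crest, metres.
#' @param furrow_width Width of the flat furrow bottom, metres.
#' @param plant_spacing In-row plant spacing, metres.
#' @param canopy_shape `"hemiellipsoid"` or `"cuboid"`.
#' @param canopy_radius_x,canopy_radius_y Footprint semi-axes (half-widths
#'   for cuboids) along x and y, metres.
#' @param canopy_height Canopy apex height above the ridge crest, metres.
#' @param canopy_scale Scalar (or per-plot vector) multiplying radii and
#'   height, e.g. to emulate plots at different growth stages.
#' @param plants Optional explicit canopy table overriding the regular
#'   stand: data.frame with columns `plot` (plot index), `x`, `y` (centre,
#'   metres relative to the plot's SW corner), `a`, `b`, `height`, and
#'   optionally `shape`.
#' @param soil_reflectance,leaf_reflectance Named reflectance vectors in
#'   `[0, 1]` for bands `blue`, `green`, `red`, `rededge`, `nir`.
#' @param dsm_noise_sd Standard deviation of i.i.d. Gaussian elevation
#'   noise added to the sampled DSM, metres (0 = noise-free).
#' @param base_altitude Absolute altitude of the furrow bottom, metres.
#' @param mixed_pixels If `TRUE`, band values of partially covered pixels
#'   are linearly mixed by sub-pixel canopy fraction; default `FALSE`
#'   (pure spectra, keeping mask and bands exactly consistent).
#' @param grid_offset Sub-pixel phase of the raster grid relative to the
#'   field: `"random"` (default) draws a seeded uniform offset in
#'   `[0, 1)^2` pixel per acquisition, emulating the arbitrary sub-pixel
#'   registration of an SfM raster product relative to the planting
#'   pattern; `"none"` anchors pixel boundaries at field coordinate 0 so
#'   that metric field positions can be grid-aligned exactly (used for
#'   controlled exactness experiments); a numeric length-2 vector in
#'   `[0, 1)` fixes the phase explicitly.
#' @param varieties Character vector of variety names assigned to plots in
#'   order (recycled); replicate numbers count repeats per variety.
#' @param seed Integer seed controlling the noise draws.
#' @return An object of class `scene_truth`; component `$plot_truth` is a
#'   data.frame of closed-form per-plot mean height (m), volume (m^3) and
#'   coverage (fraction).
#' @seealso [make_scene()], [make_height_pair()], [make_bareground_scene()]
#' @export
scene_truth <- function(n_plots = 3L,
                        plot_length = 4.5, plot_width = 2.25,
                        plot_gap = 0.75, margin = 0.375,
                        ridge_height = 0.30, ridge_spacing = 0.75,
                        ridge_top_width = 0.30, furrow_width = 0.15,
                        plant_spacing = 0.30,
                        canopy_shape = c("hemiellipsoid", "cuboid"),
                        canopy_radius_x = 0.15, canopy_radius_y = 0.15,
                        canopy_height = 0.40, canopy_scale = 1,
                        plants = NULL,
                        soil_reflectance = c(blue = 0.06, green = 0.08,
                                             red = 0.15, rededge = 0.18,
                                             nir = 0.25),
                        leaf_reflectance = c(blue = 0.04, green = 0.10,
                                             red = 0.05, rededge = 0.35,
                                             nir = 0.80),
                        dsm_noise_sd = 0.01, base_altitude = 100,
                        mixed_pixels = FALSE, grid_offset = "random",
                        varieties = c("Euroviva", "Etana", "Priska",
                                      "Sorentina", "Montana", "Toyoshiro",
                                      "Konahime", "Irish cobbler"),
                        seed = 1L) {
  canopy_shape <- match.arg(canopy_shape)
  n_plots <- as.integer(n_plots)
  stopifnot(n_plots >= 1L, plot_length > 0, plot_width > 0, margin >= 0,
            ridge_height >= 0, ridge_spacing > 0, plant_spacing > 0,
            ridge_top_width > 0, furrow_width >= 0, dsm_noise_sd >= 0,
            canopy_height >= 0)
  n_ridges <- plot_width / ridge_spacing
  if (abs(n_ridges - round(n_ridges)) > 1e-9)
    stop("`plot_width` must be an integer multiple of `ridge_spacing`",
         call. = FALSE)
  n_ridges <- as.integer(round(n_ridges))
  if (ridge_top_width + furrow_width >= ridge_spacing)
    stop("ridge top plus furrow bottom exceed the ridge spacing", call. = FALSE)
  bands <- c("blue", "green", "red", "rededge", "nir")
  for (nm in c("soil_reflectance", "leaf_reflectance")) {
    v <- get(nm)
    if (!all(bands %in% names(v)))
      stop(sprintf("`%s` must name all of: %s", nm,
                   paste(bands, collapse = ", ")), call. = FALSE)
    if (any(v < 0 | v > 1))
      stop(sprintf("`%s` values must be in [0, 1]", nm), call. = FALSE)
  }
  canopy_scale <- rep_len(canopy_scale, n_plots)
  if (any(canopy_scale < 0)) stop("`canopy_scale` must be >= 0", call. = FALSE)
  if (is.character(grid_offset)) {
    if (!grid_offset %in% c("random", "none"))
      stop('`grid_offset` must be "random", "none" or two numbers in [0, 1)',
           call. = FALSE)
  } else {
    grid_offset <- rep_len(as.numeric(grid_offset), 2L)
    if (any(grid_offset < 0 | grid_offset >= 1))
      stop("numeric `grid_offset` must lie in [0, 1)", call. = FALSE)
  }

  # plot rectangles (one row along x), SW corners
  x0 <- margin + (seq_len(n_plots) - 1L) * (plot_length + plot_gap)
  y0 <- rep(margin, n_plots)
  field_length <- 2 * margin + n_plots * plot_length +
    (n_plots - 1L) * plot_gap
  field_width <- 2 * margin + plot_width

  vars <- rep_len(varieties, n_plots)
  reps <- stats::ave(seq_len(n_plots), vars, FUN = seq_along)
  plot_ids <- sprintf("P%02d", seq_len(n_plots))

  if (is.null(plants)) {
    n_per_row <- as.integer(floor(plot_length / plant_spacing + 1e-9))
    plants <- do.call(rbind, lapply(seq_len(n_plots), function(p) {
      s <- canopy_scale[p]
      if (s == 0 || n_per_row == 0L) return(NULL)
      px <- (seq_len(n_per_row) - 0.5) * plant_spacing
      py <- (seq_len(n_ridges) - 0.5) * ridge_spacing
      data.frame(plot = p,
                 x = rep(px, times = n_ridges),
                 y = rep(py, each = n_per_row),
                 a = canopy_radius_x * s, b = canopy_radius_y * s,
                 height = canopy_height * s, shape = canopy_shape)
    }))
    if (is.null(plants))
      plants <- data.frame(plot = integer(), x = numeric(), y = numeric(),
                           a = numeric(), b = numeric(), height = numeric(),
                           shape = character())
  } else {
    plants <- as.data.frame(plants)
    need <- c("plot", "x", "y", "a", "b", "height")
    if (!all(need %in% names(plants)))
      stop(sprintf("`plants` must have columns: %s",
                   paste(need, collapse = ", ")), call. = FALSE)
    if (is.null(plants$shape)) plants$shape <- canopy_shape
  }
  .validate_plants(plants, x0, y0, plot_length, plot_width)

  # closed-form per-plot truth
  shp <- plants$shape
  v_one <- ifelse(shp == "hemiellipsoid",
                  (2 / 3) * pi * plants$a * plants$b * plants$height,
                  4 * plants$a * plants$b * plants$height)
  a_one <- ifelse(shp == "hemiellipsoid", pi * plants$a * plants$b,
                  4 * plants$a * plants$b)
  vol <- fpr <- numeric(n_plots)
  if (nrow(plants)) {
    agg_v <- rowsum(v_one, plants$plot)
    agg_a <- rowsum(a_one, plants$plot)
    idx <- as.integer(rownames(agg_v))
    vol[idx] <- agg_v; fpr[idx] <- agg_a
  }
  plot_area <- plot_length * plot_width
  plot_truth <- data.frame(
    plot_id = plot_ids, variety = vars, replicate = reps,
    true_mean_height = ifelse(fpr > 0, vol / fpr, 0),
    true_volume = vol,
    true_coverage = fpr / plot_area,
    stringsAsFactors = FALSE)
  if (any(plot_truth$true_coverage > 1 + 1e-9))
    stop("canopy footprint exceeds plot area", call. = FALSE)

  structure(list(
    n_plots = n_plots, plot_length = plot_length, plot_width = plot_width,
    plot_gap = plot_gap, margin = margin,
    plot_x0 = x0, plot_y0 = y0, plot_ids = plot_ids,
    varieties = vars, replicates = reps,
    field_length = field_length, field_width = field_width,
    ridge_height = ridge_height, ridge_spacing = ridge_spacing,
    ridge_top_width = ridge_top_width, furrow_width = furrow_width,
    plant_spacing = plant_spacing, canopy_shape = canopy_shape,
    canopy_radius_x = canopy_radius_x, canopy_radius_y = canopy_radius_y,
    canopy_height = canopy_height, canopy_scale = canopy_scale,
    plants = plants,
    soil_reflectance = soil_reflectance[bands],
    leaf_reflectance = leaf_reflectance[bands],
    dsm_noise_sd = dsm_noise_sd, base_altitude = base_altitude,
    mixed_pixels = mixed_pixels, grid_offset = grid_offset,
    seed = as.integer(seed), plot_truth = plot_truth),
    class = "scene_truth")
}

.validate_plants <- function(plants, x0, y0, plot_length, plot_width) {
  if (!nrow(plants)) return(invisible(TRUE))
  eps <- 1e-9
  for (i in seq_len(nrow(plants))) {
    p <- plants[i, ]
    if (p$x - p$a < -eps || p$x + p$a > plot_length + eps ||
        p$y - p$b < -eps || p$y + p$b > plot_width + eps)
      stop(sprintf("canopy footprint %d extends outside its plot", i),
           call. = FALSE)
  }
  # non-overlap (bbox interiors) within each plot keeps truth a plain sum
  for (pl in unique(plants$plot)) {
    pp <- plants[plants$plot == pl, ]
    n <- nrow(pp)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (abs(pp$x[i] - pp$x[j]) < pp$a[i] + pp$a[j] - eps &&
          abs(pp$y[i] - pp$y[j]) < pp$b[i] + pp$b[j] - eps)
        stop("overlapping canopy footprints: ground truth would not be a sum of single-plant volumes",
             call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %d plot(s) %.3g x %.3g m, %d plant(s), shape %s\n",
              x$n_plots, x$plot_length, x$plot_width, nrow(x$plants),
              x$canopy_shape))
  cat(sprintf("  ridges %.2f m high every %.2f m; dsm noise sd %.3g m; seed %d\n",
              x$ridge_height, x$ridge_spacing, x$dsm_noise_sd, x$seed))
  print(x$plot_truth, row.names = FALSE)
  invisible(x)
}

# trapezoid-wave ridge cross-section as a function of y (crests run along x)
.soil_profile <- function(y, truth) {
  p2 <- truth$ridge_spacing / 2
  t2 <- truth$ridge_top_width / 2
  f2 <- truth$furrow_width / 2
  rel <- (y - truth$margin) %% truth$ridge_spacing
  d <- abs(rel - p2)                       # distance from nearest crest centre
  h <- numeric(length(y))
  h[d <= t2] <- truth$ridge_height
  flank <- d > t2 & d < p2 - f2
  h[flank] <- truth$ridge_height * (p2 - f2 - d[flank]) / (p2 - f2 - t2)
  h
}

# canopy height surface sampled at pixel centres; 0 where uncovered
.canopy_surface <- function(truth, cx, cy) {
  h <- matrix(0, length(cy), length(cx))
  if (!nrow(truth$plants)) return(h)
  for (i in seq_len(nrow(truth$plants))) {
    p <- truth$plants[i, ]
    ax <- truth$plot_x0[p$plot] + p$x
    ay <- truth$plot_y0[p$plot] + p$y
    jc <- which(cx >= ax - p$a & cx <= ax + p$a)
    jr <- which(cy >= ay - p$b & cy <= ay + p$b)
    if (!length(jc) || !length(jr)) next
    dx <- (cx[jc] - ax) / p$a
    dy <- (cy[jr] - ay) / p$b
    if (p$shape == "hemiellipsoid") {
      u <- outer(dy^2, dx^2, `+`)
      hp <- matrix(0, length(jr), length(jc))
      inside <- u < 1
      hp[inside] <- p$height * sqrt(1 - u[inside])
    } else {
      hp <- matrix(p$height, length(jr), length(jc))
    }
    h[jr, jc] <- pmax(h[jr, jc], hp)
  }
  h
}

# run `code` under `seed` without disturbing the caller's RNG stream
with_preserved_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Sample a synthetic field scene at a given ground sampling distance
#'
#' Point-samples the analytic field surface of a [scene_truth] at pixel
#' centres on a regular grid of the requested GSD. The DSM at a pixel
#' centre is the soil surface (ridge profile) where uncovered, and
#' ridge-crest altitude plus the canopy height function where a canopy
#' covers the centre (the sensor sees the canopy surface, which sits on
#' the ridge crest), plus seeded i.i.d. Gaussian noise. Band rasters carry
#' the pure leaf spectrum on covered pixel centres and the pure soil
#' spectrum elsewhere; the mask is 1 exactly where the canopy height at
#' the pixel centre is positive. Identical seeds give bit-identical
#' scenes.
#'
#' @param truth A [scene_truth].
#' @param gsd Ground sampling distance, metres/pixel (see [gsd_pair()] for
#'   the 15 m / 30 m survey values).
#' @param crs CRS identifier stamped on the generated rasters.
#' @return An object of class `uav_scene`: list with elements `dsm`,
#'   `bands` (named list of five [raster_grid]s), `mask`, `plots`
#'   (a `uav_plots` collection), `truth`, and `gsd`.
#' @export
make_scene <- function(truth, gsd, crs = "EPSG:32654") {
  stopifnot(inherits(truth, "scene_truth"))
  if (!is.numeric(gsd) || length(gsd) != 1L || gsd <= 0)
    stop("`gsd` must be a positive scalar in metres/pixel", call. = FALSE)
  if (gsd > min(truth$plot_length, truth$plot_width))
    stop(sprintf("plot unresolvable: gsd %.4g m exceeds the plot's short side %.4g m",
                 gsd, min(truth$plot_length, truth$plot_width)), call. = FALSE)
  # one seeded stream per acquisition: sub-pixel grid phase, then noise
  drawn <- with_preserved_seed(truth$seed, {
    off <- truth$grid_offset %||% "none"
    u <- if (identical(off, "random")) stats::runif(2L)
         else if (identical(off, "none")) c(0, 0) else off
    origin_x <- -u[1L] * gsd
    origin_y <- truth$field_width + u[2L] * gsd
    nc <- as.integer(ceiling((truth$field_length - origin_x) / gsd - 1e-9))
    nr <- as.integer(ceiling(origin_y / gsd - 1e-9))
    noise <- if (truth$dsm_noise_sd > 0)
      matrix(stats::rnorm(nr * nc, 0, truth$dsm_noise_sd), nr, nc)
    else NULL
    list(origin = c(origin_x, origin_y), nc = nc, nr = nr, noise = noise)
  })
  origin <- drawn$origin; nc <- drawn$nc; nr <- drawn$nr
  cx <- origin[1L] + (seq_len(nc) - 0.5) * gsd
  cy <- origin[2L] - (seq_len(nr) - 0.5) * gsd   # north to south

  soil <- truth$base_altitude +
    matrix(.soil_profile(cy, truth), nr, nc)
  canopy <- .canopy_surface(truth, cx, cy)
  covered <- canopy > 0
  dsm <- soil
  dsm[covered] <- truth$base_altitude + truth$ridge_height + canopy[covered]
  if (!is.null(drawn$noise)) dsm <- dsm + drawn$noise

  frac <- NULL
  if (isTRUE(truth$mixed_pixels)) frac <- .subpixel_fraction(truth, cx, cy, gsd)
  bands <- lapply(names(truth$soil_reflectance), function(bn) {
    s <- truth$soil_reflectance[[bn]]; l <- truth$leaf_reflectance[[bn]]
    if (is.null(frac)) {
      m <- matrix(s, nr, nc); m[covered] <- l
    } else {
      m <- s + (l - s) * frac
    }
    raster_grid(m, origin = origin, gsd = gsd, crs = crs)
  })
  names(bands) <- names(truth$soil_reflectance)

  plots <- as_plot_collection(lapply(seq_len(truth$n_plots), function(p)
    rect_plot(truth$plot_ids[p], truth$plot_x0[p], truth$plot_y0[p],
              truth$plot_length, truth$plot_width,
              variety = truth$varieties[p],
              replicate = truth$replicates[p])))
  attr(plots, "crs") <- crs

  structure(list(
    dsm = raster_grid(dsm, origin = origin, gsd = gsd, crs = crs),
    bands = bands,
    mask = raster_grid(covered + 0, origin = origin, gsd = gsd, crs = crs),
    plots = plots, truth = truth, gsd = gsd),
    class = "uav_scene")
}

# 3x3 sub-pixel canopy coverage fraction, used only when mixed_pixels=TRUE
.subpixel_fraction <- function(truth, cx, cy, gsd) {
  off <- (c(1, 2, 3) / 3 - 0.5) * gsd  # sub-centre offsets
  acc <- 0
  for (ox in off) for (oy in off)
    acc <- acc + (.canopy_surface(truth, cx + ox, cy + oy) > 0)
  acc / 9
}

#' @export
print.uav_scene <- function(x, ...) {
  cat(sprintf("<uav_scene> gsd %.5g m/pixel, %d x %d pixels, %d plot(s)\n",
              x$gsd, nrow(x$dsm$values), ncol(x$dsm$values),
              length(x$plots)))
  invisible(x)
}

#' Bare-ground scene (pre-emergence survey)
#'
#' Same field and seed as [make_scene()] but with every plant removed:
#' the DSM is the pure ridge profile plus noise and the mask is all zero.
#' This is the synthetic counterpart of the early bare-soil flight used to
#' estimate per-plot base planes.
#'
#' @inheritParams make_scene
#' @return A `uav_scene` with zero canopy and zero true volume/coverage.
#' @export
make_bareground_scene <- function(truth, gsd, crs = "EPSG:32654") {
  stopifnot(inherits(truth, "scene_truth"))
  bare <- truth
  bare$plants <- truth$plants[0, , drop = FALSE]
  bare$plot_truth$true_mean_height <- 0
  bare$plot_truth$true_volume <- 0
  bare$plot_truth$true_coverage <- 0
  make_scene(bare, gsd, crs = crs)
}

#' Paired acquisitions of one field at two flight altitudes
#'
#' Samples the same continuous field surface at the two survey GSDs
#' (defaults: 0.833 cm/pixel for the 15 m flight and 1.667 cm/pixel for
#' 30 m, i.e. exactly 1/120 and 1/60 m). Both scenes share one seed and
#' one underlying surface; only the sampling density (and hence the
#' per-pixel noise draws) differ.
#'
#' @inheritParams make_scene
#' @param gsd Named length-2 vector of GSDs in metres; see [gsd_pair()].
#' @return List with elements `fine` and `coarse`, each a `uav_scene`.
#' @export
make_height_pair <- function(truth, gsd = gsd_pair(), crs = "EPSG:32654") {
  stopifnot(length(gsd) == 2L)
  gsd <- sort(as.numeric(gsd))
  list(fine = make_scene(truth, gsd[1L], crs = crs),
       coarse = make_scene(truth, gsd[2L], crs = crs))
}

#' Export a scene to disk
#'
#' Writes the DSM, the five band rasters and the mask as ESRI ASCII grids,
#' the plot polygons as GeoJSON, and the generator parameters plus
#' closed-form truth as a JSON sidecar.
#'
#' @param scene A `uav_scene` from [make_scene()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the files written, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "uav_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(dsm = file.path(dir, "dsm.asc"))
  write_raster(scene$dsm, paths[["dsm"]])
  for (bn in names(scene$bands)) {
    p <- file.path(dir, sprintf("band_%s.asc", bn))
    write_raster(scene$bands[[bn]], p)
    paths[[paste0("band_", bn)]] <- p
  }
  paths[["mask"]] <- file.path(dir, "mask.asc")
  write_raster(scene$mask, paths[["mask"]])
  paths[["plots"]] <- file.path(dir, "plots.geojson")
  write_plots(scene$plots, paths[["plots"]], crs = scene$dsm$crs)
  paths[["truth"]] <- file.path(dir, "truth.json")
  tr <- scene$truth
  tr$plants <- as.list(tr$plants)
  tr$plot_truth <- as.list(tr$plot_truth)
  class(tr) <- NULL
  jsonlite::write_json(list(gsd = scene$gsd, truth = tr), paths[["truth"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
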