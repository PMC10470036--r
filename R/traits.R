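#' Vegetation index definitions
#'
#' The four red/red-edge indices computed by the pipeline, plus the
#' green-band NDVI variant:
#'
#' * `ndvi`  = (NIR - Red) / (NIR + Red)
#' * `gndvi` = (NIR - Green) / (NIR + Green)
#' * `ndre`  = (NIR - RedEdge) / (NIR + RedEdge)
#' * `cire`  = NIR / RedEdge - 1 (chlorophyll index, red edge)
#' * `lci`   = (NIR - RedEdge) / (NIR + Red) (leaf chlorophyll index)
#'
#' NDVI is defined on the Red band by default; the green-band normalised
#' difference is exposed separately as GNDVI so either can be selected
#' explicitly. For reflectances in `[0, 1]`, `ndvi`, `gndvi` and `ndre`
#' lie in `[-1, 1]` and `cire >= -1`.
#'
#' @return Named list; each element has `bands` (character vector of band
#'   names used) and `fun` (vectorised formula over those bands).
#' @export
vegetation_indices <- function() {
  list(
    ndvi  = list(bands = c("nir", "red"),
                 fun = function(nir, red) (nir - red) / (nir + red)),
    gndvi = list(bands = c("nir", "green"),
                 fun = function(nir, green) (nir - green) / (nir + green)),
    ndre  = list(bands = c("nir", "rededge"),
                 fun = function(nir, rededge) (nir - rededge) / (nir + rededge)),
    cire  = list(bands = c("nir", "rededge"),
                 fun = function(nir, rededge) nir / rededge - 1),
    lci   = list(bands = c("nir", "rededge", "red"),
                 fun = function(nir, rededge, red) (nir - rededge) / (nir + red))
  )
}

#' Per-pixel vegetation-index map
#'
#' Evaluates an index formula pixelwise over aligned band rasters. A pixel
#' is nodata where any operand band is nodata or the formula's denominator
#' is zero (division by zero yields nodata, never infinity; the count of
#' zero-denominator pixels is attached as attribute `"n_zero_denom"`).
#'
#' @param bands Named list of aligned [raster_grid]s; names among `blue`,
#'   `green`, `red`, `rededge`, `nir`.
#' @param index Index name (see [vegetation_indices()]) or a list with
#'   elements `bands` and `fun` for a custom definition.
#' @return A [raster_grid] of index values on the bands' frame.
#' @export
index_map <- function(bands, index = "ndvi") {
  defs <- vegetation_indices()
  if (is.character(index)) {
    index <- tolower(index)
    if (!index %in% names(defs))
      stop(sprintf("unknown index '%s' (available: %s)", index,
                   paste(names(defs), collapse = ", ")), call. = FALSE)
    def <- defs[[index]]
  } else def <- index
  missing <- setdiff(def$bands, names(bands))
  if (length(missing))
    stop(sprintf("missing band(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  ref <- bands[[def$bands[1L]]]
  for (bn in def$bands[-1L])
    if (!grids_aligned(bands[[bn]], ref))
      stop(sprintf("band '%s' is not aligned to band '%s'", bn,
                   def$bands[1L]), call. = FALSE)
  args <- lapply(def$bands, function(bn) bands[[bn]]$values)
  names(args) <- def$bands
  old <- options(warn = -1); on.exit(options(old))
  v <- do.call(def$fun, args)
  nz <- sum(is.infinite(v), na.rm = TRUE)
  v[!is.finite(v)] <- NA_real_
  out <- raster_grid(v, origin = c(ref$origin_x, ref$origin_y),
                     gsd = c(ref$gsd_x, ref$gsd_y), crs = ref$crs)
  attr(out, "n_zero_denom") <- nz
  out
}

#' Per-pixel canopy height map of one plot
#'
#' Canopy height is DSM altitude minus the plot's base-plane altitude,
#' `H = Z - zplane`, evaluated at masked (vegetation) pixel centres inside
#' the plot polygon; everything else is nodata. Negative differences —
#' typically furrow or soil pixels misclassified as canopy, or elevation
#' noise early in the season — are clipped to 0 by default so that they
#' cannot produce negative volumes.
#'
#' @param dsm [raster_grid] of surface altitudes (m), same frame as the
#'   mask.
#' @param plane A `base_plane` for this plot, or the planes data.frame
#'   from [estimate_base_planes()].
#' @param mask A [vegetation_mask] (or 0/1 grid) aligned to `dsm`.
#' @param plot The [plot_geometry] the plane belongs to.
#' @param clip_negative Clip negative heights to 0 (default `TRUE`).
#' @return [raster_grid] of heights in metres; nodata outside the masked
#'   plot canopy.
#' @export
height_map <- function(dsm, plane, mask, plot, clip_negative = TRUE) {
  stopifnot(inherits(dsm, "raster_grid"), inherits(plot, "plot_geometry"))
  mg <- mask_grid(mask)
  if (!grids_aligned(dsm, mg))
    stop("DSM and mask grids are not aligned", call. = FALSE)
  plane <- .plane_for(plane, plot$plot_id)
  sel <- pixels_in_plot(dsm, plot) & !is.na(mg$values) & mg$values == 1 &
    !is.na(dsm$values)
  h <- matrix(NA_real_, nrow(dsm$values), ncol(dsm$values))
  hv <- dsm$values[sel] - plane$zplane
  if (clip_negative) hv <- pmax(hv, 0)
  h[sel] <- hv
  raster_grid(h, origin = c(dsm$origin_x, dsm$origin_y),
              gsd = c(dsm$gsd_x, dsm$gsd_y), crs = dsm$crs)
}

#' Plot-level aggregates of a height map
#'
#' `plot_mean_height()` is the arithmetic mean of the height map's
#' non-nodata (masked canopy) pixels; `plot_volume()` is the sum of
#' per-pixel volumes `gsd_x * gsd_y * H` over the same pixels, i.e. each
#' pixel contributes a column whose footprint is one ground cell. The two
#' are linked by the exact identity
#' `volume = pixel_area * n_pixels * mean_height`.
#'
#' A plot with no canopy pixels (legitimate before emergence) yields 0
#' with attribute `no_canopy = TRUE` rather than an error.
#'
#' @param hmap Height map from [height_map()].
#' @return Mean height in metres, resp. volume in cubic metres; attribute
#'   `"n_pixels"` carries the canopy pixel count.
#' @export
plot_mean_height <- function(hmap) {
  v <- hmap$values[!is.na(hmap$values)]
  out <- if (length(v)) mean(v) else 0
  attr(out, "n_pixels") <- length(v)
  attr(out, "no_canopy") <- length(v) == 0L
  out
}

#' @rdname plot_mean_height
#' @export
plot_volume <- function(hmap) {
  v <- hmap$values[!is.na(hmap$values)]
  out <- if (length(v)) sum(v) * pixel_area(hmap) else 0
  attr(out, "n_pixels") <- length(v)
  attr(out, "no_canopy") <- length(v) == 0L
  out
}

#' Ground coverage of a plot
#'
#' Fraction of the plot polygon's area covered by vegetation pixels:
#' (count of mask = 1 pixel centres inside the polygon) x pixel area,
#' divided by the polygon area. Values can exceed 1 by at most one
#' boundary-pixel layer's worth of discretisation.
#'
#' @param mask [vegetation_mask] or 0/1 [raster_grid].
#' @param plot A [plot_geometry].
#' @return Coverage fraction; attribute `"n_pixels"` is the canopy count.
#' @export
plot_coverage <- function(mask, plot) {
  mg <- mask_grid(mask)
  inside <- pixels_in_plot(mg, plot)
  if (!any(inside))
    stop(sprintf("no mask pixel centres fall inside plot '%s'", plot$plot_id),
         call. = FALSE)
  mv <- mg$values[inside]
  n1 <- sum(mv == 1, na.rm = TRUE)
  out <- n1 * pixel_area(mg) / polygon_area(plot)
  attr(out, "n_pixels") <- n1
  out
}

#' Plot-mean vegetation index
#'
#' Mean of an index map over the plot's pixels. With
#' `mask_mode = "canopy"` (the default, matching segmented-pixel
#' averaging) only masked vegetation pixels enter the mean; with
#' `mask_mode = "plot"` all plot pixels do, which mimics whole-plot
#' proximal sensors such as a handheld GreenSeeker scan.
#'
#' @param index_grid [raster_grid] from [index_map()].
#' @param mask [vegetation_mask] or 0/1 grid aligned to `index_grid`
#'   (ignored when `mask_mode = "plot"`).
#' @param plot A [plot_geometry].
#' @param mask_mode `"canopy"` or `"plot"`.
#' @return Mean index value; `NA` with attribute `no_canopy = TRUE` when
#'   the selection is empty.
#' @export
plot_index_mean <- function(index_grid, mask, plot,
                            mask_mode = c("canopy", "plot")) {
  mask_mode <- match.arg(mask_mode)
  stopifnot(inherits(index_grid, "raster_grid"))
  sel <- pixels_in_plot(index_grid, plot)
  if (mask_mode == "canopy") {
    mg <- mask_grid(mask)
    if (!grids_aligned(index_grid, mg))
      stop("index and mask grids are not aligned", call. = FALSE)
    sel <- sel & !is.na(mg$values) & mg$values == 1
  }
  v <- index_grid$values[sel]
  v <- v[!is.na(v)]
  out <- if (length(v)) mean(v) else NA_real_
  attr(out, "no_canopy") <- length(v) == 0L
  out
}

#' Extract the full per-plot trait table
#'
#' Runs the whole per-date pipeline over a plot collection: canopy height
#' map and its mean, summed canopy volume, ground coverage, and plot-mean
#' vegetation indices. One row per plot; plots that fail (e.g. no pixels
#' inside the DSM) are reported in attribute `"errors"` with their plot id
#' while the remaining plots are still processed. Output is deterministic
#' given identical inputs.
#'
#' @param dsm [raster_grid] of surface altitude for the acquisition date.
#' @param bands Named list of aligned reflectance [raster_grid]s.
#' @param mask [vegetation_mask] (or 0/1 grid) aligned to `dsm`.
#' @param plots `uav_plots` collection.
#' @param planes Planes data.frame from [estimate_base_planes()] /
#'   [read_base_planes()]; every plot must have one.
#' @param date_label Acquisition label stored in the records.
#' @param days_after_planting Integer DAP stored in the records.
#' @param indices Character vector of index names to report.
#' @param mask_mode Index averaging mode, see [plot_index_mean()].
#' @param clip_negative Clip negative heights, see [height_map()].
#' @return data.frame (one `TraitRecord` per plot): identity columns,
#'   `mean_height` (m), `volume` (m^3), `coverage` (fraction), one column
#'   per index, `n_canopy_pixels`, `no_canopy`.
#' @export
extract_traits <- function(dsm, bands, mask, plots, planes,
                           date_label = NA_character_,
                           days_after_planting = NA_integer_,
                           indices = c("ndvi", "ndre", "cire", "lci"),
                           mask_mode = c("canopy", "plot"),
                           clip_negative = TRUE) {
  mask_mode <- match.arg(mask_mode)
  plots <- as_plot_collection(plots)
  mg <- mask_grid(mask)
  imaps <- lapply(indices, function(ix) index_map(bands, ix))
  names(imaps) <- indices
  errors <- character()
  rows <- lapply(plots, function(p) {
    tryCatch({
      hm <- height_map(dsm, planes, mask, p, clip_negative = clip_negative)
      mh <- plot_mean_height(hm)
      vol <- plot_volume(hm)
      cov <- plot_coverage(mask, p)
      rec <- data.frame(plot_id = p$plot_id, variety = p$variety,
                        replicate = p$replicate, date_label = date_label,
                        days_after_planting = days_after_planting,
                        mean_height = as.numeric(mh),
                        volume = as.numeric(vol),
                        coverage = as.numeric(cov),
                        stringsAsFactors = FALSE)
      for (ix in indices)
        rec[[ix]] <- as.numeric(plot_index_mean(imaps[[ix]], mask, p,
                                                mask_mode = mask_mode))
      rec$n_canopy_pixels <- attr(mh, "n_pixels")
      rec$no_canopy <- attr(mh, "no_canopy")
      rec
    }, error = function(e) {
      errors[[length(errors) + 1L]] <<-
        sprintf("plot %s (%s): %s", p$plot_id,
                if (is.na(date_label)) "no date" else date_label,
                conditionMessage(e))
      NULL
    })
  })
  out <- do.call(rbind, c(rows[!vapply(rows, is.null, logical(1))],
                          make.row.names = FALSE))
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  if (length(errors)) {
    warning(paste(errors, collapse = "; "), call. = FALSE)
    attr(out, "errors") <- errors
  }
  out
}

#' Write / read a trait table
#'
#' Plain-CSV persistence of [extract_traits()] output, one row per
#' (plot, date). Column order and names are fixed, so re-running the
#' pipeline on identical inputs reproduces the file byte-for-byte.
#'
#' @param records Trait data.frame.
#' @param path CSV path.
#' @return `write_traits()`: `path` invisibly; `read_traits()`: the
#'   data.frame.
#' @export
write_traits <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traits
#' @export
read_traits <- function(path) {
  if (!file.exists(path)) stop(sprintf("trait file not found: %s", path),
                               call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
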