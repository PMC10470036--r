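#' Read a georeferenced raster from disk
#'
#' Reads a single-band raster in ESRI ASCII grid format (`.asc`), the
#' plain-text raster interchange format understood by GDAL, QGIS and
#' ArcGIS. Both the classic square-pixel header (`CELLSIZE`) and the
#' rectangular-pixel extension (`DX`/`DY`) are supported, as are
#' `XLLCORNER`/`YLLCORNER` and `XLLCENTER`/`YLLCENTER` anchors. A sidecar
#' `.prj` file, when present, supplies the CRS, which must be projected
#' (metre units); geographic (degree) CRSs are rejected because all
#' internal lengths are metres. ASCII grids are north-up by construction,
#' so rotated or sheared geotransforms cannot occur.
#'
#' GSD values quoted in cm/pixel elsewhere (survey reports, flight logs)
#' must be converted to metres at this boundary; see [gsd_at_altitude()].
#'
#' @param path Path to a `.asc` file.
#' @return A [raster_grid]; file nodata cells become `NA`.
#' @seealso [write_raster()]
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop(sprintf("raster file not found: %s", path),
                               call. = FALSE)
  if (!grepl("\\.(asc|agr)$", path, ignore.case = TRUE))
    stop(sprintf("unsupported raster format: %s (ESRI ASCII grid required)",
                 path), call. = FALSE)
  lines <- readLines(path, n = 8L)
  hdr <- list(); nskip <- 0L
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(tok) == 2L && grepl("^[A-Za-z_]+$", tok[1L]) &&
        !is.na(suppressWarnings(as.numeric(tok[2L])))) {
      hdr[[tolower(tok[1L])]] <- as.numeric(tok[2L])
      nskip <- nskip + 1L
    } else break
  }
  req <- c("ncols", "nrows")
  if (!all(req %in% names(hdr)))
    stop(sprintf("malformed ASCII grid header in %s", path), call. = FALSE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  if (!is.null(hdr$cellsize)) {
    gsd <- c(hdr$cellsize, hdr$cellsize)
  } else if (!is.null(hdr$dx) && !is.null(hdr$dy)) {
    gsd <- c(hdr$dx, hdr$dy)
  } else stop(sprintf("no CELLSIZE or DX/DY in %s", path), call. = FALSE)
  if (!is.null(hdr$xllcorner)) {
    xll <- hdr$xllcorner; yll <- hdr$yllcorner
  } else if (!is.null(hdr$xllcenter)) {
    xll <- hdr$xllcenter - gsd[1L] / 2; yll <- hdr$yllcenter - gsd[2L] / 2
  } else stop(sprintf("no lower-left anchor in %s", path), call. = FALSE)
  vals <- scan(path, skip = nskip, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d values in %s, found %d", nr * nc, path,
                 length(vals)), call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)  # first row = north
  crs <- NA_character_
  prj <- sub("\\.[^.]+$", ".prj", path)
  if (file.exists(prj)) {
    crs <- trimws(paste(readLines(prj, warn = FALSE), collapse = " "))
    assert_projected_crs(crs)
  }
  raster_grid(m, origin = c(xll, yll + nr * gsd[2L]), gsd = gsd,
              nodata = hdr$nodata_value, crs = crs)
}

#' Write a raster to disk
#'
#' Writes ESRI ASCII grid (`.asc`); `NA` cells are written as the grid's
#' nodata sentinel (default -9999). If the grid carries a CRS a sidecar
#' `.prj` is written next to the raster. Values are written with full
#' double precision so write-then-read is the identity.
#'
#' @param grid A [raster_grid].
#' @param path Output path ending in `.asc`.
#' @param nodata Sentinel for `NA` cells; defaults to the grid's own
#'   sentinel, or -9999.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, nodata = NULL) {
  stopifnot(inherits(grid, "raster_grid"))
  if (!grepl("\\.(asc|agr)$", path, ignore.case = TRUE))
    stop(sprintf("unsupported raster format: %s (ESRI ASCII grid required)",
                 path), call. = FALSE)
  if (is.null(nodata)) nodata <- if (is.null(grid$nodata)) -9999 else grid$nodata
  v <- grid$values
  if (any(v == nodata, na.rm = TRUE))
    stop("grid contains cells equal to the nodata sentinel", call. = FALSE)
  v[is.na(v)] <- nodata
  nr <- nrow(v); nc <- ncol(v)
  square <- isTRUE(all.equal(grid$gsd_x, grid$gsd_y, tolerance = 0))
  hdr <- c(sprintf("NCOLS %d", nc), sprintf("NROWS %d", nr),
           sprintf("XLLCORNER %.17g", grid$origin_x),
           sprintf("YLLCORNER %.17g", grid$origin_y - nr * grid$gsd_y),
           if (square) sprintf("CELLSIZE %.17g", grid$gsd_x)
           else c(sprintf("DX %.17g", grid$gsd_x),
                  sprintf("DY %.17g", grid$gsd_y)),
           sprintf("NODATA_VALUE %.17g", nodata))
  body <- apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  if (!is.na(grid$crs))
    writeLines(grid$crs, sub("\\.[^.]+$", ".prj", path))
  invisible(path)
}

# Geographic CRSs carry degree units and would corrupt every length in the
# pipeline; reject them at the boundary. Identifier-string heuristic only;
# reprojection is out of scope.
assert_projected_crs <- function(crs) {
  if (is.na(crs) || !nzchar(crs)) return(invisible(TRUE))
  geographic_epsg <- c("4326", "4269", "4258", "4267", "4283", "4301", "4612", "6668")
  code <- sub("^\\s*EPSG:\\s*", "", crs, ignore.case = TRUE)
  looks_geo <- (grepl("^EPSG:", crs, ignore.case = TRUE) && code %in% geographic_epsg) ||
    grepl("longlat|longitude", crs, ignore.case = TRUE) ||
    (grepl("GEOGCS|GEOGCRS", crs) && !grepl("PROJCS|PROJCRS", crs))
  if (looks_geo)
    stop(sprintf("projected CRS required, got geographic CRS '%s'",
                 substr(crs, 1, 40)), call. = FALSE)
  invisible(TRUE)
}

#' Read plot polygons from GeoJSON
#'
#' Reads a GeoJSON `FeatureCollection` of single-ring polygons, one per
#' breeding plot, with identity attributes in the feature properties.
#' Attribute names are configurable for files produced with other naming
#' conventions.
#'
#' @param path Path to a `.geojson`/`.json` file.
#' @param id_field,variety_field,replicate_field Property names holding the
#'   plot id, variety and replicate.
#' @return A `uav_plots` collection (see [as_plot_collection()]); the
#'   file-level `crs` member, if present, is attached as attribute `"crs"`.
#' @export
read_plots <- function(path, id_field = "plot_id", variety_field = "variety",
                       replicate_field = "replicate") {
  if (!file.exists(path)) stop(sprintf("plots file not found: %s", path),
                               call. = FALSE)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  crs <- NA_character_
  if (!is.null(gj$crs$properties$name)) crs <- gj$crs$properties$name
  feats <- gj$features
  if (!length(feats)) {
    warning("empty feature collection: no plots read", call. = FALSE)
    out <- as_plot_collection(list())
    attr(out, "crs") <- crs
    return(out)
  }
  plots <- lapply(feats, function(f) {
    props <- f$properties
    for (fld in c(id_field, variety_field, replicate_field))
      if (!fld %in% names(props))
        stop(sprintf("feature missing required attribute '%s'", fld),
             call. = FALSE)
    # a present-but-null attribute (e.g. unknown variety) reads as NA
    if (is.null(props[[variety_field]])) props[[variety_field]] <- NA
    if (is.null(props[[replicate_field]])) props[[replicate_field]] <- 1L
    geom <- f$geometry
    if (!identical(geom$type, "Polygon"))
      stop(sprintf("plot '%s': only Polygon geometries are supported (got %s)",
                   props[[id_field]], geom$type), call. = FALSE)
    ring <- geom$coordinates[[1L]]
    coords <- do.call(rbind, lapply(ring, function(p) c(p[[1L]], p[[2L]])))
    plot_geometry(props[[id_field]], props[[variety_field]],
                  props[[replicate_field]], coords)
  })
  out <- as_plot_collection(plots)
  attr(out, "crs") <- crs
  out
}

#' Write plot polygons to GeoJSON
#'
#' @param plots A `uav_plots` collection or list of [plot_geometry].
#' @param path Output path.
#' @param crs Optional CRS identifier stored in the (legacy) top-level
#'   `crs` member.
#' @return `path`, invisibly.
#' @export
write_plots <- function(plots, path, crs = NA_character_) {
  plots <- as_plot_collection(plots)
  if (is.na(crs) && !is.null(attr(plots, "crs"))) crs <- attr(plots, "crs")
  feats <- lapply(unname(plots), function(p) {
    ring <- rbind(p$coords, p$coords[1L, ])
    list(type = "Feature",
         properties = list(plot_id = p$plot_id, variety = p$variety,
                           replicate = p$replicate),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) as.list(ring[i, ])))))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  if (!is.na(crs))
    gj$crs <- list(type = "name", properties = list(name = crs))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}
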