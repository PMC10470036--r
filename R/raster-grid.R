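#' In-memory georeferenced raster grid
#'
#' `raster_grid()` builds the package's basic raster container: a numeric
#' matrix of cell values plus a north-up affine geotransform. Row 1 is the
#' northern edge of the raster; world coordinates refer to pixel centres.
#' Missing cells are stored as `NA`; the `nodata` field only records the
#' sentinel used when the grid is written to disk.
#'
#' Only unrotated, north-up transforms are representable: the pixel at
#' (row `r`, column `c`, both 1-based) has centre
#' `x = origin_x + (c - 0.5) * gsd_x`, `y = origin_y - (r - 0.5) * gsd_y`,
#' where (`origin_x`, `origin_y`) is the outer north-west corner. All
#' lengths are metres, so `gsd_x * gsd_y` is the exact ground area of every
#' pixel.
#'
#' @param values Numeric matrix (rows x cols), row 1 at the north edge.
#'   `NA` marks missing cells.
#' @param origin Numeric length-2: x (west edge) and y (north edge) of the
#'   raster's outer north-west corner, in metres.
#' @param gsd Ground sampling distance in metres per pixel; length 1
#'   (square pixels) or 2 (`gsd_x`, `gsd_y`). Must be positive.
#' @param nodata Sentinel value used on disk for missing cells, or `NULL`.
#' @param crs Coordinate reference system identifier (e.g. `"EPSG:32654"`),
#'   or `NA`. Must describe a projected, metre-unit CRS.
#' @return An object of class `raster_grid`.
#' @examples
#' g <- raster_grid(matrix(1:12, 3, 4), origin = c(0, 3), gsd = 0.5)
#' dim(g)
#' pixel_area(g)
#' @export
raster_grid <- function(values, origin = c(0, 0), gsd = c(1, 1),
                        nodata = NULL, crs = NA_character_) {
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("raster must have at least one row and one column", call. = FALSE)
  gsd <- rep_len(as.numeric(gsd), 2L)
  if (any(!is.finite(gsd)) || any(gsd <= 0))
    stop("`gsd` must be positive and finite", call. = FALSE)
  origin <- as.numeric(origin)
  if (length(origin) != 2L || any(!is.finite(origin)))
    stop("`origin` must be two finite numbers (x, y)", call. = FALSE)
  if (!is.null(nodata)) {
    nodata <- as.numeric(nodata)
    values[values == nodata] <- NA_real_
  }
  structure(
    list(values = values, origin_x = origin[1L], origin_y = origin[2L],
         gsd_x = gsd[1L], gsd_y = gsd[2L],
         nodata = nodata, crs = as.character(crs)),
    class = "raster_grid"
  )
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' @export
as.matrix.raster_grid <- function(x, ...) x$values

#' @export
print.raster_grid <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<raster_grid> %d rows x %d cols\n", d[1L], d[2L]))
  cat(sprintf("  gsd     : %.6g x %.6g m/pixel\n", x$gsd_x, x$gsd_y))
  cat(sprintf("  origin  : (%.6g, %.6g) (NW corner)\n", x$origin_x, x$origin_y))
  cat(sprintf("  crs     : %s\n", if (is.na(x$crs)) "<unset>" else x$crs))
  v <- x$values[!is.na(x$values)]
  if (length(v))
    cat(sprintf("  values  : [%.6g, %.6g], %d NA\n", min(v), max(v),
                sum(is.na(x$values))))
  else cat("  values  : all NA\n")
  invisible(x)
}

#' Pixel-centre coordinates and pixel area
#'
#' `x_centers()` / `y_centers()` return the west-to-east (resp.
#' north-to-south) pixel-centre coordinates of a grid; `pixel_area()`
#' returns the exact ground area of one pixel in square metres.
#'
#' @param grid A [raster_grid].
#' @return Numeric vector of coordinates, or a single area.
#' @export
x_centers <- function(grid) {
  grid$origin_x + (seq_len(ncol(grid$values)) - 0.5) * grid$gsd_x
}

#' @rdname x_centers
#' @export
y_centers <- function(grid) {
  grid$origin_y - (seq_len(nrow(grid$values)) - 0.5) * grid$gsd_y
}

#' @rdname x_centers
#' @export
pixel_area <- function(grid) grid$gsd_x * grid$gsd_y

#' Extent of a grid
#'
#' @param grid A [raster_grid].
#' @return Named numeric: `xmin`, `xmax`, `ymin`, `ymax` (outer edges).
#' @export
grid_extent <- function(grid) {
  c(xmin = grid$origin_x,
    xmax = grid$origin_x + ncol(grid$values) * grid$gsd_x,
    ymin = grid$origin_y - nrow(grid$values) * grid$gsd_y,
    ymax = grid$origin_y)
}

#' Do two grids share one frame?
#'
#' Grids are aligned when they have identical shape, geotransform and
#' (where both are set) CRS, so their pixels correspond one-to-one.
#'
#' @param a,b [raster_grid] objects.
#' @param tol Absolute tolerance on origin and gsd, metres.
#' @return Logical scalar.
#' @export
grids_aligned <- function(a, b, tol = 1e-9) {
  identical(dim(a), dim(b)) &&
    abs(a$origin_x - b$origin_x) <= tol &&
    abs(a$origin_y - b$origin_y) <= tol &&
    abs(a$gsd_x - b$gsd_x) <= tol &&
    abs(a$gsd_y - b$gsd_y) <= tol &&
    crs_compatible(a$crs, b$crs)
}

crs_compatible <- function(a, b) {
  if (is.na(a) || is.na(b)) TRUE else identical(a, b)
}

stop_crs_mismatch <- function(a, b) {
  if (!crs_compatible(a$crs, b$crs))
    stop(sprintf("CRS mismatch: '%s' vs '%s'", a$crs, b$crs), call. = FALSE)
  invisible(TRUE)
}

#' Resample a grid onto another grid's frame
#'
#' Puts `grid` onto the shape and geotransform of `reference`.
#' `method = "nearest"` picks, for each reference pixel centre, the source
#' pixel containing that point (required for 0/1 masks).
#' `method = "average"` assigns each reference pixel the arithmetic mean of
#' the source pixels whose centres fall inside it; `NA` (nodata) source
#' pixels never enter the mean. Reference pixels that receive no source
#' pixel, or whose centre falls outside the source extent, are `NA`.
#'
#' @param grid Source [raster_grid].
#' @param reference [raster_grid] supplying the target frame.
#' @param method `"nearest"` or `"average"`.
#' @return A [raster_grid] on `reference`'s frame carrying `grid`'s values.
#' @export
resample_to <- function(grid, reference, method = c("nearest", "average")) {
  method <- match.arg(method)
  stop_crs_mismatch(grid, reference)
  es <- grid_extent(grid); er <- grid_extent(reference)
  if (es["xmin"] >= er["xmax"] || es["xmax"] <= er["xmin"] ||
      es["ymin"] >= er["ymax"] || es["ymax"] <= er["ymin"])
    stop("grids do not overlap", call. = FALSE)
  nr <- nrow(reference$values); nc <- ncol(reference$values)
  out <- matrix(NA_real_, nr, nc)
  if (method == "nearest") {
    # source (row, col) containing each reference pixel centre
    cx <- x_centers(reference); cy <- y_centers(reference)
    col_s <- floor((cx - grid$origin_x) / grid$gsd_x + 1e-9) + 1L
    row_s <- floor((grid$origin_y - cy) / grid$gsd_y + 1e-9) + 1L
    okc <- col_s >= 1L & col_s <= ncol(grid$values)
    okr <- row_s >= 1L & row_s <= nrow(grid$values)
    rr <- rep(row_s, times = nc); cc <- rep(col_s, each = nr)
    ok <- rep(okr, times = nc) & rep(okc, each = nr)
    out[ok] <- grid$values[cbind(rr[ok], cc[ok])]
  } else {
    # bin source pixel centres into reference cells, then mean per cell
    sx <- x_centers(grid); sy <- y_centers(grid)
    col_t <- floor((sx - reference$origin_x) / reference$gsd_x + 1e-9) + 1L
    row_t <- floor((reference$origin_y - sy) / reference$gsd_y + 1e-9) + 1L
    okc <- col_t >= 1L & col_t <= nc
    okr <- row_t >= 1L & row_t <= nr
    v <- grid$values
    rr <- rep(row_t, times = ncol(v)); cc <- rep(col_t, each = nrow(v))
    keep <- rep(okr, times = ncol(v)) & rep(okc, each = nrow(v)) & !is.na(v)
    if (any(keep)) {
      cell <- (cc[keep] - 1L) * nr + rr[keep]
      sums <- rowsum(as.numeric(v[keep]), cell)
      cnts <- rowsum(rep(1, sum(keep)), cell)
      out[as.integer(rownames(sums))] <- sums / cnts
    }
  }
  raster_grid(out, origin = c(reference$origin_x, reference$origin_y),
              gsd = c(reference$gsd_x, reference$gsd_y),
              crs = if (is.na(grid$crs)) reference$crs else grid$crs)
}
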