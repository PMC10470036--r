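#' Breeding-plot polygon with identity attributes
#'
#' A plot geometry ties a simple polygon (in the raster CRS, metres) to the
#' trial identity used throughout the pipeline: the plot id, the variety
#' grown on it and the replicate number.
#'
#' @param plot_id Unique plot identifier (string).
#' @param variety Variety name.
#' @param replicate Replicate number (integer >= 1).
#' @param coords Two-column matrix of ring vertices (x, y). The ring may be
#'   open (it is closed automatically) and must be simple with positive
#'   area.
#' @return An object of class `plot_geometry`.
#' @seealso [rect_plot()] for the common rectangular case, [read_plots()].
#' @export
plot_geometry <- function(plot_id, variety = NA_character_,
                          replicate = 1L, coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L)
    stop("`coords` must have two columns (x, y)", call. = FALSE)
  storage.mode(coords) <- "double"
  # drop a closing vertex if present; we store the open ring
  n <- nrow(coords)
  if (n >= 2L && all(coords[1L, ] == coords[n, ]))
    coords <- coords[-n, , drop = FALSE]
  if (nrow(coords) < 3L)
    stop("polygon needs at least 3 distinct vertices", call. = FALSE)
  if (any(!is.finite(coords)))
    stop("polygon vertices must be finite", call. = FALSE)
  if (.ring_self_intersects(coords))
    stop(sprintf("polygon of plot '%s' is self-intersecting", plot_id),
         call. = FALSE)
  if (polygon_area(coords) <= 0)
    stop(sprintf("polygon of plot '%s' has zero area", plot_id),
         call. = FALSE)
  replicate <- as.integer(replicate)
  if (is.na(replicate) || replicate < 1L)
    stop("`replicate` must be an integer >= 1", call. = FALSE)
  structure(list(plot_id = as.character(plot_id),
                 variety = as.character(variety),
                 replicate = replicate, coords = coords),
            class = "plot_geometry")
}

#' @export
print.plot_geometry <- function(x, ...) {
  cat(sprintf("<plot_geometry> %s (variety %s, rep %d), area %.4g m^2\n",
              x$plot_id, x$variety, x$replicate, polygon_area(x$coords)))
  invisible(x)
}

#' Rectangular plot helper
#'
#' @param plot_id,variety,replicate See [plot_geometry()].
#' @param x0,y0 South-west corner of the rectangle (metres).
#' @param width,height Edge lengths along x and y (metres).
#' @return A [plot_geometry].
#' @export
rect_plot <- function(plot_id, x0, y0, width, height,
                      variety = NA_character_, replicate = 1L) {
  plot_geometry(plot_id, variety, replicate,
                cbind(c(x0, x0 + width, x0 + width, x0),
                      c(y0, y0, y0 + height, y0 + height)))
}

#' Planar polygon area (shoelace formula)
#'
#' @param coords Two-column vertex matrix, or a [plot_geometry].
#' @return Area in squared input units (m^2 here); always non-negative.
#' @export
polygon_area <- function(coords) {
  if (inherits(coords, "plot_geometry")) coords <- coords$coords
  x <- coords[, 1L]; y <- coords[, 2L]
  n <- length(x); j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# O(n^2) simple-polygon check: no two non-adjacent edges may cross.
.ring_self_intersects <- function(coords) {
  n <- nrow(coords)
  a <- coords; b <- coords[c(2:n, 1L), , drop = FALSE]
  seg_int <- function(p1, p2, p3, p4) {
    d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
    d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  if (n > 3L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (j == i || j == i %% n + 1L || i == j %% n + 1L) next
        if (seg_int(a[i, ], b[i, ], a[j, ], b[j, ])) return(TRUE)
      }
    }
  }
  FALSE
}

#' Point-in-polygon test (even-odd rule)
#'
#' Vectorised even-odd ray-casting. For axis-aligned rectangles the rule is
#' half-open: points on the south and west edges are inside, points on the
#' north and east edges are outside. This makes pixel-centre zonal counts
#' reproducible bit-exactly and never double-counts a pixel shared by two
#' abutting plots.
#'
#' @param px,py Point coordinates (equal-length numeric vectors).
#' @param polygon A [plot_geometry] or a two-column vertex matrix.
#' @return Logical vector, `TRUE` where the point is inside.
#' @export
point_in_polygon <- function(px, py, polygon) {
  if (inherits(polygon, "plot_geometry")) polygon <- polygon$coords
  xp <- polygon[, 1L]; yp <- polygon[, 2L]
  n <- length(xp)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xp[i]; yi <- yp[i]; xj <- xp[j]; yj <- yp[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Logical matrix of pixel centres falling inside a plot
#'
#' @param grid A [raster_grid].
#' @param plot A [plot_geometry].
#' @return Logical matrix with `grid`'s shape.
#' @export
pixels_in_plot <- function(grid, plot) {
  cx <- x_centers(grid); cy <- y_centers(grid)
  ext <- range(plot$coords[, 1L]); eyt <- range(plot$coords[, 2L])
  # cheap bbox pre-filter, exact test only inside the bbox
  sel_c <- which(cx >= ext[1L] & cx <= ext[2L])
  sel_r <- which(cy >= eyt[1L] & cy <= eyt[2L])
  out <- matrix(FALSE, nrow(grid$values), ncol(grid$values))
  if (!length(sel_c) || !length(sel_r)) return(out)
  px <- rep(cx[sel_c], each = length(sel_r))
  py <- rep(cy[sel_r], times = length(sel_c))
  out[sel_r, sel_c] <- point_in_polygon(px, py, plot)
  out
}

#' Validate a collection of plot geometries
#'
#' Checks every element is a [plot_geometry] and that plot ids are unique.
#'
#' @param plots List of [plot_geometry] objects.
#' @return The list, invisibly, with class `uav_plots`.
#' @export
as_plot_collection <- function(plots) {
  if (inherits(plots, "plot_geometry")) plots <- list(plots)
  ok <- vapply(plots, inherits, logical(1), "plot_geometry")
  if (!all(ok)) stop("all elements must be plot_geometry objects", call. = FALSE)
  ids <- vapply(plots, `[[`, character(1), "plot_id")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate plot_id: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  names(plots) <- ids
  structure(plots, class = c("uav_plots", "list"))
}

#' @export
print.uav_plots <- function(x, ...) {
  cat(sprintf("<uav_plots> %d plot(s)\n", length(x)))
  for (p in x)
    cat(sprintf("  %s  variety=%s rep=%d area=%.4g m^2\n",
                p$plot_id, p$variety, p$replicate, polygon_area(p)))
  invisible(x)
}
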