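#' Estimate a plot's base plane from a bare-soil DSM
#'
#' The per-plot reference altitude ("base plane") against which later
#' canopy heights are measured. Following the sorted-selection rule used
#' on ridge-tilled fields, the DSM values at all pixel centres inside the
#' plot polygon are sorted ascending and the value at the 90% position is
#' selected (nearest-rank convention, 1-based rank `ceiling(p * n)`, no
#' interpolation — the result is always an element of the data). On a
#' ridged plot whose flat crests occupy more than 10% of the pixels this
#' lands on the crest plateau, skipping both furrow values below and
#' reconstruction-noise spikes above; on flat noisy soil it estimates the
#' 90th percentile of the noise distribution (soil + 1.2816 sd for
#' Gaussian noise).
#'
#' The estimate is a single horizontal plane per plot (one scalar
#' altitude), is invariant to pixel ordering, monotone in `percentile`,
#' and shifts by exactly `c` when the DSM is shifted by `c`.
#'
#' @param dsm Bare-soil [raster_grid] (altitudes in metres).
#' @param plot A [plot_geometry].
#' @param percentile Selection fraction in (0, 1]; default 0.90.
#' @param source_date Label of the bare-soil survey (provenance only).
#' @return An object of class `base_plane`: list with `plot_id`, `zplane`
#'   (m), `n_pixels`, `percentile`, `source_date`.
#' @seealso [estimate_base_planes()] for a whole plot collection.
#' @export
estimate_base_plane <- function(dsm, plot, percentile = 0.90,
                                source_date = NA_character_) {
  stopifnot(inherits(dsm, "raster_grid"), inherits(plot, "plot_geometry"))
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      percentile <= 0 || percentile > 1)
    stop("`percentile` must be in (0, 1]", call. = FALSE)
  inside <- pixels_in_plot(dsm, plot)
  if (!any(inside))
    stop(sprintf("no DSM pixel centres fall inside plot '%s'", plot$plot_id),
         call. = FALSE)
  vals <- dsm$values[inside]
  vals <- vals[!is.na(vals)]
  n <- length(vals)
  if (n == 0L)
    stop(sprintf("all DSM pixels inside plot '%s' are nodata", plot$plot_id),
         call. = FALSE)
  rank <- min(max(ceiling(percentile * n), 1L), n)
  structure(list(plot_id = plot$plot_id,
                 zplane = sort(vals)[rank],
                 n_pixels = n, percentile = percentile,
                 source_date = source_date),
            class = "base_plane")
}

#' @export
print.base_plane <- function(x, ...) {
  cat(sprintf("<base_plane> plot %s: zplane %.4f m (%g%% of %d pixels%s)\n",
              x$plot_id, x$zplane, 100 * x$percentile, x$n_pixels,
              if (is.na(x$source_date)) ""
              else paste0(", survey ", x$source_date)))
  invisible(x)
}

#' Base planes for a plot collection
#'
#' @inheritParams estimate_base_plane
#' @param plots A `uav_plots` collection (or list of [plot_geometry]).
#' @return data.frame with one row per plot: `plot_id`, `zplane`,
#'   `n_pixels`, `percentile`, `source_date` — the on-disk CSV layout used
#'   to persist planes across a season (see [write_base_planes()]).
#' @export
estimate_base_planes <- function(dsm, plots, percentile = 0.90,
                                 source_date = NA_character_) {
  plots <- as_plot_collection(plots)
  rows <- lapply(plots, function(p) {
    bp <- estimate_base_plane(dsm, p, percentile, source_date)
    data.frame(plot_id = bp$plot_id, zplane = bp$zplane,
               n_pixels = bp$n_pixels, percentile = bp$percentile,
               source_date = bp$source_date, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  rownames(out) <- NULL
  out
}

#' Persist / reload base planes
#'
#' Base planes are estimated once per season from the bare-soil survey and
#' reused for every later acquisition date; these helpers store them as a
#' plain CSV.
#'
#' @param planes data.frame from [estimate_base_planes()].
#' @param path CSV path.
#' @return `write_base_planes()`: `path` invisibly. `read_base_planes()`:
#'   the planes data.frame.
#' @export
write_base_planes <- function(planes, path) {
  utils::write.csv(planes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_base_planes
#' @export
read_base_planes <- function(path) {
  if (!file.exists(path)) stop(sprintf("base-plane file not found: %s", path),
                               call. = FALSE)
  planes <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "zplane")
  if (!all(need %in% names(planes)))
    stop("base-plane CSV must have columns plot_id and zplane", call. = FALSE)
  planes
}

# look a plot's plane up in a planes data.frame (or pass a base_plane through)
.plane_for <- function(planes, plot_id) {
  if (inherits(planes, "base_plane")) {
    if (!identical(planes$plot_id, plot_id))
      stop(sprintf("base plane belongs to plot '%s', not '%s'",
                   planes$plot_id, plot_id), call. = FALSE)
    return(planes)
  }
  i <- which(planes$plot_id == plot_id)
  if (length(i) != 1L)
    stop(sprintf("no base plane for plot '%s'", plot_id), call. = FALSE)
  structure(list(plot_id = plot_id, zplane = planes$zplane[i],
                 n_pixels = planes$n_pixels[i] %||% NA_integer_,
                 percentile = planes$percentile[i] %||% NA_real_,
                 source_date = planes$source_date[i] %||% NA_character_),
            class = "base_plane")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
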