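#' Vegetation mask
#'
#' A vegetation mask is a 0/1 [raster_grid] aligned to the reference
#' raster it will be applied to, together with a record of where it came
#' from. Masks are a pluggable input: the intended source is an externally
#' produced semantic-segmentation raster (e.g. from a trained DeepLabV3+
#' model); [threshold_mask()] provides a simple index-threshold fallback
#' that is adequate on scenes with well-separated soil and canopy spectra
#' but is explicitly weaker than learned segmentation under field
#' conditions (shadow, specular soil, full canopy closure).
#'
#' @name vegetation_mask
NULL

new_vegetation_mask <- function(grid, source, threshold = NA_real_,
                                index = NA_character_) {
  structure(list(grid = grid, source = source, threshold = threshold,
                 index = index),
            class = "vegetation_mask")
}

#' @export
print.vegetation_mask <- function(x, ...) {
  n1 <- sum(x$grid$values == 1, na.rm = TRUE)
  cat(sprintf("<vegetation_mask> source=%s, %d canopy pixel(s)\n",
              x$source, n1))
  if (!is.na(x$threshold))
    cat(sprintf("  threshold: %s >= %.4g\n", x$index, x$threshold))
  invisible(x)
}

# accept a vegetation_mask or a bare 0/1 raster_grid
mask_grid <- function(mask) {
  if (inherits(mask, "vegetation_mask")) return(mask$grid)
  if (inherits(mask, "raster_grid")) {
    .check_binary(mask$values)
    return(mask)
  }
  stop("`mask` must be a vegetation_mask or a 0/1 raster_grid", call. = FALSE)
}

.check_binary <- function(v) {
  bad <- !is.na(v) & v != 0 & v != 1
  if (any(bad))
    stop(sprintf("mask contains %d value(s) outside {0, 1, nodata}",
                 sum(bad)), call. = FALSE)
  invisible(TRUE)
}

#' Load an externally produced vegetation mask
#'
#' Reads (or accepts) a segmentation raster, resamples it onto the
#' reference grid with nearest-neighbour lookup if the frames differ, and
#' coerces values to {0, 1}: values within `tol` of 0 or 1 are snapped,
#' anything else is a validation error.
#'
#' @param x Path to a mask raster, or a [raster_grid].
#' @param reference [raster_grid] defining the frame the mask must match
#'   (typically the DSM).
#' @param tol Snap tolerance for coercion to {0, 1}.
#' @return A [vegetation_mask] with `source = "external"`.
#' @export
load_external_mask <- function(x, reference, tol = 1e-6) {
  grid <- if (is.character(x)) read_raster(x) else x
  stopifnot(inherits(grid, "raster_grid"), inherits(reference, "raster_grid"))
  stop_crs_mismatch(grid, reference)
  if (!grids_aligned(grid, reference))
    grid <- resample_to(grid, reference, method = "nearest")
  v <- grid$values
  v[!is.na(v) & abs(v) <= tol] <- 0
  v[!is.na(v) & abs(v - 1) <= tol] <- 1
  .check_binary(v)
  grid$values <- v
  new_vegetation_mask(grid, source = "external")
}

#' Vegetation mask by index thresholding
#'
#' Classifies a pixel as vegetation where the index value is greater than
#' or equal to `threshold` (the comparison is inclusive; ties are
#' vegetation). Nodata propagates. Raising the threshold can only remove
#' mask pixels, never add them.
#'
#' @param index_grid A [raster_grid] of vegetation-index values (e.g. an
#'   NDVI map from [index_map()]).
#' @param threshold Classification threshold.
#' @param index Name recorded for provenance.
#' @return A [vegetation_mask] with `source = "threshold"`.
#' @export
threshold_mask <- function(index_grid, threshold, index = "ndvi") {
  stopifnot(inherits(index_grid, "raster_grid"), is.numeric(threshold),
            length(threshold) == 1L)
  v <- index_grid$values
  if (any(is.infinite(v), na.rm = TRUE))
    stop("index grid contains non-finite values", call. = FALSE)
  out <- index_grid
  out$values <- (v >= threshold) + 0
  new_vegetation_mask(out, source = "threshold", threshold = threshold,
                      index = index)
}
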