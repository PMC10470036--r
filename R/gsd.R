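#' Ground sampling distance as a function of flight altitude
#'
#' For a fixed camera, the ground sampling distance scales proportionally
#' with flight altitude: `gsd(h) = ref_gsd_cm * h / ref_altitude`. The
#' default reference is the 15 m potato-survey flight with 5/6 cm/pixel
#' (printed as 0.833 cm/pixel), so a 30 m flight gives 5/3 cm/pixel
#' (printed 1.667).
#'
#' @param altitude_m Flight altitude(s), metres.
#' @param ref_altitude Reference altitude, metres.
#' @param ref_gsd_cm GSD at the reference altitude, cm/pixel.
#' @return GSD in cm/pixel (same unit the survey literature quotes).
#' @examples
#' gsd_at_altitude(30)            # 1.667 cm/pixel (rounded)
#' gsd_at_altitude(c(15, 30)) / 100  # in metres, for raster transforms
#' @export
gsd_at_altitude <- function(altitude_m, ref_altitude = 15, ref_gsd_cm = 5 / 6) {
  stopifnot(all(altitude_m > 0), ref_altitude > 0, ref_gsd_cm > 0)
  ref_gsd_cm * altitude_m / ref_altitude
}

#' The 15 m / 30 m survey GSD pair, in metres
#'
#' Convenience wrapper returning the two acquisition GSDs in metres per
#' pixel, as required by [make_scene()] and raster transforms: exactly
#' 1/120 m (0.833 cm/pixel) and 1/60 m (1.667 cm/pixel).
#'
#' @param altitudes_m The two flight altitudes, metres.
#' @return Named numeric vector `c(fine = ..., coarse = ...)` in m/pixel.
#' @export
gsd_pair <- function(altitudes_m = c(15, 30)) {
  stopifnot(length(altitudes_m) == 2L)
  g <- sort(gsd_at_altitude(altitudes_m)) / 100
  c(fine = g[1L], coarse = g[2L])
}
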