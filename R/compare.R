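#' Ordinary least-squares comparison of two trait series
#'
#' Regresses `y` on `x` and reports the statistics used to compare trait
#' series from two acquisitions (e.g. coarse-GSD vs fine-GSD, or
#' UAV-derived vs manually measured): slope, intercept, R^2 (squared
#' Pearson correlation), adjusted R^2 with one predictor
#' `1 - (1 - R^2) (n - 1) / (n - 2)`, RMSE (root mean squared residual,
#' in the trait's unit), and the two-sided p-value of the slope. R^2 is
#' symmetric in the two series; slope and intercept are not, so the
#' output records which series was the predictor. p-values below 1e-300
#' are reported as exactly 0.
#'
#' @param x Predictor series (must not be constant).
#' @param y Response series, same length as `x`.
#' @param xlab,ylab Labels recorded for the predictor and response.
#' @return An object of class `comparison_stats`: list with `n`, `slope`,
#'   `intercept`, `r2`, `adjusted_r2`, `rmse`, `p_value`, `predictor`,
#'   `response`.
#' @export
paired_regression <- function(x, y, xlab = "x", ylab = "y") {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop(sprintf("length mismatch: %d vs %d", length(x), length(y)),
         call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate predictor: x is constant",
                              call. = FALSE)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  r2 <- stats::cor(x, y)^2
  p <- suppressWarnings(summary(fit)$coefficients["x", "Pr(>|t|)"])
  if (is.nan(p)) p <- 0  # perfect fit: zero residual variance
  if (p < 1e-300) p <- 0
  structure(list(
    n = n,
    slope = unname(co["x"]), intercept = unname(co["(Intercept)"]),
    r2 = r2,
    adjusted_r2 = 1 - (1 - r2) * (n - 1) / (n - 2),
    rmse = sqrt(mean(stats::residuals(fit)^2)),
    p_value = p,
    predictor = xlab, response = ylab),
    class = "comparison_stats")
}

#' @export
print.comparison_stats <- function(x, digits = 4, ...) {
  cat(sprintf("<comparison_stats> %s ~ %s (n = %d)\n", x$response,
              x$predictor, x$n))
  cat(sprintf("  slope %.*g, intercept %.*g\n", digits, x$slope, digits,
              x$intercept))
  cat(sprintf("  R^2 %.*g, adjusted R^2 %.*g, RMSE %.*g, p %.3g\n",
              digits, x$r2, digits, x$adjusted_r2, digits, x$rmse,
              x$p_value))
  invisible(x)
}

#' @export
as.data.frame.comparison_stats <- function(x, ...) {
  data.frame(predictor = x$predictor, response = x$response, n = x$n,
             slope = x$slope, intercept = x$intercept, r2 = x$r2,
             adjusted_r2 = x$adjusted_r2, rmse = x$rmse,
             p_value = x$p_value, stringsAsFactors = FALSE)
}

#' Replicate standard deviation
#'
#' Sample standard deviation (n - 1 denominator) of the trait values of
#' one variety's replicates on one date — the per-variety spread
#' statistic used to compare acquisition precision.
#'
#' @param values Numeric vector of replicate trait values (n >= 2).
#' @return Standard deviation in the trait's unit.
#' @export
replicate_sd <- function(values) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  if (length(values) < 2L)
    stop("need at least 2 replicate values", call. = FALSE)
  stats::sd(values)
}

#' Simulated two-altitude acquisition experiment
#'
#' Re-creates, on synthetic fields with known truth, the design of flying
#' one field at two altitudes: `n_scenes` paired acquisitions are
#' generated with [make_height_pair()], varying the canopy size (growth
#' stage) and slightly varying the leaf spectrum from scene to scene; the
#' full pipeline (bare-soil base planes, height, volume, coverage, NDVI)
#' runs on both members of each pair, and each trait is compared by
#' [paired_regression()] — coarse against fine, and each against the
#' closed-form truth.
#'
#' Base planes are estimated once per GSD from a bare-ground scene, as a
#' real season does, and reused for every scene.
#'
#' @param truth A [scene_truth] template; its canopy parameters are
#'   rescaled per scene.
#' @param n_scenes Number of paired scenes (>= 3).
#' @param seed Integer seed for the scene-level parameter draws and all
#'   elevation noise.
#' @param gsd Length-2 GSD vector in metres, see [gsd_pair()].
#' @param scale_range Range of canopy scale factors (sizes/growth stages);
#'   `n_scenes * n_plots` sizes are spread linearly over this range so that
#'   every plot of every scene has its own canopy size, as a trial pooling
#'   varieties and dates does.
#' @param scales Optional explicit scale matrix (`n_scenes` rows,
#'   `n_plots` columns; a vector is recycled per scene), overriding
#'   `scale_range` — e.g. to keep scaled cuboids grid-aligned.
#' @param traits Trait columns to compare.
#' @return Object of class `gsd_experiment`: list with `records` (per
#'   plot x scene x resolution trait table joined with truth), `stats`
#'   (data.frame of regression statistics per trait and comparison), and
#'   `comparisons` (nested list of `comparison_stats`).
#' @export
gsd_experiment <- function(truth = scene_truth(), n_scenes = 6L, seed = 1L,
                           gsd = gsd_pair(), scale_range = c(0.4, 1),
                           scales = NULL,
                           traits = c("mean_height", "volume", "coverage",
                                      "ndvi")) {
  stopifnot(inherits(truth, "scene_truth"))
  n_scenes <- as.integer(n_scenes)
  if (n_scenes < 3L) stop("`n_scenes` must be >= 3", call. = FALSE)
  gsd <- sort(as.numeric(gsd))
  seed <- as.integer(seed) %% .Machine$integer.max

  # every plot in every scene gets its own canopy size (the field design
  # this emulates pools varieties of different statures and several dates
  # into one regression); sizes are stratified over scenes
  n_plots <- truth$n_plots
  if (is.null(scales)) {
    all_scales <- seq(scale_range[1L], scale_range[2L],
                      length.out = n_scenes * n_plots)
    # column p = plot p: each scene spans small to large canopies, and the
    # whole grid of sizes shifts slightly from scene to scene
    scales <- matrix(all_scales, nrow = n_scenes)
  } else if (is.matrix(scales)) {
    stopifnot(nrow(scales) == n_scenes, ncol(scales) == n_plots)
  } else {
    scales <- matrix(rep_len(as.numeric(scales), n_scenes), n_scenes,
                     n_plots)
  }
  # per-scene leaf-spectrum variation so indices vary across scenes
  jit <- with_preserved_seed(seed, list(
    nir = stats::runif(n_scenes, -0.05, 0.05),
    red = stats::runif(n_scenes, -0.02, 0.02)))

  # one bare-soil survey per resolution, reused for all scenes
  bare_truth <- truth
  bare_truth$seed <- seed
  planes <- lapply(gsd, function(g) {
    bare <- make_bareground_scene(bare_truth, g)
    estimate_base_planes(bare$dsm, bare$plots, source_date = "bare-soil")
  })
  names(planes) <- c("fine", "coarse")

  records <- list()
  for (s in seq_len(n_scenes)) {
    leaf <- truth$leaf_reflectance
    leaf[["nir"]] <- min(max(leaf[["nir"]] + jit$nir[s], 0), 1)
    leaf[["red"]] <- min(max(leaf[["red"]] + jit$red[s], 0), 1)
    ts <- scene_truth(
      n_plots = truth$n_plots, plot_length = truth$plot_length,
      plot_width = truth$plot_width, plot_gap = truth$plot_gap,
      margin = truth$margin, ridge_height = truth$ridge_height,
      ridge_spacing = truth$ridge_spacing,
      ridge_top_width = truth$ridge_top_width,
      furrow_width = truth$furrow_width,
      plant_spacing = truth$plant_spacing,
      canopy_shape = truth$canopy_shape,
      canopy_radius_x = truth$canopy_radius_x %||% 0.15,
      canopy_radius_y = truth$canopy_radius_y %||% 0.15,
      canopy_height = truth$canopy_height %||% 0.40,
      canopy_scale = scales[s, ],
      soil_reflectance = truth$soil_reflectance,
      leaf_reflectance = leaf,
      dsm_noise_sd = truth$dsm_noise_sd,
      base_altitude = truth$base_altitude,
      grid_offset = truth$grid_offset %||% "random",
      seed = (seed * 1000L + s) %% .Machine$integer.max)
    pair <- make_height_pair(ts, gsd = gsd)
    for (res in c("fine", "coarse")) {
      sc <- pair[[res]]
      rec <- extract_traits(sc$dsm, sc$bands, sc$mask, sc$plots,
                            planes[[res]],
                            date_label = sprintf("scene%02d", s))
      rec$scene <- s
      rec$resolution <- res
      rec$gsd <- sc$gsd
      rec <- merge(rec, ts$plot_truth[, c("plot_id", "true_mean_height",
                                          "true_volume", "true_coverage")],
                   by = "plot_id", sort = TRUE)
      records[[length(records) + 1L]] <- rec
    }
  }
  records <- do.call(rbind, c(records, make.row.names = FALSE))
  records <- records[order(records$scene, records$resolution,
                           records$plot_id), ]
  rownames(records) <- NULL

  fine <- records[records$resolution == "fine", ]
  coarse <- records[records$resolution == "coarse", ]
  stopifnot(identical(fine$plot_id, coarse$plot_id),
            identical(fine$scene, coarse$scene))
  truth_col <- c(mean_height = "true_mean_height", volume = "true_volume",
                 coverage = "true_coverage", ndvi = NA)
  comparisons <- lapply(traits, function(tr) {
    out <- list(coarse_vs_fine = paired_regression(
      fine[[tr]], coarse[[tr]], xlab = paste0("fine_", tr),
      ylab = paste0("coarse_", tr)))
    tc <- truth_col[[tr]]
    if (!is.na(tc) && tc %in% names(fine)) {
      out$fine_vs_truth <- paired_regression(
        fine[[tc]], fine[[tr]], xlab = paste0("true_", tr),
        ylab = paste0("fine_", tr))
      out$coarse_vs_truth <- paired_regression(
        coarse[[tc]], coarse[[tr]], xlab = paste0("true_", tr),
        ylab = paste0("coarse_", tr))
    }
    out
  })
  names(comparisons) <- traits
  stats_df <- do.call(rbind, c(lapply(traits, function(tr) {
    cmp <- comparisons[[tr]]
    df <- do.call(rbind, lapply(names(cmp), function(nm)
      cbind(data.frame(trait = tr, comparison = nm,
                       stringsAsFactors = FALSE),
            as.data.frame(cmp[[nm]]))))
    df
  }), make.row.names = FALSE))
  rownames(stats_df) <- NULL

  structure(list(records = records, stats = stats_df,
                 comparisons = comparisons, gsd = gsd, seed = seed,
                 n_scenes = n_scenes),
            class = "gsd_experiment")
}

#' @export
print.gsd_experiment <- function(x, ...) {
  cat(sprintf("<gsd_experiment> %d scene pair(s) at gsd %.5g / %.5g m, seed %d\n",
              x$n_scenes, x$gsd[1L], x$gsd[2L], x$seed))
  df <- x$stats[, c("trait", "comparison", "n", "r2", "adjusted_r2",
                    "rmse", "p_value")]
  df$r2 <- signif(df$r2, 5); df$adjusted_r2 <- signif(df$adjusted_r2, 5)
  df$rmse <- signif(df$rmse, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
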