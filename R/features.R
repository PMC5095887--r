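.spectral_names <- c("SWIR1", "SWIR2", "EVI", "NDTI", "VI64", "DIF64", "DIF67")

#' Names of the classification features
#'
#' Full-season mapping uses 27 variables: 13 phenological metrics plus the 7
#' spectral metrics evaluated at the `avg` and `peak` stages. Early-season
#' mapping drops the 6 falling-limb ("late") phenology metrics, leaving
#' 21 variables (7 + 7 x 2). Name order is stable.
#'
#' @param mode `"full"` or `"early"`.
#' @return Character vector of feature names (length 27 or 21).
#' @examples
#' length(feature_names("full"))  # 27
#' length(feature_names("early")) # 21
#' @export
feature_names <- function(mode = c("full", "early")) {
  mode <- match.arg(mode)
  c(.pheno_metric_names[[mode]],
    paste0(.spectral_names, "_avg"),
    paste0(.spectral_names, "_peak"))
}

.band_cols <- paste0("b", 1:7)

.valid_band_rows <- function(series) {
  good <- if ("good" %in% names(series)) series$good else rep(TRUE, nrow(series))
  vals <- as.matrix(series[, .band_cols, drop = FALSE])
  good & rowSums(!is.finite(vals) | vals < 0 | vals > 1) == 0
}

#' Interpolate reflectance bands to a target date
#'
#' Linear interpolation of each band between the nearest valid composites
#' bracketing `target_doy`; exact when the target coincides with a valid
#' composite. A target outside the valid-observation span yields `NA` for all
#' bands (the metric is flagged missing rather than extrapolated).
#'
#' @param series Reflectance table with columns `doy`, `b1`..`b7` and
#'   optionally `good`.
#' @param target_doy Day of year to interpolate to.
#' @return Named numeric vector `b1`..`b7`.
#' @export
interpolate_at <- function(series, target_doy) {
  .assert_cols(series, c("doy", .band_cols))
  keep <- .valid_band_rows(series)
  d <- series$doy[keep]
  if (length(d) == 0 || is.na(target_doy) ||
      target_doy < min(d) || target_doy > max(d)) {
    return(setNames(rep(NA_real_, 7), .band_cols))
  }
  vals <- as.matrix(series[keep, .band_cols, drop = FALSE])
  hit <- which(d == target_doy)
  if (length(hit) > 0) {
    return(setNames(as.numeric(vals[hit[1], ]), .band_cols))
  }
  lo <- max(which(d < target_doy))
  hi <- min(which(d > target_doy))
  w <- (target_doy - d[lo]) / (d[hi] - d[lo])
  setNames(as.numeric((1 - w) * vals[lo, ] + w * vals[hi, ]), .band_cols)
}

#' Average reflectance bands over a date range
#'
#' Arithmetic mean of each band over valid composites with dates in
#' `[start, end]`. Used for the `avg` stage: between `D_i` and `D_d` in full
#' mode, or from `D_i` to the early-window end when `D_d` is not yet
#' observable. No valid composite in range yields `NA`.
#'
#' @inheritParams interpolate_at
#' @param start,end Day-of-year range (inclusive); `start < end` required.
#' @return Named numeric vector `b1`..`b7`.
#' @export
average_between <- function(series, start, end) {
  .assert_cols(series, c("doy", .band_cols))
  if (is.na(start) || is.na(end) || start >= end) {
    return(setNames(rep(NA_real_, 7), .band_cols))
  }
  keep <- .valid_band_rows(series) & series$doy >= start & series$doy <= end
  if (!any(keep)) {
    return(setNames(rep(NA_real_, 7), .band_cols))
  }
  setNames(colMeans(series[keep, .band_cols, drop = FALSE]), .band_cols)
}

# the 7 spectral metrics from a named vector of band reflectances;
# band 4 is green (545-565 nm), bands 6/7 shortwave infrared
.spectral_indices <- function(b) {
  c(SWIR1 = unname(b["b6"]),
    SWIR2 = unname(b["b7"]),
    EVI = unname(compute_evi(b["b1"], b["b2"], b["b3"])),
    NDTI = unname((b["b6"] - b["b7"]) / (b["b6"] + b["b7"])),
    VI64 = unname((b["b6"] - b["b4"]) / (b["b6"] + b["b4"])),
    DIF64 = unname(b["b6"] - b["b4"]),
    DIF67 = unname(b["b6"] - b["b7"]))
}

#' Phenology-anchored spectral metrics
#'
#' Evaluates the 7 spectral metrics (SWIR1, SWIR2, EVI, NDTI, VI64, DIF64,
#' DIF67) at the two phenological stages: `avg`, the mean over the
#' high-growth period from `D_i` to `D_d` (to the early-window end when `D_d`
#' is unavailable), and `peak`, interpolated to `D_peak`. Reflectances are
#' averaged/interpolated first and the indices computed from the resulting
#' band values, one consistent convention.
#'
#' @inheritParams interpolate_at
#' @param metrics A `pheno_metrics` row from [derive_pheno_metrics()].
#' @param early_end Early-window end day of year used when `D_d` is absent.
#' @return A `spectral_metrics` object: list with named vectors `avg` and
#'   `peak` and the `mode`.
#' @export
spectral_at_stages <- function(series, metrics, early_end = 224) {
  stopifnot(inherits(metrics, "pheno_metrics"))
  mode <- metrics$mode
  end <- if (mode == "full") metrics$D_d else early_end
  avg_b <- average_between(series, metrics$D_i, end)
  peak_b <- interpolate_at(series, metrics$D_peak)
  structure(
    list(avg = .spectral_indices(avg_b), peak = .spectral_indices(peak_b),
         mode = mode),
    class = "spectral_metrics"
  )
}

#' Assemble the classification feature vector
#'
#' Binds phenological metrics and stage-anchored spectral metrics into the
#' named feature vector used for training and prediction: 27 features in full
#' mode, 21 in early mode, in the stable [feature_names()] order. The two
#' inputs must come from the same season mode.
#'
#' @param metrics A `pheno_metrics` row.
#' @param spectral A `spectral_metrics` object from [spectral_at_stages()].
#' @return One-row tibble of features, with attribute `season` set to the mode.
#' @export
build_features <- function(metrics, spectral) {
  stopifnot(inherits(metrics, "pheno_metrics"),
            inherits(spectral, "spectral_metrics"))
  if (!identical(metrics$mode, spectral$mode)) {
    abort(sprintf("mode mismatch: phenological metrics are '%s' but spectral metrics are '%s'",
                  metrics$mode, spectral$mode))
  }
  mode <- metrics$mode
  ph <- as.numeric(metrics[1, .pheno_metric_names[[mode]]])
  vec <- c(setNames(ph, .pheno_metric_names[[mode]]),
           setNames(spectral$avg, paste0(.spectral_names, "_avg")),
           setNames(spectral$peak, paste0(.spectral_names, "_peak")))
  out <- tibble::as_tibble(as.list(vec[feature_names(mode)]))
  attr(out, "season") <- mode
  out
}

# feature extraction for one pixel: window truncation, EVI reduction, curve
# fit, metric derivation, stage-anchored spectral metrics
.pixel_features <- function(series, mode, early_end = 224) {
  window <- season_window(mode)
  s <- truncate_to_window(series, window)
  ev <- evi_series(s)
  fit <- fit_double_sigmoid(ev, mode, early_end = early_end)
  fn <- feature_names(mode)
  if (!fit$ok) {
    out <- tibble::as_tibble(as.list(setNames(rep(NA_real_, length(fn)), fn)))
    out$fit_ok <- FALSE
    out$fit_rmse <- NA_real_
    return(out)
  }
  metrics <- derive_pheno_metrics(fit)
  spectral <- spectral_at_stages(s, metrics, early_end = early_end)
  out <- build_features(metrics, spectral)
  out$fit_ok <- TRUE
  out$fit_rmse <- fit$fit_rmse
  out
}

#' Extract classification features for a set of pixels
#'
#' Runs the per-pixel feature pipeline (season-window truncation, EVI
#' reduction, double-sigmoid fit, phenological metrics, stage-anchored
#' spectral metrics) over a multi-pixel reflectance table. Pixels whose curve
#' fit fails are kept as all-`NA` rows with `fit_ok = FALSE` so that no-data
#' propagates to prediction.
#'
#' @param series Long reflectance table with columns `pixel`, `doy`,
#'   `b1`..`b7`, optional `good`, and optional `row`/`col` carried through.
#' @param mode Season mode, `"full"` or `"early"`.
#' @param early_end Early-window end day of year.
#' @return Tibble with one row per pixel: id columns, the 27/21 features,
#'   `fit_ok` and `fit_rmse`; attribute `season` records the mode.
#' @export
extract_features <- function(series, mode = c("full", "early"), early_end = 224) {
  mode <- match.arg(mode)
  .assert_cols(series, c("pixel", "doy", .band_cols))
  parts <- split(series, series$pixel)
  rows <- purrr::map(parts, .pixel_features, mode = mode, early_end = early_end)
  out <- dplyr::bind_rows(rows)
  ids <- purrr::map(parts, function(df) df[1, intersect(c("pixel", "row", "col"), names(df)), drop = FALSE])
  out <- dplyr::bind_cols(dplyr::bind_rows(ids), out)
  out <- out[order(out$pixel), , drop = FALSE]
  attr(out, "season") <- mode
  out
}

# infer the season mode of a feature table from its columns
.infer_season <- function(features) {
  if (!is.null(attr(features, "season"))) return(attr(features, "season"))
  if (all(feature_names("full") %in% names(features))) return("full")
  if (all(feature_names("early") %in% names(features))) return("early")
  abort("cannot infer season mode: feature columns match neither the 27-name nor the 21-name set")
}
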