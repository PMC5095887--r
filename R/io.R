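# Plain-text exchange formats: CSV tables with JSON sidecars where band
# order / class coding needs documenting, headerless CSV matrices for label
# and zone rasters, RDS + JSON manifest for trained models.

#' Read and write label/zone rasters as headerless CSV matrices
#'
#' Label rasters use the class coding 0 = other, 1 = corn, 5 = soybean
#' (echoing CDL codes); zone rasters hold county ids. A JSON sidecar
#' (`<path>.json`) records the coding and dimensions.
#'
#' @param x Integer matrix.
#' @param path Output CSV path.
#' @return `write_label_raster()` returns `path` invisibly;
#'   `read_label_raster()` returns the integer matrix.
#' @export
write_label_raster <- function(x, path) {
  stopifnot(is.matrix(x))
  utils::write.table(x, path, sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(nrow = nrow(x), ncol = ncol(x),
         codes = list(other = 0L, corn = 1L, soybean = 5L)),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_label_raster
#' @export
read_label_raster <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                              colClasses = "integer"))
}

#' Read and write reflectance series tables
#'
#' Long CSV with columns `pixel`, (`row`, `col`,) `doy`, `b1`..`b7`, `good`;
#' the sidecar documents the band order and the day-of-year convention.
#'
#' @param series Reflectance series tibble.
#' @param path CSV path.
#' @export
write_series_csv <- function(series, path) {
  .assert_cols(series, c("pixel", "doy", .band_cols, "good"))
  readr::write_csv(series, path)
  jsonlite::write_json(
    list(bands = list(b1 = "red", b2 = "nir", b3 = "blue", b4 = "green",
                      b5 = "nir2", b6 = "swir1", b7 = "swir2"),
         doy = "1-based composite start day; composite n covers [8(n-1)+1, 8n]"),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Read and write coverage tables
#'
#' @param coverage Coverage tibble (`pixel`, `row`, `col`, `corn`,
#'   `soybean`, `other`).
#' @param path CSV path.
#' @export
write_coverage_csv <- function(coverage, path) {
  .assert_cols(coverage, c("row", "col", "corn", "soybean", "other"))
  readr::write_csv(tibble::as_tibble(coverage), path)
  invisible(path)
}

#' @rdname write_coverage_csv
#' @export
read_coverage_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  class(out) <- c("coverage_raster", class(out))
  out
}

#' Read and write weekly progress tables
#'
#' @param progress Progress tibble (`state`, `year`, `crop`, `stage`,
#'   `week_ending_doy`, `percent`).
#' @param path CSV path.
#' @export
write_progress_csv <- function(progress, path) {
  .assert_cols(progress, c("state", "year", "crop", "stage",
                           "week_ending_doy", "percent"))
  readr::write_csv(progress, path)
  invisible(path)
}

#' @rdname write_progress_csv
#' @export
read_progress_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Read and write feature tables
#'
#' The season mode travels in a JSON sidecar so a reloaded table keeps its
#' 27-name or 21-name contract.
#'
#' @param features Feature tibble from [extract_features()].
#' @param path CSV path.
#' @export
write_features_csv <- function(features, path) {
  season <- .infer_season(features)
  readr::write_csv(tibble::as_tibble(features), path)
  jsonlite::write_json(
    list(season = season, features = feature_names(season)),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    attr(out, "season") <- jsonlite::read_json(side)$season
  }
  out
}

#' Persist and reload a trained model
#'
#' Writes the forest object as RDS next to a JSON manifest describing the
#' model (pixel definition, season, k, m, seed, training state/year,
#' adjustment, feature list), realizing a versioned registry of trained
#' classifiers keyed by those options.
#'
#' @param model A `crop_model`.
#' @param dir Directory to create/use.
#' @export
write_model <- function(model, dir) {
  stopifnot(inherits(model, "crop_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(dir, "model.rds"))
  jsonlite::write_json(
    list(pixel = model$pixel, season = model$season, k = model$k, m = model$m,
         seed = model$seed, state = model$state, year = model$year,
         adjustment = model$adjustment, n_train = model$n_train,
         oob = as.list(model$oob), features = model$feature_names),
    file.path(dir, "manifest.json"), auto_unbox = TRUE
  )
  invisible(dir)
}

#' @rdname write_model
#' @export
read_model <- function(dir) {
  readRDS(file.path(dir, "model.rds"))
}
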