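#' Train a random-forest crop classifier
#'
#' Trains the per-state, per-year random forest used for cross-year mapping.
#' Two pixel definitions: `"fuzzy"` fits one regression forest per crop with
#' the per-pixel coverage percentage (0-100) as target, using the valuable
#' sub-pixel information of mixed pixels; `"hard"` fits a single 3-class
#' forest on discrete labels (normally pure pixels from
#' [select_pure_pixels()]). Defaults `k = 100` trees and `m = 1` candidate
#' variable per node: accuracy is insensitive to `k` once the forest is large,
#' and `m = 1` keeps the cost low. Training rows with any missing feature are
#' dropped; feature-wise medians of the training set are stored for
#' imputation at prediction time. Results are deterministic given `seed`.
#'
#' @param features Feature table from [extract_features()] with a `pixel`
#'   column.
#' @param targets For `"fuzzy"`: table with `pixel`, `corn`, `soybean`
#'   percent columns (e.g. [aggregate_coverage()]); for `"hard"`: table with
#'   `pixel` and a `label` factor.
#' @param pixel Pixel definition, `"fuzzy"` or `"hard"`.
#' @param k Number of trees.
#' @param m Variables tried per node (`mtry`).
#' @param seed Forest seed.
#' @param state,year,adjustment Optional bookkeeping recorded in the model,
#'   keying the registry of trained classifiers.
#' @return A `crop_model` object: ranger forest(s), the feature name list,
#'   training medians, out-of-bag error(s) and metadata.
#' @export
train_classifier <- function(features, targets, pixel = c("fuzzy", "hard"),
                             k = 100, m = 1, seed = 1,
                             state = NA_character_, year = NA_integer_,
                             adjustment = "A0") {
  pixel <- match.arg(pixel)
  stopifnot(k >= 1, m >= 1)
  .assert_cols(features, "pixel")
  .assert_cols(targets, "pixel")
  season <- .infer_season(features)
  fn <- feature_names(season)
  .assert_cols(features, fn)

  df <- dplyr::inner_join(tibble::as_tibble(features),
                          tibble::as_tibble(targets), by = "pixel")
  if (nrow(df) == 0) abort("features and targets share no pixels")
  x <- as.data.frame(df[, fn, drop = FALSE])
  ok <- complete.cases(x)

  if (pixel == "fuzzy") {
    .assert_cols(targets, c("corn", "soybean"))
    for (cls in c("corn", "soybean")) {
      bad <- !is.na(df[[cls]]) & (df[[cls]] < 0 | df[[cls]] > 100)
      if (any(bad)) abort(sprintf("fuzzy targets for %s outside [0, 100]", cls))
    }
    ok <- ok & !is.na(df$corn) & !is.na(df$soybean)
    if (sum(ok) < 2) abort("fuzzy training needs at least 2 complete samples")
    models <- lapply(setNames(c("corn", "soybean"), c("corn", "soybean")),
                     function(cls) {
      ranger::ranger(x = x[ok, , drop = FALSE], y = df[[cls]][ok],
                     num.trees = k, mtry = m, seed = seed,
                     num.threads = 1)
    })
    oob <- vapply(models, function(mo) mo$prediction.error, numeric(1))
  } else {
    .assert_cols(targets, "label")
    y <- factor(df$label, levels = .crop_classes)
    ok <- ok & !is.na(y)
    counts <- table(y[ok])
    empty <- names(counts)[counts == 0]
    if (length(empty) > 0) {
      abort(sprintf("no training samples for class(es): %s",
                    paste(empty, collapse = ", ")))
    }
    models <- list(hard = ranger::ranger(
      x = x[ok, , drop = FALSE], y = droplevels(y[ok]),
      num.trees = k, mtry = m, seed = seed, num.threads = 1
    ))
    oob <- c(hard = models$hard$prediction.error)
  }

  structure(
    list(pixel = pixel, season = season, models = models,
         k = as.integer(k), m = as.integer(m), seed = as.integer(seed),
         feature_names = fn,
         medians = vapply(x[ok, , drop = FALSE], median, numeric(1)),
         n_train = sum(ok), oob = oob,
         state = state, year = year, adjustment = adjustment),
    class = "crop_model"
  )
}

#' @export
print.crop_model <- function(x, ...) {
  cat(sprintf("<crop_model> %s / %s season, k=%d trees, m=%d, %d training pixels\n",
              x$pixel, x$season, x$k, x$m, x$n_train))
  if (!is.na(x$state)) cat(sprintf("  trained on state %s, year %s, adjustment %s\n",
                                   x$state, x$year, x$adjustment))
  cat("  out-of-bag error:", paste(sprintf("%s=%.3f", names(x$oob), x$oob),
                                   collapse = ", "), "\n")
  invisible(x)
}

#' @rdname train_classifier
#' @param x A `crop_model` object.
#' @method glance crop_model
#' @export
glance.crop_model <- function(x, ...) {
  out <- tibble::tibble(pixel = x$pixel, season = x$season, k = x$k, m = x$m,
                        n_train = x$n_train, state = x$state, year = x$year,
                        adjustment = x$adjustment)
  for (nm in names(x$oob)) out[[paste0("oob_", nm)]] <- unname(x$oob[nm])
  out
}

#' Predict crop coverage (or hard labels) for new pixels
#'
#' Applies a trained model to a mapping-year feature table. Fuzzy models
#' predict corn and soybean coverage percent per pixel, clipped to
#' \[0, 100\]; when the two crops jointly exceed 100% they are rescaled
#' proportionally to sum to 100, and `other` takes the remainder. Hard models
#' return one label per pixel. Pixels whose curve fit failed (`fit_ok` is
#' `FALSE`, or every feature missing) propagate as no-data rows; other
#' missing features are imputed with the training-set medians.
#'
#' @param model A `crop_model` from [train_classifier()].
#' @param features Feature table with the model's feature columns.
#' @return Fuzzy: tibble of class `coverage_raster` with `corn`, `soybean`,
#'   `other` percent. Hard: tibble with a `label` column.
#' @export
predict_coverage <- function(model, features) {
  stopifnot(inherits(model, "crop_model"))
  fn <- model$feature_names
  miss <- setdiff(fn, names(features))
  if (length(miss) > 0) {
    abort(sprintf("features do not match the model: missing %s",
                  paste(miss, collapse = ", ")))
  }
  x <- as.data.frame(features[, fn, drop = FALSE])
  nodata <- rowSums(!is.na(x)) == 0
  if ("fit_ok" %in% names(features)) {
    nodata <- nodata | !features$fit_ok
  }
  for (nm in fn) {
    x[[nm]][is.na(x[[nm]])] <- model$medians[[nm]]
  }
  ids <- intersect(c("pixel", "row", "col"), names(features))
  out <- tibble::as_tibble(features[, ids, drop = FALSE])

  if (model$pixel == "fuzzy") {
    corn <- predict(model$models$corn, data = x, num.threads = 1)$predictions
    soy <- predict(model$models$soybean, data = x, num.threads = 1)$predictions
    corn <- pmin(pmax(corn, 0), 100)
    soy <- pmin(pmax(soy, 0), 100)
    tot <- corn + soy
    over <- tot > 100
    corn[over] <- corn[over] * 100 / tot[over]
    soy[over] <- soy[over] * 100 / tot[over]
    corn[nodata] <- NA_real_
    soy[nodata] <- NA_real_
    out$corn <- corn
    out$soybean <- soy
    out$other <- 100 - corn - soy
    class(out) <- c("coverage_raster", class(out))
  } else {
    lab <- predict(model$models$hard, data = x, num.threads = 1)$predictions
    lab <- factor(as.character(lab), levels = .crop_classes)
    lab[nodata] <- NA
    out$label <- lab
  }
  out
}
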