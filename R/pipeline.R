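#' Extract features for every scene of an experiment
#'
#' Convenience wrapper running [extract_features()] over all (or selected)
#' years of a simulated experiment; the expensive step of the workflow, so
#' results are reusable across mapping runs.
#'
#' @param experiment A `crop_experiment` from [simulate_experiment()].
#' @param season `"full"` or `"early"`.
#' @param years Years to process (default all).
#' @return Named list (by year) of feature tables.
#' @export
experiment_features <- function(experiment, season = c("full", "early"),
                                years = experiment$config$years) {
  stopifnot(inherits(experiment, "crop_experiment"))
  season <- match.arg(season)
  out <- lapply(as.character(years), function(y) {
    extract_features(experiment$scenes[[y]]$series, mode = season)
  })
  names(out) <- as.character(years)
  out
}

#' Run one cross-year mapping experiment
#'
#' The end-to-end workflow for one mapping year: select a training year
#' (by progress similarity or the close-year rule), optionally fit and apply
#' the phenological adjustment moving mapping-year metrics into the training
#' year's frame, train the classifier on the training scene's features and
#' reference coverage (or pure-pixel labels), predict the mapping year, and
#' validate the predicted map against the mapping year's reference coverage
#' at county level.
#'
#' @param experiment A `crop_experiment`.
#' @param mapping_year Year to map.
#' @param strategy Training-year selection strategy, `"similar_progress"` or
#'   `"close_year"`.
#' @param season Season mode, `"full"` or `"early"`.
#' @param adjust Phenological adjustment kind, `"A0"`, `"A1"` or `"A2"`.
#' @param pixel Pixel definition, `"fuzzy"` or `"hard"`.
#' @param k,m,seed Forest parameters (see [train_classifier()]).
#' @param features Optional precomputed [experiment_features()] list.
#' @param pixel_area Coarse pixel area for county aggregation.
#' @return A `crop_map_run` list: `selection`, `adjustment`, `model`,
#'   `prediction`, `report` (a `validation_report`), plus the mapping and
#'   training years.
#' @export
run_cross_year <- function(experiment, mapping_year,
                           strategy = c("similar_progress", "close_year"),
                           season = c("full", "early"),
                           adjust = c("A0", "A1", "A2"),
                           pixel = c("fuzzy", "hard"),
                           k = 100, m = 1, seed = 1,
                           features = NULL, pixel_area = 25) {
  stopifnot(inherits(experiment, "crop_experiment"))
  strategy <- match.arg(strategy)
  season <- match.arg(season)
  adjust <- match.arg(adjust)
  pixel <- match.arg(pixel)
  cfg <- experiment$config

  selection <- select_training_year(
    experiment$progress, mapping_year,
    candidates = setdiff(cfg$years, mapping_year),
    strategy = strategy, state = cfg$state
  )
  train_year <- selection$selected

  features <- features %||%
    experiment_features(experiment, season, years = c(train_year, mapping_year))
  f_train <- features[[as.character(train_year)]]
  f_map <- features[[as.character(mapping_year)]]

  adjustment <- if (adjust == "A0") {
    fit_adjustment(kind = "A0")
  } else {
    sd_all <- stage_dates(experiment$progress)
    fit_adjustment(
      sd_all[sd_all$state == cfg$state & sd_all$year == mapping_year, ],
      sd_all[sd_all$state == cfg$state & sd_all$year == train_year, ],
      kind = adjust
    )
  }
  if (adjust != "A0") f_map <- apply_adjustment(f_map, adjustment)

  train_scene <- experiment$scenes[[as.character(train_year)]]
  map_scene <- experiment$scenes[[as.character(mapping_year)]]
  targets <- if (pixel == "fuzzy") {
    train_scene$coverage
  } else {
    labs <- select_pure_pixels(train_scene$coverage)
    labs[!is.na(labs$label), , drop = FALSE]
  }
  model <- train_classifier(f_train, targets, pixel = pixel, k = k, m = m,
                            seed = seed, state = cfg$state, year = train_year,
                            adjustment = adjust)
  prediction <- predict_coverage(model, f_map)
  pred_cov <- if (pixel == "hard") labels_to_coverage(prediction) else prediction

  mapped_stats <- county_aggregate(pred_cov, map_scene$zones, pixel_area)
  ref_stats <- county_aggregate(map_scene$coverage, map_scene$zones, pixel_area)
  report <- compare_counties(mapped_stats, ref_stats)

  structure(
    list(mapping_year = mapping_year, training_year = train_year,
         strategy = strategy, season = season, adjust = adjust, pixel = pixel,
         selection = selection, adjustment = adjustment, model = model,
         prediction = prediction, report = report),
    class = "crop_map_run"
  )
}

#' @export
print.crop_map_run <- function(x, ...) {
  cat(sprintf("<crop_map_run> mapping %d from %d (%s, %s season, %s, %s)\n",
              x$mapping_year, x$training_year, x$strategy, x$season,
              x$adjust, x$pixel))
  print(x$report$summary)
  invisible(x)
}

#' @rdname run_cross_year
#' @param x A `crop_map_run` object.
#' @method glance crop_map_run
#' @export
glance.crop_map_run <- function(x, ...) {
  out <- glance(x$report)
  tibble::add_column(out,
    mapping_year = x$mapping_year, training_year = x$training_year,
    strategy = x$strategy, season = x$season, adjust = x$adjust,
    pixel = x$pixel, .before = 1)
}
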