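#' Aggregate a coverage map to county crop areas
#'
#' Coverage-weighted crop area per county: for each county, the sum over its
#' coarse pixels of `coverage% / 100 * pixel_area`. Pixels with no-data
#' coverage contribute nothing (they are counted in `n_pixels` but not area).
#' Counties are assigned at coarse-pixel centers via the zone raster.
#'
#' @param coverage Coverage table with `row`, `col` and `corn`, `soybean`,
#'   `other` percent columns.
#' @param zones Integer matrix of county ids with the same dimensions as the
#'   coarse grid; mismatched dimensions are a misalignment error.
#' @param pixel_area Area of one coarse pixel (default 25 ha for a ~500 m
#'   pixel).
#' @return Tibble of class `county_stats`: `county`, `n_pixels`, and per-crop
#'   areas `corn`, `soybean`, `other`.
#' @export
county_aggregate <- function(coverage, zones, pixel_area = 25) {
  .assert_cols(coverage, c("row", "col", "corn", "soybean", "other"))
  stopifnot(is.matrix(zones))
  if (max(coverage$row) > nrow(zones) || max(coverage$col) > ncol(zones)) {
    abort("coverage and zone rasters are misaligned (zone raster too small)")
  }
  cov <- tibble::as_tibble(coverage)
  cov$county <- zones[cbind(cov$row, cov$col)]
  out <- cov %>%
    dplyr::filter(!is.na(.data$county)) %>%
    dplyr::group_by(county = .data$county) %>%
    dplyr::summarise(
      n_pixels = dplyr::n(),
      corn = sum(.data$corn / 100 * pixel_area, na.rm = TRUE),
      soybean = sum(.data$soybean / 100 * pixel_area, na.rm = TRUE),
      other = sum(.data$other / 100 * pixel_area, na.rm = TRUE),
      .groups = "drop"
    )
  class(out) <- c("county_stats", class(out))
  out
}

#' Compare mapped and reference county areas
#'
#' The two county-level agreement measures: per crop, the coefficient of
#' determination of mapped versus reference county areas (squared Pearson
#' correlation; the alternative one-to-one estimator
#' `1 - SS_res / SS_tot` is reported alongside as `r2_one_to_one`), and the
#' percentage difference of total cropped area,
#' `100 (mapped_total - reference_total) / reference_total`.
#'
#' @param mapped,reference `county_stats` tables sharing at least 2 counties;
#'   each crop's reference total must be positive.
#' @param crops Crops to evaluate.
#' @return A `validation_report`: `summary` tibble (per crop: `n_counties`,
#'   `r2`, `r2_one_to_one`, `pct_diff`) and a per-county `scatter` table.
#' @export
compare_counties <- function(mapped, reference, crops = c("corn", "soybean")) {
  .assert_cols(mapped, c("county", crops))
  .assert_cols(reference, c("county", crops))
  j <- dplyr::inner_join(tibble::as_tibble(mapped),
                         tibble::as_tibble(reference),
                         by = "county", suffix = c("_map", "_ref"))
  if (nrow(j) < 2) abort("fewer than 2 shared counties")
  summary <- purrr::map_dfr(crops, function(cls) {
    m <- j[[paste0(cls, "_map")]]
    r <- j[[paste0(cls, "_ref")]]
    if (sum(r) <= 0) abort(sprintf("reference total for %s is not positive", cls))
    tibble::tibble(
      crop = cls,
      n_counties = nrow(j),
      r2 = cor(m, r)^2,
      r2_one_to_one = 1 - sum((m - r)^2) / sum((r - mean(r))^2),
      pct_diff = 100 * (sum(m) - sum(r)) / sum(r)
    )
  })
  scatter <- purrr::map_dfr(crops, function(cls) {
    tibble::tibble(county = j$county, crop = cls,
                   mapped = j[[paste0(cls, "_map")]],
                   reference = j[[paste0(cls, "_ref")]])
  })
  structure(list(summary = summary, scatter = scatter),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  print(x$summary)
  invisible(x)
}

#' @rdname compare_counties
#' @param x A `validation_report` object.
#' @method tidy validation_report
#' @export
tidy.validation_report <- function(x, ...) {
  x$summary
}

#' @rdname compare_counties
#' @method glance validation_report
#' @export
glance.validation_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    x$summary[, c("crop", "r2", "pct_diff")],
    names_from = "crop", values_from = c("r2", "pct_diff")
  )
  wide$n_counties <- x$summary$n_counties[1]
  wide
}

#' @method autoplot validation_report
#' @export
autoplot.validation_report <- function(object, ...) {
  ggplot2::ggplot(object$scatter,
                  ggplot2::aes(x = .data$reference, y = .data$mapped)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~crop) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Reference county area", y = "Mapped county area")
}
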