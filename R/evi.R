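#' Enhanced Vegetation Index
#'
#' Computes the standard three-band EVI,
#' \deqn{EVI = 2.5 (NIR - red) / (NIR + 6\,red - 7.5\,blue + 1),}
#' the greenness index used throughout the package because it saturates less
#' than NDVI over high-biomass crops. Degenerate inputs (non-positive
#' denominator, or a result outside \[-1, 1.5\]) are flagged invalid by
#' returning `NA` rather than raising an error, so bad composites propagate
#' as missing observations.
#'
#' @param red,nir,blue Surface reflectance in \[0, 1\] (MODIS bands 1, 2, 3).
#' @return Numeric vector of EVI values with `NA` where the index is invalid.
#' @examples
#' compute_evi(red = 0.1, nir = 0.5, blue = 0.05)
#' compute_evi(red = 0.9, nir = 0.0, blue = 1.0) # degenerate -> NA
#' @export
compute_evi <- function(red, nir, blue) {
  den <- nir + 6 * red - 7.5 * blue + 1
  evi <- 2.5 * (nir - red) / den
  bad <- !is.finite(evi) | den <= 0 | evi < -1 | evi > 1.5
  evi[bad] <- NA_real_
  evi
}

#' Per-composite EVI series from a reflectance table
#'
#' Reduces a reflectance time-series table (columns `doy`, `b1`..`b7`,
#' logical `good`) to the EVI series used for curve fitting. A composite is
#' valid only when it is flagged good, the bands entering the index are
#' within \[0, 1\], and the index itself is valid.
#'
#' @param series Data frame with columns `doy`, `b1` (red), `b2` (NIR),
#'   `b3` (blue) and optionally `good` (assumed all good when absent).
#' @return Tibble with columns `doy`, `evi`, `valid`.
#' @export
evi_series <- function(series) {
  .assert_cols(series, c("doy", "b1", "b2", "b3"))
  good <- if ("good" %in% names(series)) series$good else rep(TRUE, nrow(series))
  in_range <- series$b1 >= 0 & series$b1 <= 1 &
    series$b2 >= 0 & series$b2 <= 1 &
    series$b3 >= 0 & series$b3 <= 1
  evi <- compute_evi(series$b1, series$b2, series$b3)
  tibble::tibble(
    doy = series$doy,
    evi = evi,
    valid = good & !is.na(in_range) & in_range & !is.na(evi)
  )
}
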