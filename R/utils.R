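# ln(2 + sqrt(3)): half-width, in units of 1/slope, between a logistic
# mid-date and the extrema of its second derivative.
.sigmoid_k <- log(2 + sqrt(3))

#' Nominal start days of year of the 8-day composites
#'
#' Composite `n` covers days of year `[8(n-1)+1, 8n]` (1-based); its nominal
#' date is the start day, so a complete year has composites at days
#' 1, 9, ..., 361.
#'
#' @param n Number of composites (46 for a complete year).
#' @return Integer vector of start days of year.
#' @export
doy_composites <- function(n = 46L) {
  stopifnot(n >= 1, n <= 46)
  seq(1L, by = 8L, length.out = n)
}

.crop_classes <- c("corn", "soybean", "other")

# class codes used in label rasters (echo CDL: 1 corn, 5 soybean, 0 other)
.class_codes <- c(other = 0L, corn = 1L, soybean = 5L)

.assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}
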