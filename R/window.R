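#' Season window
#'
#' Defines the part of the composite year visible to the workflow. The full
#' window covers all 46 composites. The early window ends with the 28th
#' composite, whose last covered day is day of year `8 * 28 = 224`
#' (12 August, or 11 August in leap years; the day-of-year cutoff is primary).
#' By that date corn and soybean have normally reached peak growth, so the
#' rising limb of the EVI profile is observable but the senescing limb is not.
#'
#' @param mode `"full"` or `"early"`.
#' @param n_composites Number of composites retained; defaults to 46 (full)
#'   or 28 (early).
#' @return A `season_window` object with fields `mode`, `n_composites` and
#'   `end_doy` (= `8 * n_composites`).
#' @examples
#' season_window("early")$end_doy # 224
#' @export
season_window <- function(mode = c("full", "early"), n_composites = NULL) {
  mode <- match.arg(mode)
  n_composites <- as.integer(n_composites %||% if (mode == "early") 28L else 46L)
  stopifnot(n_composites >= 1, n_composites <= 46)
  structure(
    list(mode = mode, n_composites = n_composites, end_doy = 8L * n_composites),
    class = "season_window"
  )
}

#' @export
print.season_window <- function(x, ...) {
  cat(sprintf("<season_window> mode=%s, %d composites, end DOY %d\n",
              x$mode, x$n_composites, x$end_doy))
  invisible(x)
}

#' Truncate a composite series to a season window
#'
#' Removes composites whose nominal start day of year falls after the window
#' end; observations beyond the window are treated as not yet acquired. The
#' full window is the identity and truncation is idempotent.
#'
#' @param series Data frame with a `doy` column of composite start days.
#' @param window A [season_window()].
#' @return The input with out-of-window rows dropped.
#' @export
truncate_to_window <- function(series, window) {
  stopifnot(inherits(window, "season_window"))
  .assert_cols(series, "doy")
  if (window$mode == "full" && window$n_composites == 46L) {
    return(series)
  }
  series[series$doy <= window$end_doy, , drop = FALSE]
}
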