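#' Day of year of 50% crop progress
#'
#' Interpolates a weekly cumulative-progress series (percent of cropland
#' having reached a stage by each week's end) to the day of year at which it
#' crosses 50%. Linear interpolation between the bracketing weeks; exact when
#' a report hits 50 exactly. A series that never reaches 50 is missing
#' (`NA`). When the first report is already above 50, the date is
#' back-extrapolated from the first two reports, clipped to no more than 7
#' days before the first report (sparse early reports otherwise produce
#' absurdly early dates).
#'
#' @param doy Week-ending days of year, increasing.
#' @param percent Cumulative percent complete, non-decreasing, in \[0, 100\].
#' @return Day of year (numeric scalar) or `NA` when the stage never reaches
#'   50%.
#' @examples
#' fifty_percent_date(c(140, 147), c(30, 65)) # 144
#' @export
fifty_percent_date <- function(doy, percent) {
  keep <- is.finite(doy) & is.finite(percent)
  doy <- doy[keep]
  percent <- percent[keep]
  if (length(doy) == 0) return(NA_real_)
  ord <- order(doy)
  doy <- doy[ord]
  percent <- percent[ord]
  if (is.unsorted(percent)) abort("cumulative progress must be non-decreasing")
  if (max(percent) < 50) return(NA_real_)
  hit <- which(percent == 50)
  if (length(hit) > 0) return(doy[hit[1]])
  if (percent[1] > 50) {
    if (length(doy) < 2 || percent[2] == percent[1]) return(doy[1] - 7)
    slope <- (percent[2] - percent[1]) / (doy[2] - doy[1])
    return(max(doy[1] - (percent[1] - 50) / slope, doy[1] - 7))
  }
  i <- max(which(percent < 50))
  doy[i] + (doy[i + 1] - doy[i]) * (50 - percent[i]) / (percent[i + 1] - percent[i])
}

#' 50%-progress dates for every state-year-stage
#'
#' Reduces a weekly crop-progress table to one 50%-progress day of year per
#' (state, year, crop, stage). Corn and soybean stages are pooled into a
#' single progress-item vector per state-year (items named `crop:stage`),
#' which is the form entering the year-similarity RMSD and the phenological
#' adjustment fit. Stages that never reach 50% yield `NA` and are treated as
#' missing downstream.
#'
#' @param progress Table with columns `state`, `year`, `crop`, `stage`,
#'   `week_ending_doy`, `percent`.
#' @return Tibble of class `stage_dates` with columns `state`, `year`,
#'   `item`, `doy`.
#' @export
stage_dates <- function(progress) {
  .assert_cols(progress, c("state", "year", "crop", "stage",
                           "week_ending_doy", "percent"))
  out <- progress %>%
    dplyr::group_by(.data$state, .data$year, .data$crop, .data$stage) %>%
    dplyr::summarise(
      doy = fifty_percent_date(.data$week_ending_doy, .data$percent),
      .groups = "drop"
    ) %>%
    dplyr::mutate(item = paste(.data$crop, .data$stage, sep = ":")) %>%
    dplyr::select("state", "year", "item", "doy")
  class(out) <- c("stage_dates", class(out))
  out
}

#' Phenological similarity between two years
#'
#' Root-mean-square deviation of the 50%-progress dates over the progress
#' items shared by two stage-date vectors:
#' \deqn{RMSD = \sqrt{\frac{1}{n}\sum_i (X_{i,v} - X_{i,t})^2}}
#' where \eqn{X_{i,v}} and \eqn{X_{i,t}} are the 50% dates of item \eqn{i} in
#' the two years. Items missing in either year are excluded; no shared item
#' is an error.
#'
#' @param a,b Tables with columns `item` and `doy` (e.g. one year's rows of
#'   [stage_dates()]).
#' @return RMSD in days.
#' @examples
#' a <- data.frame(item = c("s1", "s2", "s3"), doy = c(150, 180, 210))
#' b <- data.frame(item = c("s1", "s2", "s3"), doy = c(153, 184, 212))
#' progress_rmsd(a, b) # sqrt(29/3)
#' @export
progress_rmsd <- function(a, b) {
  .assert_cols(a, c("item", "doy"))
  .assert_cols(b, c("item", "doy"))
  j <- dplyr::inner_join(
    a[, c("item", "doy")], b[, c("item", "doy")],
    by = "item", suffix = c("_a", "_b")
  )
  j <- j[is.finite(j$doy_a) & is.finite(j$doy_b), , drop = FALSE]
  if (nrow(j) == 0) abort("no shared progress items between the two years")
  sqrt(mean((j$doy_a - j$doy_b)^2))
}

#' Select a training year for cross-year mapping
#'
#' Two strategies. `"similar_progress"`: among candidate years, pick the one
#' whose 50%-progress date vector has the smallest RMSD
#' ([progress_rmsd()]) to the mapping year's, ties broken toward the most
#' recent year. `"close_year"`: ignore progress and pick the prior year
#' (for the earliest mapping year, the following year). States without
#' progress records can fall back to a configured neighboring state's data.
#'
#' @param progress Weekly progress table (see [stage_dates()]); may be `NULL`
#'   for `"close_year"`.
#' @param mapping_year Year being mapped.
#' @param candidates Candidate training years (never includes the mapping
#'   year; it is removed if present).
#' @param strategy `"similar_progress"` or `"close_year"`.
#' @param state State whose progress drives the similarity; defaults to the
#'   single state present in `progress`.
#' @param fallback_state Neighboring state used when `state` has no progress
#'   records.
#' @return A `year_selection` object: fields `mapping_year`, `strategy`,
#'   `state`, `selected`, and a per-candidate `table` (with RMSD under
#'   `"similar_progress"`).
#' @export
select_training_year <- function(progress, mapping_year, candidates,
                                 strategy = c("similar_progress", "close_year"),
                                 state = NULL, fallback_state = NULL) {
  strategy <- match.arg(strategy)
  candidates <- sort(setdiff(candidates, mapping_year))
  if (length(candidates) == 0) abort("no candidate training years")

  if (strategy == "close_year") {
    prior <- candidates[candidates < mapping_year]
    selected <- if (length(prior) > 0) max(prior) else min(candidates)
    table <- tibble::tibble(candidate = candidates, rmsd = NA_real_,
                            selected = candidates == selected)
  } else {
    sd_all <- stage_dates(progress)
    state <- state %||% unique(sd_all$state)
    if (length(state) != 1) abort("specify `state`: progress covers multiple states")
    rows <- sd_all[sd_all$state == state, , drop = FALSE]
    if (!any(is.finite(rows$doy))) {
      if (is.null(fallback_state)) {
        abort(sprintf("no progress records for state '%s' and no fallback_state given", state))
      }
      state <- fallback_state
      rows <- sd_all[sd_all$state == state, , drop = FALSE]
      if (!any(is.finite(rows$doy))) {
        abort(sprintf("no progress records for fallback state '%s'", state))
      }
    }
    map_dates <- rows[rows$year == mapping_year, , drop = FALSE]
    if (!any(is.finite(map_dates$doy))) {
      abort(sprintf("no progress records for mapping year %s", mapping_year))
    }
    rmsd <- vapply(candidates, function(y) {
      cand <- rows[rows$year == y, , drop = FALSE]
      if (!any(is.finite(cand$doy))) return(NA_real_)
      progress_rmsd(map_dates, cand)
    }, numeric(1))
    if (all(is.na(rmsd))) abort("no candidate year has progress records")
    best <- min(rmsd, na.rm = TRUE)
    # ties to the most recent year
    selected <- max(candidates[!is.na(rmsd) & rmsd == best])
    table <- tibble::tibble(candidate = candidates, rmsd = rmsd,
                            selected = candidates == selected)
  }
  structure(
    list(mapping_year = mapping_year, strategy = strategy,
         state = if (strategy == "close_year") NA_character_ else state,
         selected = selected, table = table),
    class = "year_selection"
  )
}

#' @export
print.year_selection <- function(x, ...) {
  cat(sprintf("<year_selection> mapping %s -> training %s (%s)\n",
              x$mapping_year, x$selected, x$strategy))
  print(x$table)
  invisible(x)
}

#' @rdname select_training_year
#' @param x A `year_selection` object.
#' @method tidy year_selection
#' @export
tidy.year_selection <- function(x, ...) {
  dplyr::mutate(x$table, mapping_year = x$mapping_year, strategy = x$strategy)
}

#' @method autoplot year_selection
#' @export
autoplot.year_selection <- function(object, ...) {
  dat <- object$table[!is.na(object$table$rmsd), , drop = FALSE]
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$candidate), y = .data$rmsd,
                                    fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Candidate training year", y = "Progress RMSD (days)",
                  title = sprintf("Mapping year %s", object$mapping_year)) +
    ggplot2::guides(fill = "none")
}
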