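# sum an nr x nc matrix over fct x fct blocks
.block_sum <- function(m, fct) {
  nrb <- nrow(m) %/% fct
  ncb <- ncol(m) %/% fct
  m1 <- rowsum(m, group = rep(seq_len(nrb), each = fct), reorder = FALSE)
  t(rowsum(t(m1), group = rep(seq_len(ncb), each = fct), reorder = FALSE))
}

#' Aggregate a fine label raster to coverage percentages
#'
#' Converts a fine-resolution crop-label raster (integer codes: 1 corn,
#' 5 soybean, 0 other, echoing CDL codes) into per-coarse-pixel coverage
#' percentages: for each `factor x factor` block, the count of fine cells of
#' each class divided by the block size, times 100. These percentages are the
#' regression targets of fuzzy classification. Dimensions not divisible by
#' `factor` are cropped at the trailing edge with a warning.
#'
#' @param fine Integer matrix of class codes.
#' @param factor Block edge length in fine cells (default 16, emulating 30 m
#'   cells under a 480 m coarse pixel).
#' @return Tibble of class `coverage_raster` with columns `pixel`, `row`,
#'   `col`, `corn`, `soybean`, `other` (percent, summing to 100).
#' @examples
#' fine <- matrix(c(1L, 1L, 5L, 0L), 2, 2)
#' aggregate_coverage(fine, factor = 2)
#' @export
aggregate_coverage <- function(fine, factor = 16L) {
  stopifnot(is.matrix(fine), factor >= 1)
  factor <- as.integer(factor)
  nr <- nrow(fine) %/% factor * factor
  nc <- ncol(fine) %/% factor * factor
  if (nr == 0 || nc == 0) abort("raster smaller than one aggregation block")
  if (nr < nrow(fine) || nc < ncol(fine)) {
    warn(sprintf("raster dimensions not divisible by %d; cropping to %d x %d",
                 factor, nr, nc))
    fine <- fine[seq_len(nr), seq_len(nc), drop = FALSE]
  }
  scale <- 100 / factor^2
  pct <- lapply(c(corn = 1L, soybean = 5L, other = 0L), function(code) {
    as.vector(.block_sum((fine == code) + 0L, factor)) * scale
  })
  nrb <- nr %/% factor
  ncb <- nc %/% factor
  out <- tibble::tibble(
    row = rep(seq_len(nrb), times = ncb),
    col = rep(seq_len(ncb), each = nrb),
    corn = pct$corn, soybean = pct$soybean, other = pct$other
  )
  out$pixel <- (out$row - 1L) * ncb + out$col
  out <- out[order(out$pixel), c("pixel", "row", "col", "corn", "soybean", "other")]
  class(out) <- c("coverage_raster", class(out))
  out
}

#' Select pure pixels for hard classification
#'
#' Assigns a discrete label to coarse pixels whose single-class coverage
#' strictly exceeds the purity threshold (default 75%, i.e. more than 75% of
#' the coarse pixel covered by one class); all other pixels are left
#' unlabeled (`NA`) and excluded from hard training. The same rule is applied
#' symmetrically to the "other" class.
#'
#' @param coverage A coverage table with columns `corn`, `soybean`, `other`.
#' @param threshold Purity threshold in percent, strictly between 50 and 100.
#' @return The input id columns plus a `label` factor
#'   (`corn`/`soybean`/`other`, `NA` when mixed).
#' @export
select_pure_pixels <- function(coverage, threshold = 75) {
  .assert_cols(coverage, c("corn", "soybean", "other"))
  stopifnot(threshold > 50, threshold < 100)
  label <- dplyr::case_when(
    coverage$corn > threshold ~ "corn",
    coverage$soybean > threshold ~ "soybean",
    coverage$other > threshold ~ "other",
    TRUE ~ NA_character_
  )
  ids <- intersect(c("pixel", "row", "col"), names(coverage))
  out <- tibble::as_tibble(coverage[, ids, drop = FALSE])
  out$label <- factor(label, levels = .crop_classes)
  out
}

#' Convert hard labels to one-hot coverage
#'
#' Expands discrete labels into 0/100 coverage percentages so hard
#' classification maps can enter the same county aggregation and validation
#' path as fuzzy maps. Unlabeled pixels become all-`NA` rows.
#'
#' @param labels Table with a `label` column (`corn`/`soybean`/`other`).
#' @return Tibble with `corn`, `soybean`, `other` percent columns.
#' @export
labels_to_coverage <- function(labels) {
  .assert_cols(labels, "label")
  ids <- intersect(c("pixel", "row", "col"), names(labels))
  out <- tibble::as_tibble(labels[, ids, drop = FALSE])
  lab <- as.character(labels$label)
  for (cls in .crop_classes) {
    out[[cls]] <- ifelse(is.na(lab), NA_real_, 100 * (lab == cls))
  }
  class(out) <- c("coverage_raster", class(out))
  out
}

#' @method autoplot coverage_raster
#' @export
autoplot.coverage_raster <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object[, c("row", "col", "corn", "soybean", "other")]),
    cols = c("corn", "soybean", "other"),
    names_to = "class", values_to = "percent"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$col, y = .data$row,
                                     fill = .data$percent)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~class) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "% cover")
}
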