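# how each feature responds to the cross-year date transform x -> a + b x:
# dates map affinely, date differences scale by b, per-day rates divide by b;
# everything else (amplitudes, spectral metrics) is left untouched
.metric_adjust_class <- c(
  V_b = "none", V_a = "none",
  p = "rate", q = "rate",
  D_i = "date", D_d = "date", D_1 = "date", D_2 = "date",
  D_3 = "date", D_4 = "date", D_peak = "date",
  L_id = "length", L_14 = "length"
)

.feature_meta_cols <- c("pixel", "row", "col", "mode", "season", "label",
                        "fit_ok", "fit_rmse", "n_obs")

.adjust_class_of <- function(nm) {
  if (nm %in% names(.metric_adjust_class)) {
    return(unname(.metric_adjust_class[nm]))
  }
  base <- sub("_(avg|peak)$", "", nm)
  if (grepl("_(avg|peak)$", nm) && base %in% .spectral_names) {
    return("none")
  }
  abort(sprintf("unknown metric class for feature '%s'", nm))
}

#' Fit a cross-year phenological adjustment
#'
#' Builds the transform that moves mapping-year phenological dates into the
#' training-year frame, `X_t = a + b X_v`, from the 50%-progress dates shared
#' by the two years. Three kinds: `"A0"` is the identity (no adjustment,
#' `a = 0`, `b = 1`); `"A1"` fits `a` and `b` by ordinary least squares of
#' training-year on mapping-year dates (at least 2 shared items; a
#' non-positive slope is a degenerate regression and errors); `"A2"` fixes
#' `b = 1` and shifts by the mean date difference (at least 1 shared item).
#'
#' @param map_dates,train_dates 50%-progress dates of the mapping and
#'   training year: tables with columns `item`, `doy` (see [stage_dates()]),
#'   ignored for `"A0"`.
#' @param kind `"A0"`, `"A1"` or `"A2"`.
#' @return A `pheno_adjustment` object with fields `kind`, `a`, `b`, the
#'   shared-stage table `stages`, and the date correlation `correlation`.
#' @examples
#' v <- data.frame(item = c("s1", "s2", "s3"), doy = c(140, 170, 200))
#' t <- data.frame(item = c("s1", "s2", "s3"), doy = c(150, 182, 214))
#' fit_adjustment(v, t, "A1") # exact line through collinear points
#' @export
fit_adjustment <- function(map_dates = NULL, train_dates = NULL,
                           kind = c("A0", "A1", "A2")) {
  kind <- match.arg(kind)
  if (kind == "A0") {
    return(structure(
      list(kind = "A0", a = 0, b = 1, stages = NULL, correlation = NA_real_),
      class = "pheno_adjustment"
    ))
  }
  .assert_cols(map_dates, c("item", "doy"))
  .assert_cols(train_dates, c("item", "doy"))
  j <- dplyr::inner_join(
    map_dates[, c("item", "doy")], train_dates[, c("item", "doy")],
    by = "item", suffix = c("_v", "_t")
  )
  j <- j[is.finite(j$doy_v) & is.finite(j$doy_t), , drop = FALSE]
  need <- if (kind == "A1") 2L else 1L
  if (nrow(j) < need) {
    abort(sprintf("adjustment %s needs at least %d shared stage date(s), got %d",
                  kind, need, nrow(j)))
  }
  if (kind == "A1") {
    fit <- lm(doy_t ~ doy_v, data = j)
    b <- unname(coef(fit)["doy_v"])
    a <- unname(coef(fit)["(Intercept)"])
    if (!is.finite(b) || b <= 0) {
      abort("degenerate A1 regression: fitted slope is not positive")
    }
  } else {
    b <- 1
    a <- mean(j$doy_t) - mean(j$doy_v)
  }
  correlation <- if (nrow(j) >= 2 && sd(j$doy_v) > 0 && sd(j$doy_t) > 0) {
    cor(j$doy_v, j$doy_t)
  } else {
    NA_real_
  }
  structure(
    list(kind = kind, a = a, b = b, stages = tibble::as_tibble(j),
         correlation = correlation),
    class = "pheno_adjustment"
  )
}

#' @export
print.pheno_adjustment <- function(x, ...) {
  cat(sprintf("<pheno_adjustment> %s: X_t = %.4f + %.4f * X_v (r = %s, %d stages)\n",
              x$kind, x$a, x$b,
              ifelse(is.na(x$correlation), "NA", sprintf("%.3f", x$correlation)),
              if (is.null(x$stages)) 0L else nrow(x$stages)))
  invisible(x)
}

#' @rdname fit_adjustment
#' @param x A `pheno_adjustment` object.
#' @method tidy pheno_adjustment
#' @export
tidy.pheno_adjustment <- function(x, ...) {
  tibble::tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @rdname fit_adjustment
#' @method glance pheno_adjustment
#' @export
glance.pheno_adjustment <- function(x, ...) {
  tibble::tibble(kind = x$kind, a = x$a, b = x$b,
                 correlation = x$correlation,
                 n_stages = if (is.null(x$stages)) 0L else nrow(x$stages))
}

#' Apply a phenological adjustment to features
#'
#' Transforms the phenological metrics of a feature table into the training
#' year's frame: date metrics (`D_i`, `D_d`, `D_1`..`D_4`, `D_peak`) become
#' `a + b x`, season lengths (`L_id`, `L_14`) scale by `b`, per-day rates
#' (`p`, `q`) divide by `b`. Amplitudes and spectral metrics are never
#' adjusted. A feature column that is neither a known phenological metric nor
#' a stage-anchored spectral metric is an error.
#'
#' @param features Feature table (e.g. from [extract_features()]) or a
#'   `pheno_metrics` row; id/bookkeeping columns pass through unchanged.
#' @param model A `pheno_adjustment` from [fit_adjustment()].
#' @return The feature table with adjusted phenological metrics.
#' @export
apply_adjustment <- function(features, model) {
  stopifnot(inherits(model, "pheno_adjustment"))
  out <- features
  for (nm in setdiff(names(features), .feature_meta_cols)) {
    cls <- .adjust_class_of(nm)
    out[[nm]] <- switch(cls,
      date = model$a + model$b * features[[nm]],
      length = model$b * features[[nm]],
      rate = features[[nm]] / model$b,
      none = features[[nm]]
    )
  }
  out
}
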