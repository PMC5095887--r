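#' Asymmetric double-sigmoid growth curve
#'
#' The seasonal EVI model used for phenology retrieval:
#' \deqn{f(t) = V_b + V_a [\sigma(p (t - D_i)) - \sigma(q (t - D_d))]}
#' with \eqn{\sigma} the standard logistic. `V_b` is the background
#' (non-growing-season) EVI, `V_a` the amplitude, `p`/`q` the rising/falling
#' slope parameters (per day) and `D_i`/`D_d` the mid-dates of the rising and
#' falling limbs (day of year). With `q = NULL` the falling term is dropped,
#' giving the rising-only model used for early-season retrieval.
#'
#' @param doy Day of year (numeric vector).
#' @param V_b,V_a,p,D_i Background, amplitude, rising slope, rising mid-date.
#' @param q,D_d Falling slope and mid-date, or `NULL` for the rising-only form.
#' @return Modeled EVI at `doy`.
#' @export
double_sigmoid <- function(doy, V_b, V_a, p, D_i, q = NULL, D_d = NULL) {
  r <- stats::plogis(p * (doy - D_i))
  if (!is.null(q)) {
    r <- r - stats::plogis(q * (doy - D_d))
  }
  V_b + V_a * r
}

# fitting bounds; D_d is parameterized as D_i + L with L >= 8 so the falling
# mid-date cannot cross the rising one
.fit_bounds <- list(
  full = list(
    lower = c(V_b = -0.2, V_a = 0, p = 0.01, D_i = 1, q = 0.01, L = 8),
    upper = c(V_b = 0.6, V_a = 1.2, p = 1, D_i = 366, q = 1, L = 365)
  ),
  early = list(
    lower = c(V_b = -0.2, V_a = 0, p = 0.01, D_i = 1),
    upper = c(V_b = 0.6, V_a = 1.2, p = 1, D_i = 366)
  )
)

.unfit <- function(mode, reason, n_obs, data) {
  structure(
    list(ok = FALSE, mode = mode, reason = reason, par = NULL,
         fit_rmse = NA_real_, n_obs = n_obs, data = data),
    class = "pheno_fit"
  )
}

#' Fit the double sigmoid to an EVI time series
#'
#' Bounded Levenberg-Marquardt least squares of the [double_sigmoid()] model
#' against one pixel-year of EVI observations. In `"early"` mode only the
#' rising limb is fitted (4 parameters) and all observations must fall within
#' the early window. Pixels with too few valid observations (fewer than 10 in
#' full mode, 6 in early mode: below that the 6-parameter fit is ill-posed)
#' or for which the optimizer fails are returned as unfit rather than raising,
#' so no-data propagates downstream.
#'
#' Initial values come from the data: `V_b` at the 5th percentile of valid
#' EVI, `V_a` as the 95th-5th percentile range, mid-dates at the first/last
#' half-amplitude crossing, slopes 0.1 per day (with two fallback slope
#' starts retried if the first fit is poor).
#'
#' @param series Data frame with columns `doy`, `evi` and optionally `valid`
#'   (defaults to non-missing `evi`), e.g. from [evi_series()].
#' @param mode `"full"` or `"early"`.
#' @param early_end Last day of year of the early window (default 224).
#' @param min_obs Minimum valid observations; defaults to 10 (full) / 6 (early).
#' @return A `pheno_fit` object: fields `ok`, `mode`, `par` (named vector
#'   `V_b`, `V_a`, `p`, `D_i` and in full mode `q`, `D_d`), `fit_rmse`,
#'   `n_obs`, and the observation table in `data`.
#' @examples
#' doy <- doy_composites()
#' evi <- double_sigmoid(doy, 0.15, 0.55, 0.12, 160, 0.10, 250)
#' fit <- fit_double_sigmoid(data.frame(doy = doy, evi = evi))
#' fit$par
#' @export
fit_double_sigmoid <- function(series, mode = c("full", "early"),
                               early_end = 224, min_obs = NULL) {
  mode <- match.arg(mode)
  .assert_cols(series, c("doy", "evi"))
  valid <- if ("valid" %in% names(series)) series$valid else rep(TRUE, nrow(series))
  valid <- valid & is.finite(series$evi)
  data <- tibble::tibble(doy = series$doy, evi = series$evi, valid = valid)
  if (mode == "early" && any(series$doy > early_end)) {
    abort(sprintf("early-mode series contains dates after DOY %d; apply truncate_to_window() first",
                  early_end))
  }
  d <- series$doy[valid]
  v <- series$evi[valid]
  min_obs <- min_obs %||% if (mode == "full") 10L else 6L
  if (length(d) < min_obs) {
    return(.unfit(mode, "too few valid observations", length(d), data))
  }

  vb0 <- unname(quantile(v, 0.05, names = FALSE))
  va0 <- max(unname(quantile(v, 0.95, names = FALSE)) - vb0, 0.01)
  half <- vb0 + va0 / 2
  above <- which(v >= half)
  di0 <- if (length(above) > 0) d[above[1]] else median(d)
  dd0 <- if (length(above) > 0) d[above[length(above)]] else di0 + 60
  di0 <- min(max(di0, 2), 360)
  L0 <- min(max(dd0 - di0, 16), 200)

  df <- data.frame(doy = d, evi = v)
  bounds <- .fit_bounds[[mode]]
  best <- NULL
  for (slope0 in c(0.1, 0.05, 0.25)) {
    start <- if (mode == "full") {
      list(V_b = vb0, V_a = va0, p = slope0, D_i = di0, q = slope0, L = L0)
    } else {
      list(V_b = vb0, V_a = va0, p = slope0, D_i = di0)
    }
    form <- if (mode == "full") {
      evi ~ V_b + V_a * (plogis(p * (doy - D_i)) - plogis(q * (doy - D_i - L)))
    } else {
      evi ~ V_b + V_a * plogis(p * (doy - D_i))
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = df, start = start,
                        lower = bounds$lower, upper = bounds$upper,
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rmse <- sqrt(mean(resid(fit)^2))
    if (is.null(best) || rmse < best$rmse) best <- list(fit = fit, rmse = rmse)
    if (rmse < 0.005) break
  }

  if (is.null(best)) {
    # a flat signal has no seasonal cycle to fit; report it as background only
    if (sd(v) < 1e-3) {
      par <- c(V_b = mean(v), V_a = 0, p = 0.1, D_i = median(d))
      if (mode == "full") par <- c(par, q = 0.1, D_d = unname(median(d)) + 8)
      return(structure(
        list(ok = TRUE, mode = mode, par = par, fit_rmse = sd(v),
             n_obs = length(d), data = data),
        class = "pheno_fit"
      ))
    }
    return(.unfit(mode, "optimizer did not converge", length(d), data))
  }

  cf <- coef(best$fit)
  par <- if (mode == "full") {
    c(V_b = unname(cf["V_b"]), V_a = unname(cf["V_a"]), p = unname(cf["p"]),
      D_i = unname(cf["D_i"]), q = unname(cf["q"]),
      D_d = unname(cf["D_i"] + cf["L"]))
  } else {
    c(V_b = unname(cf["V_b"]), V_a = unname(cf["V_a"]), p = unname(cf["p"]),
      D_i = unname(cf["D_i"]))
  }
  structure(
    list(ok = TRUE, mode = mode, par = par, fit_rmse = best$rmse,
         n_obs = length(d), data = data),
    class = "pheno_fit"
  )
}

#' @export
print.pheno_fit <- function(x, ...) {
  if (!x$ok) {
    cat(sprintf("<pheno_fit> unfit (%s), mode=%s, n_obs=%d\n",
                x$reason, x$mode, x$n_obs))
    return(invisible(x))
  }
  cat(sprintf("<pheno_fit> mode=%s, rmse=%.4f, n_obs=%d\n",
              x$mode, x$fit_rmse, x$n_obs))
  print(round(x$par, 4))
  invisible(x)
}

#' @export
predict.pheno_fit <- function(object, doy = NULL, ...) {
  if (!object$ok) abort("cannot predict from an unfit pheno_fit")
  doy <- doy %||% object$data$doy
  p <- object$par
  if (object$mode == "full") {
    double_sigmoid(doy, p["V_b"], p["V_a"], p["p"], p["D_i"], p["q"], p["D_d"])
  } else {
    double_sigmoid(doy, p["V_b"], p["V_a"], p["p"], p["D_i"])
  }
}

#' @rdname fit_double_sigmoid
#' @param x A `pheno_fit` object.
#' @method tidy pheno_fit
#' @export
tidy.pheno_fit <- function(x, ...) {
  if (!x$ok) return(tibble::tibble(term = character(), estimate = double()))
  tibble::tibble(term = names(x$par), estimate = unname(x$par))
}

#' @rdname fit_double_sigmoid
#' @method glance pheno_fit
#' @export
glance.pheno_fit <- function(x, ...) {
  tibble::tibble(ok = x$ok, mode = x$mode, fit_rmse = x$fit_rmse,
                 n_obs = x$n_obs)
}

.pheno_metric_names <- list(
  full = c("V_b", "V_a", "p", "D_i", "q", "D_d", "D_1", "D_2", "D_3", "D_4",
           "L_id", "L_14", "D_peak"),
  early = c("V_b", "V_a", "p", "D_i", "D_1", "D_2", "D_peak")
)

# "late" metrics: everything tied to the falling limb, absent in early mode
.late_metrics <- c("q", "D_d", "D_3", "D_4", "L_id", "L_14")

#' Derive phenological metrics from a fitted curve
#'
#' Turns fitted double-sigmoid parameters into the metric set used for
#' classification. The second derivative of a logistic limb with slope `s`
#' and mid-date `D` has extrema at `D +/- ln(2 + sqrt(3)) / s`, giving closed
#' forms for the transition dates:
#' `D_1 = D_i - ln(2+sqrt(3))/p` (greenup onset), `D_2 = D_i + ln(2+sqrt(3))/p`
#' (end of greenup), and in full mode `D_3 = D_d - ln(2+sqrt(3))/q`,
#' `D_4 = D_d + ln(2+sqrt(3))/q`, plus season lengths `L_id = D_d - D_i` and
#' `L_14 = D_4 - D_1`. `D_peak` is the date of maximum EVI: the argmax of the
#' fitted curve over the observation window in full mode (0.05-day grid, ties
#' to the earlier day), or the day of the maximum quality-masked observation
#' in early mode, where the fitted rising limb is monotone and its argmax
#' would degenerate to the window end.
#'
#' Full mode yields 13 metrics; early mode yields the 7 metrics not tied to
#' the falling limb, with the "late" set returned as `NA`.
#'
#' @param fit A `pheno_fit` from [fit_double_sigmoid()]. An unfit input yields
#'   an all-`NA` row.
#' @return A one-row tibble of class `pheno_metrics`: column `mode` plus the
#'   13 metric columns (late metrics `NA` in early mode).
#' @export
derive_pheno_metrics <- function(fit) {
  stopifnot(inherits(fit, "pheno_fit"))
  all_names <- .pheno_metric_names$full
  out <- setNames(rep(NA_real_, length(all_names)), all_names)
  if (fit$ok) {
    par <- fit$par
    k <- .sigmoid_k
    out["V_b"] <- par["V_b"]
    out["V_a"] <- par["V_a"]
    out["p"] <- par["p"]
    out["D_i"] <- par["D_i"]
    out["D_1"] <- par["D_i"] - k / par["p"]
    out["D_2"] <- par["D_i"] + k / par["p"]
    obs <- fit$data[fit$data$valid, , drop = FALSE]
    if (fit$mode == "full") {
      out["q"] <- par["q"]
      out["D_d"] <- par["D_d"]
      out["D_3"] <- par["D_d"] - k / par["q"]
      out["D_4"] <- par["D_d"] + k / par["q"]
      out["L_id"] <- par["D_d"] - par["D_i"]
      out["L_14"] <- out["D_4"] - out["D_1"]
      grid <- seq(min(obs$doy), max(obs$doy), by = 0.05)
      out["D_peak"] <- grid[which.max(predict(fit, grid))]
    } else {
      out["D_peak"] <- obs$doy[which.max(obs$evi)]
    }
  }
  res <- tibble::as_tibble(as.list(out))
  res <- tibble::add_column(res, mode = fit$mode, .before = 1)
  class(res) <- c("pheno_metrics", class(res))
  res
}

#' @method autoplot pheno_fit
#' @export
autoplot.pheno_fit <- function(object, ...) {
  dat <- object$data
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$doy, y = .data$evi)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$valid), na.rm = TRUE) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 4)) +
    ggplot2::labs(x = "Day of year", y = "EVI", shape = "valid")
  if (object$ok) {
    grid <- seq(min(dat$doy), max(dat$doy), by = 1)
    curve <- tibble::tibble(doy = grid, evi = predict(object, grid))
    p <- p + ggplot2::geom_line(data = curve, colour = "forestgreen")
  }
  p
}
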