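test_that("noise-free double-sigmoid parameters are recovered almost exactly", {
  truth <- c(V_b = 0.15, V_a = 0.55, p = 0.12, D_i = 160, q = 0.10, D_d = 250)
  ser <- make_sigmoid_series()
  fit <- fit_double_sigmoid(ser)
  expect_true(fit$ok)
  err <- abs(fit$par[names(truth)] - truth)
  expect_lt(max(err[c("V_b", "V_a", "p", "q")]), 1e-3)
  expect_lt(max(err[c("D_i", "D_d")]), 0.1)
})

test_that("a constant series fits as background with near-zero amplitude", {
  fit <- fit_double_sigmoid(data.frame(doy = doy_composites(), evi = 0.2))
  expect_true(fit$ok)
  expect_equal(unname(fit$par["V_b"]), 0.2, tolerance = 0.01)
  expect_lt(unname(fit$par["V_a"]), 0.01)
})

test_that("early-mode fitting on a truncated series recovers the rising mid-date", {
  ser <- make_sigmoid_series()
  early <- ser[ser$doy <= 224, ]
  fit <- fit_double_sigmoid(early, mode = "early")
  expect_true(fit$ok)
  expect_lt(abs(fit$par["D_i"] - 160), 0.5)
  expect_false("q" %in% names(fit$par))
  expect_false("D_d" %in% names(fit$par))
  # dates beyond the window violate the early-mode contract
  expect_error(fit_double_sigmoid(ser, mode = "early"), "truncate")
})

test_that("too few valid observations yield an unfit pixel, not an error", {
  ser <- make_sigmoid_series()[1:8, ]
  fit <- fit_double_sigmoid(ser)
  expect_false(fit$ok)
  expect_match(fit$reason, "too few")
  m <- derive_pheno_metrics(fit)
  expect_true(all(is.na(m[1, setdiff(names(m), "mode")])))
})

test_that("random noise-free curves refit within tight bounds (property)", {
  set.seed(101)
  for (i in 1:25) {
    truth <- random_curve_params()
    ser <- make_sigmoid_series(truth["V_b"], truth["V_a"], truth["p"],
                               truth["D_i"], truth["q"], truth["D_d"])
    fit <- fit_double_sigmoid(ser)
    expect_true(fit$ok)
    err <- abs(fit$par[names(truth)] - truth)
    expect_lt(max(err[c("V_b", "V_a", "p", "q")]), 1e-2)
    expect_lt(max(err[c("D_i", "D_d")]), 0.5)
  }
})

test_that("closed-form transition dates match the numerical second-derivative oracle", {
  set.seed(202)
  for (i in 1:10) {
    truth <- random_curve_params(min_sep = 10)
    ser <- make_sigmoid_series(truth["V_b"], truth["V_a"], truth["p"],
                               truth["D_i"], truth["q"], truth["D_d"])
    fit <- fit_double_sigmoid(ser)
    m <- derive_pheno_metrics(fit)
    oracle <- numeric_transition_dates(fit)
    expect_lt(max(abs(c(m$D_1, m$D_2, m$D_3, m$D_4) - oracle)), 0.05)
  }
})

test_that("transition dates bracket the mid-dates in order", {
  set.seed(303)
  for (i in 1:10) {
    truth <- random_curve_params()
    ser <- make_sigmoid_series(truth["V_b"], truth["V_a"], truth["p"],
                               truth["D_i"], truth["q"], truth["D_d"])
    m <- derive_pheno_metrics(fit_double_sigmoid(ser))
    expect_true(m$D_1 < m$D_i && m$D_i < m$D_2)
    expect_true(m$D_3 < m$D_d && m$D_d < m$D_4)
    expect_true(m$D_i <= m$D_peak && m$D_peak <= m$D_d)
    expect_equal(m$L_id, m$D_d - m$D_i)
    expect_equal(m$L_14, m$D_4 - m$D_1)
  }
})

test_that("a symmetric curve peaks at the midpoint of the mid-dates", {
  ser <- make_sigmoid_series(p = 0.1, D_i = 160, q = 0.1, D_d = 250)
  m <- derive_pheno_metrics(fit_double_sigmoid(ser))
  expect_equal(m$D_peak, 205, tolerance = 0.051)
})

test_that("early-mode metrics use the observed peak and expose 7 metrics", {
  # senescence well after the window, so the observed profile is still rising
  ser <- make_sigmoid_series(D_d = 300)
  early <- ser[ser$doy <= 224, ]
  m <- derive_pheno_metrics(fit_double_sigmoid(early, mode = "early"))
  expect_equal(sum(!is.na(m[1, setdiff(names(m), "mode")])), 7)
  # observed EVI is maximal at the last composite of a still-rising profile
  expect_equal(m$D_peak, max(early$doy))
  # with senescence already underway inside the window, the observed maximum
  # (not the window end) is reported
  ser2 <- make_sigmoid_series()   # D_d = 250
  early2 <- ser2[ser2$doy <= 224, ]
  m2 <- derive_pheno_metrics(fit_double_sigmoid(early2, mode = "early"))
  expect_equal(m2$D_peak, early2$doy[which.max(early2$evi)])
  expect_lt(m2$D_peak, max(early2$doy))
})

test_that("moderate EVI noise shifts the rising mid-date by a couple of days at most", {
  set.seed(404)
  errs <- replicate(30, {
    ser <- make_sigmoid_series(noise_sd = 0.02)
    fit <- fit_double_sigmoid(ser)
    abs(fit$par["D_i"] - 160)
  })
  expect_lt(median(errs), 2)
})
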