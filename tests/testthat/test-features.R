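make_band_series <- function(doy = doy_composites(), value = 0.3, good = TRUE) {
  ser <- data.frame(doy = doy)
  for (b in paste0("b", 1:7)) ser[[b]] <- value
  ser$good <- good
  ser
}

test_that("interpolation is linear between valid composites and exact on them", {
  ser <- make_band_series(doy = c(209, 217), value = 0)
  ser[1, paste0("b", 1:7)] <- 0.30
  ser[2, paste0("b", 1:7)] <- 0.40
  expect_equal(unname(interpolate_at(ser, 213)["b6"]), 0.35)
  expect_equal(unname(interpolate_at(ser, 209)["b6"]), 0.30)
  # out-of-span target flags all bands missing
  expect_true(all(is.na(interpolate_at(ser, 201))))
  # a bad composite cannot bracket
  ser$good <- c(FALSE, TRUE)
  expect_true(all(is.na(interpolate_at(ser, 213))))
})

test_that("interpolation is exact on signals linear in time (property)", {
  doy <- doy_composites()
  ser <- make_band_series(doy = doy)
  for (b in paste0("b", 1:7)) ser[[b]] <- 0.1 + 0.001 * doy
  for (target in c(100, 153.5, 222)) {
    expect_equal(unname(interpolate_at(ser, target)["b3"]), 0.1 + 0.001 * target,
                 tolerance = 1e-12)
  }
})

test_that("averaging uses only valid composites in range", {
  ser <- make_band_series(doy = c(150, 160, 170, 300))
  ser[, "b6"] <- c(0.2, 0.3, 0.4, 9)   # out-of-range band value is invalid too
  ser$good <- c(TRUE, TRUE, TRUE, TRUE)
  expect_equal(unname(average_between(ser, 145, 250)["b6"]), 0.3)
  expect_equal(unname(average_between(ser, 155, 165)["b6"]), 0.3)
  expect_true(all(is.na(average_between(ser, 1, 100))))
  # a constant series averages to the constant
  expect_equal(unname(average_between(make_band_series(value = 0.25), 1, 361)["b2"]), 0.25)
})

test_that("full and early feature vectors have exactly 27 and 21 named entries", {
  expect_length(feature_names("full"), 27)
  expect_length(feature_names("early"), 21)
  # early names are the full names minus the six late phenology metrics
  late <- c("q", "D_d", "D_3", "D_4", "L_id", "L_14")
  expect_setequal(feature_names("early"), setdiff(feature_names("full"), late))
})

test_that("the feature pipeline emits the right width and mode mismatch errors", {
  cfg <- small_config()
  px <- simulate_pixel_series(cfg, "corn", seed = 5)
  px$pixel <- 1L

  full <- extract_features(px, "full")
  expect_true(all(feature_names("full") %in% names(full)))
  expect_equal(sum(names(full) %in% feature_names("full")), 27)

  early <- extract_features(px, "early")
  expect_equal(sum(names(early) %in% feature_names("early")), 21)

  # mode mismatch between components is a contract violation
  ev <- evi_series(px)
  fit_f <- fit_double_sigmoid(ev)
  m_f <- derive_pheno_metrics(fit_f)
  ev_e <- ev[ev$doy <= 224, ]
  m_e <- derive_pheno_metrics(fit_double_sigmoid(ev_e, "early"))
  sp_f <- spectral_at_stages(px, m_f)
  expect_error(build_features(m_e, sp_f), "mode mismatch")
})

test_that("index signs agree with their difference counterparts", {
  cfg <- small_config()
  px <- simulate_pixel_series(cfg, "soybean", seed = 9)
  px$pixel <- 1L
  ft <- extract_features(px, "full")
  for (stage in c("avg", "peak")) {
    expect_equal(sign(ft[[paste0("VI64_", stage)]]),
                 sign(ft[[paste0("DIF64_", stage)]]))
    expect_equal(sign(ft[[paste0("NDTI_", stage)]]),
                 sign(ft[[paste0("DIF67_", stage)]]))
  }
})
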