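test_that("landscape proportions realize the configured targets", {
  cfg <- sim_config(seed = 5)
  fine <- simulate_landscape(cfg, cfg$years[1])
  frac <- c(corn = mean(fine == 1L), soybean = mean(fine == 5L),
            other = mean(fine == 0L))
  expect_true(all(abs(frac - cfg$prop) < 0.02))
  # determinism and degenerate proportions
  expect_identical(fine, simulate_landscape(cfg, cfg$years[1]))
  all_corn <- sim_config(seed = 5, prop = c(corn = 1, soybean = 0, other = 0),
                         prop_gradient = 0)
  expect_true(all(simulate_landscape(all_corn, 2012) == 1L))
})

test_that("refitting a noise-free simulated pixel recovers the injected parameters", {
  cfg <- small_config(evi_noise_sd = 0, band_noise_sd = 0, missing_rate = 0)
  for (cls in c("corn", "soybean")) {
    px <- simulate_pixel_series(cfg, cls, seed = 31)
    fit <- fit_double_sigmoid(evi_series(px))
    truth <- attr(px, "params")
    err <- abs(fit$par[names(truth)] - truth)
    expect_lt(max(err[c("D_i", "D_d")]), 0.5)
    expect_lt(max(err[c("V_b", "V_a", "p", "q")]), 0.01)
  }
})

test_that("the aseasonal class fits with amplitude below the crop range", {
  cfg <- small_config(evi_noise_sd = 0, band_noise_sd = 0, missing_rate = 0)
  px <- simulate_pixel_series(cfg, "other", seed = 8)
  fit <- fit_double_sigmoid(evi_series(px))
  crop_min <- min(cfg$pheno$V_a[cfg$pheno$class != "other"]) - 0.2
  expect_lt(fit$par["V_a"], crop_min)
})

test_that("composites go bad at roughly the configured rate", {
  cfg <- small_config(missing_rate = 0.1)
  n_bad <- vapply(1:40, function(i) {
    sum(!simulate_pixel_series(cfg, "corn", seed = 1000 + i)$good)
  }, numeric(1))
  expect_gt(mean(n_bad), 3)   # expectation 4.6 of 46
  expect_lt(mean(n_bad), 6.5)
})

test_that("a +5 day phenology shift moves all 50% progress dates by about +5", {
  cfg <- small_config(seed = 41, shifts = c(0, 15, 5), stage_jitter_sd = 0)
  prog <- simulate_progress_table(cfg)
  sd_all <- stage_dates(prog)
  base <- sd_all[sd_all$year == 2012, ]
  plus5 <- sd_all[sd_all$year == 2014, ]
  j <- dplyr::inner_join(base, plus5, by = "item")
  diffs <- j$doy.y - j$doy.x
  expect_true(all(abs(diffs - 5) < 1))
})

test_that("identically configured years have near-zero progress RMSD", {
  cfg <- small_config(seed = 42, shifts = c(0, 0, 0), stage_jitter_sd = 0)
  prog <- simulate_progress_table(cfg)
  sd_all <- stage_dates(prog)
  r <- progress_rmsd(sd_all[sd_all$year == 2012, ], sd_all[sd_all$year == 2013, ])
  expect_lt(r, 0.5)
})

test_that("the scene's coverage is exactly the aggregation of its fine labels", {
  cfg <- small_config(seed = 17)
  sc <- simulate_scene(cfg, cfg$years[1])
  expect_equal(sc$coverage, aggregate_coverage(sc$fine, cfg$factor))
  # every coarse pixel has 46 composites and the series is seed-stable
  expect_equal(nrow(sc$series), nrow(sc$coverage) * 46)
  sc2 <- simulate_scene(cfg, cfg$years[1])
  expect_identical(sc$series, sc2$series)
})

test_that("the simulated stage-date population matches its own progress table", {
  # the 50% date read back from the table should sit near the population mean
  cfg <- small_config(seed = 43, stage_jitter_sd = 0)
  prog <- simulate_progress_table(cfg, years = 2012)
  sd_all <- stage_dates(prog)
  anchors_corn <- c(D_1 = unname(cfg$pheno$D_i[1] - log(2 + sqrt(3)) / cfg$pheno$p[1]))
  emerged <- sd_all$doy[sd_all$item == "corn:emerged"]
  expect_lt(abs(emerged - anchors_corn["D_1"]), 1)
})

test_that("similar-progress selection on generated tables picks the true nearest year", {
  cfg <- small_config(seed = 44, shifts = c(0, 15, 5))
  prog <- simulate_progress_table(cfg)
  sel <- select_training_year(prog, 2014, candidates = c(2012, 2013),
                              strategy = "similar_progress", state = cfg$state)
  expect_equal(sel$selected, 2012)
  expect_lt(sel$table$rmsd[sel$table$candidate == 2012],
            sel$table$rmsd[sel$table$candidate == 2013])
})
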