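test_that("the 50% date interpolates linearly between weekly reports", {
  expect_equal(fifty_percent_date(c(140, 147), c(30, 65)),
               140 + 7 * (50 - 30) / (65 - 30))
  expect_equal(fifty_percent_date(c(140, 147), c(30, 65)), 144)
  # an exact 50 report is returned as-is
  expect_equal(fifty_percent_date(c(140, 147, 154), c(20, 50, 90)), 147)
  # a stage that never reaches 50% is missing
  expect_true(is.na(fifty_percent_date(c(140, 147), c(20, 40))))
})

test_that("back-extrapolation from an early >50 start is clipped to 7 days", {
  # slope 5 %/day: crossing would be 4 days before the first report
  expect_equal(fifty_percent_date(c(140, 147), c(70, 105)), 136)
  # slope 1 %/day: crossing 20 days before gets clipped to 7
  expect_equal(fifty_percent_date(c(140, 147), c(70, 77)), 133)
})

test_that("the 50% date is equivariant under uniform date shifts (property)", {
  set.seed(31)
  for (i in 1:20) {
    doy <- seq(120, 190, by = 7)
    pct <- sort(pmin(cumsum(runif(length(doy), 0, 25)), 100))
    d0 <- fifty_percent_date(doy, pct)
    if (is.na(d0)) next
    delta <- runif(1, -20, 20)
    expect_equal(fifty_percent_date(doy + delta, pct), d0 + delta,
                 tolerance = 1e-9)
  }
})

test_that("progress RMSD matches the closed form and is a semimetric", {
  a <- data.frame(item = c("s1", "s2", "s3"), doy = c(150, 180, 210))
  b <- data.frame(item = c("s1", "s2", "s3"), doy = c(153, 184, 212))
  expect_equal(progress_rmsd(a, b), sqrt(29 / 3))
  expect_equal(progress_rmsd(a, a), 0)
  expect_equal(progress_rmsd(a, b), progress_rmsd(b, a))
  # stages missing on either side are excluded; disjoint stages error
  b2 <- data.frame(item = c("s1", "s4"), doy = c(153, 300))
  expect_equal(progress_rmsd(a, b2), 3)
  expect_error(progress_rmsd(a, data.frame(item = "s9", doy = 100)), "shared")
})

test_that("similar-progress selection takes the RMSD argmin with recency ties", {
  cfg <- small_config(shifts = c(0, 15, 5))
  prog <- simulate_progress_table(cfg)
  sel <- select_training_year(prog, 2014, candidates = c(2012, 2013),
                              strategy = "similar_progress", state = cfg$state)
  expect_equal(sel$selected, 2012)
  expect_equal(sel$table$rmsd[sel$table$selected],
               min(sel$table$rmsd, na.rm = TRUE))
})

test_that("close-year selection takes the prior year, or the next for the first year", {
  sel <- select_training_year(NULL, 2014, candidates = 2008:2013,
                              strategy = "close_year")
  expect_equal(sel$selected, 2013)
  first <- select_training_year(NULL, 2008, candidates = 2009:2014,
                                strategy = "close_year")
  expect_equal(first$selected, 2009)
})

test_that("a state without records falls back to the configured neighbor", {
  cfg <- small_config()
  prog <- simulate_progress_table(cfg)
  expect_error(
    select_training_year(prog, 2014, candidates = c(2012, 2013),
                         strategy = "similar_progress", state = "TX"),
    "fallback"
  )
  sel <- select_training_year(prog, 2014, candidates = c(2012, 2013),
                              strategy = "similar_progress", state = "TX",
                              fallback_state = "IA")
  expect_equal(sel$selected, 2012)
  expect_equal(sel$state, "IA")
})

test_that("selection identifies the truly most similar year on simulated progress", {
  # mapping year shifted +5: the 0-shift year should beat the +15-shift year
  hits <- vapply(1:10, function(s) {
    cfg <- small_config(seed = 700 + s, shifts = c(0, 15, 5))
    prog <- simulate_progress_table(cfg)
    sel <- select_training_year(prog, 2014, candidates = c(2012, 2013),
                                strategy = "similar_progress", state = cfg$state)
    sel$selected == 2012
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
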