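# three well-separated synthetic feature clusters, one per class
make_cluster_features <- function(n_per, sd = 0.02, seed = 1) {
  withr::with_seed(seed, {
    fn <- feature_names("full")
    centers <- c(corn = 1, soybean = 3, other = -1)
    rows <- purrr::map2_dfr(centers, names(centers), function(center, cls) {
      out <- tibble::as_tibble(
        setNames(as.data.frame(matrix(rnorm(n_per * length(fn), center, sd),
                                      n_per, length(fn))), fn)
      )
      out$truth <- cls
      out
    })
    rows$pixel <- seq_len(nrow(rows))
    attr(rows, "season") <- "full"
    rows
  })
}

cluster_targets <- function(features) {
  tibble::tibble(
    pixel = features$pixel,
    corn = ifelse(features$truth == "corn", 100, 0),
    soybean = ifelse(features$truth == "soybean", 100, 0)
  )
}

test_that("the model records the forest parameters and is seed-deterministic", {
  feats <- make_cluster_features(20)
  targ <- cluster_targets(feats)
  mod <- train_classifier(feats, targ, "fuzzy", seed = 7)
  expect_equal(mod$k, 100L)
  expect_equal(mod$m, 1L)
  mod2 <- train_classifier(feats, targ, "fuzzy", seed = 7)
  p1 <- predict_coverage(mod, feats)
  p2 <- predict_coverage(mod2, feats)
  expect_identical(p1$corn, p2$corn)
})

test_that("fuzzy regression separates disjoint clusters with small OOB error", {
  feats <- make_cluster_features(40)
  targ <- cluster_targets(feats)
  mod <- train_classifier(feats, targ, "fuzzy", seed = 2)
  # out-of-bag predictions of each crop's forest against the 0/100 truth
  expect_lt(mean(abs(mod$models$corn$predictions - targ$corn)), 5)
  expect_lt(mean(abs(mod$models$soybean$predictions - targ$soybean)), 5)
  # nearest-centroid oracle on the same set agrees with the forest's calls
  centers <- c(corn = 1, soybean = 3, other = -1)
  fm <- rowMeans(feats[, feature_names("full")])
  centroid_call <- names(centers)[apply(abs(outer(fm, centers, "-")), 1, which.min)]
  pred <- predict_coverage(mod, feats)
  expect_gte(mean((pred$corn > 50) == (centroid_call == "corn")), 0.99)
})

test_that("a pixel identical to a pure training pixel is predicted near its target", {
  feats <- make_cluster_features(30)
  targ <- cluster_targets(feats)
  mod <- train_classifier(feats, targ, "fuzzy", seed = 3)
  pred <- predict_coverage(mod, feats[feats$truth == "corn", ][1, ])
  expect_gte(pred$corn, 95)
})

test_that("joint corn+soybean overflow is rescaled proportionally to 100", {
  # the reconciliation rule itself on raw predictions 70 and 50
  expect_equal(c(70, 50) * 100 / 120, c(58.33333, 41.66667), tolerance = 1e-5)
  # and end-to-end: reconciled predictions always close to a 100 sum
  feats <- make_cluster_features(30)
  targ <- cluster_targets(feats)
  mod <- train_classifier(feats, targ, "fuzzy", seed = 5)
  pred <- predict_coverage(mod, feats)
  expect_true(all(pred$corn + pred$soybean <= 100 + 1e-9))
  expect_true(all(pred$corn >= 0 & pred$corn <= 100))
  expect_equal(pred$corn + pred$soybean + pred$other, rep(100, nrow(pred)))
})

test_that("no-data pixels propagate and partial gaps are median-imputed", {
  feats <- make_cluster_features(30)
  targ <- cluster_targets(feats)
  mod <- train_classifier(feats, targ, "fuzzy", seed = 11)
  probe <- feats[1:3, ]
  fn <- feature_names("full")
  probe[1, fn] <- NA_real_            # all features missing -> no-data
  probe[2, fn[1]] <- NA_real_         # one gap -> imputed, still predicted
  pred <- predict_coverage(mod, probe)
  expect_true(is.na(pred$corn[1]))
  expect_false(is.na(pred$corn[2]))
})

test_that("hard classification errors on an empty class and predicts labels", {
  feats <- make_cluster_features(25)
  labs <- tibble::tibble(
    pixel = feats$pixel,
    label = factor(feats$truth, levels = c("corn", "soybean", "other"))
  )
  no_soy <- labs
  no_soy$label[no_soy$label == "soybean"] <- NA
  expect_error(train_classifier(feats, no_soy, "hard"), "soybean")
  mod <- train_classifier(feats, labs, "hard", seed = 1)
  pred <- predict_coverage(mod, feats)
  expect_equal(as.character(pred$label), feats$truth)
})

test_that("hard and fuzzy agree on the pure pixels of a simulated landscape", {
  cfg <- small_config(seed = 21, field_size = c(16L, 16L))
  sc <- simulate_scene(cfg, cfg$years[1])
  ft <- extract_features(sc$series, "full")
  pure <- select_pure_pixels(sc$coverage, 75)
  pure <- pure[!is.na(pure$label), ]
  strict <- sc$coverage[sc$coverage$corn == 100 | sc$coverage$soybean == 100 |
                          sc$coverage$other == 100, ]
  hard <- train_classifier(ft, pure, "hard", seed = 4)
  fuzzy <- train_classifier(ft, sc$coverage, "fuzzy", seed = 4)
  fh <- predict_coverage(hard, ft)
  ff <- predict_coverage(fuzzy, ft)
  keep <- fh$pixel %in% strict$pixel
  agree <- (ff$corn[keep] > 50) == (as.character(fh$label[keep]) == "corn")
  expect_gte(mean(agree, na.rm = TRUE), 0.95)
})
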