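test_that("temporal profile is unimodal with its peak in the 12-60 s window", {
  m <- rating_model()
  ts <- seq(12, 144, by = 12)
  prof <- temporal_profile(ts, m)
  expect_equal(ts[which.max(prof)], 36)
  expect_true(ts[which.max(prof)] >= 12 && ts[which.max(prof)] <= 60)
  expect_lt(temporal_profile(144, m), temporal_profile(m$peak_time, m))
  # unimodal: increases up to the peak, decreases after
  expect_true(all(diff(prof[ts <= 36]) > 0))
  expect_true(all(diff(prof[ts >= 36]) < 0))
  expect_equal(temporal_profile(0, m), 0)
})

test_that("noiseless ratings equal the rounded deterministic mean", {
  m <- rating_model(coefficients = c(), entity_sd = 0, resid_sd0 = 0,
                    resid_growth = 0, n_raters = 5)
  feats <- data.frame(sequence_id = rep("A", 12),
                      time_s = seq(12, 144, by = 12))
  rt <- simulate_ratings(feats, m, seed = 1)
  expected <- pmin(pmax(round(4 + temporal_profile(feats$time_s, m)), 1), 7)
  expect_equal(rt$aggregates$mean_rating, expected)
  expect_true(all(rt$ratings$rating %in% 1:7))
})

test_that("ratings are integers in 1..7 and aggregates match the rows", {
  m <- rating_model(n_raters = 40)
  feats <- data.frame(sequence_id = rep(c("A", "B"), each = 12),
                      time_s = rep(seq(12, 144, by = 12), 2),
                      skewness = rnorm(24), symmetry_lr = rnorm(24),
                      horizontal_balance = rnorm(24),
                      vertical_balance = rnorm(24), anisotropy = rnorm(24),
                      hue_avg = rnorm(24))
  rt <- simulate_ratings(feats, m, seed = 2)
  expect_true(all(rt$ratings$rating %in% 1:7))
  expect_equal(nrow(rt$ratings), 24 * 40)
  # aggregates are consistent with the long rows
  agg2 <- aggregate(rating ~ sequence_id + time_s, rt$ratings, mean)
  key <- paste(rt$aggregates$sequence_id, rt$aggregates$time_s)
  key2 <- paste(agg2$sequence_id, agg2$time_s)
  expect_equal(rt$aggregates$mean_rating, agg2$rating[match(key, key2)])
  # deterministic given seed
  rt2 <- simulate_ratings(feats, m, seed = 2)
  expect_identical(rt$aggregates, rt2$aggregates)
})

test_that("per-image rating dispersion grows with time", {
  m <- rating_model(n_raters = 500, resid_growth = 0.004)
  feats <- data.frame(sequence_id = rep("A", 12),
                      time_s = seq(12, 144, by = 12))
  rt <- suppressWarnings(simulate_ratings(feats, m, seed = 3))
  sds <- rt$aggregates$sd_rating
  expect_gt(cor(seq_along(sds), sds, method = "spearman"), 0.8)
})

test_that("mean ratings correlate negatively with time at the defaults", {
  m <- rating_model(n_raters = 200)
  feats <- data.frame(sequence_id = rep(c("A", "B", "C"), each = 12),
                      time_s = rep(seq(12, 144, by = 12), 3))
  rt <- suppressWarnings(simulate_ratings(feats, m, seed = 4))
  expect_lt(cor(rt$aggregates$time_s, rt$aggregates$mean_rating,
                method = "spearman"), 0)
})
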