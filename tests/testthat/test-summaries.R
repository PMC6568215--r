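test_that("learning scores are mean reciprocal latencies", {
  expect_equal(learning_scores(list(a = rep(60, 12)))$score, 1 / 60)
  expect_equal(learning_scores(list(a = c(10, 20)))$score, 0.075)
  # many-exits: novel trials 1, 5, 9 excluded leaves 9 trials
  lat <- c(50, rep(10, 3), 50, rep(10, 3), 50, rep(10, 3))
  s <- learning_scores(list(a = lat), exclude_trials = c(1, 5, 9))
  expect_equal(s$score, 0.1)
  expect_error(learning_scores(list(a = c(0, 10))),
               class = "cm_validation_error")
  expect_error(learning_scores(list(a = c(10, 20)),
                               exclude_trials = 1:2),
               class = "cm_validation_error")
  # linear variant stays in [0, 1)
  expect_equal(learning_scores(list(a = rep(60, 4)),
                               method = "linear")$score, 0)
})

test_that("learning scores are antitone in each latency", {
  set.seed(8)
  lat <- runif(12, 5, 59)
  base <- learning_scores(list(a = lat))$score
  for (i in c(1, 6, 12)) {
    worse <- lat
    worse[i] <- min(60, worse[i] + 5)
    expect_lt(learning_scores(list(a = worse))$score, base)
  }
})

test_that("novelty differences subtract the pre-switch trial", {
  lat <- c(30, 20, 15, 10, 40, 30, 20, 12, 45, 30, 20, 10)
  d <- novelty_differences(lat, c(5, 9))
  expect_equal(d, c(30, 33))
  expect_equal(novelty_differences(c(10, 10), 2), 0)
  expect_error(novelty_differences(lat, 1), class = "cm_validation_error")
  expect_error(novelty_differences(lat, 13), class = "cm_validation_error")
})

test_that("simulated exit switches cost time on average", {
  ar <- build_arena()
  coh <- simulate_cohort(make_roster(40), make_schedule("three_exits"),
                         ar, sim_config(), seed = 6, tracks = FALSE)
  tf <- truth_features(coh)
  diffs <- sapply(split(tf, tf$subject_id), function(s) {
    novelty_differences(s$latency_s[order(s$trial_index)], c(5, 9))
  })
  expect_gt(mean(diffs[1, ]), 0)
  expect_gt(mean(diffs[2, ]), 0)
})

test_that("probe zone preference splits TZ and NT dwell", {
  ar <- build_arena()
  hp <- hole_positions(ar)
  inside_tz <- hp[9, ] * (38 / 42.5)  # 4.5 cm from hole 9: inside 6 cm zone
  tz_only <- point_track(matrix(rep(inside_tz, each = 600), 600, 2))
  pr <- probe_zone_preference(tz_only, ar, former_exit = 9)
  expect_equal(pr$tz_pct, 100, tolerance = 1e-6)
  expect_equal(pr$nt_pct, 0)

  center <- point_track(matrix(0, 600, 2) + 0.01)
  pr2 <- probe_zone_preference(center, ar, former_exit = 9)
  expect_equal(pr2$tz_pct, 0)
  expect_equal(pr2$nt_pct, 0)

  # equal dwell in all 12 probe zones: tz equals the per-zone nt mean
  pts <- hp * (38 / 42.5)
  xy <- do.call(rbind, lapply(1:12, function(k)
    matrix(rep(pts[k, ], each = 50), 50, 2)))
  split_tr <- point_track(xy)
  pr3 <- probe_zone_preference(split_tr, ar, former_exit = 9)
  expect_equal(pr3$tz_pct, pr3$nt_pct, tolerance = 2)
  # disjoint probe zones: tz + 11 * nt covers at most the whole trial
  expect_lte(pr3$tz_pct + 11 * pr3$nt_pct, 100 + 1e-6)
  expect_error(probe_zone_preference(split_tr, ar),
               class = "cm_validation_error")
})

test_that("EPM ratio follows its closed form and antisymmetry", {
  expect_equal(epm_ratio(150, 150), 0)
  expect_equal(epm_ratio(300, 0), 1)
  expect_equal(epm_ratio(200, 100), 1 / 3)
  expect_equal(epm_ratio(100, 200), -epm_ratio(200, 100))
  expect_error(epm_ratio(0, 0), class = "cm_validation_error")
  expect_error(epm_ratio(-1, 10), class = "cm_validation_error")
})

test_that("spearman_rho handles ties like the mid-rank oracle", {
  expect_equal(spearman_rho(1:10, (1:10)^3), 1)
  expect_equal(spearman_rho(1:10, 10:1), -1)
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  y <- c(2, 7, 1, 8, 2, 8, 1, 8, 2, 8)
  # independent oracle: base R's tie-aware Spearman on the same fixture
  expect_equal(spearman_rho(x, y),
               suppressWarnings(cor(x, y, method = "spearman")),
               tolerance = 1e-12)
  # frozen value computed from the mid-rank oracle
  expect_equal(spearman_rho(x, y), 0.1347150628, tolerance = 1e-9)
  expect_true(is.na(spearman_rho(rep(1, 5), 1:5)))
  expect_error(spearman_rho(1:5, 1:4), class = "cm_validation_error")
})

test_that("spearman_rho is invariant under monotone transforms", {
  set.seed(12)
  x <- rnorm(50)
  y <- rnorm(50)
  base <- spearman_rho(x, y)
  expect_equal(spearman_rho(exp(x), y), base)
  expect_equal(spearman_rho(x, 3 * y - 7), base)
})

test_that("ensemble bands interpolate order statistics", {
  m <- matrix(rep(c(10, 20, 30), each = 5), 5, 3)
  b <- ensemble_band(m)
  expect_equal(b$mean, c(10, 20, 30))
  expect_equal(b$lower, b$mean)   # identical subjects collapse the band
  expect_equal(b$upper, b$mean)
  one <- ensemble_band(matrix(c(5, 6), 1, 2))
  expect_equal(one$lower, one$mean)

  set.seed(4)
  m20 <- matrix(runif(20 * 3, 1, 60), 20, 3)
  b20 <- ensemble_band(m20, lower_pct = 5, upper_pct = 95)
  for (j in 1:3) {
    srt <- sort(m20[, j])
    h <- (20 - 1) * 0.05 + 1       # linear interpolation between order stats
    lo <- srt[floor(h)] + (h - floor(h)) * (srt[ceiling(h)] - srt[floor(h)])
    expect_equal(b20$lower[j], lo, tolerance = 1e-12)
    expect_true(b20$lower[j] <= b20$mean[j] && b20$mean[j] <= b20$upper[j])
  }
})

test_that("temperature-latency fits recover the generative slope", {
  lat <- seq(5, 55, length.out = 30)
  fit <- temp_latency_fit(lat, -0.05 * lat)
  expect_equal(fit$rho, -1)
  expect_equal(fit$coefficients[2], -0.05, tolerance = 1e-9)

  set.seed(10)
  null <- temp_latency_fit(runif(200, 1, 60), rnorm(200))
  expect_lt(abs(null$rho), 0.3)

  # simulator default PPT noise: strong inverse relation
  cfg <- sim_config()
  lat2 <- runif(200, 5, 60)
  dT <- temperature_model(lat2, "PPT", cfg)
  fit2 <- temp_latency_fit(lat2, dT)
  expect_lt(fit2$rho, -0.6)
  expect_true(is.na(temp_latency_fit(rep(30, 5), rnorm(5))$rho))
})
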