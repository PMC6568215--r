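# Fixtures are built analytically; the inspection detector is also checked
# against the literal per-frame oracle from helper-fixtures.R.

arena <- build_arena()
hp <- hole_positions(arena)

# piecewise-linear point track through waypoints with optional dwells
path_track <- function(pts, dwell_s = rep(0, nrow(pts)), speed = 20,
                       dt = 1 / 30) {
  xy <- pts[1, , drop = FALSE]
  for (i in 2:nrow(pts)) {
    d <- sqrt(sum((pts[i, ] - pts[i - 1, ])^2))
    n <- max(1, round(d / (speed * dt)))
    s <- seq_len(n) / n
    xy <- rbind(xy, cbind(pts[i - 1, 1] + s * (pts[i, 1] - pts[i - 1, 1]),
                          pts[i - 1, 2] + s * (pts[i, 2] - pts[i - 1, 2])))
    nd <- round(dwell_s[i] / dt)
    if (nd > 0) xy <- rbind(xy, matrix(rep(pts[i, ], each = nd), nd, 2))
  }
  point_track(xy, dt = dt)
}

test_that("inspections: two decoy visits then escape give two errors", {
  pts <- rbind(c(0, 0), hp[2, ], hp[3, ], hp[9, ])
  tr <- path_track(pts, dwell_s = c(0, 0.3, 0.3, 0.3))
  ev <- detect_inspections(tr, arena, true_exit = 9)
  expect_equal(ev$hole, c(2L, 3L, 9L))
  expect_equal(ev$is_true_exit, c(FALSE, FALSE, TRUE))
  expect_true(all(ev$t_off >= ev$t_on + 0.1))
  # matches the per-frame oracle
  orc <- oracle_inspections(tr, arena, 9)
  expect_equal(ev$hole, orc$hole)
  expect_equal(ev$t_on, orc$t_on, tolerance = 1e-9)
  expect_equal(ev$t_off, orc$t_off, tolerance = 1e-9)
})

test_that("a single-frame graze is debounced away", {
  far <- c(0, 0)
  xy <- rbind(matrix(rep(far, each = 10), 10, 2), hp[5, ],
              matrix(rep(far, each = 10), 10, 2))
  tr <- point_track(xy)
  expect_equal(nrow(detect_inspections(tr, arena, 9)), 0L)
})

test_that("re-entry after leaving the dilated zone re-arms the decoy", {
  inside <- hp[5, ] * (1 - 0.001)          # within the 2 cm zone
  nearby <- hp[5, ] * (40.5 / 42.5)        # 2 cm away: inside dilated 3 cm
  outside <- hp[5, ] * (37 / 42.5)         # 5.5 cm away: re-arms
  dwell <- function(p, n) matrix(rep(p, each = n), n, 2)
  xy <- rbind(dwell(c(0, 0), 5), dwell(inside, 10), dwell(nearby, 5),
              dwell(inside, 10), dwell(outside, 5), dwell(inside, 10),
              dwell(c(0, 0), 5))
  tr <- point_track(xy)
  ev <- detect_inspections(tr, arena, true_exit = 9)
  expect_equal(nrow(ev), 2L)               # bounce within dilated zone merged
  expect_true(all(ev$hole == 5L))
  orc <- oracle_inspections(tr, arena, 9)
  expect_equal(ev$t_on, orc$t_on, tolerance = 1e-9)
})

test_that("detector equals the per-frame oracle on random walks", {
  set.seed(42)
  for (i in 1:20) {
    tr <- random_walk_track(duration_s = 6)
    ev <- detect_inspections(tr, arena, true_exit = 9)
    orc <- oracle_inspections(tr, arena, 9)
    expect_equal(nrow(ev), nrow(orc))
    if (nrow(ev)) {
      expect_equal(ev$hole, orc$hole)
      expect_equal(ev$t_on, orc$t_on, tolerance = 1e-9)
      expect_equal(ev$t_off, orc$t_off, tolerance = 1e-9)
    }
  }
})

test_that("straight run to hole 3: latency, distance and zero errors", {
  tr <- straight_track(c(0, 0), c(40.5, 0), speed = 10)
  tri <- trial_record("S1", trial_index = 1, true_exit_hole = 3)
  m <- compute_trial_metrics(tr, tri, arena)
  expect_true(m$escaped)
  expect_equal(m$latency_s, 4.05, tolerance = 1e-6)
  expect_equal(m$n_errors, 0L)
  expect_equal(m$distance_cm, 40.5, tolerance = 1e-6)
  expect_equal(m$mean_speed_cm_s, 10, tolerance = 1e-6)
  expect_equal(m$heading_to_exit_deg, 0, tolerance = 1e-6)
})

test_that("a 60 s track that never escapes is censored at the cutoff", {
  set.seed(1)
  n <- 1801L
  jit <- matrix(runif(2 * n, -0.02, 0.02), n, 2)  # sub-threshold jitter
  tr <- point_track(jit)
  tri <- trial_record("S1", trial_index = 1, true_exit_hole = 9)
  m <- compute_trial_metrics(tr, tri, arena)
  expect_false(m$escaped)
  expect_equal(m$latency_s, 60)
  expect_equal(m$distance_cm, 0)
  expect_equal(m$mean_speed_cm_s, 0)
})

test_that("a truncated escape track is rejected as malformed", {
  tr <- straight_track(c(0, 0), c(10, 0), speed = 10)  # ends mid-arena
  tri <- trial_record("S1", trial_index = 1, true_exit_hole = 3)
  expect_error(compute_trial_metrics(tr, tri, arena), "malformed",
               class = "cm_validation_error")
})

test_that("probe trials are censored with no error count", {
  xy <- matrix(rep(c(5, 5), each = 1801), 1801, 2)
  tr <- point_track(xy)
  tri <- trial_record("S1", trial_index = 13, true_exit_hole = 9,
                      probe = TRUE)
  m <- compute_trial_metrics(tr, tri, arena)
  expect_false(m$escaped)
  expect_equal(m$latency_s, 60)
  expect_null(m$n_errors)
})

test_that("path_length follows the dead-band rule", {
  expect_equal(path_length(point_track(rbind(c(0, 0), c(3, 0), c(6, 0)))), 6)
  expect_equal(path_length(point_track(rbind(c(0, 0), c(5, 0), c(0, 0)))), 10)
  # noisy straight path: dead-band matched to the noise scale (10 sigma)
  set.seed(9)
  true_xy <- cbind(seq(0, 60, by = 10 / 30), 0)   # 60 cm at 10 cm/s, 30 Hz
  noisy <- true_xy + matrix(rnorm(2 * nrow(true_xy), 0, 0.1),
                            nrow(true_xy), 2)
  est <- path_length(point_track(noisy), jitter_cm = 1.0)
  expect_lt(abs(est - 60) / 60, 0.05)
})

test_that("rotation counting follows the unwrap-and-reset rule", {
  spin_track <- function(theta_deg) {
    g <- cbind(cos(theta_deg * pi / 180), sin(theta_deg * pi / 180))
    ctr <- matrix(0, length(theta_deg), 2)
    track((seq_along(theta_deg) - 1) / 30, ctr + 4 * g, ctr, ctr - 4 * g)
  }
  expect_equal(count_rotations(spin_track(seq(0, 750, by = 5))), 2L)
  expect_equal(count_rotations(spin_track(90 * sin(seq(0, 6 * pi,
                                                       length.out = 300)))),
               0L)
  cw_ccw <- c(seq(0, -360, by = -5), seq(-355, 0, by = 5))
  expect_equal(count_rotations(spin_track(cw_ccw)), 2L)
  expect_error(count_rotations(track(1:10 / 30, NULL,
                                     matrix(rnorm(20), 10, 2), NULL)),
               class = "cm_capability_error")
})

test_that("meander counts sign reversals of significant turns", {
  straight <- straight_track(c(0, 0), c(30, 0), speed = 10)
  expect_equal(meander_count(straight), 0L)
  # staircase zigzag (alternating +90/-90 corners):
  # s straight runs -> s - 1 corners -> s - 2 sign reversals
  s_runs <- 7
  pts <- matrix(0, s_runs + 1, 2)
  for (i in 2:(s_runs + 1)) {
    pts[i, ] <- pts[i - 1, ] + if (i %% 2 == 0) c(8, 0) else c(0, 8)
  }
  zig <- path_track(pts, speed = 15)
  expect_equal(meander_count(zig, smooth_window = 1), s_runs - 2L)
  # smooth arc with per-step turns under the threshold
  th <- seq(0, pi, length.out = 400)
  arc <- point_track(cbind(20 * cos(th), 20 * sin(th)))
  expect_equal(meander_count(arc), 0L)
})

test_that("heading_to_exit matches the per-step oracle", {
  tr <- straight_track(c(0, 0), c(40.5, 0), speed = 10)
  expect_equal(heading_to_exit(tr, c(42.5, 0)), 0, tolerance = 1e-9)
  away <- straight_track(c(0, 0), c(-40, 0), speed = 10)
  expect_equal(heading_to_exit(away, c(42.5, 0)), 180, tolerance = 1e-9)
  # concentric circle, exit on the wall: brute-force per-step computation
  th <- seq(0, 2 * pi, length.out = 500)[-500]
  circ <- point_track(cbind(20 * cos(th), 20 * sin(th)))
  got <- heading_to_exit(circ, c(42.5, 0), speed_floor_cm_s = 0)
  p <- circ$center
  want <- mean(sapply(seq_len(nrow(p) - 1), function(i) {
    mv <- atan2(p[i + 1, 2] - p[i, 2], p[i + 1, 1] - p[i, 1])
    tg <- atan2(0 - p[i, 2], 42.5 - p[i, 1])
    d <- abs((mv - tg) * 180 / pi) %% 360
    min(d, 360 - d)
  }))
  expect_equal(got, want, tolerance = 1e-9)
  stationary <- point_track(matrix(0.001 * rnorm(20), 10, 2))
  expect_true(is.na(heading_to_exit(stationary, c(42.5, 0))))
})

test_that("zone dwell accumulates sample intervals per zone", {
  th <- seq(0, 2 * pi, length.out = 1801)
  peri <- point_track(cbind(38.5 * cos(th), 38.5 * sin(th)))
  dw <- zone_dwell_times(peri, arena$zones$periphery)
  expect_equal(unname(dw), 60, tolerance = 1e-6)

  ctr <- point_track(matrix(0, 100, 2) + 0.001)
  hole_dw <- zone_dwell_times(ctr, arena$zones[grepl("^hole_",
                                                     names(arena$zones))])
  expect_true(all(hole_dw == 0))

  # half in NE quadrant, half in SW
  xy <- rbind(matrix(rep(c(10, 10), each = 450), 450, 2),
              matrix(rep(c(-10, -10), each = 450), 450, 2))
  half <- point_track(xy)
  qd <- zone_dwell_times(half, arena$zones[c("quadrant_NE", "quadrant_SW")])
  dur <- 899 / 30
  expect_lt(abs(qd[["quadrant_NE"]] - dur / 2), 1 / 30 + 1e-9)
  expect_lt(abs(qd[["quadrant_SW"]] - dur / 2), 1 / 30 + 1e-9)
})

test_that("occupancy maps conserve trial duration", {
  still <- point_track(matrix(rep(c(3.2, -7.8), each = 90), 90, 2))
  om <- occupancy_map(still, bin_cm = 1, radius_cm = 42.5)
  expect_equal(sum(om$grid > 0), 1L)
  expect_equal(sum(om$grid), track_dur <- 89 / 30, tolerance = 1e-9)

  xy <- matrix(rep(c(0.5, 0.5, 10.5, 0.5), 300), ncol = 2, byrow = TRUE)
  alt <- point_track(xy)
  om2 <- occupancy_map(alt, bin_cm = 1, radius_cm = 42.5)
  expect_equal(sum(om2$grid > 0), 2L)
  expect_equal(max(om2$grid) - min(om2$grid[om2$grid > 0]), 1 / 30,
               tolerance = 1e-9)

  set.seed(3)
  for (i in 1:5) {
    tr <- random_walk_track(duration_s = runif(1, 2, 8))
    om3 <- occupancy_map(tr, bin_cm = 1, radius_cm = 42.5)
    expect_lt(abs(sum(om3$grid) - track_duration(tr)), 1 / 30 + 1e-9)
  }
  expect_error(occupancy_map(still, bin_cm = 0), class = "cm_validation_error")
})

test_that("occupancy maps are additive over concatenated trials", {
  set.seed(21)
  trs <- lapply(1:10, function(i) random_walk_track(duration_s = 3))
  maps <- lapply(trs, occupancy_map, bin_cm = 2, radius_cm = 42.5)
  total <- Reduce(`+`, lapply(maps, `[[`, "grid"))
  dt <- 1 / 30
  cat_xy <- do.call(rbind, lapply(trs, `[[`, "center"))
  cat_tr <- point_track(cat_xy, dt = dt)
  cat_map <- occupancy_map(cat_tr, bin_cm = 2, radius_cm = 42.5)
  # junction samples carry one extra interval each (9 junctions)
  expect_lt(max(abs(cat_map$grid - total)), 9 * dt + 1e-9)
  expect_equal(sum(cat_map$grid) - sum(total), 9 * dt, tolerance = 1e-9)
})

test_that("occupancy files carry the 3-line header", {
  om <- occupancy_map(random_walk_track(2), bin_cm = 5, radius_cm = 42.5)
  f <- tempfile()
  write_occupancy(om, f)
  hdr <- readLines(f, n = 3)
  expect_match(hdr[1], "^# bin_cm")
  expect_match(hdr[3], "^# duration_s")
})

test_that("metric invariants hold on simulated trials", {
  cfg <- sim_config()
  set.seed(99)
  tri <- function(i, ex) trial_record("S1", trial_index = i,
                                      true_exit_hole = ex)
  for (i in 1:12) {
    pol <- c("spatial", "chain", "futile")[(i %% 3) + 1]
    sim <- simulate_trial(pol, arena, tri(i, 9), cfg)
    m <- compute_trial_metrics(sim$track, tri(i, 9), arena)
    expect_identical(m$escaped, m$latency_s < 60)
    disp <- sqrt(sum((sim$track$center[nrow(sim$track$center), ] -
                      sim$track$center[1, ])^2))
    expect_gte(m$distance_cm, disp - 0.05)
    expect_lte(m$periphery_s, m$duration_s + 1e-9)
    expect_true(m$heading_to_exit_deg >= 0 && m$heading_to_exit_deg <= 180)
    expect_true(all(m$zone_dwell <= m$duration_s + 1e-9))
  }
})
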