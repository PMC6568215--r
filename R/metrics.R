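# Per-trial trajectory metrics: decoy-inspection (error) events, escape
# latency, path length, rotations, meander, heading-to-exit, zone dwell and
# occupancy maps.

#' Detect hole-inspection events
#'
#' An inspection ("error" when at a decoy) opens once the nose stays inside a
#' hole zone continuously for at least `debounce_s`; the event then closes and
#' the zone re-arms only after the nose has left the zone dilated by
#' `rearm_factor`, so tracking jitter at the zone edge cannot split one
#' inspection into many.
#'
#' @param track A `cm_track` with nose coordinates.
#' @param arena A clockmaze `cm_arena`.
#' @param true_exit Hole index of the open exit (events there are flagged
#'   `is_true_exit`, not errors), or `NA` (probe).
#' @param debounce_s Minimum continuous in-zone time to open an event (s).
#' @param rearm_factor Zone dilation factor that must be exited to re-arm.
#' @return `data.table` with columns `zone_name`, `hole`, `t_on`, `t_off`,
#'   `is_true_exit`, ordered by `t_on`.
#' @export
detect_inspections <- function(track, arena, true_exit = NA,
                               debounce_s = 0.1, rearm_factor = 1.5) {
  stopifnot(inherits(track, "cm_track"), inherits(arena, "cm_arena"))
  if (track$degraded || is.null(track$nose))
    stop_capability("inspection detection needs nose coordinates (degraded track)")
  if (arena$config$variant != "clockmaze")
    stop_capability("inspection detection is defined for the clockmaze variant")
  t <- track$t - track$t[1]
  nose <- track$nose
  r_in <- arena$config$hole_zone_radius_cm
  r_dil <- r_in * rearm_factor
  out <- vector("list", arena$config$n_holes)
  for (k in seq_len(arena$config$n_holes)) {
    ctr <- arena$hole_centers[k, ]
    d2 <- (nose[, 1] - ctr[1])^2 + (nose[, 2] - ctr[2])^2
    inz <- d2 <= r_in^2 + 1e-12
    if (!any(inz)) next
    dil <- d2 <= r_dil^2 + 1e-12
    ev <- zone_events(t, inz, dil, debounce_s)
    if (nrow(ev)) {
      ev$zone_name <- sprintf("hole_%02d", k)
      ev$hole <- k
      out[[k]] <- ev
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.table::data.table(zone_name = character(0), hole = integer(0),
                                  t_on = numeric(0), t_off = numeric(0),
                                  is_true_exit = logical(0)))
  ev <- data.table::rbindlist(out)
  ev$is_true_exit <- !is.na(true_exit) & ev$hole == true_exit
  data.table::setcolorder(ev, c("zone_name", "hole", "t_on", "t_off",
                                "is_true_exit"))
  ev[order(ev$t_on), ]
}

# Run-length state machine for a single zone. `inz` implies `dil`.
zone_events <- function(t, inz, dil, debounce_s) {
  r <- rle(inz)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs_in <- which(r$values)
  t_on <- numeric(0); t_off <- numeric(0)
  open_end <- NA_integer_  # last sample index of the run that fired
  for (ri in runs_in) {
    a <- starts[ri]; b <- ends[ri]
    if (!is.na(open_end)) {
      # triggered: find first frame after the firing run that left the
      # dilated zone; the zone is re-armed from there on
      q <- which(!dil[(open_end + 1L):length(t)])
      q <- if (length(q)) open_end + q[1L] else NA_integer_
      if (is.na(q) || q > a) next  # still within the dilated period
      t_off <- c(t_off, t[q])
      open_end <- NA_integer_
    }
    if (t[b] - t[a] >= debounce_s - 1e-9) {
      t_on <- c(t_on, t[a])
      open_end <- b
    }
  }
  if (!is.na(open_end)) {
    q <- which(!dil[(open_end + 1L):length(t)])
    t_off <- c(t_off,
               if (length(q)) t[open_end + q[1L]] else t[length(t)])
  }
  data.table::data.table(t_on = t_on, t_off = t_off)
}

#' Path length with a jitter dead-band
#'
#' Distance accrues only when the body center has moved at least `jitter_cm`
#' away from the last counted position (an anchor rule), so sub-threshold
#' tracking jitter around a stationary animal contributes zero distance. For
#' noisy tracks the dead-band should be matched to the noise scale (about ten
#' times the per-axis jitter SD keeps the bias under a few percent).
#'
#' @param track A `cm_track`.
#' @param jitter_cm Dead-band radius (cm).
#' @return Total path length (cm).
#' @export
path_length <- function(track, jitter_cm = 0.05) {
  stopifnot(inherits(track, "cm_track"))
  p <- track$center
  n <- nrow(p)
  total <- 0
  ax <- p[1, 1]; ay <- p[1, 2]
  thr2 <- jitter_cm^2
  for (i in 2:n) {
    dx <- p[i, 1] - ax; dy <- p[i, 2] - ay
    d2 <- dx * dx + dy * dy
    if (d2 >= thr2) {
      total <- total + sqrt(d2)
      ax <- p[i, 1]; ay <- p[i, 2]
    }
  }
  unname(total)
}

#' Count full-body rotations
#'
#' The body axis (nose minus tail base) heading is unwrapped over time;
#' every completed 360 degree excursion in either direction counts once,
#' after which the reference resets, so edge jitter far below
#' `hysteresis_deg` can never double-count an excursion.
#'
#' @param track A `cm_track` with nose and tail coordinates.
#' @param hysteresis_deg Guard band documented for edge jitter (degrees).
#' @return Total number of completed clockwise plus counterclockwise
#'   rotations.
#' @export
count_rotations <- function(track, hysteresis_deg = 45) {
  stopifnot(inherits(track, "cm_track"))
  if (track$degraded)
    stop_capability("rotation counting needs nose and tail coordinates")
  axis <- track$nose - track$tail
  ok <- rowSums(abs(axis)) > 1e-9
  if (sum(ok) < 2L) return(0L)
  h <- rad2deg(atan2(axis[ok, 2], axis[ok, 1]))
  unwrapped <- cumsum(c(h[1], ang_diff(h[-1], h[-length(h)])))
  count <- 0L
  ref <- unwrapped[1]
  for (v in unwrapped[-1]) {
    if (abs(v - ref) >= 360 - 1e-9) {
      count <- count + 1L
      ref <- v
    }
  }
  count
}

#' Count meander turns (direction changes)
#'
#' The center path is smoothed with a centered moving average, per-step
#' turning angles are computed for steps moving at least `speed_floor_cm_s`,
#' and a direction change is counted at every sign reversal between
#' consecutive significant turns (both flanking turns exceeding
#' `turn_threshold_deg`; sub-threshold wobble in between is ignored, since
#' smoothing spreads a sharp corner over several small steps).
#'
#' @param track A `cm_track`.
#' @param smooth_window Moving-average window (samples).
#' @param turn_threshold_deg Minimum turn magnitude on both sides of a
#'   reversal (degrees).
#' @param speed_floor_cm_s Steps slower than this are ignored (cm/s).
#' @return Number of direction changes.
#' @export
meander_count <- function(track, smooth_window = 5, turn_threshold_deg = 20,
                          speed_floor_cm_s = 2) {
  stopifnot(inherits(track, "cm_track"))
  n <- nrow(track$center)
  if (n < smooth_window) stop_validation("track shorter than smooth_window")
  x <- moving_average(track$center[, 1], smooth_window)
  y <- moving_average(track$center[, 2], smooth_window)
  dt <- diff(track$t)
  vx <- diff(x); vy <- diff(y)
  speed <- sqrt(vx^2 + vy^2) / dt
  keep <- speed >= speed_floor_cm_s
  if (sum(keep) < 3L) return(0L)
  ang <- rad2deg(atan2(vy[keep], vx[keep]))
  turn <- ang_diff(ang[-1], ang[-length(ang)])
  sig <- turn[abs(turn) > turn_threshold_deg]
  if (length(sig) < 2L) return(0L)
  s <- sign(sig)
  sum(s[-length(s)] * s[-1] < 0)
}

#' Mean absolute heading error toward the exit
#'
#' For every moving step, the absolute angle between the movement vector and
#' the vector from the current position to `exit_center`, averaged; 0 degrees
#' is a dead-straight run at the exit, 180 a run directly away.
#'
#' @param track A `cm_track`.
#' @param exit_center Numeric (x, y) of the target, cm.
#' @param speed_floor_cm_s Steps slower than this are ignored (cm/s).
#' @return Mean angle in `[0, 180]` degrees, or `NA` if nothing moved.
#' @export
heading_to_exit <- function(track, exit_center, speed_floor_cm_s = 2) {
  stopifnot(inherits(track, "cm_track"))
  p <- track$center
  dt <- diff(track$t)
  vx <- diff(p[, 1]); vy <- diff(p[, 2])
  speed <- sqrt(vx^2 + vy^2) / dt
  keep <- speed >= speed_floor_cm_s
  if (!any(keep)) return(NA_real_)
  mv <- rad2deg(atan2(vy[keep], vx[keep]))
  tx <- exit_center[1] - p[which(keep), 1]
  ty <- exit_center[2] - p[which(keep), 2]
  tg <- rad2deg(atan2(ty, tx))
  mean(abs(ang_diff(mv, tg)))
}

#' Zone dwell times
#'
#' Each sample contributes its forward inter-sample interval to every zone
#' containing it. Hole-like zones (kinds `hole`, `target`, `nontarget`) are
#' scored on the nose when available, all other zones on the body center.
#'
#' @param track A `cm_track`.
#' @param zones A list of `cm_zone` (or a single zone).
#' @return Named numeric vector of dwell seconds.
#' @export
zone_dwell_times <- function(track, zones) {
  stopifnot(inherits(track, "cm_track"))
  if (inherits(zones, "cm_zone")) zones <- list(zones)
  w <- diff(track$t)
  n <- length(track$t)
  out <- numeric(length(zones))
  nm <- character(length(zones))
  for (i in seq_along(zones)) {
    z <- zones[[i]]
    pts <- if (z$kind %in% c("hole", "target", "nontarget") &&
               !is.null(track$nose)) track$nose else track$center
    inz <- point_in_zone(pts[-n, , drop = FALSE], z)
    out[i] <- sum(w[inz])
    nm[i] <- z$name
  }
  stats::setNames(out, nm)
}

#' Occupancy heatmap
#'
#' Square grid of dwell seconds over `[-R, R]^2`; each sample deposits its
#' forward inter-sample interval into the bin holding the body center, so the
#' grid total equals the trial duration.
#'
#' @param track A `cm_track`.
#' @param bin_cm Bin side length (cm).
#' @param radius_cm Half-extent `R` of the grid; defaults to the smallest
#'   whole-bin radius covering the track.
#' @return Object of class `cm_occupancy`: list with `grid` (seconds),
#'   `bin_cm`, `origin` (coordinate of the lower-left grid corner) and
#'   `duration_s`.
#' @export
occupancy_map <- function(track, bin_cm = 1.0, radius_cm = NULL) {
  stopifnot(inherits(track, "cm_track"))
  if (!is.finite(bin_cm) || bin_cm <= 0)
    stop_validation("bin_cm must be > 0, got %s", bin_cm)
  p <- track$center
  if (is.null(radius_cm))
    radius_cm <- bin_cm * ceiling((max(abs(p)) + 1e-9) / bin_cm)
  nb <- as.integer(ceiling(2 * radius_cm / bin_cm))
  w <- diff(track$t)
  ix <- pmin(pmax(floor((p[-nrow(p), 1] + radius_cm) / bin_cm), 0), nb - 1L) + 1L
  iy <- pmin(pmax(floor((p[-nrow(p), 2] + radius_cm) / bin_cm), 0), nb - 1L) + 1L
  grid <- matrix(0, nb, nb)
  idx <- (iy - 1L) * nb + ix
  acc <- rowsum(w, idx)
  grid[as.integer(rownames(acc))] <- acc[, 1]
  structure(list(grid = grid, bin_cm = bin_cm, origin = c(-radius_cm, -radius_cm),
                 duration_s = track_duration(track)),
            class = "cm_occupancy")
}

#' Write an occupancy map as a delimited grid with a 3-line header
#' @param map A `cm_occupancy`.
#' @param path Output path.
#' @export
write_occupancy <- function(map, path) {
  stopifnot(inherits(map, "cm_occupancy"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# bin_cm %.6f", map$bin_cm),
               sprintf("# origin %.6f %.6f", map$origin[1], map$origin[2]),
               sprintf("# duration_s %.6f", map$duration_s)), con)
  utils::write.table(map$grid, con, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Compute the full per-trial metric set
#'
#' Orchestrates the individual metric operations. Termination rule: a track
#' that ends before the cutoff must end with the nose inside the true-exit
#' zone (the animal left through the pipe) and its latency is the final
#' timestamp; tracks reaching the cutoff are censored at `cutoff_s`
#' (`escaped = FALSE` if and only if `latency_s == cutoff_s`). Samples beyond
#' the cutoff (experimenter-guided escapes) are truncated before analysis.
#' Probe trials are censored by definition and carry no error count.
#'
#' @param track A `cm_track`.
#' @param trial A [trial_record()].
#' @param arena A `cm_arena`.
#' @param params Optional named list overriding metric defaults
#'   (`debounce_s`, `rearm_factor`, `jitter_cm`, `smooth_window`,
#'   `turn_threshold_deg`, `speed_floor_cm_s`, `hysteresis_deg`).
#' @return Object of class `cm_trial_metrics`.
#' @export
compute_trial_metrics <- function(track, trial, arena, params = list()) {
  stopifnot(inherits(track, "cm_track"), inherits(trial, "cm_trial"),
            inherits(arena, "cm_arena"))
  p <- utils::modifyList(list(debounce_s = 0.1, rearm_factor = 1.5,
                              jitter_cm = 0.05, smooth_window = 5,
                              turn_threshold_deg = 20, speed_floor_cm_s = 2,
                              hysteresis_deg = 45), params)
  cutoff <- trial$cutoff_s
  t0 <- track$t - track$t[1]
  keep <- t0 <= cutoff + 1e-9
  if (sum(keep) < 2L)
    stop_validation("track has fewer than 2 samples before the cutoff")
  sub <- function(m) if (is.null(m)) NULL else m[keep, , drop = FALSE]
  tr <- track(t0[keep], sub(track$nose), sub(track$center), sub(track$tail),
              rate_hz = track$rate_hz)
  duration <- track_duration(tr)
  dt_typ <- stats::median(diff(tr$t))
  watermaze <- arena$config$variant == "watermaze"

  exit_zone <- NULL
  exit_center <- NULL
  if (watermaze) {
    exit_zone <- arena$zones$platform
    exit_center <- arena$config$platform_center
  } else if (!is.na(trial$true_exit_hole)) {
    exit_zone <- arena$zones[[sprintf("hole_%02d", trial$true_exit_hole)]]
    exit_center <- arena$hole_centers[trial$true_exit_hole, ]
  }

  if (trial$probe) {
    escaped <- FALSE
    latency <- cutoff
  } else if (duration >= cutoff - 1.5 * dt_typ) {
    escaped <- FALSE
    latency <- cutoff
  } else {
    endpoint <- if (watermaze || is.null(tr$nose)) {
      tr$center[nrow(tr$center), ]
    } else {
      tr$nose[nrow(tr$nose), ]
    }
    if (is.null(exit_zone) || !point_in_zone(endpoint, exit_zone))
      stop_validation(
        "malformed trial: track ends at %.2f s (< cutoff) outside the exit zone",
        duration)
    escaped <- TRUE
    latency <- duration
  }

  n_errors <- NULL
  events <- NULL
  if (!trial$probe && !watermaze) {
    events <- detect_inspections(tr, arena, trial$true_exit_hole,
                                 debounce_s = p$debounce_s,
                                 rearm_factor = p$rearm_factor)
    esc_t <- if (escaped) latency else cutoff
    n_errors <- sum(!events$is_true_exit & events$t_on < esc_t)
  }

  distance <- path_length(tr, jitter_cm = p$jitter_cm)
  rotations <- if (tr$degraded) NA_integer_ else
    count_rotations(tr, hysteresis_deg = p$hysteresis_deg)
  meander <- meander_count(tr, smooth_window = p$smooth_window,
                           turn_threshold_deg = p$turn_threshold_deg,
                           speed_floor_cm_s = p$speed_floor_cm_s)
  heading <- if (is.null(exit_center)) NA_real_ else
    heading_to_exit(tr, exit_center, speed_floor_cm_s = p$speed_floor_cm_s)
  dwell <- zone_dwell_times(tr, arena$zones)

  structure(list(
    escaped = escaped,
    latency_s = latency,
    n_errors = if (is.null(n_errors)) NULL else as.integer(n_errors),
    distance_cm = distance,
    mean_speed_cm_s = distance / latency,
    rotations = rotations,
    meander_turns = meander,
    heading_to_exit_deg = heading,
    periphery_s = unname(dwell["periphery"]),
    zone_dwell = dwell,
    events = events,
    duration_s = duration), class = "cm_trial_metrics")
}
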