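# Agent-based synthetic cohort generator. Trajectories are assembled from
# parameterized segments (straight legs with lateral OU-style wiggle,
# wall-following arcs, hole dwells) sampled at the tracking rate, under three
# movement policies:
#   spatial - steer to the true exit, optionally inspecting up to 3 nearby
#             decoys on the way;
#   chain   - head to the wall at a random bearing, then wall-follow in one
#             direction dwelling 0.5-1.5 s at every hole until the true exit;
#   futile  - wall-follow with random reversals, inspecting decoys but never
#             satisfying the exit-entry rule, until the cutoff.
# The per-trial policy is drawn from a logistic learning-curve mixture that
# shifts toward spatial across trials.

#' Simulator configuration
#'
#' @param seed Root seed for cohort generation.
#' @param dt Sampling interval (s); 1/30 matches the 30 Hz tracking rate.
#' @param speed_mean,speed_sd Paddling speed draw per trial (cm/s).
#' @param body_length_mean,body_length_sd Nose-to-tail length draw (cm).
#' @param heading_noise_kappa Concentration of heading noise on straight legs
#'   (larger = straighter).
#' @param p_inspect_near Probability that a spatial trial inspects any given
#'   neighbor decoy of the exit (up to 3).
#' @param chain_dwell_range Hole dwell range for chain/futile policies (s).
#' @param learning_a,learning_b Logistic coefficients of the learning curve
#'   `P(spatial | trial t) = plogis(a + b t)`.
#' @param futile_base Share of the non-spatial probability mass that is
#'   futile on trial 1.
#' @param futile_weight_decay Per-trial multiplier on the futile share.
#' @param jitter_sd Per-coordinate Gaussian tracking jitter (cm).
#' @param temp_rate_ppt,temp_rate_mwm Body-temperature drop per 60 s trial
#'   (degrees C) for the paddling pool and the watermaze.
#' @param temp_noise_sd Gaussian noise on the temperature drop (degrees C).
#' @return Object of class `cm_sim_config`.
#' @export
sim_config <- function(seed = 1L, dt = 1 / 30,
                       speed_mean = 10, speed_sd = 2,
                       body_length_mean = 8.0, body_length_sd = 0.5,
                       heading_noise_kappa = 8,
                       p_inspect_near = 0.15,
                       chain_dwell_range = c(0.5, 1.5),
                       learning_a = -1.5, learning_b = 0.35,
                       futile_base = 0.5, futile_weight_decay = 0.7,
                       jitter_sd = 0.1,
                       temp_rate_ppt = 2.0, temp_rate_mwm = 5.0,
                       temp_noise_sd = 0.3) {
  cfg <- structure(as.list(environment()), class = "cm_sim_config")
  if (cfg$dt <= 0) stop_validation("dt must be > 0")
  if (cfg$speed_mean <= 0 || cfg$speed_sd < 0 || cfg$body_length_sd < 0 ||
      cfg$jitter_sd < 0 || cfg$temp_noise_sd < 0)
    stop_validation("speeds must be > 0 and sds >= 0")
  if (cfg$p_inspect_near < 0 || cfg$p_inspect_near > 1 ||
      cfg$futile_base < 0 || cfg$futile_base > 1)
    stop_validation("probabilities must lie in [0, 1]")
  cfg
}

#' Strategy mixture of the learning curve at a given trial
#'
#' @param trial_index 1-based trial index (vectorized).
#' @param config A [sim_config()].
#' @return Matrix with columns `spatial`, `chain`, `futile` summing to 1.
#' @export
policy_mixture <- function(trial_index, config = sim_config()) {
  t <- as.numeric(trial_index)
  p_s <- stats::plogis(config$learning_a + config$learning_b * t)
  p_f <- (1 - p_s) * config$futile_base * config$futile_weight_decay^(t - 1)
  cbind(spatial = p_s, chain = 1 - p_s - p_f, futile = p_f)
}

#' Body-temperature drop model
#'
#' `dT = -rate_task * latency / 60 + N(0, temp_noise_sd)`, with a drop of
#' about 2 degrees C per full 60 s paddling-pool trial and about 5 degrees C
#' in the watermaze. Set `temp_noise_sd = 0` in the config to suppress noise.
#'
#' @param latency_s Trial latency (s), vectorized.
#' @param task `"PPT"` or `"MWM"`.
#' @param config A [sim_config()].
#' @return Temperature change in degrees C (negative = cooling).
#' @export
temperature_model <- function(latency_s, task = c("PPT", "MWM"),
                              config = sim_config()) {
  task <- match.arg(task)
  rate <- if (task == "PPT") config$temp_rate_ppt else config$temp_rate_mwm
  -rate * latency_s / 60 +
    stats::rnorm(length(latency_s), 0, config$temp_noise_sd)
}

# ---- segment builders -------------------------------------------------------
# Each builder returns list(pos = n x 2 positions, gaze = n x 2 unit headings)
# for the samples AFTER its starting point (the start is owned by the
# previous segment).

seg_line <- function(from, to, v, dt, kappa) {
  d <- sqrt(sum((to - from)^2))
  n <- max(1L, as.integer(round(d / (v * dt))))
  s <- seq_len(n) / n
  base <- cbind(from[1] + s * (to[1] - from[1]),
                from[2] + s * (to[2] - from[2]))
  u <- (to - from) / d
  perp <- c(-u[2], u[1])
  if (n > 2L) {
    innov <- stats::rnorm(n, 0, v * dt / sqrt(kappa))
    w <- as.numeric(stats::filter(innov, 0.9, method = "recursive"))
    w <- w * 4 * s * (1 - s)  # pinned to the endpoints
    base <- base + cbind(w * perp[1], w * perp[2])
  }
  gaze <- rbind(base[1, ] - from, diff(base))
  list(pos = base, gaze = unit_rows(gaze, fallback = u))
}

# Arc at constant radius from angle a0 to a1 (radians), signed sweep.
seg_arc <- function(radius, a0, sweep, v, dt) {
  arc_len <- abs(sweep) * radius
  n <- max(1L, as.integer(round(arc_len / (v * dt))))
  ang <- a0 + sweep * seq_len(n) / n
  pos <- cbind(radius * cos(ang), radius * sin(ang))
  tangent <- sign(sweep)
  gaze <- cbind(-sin(ang) * tangent, cos(ang) * tangent)
  list(pos = pos, gaze = gaze)
}

seg_dwell <- function(at, gaze_dir, duration, dt) {
  n <- max(1L, as.integer(round(duration / dt)))
  list(pos = matrix(rep(at, each = n), n, 2),
       gaze = matrix(rep(gaze_dir, each = n), n, 2))
}

unit_rows <- function(m, fallback = c(1, 0)) {
  nrm <- sqrt(m[, 1]^2 + m[, 2]^2)
  zero <- nrm < 1e-12
  nrm[zero] <- 1
  out <- m / nrm
  out[zero, 1] <- fallback[1]
  out[zero, 2] <- fallback[2]
  out
}

# ---- trial simulation -------------------------------------------------------

#' Simulate one trial
#'
#' Generates an Ethovision-style 3-point track under a movement policy,
#' plus the constructive ground truth (intended policy, decoys inspected,
#' escape time, temperature drop). Clockmaze policies: `spatial`, `chain`,
#' `futile`; watermaze: `spatial` (goal-directed) and `futile`
#' (periphery-biased thigmotaxis).
#'
#' @param policy Movement policy.
#' @param arena A `cm_arena`.
#' @param trial A [trial_record()].
#' @param config A [sim_config()].
#' @param seed Optional seed for this trial's RNG substream.
#' @return List with elements `track` (`cm_track`) and `truth` (list with
#'   `policy`, `n_errors`, `escaped`, `escape_time_s`, `delta_T`).
#' @export
simulate_trial <- function(policy, arena, trial, config = sim_config(),
                           seed = NULL) {
  stopifnot(inherits(arena, "cm_arena"), inherits(trial, "cm_trial"))
  if (!is.null(seed)) set.seed(seed)
  if (arena$config$variant == "watermaze")
    return(simulate_trial_watermaze(policy, arena, trial, config))
  if (!policy %in% c("spatial", "chain", "futile"))
    stop_validation("unknown policy: %s", policy)
  R <- arena$config$radius_cm
  dt <- config$dt
  v <- max(3, stats::rnorm(1, config$speed_mean, config$speed_sd))
  L <- max(5, stats::rnorm(1, config$body_length_mean, config$body_length_sd))
  exit <- trial$true_exit_hole
  n_holes <- arena$config$n_holes
  hole_ang <- deg2rad(90 - (360 / n_holes) * seq_len(n_holes))
  approach_r <- R - 4      # nose (L/2 ahead) reaches the wall from here
  follow_r <- R - 4.5      # wall-following radius
  segs <- list()
  pos0 <- c(0, 0)
  n_true_errors <- 0L

  add_leg <- function(from, to) seg_line(from, to, v, dt, config$heading_noise_kappa)
  hole_pt <- function(k, r) r * c(cos(hole_ang[k]), sin(hole_ang[k]))
  hole_dir <- function(k) c(cos(hole_ang[k]), sin(hole_ang[k]))

  if (policy == "spatial") {
    neigh <- setdiff(unique(((exit + c(-2L, -1L, 1L, 2L) - 1L) %% n_holes) + 1L),
                     exit)
    picked <- neigh[stats::runif(length(neigh)) < config$p_inspect_near]
    if (length(picked) > 3L) picked <- sample(picked, 3L)
    if (length(picked) > 1L) picked <- sample(picked)   # visit order
    cur <- pos0
    for (h in picked) {
      tgt <- hole_pt(h, approach_r)
      segs[[length(segs) + 1L]] <- add_leg(cur, tgt)
      segs[[length(segs) + 1L]] <-
        seg_dwell(tgt, hole_dir(h), stats::runif(1, 0.3, 0.6), dt)
      cur <- tgt
      n_true_errors <- n_true_errors + 1L
    }
    tgt <- hole_pt(exit, approach_r)
    segs[[length(segs) + 1L]] <- add_leg(cur, tgt)
    segs[[length(segs) + 1L]] <-
      seg_dwell(tgt, hole_dir(exit), stats::runif(1, 0.25, 0.4), dt)
    intended_escape <- TRUE
  } else {
    # chain and futile: reach the wall between two holes, then wall-follow
    j <- sample.int(n_holes, 1L)
    bearing <- hole_ang[j] - deg2rad(360 / n_holes / 2)
    d <- sample(c(-1, 1), 1L)         # sweep direction (CCW positive)
    wall_pt <- follow_r * c(cos(bearing), sin(bearing))
    segs[[1L]] <- add_leg(pos0, wall_pt)
    cur_ang <- bearing
    # hole visiting order along direction d
    step_ang <- d * deg2rad(360 / n_holes)
    k <- j
    if (d > 0) k <- j else k <- (j %% n_holes) + 1L  # first hole hit
    # walk holes until exit (chain) or until cutoff (futile)
    max_t <- trial$cutoff_s + 5
    elapsed <- function() sum(vapply(segs, function(s) nrow(s$pos), 0L)) * dt
    repeat {
      sweep <- ang_sweep(cur_ang, hole_ang[k], d)
      segs[[length(segs) + 1L]] <- seg_arc(follow_r, cur_ang, sweep, v, dt)
      cur_ang <- cur_ang + sweep
      at_exit <- (k == exit)
      if (policy == "chain" && at_exit) {
        tgt <- hole_pt(exit, approach_r)
        segs[[length(segs) + 1L]] <-
          seg_dwell(tgt, hole_dir(exit), stats::runif(1, 0.25, 0.4), dt)
        break
      }
      if (!at_exit) {
        # poke the nose into the decoy and dwell
        tgt <- hole_pt(k, approach_r)
        segs[[length(segs) + 1L]] <-
          seg_dwell(tgt, hole_dir(k),
                    stats::runif(1, config$chain_dwell_range[1],
                                 config$chain_dwell_range[2]), dt)
        segs[[length(segs) + 1L]] <-
          seg_line(hole_pt(k, approach_r), hole_pt(k, follow_r), v, dt,
                   config$heading_noise_kappa)
        n_true_errors <- n_true_errors + 1L
      }
      if (policy == "futile" && stats::runif(1) < 0.2) d <- -d
      k <- ((k - 1L + as.integer(d * sign(-1))) %% n_holes) + 1L
      # CCW (d = +1) decreases the clock index, CW increases it
      if (elapsed() > max_t) break
    }
    intended_escape <- policy == "chain"
  }

  asm <- assemble_track(segs, pos0, dt, L, config$jitter_sd, trial$cutoff_s,
                        intended_escape)
  escaped <- asm$escaped
  esc_t <- if (escaped) asm$duration else NA_real_
  lat <- if (escaped) asm$duration else trial$cutoff_s
  truth <- list(policy = policy, n_errors = n_true_errors,
                escaped = escaped,
                escape_time_s = if (policy == "futile") trial$cutoff_s else lat,
                delta_T = temperature_model(lat, "PPT", config))
  list(track = asm$track, truth = truth)
}

# signed sweep from angle a to the hole angle in direction d (never 0)
ang_sweep <- function(a, target, d) {
  delta <- (target - a) %% (2 * pi)
  if (d > 0) {
    if (delta < 1e-9) delta <- 2 * pi
    delta
  } else {
    delta <- delta - 2 * pi
    if (delta > -1e-9) delta <- -2 * pi
    delta
  }
}

assemble_track <- function(segs, pos0, dt, L, jitter_sd, cutoff_s,
                           intended_escape) {
  pos <- do.call(rbind, lapply(segs, `[[`, "pos"))
  gaze <- do.call(rbind, lapply(segs, `[[`, "gaze"))
  pos <- rbind(pos0, pos)
  gaze <- rbind(gaze[1, ], gaze)
  n_max <- as.integer(round(cutoff_s / dt)) + 1L
  escaped <- intended_escape
  if (nrow(pos) >= n_max - 2L) {   # censored at the cutoff
    if (nrow(pos) < n_max) {       # escape landed on the boundary: pad to 60 s
      extra <- n_max - nrow(pos)
      pos <- rbind(pos, matrix(rep(pos[nrow(pos), ], each = extra), extra, 2))
      gaze <- rbind(gaze, matrix(rep(gaze[nrow(gaze), ], each = extra), extra, 2))
    }
    pos <- pos[seq_len(n_max), , drop = FALSE]
    gaze <- gaze[seq_len(n_max), , drop = FALSE]
    escaped <- FALSE
  }
  n <- nrow(pos)
  t <- (seq_len(n) - 1L) * dt
  half <- L / 2
  nose <- pos + half * gaze
  tail <- pos - half * gaze
  jit <- function(m) m + matrix(stats::rnorm(2 * n, 0, jitter_sd), n, 2)
  tr <- track(t, jit(nose), jit(pos), jit(tail), rate_hz = 1 / dt)
  list(track = tr, duration = t[n], escaped = escaped)
}

simulate_trial_watermaze <- function(policy, arena, trial, config) {
  if (!policy %in% c("spatial", "futile"))
    stop_validation("watermaze policies are 'spatial' and 'futile', got %s",
                    policy)
  R <- arena$config$radius_cm
  dt <- config$dt
  v <- max(5, stats::rnorm(1, config$speed_mean * 1.6, config$speed_sd))
  L <- max(5, stats::rnorm(1, config$body_length_mean, config$body_length_sd))
  start_ang <- deg2rad(sample(c(90, 180, 270, 0), 1L))
  pos0 <- (R - 5) * c(cos(start_ang), sin(start_ang))
  segs <- list()
  if (policy == "spatial") {
    tgt <- arena$config$platform_center
    segs[[1L]] <- seg_line(pos0, tgt, v, dt, config$heading_noise_kappa)
    intended_escape <- TRUE
  } else {
    cur_ang <- start_ang
    total <- 0
    while (total < trial$cutoff_s + 2) {
      sweep <- sample(c(-1, 1), 1L) * stats::runif(1, pi / 2, pi)
      seg <- seg_arc(R - 5, cur_ang, sweep, v, dt)
      segs[[length(segs) + 1L]] <- seg
      cur_ang <- cur_ang + sweep
      total <- total + nrow(seg$pos) * dt
    }
    intended_escape <- FALSE
  }
  asm <- assemble_track(segs, pos0, dt, L, config$jitter_sd, trial$cutoff_s,
                        intended_escape)
  lat <- if (asm$escaped) asm$duration else trial$cutoff_s
  truth <- list(policy = policy, n_errors = NA_integer_,
                escaped = asm$escaped,
                escape_time_s = if (policy == "futile") trial$cutoff_s else lat,
                delta_T = temperature_model(lat, "MWM", config))
  list(track = asm$track, truth = truth)
}

# ---- cohort simulation ------------------------------------------------------

#' Build a subject roster
#'
#' @param n Number of subjects.
#' @param strains,sexes Factors cycled over the roster.
#' @param prefix Subject id prefix.
#' @return `data.frame` with `subject_id`, `strain`, `sex`.
#' @export
make_roster <- function(n, strains = c("C57", "BALBc"), sexes = c("M", "F"),
                        prefix = "S") {
  data.frame(subject_id = sprintf("%s%03d", prefix, seq_len(n)),
             strain = rep_len(rep(strains, each = length(sexes)), n),
             sex = rep_len(sexes, n),
             stringsAsFactors = FALSE)
}

#' Simulate a full cohort
#'
#' Draws each subject's per-trial policy from the learning-curve mixture and
#' simulates every trial. On novel trials (the first trial of a day with a
#' relocated exit) a drawn spatial policy is executed as chain: an animal
#' cannot steer spatially to an exit location it has never experienced, which
#' is what makes exit switches cost time. Reproducible: each trial runs in an
#' RNG substream derived from `(seed, subject_id, trial_index)`, so results
#' are identical for identical inputs regardless of iteration order.
#'
#' @param roster Subject table from [make_roster()] (columns `subject_id`,
#'   `strain`, `sex`).
#' @param schedule A [make_schedule()].
#' @param arena A `cm_arena`.
#' @param config A [sim_config()].
#' @param seed Root seed (defaults to `config$seed`).
#' @param tracks Keep the full tracks (set `FALSE` to retain only trial
#'   records and ground truth, e.g. for large property sweeps).
#' @return Object of class `cm_cohort`: list of records, each with `trial`,
#'   `track` (or `NULL`), `truth`.
#' @export
simulate_cohort <- function(roster, schedule, arena = build_arena(),
                            config = sim_config(), seed = config$seed,
                            tracks = TRUE) {
  stopifnot(inherits(schedule, "cm_schedule"))
  st <- schedule_trials(schedule)
  mix <- policy_mixture(st$trial_index, config)
  records <- vector("list", nrow(roster) * nrow(st))
  i <- 0L
  for (s in seq_len(nrow(roster))) {
    for (k in seq_len(nrow(st))) {
      i <- i + 1L
      sub_seed <- substream_seed(seed, roster$subject_id[s], st$trial_index[k])
      set.seed(sub_seed)
      pol <- sample(colnames(mix), 1L, prob = mix[k, ])
      if (st$novel[k] && pol == "spatial") pol <- "chain"
      tri <- trial_record(roster$subject_id[s], roster$strain[s],
                          roster$sex[s], day = st$day[k],
                          trial_index = st$trial_index[k],
                          true_exit_hole = st$true_exit_hole[k])
      sim <- simulate_trial(pol, arena, tri, config)
      records[[i]] <- list(trial = tri,
                           track = if (tracks) sim$track else NULL,
                           truth = sim$truth)
    }
  }
  structure(records, class = "cm_cohort")
}

#' @export
print.cm_cohort <- function(x, ...) {
  cat(sprintf("<cm_cohort: %d trials, %d subjects>\n", length(x),
              length(unique(vapply(x, function(r) r$trial$subject_id, "")))))
  invisible(x)
}

#' Write a cohort to disk in the canonical track formats
#'
#' One track file per trial plus a trial metadata table; ground truth goes to
#' a separate table so blinded analysis runs are possible.
#'
#' @param cohort A `cm_cohort` (with tracks).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the metadata table.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- data.table::rbindlist(lapply(seq_along(cohort), function(i) {
    r <- cohort[[i]]
    fn <- sprintf("track_%s_t%02d.csv", r$trial$subject_id,
                  r$trial$trial_index)
    if (is.null(r$track))
      stop_validation("cohort was simulated without tracks")
    write_track(r$track, file.path(dir, fn))
    data.table::data.table(
      subject_id = r$trial$subject_id, strain = r$trial$strain,
      sex = r$trial$sex, day = r$trial$day,
      trial_index = r$trial$trial_index,
      true_exit_hole = r$trial$true_exit_hole,
      cutoff_s = r$trial$cutoff_s, probe = r$trial$probe,
      track_file = fn)
  }))
  truth <- data.table::rbindlist(lapply(cohort, function(r) {
    data.table::data.table(
      subject_id = r$trial$subject_id, trial_index = r$trial$trial_index,
      policy = r$truth$policy, n_errors_true = r$truth$n_errors,
      escaped = r$truth$escaped, escape_time_s = r$truth$escape_time_s,
      delta_T = r$truth$delta_T)
  }))
  utils::write.table(meta, file.path(dir, "trials.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth, file.path(dir, "ground_truth.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  invisible(meta)
}
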