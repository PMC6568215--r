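# Track and table I/O plus protocol schedules.
#
# The canonical track format is a delimited text file (comma or tab, auto
# detected) with header
#   time_s,nose_x,nose_y,center_x,center_y,tail_x,tail_y
# modeled on Ethovision-style raw exports of a 3-point (nose / body center /
# tail base) detection at 30 Hz.

TRACK_COLUMNS <- c("time_s", "nose_x", "nose_y", "center_x", "center_y",
                   "tail_x", "tail_y")

METRICS_COLUMNS <- c("subject_id", "strain", "sex", "day", "trial_index",
                     "true_exit_hole", "escaped", "latency_s", "n_errors",
                     "distance_cm", "mean_speed_cm_s", "rotations",
                     "meander_turns", "heading_to_exit_deg", "periphery_s",
                     "strategy")

#' Construct a track object
#'
#' @param time_s Strictly increasing, non-negative timestamps (s).
#' @param nose,center,tail n x 2 coordinate matrices (cm). `nose`/`tail` may be
#'   `NULL` for degraded tracks (nose-based operations then refuse to run).
#' @param rate_hz Nominal sampling rate (default 30).
#' @param validate_arena Optional `cm_arena`; if given, the body center must
#'   stay within `radius_cm + 1` cm.
#' @return Object of class `cm_track`: a list with `t`, `nose`, `center`,
#'   `tail`, `rate_hz`, `degraded`.
#' @export
track <- function(time_s, nose, center, tail, rate_hz = 30,
                  validate_arena = NULL) {
  t <- as.numeric(time_s)
  n <- length(t)
  if (n < 2L)
    stop_validation("a track needs at least 2 samples, got %d", n)
  if (anyNA(t) || any(!is.finite(t)) || any(t < 0))
    stop_validation("timestamps must be finite and non-negative")
  bad <- which(diff(t) <= 0)
  if (length(bad))
    stop_format("timestamps not strictly increasing at row %d (t = %s)",
                bad[1] + 1L, format(t[bad[1] + 1L]))
  as_mat <- function(m, what) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    if (nrow(m) != n || ncol(m) != 2)
      stop_validation("%s must be an %d x 2 matrix", what, n)
    if (anyNA(m) || any(!is.finite(m)))
      stop_validation("%s coordinates must be finite", what)
    dimnames(m) <- list(NULL, c("x", "y"))
    m
  }
  center <- as_mat(center, "center")
  if (is.null(center)) stop_validation("center coordinates are required")
  nose <- as_mat(nose, "nose")
  tail <- as_mat(tail, "tail")
  if (!is.null(validate_arena)) {
    r <- row_norm(center)
    out <- which(r > validate_arena$config$radius_cm + 1.0)
    if (length(out))
      stop_validation(
        "center outside arena (+1 cm tolerance) at sample(s) %s",
        paste(utils::head(out, 5L), collapse = ", "))
  }
  structure(list(t = t, nose = nose, center = center, tail = tail,
                 rate_hz = rate_hz, degraded = is.null(nose) || is.null(tail)),
            class = "cm_track")
}

#' @export
print.cm_track <- function(x, ...) {
  cat(sprintf("<cm_track: %d samples, %.2f s%s>\n", length(x$t),
              x$t[length(x$t)] - x$t[1],
              if (x$degraded) ", degraded (center only)" else ""))
  invisible(x)
}

track_duration <- function(tr) tr$t[length(tr$t)] - tr$t[1]

#' Read a track file
#'
#' Comma and tab dialects are auto-detected. Missing nose/tail columns are
#' accepted and yield a degraded track (center only); a missing center or time
#' column is a format error.
#'
#' @param source Path to a delimited track file.
#' @param arena Optional `cm_arena` for the out-of-arena validation.
#' @param rate_hz Nominal sampling rate stored on the track.
#' @return A `cm_track`.
#' @export
read_track <- function(source, arena = NULL, rate_hz = 30) {
  dt <- data.table::fread(source, sep = "auto", header = TRUE,
                          data.table = TRUE, showProgress = FALSE)
  need <- c("time_s", "center_x", "center_y")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop_format("track file %s is missing required column(s): %s",
                source, paste(miss, collapse = ", "))
  has_nose <- all(c("nose_x", "nose_y") %in% names(dt))
  has_tail <- all(c("tail_x", "tail_y") %in% names(dt))
  track(dt$time_s,
        nose = if (has_nose) cbind(dt$nose_x, dt$nose_y) else NULL,
        center = cbind(dt$center_x, dt$center_y),
        tail = if (has_tail) cbind(dt$tail_x, dt$tail_y) else NULL,
        rate_hz = rate_hz, validate_arena = arena)
}

#' Write a track file
#'
#' Coordinates are written at micro-centimeter precision so a
#' write/read round trip is lossless to 1e-6 cm.
#'
#' @param tr A `cm_track`.
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @export
write_track <- function(tr, path, sep = ",") {
  stopifnot(inherits(tr, "cm_track"))
  if (tr$degraded)
    cols <- data.frame(time_s = sprintf("%.6f", tr$t),
                       center_x = sprintf("%.6f", tr$center[, 1]),
                       center_y = sprintf("%.6f", tr$center[, 2]))
  else
    cols <- data.frame(time_s = sprintf("%.6f", tr$t),
                       nose_x = sprintf("%.6f", tr$nose[, 1]),
                       nose_y = sprintf("%.6f", tr$nose[, 2]),
                       center_x = sprintf("%.6f", tr$center[, 1]),
                       center_y = sprintf("%.6f", tr$center[, 2]),
                       tail_x = sprintf("%.6f", tr$tail[, 1]),
                       tail_y = sprintf("%.6f", tr$tail[, 2]))
  utils::write.table(cols, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Trial metadata record
#'
#' @param subject_id Subject identifier.
#' @param strain One of `"C57"`, `"BALBc"`, `"other"`.
#' @param sex `"M"` or `"F"`.
#' @param day Testing day (1-based).
#' @param trial_index Global 1-based trial index for the subject.
#' @param true_exit_hole Open-hole index 1..12, or `NA` for probe trials.
#' @param cutoff_s Trial cutoff (default 60 s).
#' @param probe Logical; probe trials have all exits blocked.
#' @return Object of class `cm_trial`.
#' @export
trial_record <- function(subject_id, strain = "C57", sex = "M", day = 1L,
                         trial_index = 1L, true_exit_hole = NA_integer_,
                         cutoff_s = 60, probe = FALSE) {
  strain <- match.arg(strain, c("C57", "BALBc", "other"))
  sex <- match.arg(sex, c("M", "F"))
  if (trial_index < 1) stop_validation("trial_index must be >= 1")
  if (!is.finite(cutoff_s) || cutoff_s <= 0)
    stop_validation("cutoff_s must be > 0")
  if (!probe && (is.na(true_exit_hole) || true_exit_hole < 1))
    stop_validation("non-probe trials need a true_exit_hole index")
  structure(list(subject_id = as.character(subject_id), strain = strain,
                 sex = sex, day = as.integer(day),
                 trial_index = as.integer(trial_index),
                 true_exit_hole = as.integer(true_exit_hole),
                 cutoff_s = as.numeric(cutoff_s), probe = isTRUE(probe)),
            class = "cm_trial")
}

#' Write the per-trial metrics table
#'
#' One delimited row per trial with a stable column order
#' (`subject_id, strain, sex, day, trial_index, true_exit_hole, escaped,
#' latency_s, n_errors, distance_cm, mean_speed_cm_s, rotations,
#' meander_turns, heading_to_exit_deg, periphery_s, strategy`).
#'
#' @param records List of lists with elements `trial` (`cm_trial`), `metrics`
#'   (`cm_trial_metrics`) and optional `strategy` (label string).
#' @param sink Output path.
#' @param sep Field separator.
#' @return The table, invisibly, as a `data.table`.
#' @export
write_metrics_table <- function(records, sink, sep = ",") {
  tab <- metrics_table(records)
  utils::write.table(tab, sink, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(tab)
}

#' Assemble the metrics table in memory
#' @rdname write_metrics_table
#' @export
metrics_table <- function(records) {
  rows <- lapply(records, function(r) {
    tr <- r$trial; m <- r$metrics
    data.table::data.table(
      subject_id = tr$subject_id, strain = tr$strain, sex = tr$sex,
      day = tr$day, trial_index = tr$trial_index,
      true_exit_hole = tr$true_exit_hole,
      escaped = m$escaped, latency_s = m$latency_s,
      n_errors = if (is.null(m$n_errors)) NA_integer_ else m$n_errors,
      distance_cm = m$distance_cm, mean_speed_cm_s = m$mean_speed_cm_s,
      rotations = m$rotations, meander_turns = m$meander_turns,
      heading_to_exit_deg = m$heading_to_exit_deg,
      periphery_s = m$periphery_s,
      strategy = r$strategy %||% NA_character_)
  })
  if (!length(rows)) {
    tab <- data.table::as.data.table(
      stats::setNames(rep(list(logical(0)), length(METRICS_COLUMNS)),
                      METRICS_COLUMNS))
    return(tab)
  }
  data.table::rbindlist(rows)
}

#' Read a metrics table written by [write_metrics_table()]
#' @param path File path.
#' @return A `data.table`.
#' @export
read_metrics_table <- function(path) {
  dt <- data.table::fread(path, sep = "auto", header = TRUE,
                          showProgress = FALSE)
  miss <- setdiff(METRICS_COLUMNS, names(dt))
  if (length(miss))
    stop_format("metrics table missing column(s): %s",
                paste(miss, collapse = ", "))
  dt
}

# ---- schedules --------------------------------------------------------------

#' Build a trial schedule for the one-exit / many-exits protocols
#'
#' * `one_exit`: 3 days x 4 trials, a single exit throughout (12 trials).
#' * `three_exits`: 3 days x 4 trials, default exit sequence 4, 10, 2.
#' * `eight_exits`: 8 days, 5 trials/day on days 1-4 and 4 trials/day on days
#'   5-8 (36 trials), default sequence 7, 11, 4, 9, 3, 5, 1, 6.
#' * `custom`: caller supplies `exits` (one per day) and `trials_per_day`.
#'
#' When `exits` is not given and a `seed` is supplied, a pseudo-random
#' sequence is drawn uniformly without replacement so no exit repeats across
#' days (blocks of at most 12 days).
#'
#' @param protocol One of `"one_exit"`, `"three_exits"`, `"eight_exits"`,
#'   `"custom"`.
#' @param exits Optional integer vector of exits, one per day.
#' @param seed Optional integer seed for pseudo-random exit draws.
#' @param trials_per_day Optional trial counts per day (custom protocol).
#' @return Object of class `cm_schedule` with `protocol`, `exits` (per day),
#'   `trials_per_day`, and `n_trials`.
#' @export
make_schedule <- function(protocol = c("one_exit", "three_exits",
                                       "eight_exits", "custom"),
                          exits = NULL, seed = NULL, trials_per_day = NULL) {
  protocol <- match.arg(protocol)
  defaults <- switch(protocol,
    one_exit    = list(days = 3L, tpd = rep(4L, 3), exits = rep(9L, 3)),
    three_exits = list(days = 3L, tpd = rep(4L, 3), exits = c(4L, 10L, 2L)),
    eight_exits = list(days = 8L, tpd = c(rep(5L, 4), rep(4L, 4)),
                       exits = c(7L, 11L, 4L, 9L, 3L, 5L, 1L, 6L)),
    custom      = NULL)
  if (protocol == "custom") {
    if (is.null(exits))
      stop_validation("custom schedules require an explicit exits vector")
    if (is.null(trials_per_day)) trials_per_day <- rep(4L, length(exits))
    if (length(trials_per_day) != length(exits))
      stop_validation("trials_per_day and exits must have equal length")
  } else {
    trials_per_day <- defaults$tpd
    if (is.null(exits)) {
      if (is.null(seed)) {
        exits <- defaults$exits
      } else {
        set.seed(substream_seed(seed, "schedule", protocol))
        ndays <- defaults$days
        if (protocol == "one_exit") {
          exits <- rep(sample.int(12L, 1L), ndays)
        } else {
          # uniform without replacement per block of <= 12 days
          exits <- integer(0)
          while (length(exits) < ndays) {
            exits <- c(exits, sample.int(12L,
                                         min(12L, ndays - length(exits))))
          }
        }
      }
    } else {
      if (protocol == "one_exit" && length(exits) == 1L)
        exits <- rep(as.integer(exits), defaults$days)
      if (length(exits) != defaults$days)
        stop_validation("%s expects %d per-day exits, got %d",
                        protocol, defaults$days, length(exits))
    }
  }
  exits <- as.integer(exits)
  if (any(exits < 1L | exits > 12L))
    stop_validation("exits must lie in 1..12")
  structure(list(protocol = protocol, exits = exits,
                 trials_per_day = as.integer(trials_per_day),
                 n_trials = sum(trials_per_day)),
            class = "cm_schedule")
}

#' Expand a schedule to a per-trial table
#'
#' @param schedule A `cm_schedule`.
#' @return `data.table` with columns `trial_index`, `day`, `true_exit_hole`,
#'   `novel` (first trial of a day introducing a new exit).
#' @export
schedule_trials <- function(schedule) {
  stopifnot(inherits(schedule, "cm_schedule"))
  day <- rep(seq_along(schedule$trials_per_day), schedule$trials_per_day)
  exit <- rep(schedule$exits, schedule$trials_per_day)
  idx <- seq_along(day)
  first_of_day <- !duplicated(day)
  new_exit <- c(TRUE, schedule$exits[-1] != schedule$exits[-length(schedule$exits)])
  novel <- first_of_day & new_exit[day] & day > 1L
  # trial 1 of day 1 is the subject's first exposure; "novel" marks exit switches
  data.table::data.table(trial_index = idx, day = day,
                         true_exit_hole = exit, novel = novel)
}

#' Indices of the first trial of each new-exit day (including trial 1)
#'
#' For the default three-exits schedule these are exactly 1, 5, 9.
#' @param schedule A `cm_schedule`.
#' @return Integer vector of trial indices.
#' @export
novel_trial_indices <- function(schedule) {
  st <- schedule_trials(schedule)
  sort(unique(c(1L, st$trial_index[st$novel])))
}
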