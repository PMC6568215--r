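# Group-level derived measures: learning scores, novelty differences,
# probe-zone preference, ensemble bands, EPM ratio, Spearman correlation and
# the temperature-latency relation.

#' Per-subject learning scores (inversed latencies)
#'
#' The default score is the mean of per-trial reciprocal latencies
#' (`1/latency`, failed trials contributing `1/cutoff`), so it lives in
#' `[1/cutoff, 1/latency_min]` and increases with faster escapes. An
#' alternative linear normalization `(cutoff - latency)/cutoff` is available
#' via `method` since "inversed" admits either reading.
#'
#' @param latencies Named list: one numeric latency vector per subject
#'   (ordered by trial index).
#' @param cutoff Trial cutoff (s).
#' @param exclude_trials Trial indices to drop (e.g. the novel trials
#'   `c(1, 5, 9)` in the three-exits test).
#' @param method `"reciprocal"` (default) or `"linear"`.
#' @return `data.frame` with columns `subject_id`, `score`.
#' @export
learning_scores <- function(latencies, cutoff = 60,
                            exclude_trials = integer(0),
                            method = c("reciprocal", "linear")) {
  method <- match.arg(method)
  if (!length(latencies)) stop_validation("no subjects supplied")
  ids <- names(latencies) %||% as.character(seq_along(latencies))
  score <- vapply(latencies, function(lat) {
    lat <- as.numeric(lat)
    if (any(lat <= 0 | lat > cutoff + 1e-9))
      stop_validation("latencies must lie in (0, cutoff]")
    keep <- setdiff(seq_along(lat), exclude_trials)
    if (!length(keep))
      stop_validation("no trials left after exclusion")
    s <- switch(method,
                reciprocal = 1 / lat[keep],
                linear = (cutoff - lat[keep]) / cutoff)
    mean(s)
  }, numeric(1))
  data.frame(subject_id = ids, score = unname(score),
             stringsAsFactors = FALSE)
}

#' Latency differences at exit-switch (novel) trials
#'
#' For each novel trial `i` (first trial with a relocated exit), the signed
#' difference `latency[i] - latency[i - 1]`; positive values mean the switch
#' cost time, i.e. the animal had learned the previous exit.
#'
#' @param latencies Numeric vector of one subject's latencies in trial order.
#' @param novel_indices Trial indices of the exit switches (each >= 2).
#' @return Numeric vector of signed differences (s), one per novel index.
#' @export
novelty_differences <- function(latencies, novel_indices) {
  novel_indices <- as.integer(novel_indices)
  if (any(novel_indices < 2L | novel_indices > length(latencies)))
    stop_validation("novel indices must lie in 2..%d", length(latencies))
  latencies[novel_indices] - latencies[novel_indices - 1L]
}

#' Probe-test zone preference
#'
#' Dwell in the target zone (probe zone at the former exit) and the mean
#' dwell over the 11 non-target (decoy) probe zones, as percentages of the
#' probe duration.
#'
#' @param track Probe-trial `cm_track` (duration at most the cutoff plus
#'   tolerance).
#' @param arena A clockmaze `cm_arena`.
#' @param former_exit Hole index of the formerly open exit.
#' @param probe_zone_radius_cm Optional override of the probe-zone radius.
#' @return List with `tz_pct`, `nt_pct`, `tz_s`, `nt_zone_s` (per-zone dwell).
#' @export
probe_zone_preference <- function(track, arena, former_exit,
                                  probe_zone_radius_cm = NULL) {
  stopifnot(inherits(track, "cm_track"), inherits(arena, "cm_arena"))
  if (!is.null(probe_zone_radius_cm)) {
    arena$config$probe_zone_radius_cm <- probe_zone_radius_cm
  }
  pz <- probe_zones(arena, former_exit)
  dur <- track_duration(track)
  if (dur <= 0) stop_validation("probe track has no duration")
  tz_s <- unname(zone_dwell_times(track, pz$target))
  nt_s <- zone_dwell_times(track, pz$nontarget)
  list(tz_pct = 100 * tz_s / dur,
       nt_pct = 100 * mean(nt_s) / dur,
       tz_s = tz_s,
       nt_zone_s = nt_s)
}

#' Watermaze probe quadrant preference
#'
#' Percent of probe time spent in each quadrant plus platform-zone dwell.
#' @param track A `cm_track`.
#' @param arena A watermaze `cm_arena`.
#' @return List with `quadrant_pct` (named) and `platform_zone_s`.
#' @export
probe_quadrant_preference <- function(track, arena) {
  stopifnot(inherits(arena, "cm_arena"))
  if (arena$config$variant != "watermaze")
    stop_capability("quadrant preference is reported for the watermaze variant")
  dur <- track_duration(track)
  q <- arena$zones[grepl("^quadrant_", names(arena$zones))]
  dw <- zone_dwell_times(track, q)
  list(quadrant_pct = 100 * dw / dur,
       platform_zone_s = unname(zone_dwell_times(track, arena$zones$platform)))
}

#' Elevated-plus-maze anxiety ratio
#'
#' `(T_C - T_O) / (T_C + T_O)` with `T_C` the closed-arm and `T_O` the
#' open-arm time; 1 means all time in the closed arms (most anxious),
#' -1 all time in the open arms.
#'
#' @param t_closed,t_open Arm times in seconds (vectorized).
#' @return Ratio in `[-1, 1]`.
#' @export
epm_ratio <- function(t_closed, t_open) {
  if (any(t_closed < 0 | t_open < 0))
    stop_validation("arm times must be non-negative")
  tot <- t_closed + t_open
  if (any(tot <= 0))
    stop_validation("T_C + T_O must be positive")
  (t_closed - t_open) / tot
}

#' Spearman rank correlation with mid-ranks
#'
#' Pearson correlation of mid-ranks (ties receive their average rank).
#'
#' @param x,y Equal-length numeric vectors (length >= 3).
#' @return rho in `[-1, 1]`, or `NA` when either input is constant.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop_validation("x and y lengths differ")
  if (length(x) < 3L) stop_validation("need at least 3 pairs")
  rx <- midrank(x); ry <- midrank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sx <- sqrt(sum(dx^2)); sy <- sqrt(sum(dy^2))
  if (sx == 0 || sy == 0) return(NA_real_)
  sum(dx * dy) / (sx * sy)
}

# average ranks for ties, built from order statistics
midrank <- function(x) {
  o <- order(x)
  r <- numeric(length(x))
  i <- 1L
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[o[j + 1L]] == x[o[i]]) j <- j + 1L
    r[o[i:j]] <- (i + j) / 2
    i <- j + 1L
  }
  r
}

#' Per-trial ensemble mean with a percentile envelope
#'
#' Per-trial mean across subjects plus an empirical percentile band (default
#' 5th-95th), percentiles computed by linear interpolation between the
#' closest order statistics.
#'
#' @param latency_table Numeric matrix, subjects x trials.
#' @param lower_pct,upper_pct Envelope percentiles.
#' @return Object of class `cm_band`: list with `trial`, `mean`, `lower`,
#'   `upper`.
#' @export
ensemble_band <- function(latency_table, lower_pct = 5, upper_pct = 95) {
  m <- as.matrix(latency_table)
  if (nrow(m) < 1L) stop_validation("need at least one subject")
  pct <- function(col, p) {
    col <- sort(col[!is.na(col)])
    n <- length(col)
    if (n == 1L) return(col)
    h <- (n - 1) * p / 100 + 1
    lo <- floor(h); hi <- ceiling(h)
    col[lo] + (h - lo) * (col[hi] - col[lo])
  }
  structure(list(trial = seq_len(ncol(m)),
                 mean = colMeans(m, na.rm = TRUE),
                 lower = apply(m, 2, pct, p = lower_pct),
                 upper = apply(m, 2, pct, p = upper_pct)),
            class = "cm_band")
}

#' Temperature-drop versus latency relation
#'
#' Rank correlation plus least-squares polynomial coefficients for the body
#' temperature change as a function of escape latency (successful trials
#' only).
#'
#' @param latencies Numeric latencies (s) of successful trials.
#' @param delta_temps Body-temperature changes (degrees C), same length.
#' @param degree Polynomial degree (default 1, a line).
#' @return Object of class `cm_tempfit`: list with `rho`, `coefficients`
#'   (intercept first).
#' @export
temp_latency_fit <- function(latencies, delta_temps, degree = 1) {
  if (length(latencies) != length(delta_temps))
    stop_validation("latencies and delta_temps lengths differ")
  if (length(latencies) < 3L) stop_validation("need at least 3 trials")
  rho <- if (length(unique(latencies)) < 2L) NA_real_ else
    spearman_rho(latencies, delta_temps)
  X <- stats::poly(latencies, degree = degree, raw = TRUE)
  fit <- stats::lm.fit(cbind(1, X), delta_temps)
  structure(list(rho = rho,
                 coefficients = unname(fit$coefficients)),
            class = "cm_tempfit")
}
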