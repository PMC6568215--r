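# Fixture builders and independent oracles shared across the suite.

# Track whose nose/center/tail all follow the given center path (zero body
# length); handy for analytic constructions.
point_track <- function(xy, dt = 1 / 30, t = NULL) {
  n <- nrow(xy)
  track(t %||% ((seq_len(n) - 1) * dt), nose = xy, center = xy, tail = xy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Straight run at constant speed from `from` to `to` (cm), nose = center.
straight_track <- function(from, to, speed = 10, dt = 1 / 30) {
  d <- sqrt(sum((to - from)^2))
  n <- max(2L, round(d / (speed * dt)) + 1L)
  s <- seq(0, 1, length.out = n)
  xy <- cbind(from[1] + s * (to[1] - from[1]),
              from[2] + s * (to[2] - from[2]))
  point_track(xy, dt = d / speed / (n - 1))
}

# Random confined walk: heading random walk, speed ~U(2, 14), reflected at
# radius `rmax`; nose/tail offset along the heading.
random_walk_track <- function(duration_s = 8, dt = 1 / 30, rmax = 40,
                              body = 8) {
  n <- round(duration_s / dt) + 1L
  th <- cumsum(c(runif(1, 0, 2 * pi), rnorm(n - 1, 0, 0.5)))
  sp <- runif(n, 2, 14)
  x <- numeric(n); y <- numeric(n)
  for (i in 2:n) {
    x[i] <- x[i - 1] + cos(th[i]) * sp[i] * dt
    y[i] <- y[i - 1] + sin(th[i]) * sp[i] * dt
    r <- sqrt(x[i]^2 + y[i]^2)
    if (r > rmax) {
      x[i] <- x[i] * (2 * rmax - r) / r
      y[i] <- y[i] * (2 * rmax - r) / r
      th[i] <- th[i] + pi
    }
  }
  ctr <- cbind(x, y)
  gaze <- cbind(cos(th), sin(th))
  track((seq_len(n) - 1) * dt, ctr + body / 2 * gaze, ctr,
        ctr - body / 2 * gaze)
}

# Literal per-frame state-machine oracle for inspection events: walks every
# frame of every hole zone independently of the production (run-length)
# implementation.
oracle_inspections <- function(track, arena, true_exit = NA,
                               debounce_s = 0.1, rearm_factor = 1.5) {
  t <- track$t - track$t[1]
  r_in <- arena$config$hole_zone_radius_cm
  r_dil <- r_in * rearm_factor
  out <- list()
  for (k in seq_len(arena$config$n_holes)) {
    ctr <- arena$hole_centers[k, ]
    d <- sqrt((track$nose[, 1] - ctr[1])^2 + (track$nose[, 2] - ctr[2])^2)
    state <- "armed"   # armed -> pending -> triggered -> armed
    t_enter <- NA
    for (i in seq_along(t)) {
      inside <- d[i] <= r_in + 1e-9
      in_dil <- d[i] <= r_dil + 1e-9
      if (state == "armed") {
        if (inside) { state <- "pending"; t_enter <- t[i] }
      } else if (state == "pending") {
        if (!inside) {
          state <- "armed"
        } else if (t[i] - t_enter >= debounce_s - 1e-9) {
          state <- "triggered"
          out[[length(out) + 1]] <- list(hole = k, t_on = t_enter,
                                         t_off = NA)
        }
      } else if (state == "triggered") {
        if (!in_dil) {
          out[[length(out)]]$t_off <- t[i]
          state <- "armed"
        }
      }
    }
    if (state == "triggered") out[[length(out)]]$t_off <- t[length(t)]
  }
  if (!length(out))
    return(data.frame(hole = integer(0), t_on = numeric(0),
                      t_off = numeric(0)))
  df <- do.call(rbind, lapply(out, as.data.frame))
  df <- df[order(df$t_on), ]
  rownames(df) <- NULL
  df
}

# Exhaustive-search CART oracle: every axis split at every midpoint of sorted
# unique values, weighted Gini, ties broken by lowest feature name then
# lowest threshold. Grows to the requested depth with no other stopping rule
# except purity/min_leaf.
oracle_tree <- function(X, y, depth, min_leaf = 1L) {
  majority <- function(yy) {
    tb <- table(yy)
    names(tb)[which.max(tb)]  # first max = alphabetically lowest on ties
  }
  gini <- function(yy) 1 - sum((table(yy) / length(yy))^2)
  if (depth == 0L || length(unique(y)) == 1L || length(y) < 2 * min_leaf)
    return(list(leaf = TRUE, class = majority(y)))
  best <- NULL
  best_score <- gini(y) - 1e-12
  for (f in sort(colnames(X))) {
    vals <- sort(unique(X[, f]))
    if (length(vals) < 2) next
    for (thr in (vals[-1] + vals[-length(vals)]) / 2) {
      l <- X[, f] <= thr
      if (sum(l) < min_leaf || sum(!l) < min_leaf) next
      sc <- (sum(l) * gini(y[l]) + sum(!l) * gini(y[!l])) / length(y)
      if (sc < best_score - 1e-12) { best_score <- sc
        best <- list(f = f, thr = thr) }
    }
  }
  if (is.null(best)) return(list(leaf = TRUE, class = majority(y)))
  l <- X[, best$f] <= best$thr
  list(leaf = FALSE, feature = best$f, threshold = best$thr,
       left = oracle_tree(X[l, , drop = FALSE], y[l], depth - 1L, min_leaf),
       right = oracle_tree(X[!l, , drop = FALSE], y[!l], depth - 1L,
                           min_leaf))
}

oracle_predict <- function(node, X) {
  vapply(seq_len(nrow(X)), function(i) {
    nd <- node
    while (!nd$leaf) nd <- if (X[i, nd$feature] <= nd$threshold) nd$left
                           else nd$right
    nd$class
  }, character(1))
}

# Ground-truth (latency, errors) table of a cohort, labeled by the classifier.
truth_features <- function(cohort, cutoff = 60) {
  lat <- vapply(cohort, function(r)
    if (r$truth$escaped) r$truth$escape_time_s else cutoff, numeric(1))
  err <- vapply(cohort, function(r) r$truth$n_errors, numeric(1))
  data.frame(
    subject_id = vapply(cohort, function(r) r$trial$subject_id, ""),
    trial_index = vapply(cohort, function(r) r$trial$trial_index, 0L),
    policy = vapply(cohort, function(r) r$truth$policy, ""),
    latency_s = lat, n_errors = err,
    label = classify_trial(lat, err, cutoff_s = cutoff))
}
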