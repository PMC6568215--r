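# Escape-strategy classification (spatial / chain / futile) and strategy-use
# trend analysis.

#' Classify an escape strategy from latency and error count
#'
#' A trial that reaches the cutoff (censored, the animal never escaped) is
#' `futile` regardless of its error count; otherwise the trial is `spatial`
#' when the number of decoy-inspection errors is at most `error_threshold`
#' and `chain` when it exceeds it.
#'
#' @param latency_s Escape latency (s), vectorized; censored trials carry the
#'   cutoff value.
#' @param n_errors Decoy inspection count, vectorized. `NA` (degraded track)
#'   yields `NA` for sub-cutoff trials rather than a silent label.
#' @param cutoff_s Trial cutoff (default 60 s).
#' @param error_threshold Largest error count still called spatial (default 3).
#' @return Character vector with levels `spatial`, `chain`, `futile`.
#' @export
classify_trial <- function(latency_s, n_errors, cutoff_s = 60,
                           error_threshold = 3) {
  latency_s <- as.numeric(latency_s)
  n_errors <- as.numeric(n_errors)
  if (length(n_errors) == 1L && length(latency_s) > 1L)
    n_errors <- rep(n_errors, length(latency_s))
  if (length(latency_s) == 1L && length(n_errors) > 1L)
    latency_s <- rep(latency_s, length(n_errors))
  if (length(latency_s) != length(n_errors))
    stop_validation("latency_s and n_errors lengths differ")
  if (any(latency_s <= 0 | latency_s > cutoff_s + 1e-9, na.rm = TRUE))
    stop_validation("latency_s must lie in (0, cutoff_s]")
  if (any(n_errors < 0, na.rm = TRUE))
    stop_validation("n_errors must be >= 0")
  futile <- latency_s >= cutoff_s - 1e-9
  out <- ifelse(futile, "futile",
                ifelse(n_errors <= error_threshold, "spatial", "chain"))
  out[!futile & is.na(n_errors)] <- NA_character_
  out
}

#' Subjects x trials strategy matrix
#'
#' @param labels Character vector of strategy labels.
#' @param subject_id,trial_index Parallel vectors identifying each label.
#' @return Object of class `cm_strategy_matrix`: a character matrix (rows =
#'   subjects, columns = trial indices).
#' @export
strategy_matrix <- function(labels, subject_id, trial_index) {
  if (length(labels) != length(subject_id) ||
      length(labels) != length(trial_index))
    stop_validation("labels, subject_id and trial_index lengths differ")
  subj <- sort(unique(as.character(subject_id)))
  trials <- sort(unique(as.integer(trial_index)))
  m <- matrix(NA_character_, length(subj), length(trials),
              dimnames = list(subj, as.character(trials)))
  m[cbind(match(as.character(subject_id), subj),
          match(as.integer(trial_index), trials))] <- labels
  structure(m, class = c("cm_strategy_matrix", "matrix"))
}

#' Write a strategy matrix as a delimited table
#' @param m A `cm_strategy_matrix`.
#' @param path Output path.
#' @export
write_strategy_matrix <- function(m, path) {
  df <- data.frame(subject_id = rownames(m), unclass(m),
                   check.names = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Trend in spatial-strategy use across trials
#'
#' Computes the fraction of subjects labeled `spatial` at each trial index,
#' fits an ordinary least-squares line over (trial, fraction) and reports the
#' Spearman rank correlation of the same pairs.
#'
#' @param m A [strategy_matrix()] (or plain character matrix, subjects x
#'   trials).
#' @return Object of class `cm_trend`: list with `trial`, `spatial_fraction`,
#'   `slope`, `intercept`, `rho`.
#' @export
spatial_use_trend <- function(m) {
  if (!is.matrix(m)) stop_validation("expected a subjects x trials matrix")
  if (ncol(m) < 2L || nrow(m) < 1L)
    stop_validation("need at least 2 trials and 1 subject")
  frac <- apply(m, 2, function(col) {
    ok <- !is.na(col)
    if (!any(ok)) return(NA_real_)
    mean(col[ok] == "spatial")
  })
  trial <- as.integer(colnames(m) %||% seq_len(ncol(m)))
  if (anyNA(trial)) trial <- seq_len(ncol(m))
  ok <- !is.na(frac)
  fit <- stats::lm.fit(cbind(1, trial[ok]), frac[ok])
  rho <- if (length(unique(frac[ok])) < 2L) NA_real_ else
    spearman_rho(trial[ok], frac[ok])
  structure(list(trial = trial, spatial_fraction = unname(frac),
                 slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 rho = rho),
            class = "cm_trend")
}

#' @export
print.cm_trend <- function(x, ...) {
  cat(sprintf("<cm_trend: slope %.4f / trial, rho %s over %d trials>\n",
              x$slope,
              if (is.na(x$rho)) "NA" else sprintf("%.3f", x$rho),
              length(x$trial)))
  invisible(x)
}
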