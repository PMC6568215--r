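# From-scratch CART classifier (Gini impurity, axis-aligned binary splits)
# and the feature-ablation harness used to validate escape latency and error
# count as strategy predictors.

CART_FEATURES <- c("latency_s", "n_errors", "rotations", "distance_cm",
                   "heading_to_exit_deg", "meander_turns", "mean_speed_cm_s")

#' Fit a CART classification tree
#'
#' Greedy binary splitting that minimizes weighted Gini impurity. Candidate
#' thresholds are the midpoints between consecutive sorted unique feature
#' values; ties between equally good splits are broken by the
#' lexicographically lowest feature name, then the lowest threshold, so the
#' fit is deterministic. No pruning: `max_depth` and `min_leaf` are the only
#' regularizers.
#'
#' @param data Data frame of numeric features (rows = trials).
#' @param labels Class label per row (character or factor).
#' @param feature_subset Features to consider (default: all numeric columns
#'   of `data` drawn from the canonical feature set).
#' @param max_depth Maximum tree depth (root = depth 0).
#' @param min_leaf Minimum number of rows in a leaf.
#' @return Object of class `cm_tree`.
#' @export
fit_cart <- function(data, labels, feature_subset = NULL, max_depth = 5,
                     min_leaf = 5) {
  data <- as.data.frame(data)
  labels <- as.character(labels)
  if (nrow(data) != length(labels))
    stop_validation("data and labels lengths differ")
  if (is.null(feature_subset))
    feature_subset <- intersect(CART_FEATURES, names(data))
  feature_subset <- sort(unique(feature_subset))
  if (!length(feature_subset))
    stop_validation("feature_subset must name at least one feature")
  miss <- setdiff(feature_subset, names(data))
  if (length(miss))
    stop_validation("features not in data: %s", paste(miss, collapse = ", "))
  if (nrow(data) < min_leaf)
    stop_validation("need at least min_leaf = %d rows", min_leaf)
  X <- as.matrix(data[feature_subset])
  if (anyNA(X) || any(!is.finite(X)))
    stop_validation("features must be finite and non-missing")
  classes <- sort(unique(labels))
  y <- match(labels, classes)
  node <- grow_node(X, y, classes, depth = 0L,
                    max_depth = max_depth, min_leaf = min_leaf)
  structure(list(root = node, classes = classes, features = feature_subset),
            class = "cm_tree")
}

gini_from_counts <- function(cnt) {
  n <- sum(cnt)
  if (n == 0) return(0)
  1 - sum((cnt / n)^2)
}

make_leaf <- function(y, classes) {
  cnt <- tabulate(y, nbins = length(classes))
  lab <- classes[which.max(cnt)]  # ties: first (alphabetically lowest) class
  list(leaf = TRUE, class = lab, counts = stats::setNames(cnt, classes))
}

grow_node <- function(X, y, classes, depth, max_depth, min_leaf) {
  n <- length(y)
  if (depth >= max_depth || n < 2 * min_leaf || length(unique(y)) == 1L)
    return(make_leaf(y, classes))
  best <- find_best_split(X, y, length(classes), min_leaf)
  if (is.null(best)) return(make_leaf(y, classes))
  go_left <- X[, best$j] <= best$threshold
  list(leaf = FALSE,
       feature = colnames(X)[best$j],
       threshold = best$threshold,
       left = grow_node(X[go_left, , drop = FALSE], y[go_left], classes,
                        depth + 1L, max_depth, min_leaf),
       right = grow_node(X[!go_left, , drop = FALSE], y[!go_left], classes,
                         depth + 1L, max_depth, min_leaf))
}

# Vectorized search over all features and midpoint thresholds.
# Returns list(j, threshold) or NULL when no split improves impurity.
find_best_split <- function(X, y, n_classes, min_leaf) {
  n <- length(y)
  parent <- gini_from_counts(tabulate(y, nbins = n_classes))
  best <- NULL
  best_score <- parent - 1e-12
  for (j in seq_len(ncol(X))) {      # columns already in sorted name order
    x <- X[, j]
    o <- order(x, method = "radix")
    xs <- x[o]; ys <- y[o]
    # cumulative class counts after each sorted row
    cum <- matrix(0, n, n_classes)
    cum[cbind(seq_len(n), ys)] <- 1
    cum <- apply(cum, 2, cumsum)
    tot <- cum[n, ]
    # split after position i (left = rows 1..i) only where value changes
    i <- which(diff(xs) > 0)
    i <- i[i >= min_leaf & (n - i) >= min_leaf]
    if (!length(i)) next
    nl <- i; nr <- n - i
    gl <- 1 - rowSums((cum[i, , drop = FALSE] / nl)^2)
    right_cnt <- matrix(tot, length(i), n_classes, byrow = TRUE) -
      cum[i, , drop = FALSE]
    gr <- 1 - rowSums((right_cnt / nr)^2)
    score <- (nl * gl + nr * gr) / n
    k <- which.min(score)            # which.min -> lowest threshold on ties
    if (score[k] < best_score - 1e-12) {
      best_score <- score[k]
      best <- list(j = j, threshold = (xs[i[k]] + xs[i[k] + 1]) / 2)
    }
  }
  best
}

#' Predict classes from a fitted CART tree
#' @param object A `cm_tree`.
#' @param newdata Data frame containing the tree's features.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.cm_tree <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  miss <- setdiff(object$features, names(newdata))
  if (length(miss))
    stop_validation("newdata missing feature(s): %s",
                    paste(miss, collapse = ", "))
  vapply(seq_len(nrow(newdata)), function(i) {
    node <- object$root
    while (!node$leaf) {
      node <- if (newdata[[node$feature]][i] <= node$threshold) node$left
              else node$right
    }
    node$class
  }, character(1))
}

#' Misclassification rate of a tree on labeled data
#' @param tree A `cm_tree`.
#' @param data Feature data frame.
#' @param labels True labels.
#' @return Fraction of mismatched predictions in `[0, 1]`.
#' @export
misclassification <- function(tree, data, labels) {
  mean(predict(tree, data) != as.character(labels))
}

#' Classes a tree can ever predict (its leaf labels)
#' @param tree A `cm_tree`.
#' @return Character vector of reachable leaf classes.
#' @export
predicted_classes <- function(tree) {
  walk <- function(node) {
    if (node$leaf) return(node$class)
    c(walk(node$left), walk(node$right))
  }
  sort(unique(walk(tree$root)))
}

#' Feature-ablation study
#'
#' Refits the tree with feature sets excluded and records the resulting
#' misclassification rate and whether the `futile` class remains predictable.
#' The default exclusion ladder is: nothing excluded; errors excluded;
#' latency excluded; both excluded.
#'
#' @param data Feature data frame (canonical feature columns).
#' @param labels Strategy label per row.
#' @param exclusions List of character vectors of features to drop
#'   (`character(0)` = full model).
#' @param max_depth,min_leaf Passed to [fit_cart()].
#' @param k_fold Optional integer: additionally report seeded k-fold
#'   cross-validated misclassification.
#' @param seed Seed for the k-fold partition.
#' @return `data.frame` of class `cm_ablation` with columns `excluded`,
#'   `n_features`, `misclassification`, `cv_misclassification` (if requested),
#'   `predicts_futile`, `predicted_classes`.
#' @export
ablation_study <- function(data, labels,
                           exclusions = list(character(0),
                                             "n_errors",
                                             "latency_s",
                                             c("latency_s", "n_errors")),
                           max_depth = 5, min_leaf = 5,
                           k_fold = NULL, seed = 1L) {
  data <- as.data.frame(data)
  feats_all <- intersect(CART_FEATURES, names(data))
  rows <- lapply(exclusions, function(ex) {
    keep <- setdiff(feats_all, ex)
    if (!length(keep))
      stop_validation("exclusion removes every feature")
    tree <- fit_cart(data, labels, feature_subset = keep,
                     max_depth = max_depth, min_leaf = min_leaf)
    pc <- predicted_classes(tree)
    row <- data.frame(
      excluded = if (length(ex)) paste(sort(ex), collapse = "+") else "none",
      n_features = length(keep),
      misclassification = misclassification(tree, data, labels),
      predicts_futile = "futile" %in% pc,
      predicted_classes = paste(pc, collapse = "+"),
      stringsAsFactors = FALSE)
    if (!is.null(k_fold)) {
      row$cv_misclassification <-
        cv_misclassification(data, labels, keep, k_fold, seed,
                             max_depth, min_leaf)
    }
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cm_ablation", "data.frame")
  out
}

cv_misclassification <- function(data, labels, features, k, seed,
                                 max_depth, min_leaf) {
  n <- nrow(data)
  set.seed(substream_seed(seed, "cv", k))
  fold <- sample(rep_len(seq_len(k), n))
  errs <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    tree <- fit_cart(data[tr, , drop = FALSE], labels[tr],
                     feature_subset = features,
                     max_depth = max_depth, min_leaf = min_leaf)
    sum(predict(tree, data[!tr, , drop = FALSE]) != labels[!tr])
  }, numeric(1))
  sum(errs) / n
}

#' Serialize a tree to an indented plain-text structure
#' @param x A `cm_tree`.
#' @param ... Unused.
#' @return Character vector of lines.
#' @export
format.cm_tree <- function(x, ...) {
  walk <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$leaf) {
      cnt <- paste(sprintf("%s=%d", names(node$counts), node$counts),
                   collapse = " ")
      return(sprintf("%sleaf %s [%s]", pad, node$class, cnt))
    }
    c(sprintf("%ssplit %s <= %.6g", pad, node$feature, node$threshold),
      walk(node$left, indent + 1L),
      walk(node$right, indent + 1L))
  }
  walk(x$root, 0L)
}

#' @export
print.cm_tree <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}
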