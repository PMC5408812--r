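## Grid-search threshold calibration, test evaluation, window-based K-fold
## cross-validation, ROC-like threshold sweeps and learning curves.

labels_in_windows <- function(labels, window_ids) {
  labels[labels$window_id %in% window_ids]
}

#' Train a peak detector by grid search over its significance threshold
#'
#' Evaluates the total label error at every threshold of the call set's grid
#' and returns the minimizer. Among thresholds attaining the minimal error
#' the *largest* is chosen: the most conservative (fewest-peak) model, since
#' over-calling is the characteristic failure mode of untrained thresholds.
#'
#' @param call_set a [call_set()] with one sample's calls per threshold.
#' @param train_labels label table of the training windows.
#' @param sample_groups optional sample id -> group mapping.
#' @return a `TrainedModel` list: `algorithm`, `chosen_threshold` (the
#'   error-minimizing threshold), `train_error` (its one-row summary) and
#'   `per_threshold_errors` (`data.table` with one row per grid threshold).
#' @export
train <- function(call_set, train_labels, sample_groups = NULL) {
  if (!nrow(train_labels)) stop("no training labels")
  profile <- rbindlist(lapply(call_set$thresholds, function(lam) {
    s <- total_error(calls_at(call_set, lam), train_labels, sample_groups)
    data.table(threshold = lam, s)
  }))
  best <- profile$errors == min(profile$errors)
  chosen <- max(profile$threshold[best])
  structure(list(algorithm = call_set$algorithm,
                 chosen_threshold = chosen,
                 train_error = profile[abs(profile$threshold - chosen) < 1e-9,
                                       !"threshold"],
                 per_threshold_errors = profile),
            class = "TrainedModel")
}

#' @export
print.TrainedModel <- function(x, ...) {
  cat(sprintf("TrainedModel '%s': chosen threshold %g, training error %d/%d (%.1f%%)\n",
              x$algorithm, x$chosen_threshold, x$train_error$errors,
              x$train_error$n_labels, x$train_error$percent_error))
  invisible(x)
}

#' Evaluate a threshold on held-out labels
#'
#' @param call_set a [call_set()].
#' @param lambda a threshold on the call set's grid (no interpolation;
#'   anything else is an error).
#' @param test_labels label table of the test windows.
#' @param sample_groups optional sample id -> group mapping.
#' @return one-row error summary (see [total_error()]).
#' @export
evaluate <- function(call_set, lambda, test_labels, sample_groups = NULL) {
  total_error(calls_at(call_set, lambda), test_labels, sample_groups)
}

#' Randomly assign labeled windows to folds
#'
#' Seeded shuffle followed by round-robin assignment, so fold sizes differ
#' by at most one and the result is deterministic given the window order,
#' `k` and `seed`. Windows -- not labels or samples -- are the resampling
#' unit, because each window was labeled independently while labels within a
#' window are not independent.
#'
#' @param windows a label table or a [window_table()]; only the distinct
#'   `window_id` values are used.
#' @param k number of folds (>= 2).
#' @param seed integer RNG seed.
#' @return a `FoldAssignment` list: `k`, `seed` and `assignment`, a named
#'   integer vector mapping window id to fold in `1..k`.
#' @export
assign_folds <- function(windows, k, seed) {
  ids <- unique(windows$window_id)
  if (k < 2L) stop("k must be >= 2")
  if (length(ids) < k)
    stop("fewer windows (", length(ids), ") than folds (", k, ")")
  shuffled <- with_seed(seed, sample(ids))
  fold <- rep(seq_len(k), length.out = length(shuffled))
  assignment <- stats::setNames(fold, shuffled)[as.character(ids)]
  names(assignment) <- ids
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 assignment = assignment),
            class = "FoldAssignment")
}

## evaluate a seeded expression without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Window-based K-fold cross-validation of trained vs default thresholds
#'
#' For each fold, trains on the labels of all other folds and evaluates both
#' the trained threshold and (when the call set has one) the default
#' threshold on the held-out fold.
#'
#' @param call_set a [call_set()].
#' @param labels label table covering the windows.
#' @param k number of folds.
#' @param seed RNG seed for the fold assignment.
#' @param sample_groups optional sample id -> group mapping.
#' @param compare_default evaluate the call set's default threshold too
#'   (requires `call_set$default_threshold`).
#' @return list with `folds` (a `FoldAssignment`), `per_fold` (`data.table`:
#'   fold, model `trained`/`default`, threshold, fp_total, fn_total, errors,
#'   n_labels, percent_error) and `summary` (mean and sample standard
#'   deviation of percent error per model).
#' @export
cross_validate <- function(call_set, labels, k = 4L, seed = 1L,
                           sample_groups = NULL, compare_default = TRUE) {
  if (compare_default && is.null(call_set$default_threshold))
    stop("call set has no default threshold; use compare_default = FALSE")
  folds <- assign_folds(labels, k, seed)
  per_fold <- rbindlist(lapply(seq_len(folds$k), function(f) {
    test_ids <- as.integer(names(folds$assignment))[folds$assignment == f]
    train_ids <- setdiff(unique(labels$window_id), test_ids)
    fit <- train(call_set, labels_in_windows(labels, train_ids), sample_groups)
    rows <- data.table(fold = f, model = "trained",
                       threshold = fit$chosen_threshold,
                       evaluate(call_set, fit$chosen_threshold,
                                labels_in_windows(labels, test_ids),
                                sample_groups))
    if (compare_default) {
      rows <- rbind(rows, data.table(
        fold = f, model = "default", threshold = call_set$default_threshold,
        evaluate(call_set, call_set$default_threshold,
                 labels_in_windows(labels, test_ids), sample_groups)))
    }
    rows
  }))
  summary <- per_fold[, list(mean_percent_error = mean(percent_error),
                             sd_percent_error = stats::sd(percent_error)),
                      by = model]
  list(folds = folds, per_fold = per_fold, summary = summary)
}

#' ROC-like curve over the threshold grid
#'
#' For each threshold: the true positive rate is the fraction of positive
#' labels (`peaks`, `peakStart`, `peakEnd`) not scored a false negative, and
#' the false positive rate is the fraction of false-positive-capable labels
#' (`noPeaks`, `peakStart`, `peakEnd`) scored a false positive. `peaks`
#' labels are excluded from the false-positive denominator because the error
#' rules never charge them a false positive, so including them would make
#' fpr = 1 unattainable. "ROC-like" is deliberate: the two denominators are
#' different label subsets, unlike a classical per-instance ROC.
#'
#' @param call_set a [call_set()].
#' @param labels label table.
#' @param sample_groups optional sample id -> group mapping.
#' @return `RocCurve`: `data.table` with one row per threshold (threshold,
#'   tpr, fpr, plus the fp/fn totals), ordered by threshold.
#' @export
roc_like_curve <- function(call_set, labels, sample_groups = NULL) {
  points <- rbindlist(lapply(call_set$thresholds, function(lam) {
    res <- label_error(calls_at(call_set, lam), labels, sample_groups)
    n_pos <- sum(res$type %in% c("peaks", "peakStart", "peakEnd"))
    n_fpc <- sum(res$type %in% c("noPeaks", "peakStart", "peakEnd"))
    if (n_pos == 0L)
      stop("no positive labels: true positive rate undefined")
    if (n_fpc == 0L)
      stop("no false-positive-capable labels: false positive rate undefined")
    data.table(threshold = lam,
               tpr = 1 - sum(res$fn) / n_pos,
               fpr = sum(res$fp) / n_fpc,
               fp_total = sum(res$fp), fn_total = sum(res$fn),
               n_positive = n_pos, n_fp_capable = n_fpc)
  }))
  structure(points, class = c("RocCurve", class(points)))
}

#' Learning curve: test error versus number of labeled training windows
#'
#' Fixes one fold as the test set, then trains on growing prefixes of a
#' random ordering of the remaining windows -- nested training sets, so each
#' size adds one window to the previous. Size 0 uses the call set's default
#' threshold (the no-label model). Several random orderings give a mean line
#' and a min/max band.
#'
#' @param call_set a [call_set()].
#' @param labels label table.
#' @param folds a `FoldAssignment` from [assign_folds()].
#' @param test_fold which fold is the fixed test set.
#' @param max_train largest training-set size (defaults to all training
#'   windows).
#' @param n_orders number of random orderings (>= 1).
#' @param seed RNG seed; ordering `o` uses `seed + o`.
#' @param sample_groups optional sample id -> group mapping.
#' @return list with `per_order` (`data.table`: order, n_windows_trained,
#'   threshold, percent_error, ...) and `curve` (`data.table`:
#'   n_windows_trained, mean/min/max percent error across orderings).
#' @export
learning_curve <- function(call_set, labels, folds, test_fold,
                           max_train = NULL, n_orders = 2L, seed = 1L,
                           sample_groups = NULL) {
  if (n_orders < 1L) stop("n_orders must be >= 1")
  ids <- as.integer(names(folds$assignment))
  test_ids <- ids[folds$assignment == test_fold]
  if (!length(test_ids)) stop("test fold ", test_fold, " is empty")
  pool <- ids[folds$assignment != test_fold]
  if (is.null(max_train)) max_train <- length(pool)
  if (max_train > length(pool))
    stop("max_train (", max_train, ") exceeds the ", length(pool),
         " training windows")
  if (is.null(call_set$default_threshold))
    stop("learning curves start at size 0, which needs a default threshold")
  test_labels <- labels_in_windows(labels, test_ids)
  per_order <- rbindlist(lapply(seq_len(n_orders), function(o) {
    ordering <- with_seed(seed + o, sample(pool))
    rbindlist(lapply(0:max_train, function(s) {
      if (s == 0L) {
        lam <- call_set$default_threshold
      } else {
        fit <- train(call_set, labels_in_windows(labels, ordering[seq_len(s)]),
                     sample_groups)
        lam <- fit$chosen_threshold
      }
      data.table(order = o, n_windows_trained = s, threshold = lam,
                 evaluate(call_set, lam, test_labels, sample_groups))
    }))
  }))
  curve <- per_order[, list(mean_percent_error = mean(percent_error),
                            min_percent_error = min(percent_error),
                            max_percent_error = max(percent_error)),
                     by = n_windows_trained]
  list(per_order = per_order, curve = curve)
}
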