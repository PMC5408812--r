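#' Configuration of the built-in thresholding peak caller
#'
#' The built-in caller smooths the coverage with a centered moving average,
#' marks bases whose smoothed value reaches the significance threshold
#' lambda, bridges marked runs separated by at most `max_gap` bases, and
#' drops runs shorter than `min_peak_width`. It exists to provide a real
#' one-parameter peak-calling family c_lambda so training and evaluation can
#' be exercised end to end; it is deliberately simple, not a replacement for
#' a production caller.
#'
#' @param bandwidth moving-average window width in bases (>= 1; 1 = no
#'   smoothing). At chromosome edges the window is truncated and the mean
#'   taken over the bases actually covered.
#' @param min_peak_width minimum called-peak width in bases (>= 1).
#' @param max_gap marked runs separated by <= this many bases are merged
#'   (>= 0).
#' @return a `CallerConfig` list.
#' @export
caller_config <- function(bandwidth = 1L, min_peak_width = 1L, max_gap = 0L) {
  bandwidth <- as.integer(bandwidth)
  min_peak_width <- as.integer(min_peak_width)
  max_gap <- as.integer(max_gap)
  if (is.na(bandwidth) || bandwidth < 1L) stop("bandwidth must be a positive integer")
  if (is.na(min_peak_width) || min_peak_width < 1L)
    stop("min_peak_width must be a positive integer")
  if (is.na(max_gap) || max_gap < 0L) stop("max_gap must be >= 0")
  structure(list(bandwidth = bandwidth, min_peak_width = min_peak_width,
                 max_gap = max_gap), class = "CallerConfig")
}

## centered moving average with edge truncation, O(b) via cumulative sums
smooth_counts <- function(x, bandwidth) {
  n <- length(x)
  if (bandwidth <= 1L || n == 0L) return(as.numeric(x))
  h1 <- (bandwidth - 1L) %/% 2L
  h2 <- bandwidth - 1L - h1
  cs <- cumsum(c(0, as.numeric(x)))
  i <- seq_len(n)
  lo <- pmax(i - h1, 1L)
  hi <- pmin(i + h2, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

call_peaks_smoothed <- function(smoothed, lambda, config, chrom, sample_id) {
  marked <- as.integer(smoothed >= lambda)
  runs <- peaks_from_binary(if (length(marked)) marked else 0L, chrom)
  if (nrow(runs) > 1L && config$max_gap > 0L) {
    gap_ok <- runs$start[-1L] - runs$end[-nrow(runs)] <= config$max_gap
    grp <- cumsum(c(TRUE, !gap_ok))
    runs <- runs[, list(chrom = chrom[1L], start = min(start), end = max(end)),
                 by = grp][, grp := NULL]
  }
  runs <- runs[runs$end - runs$start >= config$min_peak_width]
  peak_calls(runs, sample_id)
}

#' Call peaks on a coverage profile at one threshold
#'
#' @param profile a [coverage_profile()].
#' @param lambda significance threshold (>= 0); bases whose smoothed
#'   coverage is `>= lambda` are marked. Low thresholds yield too many
#'   peaks, high thresholds too few.
#' @param config a [caller_config()].
#' @return a [peak_calls()] object for `profile$sample_id`.
#' @examples
#' prof <- coverage_profile(data.frame(start = 50, end = 100, count = 10),
#'                          b = 150)
#' call_peaks(prof, lambda = 5) # single peak [50, 100)
#' @export
call_peaks <- function(profile, lambda, config = caller_config()) {
  if (lambda < 0) stop("lambda must be >= 0")
  smoothed <- smooth_counts(coverage_vector(profile), config$bandwidth)
  call_peaks_smoothed(smoothed, lambda, config, profile$chrom, profile$sample_id)
}

#' Linear threshold grid covering the dynamic range of a profile set
#'
#' The grid spans `[0, M + 1]` where `M` is the maximum smoothed coverage
#' over all profiles, so its extremes are guaranteed to call every nonzero
#' plateau (lambda = 0 marks everything with coverage, modulo the width
#' filter) and nothing at all (lambda = M + 1 exceeds every smoothed value).
#'
#' @param profiles list of [coverage_profile()] objects.
#' @param n_points number of grid points (>= 2).
#' @param config [caller_config()] whose bandwidth defines "smoothed";
#'   defaults to no smoothing.
#' @return strictly increasing numeric vector of length `n_points`.
#' @export
threshold_grid <- function(profiles, n_points, config = caller_config()) {
  if (!length(profiles)) stop("empty profile set")
  if (n_points < 2L) stop("n_points must be >= 2")
  M <- max(vapply(profiles, function(p) {
    v <- smooth_counts(coverage_vector(p), config$bandwidth)
    if (length(v)) max(v) else 0
  }, 0))
  seq(0, M + 1, length.out = n_points)
}

#' Naive default threshold: the global mean coverage
#'
#' A deliberately label-free default, playing the role of the significance
#' threshold an algorithm's author might suggest. Because the mean sits just
#' above background whenever peaks occupy a minority of the genome, this
#' default tends to over-call, which is exactly the failure mode supervised
#' calibration is meant to fix.
#'
#' @param profiles list of [coverage_profile()] objects.
#' @return mean count per base over all profiles.
#' @export
default_threshold <- function(profiles) {
  if (!length(profiles)) stop("empty profile set")
  tot <- sum(vapply(profiles, function(p)
    sum(as.numeric(p$runs$count) * (p$runs$end - p$runs$start)), 0))
  bases <- sum(vapply(profiles, function(p) as.numeric(p$b), 0))
  if (bases == 0) stop("profiles cover zero bases")
  tot / bases
}

#' Run the built-in caller over a whole threshold grid
#'
#' Smooths each profile once and thresholds the smoothed signal at every
#' grid value, producing the thresholded call-set family used for training.
#' If `default_lambda` is given and absent from the grid it is inserted (the
#' grid stays strictly increasing).
#'
#' @param profiles named list of [coverage_profile()] keyed by sample id.
#' @param thresholds increasing numeric grid.
#' @param config a [caller_config()].
#' @param default_lambda optional default threshold to flag.
#' @param algorithm name recorded in the call set.
#' @return a [call_set()].
#' @export
build_call_set <- function(profiles, thresholds, config = caller_config(),
                           default_lambda = NULL,
                           algorithm = "threshold_caller") {
  if (is.null(names(profiles)) || any(!nzchar(names(profiles))))
    stop("profiles must be a named list keyed by sample id")
  if (!is.null(default_lambda) &&
      !any(abs(thresholds - default_lambda) < 1e-9)) {
    thresholds <- sort(c(thresholds, default_lambda))
  }
  smoothed <- lapply(profiles, function(p)
    smooth_counts(coverage_vector(p), config$bandwidth))
  calls <- list()
  for (lam in thresholds) {
    calls[[as.character(lam)]] <- mapply(function(sm, p) {
      call_peaks_smoothed(sm, lam, config, p$chrom, p$sample_id)
    }, smoothed, profiles, SIMPLIFY = FALSE)
  }
  call_set(algorithm, thresholds, calls, default_lambda)
}
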