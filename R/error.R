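#' Per-label error status of one sample's peak calls
#'
#' Scores a single label against one sample's predicted peaks. With
#' `k` the observed count (overlapping peaks, or in-region boundaries):
#'
#' * `noPeaks`: k = peaks overlapping the region; false positive iff k >= 1;
#'   never a false negative (the label asserts absence only).
#' * `peaks`: k = peaks overlapping the region; false negative iff k = 0;
#'   never a false positive (one *or more* overlapping peaks is acceptable).
#' * `peakStart`: k = peaks whose start lies in `[start, end)`; false
#'   negative iff k = 0, false positive iff k > 1 (exactly one visible start).
#' * `peakEnd`: k = peaks whose end coordinate lies in `(start, end]`; same
#'   rule. The end coordinate is exclusive, so a peak ending exactly at the
#'   region's end has its last covered base inside the region and counts.
#'
#' A peak spanning the whole of a `peakStart`/`peakEnd` region contributes no
#' boundary, so such a label is a false negative: the region demands a
#' visible boundary. Each label contributes at most one error, so
#' `fp + fn <= 1` and the total error over a label set lies in `{0, ..., |L|}`.
#'
#' @param label one-row label table (see [label_table()]).
#' @param calls a [peak_calls()] object (sorted, disjoint, non-abutting).
#' @return one-row `data.table`: chrom, start, end, type, sample_id,
#'   observed (the count k), fp, fn (each 0/1) and status
#'   (`correct`, `false-positive` or `false-negative`).
#' @export
label_error_one <- function(label, calls) {
  stopifnot(nrow(label) == 1L)
  score_labels(label, calls, attr(calls, "sample_id"))
}

## vectorized scoring of many labels against one sample's calls.
## Peaks are sorted and disjoint, so boundary/overlap counts reduce to
## rank queries on the sorted start and end coordinate vectors:
##   #(p.start <  e) - #(p.end <= s)  peaks overlapping [s, e)
##   #(s <= p.start < e)              peak starts inside the region
##   #(s <  p.end  <= e)              peak ends inside (s, e]
## (+-0.5 turns the strict/weak integer inequalities into findInterval calls)
score_labels <- function(labels, calls, sample_id) {
  n <- nrow(labels)
  observed <- integer(n)
  for (ch in unique(labels$chrom)) {
    li <- which(labels$chrom == ch)
    p <- calls[calls$chrom == ch]
    ps <- as.numeric(p$start)
    pe <- as.numeric(p$end)
    s <- labels$start[li]
    e <- labels$end[li]
    type <- labels$type[li]
    k <- integer(length(li))
    ov <- type %in% c("noPeaks", "peaks")
    if (any(ov))
      k[ov] <- findInterval(e[ov] - 0.5, ps) - findInterval(s[ov] + 0.5, pe)
    st <- type == "peakStart"
    if (any(st))
      k[st] <- findInterval(e[st] - 0.5, ps) - findInterval(s[st] - 0.5, ps)
    en <- type == "peakEnd"
    if (any(en))
      k[en] <- findInterval(e[en] + 0.5, pe) - findInterval(s[en] + 0.5, pe)
    observed[li] <- k
  }
  fp <- as.integer((labels$type == "noPeaks" & observed >= 1L) |
                   (labels$type %in% c("peakStart", "peakEnd") & observed > 1L))
  fn <- as.integer(labels$type != "noPeaks" & observed == 0L)
  data.table(chrom = labels$chrom, start = labels$start, end = labels$end,
             type = labels$type, window_id = labels$window_id,
             sample_id = sample_id,
             observed = observed, fp = fp, fn = fn,
             status = ifelse(fp == 1L, "false-positive",
                             ifelse(fn == 1L, "false-negative", "correct")))
}

#' Score every (label, applicable sample) pair
#'
#' A label whose groups field resolves to g samples contributes g rows: the
#' same region labeled on 27 samples is 27 labels for error-counting
#' purposes.
#'
#' @param calls_by_sample named list of [peak_calls()], keyed by sample id.
#' @param labels a label table.
#' @param sample_groups optional named character vector mapping sample id to
#'   group; required when any label restricts to groups.
#' @return `data.table` of per-(label, sample) results; see
#'   [label_error_one()] for columns.
#' @export
label_error <- function(calls_by_sample, labels, sample_groups = NULL) {
  all_samples <- names(calls_by_sample)
  if (is.null(all_samples) || any(!nzchar(all_samples)))
    stop("calls_by_sample must be a named list keyed by sample id")
  ## expand each label to the samples it applies to, then score per sample
  sample_sets <- lapply(labels$groups, label_samples, all_samples, sample_groups)
  empty <- which(!vapply(sample_sets, length, 0L))
  if (length(empty)) {
    i <- empty[[1L]]
    stop("label ", labels$chrom[i], ":", labels$start[i], "-", labels$end[i],
         " (groups '", labels$groups[i], "') applies to no scored sample")
  }
  row_idx <- rep(seq_len(nrow(labels)), lengths(sample_sets))
  pair_sample <- unlist(sample_sets)
  out <- lapply(all_samples, function(sid) {
    mine <- row_idx[pair_sample == sid]
    if (!length(mine)) return(NULL)
    score_labels(labels[mine], calls_by_sample[[sid]], sid)
  })
  rbindlist(out)
}

summarize_results <- function(results) {
  fp_total <- sum(results$fp)
  fn_total <- sum(results$fn)
  n_labels <- nrow(results)
  errors <- fp_total + fn_total
  data.table(fp_total = fp_total, fn_total = fn_total, errors = errors,
             n_labels = n_labels,
             percent_error = if (n_labels > 0) 100 * errors / n_labels else 0)
}

#' Total label error E = FP + FN
#'
#' Sums per-label false positives and false negatives over every
#' (label, applicable sample) pair. `E` lies between 0 (all labels correct)
#' and `|L|` (all labels incorrect).
#'
#' @inheritParams label_error
#' @return one-row `data.table`: fp_total, fn_total, errors (E), n_labels
#'   (|L|), percent_error (100 E / |L|).
#' @examples
#' calls <- list(s1 = peak_calls(data.frame(chrom = "chr1", start = 150, end = 160),
#'                               "s1"))
#' labs <- label_table("chr1", c(100, 300), c(200, 400), c("noPeaks", "peaks"))
#' total_error(calls, labs) # one false positive, one false negative
#' @export
total_error <- function(calls_by_sample, labels, sample_groups = NULL) {
  summarize_results(label_error(calls_by_sample, labels, sample_groups))
}

#' Partition an error summary by label type
#'
#' @param results per-(label, sample) results from [label_error()].
#' @return `data.table` with one row per label type (all four types always
#'   present; absent types have n_labels = 0) whose fp/fn totals sum to the
#'   global totals.
#' @export
error_by_type <- function(results) {
  out <- rbindlist(lapply(LABEL_TYPES, function(tt) {
    s <- summarize_results(results[results$type == tt])
    data.table(type = tt, s)
  }))
  out
}
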