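#' @importFrom data.table data.table as.data.table setkey setorder := .N .SD rbindlist fread fwrite setnames copy
NULL

LABEL_TYPES <- c("noPeaks", "peaks", "peakStart", "peakEnd")

## all coordinates in this package are 0-based half-open [start, end), as in BED

stop_if_bad_interval <- function(chrom, start, end) {
  if (any(is.na(chrom)) || any(is.na(start)) || any(is.na(end)))
    stop("interval fields must be non-missing")
  if (any(start != floor(start)) || any(end != floor(end)))
    stop("interval coordinates must be integers")
  if (any(start < 0))
    stop("interval start must be >= 0")
  bad <- which(start >= end)
  if (length(bad))
    stop("empty or reversed interval: start >= end at row ", bad[[1]])
  invisible(NULL)
}

#' Do two genomic intervals overlap?
#'
#' Half-open semantics: `[a_start, a_end)` and `[b_start, b_end)` overlap iff
#' their intersection is non-empty, i.e. a single shared base suffices and
#' abutting intervals (`a_end == b_start`) do not overlap. Both intervals must
#' be on the same chromosome; comparing intervals on different chromosomes is
#' an error rather than `FALSE`, because such a comparison is almost always a
#' bookkeeping bug upstream.
#'
#' @param a_chrom,a_start,a_end first interval (chromosome, 0-based start,
#'   exclusive end).
#' @param b_chrom,b_start,b_end second interval.
#' @return `TRUE` if the intervals share at least one base.
#' @examples
#' overlaps("chr1", 100, 200, "chr1", 150, 160) # TRUE
#' overlaps("chr1", 100, 200, "chr1", 200, 300) # FALSE (abutting)
#' @export
overlaps <- function(a_chrom, a_start, a_end, b_chrom, b_start, b_end) {
  stop_if_bad_interval(a_chrom, a_start, a_end)
  stop_if_bad_interval(b_chrom, b_start, b_end)
  if (a_chrom != b_chrom)
    stop("cannot compare intervals on different chromosomes (",
         a_chrom, " vs ", b_chrom, ")")
  max(a_start, b_start) < min(a_end, b_end)
}

#' Maximal runs of 1s in a binary vector, as half-open intervals
#'
#' The inverse of painting peak intervals onto a zero vector: position `i` of
#' `y` (1-based in R) corresponds to base `i - 1`, and each maximal run of 1s
#' becomes one interval `[first_base, last_base + 1)`.
#'
#' @param y binary vector (entries 0/1) over bases `[0, length(y))`.
#' @param chrom chromosome name to attach to the intervals.
#' @return `data.table` with columns chrom, start, end; zero rows if `y` is
#'   all zeros.
#' @examples
#' peaks_from_binary(c(0, 1, 1, 0, 1)) # [1,3) and [4,5)
#' @export
peaks_from_binary <- function(y, chrom = "chr1") {
  if (length(y) < 1L) stop("y must have length >= 1")
  if (any(is.na(y)) || !all(y %in% c(0L, 1L)))
    stop("y must be a binary vector with entries in {0, 1}")
  r <- rle(as.integer(y))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values == 1L
  data.table(chrom = chrom,
             start = as.integer(starts[keep]),
             end = as.integer(ends[keep]))
}

#' Paint intervals onto a zero vector
#'
#' @param peaks `data.table` with columns start, end (one chromosome).
#' @param b number of bases; the result covers `[0, b)`.
#' @return integer 0/1 vector of length `b`.
#' @export
binary_from_peaks <- function(peaks, b) {
  y <- integer(b)
  if (nrow(peaks)) {
    if (any(peaks$end > b)) stop("peak extends beyond [0, b)")
    for (i in seq_len(nrow(peaks))) {
      y[(peaks$start[i] + 1L):peaks$end[i]] <- 1L
    }
  }
  y
}

## merge overlapping OR abutting intervals; input cols chrom,start,end.
## within each chromosome a new merged run begins where start exceeds the
## running maximum of previous ends (equality = abutting = merged)
merge_intervals <- function(dt) {
  if (nrow(dt) < 2L) return(dt)
  dt <- dt[order(chrom, start, end)]
  dt[, grp := {
    cm <- cummax(end)
    cumsum(c(TRUE, start[-1L] > cm[-length(cm)]))
  }, by = chrom]
  out <- dt[, list(start = min(start), end = max(end)), by = list(chrom, grp)]
  out[, grp := NULL]
  out[]
}

#' Construct the peak calls of one sample
#'
#' Peaks are stored as a sorted `data.table` of disjoint, non-abutting
#' half-open intervals -- the maximal-run representation of the binary
#' prediction vector. Overlapping or abutting input intervals are merged on
#' construction (two abutting intervals are indistinguishable from one peak in
#' the binary representation).
#'
#' @param peaks `data.frame` with columns chrom, start, end (extra columns
#'   ignored); may have zero rows.
#' @param sample_id sample identifier.
#' @return an object of class `PeakCalls`: a `data.table` (chrom, start, end)
#'   with attribute `sample_id`.
#' @export
peak_calls <- function(peaks = data.table(chrom = character(), start = integer(),
                                          end = integer()),
                       sample_id = "sample") {
  dt <- as.data.table(peaks)[, list(chrom = as.character(chrom),
                                    start = as.integer(start),
                                    end = as.integer(end))]
  if (nrow(dt)) {
    stop_if_bad_interval(dt$chrom, dt$start, dt$end)
    dt <- merge_intervals(dt)
  }
  setattr(dt, "sample_id", sample_id)
  setattr(dt, "class", c("PeakCalls", class(dt)))
  dt
}

#' @importFrom data.table setattr
#' @export
print.PeakCalls <- function(x, ...) {
  cat(sprintf("PeakCalls for sample %s: %d peak(s)\n",
              attr(x, "sample_id"), nrow(x)))
  NextMethod()
}

sample_id_of <- function(calls) attr(calls, "sample_id")

#' Construct a run-length encoded coverage profile
#'
#' Per-base aligned-read counts over one chromosome, stored as runs of equal
#' value. Gaps between runs are implicit zeros; the profile spans `[0, b)`
#' where `b` is the end of the last run (or a larger explicit `b`).
#'
#' @param runs `data.frame` with columns start, end, count (sorted,
#'   non-overlapping, integer counts >= 0).
#' @param chrom chromosome name.
#' @param sample_id sample identifier.
#' @param b total number of bases; defaults to the end of the last run.
#' @return object of class `CoverageProfile`.
#' @export
coverage_profile <- function(runs, chrom = "chr1", sample_id = "sample", b = NULL) {
  runs <- as.data.table(runs)[, list(start = as.integer(start),
                                     end = as.integer(end),
                                     count = count)]
  if (nrow(runs)) {
    stop_if_bad_interval(rep(chrom, nrow(runs)), runs$start, runs$end)
    if (any(runs$count != floor(runs$count)))
      stop("coverage counts must be integers")
    if (any(runs$count < 0))
      stop("coverage counts must be >= 0")
    runs <- runs[order(start)]
    if (nrow(runs) > 1L && any(runs$start[-1L] < runs$end[-nrow(runs)]))
      stop("coverage runs must not overlap")
    runs[, count := as.integer(count)]
  }
  if (is.null(b)) b <- if (nrow(runs)) max(runs$end) else 0L
  if (nrow(runs) && b < max(runs$end)) stop("b smaller than last run end")
  structure(list(sample_id = sample_id, chrom = chrom,
                 runs = runs, b = as.integer(b)),
            class = "CoverageProfile")
}

#' @export
print.CoverageProfile <- function(x, ...) {
  cat(sprintf("CoverageProfile %s on %s: %d bases, %d runs, total count %.0f\n",
              x$sample_id, x$chrom, x$b, nrow(x$runs),
              sum(as.numeric(x$runs$count) * (x$runs$end - x$runs$start))))
  invisible(x)
}

#' Decompress a coverage profile to a per-base integer vector
#'
#' @param profile a `CoverageProfile`.
#' @return integer vector of length `profile$b`; position `i` holds the count
#'   at base `i - 1`.
#' @export
coverage_vector <- function(profile) {
  r <- profile$runs
  if (!nrow(r)) return(integer(profile$b))
  ## interleave implicit zero gaps (before each run and after the last one)
  gap_len <- c(r$start, profile$b) - c(0L, r$end)
  lens <- c(rbind(gap_len[-length(gap_len)], r$end - r$start),
            gap_len[length(gap_len)])
  vals <- c(rbind(0L, r$count), 0L)
  rep(vals, lens)
}

## inverse of coverage_vector: RLE-compress a per-base vector (zeros kept
## implicit only at the trailing edge; internal zero runs are stored)
rle_runs <- function(x) {
  if (!length(x)) return(data.table(start = integer(), end = integer(), count = integer()))
  r <- rle(as.integer(x))
  ends <- cumsum(r$lengths)
  data.table(start = as.integer(ends - r$lengths), end = as.integer(ends),
             count = r$values)
}
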