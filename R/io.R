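## All files are plain text, tab-separated where tabular, with 0-based
## half-open integer coordinates written back bit-exactly.

## write lines/tables atomically: temp file in the target directory, then rename
write_atomic <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("cannot write ", path)
  invisible(path)
}

parse_error <- function(path, line_no, what) {
  stop(sprintf("%s:%d: %s", path, line_no, what), call. = FALSE)
}

strip_commas <- function(x) gsub(",", "", x, fixed = TRUE)

#' Read a label file
#'
#' Two dialects are accepted and auto-detected:
#'
#' * the browser-style dialect, one label per line as
#'   `chrom:start-end labelType [group ...]` with optional commas in the
#'   numbers (as a genome browser displays positions); consecutive non-blank
#'   lines form one window and blank lines delimit windows;
#' * a plain TSV with header `chrom start end type groups window_id`
#'   (groups comma-separated, empty = all samples).
#'
#' Lines starting with `#` are ignored in both dialects. Windows get
#' sequential ids in the browser dialect. Label constraints are checked via
#' [validate_labels()]: overlap errors abort the read, missing
#' noPeaks/positive labels only warn.
#'
#' @param path label file.
#' @param sample_groups optional sample id -> group mapping forwarded to
#'   [validate_labels()].
#' @return a label table (see [label_table()]).
#' @export
read_labels <- function(path, sample_groups = NULL) {
  if (!file.exists(path)) stop("no such label file: ", path)
  lines <- readLines(path)
  content <- lines[!grepl("^\\s*#", lines)]
  nonblank <- content[nzchar(trimws(content))]
  if (length(nonblank) && grepl("^\\s*chrom\\t", nonblank[[1L]])) {
    dt <- fread(text = content, sep = "\t", header = TRUE,
                colClasses = list(character = "groups"))
    need <- c("chrom", "start", "end", "type", "groups", "window_id")
    if (!all(need %in% names(dt)))
      stop(path, ": label TSV must have columns ", paste(need, collapse = ", "))
    dt[is.na(groups), groups := ""]
    labels <- label_table(dt$chrom, dt$start, dt$end, dt$type, dt$groups,
                          dt$window_id)
  } else {
    rows <- list()
    window <- 1L
    seen_in_window <- FALSE
    for (i in seq_along(lines)) {
      line <- lines[i]
      if (grepl("^\\s*#", line)) next
      if (!nzchar(trimws(line))) {
        if (seen_in_window) { window <- window + 1L; seen_in_window <- FALSE }
        next
      }
      fields <- strsplit(trimws(line), "\\s+")[[1L]]
      m <- regmatches(fields[1L],
                      regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", fields[1L]))[[1L]]
      if (length(m) != 4L)
        parse_error(path, i, paste0("malformed coordinate '", fields[1L],
                                    "' (expected chrom:start-end)"))
      start <- as.integer(strip_commas(m[3L]))
      end <- as.integer(strip_commas(m[4L]))
      if (is.na(start) || is.na(end))
        parse_error(path, i, "non-integer coordinate")
      if (length(fields) < 2L)
        parse_error(path, i, "missing label type")
      type <- fields[2L]
      if (!type %in% LABEL_TYPES)
        parse_error(path, i, paste0("unknown label type '", type, "'"))
      if (start >= end)
        parse_error(path, i, sprintf("start >= end (%d >= %d)", start, end))
      groups <- if (length(fields) > 2L)
        paste(fields[-(1:2)], collapse = ",") else ""
      rows[[length(rows) + 1L]] <- data.table(
        chrom = m[2L], start = start, end = end, type = type,
        groups = groups, window_id = window)
      seen_in_window <- TRUE
    }
    if (!length(rows))
      return(label_table(character(), integer(), integer(), character()))
    dt <- rbindlist(rows)
    labels <- label_table(dt$chrom, dt$start, dt$end, dt$type, dt$groups,
                          dt$window_id)
  }
  report <- validate_labels(labels, sample_groups)
  errs <- report[report$severity == "error"]
  if (nrow(errs))
    stop(path, ": invalid labels:\n", paste(errs$message, collapse = "\n"))
  for (msg in report$message[report$severity == "warning"]) warning(path, ": ", msg)
  labels
}

#' Write labels in the browser-style dialect
#'
#' One label per line (`chrom:start-end type group ...`), blank lines between
#' windows; re-reading with [read_labels()] reproduces the table bit-exactly.
#'
#' @param labels a label table.
#' @param path output file.
#' @export
write_labels <- function(labels, path) {
  write_atomic(path, function(tmp) {
    con <- file(tmp, "w"); on.exit(close(con))
    wids <- unique(labels$window_id)
    for (wi in seq_along(wids)) {
      block <- labels[labels$window_id == wids[wi]]
      for (i in seq_len(nrow(block))) {
        grp <- if (nzchar(block$groups[i]))
          paste0(" ", gsub(",", " ", block$groups[i], fixed = TRUE)) else ""
        writeLines(sprintf("%s:%d-%d %s%s", block$chrom[i], block$start[i],
                           block$end[i], block$type[i], grp), con)
      }
      if (wi < length(wids)) writeLines("", con)
    }
  })
}

#' Read peak calls from a BED3 or narrowPeak file
#'
#' Only the first three columns (chrom, chromStart, chromEnd) are trusted;
#' scores, summits and the other narrowPeak columns are ignored because the
#' label error consumes positions only. Overlapping or abutting intervals are
#' merged and the result sorted, so the object satisfies the maximal-run
#' invariant of [peak_calls()].
#'
#' @param path BED3+/narrowPeak file; an empty file yields empty calls.
#' @param sample_id sample id to attach (defaults to the file name without
#'   extension).
#' @return a [peak_calls()] object.
#' @export
read_peaks <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("no such peak file: ", path)
  if (is.null(sample_id))
    sample_id <- sub("\\.(bed|narrowPeak)$", "", basename(path))
  raw <- readLines(path)
  raw <- raw[nzchar(trimws(raw)) & !grepl("^(#|track|browser)", raw)]
  if (!length(raw)) return(peak_calls(sample_id = sample_id))
  parts <- strsplit(trimws(raw), "\\s+")
  for (i in seq_along(parts)) {
    if (length(parts[[i]]) < 3L)
      parse_error(path, i, "fewer than 3 columns")
    s <- suppressWarnings(as.integer(parts[[i]][2L]))
    e <- suppressWarnings(as.integer(parts[[i]][3L]))
    if (is.na(s) || is.na(e) ||
        parts[[i]][2L] != as.character(s) || parts[[i]][3L] != as.character(e))
      parse_error(path, i, "non-integer coordinates")
    if (s >= e)
      parse_error(path, i, sprintf("chromStart >= chromEnd (%d >= %d)", s, e))
  }
  dt <- data.table(chrom = vapply(parts, `[`, "", 1L),
                   start = as.integer(vapply(parts, `[`, "", 2L)),
                   end = as.integer(vapply(parts, `[`, "", 3L)))
  peak_calls(dt, sample_id)
}

#' Write peak calls as BED3
#'
#' @param calls a [peak_calls()] object.
#' @param path output file.
#' @export
write_peaks <- function(calls, path) {
  write_atomic(path, function(tmp) {
    if (nrow(calls)) {
      fwrite(as.data.table(calls)[, list(chrom, start, end)], tmp,
             sep = "\t", col.names = FALSE)
    } else {
      file.create(tmp)
    }
  })
}

#' Read a coverage profile from a bedGraph file
#'
#' The bedGraph must hold one chromosome with sorted, non-overlapping records
#' and nonnegative integer values (read counts). Gaps between records --
#' including before the first record -- are implicit zeros; the profile spans
#' `[0, b)` with `b` the last record's end.
#'
#' @param path bedGraph file.
#' @param sample_id sample id (defaults to file name without extension).
#' @return a [coverage_profile()].
#' @export
read_coverage <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("no such coverage file: ", path)
  if (is.null(sample_id))
    sample_id <- sub("\\.(bedGraph|bedgraph|bg)$", "", basename(path))
  dt <- fread(path, header = FALSE, sep = "\t",
              colClasses = list(character = 1, numeric = 2:4))
  if (!nrow(dt)) return(coverage_profile(
    data.table(start = integer(), end = integer(), count = integer()),
    chrom = "chr1", sample_id = sample_id))
  setnames(dt, 1:4, c("chrom", "start", "end", "count"))
  if (length(unique(dt$chrom)) > 1L)
    stop(path, ": coverage profiles are per-chromosome; found ",
         length(unique(dt$chrom)), " chromosomes")
  if (any(dt$count != floor(dt$count)))
    stop(path, ": coverage values must be integers (counts of aligned reads)")
  if (any(dt$count < 0))
    stop(path, ": negative coverage value")
  dt <- dt[order(start)]
  if (nrow(dt) > 1L && any(dt$start[-1L] < dt$end[-nrow(dt)]))
    stop(path, ": overlapping bedGraph records")
  coverage_profile(dt[, list(start, end, count)], chrom = dt$chrom[1L],
                   sample_id = sample_id)
}

#' Write a coverage profile as bedGraph
#'
#' Runs are written exactly as stored, zero-count runs included, so
#' write-then-read reproduces the profile (and its length `b`) bit-exactly.
#'
#' @param profile a [coverage_profile()].
#' @param path output file.
#' @export
write_coverage <- function(profile, path) {
  write_atomic(path, function(tmp) {
    r <- profile$runs
    if (nrow(r)) {
      fwrite(data.table(chrom = profile$chrom, r), tmp,
             sep = "\t", col.names = FALSE)
    } else {
      file.create(tmp)
    }
  })
}

#' Read a thresholded call-set manifest
#'
#' The manifest is a TSV with columns `algorithm`, `threshold`, `sample_id`,
#' `peak_file` (path relative to the manifest's directory or absolute) and
#' `is_default` (0/1; at most one threshold flagged). Every referenced peak
#' file is loaded via [read_peaks()]; thresholds are sorted increasing.
#'
#' @param path manifest TSV.
#' @return a `ThresholdedCallSet`: list with elements `algorithm`,
#'   `thresholds` (increasing numeric), `calls` (list keyed by
#'   `as.character(threshold)`, each a named list of [peak_calls()]) and
#'   `default_threshold` (or `NULL`).
#' @export
read_call_manifest <- function(path) {
  if (!file.exists(path)) stop("no such manifest: ", path)
  dt <- fread(path, sep = "\t", header = TRUE,
              colClasses = list(character = c("algorithm", "sample_id", "peak_file")))
  need <- c("algorithm", "threshold", "sample_id", "peak_file", "is_default")
  if (!all(need %in% names(dt)))
    stop(path, ": manifest must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(dt[, list(threshold, sample_id)]))
    stop(path, ": duplicate (threshold, sample_id) rows")
  if (length(unique(dt$algorithm)) != 1L)
    stop(path, ": manifest must describe exactly one algorithm")
  def <- unique(dt$threshold[dt$is_default == 1])
  if (length(def) > 1L)
    stop(path, ": more than one threshold flagged is_default")
  thresholds <- sort(unique(dt$threshold))
  base_dir <- dirname(path)
  calls <- list()
  for (lam in thresholds) {
    rows <- dt[dt$threshold == lam]
    per_sample <- list()
    for (i in seq_len(nrow(rows))) {
      f <- rows$peak_file[i]
      if (!grepl("^/", f)) f <- file.path(base_dir, f)
      if (!file.exists(f))
        stop(path, ": referenced peak file does not exist: ", f)
      per_sample[[rows$sample_id[i]]] <- read_peaks(f, rows$sample_id[i])
    }
    calls[[as.character(lam)]] <- per_sample
  }
  call_set(algorithm = dt$algorithm[1L], thresholds = thresholds,
           calls = calls,
           default_threshold = if (length(def)) def else NULL)
}

#' Construct a thresholded call set in memory
#'
#' @param algorithm algorithm name.
#' @param thresholds increasing numeric grid of significance thresholds.
#' @param calls list keyed by `as.character(threshold)`; each element a named
#'   list of [peak_calls()] keyed by sample id.
#' @param default_threshold the algorithm author's suggested threshold, or
#'   `NULL`; must be one of `thresholds`.
#' @return a `ThresholdedCallSet`.
#' @export
call_set <- function(algorithm, thresholds, calls, default_threshold = NULL) {
  if (!length(thresholds)) stop("empty threshold grid")
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  missing_keys <- setdiff(as.character(thresholds), names(calls))
  if (length(missing_keys))
    stop("no calls for threshold(s): ", paste(missing_keys, collapse = ", "))
  if (!is.null(default_threshold) &&
      !any(abs(thresholds - default_threshold) < 1e-9))
    stop("default_threshold is not on the grid")
  structure(list(algorithm = algorithm, thresholds = thresholds,
                 calls = calls, default_threshold = default_threshold),
            class = "ThresholdedCallSet")
}

#' @export
print.ThresholdedCallSet <- function(x, ...) {
  cat(sprintf("ThresholdedCallSet '%s': %d thresholds in [%g, %g], %d sample(s)%s\n",
              x$algorithm, length(x$thresholds), min(x$thresholds),
              max(x$thresholds), length(x$calls[[1L]]),
              if (is.null(x$default_threshold)) ""
              else sprintf(", default threshold %g", x$default_threshold)))
  invisible(x)
}

calls_at <- function(call_set, lambda) {
  i <- which(abs(call_set$thresholds - lambda) < 1e-9)
  if (length(i) != 1L)
    stop("threshold ", lambda, " is not on the grid (no interpolation)")
  call_set$calls[[as.character(call_set$thresholds[i])]]
}

#' Write per-label results / summaries as TSV
#'
#' `write_error_table()` writes one row per (label, sample) result with
#' columns chrom, start, end, type, window_id, sample_id, observed, fp, fn,
#' status; `write_summary_table()` writes one row per summary (whatever id
#' columns the summary table carries, e.g. threshold or fold, plus fp_total,
#' fn_total, errors, n_labels, percent_error). Reading the file back with
#' `fread` reproduces the table bit-exactly.
#'
#' @param results per-(label, sample) results from [label_error()].
#' @param summaries a summary `data.table` (e.g. from [train()] or
#'   [cross_validate()]).
#' @param path output file.
#' @param header_comments optional character vector written as leading
#'   `#`-comment lines (tool version, resolved parameters).
#' @export
write_error_table <- function(results, path, header_comments = NULL) {
  write_atomic(path, function(tmp) {
    body <- tempfile(fileext = ".tsv")
    on.exit(unlink(body), add = TRUE)
    fwrite(results, body, sep = "\t", col.names = TRUE)
    con <- file(tmp, "w")
    on.exit(close(con), add = TRUE)
    if (!is.null(header_comments))
      writeLines(paste0("# ", header_comments), con)
    writeLines(readLines(body), con)
  })
}

#' @rdname write_error_table
#' @export
write_summary_table <- function(summaries, path, header_comments = NULL) {
  write_error_table(summaries, path, header_comments)
}

#' Read back a result table written by [write_error_table()]
#'
#' @param path TSV path.
#' @return the table, comment lines skipped.
#' @export
read_result_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  fread(text = paste(lines, collapse = "\n"), sep = "\t", header = TRUE)
}
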