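#' Construct a table of visual region labels
#'
#' A label is a genomic region tagged with one of four types -- `noPeaks`
#' (only background noise), `peaks` (at least one overlapping peak of any
#' size), `peakStart` / `peakEnd` (exactly one peak boundary inside the
#' region) -- and applies either to every sample (`groups == ""`) or to the
#' samples of the named cell-type groups. Labels are grouped into windows,
#' the unit of train/test splitting.
#'
#' @param chrom,start,end label regions (0-based half-open).
#' @param type one of `noPeaks`, `peaks`, `peakStart`, `peakEnd` per label.
#' @param groups comma-separated sample-group names per label; `""` means the
#'   label applies to every scored sample.
#' @param window_id integer id of the containing window.
#' @return a `data.table` with one row per label.
#' @export
label_table <- function(chrom, start, end, type, groups = "", window_id = 1L) {
  dt <- data.table(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   type = as.character(type),
                   groups = as.character(groups),
                   window_id = as.integer(window_id))
  if (nrow(dt)) {
    stop_if_bad_interval(dt$chrom, dt$start, dt$end)
    bad <- setdiff(unique(dt$type), LABEL_TYPES)
    if (length(bad))
      stop("unknown label type(s): ", paste(bad, collapse = ", "),
           " (must be one of ", paste(LABEL_TYPES, collapse = ", "), ")")
  }
  dt
}

## expand a label's groups field to the sample ids it applies to.
## sample_groups: named character vector, names = sample ids, values = group.
label_samples <- function(groups_field, all_samples, sample_groups = NULL) {
  if (identical(groups_field, "")) return(all_samples)
  wanted <- strsplit(groups_field, ",", fixed = TRUE)[[1L]]
  if (is.null(sample_groups))
    stop("labels name sample groups (", groups_field,
         ") but no sample -> group mapping was given")
  hit <- all_samples[sample_groups[all_samples] %in% wanted]
  hit
}

#' Summarize the windows of a label table
#'
#' @param labels a label table (see [label_table()]).
#' @return `data.table` with one row per window: window_id, chrom, start, end
#'   (the span of the window's labels) and n_labels.
#' @export
window_table <- function(labels) {
  labels[, list(chrom = chrom[1L], start = min(start), end = max(end),
                n_labels = .N),
         by = window_id][order(window_id)]
}

#' Check label constraints
#'
#' Two constraints are checked. Overlapping labels on the same sample are an
#' error: each labeled region must carry exactly one judgment per sample.
#' A window lacking a `noPeaks` label, or lacking a positive label (`peaks`,
#' `peakStart` or `peakEnd`), is a warning: the labeling protocol asks for
#' both in every window, but real labeled data may fall short of that and is
#' still scoreable.
#'
#' Violations are returned as data, not raised, so callers decide severity.
#'
#' @param labels a label table.
#' @param sample_groups optional named character vector mapping sample id to
#'   group name; needed to decide whether two group-restricted labels share a
#'   sample. Without it, labels are assumed to share a sample when their
#'   groups fields intersect (with `""` intersecting everything).
#' @return `data.table` with columns severity (`error`/`warning`), window_id
#'   and message; zero rows when all constraints hold.
#' @export
validate_labels <- function(labels, sample_groups = NULL) {
  out <- list()
  groups_overlap <- function(g1, g2) {
    if (g1 == "" || g2 == "") return(TRUE)
    s1 <- strsplit(g1, ",", fixed = TRUE)[[1L]]
    s2 <- strsplit(g2, ",", fixed = TRUE)[[1L]]
    if (!is.null(sample_groups)) {
      ## compare the actual sample sets
      length(intersect(names(sample_groups)[sample_groups %in% s1],
                       names(sample_groups)[sample_groups %in% s2])) > 0L
    } else {
      length(intersect(s1, s2)) > 0L
    }
  }
  dt <- labels[order(chrom, start, end)]
  if (nrow(dt) > 1L) {
    for (i in seq_len(nrow(dt) - 1L)) {
      j <- i + 1L
      while (j <= nrow(dt) && dt$chrom[j] == dt$chrom[i] && dt$start[j] < dt$end[i]) {
        if (groups_overlap(dt$groups[i], dt$groups[j])) {
          out[[length(out) + 1L]] <- data.table(
            severity = "error", window_id = dt$window_id[i],
            message = sprintf(
              "labels %s:%d-%d (%s) and %s:%d-%d (%s) overlap on a shared sample",
              dt$chrom[i], dt$start[i], dt$end[i], dt$type[i],
              dt$chrom[j], dt$start[j], dt$end[j], dt$type[j]))
        }
        j <- j + 1L
      }
    }
  }
  for (w in unique(labels$window_id)) {
    types <- labels$type[labels$window_id == w]
    if (!"noPeaks" %in% types)
      out[[length(out) + 1L]] <- data.table(
        severity = "warning", window_id = w,
        message = sprintf("window %d has no noPeaks label", w))
    if (!any(types %in% c("peaks", "peakStart", "peakEnd")))
      out[[length(out) + 1L]] <- data.table(
        severity = "warning", window_id = w,
        message = sprintf("window %d has no positive label", w))
  }
  if (!length(out))
    return(data.table(severity = character(), window_id = integer(),
                      message = character()))
  rbindlist(out)
}
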