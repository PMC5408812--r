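## Independent base-resolution oracle for the label error: rasterize the
## peaks onto a binary vector over [0, b), recover runs by scanning bases,
## and count overlaps / starts / ends directly. Shares no code with the
## interval arithmetic in the package.

oracle_scan <- function(labels, peaks, b) {
  y <- integer(b)
  for (i in seq_len(nrow(peaks))) {
    y[(peaks$start[i] + 1L):peaks$end[i]] <- 1L
  }
  is_start <- y == 1L & c(TRUE, y[-length(y)] == 0L)
  is_end <- y == 1L & c(y[-1L] == 0L, TRUE)
  run_start_base <- which(is_start) - 1L        # 0-based first base of each run
  run_end_coord <- which(is_end)                # exclusive end coordinate
  run_id_per_base <- cumsum(is_start) * y       # 0 = background
  out <- labels[, c("chrom", "start", "end", "type", "window_id")]
  obs <- integer(nrow(labels))
  for (i in seq_len(nrow(labels))) {
    s <- labels$start[i]; e <- labels$end[i]
    obs[i] <- switch(labels$type[i],
      noPeaks = ,
      peaks = {
        ids <- run_id_per_base[(s + 1L):e]
        length(unique(ids[ids > 0L]))
      },
      peakStart = sum(run_start_base >= s & run_start_base < e),
      peakEnd = sum(run_end_coord > s & run_end_coord <= e))
  }
  fp <- as.integer((labels$type == "noPeaks" & obs >= 1L) |
                   (labels$type %in% c("peakStart", "peakEnd") & obs > 1L))
  fn <- as.integer(labels$type != "noPeaks" & obs == 0L)
  out$observed <- obs
  out$fp <- fp
  out$fn <- fn
  out
}

## draw an interval that stays a distinct peak: disjoint from and
## non-abutting every existing peak (NULL if none found in a few tries)
draw_distinct_peak <- function(calls, b, tries = 30L) {
  for (i in seq_len(tries)) {
    s <- sample(0:(b - 1L), 1L)
    e <- s + sample.int(b - s, 1L)
    clear <- !any(calls$start <= e & calls$end >= s)
    if (clear) return(data.frame(chrom = "chr1", start = s, end = e))
  }
  NULL
}

## one random scoring instance: genome of <= 1000 bases, <= max_peaks
## disjoint non-abutting peaks, <= max_labels disjoint labels of all types
random_instance <- function(max_b = 1000L, max_peaks = 10L, max_labels = 10L) {
  b <- sample(50:max_b, 1L)
  n_peaks <- sample(0:max_peaks, 1L)
  peaks <- if (n_peaks > 0L) {
    cuts <- sort(sample(0:b, 2L * n_peaks))
    keep <- seq(1L, 2L * n_peaks, by = 2L)
    dt <- data.frame(chrom = "chr1", start = cuts[keep], end = cuts[keep + 1L])
    dt[dt$end > dt$start, ]
  } else {
    data.frame(chrom = character(), start = integer(), end = integer())
  }
  n_labels <- sample(1:max_labels, 1L)
  cuts <- sort(sample(0:b, 2L * n_labels))
  keep <- seq(1L, 2L * n_labels, by = 2L)
  ldt <- data.frame(chrom = "chr1", start = cuts[keep], end = cuts[keep + 1L])
  ldt <- ldt[ldt$end > ldt$start, ]
  list(b = b,
       calls = peak_calls(peaks, "s1"),
       labels = label_table(ldt$chrom, ldt$start, ldt$end,
                            sample(peakcal:::LABEL_TYPES, nrow(ldt),
                                   replace = TRUE)))
}
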