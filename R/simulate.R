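#' Configuration of the synthetic labeled benchmark
#'
#' The generator emulates the structure of a labeled multi-sample ChIP-seq
#' benchmark: per-base integer coverage with Poisson noise, peaks planted at
#' shared positions within cell types, and region labels of all four types
#' obeying the labeling constraints (every window has a noPeaks and a
#' positive label; labels never overlap on a sample; each boundary label
#' contains its true boundary strictly inside).
#'
#' Defaults describe a sharp-mark-style benchmark: 20 samples in 4 cell
#' types, 8 windows of 15 kb with 2 planted peaks each, background mean 5
#' and peak mean 30 counts per base, peak widths 200-2000 bases.
#'
#' @param n_samples number of samples.
#' @param n_cell_types number of cell-type groups; samples are spread over
#'   groups round-robin.
#' @param windows number of labeled genomic windows.
#' @param window_length window length in bases.
#' @param peaks_per_window planted peaks per window (0 allowed: windows then
#'   carry only noPeaks labels).
#' @param background_mean expected counts per base outside peaks (mu0 > 0).
#' @param peak_mean expected counts per base inside peaks (mu1 > mu0).
#' @param peak_width_range length-2 integer vector, min/max planted peak
#'   width in bases.
#' @param peak_sharing_prob probability that a planted peak is present in a
#'   given cell type (all samples of a carrying type carry it); peaks carried
#'   by no type are reassigned to one random type.
#' @param boundary_label_prob probability that a planted peak additionally
#'   gets peakStart/peakEnd labels flanking its true boundaries.
#' @param seed integer seed; the whole benchmark is deterministic given it.
#' @return a `SimulationConfig` list.
#' @export
simulation_config <- function(n_samples = 20L, n_cell_types = 4L,
                              windows = 8L, window_length = 15000L,
                              peaks_per_window = 2L,
                              background_mean = 5, peak_mean = 30,
                              peak_width_range = c(200L, 2000L),
                              peak_sharing_prob = 0.7,
                              boundary_label_prob = 0.5,
                              seed = 1L) {
  stopifnot(n_samples >= 1, n_cell_types >= 1, n_cell_types <= n_samples,
            windows >= 1, window_length >= 100, peaks_per_window >= 0,
            length(peak_width_range) == 2L,
            peak_width_range[1L] >= 10, diff(peak_width_range) >= 0,
            peak_sharing_prob >= 0, peak_sharing_prob <= 1,
            boundary_label_prob >= 0, boundary_label_prob <= 1)
  if (!(peak_mean > background_mean) || !(background_mean > 0))
    stop("need peak_mean > background_mean > 0")
  structure(list(n_samples = as.integer(n_samples),
                 n_cell_types = as.integer(n_cell_types),
                 windows = as.integer(windows),
                 window_length = as.integer(window_length),
                 peaks_per_window = as.integer(peaks_per_window),
                 background_mean = background_mean, peak_mean = peak_mean,
                 peak_width_range = as.integer(peak_width_range),
                 peak_sharing_prob = peak_sharing_prob,
                 boundary_label_prob = boundary_label_prob,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Benchmark presets for sharp and broad histone-mark styles
#'
#' `"sharp"` mimics a localized mark (H3K4me3-like): 200-2000 base peaks in
#' 15 kb windows, 20 samples. `"broad"` mimics an extended mark
#' (H3K36me3-like): 5-50 kb domains in 180 kb windows, at a smaller sample
#' count so a benchmark stays desk-sized.
#'
#' @param preset `"sharp"` or `"broad"`.
#' @param seed integer seed.
#' @param ... overrides passed to [simulation_config()].
#' @return a `SimulationConfig`.
#' @export
preset_config <- function(preset = c("sharp", "broad"), seed = 1L, ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    sharp = list(),
    broad = list(n_samples = 6L, n_cell_types = 3L, windows = 6L,
                 window_length = 180000L,
                 peak_width_range = c(5000L, 50000L)))
  args$seed <- seed
  override <- list(...)
  args[names(override)] <- override
  do.call(simulation_config, args)
}

## margin of a boundary label around a true peak edge: 10% of the peak
## width, at least 5 bases, and small enough that the interior stays nonempty
label_margin <- function(width) {
  min(max(5L, as.integer(round(0.1 * width))), (width - 2L) %/% 2L)
}

## deterministic window geometry checks, before any sampling
check_geometry <- function(config) {
  k <- config$peaks_per_window
  if (k == 0L) return(invisible(NULL))
  wmax <- config$peak_width_range[2L]
  m_max <- label_margin(wmax)
  sep <- 2L * m_max + 10L
  nz <- noise_zone(config)
  need <- nz + 2L * m_max + k * wmax + (k - 1L) * sep
  if (need > config$window_length)
    stop("infeasible geometry: ", k, " peaks of width up to ", wmax,
         " (plus label margins) need ", need,
         " bases but windows have ", config$window_length)
  invisible(NULL)
}

noise_zone <- function(config) max(100L, as.integer(round(0.1 * config$window_length)))

#' Generate a labeled multi-sample benchmark with known ground truth
#'
#' Windows are laid consecutively (with short gaps) along one synthetic
#' chromosome. Per window, `peaks_per_window` peak positions are drawn with
#' enough separation that their labels cannot collide, and each peak is
#' assigned to cell types with probability `peak_sharing_prob`; all samples
#' of a carrying type carry the peak. Coverage counts are independent
#' Poisson draws with mean `background_mean` outside the sample's peaks and
#' `peak_mean` inside.
#'
#' Labels per window: one noPeaks label over a peak-free leading zone
#' (applying to every sample); per planted peak a `peaks` label over the
#' peak's interior for the carrying cell types and, when some types do not
#' carry it, a noPeaks label over the same interior for those types; and,
#' for a random subset of peaks, peakStart/peakEnd labels flanking the true
#' boundaries (carrying types only), each true boundary strictly inside its
#' label region.
#'
#' @param config a [simulation_config()].
#' @return a `peak_benchmark` list: `coverage` (named list of
#'   [coverage_profile()]), `truth` (a `GroundTruth`: planted-peak table plus
#'   the sample -> group mapping), `labels` (label table),
#'   `sample_groups` (named character vector) and `config`.
#' @export
simulate_benchmark <- function(config = simulation_config()) {
  check_geometry(config)
  groups <- paste0("type", LETTERS[seq_len(config$n_cell_types)])
  sample_ids <- sprintf("sample%02d", seq_len(config$n_samples))
  sample_groups <- stats::setNames(
    rep(groups, length.out = config$n_samples), sample_ids)
  chrom <- "chrSim"
  gap <- max(500L, as.integer(round(0.1 * config$window_length)))
  nz <- noise_zone(config)
  k <- config$peaks_per_window
  wmax <- config$peak_width_range[2L]
  m_max <- if (k > 0L) label_margin(wmax) else 0L
  sep <- 2L * m_max + 10L

  with_seed(config$seed, {
    peak_rows <- list()
    label_rows <- list()
    peak_id <- 0L
    for (w in seq_len(config$windows)) {
      win_start <- (w - 1L) * (config$window_length + gap)
      win_end <- win_start + config$window_length
      label_rows[[length(label_rows) + 1L]] <- data.table(
        chrom = chrom, start = win_start, end = win_start + nz,
        type = "noPeaks", groups = "", window_id = w)
      if (k == 0L) next
      widths <- sample(seq(config$peak_width_range[1L],
                           config$peak_width_range[2L]), k, replace = TRUE)
      slack <- config$window_length -
        (nz + 2L * m_max + sum(widths) + (k - 1L) * sep)
      extras <- as.vector(stats::rmultinom(1L, slack, rep(1, k + 1L)))
      pos <- win_start + nz + m_max
      for (j in seq_len(k)) {
        pos <- pos + extras[j] + if (j > 1L) sep else 0L
        s <- pos; e <- pos + widths[j]
        pos <- e
        peak_id <- peak_id + 1L
        carriers <- stats::runif(config$n_cell_types) < config$peak_sharing_prob
        if (!any(carriers))
          carriers[sample.int(config$n_cell_types, 1L)] <- TRUE
        m <- label_margin(widths[j])
        carrier_groups <- paste(groups[carriers], collapse = ",")
        absent_groups <- paste(groups[!carriers], collapse = ",")
        peak_rows[[peak_id]] <- data.table(
          peak_id = peak_id, window_id = w, chrom = chrom,
          start = s, end = e, groups = carrier_groups)
        label_rows[[length(label_rows) + 1L]] <- data.table(
          chrom = chrom, start = s + m, end = e - m,
          type = "peaks", groups = carrier_groups, window_id = w)
        if (any(!carriers))
          label_rows[[length(label_rows) + 1L]] <- data.table(
            chrom = chrom, start = s + m, end = e - m,
            type = "noPeaks", groups = absent_groups, window_id = w)
        if (stats::runif(1L) < config$boundary_label_prob) {
          label_rows[[length(label_rows) + 1L]] <- data.table(
            chrom = chrom, start = s - m, end = s + m,
            type = "peakStart", groups = carrier_groups, window_id = w)
          label_rows[[length(label_rows) + 1L]] <- data.table(
            chrom = chrom, start = e - m, end = e + m,
            type = "peakEnd", groups = carrier_groups, window_id = w)
        }
      }
    }
    truth_peaks <- if (length(peak_rows)) rbindlist(peak_rows) else
      data.table(peak_id = integer(), window_id = integer(),
                 chrom = character(), start = integer(), end = integer(),
                 groups = character())
    ldt <- rbindlist(label_rows)
    labels <- label_table(ldt$chrom, ldt$start, ldt$end, ldt$type,
                          ldt$groups, ldt$window_id)
    b <- (config$windows - 1L) * (config$window_length + gap) +
      config$window_length
    coverage <- lapply(sample_ids, function(sid) {
      mu <- rep(config$background_mean, b)
      mine <- truth_peaks[grepl(paste0("(^|,)", sample_groups[[sid]], "(,|$)"),
                                truth_peaks$groups)]
      for (i in seq_len(nrow(mine)))
        mu[(mine$start[i] + 1L):mine$end[i]] <- config$peak_mean
      counts <- stats::rpois(b, mu)
      coverage_profile(rle_runs(counts), chrom = chrom, sample_id = sid, b = b)
    })
    names(coverage) <- sample_ids
    structure(list(coverage = coverage,
                   truth = structure(list(peaks = truth_peaks,
                                          sample_groups = sample_groups),
                                     class = "GroundTruth"),
                   labels = labels, sample_groups = sample_groups,
                   config = config),
              class = "peak_benchmark")
  })
}

#' @export
print.peak_benchmark <- function(x, ...) {
  cat(sprintf(paste0("peak_benchmark: %d samples in %d cell types, %d windows, ",
                     "%d planted peaks, %d labels (seed %d)\n"),
              x$config$n_samples, x$config$n_cell_types, x$config$windows,
              nrow(x$truth$peaks), nrow(x$labels), x$config$seed))
  invisible(x)
}

#' Ground-truth peaks as per-sample calls
#'
#' Each sample's calls are the planted peaks its cell type carries. By
#' construction these calls satisfy every generated label, so
#' `total_error(truth_calls(truth), labels) == 0` -- the generator's central
#' contract.
#'
#' @param truth the `GroundTruth` of a [simulate_benchmark()] result.
#' @return named list of [peak_calls()] keyed by sample id.
#' @export
truth_calls <- function(truth) {
  out <- lapply(names(truth$sample_groups), function(sid) {
    grp <- truth$sample_groups[[sid]]
    mine <- truth$peaks[grepl(paste0("(^|,)", grp, "(,|$)"), truth$peaks$groups)]
    peak_calls(mine[, list(chrom, start, end)], sid)
  })
  names(out) <- names(truth$sample_groups)
  out
}

#' Export a benchmark to a directory of plain-text files
#'
#' Writes `coverage/<sample>.bedGraph`, `labels.txt` (browser dialect),
#' `truth/<sample>_truth.bed`, `groups.tsv` (sample id -> group), and --
#' after running the built-in caller over a threshold grid --
#' `calls/<...>.bed` per (threshold, sample) plus `manifest.tsv`, so the
#' directory is a complete, re-importable benchmark.
#'
#' @param benchmark a [simulate_benchmark()] result.
#' @param dir output directory (created if needed).
#' @param n_thresholds grid size for the built-in caller.
#' @param config [caller_config()] used for the exported calls; the default
#'   uses bandwidth 11 so the exported family exercises smoothing.
#' @return `dir`, invisibly.
#' @export
export_benchmark <- function(benchmark, dir, n_thresholds = 20L,
                             config = caller_config(bandwidth = 11L,
                                                    min_peak_width = 10L)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in names(benchmark$coverage))
    write_coverage(benchmark$coverage[[sid]],
                   file.path(dir, "coverage", paste0(sid, ".bedGraph")))
  write_labels(benchmark$labels, file.path(dir, "labels.txt"))
  tc <- truth_calls(benchmark$truth)
  for (sid in names(tc))
    write_peaks(tc[[sid]], file.path(dir, "truth", paste0(sid, "_truth.bed")))
  write_atomic(file.path(dir, "groups.tsv"), function(tmp) {
    fwrite(data.table(sample_id = names(benchmark$sample_groups),
                      group = unname(benchmark$sample_groups)),
           tmp, sep = "\t")
  })
  grid <- threshold_grid(benchmark$coverage, n_thresholds, config)
  lam_default <- default_threshold(benchmark$coverage)
  cs <- build_call_set(benchmark$coverage, grid, config, lam_default)
  rows <- list()
  for (i in seq_along(cs$thresholds)) {
    lam <- cs$thresholds[i]
    for (sid in names(cs$calls[[as.character(lam)]])) {
      rel <- file.path("calls", sprintf("lambda_%03d_%s.bed", i, sid))
      write_peaks(cs$calls[[as.character(lam)]][[sid]], file.path(dir, rel))
      rows[[length(rows) + 1L]] <- data.table(
        algorithm = cs$algorithm, threshold = lam, sample_id = sid,
        peak_file = rel,
        is_default = as.integer(abs(lam - lam_default) < 1e-9))
    }
  }
  write_atomic(file.path(dir, "manifest.tsv"), function(tmp) {
    fwrite(rbindlist(rows), tmp, sep = "\t")
  })
  invisible(dir)
}

#' Read back the sample -> group mapping written by [export_benchmark()]
#'
#' @param path `groups.tsv` path.
#' @return named character vector (names = sample ids).
#' @export
read_groups <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  stats::setNames(dt$group, dt$sample_id)
}
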