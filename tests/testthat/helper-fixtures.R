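## build a small in-memory ThresholdedCallSet from plain data.frames:
## peaks_by_threshold is a named list keyed by threshold (as character),
## each element a named list sample_id -> data.frame(chrom, start, end)
tiny_call_set <- function(peaks_by_threshold, default_threshold = NULL,
                          algorithm = "toy") {
  thresholds <- sort(as.numeric(names(peaks_by_threshold)))
  calls <- list()
  for (lam in thresholds) {
    per <- peaks_by_threshold[[as.character(lam)]]
    calls[[as.character(lam)]] <- lapply(
      stats::setNames(names(per), names(per)),
      function(sid) peak_calls(per[[sid]], sid))
  }
  call_set(algorithm, thresholds, calls, default_threshold)
}

## the small benchmark used across train/eval tests: sharp geometry at a
## reduced sample count so the default unit-test run stays fast
small_benchmark <- function(seed = 1L, ...) {
  simulate_benchmark(preset_config("sharp", seed = seed, n_samples = 8L,
                                   n_cell_types = 4L, ...))
}

benchmark_caller_config <- function() {
  caller_config(bandwidth = 11L, min_peak_width = 10L)
}

## benchmark + call set over a grid including the naive default threshold
benchmark_with_calls <- function(seed = 1L, n_thresholds = 20L, ...) {
  bench <- small_benchmark(seed, ...)
  cfg <- benchmark_caller_config()
  grid <- threshold_grid(bench$coverage, n_thresholds, cfg)
  lam_default <- default_threshold(bench$coverage)
  cs <- build_call_set(bench$coverage, grid, cfg, lam_default)
  list(bench = bench, call_set = cs)
}
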