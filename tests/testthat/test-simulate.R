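test_that("identical seeds give bit-identical benchmarks", {
  cfg <- preset_config("sharp", seed = 3, n_samples = 4L, windows = 2L)
  b1 <- simulate_benchmark(cfg)
  b2 <- simulate_benchmark(cfg)
  expect_identical(as.data.frame(b1$labels), as.data.frame(b2$labels))
  expect_identical(as.data.frame(b1$truth$peaks), as.data.frame(b2$truth$peaks))
  expect_identical(lapply(b1$coverage, coverage_vector),
                   lapply(b2$coverage, coverage_vector))
  b3 <- simulate_benchmark(preset_config("sharp", seed = 4, n_samples = 4L,
                                         windows = 2L))
  expect_false(identical(as.data.frame(b1$truth$peaks),
                         as.data.frame(b3$truth$peaks)))
})

test_that("generated labels satisfy the labeling constraints", {
  bench <- small_benchmark(seed = 5)
  report <- validate_labels(bench$labels, bench$sample_groups)
  expect_equal(nrow(report), 0L)
  ## every window has a noPeaks and a positive label
  for (w in unique(bench$labels$window_id)) {
    types <- bench$labels$type[bench$labels$window_id == w]
    expect_true("noPeaks" %in% types)
    expect_true(any(types %in% c("peaks", "peakStart", "peakEnd")))
  }
  ## boundary labels contain their true boundary strictly inside
  truth <- bench$truth$peaks
  starts <- bench$labels[bench$labels$type == "peakStart"]
  for (i in seq_len(nrow(starts))) {
    hit <- truth$start[truth$start > starts$start[i] &
                       truth$start < starts$end[i]]
    expect_equal(length(hit), 1L)
  }
})

test_that("zero peaks per window degenerates to noPeaks-only labels", {
  cfg <- preset_config("sharp", seed = 1, n_samples = 4L, windows = 2L,
                       peaks_per_window = 0L)
  bench <- simulate_benchmark(cfg)
  expect_true(all(bench$labels$type == "noPeaks"))
  report <- validate_labels(bench$labels, bench$sample_groups)
  expect_true(all(report$severity == "warning"))
  expect_true(any(grepl("no positive label", report$message)))
})

test_that("infeasible geometry fails before sampling", {
  expect_error(simulate_benchmark(
    simulation_config(window_length = 3000L, peaks_per_window = 2L,
                      peak_width_range = c(1500L, 2000L))),
    "infeasible geometry")
})

test_that("coverage means match the planted Poisson rates", {
  bench <- simulate_benchmark(simulation_config(seed = 2))
  mu0 <- bench$config$background_mean
  mu1 <- bench$config$peak_mean
  truth <- bench$truth$peaks
  in_peak <- out_peak <- numeric(0)
  for (sid in names(bench$coverage)) {
    x <- coverage_vector(bench$coverage[[sid]])
    grp <- bench$sample_groups[[sid]]
    mask <- logical(length(x))
    mine <- truth[grepl(paste0("(^|,)", grp, "(,|$)"), truth$groups)]
    for (i in seq_len(nrow(mine)))
      mask[(mine$start[i] + 1):mine$end[i]] <- TRUE
    in_peak <- c(in_peak, x[mask])
    out_peak <- c(out_peak, x[!mask])
  }
  ## sample means within 3 standard errors of the planted rates
  expect_lt(abs(mean(in_peak) - mu1), 3 * sqrt(mu1 / length(in_peak)))
  expect_lt(abs(mean(out_peak) - mu0), 3 * sqrt(mu0 / length(out_peak)))
})

test_that("ground-truth calls are consistent with the labels", {
  for (seed in 1:3) {
    bench <- small_benchmark(seed)
    tc <- truth_calls(bench$truth)
    s <- total_error(tc, bench$labels, bench$sample_groups)
    expect_equal(s$errors, 0L)
    ## a sample lacking a shared peak has it absent from its calls
    truth <- bench$truth$peaks
    partial <- truth[!vapply(truth$groups, function(g)
      all(unique(bench$sample_groups) %in%
            strsplit(g, ",", fixed = TRUE)[[1]]), TRUE)]
    if (nrow(partial)) {
      g1 <- strsplit(partial$groups[1], ",", fixed = TRUE)[[1]]
      absent_sample <- names(bench$sample_groups)[
        !bench$sample_groups %in% g1][1]
      pc <- tc[[absent_sample]]
      expect_false(any(pc$start == partial$start[1] &
                       pc$end == partial$end[1]))
    }
    ## shifting every truth peak by its width breaks the labels
    shifted <- lapply(tc, function(pc) {
      df <- as.data.frame(pc)
      df$width <- df$end - df$start
      peak_calls(data.frame(chrom = df$chrom, start = df$start + df$width,
                            end = df$end + df$width),
                 attr(pc, "sample_id"))
    })
    expect_gt(total_error(shifted, bench$labels, bench$sample_groups)$errors, 0)
  }
})

test_that("export and re-import reproduce the benchmark", {
  dir <- withr::local_tempdir()
  bench <- simulate_benchmark(preset_config("sharp", seed = 7,
                                            n_samples = 4L, windows = 3L,
                                            window_length = 4000L,
                                            peak_width_range = c(200L, 600L)))
  export_benchmark(bench, dir, n_thresholds = 6L)
  labs <- read_labels(file.path(dir, "labels.txt"),
                      read_groups(file.path(dir, "groups.tsv")))
  expect_identical(as.data.frame(labs), as.data.frame(bench$labels))
  groups <- read_groups(file.path(dir, "groups.tsv"))
  expect_identical(groups, bench$sample_groups)
  for (sid in names(bench$coverage)) {
    prof <- read_coverage(file.path(dir, "coverage", paste0(sid, ".bedGraph")),
                          sid)
    expect_identical(coverage_vector(prof),
                     coverage_vector(bench$coverage[[sid]]))
  }
  tc <- truth_calls(bench$truth)
  for (sid in names(tc)) {
    back <- read_peaks(file.path(dir, "truth", paste0(sid, "_truth.bed")), sid)
    expect_identical(as.data.frame(back), as.data.frame(tc[[sid]]))
  }
  ## the manifest covers every grid threshold for every sample
  cs <- read_call_manifest(file.path(dir, "manifest.tsv"))
  expect_false(is.null(cs$default_threshold))
  for (lam in cs$thresholds)
    expect_setequal(names(cs$calls[[as.character(lam)]]),
                    names(bench$coverage))
  ## and the reloaded call set evaluates identically to the in-memory one
  mem <- build_call_set(bench$coverage,
                        threshold_grid(bench$coverage, 6L,
                                       benchmark_caller_config()),
                        benchmark_caller_config(),
                        default_threshold(bench$coverage))
  for (lam in cs$thresholds) {
    expect_identical(
      as.data.frame(evaluate(cs, lam, labs, groups)),
      as.data.frame(evaluate(mem, lam, labs, groups)))
  }
})
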