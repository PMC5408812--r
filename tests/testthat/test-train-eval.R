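## three-window label set with a toy call family whose per-threshold errors
## are easy to enumerate by hand
toy_labels <- label_table(
  chrom = rep("chr1", 6),
  start = c(0, 100, 1000, 1100, 2000, 2100),
  end = c(50, 200, 1050, 1200, 2050, 2200),
  type = rep(c("noPeaks", "peaks"), 3),
  window_id = rep(1:3, each = 2))

## lambda = 1 over-calls (noPeaks hit), lambda = 2 is perfect,
## lambda = 4 under-calls (peaks missed)
toy_set <- function(default = 1) tiny_call_set(list(
  "1" = list(s1 = data.frame(chrom = "chr1",
                             start = c(10, 110, 1010, 1110, 2010, 2110),
                             end = c(40, 190, 1040, 1190, 2040, 2190))),
  "2" = list(s1 = data.frame(chrom = "chr1", start = c(110, 1110, 2110),
                             end = c(190, 1190, 2190))),
  "4" = list(s1 = data.frame(chrom = character(), start = integer(),
                             end = integer()))),
  default_threshold = default)

test_that("grid search picks the error-minimizing threshold", {
  fit <- train(toy_set(), toy_labels)
  expect_equal(fit$chosen_threshold, 2)
  expect_equal(fit$train_error$errors, 0L)
  expect_equal(fit$per_threshold_errors$errors, c(3L, 0L, 3L))
  ## argmin property over the whole profile
  expect_true(all(fit$train_error$errors <= fit$per_threshold_errors$errors))
  expect_error(train(toy_set(), toy_labels[0]), "no training labels")
})

test_that("ties break toward the largest (most conservative) threshold", {
  cs <- tiny_call_set(list(
    "1" = list(s1 = data.frame(chrom = "chr1", start = 10, end = 40)),
    "2" = list(s1 = data.frame(chrom = "chr1", start = 110, end = 190)),
    "4" = list(s1 = data.frame(chrom = "chr1", start = 110, end = 190))))
  labs <- label_table("chr1", c(0, 100), c(50, 200), c("noPeaks", "peaks"))
  fit <- train(cs, labs)
  ## errors are (1, 0, 0): both 2 and 4 minimize; 4 wins
  expect_equal(fit$chosen_threshold, 4)
})

test_that("evaluate matches total_error and rejects off-grid thresholds", {
  cs <- toy_set()
  s <- evaluate(cs, 2, toy_labels)
  expect_equal(s$percent_error, 0)
  direct <- total_error(cs$calls[["1"]], toy_labels)
  expect_identical(as.data.frame(evaluate(cs, 1, toy_labels)),
                   as.data.frame(direct))
  ## empty calls against positive labels: every peaks label is missed
  miss <- evaluate(cs, 4, toy_labels[toy_labels$type == "peaks"])
  expect_equal(miss$percent_error, 100)
  expect_error(evaluate(cs, 3, toy_labels), "not on the grid")
})

test_that("fold assignment is balanced, deterministic and seed-sensitive", {
  w8 <- label_table("chr1", 100 * (1:8), 100 * (1:8) + 50,
                    rep("peaks", 8), window_id = 1:8)
  f <- assign_folds(w8, 4, 1)
  expect_equal(as.integer(table(f$assignment)), rep(2L, 4))
  expect_identical(f$assignment, assign_folds(w8, 4, 1)$assignment)
  expect_false(identical(f$assignment, assign_folds(w8, 4, 2)$assignment))
  expect_error(assign_folds(w8[window_id <= 3], 4, 1), "fewer windows")

  w9 <- label_table("chr1", 100 * (1:9), 100 * (1:9) + 50,
                    rep("peaks", 9), window_id = 1:9)
  for (seed in 1:25) {
    sizes <- sort(as.integer(table(assign_folds(w9, 4, seed)$assignment)),
                  decreasing = TRUE)
    expect_equal(sizes, c(3L, 2L, 2L, 2L))
  }
})

test_that("cross-validation separates trained and default thresholds", {
  cs <- toy_set(default = 1)
  cv <- cross_validate(cs, toy_labels, k = 3, seed = 1)
  expect_equal(nrow(cv$per_fold), 6L)
  ## lambda = 2 is perfect on every window, so every trained fold is 0
  expect_true(all(cv$per_fold$percent_error[cv$per_fold$model == "trained"] == 0))
  ## the over-calling default threshold hits every noPeaks label
  expect_true(all(cv$per_fold$percent_error[cv$per_fold$model == "default"] == 50))
  expect_equal(cv$summary$mean_percent_error[cv$summary$model == "trained"], 0)
  ## identical inputs and seed reproduce bit-identically
  cv2 <- cross_validate(cs, toy_labels, k = 3, seed = 1)
  expect_identical(cv$per_fold, cv2$per_fold)
  ## leave-one-window-out is the degenerate balanced case
  loo <- cross_validate(cs, toy_labels, k = 3, seed = 5)
  expect_equal(sort(as.integer(table(loo$folds$assignment))), rep(1L, 3))
  expect_error(cross_validate(toy_set(default = NULL), toy_labels, 3, 1),
               "no default threshold")
})

test_that("ROC-like curve endpoints and agreement with error_by_type", {
  labs <- label_table("chr1", c(0, 100, 90, 200), c(50, 200, 100, 260),
                      c("noPeaks", "peaks", "peakStart", "peakEnd"),
                      window_id = c(1L, 1L, 1L, 1L))
  cs <- tiny_call_set(list(
    "1" = list(s1 = data.frame(chrom = "chr1", start = c(10, 95),
                               end = c(40, 250))),
    "2" = list(s1 = data.frame(chrom = "chr1", start = 95, end = 250)),
    "4" = list(s1 = data.frame(chrom = character(), start = integer(),
                               end = integer()))))
  curve <- roc_like_curve(cs, labs)
  ## empty calls: no true or false positives
  empty_pt <- curve[curve$threshold == 4]
  expect_equal(c(empty_pt$tpr, empty_pt$fpr), c(0, 0))
  ## perfect calls: tpr 1, fpr 0
  perfect <- curve[curve$threshold == 2]
  expect_equal(c(perfect$tpr, perfect$fpr), c(1, 0))
  expect_true(all(curve$tpr >= 0 & curve$tpr <= 1))
  expect_true(all(curve$fpr >= 0 & curve$fpr <= 1))
  ## rates recompute from the by-type partition
  for (lam in cs$thresholds) {
    bt <- error_by_type(label_error(cs$calls[[as.character(lam)]], labs))
    n_pos <- sum(bt$n_labels[bt$type != "noPeaks"])
    n_fpc <- sum(bt$n_labels[bt$type != "peaks"])
    pt <- curve[abs(curve$threshold - lam) < 1e-9]
    expect_equal(pt$tpr, 1 - sum(bt$fn_total) / n_pos)
    expect_equal(pt$fpr, sum(bt$fp_total) / n_fpc)
  }
  expect_error(roc_like_curve(cs, labs[labs$type == "noPeaks"]),
               "no positive labels")
  expect_error(roc_like_curve(cs, labs[labs$type == "peaks"]),
               "no false-positive-capable labels")
})

test_that("learning curve: size 0 is the default model, curves are nested", {
  cs <- toy_set(default = 1)
  folds <- assign_folds(toy_labels, 3, 2)
  test_fold <- 1L
  lc <- learning_curve(cs, toy_labels, folds, test_fold, n_orders = 2,
                       seed = 3)
  at0 <- lc$per_order[lc$per_order$n_windows_trained == 0]
  test_ids <- as.integer(names(folds$assignment))[folds$assignment == test_fold]
  want <- evaluate(cs, 1, toy_labels[toy_labels$window_id %in% test_ids])
  expect_equal(unique(at0$percent_error), want$percent_error)
  expect_equal(unique(at0$threshold), 1)
  ## full-size training equals training on all other folds at once
  full <- lc$per_order[lc$per_order$n_windows_trained == 2]
  fit_all <- train(cs, toy_labels[!toy_labels$window_id %in% test_ids])
  expect_equal(unique(full$threshold), fit_all$chosen_threshold)
  expect_error(learning_curve(toy_set(default = NULL), toy_labels, folds, 1),
               "default threshold")
  expect_error(learning_curve(cs, toy_labels, folds, 1, max_train = 10),
               "exceeds")
})
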