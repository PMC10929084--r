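test_that("confusion counts tally by (truth, prediction)", {
  truth <- c(1, 1, 0, 0)
  pred <- c(1, 0, 0, 1)
  cc <- confusion_counts(truth, pred)
  expect_equal(cc, c(TP = 1L, TN = 1L, FP = 1L, FN = 1L))
  expect_equal(sum(cc), 4L)

  all_right <- confusion_counts(c(1, 0), c(1, 0))
  expect_equal(unname(all_right[c("FP", "FN")]), c(0L, 0L))
})

test_that("metric formulas match direct evaluation", {
  cc <- c(TP = 50, TN = 30, FP = 10, FN = 10)
  r <- metrics_from_counts(cc)
  expect_equal(r$ACC, 80 / 100)
  expect_equal(r$SEN, 50 / 60)
  expect_equal(r$SPE, 30 / 40)
  expect_equal(r$PRE, 50 / 60)
  expect_equal(r$F1, 2 * (50 / 60) * (50 / 60) / ((50 / 60) + (50 / 60)))
  expect_equal(r$MCC, (50 * 30 - 10 * 10) / sqrt(60 * 60 * 40 * 40))

  perfect <- metrics_from_counts(c(TP = 10, TN = 10, FP = 0, FN = 0),
                                 score = c(rep(0.9, 10), rep(0.1, 10)),
                                 truth = rep(c(1, 0), each = 10))
  for (m in c("ACC", "SEN", "SPE", "PRE", "F1", "MCC", "AUC")) {
    expect_equal(perfect[[m]], 1)
  }
})

test_that("degenerate denominators yield flagged zeros, not errors", {
  r <- metrics_from_counts(c(TP = 0, TN = 5, FP = 0, FN = 5))
  expect_equal(r$PRE, 0)
  expect_true("PRE" %in% r$degenerate)
  expect_equal(r$MCC, 0)
})

test_that("rank AUC matches known values and the trapezoidal oracle", {
  expect_equal(rank_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(rank_auc(c(0.5, 0.5), c(1, 0)), 0.5)   # ties: average ranks
  set.seed(91)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    truth <- rbinom(n, 1, 0.5)
    if (length(unique(truth)) < 2) truth <- c(truth[-(1:2)], 0, 1)
    score <- round(runif(n), sample(c(1, 2, 6), 1))   # induce ties sometimes
    expect_equal(rank_auc(score, truth), curves(score, truth)$auc,
                 tolerance = 1e-9)
  }
})

test_that("random scores on balanced labels give chance-level AUC", {
  set.seed(92)
  truth <- rep(0:1, each = 5000)
  score <- runif(10000)
  expect_equal(rank_auc(score, truth), 0.5, tolerance = 0.02)
})

test_that("swapping class labels swaps SEN/SPE and reflects AUC", {
  set.seed(93)
  truth <- rbinom(80, 1, 0.5)
  score <- runif(80)
  r <- classification_metrics(truth, score)
  rsw <- classification_metrics(1 - truth, 1 - score)
  expect_equal(r$SEN, rsw$SPE)
  expect_equal(r$SPE, rsw$SEN)
  expect_equal(rank_auc(score, 1 - truth), 1 - rank_auc(score, truth),
               tolerance = 1e-12)
})

test_that("curves reach (1,1), and perfect separation gives unit areas", {
  truth <- rep(c(1, 0), each = 20)
  score <- c(runif(20, 0.6, 1), runif(20, 0, 0.4))
  cv <- curves(score, truth)
  expect_equal(cv$auc, 1)
  expect_equal(cv$aupr, 1)
  expect_equal(cv$roc$fpr[1], 0)
  expect_equal(utils::tail(cv$roc$tpr, 1), 1)
  expect_error(curves(runif(5), rep(1, 5)),
               class = "rpifuse_single_class_error")
})

test_that("stratified folds are balanced, disjoint and exhaustive", {
  y <- rep(c(0, 1), times = c(33, 29))
  f <- stratified_folds(y, 5, seed = 2)
  expect_setequal(unique(f), 1:5)
  for (cls in 0:1) {
    sizes <- table(f[y == cls])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  expect_error(stratified_folds(rep(c(0, 1), c(3, 50)), 5),
               class = "rpifuse_too_few_samples")
})

test_that("cross-validation evaluates disjoint folds and averages them", {
  toy <- toy_blocks(n = 80, d1 = 25, d2 = 15, shift = 1.2, seed = 94)
  names(toy$blocks) <- c("sequence", "structure")
  cv <- cross_validate(toy$blocks, toy$y,
                       model_config(seed = 4, epochs = 3, patience = 0),
                       retain_fraction_seq = 0.8, retain_fraction_other = 0.8,
                       n_folds = 5, n_trees = 30, seed = 4)
  expect_equal(nrow(cv$folds), 5L)
  expect_equal(unname(cv$mean["ACC"]), mean(cv$folds$ACC), tolerance = 1e-12)
  expect_equal(unname(cv$mean["AUC"]), mean(cv$folds$AUC), tolerance = 1e-12)
})
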