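# Evaluation suite: confusion counts, the seven standard metrics
# (ACC, SEN, SPE, PRE, F1, MCC and rank-based AUC), ROC / PR curves, and
# a stratified five-fold cross-validation protocol that refits feature
# selection on the training folds only.

#' Confusion counts at the 0.5 threshold
#'
#' @param truth Factor or 0/1 vector of true labels.
#' @param predicted Factor or 0/1 vector of predicted classes.
#' @return Named integer vector `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, predicted) {
  t01 <- as_y01(truth); p01 <- as_y01(predicted)
  if (length(t01) == 0L) rpi_stop("no predictions", "rpifuse_dimension_error")
  c(TP = sum(t01 == 1L & p01 == 1L),
    TN = sum(t01 == 0L & p01 == 0L),
    FP = sum(t01 == 0L & p01 == 1L),
    FN = sum(t01 == 1L & p01 == 0L))
}

#' Rank-based AUC (Mann-Whitney formulation)
#'
#' \deqn{AUC = \frac{\sum_{i \in P} r_i - |P|(|P|+1)/2}{|P| \, |N|}}
#' where \eqn{r_i} are the ascending rank positions of the positive-class
#' scores in the pooled score set; ties receive average ranks.
#'
#' @param score Numeric scores.
#' @param truth True labels (factor or 0/1).
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(score, truth) {
  t01 <- as_y01(truth)
  n_pos <- sum(t01 == 1L); n_neg <- sum(t01 == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    rpi_stop("AUC needs both classes present", "rpifuse_single_class_error")
  }
  r <- rank(score, ties.method = "average")
  (sum(r[t01 == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Classification metric report
#'
#' Computes ACC, SEN (recall), SPE, PRE (positive predictive value),
#' F1, MCC and the rank-based AUC from scores and true labels at the 0.5
#' decision threshold. Metrics with an empty denominator (possible in
#' small folds) are reported as 0 and flagged in the `degenerate` field
#' rather than erroring.
#'
#' @param truth True labels (factor or 0/1).
#' @param score Numeric scores in \[0, 1\].
#' @param threshold Decision threshold (default 0.5, strict inequality).
#' @return A list of class `metric_report` with the seven metrics, the
#'   confusion counts and a `degenerate` character vector.
#' @export
classification_metrics <- function(truth, score, threshold = 0.5) {
  predicted <- threshold_scores(score, threshold)
  cc <- confusion_counts(truth, predicted)
  metrics_from_counts(cc, score = score, truth = truth)
}

#' Metrics from pre-computed confusion counts
#'
#' @param counts Named vector with `TP`, `TN`, `FP`, `FN`.
#' @param score,truth Optional scores and labels; when supplied, the
#'   rank-based AUC is included (otherwise `AUC` is `NA`).
#' @return A `metric_report` list.
#' @export
metrics_from_counts <- function(counts, score = NULL, truth = NULL) {
  TP <- counts[["TP"]]; TN <- counts[["TN"]]
  FP <- counts[["FP"]]; FN <- counts[["FN"]]
  degenerate <- character(0)
  flag <- function(name, den) {
    if (den == 0) degenerate <<- c(degenerate, name)
  }
  flag("SEN", TP + FN); flag("SPE", TN + FP); flag("PRE", TP + FP)
  acc <- safe_div(TP + TN, TP + TN + FP + FN)
  sen <- safe_div(TP, TP + FN)
  spe <- safe_div(TN, TN + FP)
  pre <- safe_div(TP, TP + FP)
  f1 <- safe_div(2 * pre * sen, pre + sen)
  if (pre + sen == 0) flag("F1", 0)
  mcc_den <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  mcc <- if (mcc_den == 0) { flag("MCC", 0); 0 }
         else (TP * TN - FP * FN) / mcc_den
  auc <- if (!is.null(score) && !is.null(truth)) rank_auc(score, truth)
         else NA_real_
  structure(list(ACC = acc, SEN = sen, SPE = spe, PRE = pre, F1 = f1,
                 MCC = mcc, AUC = auc, counts = counts,
                 degenerate = unique(degenerate)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("ACC %.4f  SEN %.4f  SPE %.4f  PRE %.4f  F1 %.4f  MCC %.4f  AUC %s\n",
              x$ACC, x$SEN, x$SPE, x$PRE, x$F1, x$MCC,
              ifelse(is.na(x$AUC), "NA", sprintf("%.4f", x$AUC))))
  if (length(x$degenerate)) {
    cat("degenerate denominators:", paste(x$degenerate, collapse = ", "), "\n")
  }
  invisible(x)
}

#' ROC and precision-recall curves
#'
#' Sweeps the decision threshold over the unique scores. The trapezoidal
#' ROC area equals the rank-based AUC; the PR area uses step-wise
#' interpolation (precision held constant between recall steps).
#'
#' @param score Numeric scores.
#' @param truth True labels (factor or 0/1); both classes must be present.
#' @return A list with data frames `roc` (`fpr`, `tpr`, `threshold`) and
#'   `pr` (`recall`, `precision`, `threshold`), plus scalars `auc`
#'   and `aupr`.
#' @export
curves <- function(score, truth) {
  t01 <- as_y01(truth)
  n_pos <- sum(t01 == 1L); n_neg <- sum(t01 == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    rpi_stop("curves need both classes present", "rpifuse_single_class_error")
  }
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; y <- t01[ord]
  tp <- cumsum(y); fp <- cumsum(1L - y)
  last <- c(s[-1] != s[-length(s)], TRUE)   # one point per unique score
  tp <- tp[last]; fp <- fp[last]; thr <- s[last]
  tpr <- c(0, tp / n_pos); fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  # step-wise PR area: precision of each threshold applies to the recall
  # increment it contributes
  aupr <- sum(diff(c(0, recall)) * precision)
  list(roc = data.frame(fpr = fpr, tpr = tpr, threshold = c(Inf, thr)),
       pr = data.frame(recall = recall, precision = precision,
                       threshold = thr),
       auc = auc, aupr = aupr)
}

#' Stratified fold assignment
#'
#' @param y Labels (factor or 0/1).
#' @param n_folds Number of folds.
#' @param seed RNG seed.
#' @return Integer vector of fold ids in `1:n_folds`, balanced per class
#'   (fold sizes differ by at most 1 within each class).
#' @export
stratified_folds <- function(y, n_folds = 5L, seed = 1L) {
  y01 <- as_y01(y)
  if (min(table(y01)) < n_folds) {
    rpi_stop(sprintf("need at least %d samples per class for %d-fold CV",
                     n_folds, n_folds),
             "rpifuse_too_few_samples")
  }
  set.seed(seed)
  folds <- integer(length(y01))
  for (cls in unique(y01)) {
    members <- sample(which(y01 == cls))
    folds[members] <- rep_len(seq_len(n_folds), length(members))
  }
  folds
}

#' Five-fold cross-validation of the full pipeline
#'
#' Pairs are partitioned into `n_folds` stratified subsets. For each fold,
#' Gini-importance feature selection is refitted on the other folds only
#' (no information from the held-out fold reaches the mask or the model),
#' the network is trained on the selected features, and the held-out fold
#' is scored. The summary row is the arithmetic mean of the fold metrics.
#'
#' @param X_blocks Named list of pre-selection feature matrices.
#' @param y Labels.
#' @param config A [model_config()].
#' @param retain_fraction_seq Retained fraction for the `sequence` block.
#' @param retain_fraction_other Retained fraction for all other blocks.
#' @param n_folds Number of folds (default 5).
#' @param n_trees Forest size for the selector.
#' @param seed Seed for the partition, the selector and training.
#' @return A list with `folds` (data frame of per-fold metrics) and `mean`
#'   (named numeric vector averaging the folds).
#' @export
cross_validate <- function(X_blocks, y, config = model_config(),
                           retain_fraction_seq = 0.8,
                           retain_fraction_other = 0.8,
                           n_folds = 5L, n_trees = 500L, seed = 1L) {
  y01 <- as_y01(y)
  folds <- stratified_folds(y01, n_folds, seed)
  rows <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- folds != f; te <- !tr
    sel <- lapply(names(X_blocks), function(bn) {
      frac <- if (identical(bn, "sequence")) retain_fraction_seq
              else retain_fraction_other
      imp <- gini_importance(X_blocks[[bn]][tr, , drop = FALSE], y01[tr],
                             n_trees = n_trees, seed = seed + f)
      select_block(imp, frac, block_name = bn)
    })
    names(sel) <- names(X_blocks)
    Xtr <- mapply(function(m, mk) apply_mask(m[tr, , drop = FALSE], mk),
                  X_blocks, sel, SIMPLIFY = FALSE)
    Xte <- mapply(function(m, mk) apply_mask(m[te, , drop = FALSE], mk),
                  X_blocks, sel, SIMPLIFY = FALSE)
    cfg <- config; cfg$seed <- config$seed + f
    fit <- fit_rpi_cnn(Xtr, y01[tr], cfg)
    pred <- predict(fit, Xte)
    rep <- classification_metrics(y01[te], pred$score)
    rows[[f]] <- data.frame(fold = f, ACC = rep$ACC, SEN = rep$SEN,
                            SPE = rep$SPE, PRE = rep$PRE, F1 = rep$F1,
                            MCC = rep$MCC, AUC = rep$AUC)
  }
  folds_df <- do.call(rbind, rows)
  list(folds = folds_df,
       mean = colMeans(folds_df[, -1, drop = FALSE]))
}
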