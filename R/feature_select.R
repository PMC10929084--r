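# Random-forest Gini-importance screening, applied independently to each
# feature block. Per-feature importance is the impurity-decrease sum
# (Gini impurity 1 - sum p_k^2, decrease at every node split on the
# feature, accumulated over all trees) normalized to sum to 1. The top
# floor(retain_fraction * dim) features are kept per block.

#' Gini (impurity-decrease) importance of each feature
#'
#' Grows a classification random forest and accumulates, for every
#' internal node split on a feature, the node Gini impurity minus the
#' weighted impurities of its children, summed over all trees; importances
#' are normalized to sum to 1. Deterministic given `seed`.
#'
#' @param X Numeric feature matrix (samples x features).
#' @param y Binary labels: factor, or coercible 0/1 vector.
#' @param n_trees Number of trees (default 500).
#' @param seed RNG seed for the forest.
#' @param ... Further arguments passed to [ranger::ranger()].
#' @return A numeric vector of importances (length `ncol(X)`, sums to 1).
#' @export
gini_importance <- function(X, y, n_trees = 500L, seed = 1L, ...) {
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2L) {
    rpi_stop("feature selection needs samples from both classes",
             "rpifuse_single_class_error")
  }
  if (min(table(y)) < 2L) {
    rpi_stop("need at least 2 samples per class", "rpifuse_single_class_error")
  }
  X <- as.matrix(X)
  if (anyNA(X)) rpi_stop("missing values in feature matrix", "rpifuse_na_error")
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  fit <- ranger::ranger(x = X, y = y, num.trees = n_trees,
                        importance = "impurity", seed = seed,
                        num.threads = 1L, ...)
  imp <- fit$variable.importance
  imp[imp < 0] <- 0
  total <- sum(imp)
  if (total == 0) return(unname(imp))
  unname(imp / total)
}

#' Select the top fraction of a feature block by importance
#'
#' Keeps the `floor(retain_fraction * dim)` highest-importance feature
#' positions; ties are broken by lower original index. The kept indices
#' are ordered by descending importance.
#'
#' @param importances Numeric importance vector for the block.
#' @param retain_fraction Fraction of features to keep, in (0, 1].
#' @param block_name Optional block label carried in the mask.
#' @return An object of class `selection_mask`: list with `block_name`,
#'   `kept_indices`, `importances`, `retain_fraction`.
#' @export
select_block <- function(importances, retain_fraction = 0.8,
                         block_name = "block") {
  if (!is.numeric(retain_fraction) || retain_fraction <= 0 ||
      retain_fraction > 1) {
    rpi_stop("retain_fraction must be in (0, 1]", "rpifuse_fraction_range_error")
  }
  d <- length(importances)
  n_keep <- floor(retain_fraction * d)
  ord <- order(-importances, seq_len(d))   # ties -> lower original index
  structure(list(block_name = block_name,
                 kept_indices = ord[seq_len(n_keep)],
                 importances = importances,
                 retain_fraction = retain_fraction),
            class = "selection_mask")
}

#' Apply a selection mask to a feature matrix
#'
#' @param X Feature matrix whose columns match the mask's original block.
#' @param mask A `selection_mask` from [select_block()].
#' @return `X` restricted to the kept columns (descending importance order).
#' @export
apply_mask <- function(X, mask) {
  if (ncol(X) != length(mask$importances)) {
    rpi_stop(sprintf("mask fitted on %d features, matrix has %d columns",
                     length(mask$importances), ncol(X)),
             "rpifuse_dimension_error")
  }
  X[, mask$kept_indices, drop = FALSE]
}

#' @export
print.selection_mask <- function(x, ...) {
  cat(sprintf("selection_mask '%s': kept %d / %d features (fraction %.2f)\n",
              x$block_name, length(x$kept_indices), length(x$importances),
              x$retain_fraction))
  invisible(x)
}
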