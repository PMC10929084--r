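# Parallel multi-branch convolutional classifier. Each feature block feeds
# its own branch of 1-D convolutions (kernel length 3; ReLU before batch
# normalization; max-pooling of width 2); flattened branch outputs are
# fused either by concatenation into one vector ahead of a fully connected
# 16-8-2 head with softmax output, or by stacking: per-branch networks are
# trained first and their predicted class probabilities become the
# meta-features of a second-stage 16-8-2 classifier. A pair is called
# interacting when the positive-class probability exceeds 0.5.

#' Classifier configuration
#'
#' @param fusion Branch fusion strategy, `"concatenate"` (default) or
#'   `"stacking"`.
#' @param optimizer `"adam"` (default, learning rate 1e-3) or `"sgd"`
#'   (momentum 0.9).
#' @param learning_rate Step size.
#' @param batch_size Minibatch size.
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience on validation loss (epochs);
#'   0 disables early stopping and the validation split.
#' @param validation_fraction Fraction of training pairs held out per class
#'   for early stopping.
#' @param channels Convolution channels per layer (all branches).
#' @param seed Seed controlling weight initialization, the validation
#'   split and minibatch shuffling.
#' @return A list of class `rpi_cnn_config`. Kernel size (3), pooling
#'   width (2), the fully connected sizes (16, 8, 2) and the 0.5 decision
#'   threshold are fixed aspects of the architecture.
#' @export
model_config <- function(fusion = c("concatenate", "stacking"),
                         optimizer = c("adam", "sgd"),
                         learning_rate = 1e-3,
                         batch_size = 32L,
                         epochs = 50L,
                         patience = 10L,
                         validation_fraction = 0.15,
                         channels = 16L,
                         seed = 1L) {
  fusion <- fuse_strategy(fusion)
  optimizer <- match.arg(optimizer)
  structure(list(fusion = fusion, optimizer = optimizer,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 channels = as.integer(channels),
                 kernel = 3L, pool = 2L, fc_sizes = c(16L, 8L, 2L),
                 threshold = 0.5, seed = as.integer(seed)),
            class = "rpi_cnn_config")
}

fuse_strategy <- function(strategy) {
  if (length(strategy) > 1L) strategy <- strategy[1L]
  if (!strategy %in% c("concatenate", "stacking")) {
    rpi_stop(sprintf("unknown fusion strategy '%s'", strategy),
             "rpifuse_strategy_error")
  }
  strategy
}

#' Fuse branch outputs
#'
#' `"concatenate"` joins the flattened branch output matrices column-wise
#' into one feature matrix. `"stacking"` expects per-branch class
#' probability matrices (n x 2) and joins them into the meta-feature
#' matrix of the second-stage classifier (n x 2 per branch).
#'
#' @param branch_outputs List of at least two numeric matrices with equal
#'   row counts.
#' @param strategy `"concatenate"` or `"stacking"`.
#' @return The fused matrix.
#' @export
fuse_branches <- function(branch_outputs, strategy = "concatenate") {
  strategy <- fuse_strategy(strategy)
  if (length(branch_outputs) < 2L) {
    rpi_stop("fusion needs at least two branch outputs",
             "rpifuse_dimension_error")
  }
  if (strategy == "stacking" &&
      !all(vapply(branch_outputs, ncol, integer(1)) == 2L)) {
    rpi_stop("stacking fusion expects n x 2 class-probability matrices",
             "rpifuse_dimension_error")
  }
  do.call(cbind, branch_outputs)
}

#' Initialize an untrained multi-branch network
#'
#' Plans one branch per feature block (full three-convolution branch where
#' the block is long enough; a single convolution + pooling block as a
#' logged fallback for very short inputs) plus the fully connected
#' 16-8-2 head.
#'
#' @param config A [model_config()].
#' @param block_dims Named integer vector of per-block input widths (the
#'   post-selection dimensions).
#' @return An object of class `rpi_cnn` (untrained).
#' @export
build_cnn <- function(config, block_dims) {
  if (any(block_dims <= 0L)) {
    rpi_stop("all block dims must be positive", "rpifuse_config_error")
  }
  set.seed(config$seed)
  plans <- lapply(as.integer(block_dims), branch_plan,
                  channels = config$channels, kernel = config$kernel)
  for (i in seq_along(plans)) {
    if (plans[[i]]$type == "short") {
      message(sprintf("branch %d (dim %d): input too short for three conv layers; using single conv + pool",
                      i, block_dims[[i]]))
    }
  }
  flat <- sum(vapply(plans, `[[`, integer(1), "flat"))
  fc <- config$fc_sizes
  par <- list(branches = lapply(plans, init_branch, kernel = config$kernel),
              head = list(d1 = init_dense(flat, fc[1]),
                          d2 = init_dense(fc[1], fc[2]),
                          d3 = init_dense(fc[2], fc[3])))
  structure(list(params = par, plans = plans, config = config,
                 block_dims = as.integer(block_dims),
                 block_names = names(block_dims),
                 fc_dims = list(d1 = c(flat, fc[1]), d2 = c(fc[1], fc[2]),
                                d3 = c(fc[2], fc[3])),
                 bn_stats = NULL, trained = FALSE),
            class = "rpi_cnn")
}

check_blocks <- function(X_blocks, block_dims = NULL) {
  if (!is.list(X_blocks)) rpi_stop("X_blocks must be a list of matrices",
                                   "rpifuse_dimension_error")
  n <- unique(vapply(X_blocks, nrow, integer(1)))
  if (length(n) != 1L) {
    rpi_stop("all feature blocks must have the same number of rows",
             "rpifuse_dimension_error")
  }
  if (!is.null(block_dims)) {
    got <- vapply(X_blocks, ncol, integer(1))
    if (!identical(unname(got), unname(block_dims))) {
      rpi_stop(sprintf("block dims (%s) do not match model (%s)",
                       paste(got, collapse = ","),
                       paste(block_dims, collapse = ",")),
               "rpifuse_dimension_error")
    }
  }
  n
}

as_y01 <- function(y) {
  if (is.factor(y)) y <- as.integer(y == "positive")
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) {
    rpi_stop("labels must be 0/1 or a negative/positive factor",
             "rpifuse_label_error")
  }
  y
}

#' Train the multi-branch CNN
#'
#' Minibatch backpropagation on the softmax cross-entropy, with Adam
#' (default) or momentum SGD, seeded weight initialization and shuffling,
#' and early stopping on a stratified validation split. With
#' `fusion = "stacking"` each block first trains its own single-branch
#' network; the per-branch predicted probabilities on the training set
#' become the 2-per-branch meta-features of a second-stage 16-8-2
#' classifier.
#'
#' @param X_blocks Named list of feature matrices (rows = pairs), one per
#'   block, all with identical row order.
#' @param y Labels: `negative`/`positive` factor or 0/1 vector.
#' @param config A [model_config()].
#' @return A trained `rpi_cnn` (for stacking, an `rpi_cnn_stack` holding
#'   the branch models and the meta-model). `$loss_history` records the
#'   mean training loss per epoch.
#' @export
fit_rpi_cnn <- function(X_blocks, y, config = model_config()) {
  n <- check_blocks(X_blocks)
  y01 <- as_y01(y)
  if (length(y01) != n) rpi_stop("label length != number of rows",
                                 "rpifuse_dimension_error")
  if (length(unique(y01)) < 2L) {
    rpi_stop("training needs at least one sample of each class",
             "rpifuse_single_class_error")
  }
  if (config$fusion == "stacking") {
    return(fit_rpi_stack(X_blocks, y01, config))
  }
  model <- build_cnn(config, vapply(X_blocks, ncol, integer(1)))
  model$block_names <- names(X_blocks)
  fit_net(model, X_blocks, y01, config)
}

# shared fitting loop for any branch layout (conv branches or identity)
fit_net <- function(model, X_blocks, y01, config) {
  set.seed(config$seed + 1L)
  n <- nrow(X_blocks[[1]])
  idx_val <- integer(0)
  if (config$patience > 0L && config$validation_fraction > 0) {
    for (cls in c(0L, 1L)) {
      members <- which(y01 == cls)
      n_val <- floor(length(members) * config$validation_fraction)
      if (n_val >= 1L && length(members) - n_val >= 2L) {
        idx_val <- c(idx_val, sample(members, n_val))
      }
    }
  }
  use_val <- length(idx_val) > 0L && length(unique(y01[idx_val])) == 2L
  idx_tr <- if (use_val) setdiff(seq_len(n), idx_val) else seq_len(n)
  Xtr <- lapply(X_blocks, function(m) m[idx_tr, , drop = FALSE])
  ytr <- y01[idx_tr]
  # per-column standardization, fitted on the training portion only;
  # puts the heterogeneous block scales (frequencies, cosine coefficients,
  # PCA scores) on a comparable footing for the convolutions
  model$scaling <- lapply(Xtr, function(m) {
    mu <- colMeans(m)
    sd <- sqrt(colMeans(sweep(m, 2L, mu)^2))
    sd[sd == 0] <- 1
    list(mu = mu, sd = sd)
  })
  Xtr <- scale_blocks(Xtr, model$scaling)
  if (use_val) {
    Xval <- scale_blocks(lapply(X_blocks,
                                function(m) m[idx_val, , drop = FALSE]),
                         model$scaling)
    yval <- y01[idx_val]
  }

  par <- model$params
  opt_m <- zeros_like(par); opt_v <- zeros_like(par)
  t_step <- 0L
  loss_history <- numeric(0)
  val_history <- numeric(0)
  best_val <- Inf; best_par <- par; stale <- 0L
  n_tr <- length(ytr)

  for (epoch in seq_len(config$epochs)) {
    ord <- sample(n_tr)
    starts <- seq(1L, n_tr, by = config$batch_size)
    batch_losses <- numeric(length(starts))
    for (s in seq_along(starts)) {
      take <- ord[starts[s]:min(starts[s] + config$batch_size - 1L, n_tr)]
      if (length(take) < 2L && length(starts) > 1L) {
        take <- c(take, ord[1L])            # avoid degenerate BN batch
      }
      Xb <- lapply(Xtr, function(m) m[take, , drop = FALSE])
      yb <- ytr[take]
      fwd <- net_fwd(par, model$plans, Xb)
      batch_losses[s] <- cross_entropy(fwd$p, yb)
      one_hot <- matrix(0, length(yb), 2L)
      one_hot[cbind(seq_along(yb), yb + 1L)] <- 1
      dZ <- (fwd$p - one_hot) / length(yb)
      grads <- net_bwd(par, model$plans, fwd$cache, dZ)
      t_step <- t_step + 1L
      if (config$optimizer == "adam") {
        r <- adam_step(par, grads, opt_m, opt_v, config$learning_rate, t_step)
        par <- r$p; opt_m <- r$m; opt_v <- r$v
      } else {
        r <- sgd_step(par, grads, opt_m, config$learning_rate)
        par <- r$p; opt_m <- r$u
      }
    }
    loss_history <- c(loss_history, mean(batch_losses))
    if (use_val) {
      pv <- net_fwd(par, model$plans, Xval)$p
      vl <- cross_entropy(pv, yval)
      val_history <- c(val_history, vl)
      if (vl < best_val - 1e-6) {
        best_val <- vl; best_par <- par; stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= config$patience) break
      }
    }
  }
  if (use_val) par <- best_par

  model$params <- par
  # inference batch-norm statistics from one pass over the training portion
  model$bn_stats <- net_fwd(par, model$plans, Xtr)$stats
  model$loss_history <- loss_history
  model$val_history <- val_history
  model$trained <- TRUE
  model
}

fit_rpi_stack <- function(X_blocks, y01, config) {
  branch_cfg <- config
  branch_cfg$fusion <- "concatenate"
  branch_models <- vector("list", length(X_blocks))
  branch_probs <- vector("list", length(X_blocks))
  for (i in seq_along(X_blocks)) {
    branch_cfg$seed <- config$seed + i
    m <- build_cnn(branch_cfg, ncol(X_blocks[[i]]))
    m <- fit_net(m, X_blocks[i], y01, branch_cfg)
    branch_models[[i]] <- m
    p <- predict_net(m, X_blocks[i])
    branch_probs[[i]] <- cbind(1 - p, p)
  }
  meta_X <- fuse_branches(branch_probs, "stacking")
  meta_cfg <- config
  meta_cfg$fusion <- "concatenate"
  meta_cfg$seed <- config$seed + length(X_blocks) + 1L
  meta <- structure(list(params = NULL,
                         plans = list(list(type = "identity", d_in = ncol(meta_X),
                                           flat = ncol(meta_X),
                                           channels = config$channels)),
                         config = meta_cfg,
                         block_dims = ncol(meta_X), block_names = "meta",
                         bn_stats = NULL, trained = FALSE),
                    class = "rpi_cnn")
  set.seed(meta_cfg$seed)
  fc <- config$fc_sizes
  meta$params <- list(branches = list(list()),
                      head = list(d1 = init_dense(ncol(meta_X), fc[1]),
                                  d2 = init_dense(fc[1], fc[2]),
                                  d3 = init_dense(fc[2], fc[3])))
  meta$fc_dims <- list(d1 = c(ncol(meta_X), fc[1]), d2 = c(fc[1], fc[2]),
                       d3 = c(fc[2], fc[3]))
  meta <- fit_net(meta, list(meta_X), y01, meta_cfg)
  structure(list(branch_models = branch_models, meta_model = meta,
                 config = config,
                 block_dims = vapply(X_blocks, ncol, integer(1)),
                 block_names = names(X_blocks),
                 loss_history = meta$loss_history, trained = TRUE),
            class = c("rpi_cnn_stack", "rpi_cnn"))
}

scale_blocks <- function(X_blocks, scaling) {
  mapply(function(m, s) sweep(sweep(m, 2L, s$mu), 2L, s$sd, "/"),
         X_blocks, scaling, SIMPLIFY = FALSE)
}

# positive-class probability from a fitted single network
predict_net <- function(model, X_blocks, chunk = 512L) {
  if (!is.null(model$scaling)) {
    X_blocks <- scale_blocks(X_blocks, model$scaling)
  }
  n <- nrow(X_blocks[[1]])
  out <- numeric(n)
  starts <- seq(1L, n, by = chunk)
  for (s in starts) {
    take <- s:min(s + chunk - 1L, n)
    Xb <- lapply(X_blocks, function(m) m[take, , drop = FALSE])
    out[take] <- net_fwd(model$params, model$plans, Xb,
                         stats = model$bn_stats)$p[, 2L]
  }
  out
}

#' Score pairs with a trained model
#'
#' @param object A trained `rpi_cnn` or `rpi_cnn_stack`.
#' @param X_blocks Named list of feature matrices with the dimensions the
#'   model was trained on.
#' @param ... Unused.
#' @return A data frame with `score` (softmax probability of the positive
#'   class) and `predicted` (factor; `positive` iff score > 0.5).
#' @export
predict.rpi_cnn <- function(object, X_blocks, ...) {
  if (!isTRUE(object$trained)) rpi_stop("model is not trained",
                                        "rpifuse_config_error")
  check_blocks(X_blocks, object$block_dims)
  score <- predict_net(object, X_blocks)
  data.frame(score = score, predicted = threshold_scores(score))
}

#' @export
predict.rpi_cnn_stack <- function(object, X_blocks, ...) {
  check_blocks(X_blocks, object$block_dims)
  probs <- lapply(seq_along(X_blocks), function(i) {
    p <- predict_net(object$branch_models[[i]], X_blocks[i])
    cbind(1 - p, p)
  })
  meta_X <- fuse_branches(probs, "stacking")
  score <- predict_net(object$meta_model, list(meta_X))
  data.frame(score = score, predicted = threshold_scores(score))
}

#' Threshold scores into classes
#'
#' A pair is called interacting only when its score strictly exceeds the
#' threshold; a score of exactly 0.5 is classed negative.
#'
#' @param score Numeric scores in \[0, 1\].
#' @param threshold Decision threshold (default 0.5).
#' @return Factor with levels `negative`, `positive`.
#' @export
threshold_scores <- function(score, threshold = 0.5) {
  factor(ifelse(score > threshold, "positive", "negative"),
         levels = c("negative", "positive"))
}

#' Trainable parameter counts per fully connected layer
#'
#' @param model An `rpi_cnn`.
#' @return Named integer vector of `(in + 1) * out` counts for the three
#'   head layers.
#' @export
fc_parameter_counts <- function(model) {
  vapply(model$fc_dims, function(d) (d[1] + 1L) * d[2], integer(1))
}

#' @export
print.rpi_cnn <- function(x, ...) {
  cat(sprintf("rpi_cnn (%s fusion, %s): %d branch(es), head %s; %s\n",
              x$config$fusion, x$config$optimizer, length(x$block_dims),
              paste(x$config$fc_sizes, collapse = "-"),
              if (isTRUE(x$trained)) sprintf("trained (%d epochs)",
                                             length(x$loss_history))
              else "untrained"))
  invisible(x)
}
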