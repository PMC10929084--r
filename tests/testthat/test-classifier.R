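test_that("fully connected head has the fixed 16-8-2 layout", {
  cfg <- model_config(seed = 1)
  model <- build_cnn(cfg, c(block = 20L))
  # dim 20 branch: conv 18 -> conv 16 -> pool 8 -> conv 6 -> pool 3,
  # 16 channels -> 48 flattened units
  expect_equal(unname(fc_parameter_counts(model)),
               c((48 + 1) * 16, (16 + 1) * 8, (8 + 1) * 2))
  expect_equal(model$config$fc_sizes, c(16L, 8L, 2L))
  expect_equal(dim(model$params$head$d3$W), c(8L, 2L))
})

test_that("short inputs fall back to one conv block; tiny inputs error", {
  cfg <- model_config(seed = 1)
  expect_message(m <- build_cnn(cfg, c(x = 6L)), "single conv")
  expect_equal(m$plans[[1]]$type, "short")
  expect_error(suppressMessages(build_cnn(cfg, c(x = 3L))),
               class = "rpifuse_config_error")
  expect_error(build_cnn(cfg, c(x = 0L)), class = "rpifuse_config_error")
})

test_that("softmax outputs are normalized probabilities", {
  cfg <- model_config(seed = 2)
  model <- build_cnn(cfg, c(a = 14L, b = 20L))
  X <- list(matrix(0, 5, 14), matrix(0, 5, 20))
  p <- rpifuse:::net_fwd(model$params, model$plans, X)$p
  expect_true(all(is.finite(p)))
  expect_equal(unname(rowSums(p)), rep(1, 5), tolerance = 1e-6)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("analytic gradients match finite differences", {
  set.seed(81)
  cfg <- model_config(seed = 3, channels = 2)
  model <- suppressMessages(build_cnn(cfg, c(a = 14L, b = 5L)))
  B <- 6L
  X <- list(matrix(rnorm(B * 14), B), matrix(rnorm(B * 5), B))
  y <- c(0L, 1L, 0L, 1L, 1L, 0L)
  par <- model$params
  fwd <- rpifuse:::net_fwd(par, model$plans, X)
  one_hot <- matrix(0, B, 2); one_hot[cbind(1:B, y + 1)] <- 1
  G <- rpifuse:::net_bwd(par, model$plans, fwd$cache, (fwd$p - one_hot) / B)
  loss_of <- function(p) rpifuse:::cross_entropy(
    rpifuse:::net_fwd(p, model$plans, X)$p, y)
  modify <- function(P, path, i, delta) {
    if (length(path) == 1L) {
      P[[path[[1]]]][i] <- P[[path[[1]]]][i] + delta
      return(P)
    }
    P[[path[[1]]]] <- modify(P[[path[[1]]]], path[-1], i, delta)
    P
  }
  paths <- list(list("head", "d3", "W"), list("head", "d1", "b"),
                list("branches", 1L, "conv1", "W", 1L),
                list("branches", 1L, "conv3", "W", 2L),
                list("branches", 1L, "bn2", "gamma"),
                list("branches", 2L, "conv1", "W", 3L),
                list("branches", 2L, "bn1", "beta"))
  eps <- 1e-5
  for (path in paths) {
    g <- G; for (k in path) g <- g[[k]]
    leaf <- par; for (k in path) leaf <- leaf[[k]]
    for (i in sample(length(leaf), min(2L, length(leaf)))) {
      num <- (loss_of(modify(par, path, i, eps)) -
                loss_of(modify(par, path, i, -eps))) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-4)
    }
  }
})

test_that("training reduces the loss on separable data, deterministically", {
  toy <- toy_blocks(n = 60, seed = 82)
  cfg <- model_config(seed = 5, epochs = 15, patience = 0, batch_size = 16)
  fit1 <- fit_rpi_cnn(toy$blocks, toy$y, cfg)
  expect_lt(utils::tail(fit1$loss_history, 1), fit1$loss_history[1])
  fit2 <- fit_rpi_cnn(toy$blocks, toy$y, cfg)
  expect_identical(fit1$loss_history, fit2$loss_history)

  pred <- predict(fit1, toy$blocks)
  expect_true(all(pred$score >= 0 & pred$score <= 1))
  acc <- mean((pred$score > 0.5) == (toy$y == 1))
  expect_gt(acc, 0.9)
  # identical inputs score identically
  rep_rows <- lapply(toy$blocks, function(m) m[c(1, 1), , drop = FALSE])
  pr <- predict(fit1, rep_rows)
  expect_equal(pr$score[1], pr$score[2])
})

test_that("single-class training data is rejected", {
  toy <- toy_blocks(n = 20, seed = 83)
  expect_error(fit_rpi_cnn(toy$blocks, rep(1L, 20), model_config(seed = 1)),
               class = "rpifuse_single_class_error")
})

test_that("SGD optimizer also trains", {
  toy <- toy_blocks(n = 40, seed = 84)
  cfg <- model_config(optimizer = "sgd", learning_rate = 0.01, seed = 6,
                      epochs = 12, patience = 0, batch_size = 10)
  fit <- fit_rpi_cnn(toy$blocks, toy$y, cfg)
  expect_lt(utils::tail(fit$loss_history, 1), fit$loss_history[1])
})

test_that("a score of exactly 0.5 is classed negative", {
  cls <- threshold_scores(c(0.5, 0.5 + 1e-9, 0.49))
  expect_identical(as.character(cls), c("negative", "positive", "negative"))
})

test_that("fusion strategies have the documented output shapes", {
  outs <- list(matrix(1, 3, 4), matrix(2, 3, 6), matrix(3, 3, 2))
  expect_equal(ncol(fuse_branches(outs, "concatenate")), 12L)

  probs <- replicate(4, {p <- runif(3); cbind(1 - p, p)}, simplify = FALSE)
  meta <- fuse_branches(probs, "stacking")
  expect_equal(dim(meta), c(3L, 8L))

  expect_error(fuse_branches(outs, "blend"), class = "rpifuse_strategy_error")
  expect_error(fuse_branches(outs, "stacking"),
               class = "rpifuse_dimension_error")
  expect_error(fuse_branches(outs[1], "concatenate"),
               class = "rpifuse_dimension_error")
  expect_error(model_config(fusion = "blend"),
               class = "rpifuse_strategy_error")
})

test_that("stacking fusion trains branch models plus a meta-classifier", {
  toy <- toy_blocks(n = 50, seed = 85)
  cfg <- model_config(fusion = "stacking", seed = 7, epochs = 6, patience = 0)
  fit <- fit_rpi_cnn(toy$blocks, toy$y, cfg)
  expect_s3_class(fit, "rpi_cnn_stack")
  expect_length(fit$branch_models, 2L)
  expect_equal(fit$meta_model$block_dims, 4L)   # 2 branches x 2 probabilities
  pred <- predict(fit, toy$blocks)
  expect_true(all(pred$score >= 0 & pred$score <= 1))
})

test_that("prediction enforces the trained feature dimensions", {
  toy <- toy_blocks(n = 30, seed = 86)
  fit <- fit_rpi_cnn(toy$blocks, toy$y,
                     model_config(seed = 8, epochs = 2, patience = 0))
  wrong <- list(toy$blocks[[1]][, -1], toy$blocks[[2]])
  expect_error(predict(fit, wrong), class = "rpifuse_dimension_error")
})
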