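# Internal neural-network primitives. Activations are 3-D arrays
# (batch, length, channels); 1-D convolutions are computed as one matrix
# product per kernel offset so all heavy lifting goes through BLAS.
# Batch normalization uses batch statistics during training; inference
# statistics are collected in a single full pass over the training set
# after fitting, which keeps the fit loop free of running-average state.

BN_EPS <- 1e-5

nn_rnorm <- function(n, sd) stats::rnorm(n, mean = 0, sd = sd)

init_conv <- function(c_in, c_out, k) {
  sd <- sqrt(2 / (k * c_in))
  list(W = lapply(seq_len(k), function(i)
         matrix(nn_rnorm(c_in * c_out, sd), c_in, c_out)),
       b = numeric(c_out))
}

init_bn <- function(c_out) list(gamma = rep(1, c_out), beta = numeric(c_out))

init_dense <- function(d_in, d_out) {
  list(W = matrix(nn_rnorm(d_in * d_out, sqrt(2 / d_in)), d_in, d_out),
       b = numeric(d_out))
}

conv1d_fwd <- function(A, layer) {
  d <- dim(A); B <- d[1]; L <- d[2]; c_in <- d[3]
  K <- length(layer$W); c_out <- length(layer$b)
  Lout <- L - K + 1L
  Y <- matrix(layer$b, B * Lout, c_out, byrow = TRUE)
  for (k in seq_len(K)) {
    Xk <- A[, k:(k + Lout - 1L), , drop = FALSE]
    dim(Xk) <- c(B * Lout, c_in)
    Y <- Y + Xk %*% layer$W[[k]]
  }
  array(Y, c(B, Lout, c_out))
}

conv1d_bwd <- function(dY, A, layer) {
  d <- dim(A); B <- d[1]; c_in <- d[3]
  K <- length(layer$W); c_out <- length(layer$b)
  Lout <- dim(dY)[2]
  dYm <- dY; dim(dYm) <- c(B * Lout, c_out)
  dA <- array(0, d)
  dW <- vector("list", K)
  for (k in seq_len(K)) {
    Xk <- A[, k:(k + Lout - 1L), , drop = FALSE]
    dim(Xk) <- c(B * Lout, c_in)
    dW[[k]] <- crossprod(Xk, dYm)
    dXk <- dYm %*% t(layer$W[[k]])
    dim(dXk) <- c(B, Lout, c_in)
    dA[, k:(k + Lout - 1L), ] <- dA[, k:(k + Lout - 1L), , drop = FALSE] + dXk
  }
  list(dA = dA, grad = list(W = dW, b = colSums(dYm)))
}

relu_fwd <- function(A) list(Y = A * (A > 0), mask = A > 0)

bn_fwd <- function(A, layer, stats = NULL) {
  d <- dim(A)
  Xm <- A; dim(Xm) <- c(d[1] * d[2], d[3])
  if (is.null(stats)) {
    mu <- colMeans(Xm)
    va <- colMeans(Xm^2) - mu^2
  } else {
    mu <- stats$mu; va <- stats$va
  }
  invstd <- 1 / sqrt(va + BN_EPS)
  xhat <- sweep(sweep(Xm, 2L, mu), 2L, invstd, "*")
  Y <- sweep(sweep(xhat, 2L, layer$gamma, "*"), 2L, layer$beta, "+")
  dim(Y) <- d
  list(Y = Y, cache = list(xhat = xhat, invstd = invstd, d = d),
       stats = list(mu = mu, va = va))
}

bn_bwd <- function(dY, layer, cache) {
  d <- cache$d
  dYm <- dY; dim(dYm) <- c(d[1] * d[2], d[3])
  xhat <- cache$xhat
  dgamma <- colSums(dYm * xhat)
  dbeta <- colSums(dYm)
  dxhat <- sweep(dYm, 2L, layer$gamma, "*")
  N <- nrow(dYm)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dXm <- sweep(N * dxhat -
                 matrix(s1, N, d[3], byrow = TRUE) -
                 xhat * matrix(s2, N, d[3], byrow = TRUE),
               2L, cache$invstd / N, "*")
  dim(dXm) <- d
  list(dA = dXm, grad = list(gamma = dgamma, beta = dbeta))
}

pool2_fwd <- function(A) {
  d <- dim(A); Lp <- d[2] %/% 2L
  i1 <- seq(1L, by = 2L, length.out = Lp)
  A1 <- A[, i1, , drop = FALSE]
  A2 <- A[, i1 + 1L, , drop = FALSE]
  mask <- A1 >= A2                      # ties routed to the earlier position
  Y <- A1 * mask + A2 * !mask
  list(Y = Y, mask = mask, d_in = d)
}

pool2_bwd <- function(dY, cache) {
  dA <- array(0, cache$d_in)
  Lp <- dim(dY)[2]
  i1 <- seq(1L, by = 2L, length.out = Lp)
  dA[, i1, ] <- dY * cache$mask
  dA[, i1 + 1L, ] <- dY * !cache$mask
  dA
}

dense_fwd <- function(X, layer) {
  sweep(X %*% layer$W, 2L, layer$b, "+")
}

dense_bwd <- function(dY, X, layer) {
  list(dX = dY %*% t(layer$W),
       grad = list(W = crossprod(X, dY), b = colSums(dY)))
}

softmax_rows <- function(Z) {
  e <- exp(Z - apply(Z, 1L, max))
  e / rowSums(e)
}

# ---- branch architecture -------------------------------------------------

# Full branch: conv-relu-bn, conv-relu-bn, pool, conv-relu-bn, pool
# (three conv layers, two pooled blocks, the first holding two of them).
# Inputs too short for the full stack fall back to a single
# conv-relu-bn-pool block; inputs too short even for that are rejected.
branch_plan <- function(d_in, channels, kernel = 3L) {
  full_l5 <- ((d_in - 2L * (kernel - 1L)) %/% 2L - (kernel - 1L)) %/% 2L
  if (full_l5 >= 1L) {
    return(list(type = "full", d_in = d_in,
                flat = full_l5 * channels, channels = channels))
  }
  short_lp <- (d_in - (kernel - 1L)) %/% 2L
  if (short_lp >= 1L) {
    return(list(type = "short", d_in = d_in,
                flat = short_lp * channels, channels = channels))
  }
  rpi_stop(sprintf("branch input dim %d too small for convolution + pooling",
                   d_in),
           "rpifuse_config_error")
}

init_branch <- function(plan, kernel = 3L) {
  ch <- plan$channels
  if (plan$type == "identity") return(list())
  if (plan$type == "short") {
    return(list(conv1 = init_conv(1L, ch, kernel), bn1 = init_bn(ch)))
  }
  list(conv1 = init_conv(1L, ch, kernel), bn1 = init_bn(ch),
       conv2 = init_conv(ch, ch, kernel), bn2 = init_bn(ch),
       conv3 = init_conv(ch, ch, kernel), bn3 = init_bn(ch))
}

branch_fwd <- function(X, par, plan, stats = NULL) {
  if (plan$type == "identity") {
    return(list(out = X, cache = list(type = "identity"), stats = list()))
  }
  st <- function(name) if (is.null(stats)) NULL else stats[[name]]
  B <- nrow(X)
  A0 <- array(X, c(B, ncol(X), 1L))
  c1 <- conv1d_fwd(A0, par$conv1)
  r1 <- relu_fwd(c1)
  n1 <- bn_fwd(r1$Y, par$bn1, st("bn1"))
  out_stats <- list(bn1 = n1$stats)
  if (plan$type == "short") {
    p1 <- pool2_fwd(n1$Y)
    out <- p1$Y; dim(out) <- c(B, plan$flat)
    return(list(out = out,
                cache = list(type = "short", A0 = A0, m1 = r1$mask,
                             bc1 = n1$cache, p1 = p1,
                             out_dim = dim(p1$Y)),
                stats = out_stats))
  }
  c2 <- conv1d_fwd(n1$Y, par$conv2)
  r2 <- relu_fwd(c2)
  n2 <- bn_fwd(r2$Y, par$bn2, st("bn2"))
  p1 <- pool2_fwd(n2$Y)
  c3 <- conv1d_fwd(p1$Y, par$conv3)
  r3 <- relu_fwd(c3)
  n3 <- bn_fwd(r3$Y, par$bn3, st("bn3"))
  p2 <- pool2_fwd(n3$Y)
  out_stats$bn2 <- n2$stats
  out_stats$bn3 <- n3$stats
  out <- p2$Y; dim(out) <- c(B, plan$flat)
  list(out = out,
       cache = list(type = "full", A0 = A0, A1 = n1$Y, A2 = p1$Y,
                    m1 = r1$mask, m2 = r2$mask, m3 = r3$mask,
                    bc1 = n1$cache, bc2 = n2$cache, bc3 = n3$cache,
                    p1 = p1, p2 = p2, out_dim = dim(p2$Y)),
       stats = out_stats)
}

branch_bwd <- function(dOut, par, cache) {
  if (cache$type == "identity") {
    return(list(dX = dOut, grad = list()))
  }
  if (cache$type == "short") {
    dP <- dOut; dim(dP) <- dim(cache$p1$Y)
    dN1 <- pool2_bwd(dP, cache$p1)
    b1 <- bn_bwd(dN1, par$bn1, cache$bc1)
    dC1 <- b1$dA * cache$m1
    cv1 <- conv1d_bwd(dC1, cache$A0, par$conv1)
    dX <- cv1$dA; dim(dX) <- c(dim(cache$A0)[1], dim(cache$A0)[2])
    return(list(dX = dX, grad = list(conv1 = cv1$grad, bn1 = b1$grad)))
  }
  dP2 <- dOut; dim(dP2) <- dim(cache$p2$Y)
  dN3 <- pool2_bwd(dP2, cache$p2)
  b3 <- bn_bwd(dN3, par$bn3, cache$bc3)
  dC3 <- b3$dA * cache$m3
  cv3 <- conv1d_bwd(dC3, cache$A2, par$conv3)
  dN2 <- pool2_bwd(cv3$dA, cache$p1)
  b2 <- bn_bwd(dN2, par$bn2, cache$bc2)
  dC2 <- b2$dA * cache$m2
  cv2 <- conv1d_bwd(dC2, cache$A1, par$conv2)
  b1 <- bn_bwd(cv2$dA, par$bn1, cache$bc1)
  dC1 <- b1$dA * cache$m1
  cv1 <- conv1d_bwd(dC1, cache$A0, par$conv1)
  dX <- cv1$dA; dim(dX) <- c(dim(cache$A0)[1], dim(cache$A0)[2])
  list(dX = dX,
       grad = list(conv1 = cv1$grad, bn1 = b1$grad,
                   conv2 = cv2$grad, bn2 = b2$grad,
                   conv3 = cv3$grad, bn3 = b3$grad))
}

# ---- whole network -------------------------------------------------------

net_fwd <- function(par, plans, X_blocks, stats = NULL) {
  branches <- vector("list", length(plans))
  outs <- vector("list", length(plans))
  all_stats <- vector("list", length(plans))
  for (i in seq_along(plans)) {
    br <- branch_fwd(X_blocks[[i]], par$branches[[i]], plans[[i]],
                     stats = if (is.null(stats)) NULL else stats[[i]])
    branches[[i]] <- br$cache
    outs[[i]] <- br$out
    all_stats[[i]] <- br$stats
  }
  flat <- do.call(cbind, outs)
  h1 <- dense_fwd(flat, par$head$d1)
  a1 <- relu_fwd(h1)
  h2 <- dense_fwd(a1$Y, par$head$d2)
  a2 <- relu_fwd(h2)
  z <- dense_fwd(a2$Y, par$head$d3)
  p <- softmax_rows(z)
  list(p = p,
       cache = list(branches = branches, flat = flat,
                    a1 = a1, a2 = a2,
                    flat_dims = vapply(outs, ncol, integer(1))),
       stats = all_stats)
}

net_bwd <- function(par, plans, cache, dZ) {
  d3 <- dense_bwd(dZ, cache$a2$Y, par$head$d3)
  dH2 <- d3$dX * cache$a2$mask
  d2 <- dense_bwd(dH2, cache$a1$Y, par$head$d2)
  dH1 <- d2$dX * cache$a1$mask
  d1 <- dense_bwd(dH1, cache$flat, par$head$d1)
  dFlat <- d1$dX
  offsets <- c(0L, cumsum(cache$flat_dims))
  gbr <- vector("list", length(plans))
  for (i in seq_along(plans)) {
    seg <- dFlat[, (offsets[i] + 1L):offsets[i + 1L], drop = FALSE]
    gbr[[i]] <- branch_bwd(seg, par$branches[[i]], cache$branches[[i]])$grad
  }
  list(branches = gbr,
       head = list(d1 = d1$grad, d2 = d2$grad, d3 = d3$grad))
}

cross_entropy <- function(p, y01) {
  -mean(log(p[cbind(seq_len(nrow(p)), y01 + 1L)] + 1e-12))
}

# ---- optimizers ----------------------------------------------------------

zeros_like <- function(p) {
  if (is.list(p)) lapply(p, zeros_like) else p * 0
}

adam_step <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.list(p)) {
    for (i in seq_along(p)) {
      r <- adam_step(p[[i]], g[[i]], m[[i]], v[[i]], lr, t, b1, b2, eps)
      p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
    }
    return(list(p = p, m = m, v = v))
  }
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g * g
  list(p = p - lr * (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + eps),
       m = m, v = v)
}

sgd_step <- function(p, g, u, lr, momentum = 0.9) {
  if (is.list(p)) {
    for (i in seq_along(p)) {
      r <- sgd_step(p[[i]], g[[i]], u[[i]], lr, momentum)
      p[[i]] <- r$p; u[[i]] <- r$u
    }
    return(list(p = p, u = u))
  }
  u <- momentum * u + g
  list(p = p - lr * u, u = u)
}
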