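test_that("PPI matrix construction fills edges, diagonal and cap", {
  edges <- data.frame(protein_a = c("p1", "p2"), protein_b = c("p2", "p1"),
                      score = 0.5)
  m <- build_ppi_matrix(edges)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(unname(diag(m)), c(1, 1))
  expect_equal(m["p1", "p2"], 0.5)

  tri <- expand.grid(a = paste0("q", 1:3), b = paste0("q", 1:3),
                     stringsAsFactors = FALSE)
  tri <- tri[tri$a != tri$b, ]
  m3 <- build_ppi_matrix(data.frame(protein_a = tri$a, protein_b = tri$b,
                                    score = 1))
  expect_true(all(m3 == 1))

  # more proteins than the reference cap: highest-degree 400 kept
  ids <- sprintf("p%03d", 1:500)
  chain <- data.frame(protein_a = ids[-500], protein_b = ids[-1], score = 0.5)
  chain <- rbind(chain, stats::setNames(chain[, c(2, 1, 3)], names(chain)))
  mcap <- build_ppi_matrix(chain)
  expect_equal(nrow(mcap), 400L)
})

test_that("projection vectors are length 100 and row-determined", {
  m <- matrix(c(1, 1, 0.3, 0.3,
                1, 1, 0.3, 0.3,
                0.3, 0.3, 1, 0.2,
                0.3, 0.3, 0.2, 1), 4, 4, byrow = TRUE,
              dimnames = list(paste0("p", 1:4), paste0("p", 1:4)))
  proj <- fit_ppi_projection(m)
  expect_equal(ncol(proj$per_protein), 100L)
  # identical rows project identically
  expect_equal(proj$per_protein["p1", ], proj$per_protein["p2", ])
})

test_that("projection matches an independent eigendecomposition oracle", {
  set.seed(61)
  side <- 5L
  a <- matrix(runif(side * side), side)
  m <- (a + t(a)) / 2; diag(m) <- 1
  dimnames(m) <- list(paste0("p", 1:side), paste0("p", 1:side))
  proj <- fit_ppi_projection(m, n_components = 10L)

  X <- sweep(m, 2L, colMeans(m))
  eig <- eigen(crossprod(X) / (side - 1), symmetric = TRUE)
  k <- side - 1L                       # rank after centering
  V <- eig$vectors[, 1:k, drop = FALSE]
  flip <- vapply(1:k, function(j) sign(V[which.max(abs(V[, j])), j]),
                 numeric(1))
  V <- sweep(V, 2L, flip, "*")
  scores <- X %*% V
  expect_equal(unname(proj$per_protein[, 1:k]), unname(scores),
               tolerance = 1e-8)
  expect_equal(unname(proj$per_protein[, (k + 1):10]),
               matrix(0, side, 10L - k))
})

test_that("truncation error equals the discarded eigenvalue mass", {
  set.seed(62)
  a <- matrix(runif(36), 6)
  m <- (a + t(a)) / 2; diag(m) <- 1
  dimnames(m) <- list(paste0("p", 1:6), paste0("p", 1:6))
  X <- sweep(m, 2L, colMeans(m))
  eig <- eigen(crossprod(X) / (6 - 1), symmetric = TRUE)
  for (k in 1:3) {
    proj <- fit_ppi_projection(m, n_components = k)
    recon <- proj$per_protein[, 1:k, drop = FALSE] %*%
      t(proj$components[, 1:k, drop = FALSE])
    err <- sum((X - recon)^2) / (6 - 1)
    expect_equal(err, sum(eig$values[-(1:k)]), tolerance = 1e-8)
  }
})

test_that("lookups return the zero vector for unknown proteins", {
  m <- build_ppi_matrix(data.frame(protein_a = c("p1", "p2"),
                                   protein_b = c("p2", "p1"), score = 0.9))
  proj <- fit_ppi_projection(m)
  expect_warning(v <- lookup_ppi(proj, "nope"), class = "rpifuse_missing_ppi")
  expect_equal(v, numeric(100))
  expect_silent(lookup_ppi(proj, "nope", quiet = TRUE))
  expect_equal(lookup_ppi(proj, "p1"), unname(proj$per_protein["p1", ]),
               ignore_attr = TRUE)
})

test_that("refitting on identical edges is bit-identical", {
  set.seed(63)
  ids <- paste0("p", 1:12)
  g <- expand.grid(a = ids, b = ids, stringsAsFactors = FALSE)
  g <- g[g$a < g$b, ]
  g <- g[runif(nrow(g)) < 0.4, ]
  edges <- data.frame(protein_a = c(g$a, g$b), protein_b = c(g$b, g$a),
                      score = rep(round(runif(nrow(g)), 3), 2))
  p1 <- fit_ppi_projection(build_ppi_matrix(edges))
  p2 <- fit_ppi_projection(build_ppi_matrix(edges))
  expect_identical(p1$per_protein, p2$per_protein)
})
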