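test_that("the interaction rule degenerates when everyone carries a motif", {
  cfg <- simulation_config(n_rna = 4, n_protein = 4, n_positive = 16,
                           label_noise = 0, motif_insertion_prob = 1,
                           rna_length_range = c(40, 60),
                           protein_length_range = c(40, 60), seed = 9)
  ds <- simulate_dataset(cfg)
  expect_equal(nrow(ds$positives), 16L)
  expect_true(all(grepl(cfg$rna_motif, ds$rna_seqs, fixed = TRUE)))
  expect_true(all(grepl(cfg$protein_motif, ds$protein_seqs, fixed = TRUE)))
})

test_that("seeded simulations write byte-identical files", {
  cfg <- simulation_config(n_rna = 10, n_protein = 10, n_positive = 12,
                           rna_length_range = c(50, 80),
                           protein_length_range = c(40, 70), seed = 10)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(simulate_rpi_data(cfg), d1)
  write_dataset(simulate_rpi_data(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})

test_that("structures are aligned and alphabet-correct; carriers cliqued", {
  ds <- tiny_dataset()
  expect_identical(nchar(ds$rna_structs$symbols),
                   unname(nchar(ds$rna_seqs[ds$rna_structs$id])))
  expect_true(all(grepl("^[.()]+$", ds$rna_structs$symbols)))
  expect_identical(nchar(ds$protein_structs$symbols),
                   unname(nchar(ds$protein_seqs[ds$protein_structs$id])))
  expect_true(all(grepl("^[CEH]+$", ds$protein_structs$symbols)))
  expect_true(all(ds$ppi_edges$score >= 0 & ds$ppi_edges$score <= 1))
})

test_that("label noise leaves the positive fraction near one half", {
  cfg <- simulation_config(n_rna = 30, n_protein = 30, n_positive = 100,
                           label_noise = 0.05,
                           rna_length_range = c(50, 80),
                           protein_length_range = c(40, 70), seed = 12)
  ds <- simulate_rpi_data(cfg)
  expect_equal(nrow(ds$pairs), 200L)
  # flips are symmetric: expected fraction exactly 0.5; allow 4 binomial sd
  frac <- mean(ds$pairs$label == "positive")
  tol <- 4 * sqrt(200 * 0.05 * 0.95) / 200
  expect_lt(abs(frac - 0.5), tol)
})

test_that("negative sampling avoids positives and honours the default count", {
  ds <- tiny_dataset()
  neg <- sample_negatives(ds$positives, names(ds$rna_seqs),
                          names(ds$protein_seqs), seed = 13)
  expect_equal(nrow(neg), nrow(ds$positives))
  keys <- function(df) paste(df$rna_id, df$protein_id)
  expect_length(intersect(keys(neg), keys(ds$positives)), 0L)
  expect_false(anyDuplicated(keys(neg)) > 0)
})

test_that("negative sampling errors when the space is exhausted", {
  pos <- data.frame(rna_id = c("r1", "r1", "r2"),
                    protein_id = c("p1", "p2", "p1"))
  expect_error(sample_negatives(pos, c("r1", "r2"), c("p1", "p2"), n = 2),
               class = "rpifuse_exhausted_space")
})

test_that("simulated datasets survive a write/load round trip", {
  ds <- tiny_dataset()
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  # truncated stem-loops may leave unbalanced brackets; that load-time
  # warning is expected here
  back <- suppressWarnings(load_dataset(dir))
  expect_identical(unname(unclass(back$rna_seqs)), unname(unclass(ds$rna_seqs)))
  expect_identical(back$pairs$rna_id, ds$pairs$rna_id)
  expect_identical(as.character(back$pairs$label), as.character(ds$pairs$label))
  m1 <- build_ppi_matrix(back$ppi_edges)
  m2 <- build_ppi_matrix(ds$ppi_edges)
  expect_equal(m1, m2, tolerance = 1e-9)
})

test_that("invalid configurations are rejected up front", {
  expect_error(simulation_config(rna_motif = "ACGT"),
               class = "rpifuse_config_error")
  expect_error(simulation_config(label_noise = 0.6),
               class = "rpifuse_config_error")
  expect_error(simulation_config(n_rna = 3, n_protein = 3, n_positive = 400),
               class = "rpifuse_config_error")
})
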