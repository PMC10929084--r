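write_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("FASTA reading normalizes case and maps T to U for RNA", {
  f <- write_lines(c(">r1", "acgu"))
  s <- read_fasta(f, "rna")
  expect_equal(unname(unclass(s)["r1"]), "ACGU", ignore_attr = TRUE)

  f2 <- write_lines(c(">r1", "ACGT"))
  expect_equal(unname(unclass(read_fasta(f2, "rna"))[[1]]), "ACGU")
})

test_that("alphabet validation is kind-specific and names the offender", {
  f <- write_lines(c(">p1", "ACGU", ">p2", "AB1"))
  err <- expect_error(read_fasta(f, "protein"), class = "rpifuse_alphabet_error")
  expect_match(conditionMessage(err), "p2")
  expect_no_match(conditionMessage(err), "p1")

  # A, C, G, U are all valid amino-acid letters
  f2 <- write_lines(c(">p1", "ACGU"))
  expect_silent(read_fasta(f2, "protein"))
  # B is not a standard nucleotide either
  f3 <- write_lines(c(">r9", "ACB"))
  err2 <- expect_error(read_fasta(f3, "rna"), class = "rpifuse_alphabet_error")
  expect_match(conditionMessage(err2), "r9")
})

test_that("FASTA round-trip preserves ids and residues", {
  set.seed(7)
  ids <- paste0("m", 1:8)
  res <- vapply(sample(20:60, 8, replace = TRUE), random_rna, character(1))
  names(res) <- ids
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(res, f)
  back <- read_fasta(f, "rna")
  expect_identical(names(back), ids)
  expect_identical(as.character(back), unname(res))
})

test_that("pair tables parse labels and reject duplicates and bad labels", {
  f <- write_lines(c("# comment", "r1\tp1\t1", "r2\tp1\t0"))
  pr <- read_pairs(f)
  expect_equal(nrow(pr), 2L)
  expect_identical(as.character(pr$label), c("positive", "negative"))

  fdup <- write_lines(c("r1\tp1\t1", "r1\tp1\t1"))
  expect_error(read_pairs(fdup), class = "rpifuse_duplicate_pair")

  fbad <- write_lines("r1\tp1\t2")
  expect_error(read_pairs(fbad), class = "rpifuse_label_error")
})

test_that("pair assembly resolves every id against the sequence sets", {
  rna <- structure(c(r1 = "ACGU"), kind = "rna")
  prot <- structure(c(p1 = "MKL"), kind = "protein")
  pairs <- data.frame(rna_id = "r1", protein_id = "p1", label = "positive")
  expect_identical(assemble_pairs(pairs, rna, prot), pairs)
  bad <- data.frame(rna_id = "r1", protein_id = "pX", label = "positive")
  err <- expect_error(assemble_pairs(bad, rna, prot),
                      class = "rpifuse_unknown_id")
  expect_match(conditionMessage(err), "pX")
})

test_that("PPI edges are symmetrized, self-edges unit, scores range-checked", {
  f <- write_lines("p1\tp2\t0.5")
  e <- read_ppi_edges(f)
  expect_true(any(e$protein_a == "p1" & e$protein_b == "p2" & e$score == 0.5))
  expect_true(any(e$protein_a == "p2" & e$protein_b == "p1" & e$score == 0.5))

  fself <- write_lines("p1\tp1\t0.3")
  eself <- read_ppi_edges(fself)
  expect_equal(eself$score[eself$protein_a == "p1" &
                             eself$protein_b == "p1"], 1.0)

  fbad <- write_lines("p1\tp2\t1.7")
  expect_error(read_ppi_edges(fbad), class = "rpifuse_score_range_error")
})

test_that("structure files validate alphabet, length and balance", {
  f <- write_lines(c("r1\t((..))", "r2\t...."))
  st <- read_structures(f, "rna")
  expect_equal(nrow(st), 2L)

  fbad <- write_lines("r1\t(.X")
  expect_error(read_structures(fbad, "rna"), class = "rpifuse_symbol_error")

  funb <- write_lines("r1\t((..")
  expect_warning(read_structures(funb, "rna"),
                 class = "rpifuse_unbalanced_structure")

  seqs <- structure(c(r1 = "ACGUAC"), kind = "rna")
  fok <- write_lines("r1\t((..))")
  expect_silent(read_structures(fok, "rna", seqs))
  fshort <- write_lines("r1\t(..)")
  expect_error(read_structures(fshort, "rna", seqs),
               class = "rpifuse_length_error")
})
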