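# Independent oracles used across the suite. These deliberately avoid the
# package's own index arithmetic: words are enumerated with sort(), windows
# with substring(), transforms with explicit double loops.

# frequency of every length-k word (lexicographic) by naive window counting
naive_kmer_freq <- function(seq, k, alphabet) {
  words <- sort(apply(expand.grid(rep(list(alphabet), k),
                                  stringsAsFactors = FALSE),
                      1L, paste0, collapse = ""))
  L <- nchar(seq)
  if (L < k) return(stats::setNames(numeric(length(words)), words))
  wins <- substring(seq, 1:(L - k + 1L), k:L)
  stats::setNames(vapply(words, function(w) sum(wins == w), numeric(1)) /
                    (L - k + 1L), words)
}

naive_rna_ik <- function(seq) {
  unname(unlist(lapply(1:4, naive_kmer_freq, seq = seq,
                       alphabet = c("A", "C", "G", "U"))))
}

ct_group_string <- function(seq) {
  groups <- c(A = "1", G = "1", V = "1", I = "2", L = "2", F = "2", P = "2",
              Y = "3", M = "3", T = "3", S = "3", H = "4", N = "4", Q = "4",
              W = "4", R = "5", K = "5", D = "6", E = "6", C = "7")
  paste0(groups[strsplit(seq, "")[[1]]], collapse = "")
}

naive_protein_ict <- function(seq) {
  g <- ct_group_string(seq)
  unname(unlist(lapply(1:3, naive_kmer_freq, seq = g,
                       alphabet = as.character(1:7))))
}

# explicit double-loop evaluation of the cosine-series coefficients
naive_cosine <- function(x, n_coeffs = 20L) {
  l <- length(x)
  vapply(0:(n_coeffs - 1L), function(i) {
    acc <- 0
    for (n in 0:(l - 1L)) {
      acc <- acc + x[n + 1L] * cos(pi / l * (n + 0.5) * (i + 0.5))
    }
    sqrt(2 / l) * acc
  }, numeric(1))
}

random_rna <- function(len) {
  paste0(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

random_protein <- function(len) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  paste0(sample(aa, len, replace = TRUE), collapse = "")
}

# small two-block gaussian classification problem for classifier tests
toy_blocks <- function(n = 60L, d1 = 20L, d2 = 14L, shift = 1.5, seed = 1L) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  b1 <- matrix(rnorm(n * d1), n, d1) + shift * y
  b2 <- matrix(rnorm(n * d2), n, d2) - shift * y
  list(blocks = list(a = b1, b = b2), y = y)
}

# one small simulated dataset shared by slower tests (built once per run)
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(n_rna = 24L, n_protein = 24L, n_positive = 36L,
                               rna_length_range = c(60L, 120L),
                               protein_length_range = c(50L, 100L),
                               seed = 401L)
      cache <<- suppressMessages(simulate_rpi_data(cfg))
    }
    cache
  }
})
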