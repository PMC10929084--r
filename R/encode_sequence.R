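# Stacked k-mer encodings. RNA: frequencies of every 1- to 4-mer over
# A<C<G<U (4 + 16 + 64 + 256 = 340 values). Protein: residues are first
# collapsed to the seven conjoint-triad groups (dipole / side-chain volume
# partition), then 1- to 3-mer group frequencies are stacked
# (7 + 49 + 343 = 399 values). Each k-mer sub-block is a frequency
# distribution over the (L - k + 1) windows, so it sums to 1 for any
# sequence of length >= k and is all-zero otherwise.

CT_GROUPS <- c(A = 1L, G = 1L, V = 1L,
               I = 2L, L = 2L, F = 2L, P = 2L,
               Y = 3L, M = 3L, T = 3L, S = 3L,
               H = 4L, N = 4L, Q = 4L, W = 4L,
               R = 5L, K = 5L,
               D = 6L, E = 6L,
               C = 7L, U = 7L)   # selenocysteine grouped with cysteine

# all length-k words over `alphabet`, lexicographic (last position fastest)
all_kmers <- function(alphabet, k) {
  grid <- expand.grid(rep(list(alphabet), k), stringsAsFactors = FALSE)
  apply(as.matrix(grid)[, k:1, drop = FALSE], 1L, paste0, collapse = "")
}

# integer codes 0..n-1 for each position of `residues`
symbol_codes <- function(residues, alphabet) {
  lut <- integer(128)
  lut[utf8ToInt(paste0(alphabet, collapse = ""))] <- seq_along(alphabet) - 1L
  lut[utf8ToInt(residues)]
}

# frequency vector of length n^k over windows of a code sequence
kmer_frequencies <- function(codes, n_symbols, k) {
  L <- length(codes)
  n_words <- n_symbols^k
  if (L < k) return(numeric(n_words))
  idx <- integer(L - k + 1L)
  for (t in seq_len(k)) {
    idx <- idx * n_symbols + codes[t:(L - k + t)]
  }
  tabulate(idx + 1L, nbins = n_words) / (L - k + 1L)
}

#' Stacked k-mer encoding of an RNA sequence
#'
#' Concatenates the frequency distributions of all 1-, 2-, 3- and 4-mers
#' (sub-block sizes 4, 16, 64, 256; 340 values in total) in lexicographic
#' order over the alphabet A < C < G < U. Sub-blocks whose word length
#' exceeds the sequence length are all-zero.
#'
#' @param seq A single RNA residue string over `ACGU`.
#' @return A named numeric vector of length 340.
#' @export
encode_rna_ik <- function(seq) {
  check_alphabet(seq, "rna", names(seq) %||% "<rna>")
  codes <- symbol_codes(seq, RNA_ALPHABET)
  out <- unlist(lapply(1:4, function(k) {
    v <- kmer_frequencies(codes, 4L, k)
    names(v) <- paste0("rna_", k, "mer_", all_kmers(RNA_ALPHABET, k))
    v
  }))
  out
}

#' Conjoint-triad group k-mer encoding of a protein sequence
#'
#' Maps each residue to one of seven physicochemical groups
#' (`{A,G,V} {I,L,F,P} {Y,M,T,S} {H,N,Q,W} {R,K} {D,E} {C}`) and stacks the
#' frequency distributions of group 1-, 2- and 3-mers (sizes 7, 49, 343;
#' 399 values) in lexicographic order over group index 1 < ... < 7.
#'
#' @param seq A single protein residue string over the 20 standard letters.
#' @return A named numeric vector of length 399.
#' @export
encode_protein_ict <- function(seq) {
  check_alphabet(seq, "protein", names(seq) %||% "<protein>")
  groups <- CT_GROUPS[strsplit(seq, "", fixed = TRUE)[[1]]]
  codes <- unname(groups) - 1L
  digits <- as.character(1:7)
  out <- unlist(lapply(1:3, function(k) {
    v <- kmer_frequencies(codes, 7L, k)
    names(v) <- paste0("prot_", k, "mer_", all_kmers(digits, k))
    v
  }))
  out
}

#' Fuse RNA and protein sequence encodings
#'
#' @param rna_block Numeric vector of length 340 from [encode_rna_ik()].
#' @param prot_block Numeric vector of length 399 from [encode_protein_ict()].
#' @return The RNA-first concatenation, length 739.
#' @export
fuse_sequence_block <- function(rna_block, prot_block) {
  check_fuse_dims(rna_block, 340L, prot_block, 399L)
  c(rna_block, prot_block)
}

check_fuse_dims <- function(a, da, b, db) {
  if (length(a) != da || length(b) != db) {
    rpi_stop(sprintf("expected block dims (%d, %d), got (%d, %d)",
                     da, db, length(a), length(b)),
             "rpifuse_dimension_error")
  }
  invisible(TRUE)
}

`%||%` <- function(x, y) if (is.null(x) || length(x) == 0L) y else x
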