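#' @importFrom Biostrings readBStringSet BStringSet writeXStringSet
NULL

RNA_ALPHABET <- c("A", "C", "G", "U")
# the 20 standard amino acids plus U (selenocysteine), which the encoders
# treat as its cysteine analogue
PROTEIN_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                      "M", "N", "P", "Q", "R", "S", "T", "U", "V", "W", "Y")

alphabet_for <- function(kind) {
  switch(kind, rna = RNA_ALPHABET, protein = PROTEIN_ALPHABET,
         rpi_stop(sprintf("unknown sequence kind '%s'", kind), "rpifuse_kind_error"))
}

check_alphabet <- function(residues, kind, ids) {
  pat <- sprintf("^[%s]+$", paste(alphabet_for(kind), collapse = ""))
  bad <- !grepl(pat, residues)
  empty <- !nzchar(residues)
  if (any(empty)) {
    rpi_stop(sprintf("empty sequence for id(s): %s",
                     paste(ids[empty], collapse = ", ")),
             "rpifuse_alphabet_error")
  }
  if (any(bad)) {
    rpi_stop(sprintf("out-of-alphabet characters for %s id(s): %s",
                     kind, paste(ids[bad], collapse = ", ")),
             "rpifuse_alphabet_error")
  }
  invisible(TRUE)
}

new_seq_set <- function(residues, kind) {
  structure(residues, kind = kind, class = "rpi_seqset")
}

#' Read RNA or protein sequences from a FASTA file
#'
#' Sequences are uppercased; for `kind = "rna"`, `T` is mapped to `U` so
#' DNA-alphabet transcript files are accepted. Records containing characters
#' outside the expected alphabet (`ACGU` for RNA, the 20 standard amino-acid
#' letters for protein) raise an `rpifuse_alphabet_error` naming the
#' offending ids. Duplicate ids raise an error.
#'
#' @param path Path to a FASTA file.
#' @param kind `"rna"` or `"protein"`.
#' @return A named character vector of residues (class `rpi_seqset`) with a
#'   `kind` attribute; names are the FASTA record ids (first whitespace-
#'   delimited token of each header).
#' @export
read_fasta <- function(path, kind = c("rna", "protein")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    rpi_stop(sprintf("FASTA file not found: %s", path), "rpifuse_malformed_fasta")
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) rpi_stop(
                    sprintf("malformed FASTA %s: %s", path, conditionMessage(e)),
                    "rpifuse_malformed_fasta"))
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    rpi_stop(sprintf("duplicate FASTA ids: %s",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")),
             "rpifuse_malformed_fasta")
  }
  residues <- toupper(as.character(set))
  if (kind == "rna") residues <- gsub("T", "U", residues, fixed = TRUE)
  names(residues) <- ids
  check_alphabet(residues, kind, ids)
  new_seq_set(residues, kind)
}

#' Write a sequence set to FASTA
#'
#' @param seqs A named character vector (e.g. from [read_fasta()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(unclass(seqs))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

read_tsv_plain <- function(path, col_names) {
  if (!file.exists(path)) {
    rpi_stop(sprintf("file not found: %s", path), "rpifuse_io_error")
  }
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE, quote = "",
                          col.names = col_names, fill = FALSE,
                          colClasses = "character")
  df
}

#' Read secondary-structure strings
#'
#' Structure annotations arrive as a two-column tab-separated file
#' (`id<TAB>symbols`), one row per molecule. RNA structures use dot-bracket
#' notation (`.` unpaired, `(`/`)` paired); protein structures use the
#' three-class alphabet `C` (coil), `E` (extended/beta), `H` (helix).
#' Several predicted structures for the same molecule may be supplied as
#' separate rows; downstream encoding averages their coefficient vectors.
#'
#' @param path Path to the TSV file. Lines starting with `#` are ignored.
#' @param kind `"rna"` or `"protein"`.
#' @param sequences Optional sequence set; when given, each structure string
#'   must have the same length as its sequence.
#' @return A data frame with columns `id` and `symbols`.
#' @export
read_structures <- function(path, kind = c("rna", "protein"), sequences = NULL) {
  kind <- match.arg(kind)
  df <- read_tsv_plain(path, c("id", "symbols"))
  pat <- if (kind == "rna") "^[.()]+$" else "^[CEH]+$"
  bad <- !grepl(pat, df$symbols)
  if (any(bad)) {
    rpi_stop(sprintf("invalid %s structure symbols for id(s): %s", kind,
                     paste(unique(df$id[bad]), collapse = ", ")),
             "rpifuse_symbol_error")
  }
  if (kind == "rna") {
    n_open <- nchar(gsub("[^(]", "", df$symbols))
    n_close <- nchar(gsub("[^)]", "", df$symbols))
    if (any(n_open != n_close)) {
      rpi_warn(sprintf("unbalanced parentheses in structure(s): %s",
                       paste(unique(df$id[n_open != n_close]), collapse = ", ")),
               "rpifuse_unbalanced_structure")
    }
  }
  if (!is.null(sequences)) {
    known <- df$id %in% names(sequences)
    if (!all(known)) {
      rpi_stop(sprintf("structure id(s) with no matching sequence: %s",
                       paste(unique(df$id[!known]), collapse = ", ")),
               "rpifuse_unknown_id")
    }
    mism <- nchar(df$symbols) != nchar(sequences[df$id])
    if (any(mism)) {
      rpi_stop(sprintf("structure length differs from sequence length for: %s",
                       paste(unique(df$id[mism]), collapse = ", ")),
               "rpifuse_length_error")
    }
  }
  df
}

#' Read labelled interaction pairs
#'
#' Expects a tab-separated file with columns `rna_id`, `protein_id`,
#' `label`, where label 1 marks an interacting (positive) pair and 0 a
#' non-interacting one. Duplicate (rna_id, protein_id) rows are rejected.
#'
#' @param path Path to the TSV file. `#` comment lines are ignored.
#' @return A data frame with character columns `rna_id`, `protein_id` and a
#'   factor `label` with levels `negative`, `positive`.
#' @export
read_pairs <- function(path) {
  df <- read_tsv_plain(path, c("rna_id", "protein_id", "label"))
  if (!all(df$label %in% c("0", "1"))) {
    bad <- setdiff(unique(df$label), c("0", "1"))
    rpi_stop(sprintf("pair labels must be 0 or 1; saw: %s",
                     paste(bad, collapse = ", ")),
             "rpifuse_label_error")
  }
  key <- paste(df$rna_id, df$protein_id, sep = "\t")
  if (anyDuplicated(key)) {
    rpi_stop(sprintf("duplicate pair(s): %s",
                     paste(unique(gsub("\t", "/", key[duplicated(key)])),
                           collapse = ", ")),
             "rpifuse_duplicate_pair")
  }
  data.frame(rna_id = df$rna_id, protein_id = df$protein_id,
             label = factor(ifelse(df$label == "1", "positive", "negative"),
                            levels = c("negative", "positive")),
             stringsAsFactors = FALSE)
}

#' Read a protein-protein interaction edge list
#'
#' Tab-separated columns `protein_a`, `protein_b`, `score` with scores in
#' \[0, 1\]. The edge list is symmetrized on load and self-edges are forced
#' to score 1.0, matching the unit diagonal of the PPI score matrix.
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns `protein_a`, `protein_b`, `score`,
#'   containing both orientations of every edge.
#' @export
read_ppi_edges <- function(path) {
  df <- read_tsv_plain(path, c("protein_a", "protein_b", "score"))
  score <- suppressWarnings(as.numeric(df$score))
  if (anyNA(score)) {
    rpi_stop("non-numeric PPI scores", "rpifuse_score_range_error")
  }
  if (any(score < 0 | score > 1)) {
    rpi_stop(sprintf("PPI scores outside [0, 1]: %s",
                     paste(utils::head(score[score < 0 | score > 1], 5),
                           collapse = ", ")),
             "rpifuse_score_range_error")
  }
  df$score <- score
  self <- df$protein_a == df$protein_b
  df$score[self] <- 1.0
  sym <- rbind(df,
               data.frame(protein_a = df$protein_b[!self],
                          protein_b = df$protein_a[!self],
                          score = df$score[!self],
                          stringsAsFactors = FALSE))
  sym <- sym[!duplicated(paste(sym$protein_a, sym$protein_b, sep = "\t")), ]
  rownames(sym) <- NULL
  sym
}

#' Resolve interaction pairs against loaded sequence collections
#'
#' @param pairs Data frame from [read_pairs()].
#' @param rna_seqs,protein_seqs Sequence sets from [read_fasta()].
#' @return `pairs`, unchanged, if every id resolves; otherwise an
#'   `rpifuse_unknown_id` error naming the missing ids.
#' @export
assemble_pairs <- function(pairs, rna_seqs, protein_seqs) {
  miss_r <- setdiff(pairs$rna_id, names(rna_seqs))
  miss_p <- setdiff(pairs$protein_id, names(protein_seqs))
  if (length(miss_r) || length(miss_p)) {
    rpi_stop(sprintf("unresolved ids in pair table: %s",
                     paste(c(miss_r, miss_p), collapse = ", ")),
             "rpifuse_unknown_id")
  }
  pairs
}
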