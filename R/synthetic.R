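# Synthetic benchmark generator. Sequences are i.i.d. uniform-composition;
# a designated block of "carrier" RNAs and proteins receives a planted
# sequence motif, and a pair is interacting exactly when both molecules
# contain their motif (then labels are flipped with a small noise
# probability). Structure strings come from a seeded stem-loop / run-length
# sampler and carrier proteins form a high-score clique in the PPI graph,
# so every feature family carries some recoverable signal, the sequence
# channel most strongly.

#' Simulation configuration
#'
#' @param n_rna,n_protein Number of RNA / protein molecules.
#' @param n_positive Number of interacting pairs to emit.
#' @param rna_length_range,protein_length_range Inclusive length intervals.
#' @param rna_motif RNA motif string (over `ACGU`) planted in carrier RNAs.
#' @param protein_motif Protein motif (20-letter alphabet) planted in
#'   carrier proteins.
#' @param motif_insertion_prob Probability that a designated carrier
#'   actually receives its motif.
#' @param label_noise Probability that a pair label is flipped, in
#'   \[0, 0.5).
#' @param ppi_density Probability of a background (non-carrier) PPI edge.
#' @param seed Master seed; all randomness flows from it.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_rna = 60L, n_protein = 60L,
                              n_positive = 400L,
                              rna_length_range = c(100L, 300L),
                              protein_length_range = c(80L, 250L),
                              rna_motif = "GACUCGAGUC",
                              protein_motif = "WKCEHM",
                              motif_insertion_prob = 1.0,
                              label_noise = 0.02,
                              ppi_density = 0.05,
                              seed = 1L) {
  if (!grepl("^[ACGU]+$", rna_motif)) {
    rpi_stop("rna_motif must be over ACGU", "rpifuse_config_error")
  }
  if (!grepl(sprintf("^[%s]+$", paste(PROTEIN_ALPHABET, collapse = "")),
             protein_motif)) {
    rpi_stop("protein_motif must be over the 20 amino-acid letters",
             "rpifuse_config_error")
  }
  if (label_noise < 0 || label_noise >= 0.5) {
    rpi_stop("label_noise must be in [0, 0.5)", "rpifuse_config_error")
  }
  if (motif_insertion_prob < 0 || motif_insertion_prob > 1 ||
      ppi_density < 0 || ppi_density > 1) {
    rpi_stop("probabilities must be in [0, 1]", "rpifuse_config_error")
  }
  n_carrier_rna <- min(n_rna, ceiling(sqrt(n_positive)))
  n_carrier_prot <- min(n_protein, ceiling(n_positive / n_carrier_rna))
  if (n_carrier_rna * n_carrier_prot < n_positive) {
    rpi_stop("n_positive exceeds the carrier pair grid; increase n_rna/n_protein",
             "rpifuse_config_error")
  }
  structure(list(n_rna = as.integer(n_rna), n_protein = as.integer(n_protein),
                 n_positive = as.integer(n_positive),
                 rna_length_range = as.integer(rna_length_range),
                 protein_length_range = as.integer(protein_length_range),
                 rna_motif = rna_motif, protein_motif = protein_motif,
                 motif_insertion_prob = motif_insertion_prob,
                 label_noise = label_noise, ppi_density = ppi_density,
                 n_carrier_rna = n_carrier_rna,
                 n_carrier_prot = n_carrier_prot,
                 seed = as.integer(seed)),
            class = "sim_config")
}

random_seq <- function(alphabet, len) {
  paste0(sample(alphabet, len, replace = TRUE), collapse = "")
}

insert_motif <- function(seq, motif) {
  L <- nchar(seq); m <- nchar(motif)
  if (m >= L) return(motif)
  at <- sample.int(L - m + 1L, 1L)
  paste0(substr(seq, 1L, at - 1L), motif, substr(seq, at + m, L))
}

sample_rna_structure <- function(len) {
  parts <- character(0); total <- 0L
  while (total < len) {
    remaining <- len - total
    if (remaining < 9L || stats::runif(1) < 0.5) {   # min stem-loop is 9 nt
      run <- min(sample(2:8, 1L), remaining)
      parts <- c(parts, strrep(".", run)); total <- total + run
    } else {
      stem_max <- min(6L, (remaining - 3L) %/% 2L)
      stem <- if (stem_max <= 3L) 3L else sample(3:stem_max, 1L)
      loop <- min(sample(3:6, 1L), remaining - 2L * stem)
      parts <- c(parts, strrep("(", stem), strrep(".", loop),
                 strrep(")", stem))
      total <- total + 2L * stem + loop
    }
  }
  paste0(parts, collapse = "")
}

sample_protein_structure <- function(len) {
  parts <- character(0); total <- 0L
  while (total < len) {
    run <- sample(3:10, 1L)
    parts <- c(parts, strrep(sample(c("C", "E", "H"), 1L), run))
    total <- total + run
  }
  substr(paste0(parts, collapse = ""), 1L, len)
}

#' Simulate a complete synthetic interaction dataset
#'
#' Generates sequences, secondary-structure strings, a PPI edge list and
#' the interacting (positive) pairs under the planted motif-containment
#' rule: a pair interacts exactly when its RNA contains `rna_motif` and
#' its protein contains `protein_motif`. Byte-identical outputs for a
#' fixed config.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `rna_seqs`, `protein_seqs` (named residue vectors),
#'   `rna_structs`, `protein_structs` (data frames `id`, `symbols`),
#'   `ppi_edges` (symmetrized data frame) and `positives`
#'   (data frame `rna_id`, `protein_id`).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  rna_ids <- sprintf("rna%04d", seq_len(cfg$n_rna))
  prot_ids <- sprintf("prot%04d", seq_len(cfg$n_protein))

  rna_len <- sample(cfg$rna_length_range[1]:cfg$rna_length_range[2],
                    cfg$n_rna, replace = TRUE)
  prot_len <- sample(cfg$protein_length_range[1]:cfg$protein_length_range[2],
                     cfg$n_protein, replace = TRUE)
  rna_seqs <- vapply(rna_len, random_seq, character(1),
                     alphabet = RNA_ALPHABET)
  prot_seqs <- vapply(prot_len, random_seq, character(1),
                      alphabet = PROTEIN_ALPHABET)
  names(rna_seqs) <- rna_ids; names(prot_seqs) <- prot_ids

  carrier_rna <- seq_len(cfg$n_carrier_rna)
  carrier_prot <- seq_len(cfg$n_carrier_prot)
  for (i in carrier_rna) {
    if (stats::runif(1) <= cfg$motif_insertion_prob) {
      rna_seqs[i] <- insert_motif(rna_seqs[i], cfg$rna_motif)
    }
  }
  for (i in carrier_prot) {
    if (stats::runif(1) <= cfg$motif_insertion_prob) {
      prot_seqs[i] <- insert_motif(prot_seqs[i], cfg$protein_motif)
    }
  }

  has_rna_motif <- grepl(cfg$rna_motif, rna_seqs, fixed = TRUE)
  has_prot_motif <- grepl(cfg$protein_motif, prot_seqs, fixed = TRUE)
  grid <- expand.grid(r = seq_len(cfg$n_rna), p = seq_len(cfg$n_protein))
  pos_idx <- which(has_rna_motif[grid$r] & has_prot_motif[grid$p])
  if (length(pos_idx) > cfg$n_positive) {
    pos_idx <- sort(sample(pos_idx, cfg$n_positive))
  }
  positives <- data.frame(rna_id = rna_ids[grid$r[pos_idx]],
                          protein_id = prot_ids[grid$p[pos_idx]],
                          stringsAsFactors = FALSE)

  rna_structs <- data.frame(id = rna_ids,
                            symbols = vapply(rna_len, sample_rna_structure,
                                             character(1)),
                            stringsAsFactors = FALSE)
  prot_structs <- data.frame(id = prot_ids,
                             symbols = vapply(prot_len,
                                              sample_protein_structure,
                                              character(1)),
                             stringsAsFactors = FALSE)

  # PPI: high-score clique over carrier proteins, sparse weak background
  pairs_ij <- which(upper.tri(matrix(TRUE, cfg$n_protein, cfg$n_protein)),
                    arr.ind = TRUE)
  in_clique <- pairs_ij[, 1] %in% carrier_prot &
               pairs_ij[, 2] %in% carrier_prot
  keep_bg <- !in_clique & stats::runif(nrow(pairs_ij)) < cfg$ppi_density
  sc <- numeric(nrow(pairs_ij))
  sc[in_clique] <- stats::runif(sum(in_clique), 0.7, 1)
  sc[keep_bg] <- stats::runif(sum(keep_bg), 0, 0.3)
  keep <- in_clique | keep_bg
  edges <- data.frame(protein_a = prot_ids[pairs_ij[keep, 1]],
                      protein_b = prot_ids[pairs_ij[keep, 2]],
                      score = sc[keep], stringsAsFactors = FALSE)
  edges <- rbind(edges,
                 data.frame(protein_a = edges$protein_b,
                            protein_b = edges$protein_a,
                            score = edges$score, stringsAsFactors = FALSE))

  list(rna_seqs = new_seq_set(rna_seqs, "rna"),
       protein_seqs = new_seq_set(prot_seqs, "protein"),
       rna_structs = rna_structs, protein_structs = prot_structs,
       ppi_edges = edges, positives = positives)
}

#' Sample non-interacting pairs
#'
#' Draws `n` (RNA, protein) combinations uniformly without replacement
#' from the combinations not present in the positive set - the standard
#' negative-sampling rule, with the negative count defaulting to the
#' positive count.
#'
#' @param positives Data frame with `rna_id`, `protein_id`.
#' @param rna_ids,protein_ids Candidate molecule id pools.
#' @param n Number of negatives (default `nrow(positives)`).
#' @param seed RNG seed.
#' @return Data frame `rna_id`, `protein_id` disjoint from `positives`.
#' @export
sample_negatives <- function(positives, rna_ids, protein_ids,
                             n = nrow(positives), seed = 1L) {
  total <- length(rna_ids) * length(protein_ids)
  pos_key <- paste(positives$rna_id, positives$protein_id, sep = "\t")
  n_free <- total - length(unique(pos_key))
  if (n > n_free) {
    rpi_stop(sprintf("requested %d negatives but only %d non-positive combinations exist",
                     n, n_free),
             "rpifuse_exhausted_space")
  }
  grid_key <- paste(rep(rna_ids, times = length(protein_ids)),
                    rep(protein_ids, each = length(rna_ids)), sep = "\t")
  free <- setdiff(grid_key, pos_key)
  set.seed(seed)
  pick <- sample(free, n)
  parts <- strsplit(pick, "\t", fixed = TRUE)
  data.frame(rna_id = vapply(parts, `[`, character(1), 1L),
             protein_id = vapply(parts, `[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

#' Simulate a labelled, ready-to-encode dataset
#'
#' [simulate_dataset()] plus negative sampling (as many negatives as
#' positives) and label-noise flips, yielding a `pairs` table with a
#' `negative`/`positive` label factor.
#'
#' @param cfg A [simulation_config()].
#' @return The [simulate_dataset()] list with an added `pairs` element.
#' @export
simulate_rpi_data <- function(cfg) {
  ds <- simulate_dataset(cfg)
  negatives <- sample_negatives(ds$positives, names(ds$rna_seqs),
                                names(ds$protein_seqs),
                                seed = cfg$seed + 1L)
  pairs <- rbind(cbind(ds$positives, label = "positive"),
                 cbind(negatives, label = "negative"))
  set.seed(cfg$seed + 2L)
  flip <- stats::runif(nrow(pairs)) < cfg$label_noise
  pairs$label[flip] <- ifelse(pairs$label[flip] == "positive",
                              "negative", "positive")
  pairs$label <- factor(pairs$label, levels = c("negative", "positive"))
  rownames(pairs) <- NULL
  ds$pairs <- pairs
  ds
}

#' Write a simulated dataset in the package's file formats
#'
#' FASTA for sequences, two-column TSV for structures, three-column TSVs
#' for pairs and PPI edges.
#'
#' @param ds Dataset from [simulate_rpi_data()] (or [simulate_dataset()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(ds$rna_seqs, file.path(dir, "rna.fasta"))
  write_fasta(ds$protein_seqs, file.path(dir, "protein.fasta"))
  utils::write.table(ds$rna_structs, file.path(dir, "rna_structures.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(ds$protein_structs,
                     file.path(dir, "protein_structures.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(ds$ppi_edges, file.path(dir, "ppi_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  if (!is.null(ds$pairs)) {
    out <- data.frame(ds$pairs$rna_id, ds$pairs$protein_id,
                      as.integer(ds$pairs$label == "positive"))
    utils::write.table(out, file.path(dir, "pairs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' Load a dataset written by [write_dataset()]
#'
#' @param dir Directory containing the dataset files.
#' @return A dataset list in the layout of [simulate_rpi_data()].
#' @export
load_dataset <- function(dir) {
  rna <- read_fasta(file.path(dir, "rna.fasta"), "rna")
  prot <- read_fasta(file.path(dir, "protein.fasta"), "protein")
  list(rna_seqs = rna, protein_seqs = prot,
       rna_structs = read_structures(file.path(dir, "rna_structures.tsv"),
                                     "rna", rna),
       protein_structs = read_structures(
         file.path(dir, "protein_structures.tsv"), "protein", prot),
       ppi_edges = read_ppi_edges(file.path(dir, "ppi_edges.tsv")),
       pairs = if (file.exists(file.path(dir, "pairs.tsv")))
                 read_pairs(file.path(dir, "pairs.tsv")) else NULL)
}
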