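# Reduced physicochemical descriptors. Each property column is z-scored
# across its units (16 dinucleotides or 20 residues); an RNA sequence then
# contributes one lag-1 auto-covariance per dinucleotide property (22
# values with the shipped table) and a protein one first-tier
# sequence-order correlation factor per residue property (3 values):
# sequence-order-aware scalars that reproduce the 22 + 3 = 25 block layout.

RNA_PROPERTY_NAMES <- c(
  "Adenine content", "GC content", "Purine content", "Keto content",
  "Cytosine content", "Thymine content", "Guanine content",
  "Tilt", "Twist", "Roll", "Rise", "Shift", "Slide",
  "Stacking energy", "Entropy", "Entropy 1", "Enthalpy", "Enthalpy 1",
  "Free energy", "Free energy 1", "Hydrophilicity", "Hydrophilicity 1")

PROTEIN_PROPERTY_NAMES <- c("hydrophobicity", "hydrophilicity", "mass")

#' Read a property table from TSV
#'
#' Rows are units (dinucleotides or residues, first column `unit`), columns
#' are named properties. `#` comment lines are ignored.
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix with unit rownames and property colnames.
#' @export
read_property_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (anyNA(m)) rpi_stop("non-numeric property values", "rpifuse_property_error")
  m
}

#' Default shipped property tables
#'
#' `default_rna_property_table()` returns the 16 x 22 dinucleotide table
#' (base-content indicators, A-form helical step geometry, nearest-neighbour
#' thermodynamics from two published parameter sets, two hydrophilicity
#' scales); `default_protein_property_table()` returns the 20 x 3 residue
#' table (Kyte-Doolittle hydropathy, Hopp-Woods hydrophilicity, average
#' residue mass).
#'
#' @return A numeric property matrix.
#' @export
default_rna_property_table <- function() {
  m <- read_property_table(system.file("extdata", "rna_dinucleotide_properties.tsv",
                                       package = "rpifuse", mustWork = TRUE))
  stopifnot(identical(colnames(m), RNA_PROPERTY_NAMES))
  m
}

#' @rdname default_rna_property_table
#' @export
default_protein_property_table <- function() {
  m <- read_property_table(system.file("extdata", "protein_residue_properties.tsv",
                                       package = "rpifuse", mustWork = TRUE))
  stopifnot(identical(colnames(m), PROTEIN_PROPERTY_NAMES))
  m
}

#' Standardize property columns
#'
#' Each property is centred and scaled to mean 0, standard deviation 1
#' across its units (population denominator). A property that is constant
#' across units carries no information and raises
#' `rpifuse_degenerate_property`.
#'
#' @param table Numeric property matrix (units x properties).
#' @return The standardized matrix.
#' @export
normalize_property <- function(table) {
  table <- as.matrix(table)
  mu <- colMeans(table)
  centred <- sweep(table, 2L, mu)
  sd_pop <- sqrt(colMeans(centred^2))
  if (any(sd_pop == 0)) {
    rpi_stop(sprintf("constant property column(s): %s",
                     paste(colnames(table)[sd_pop == 0], collapse = ", ")),
             "rpifuse_degenerate_property")
  }
  sweep(centred, 2L, sd_pop, "/")
}

#' Physicochemical encoding of an RNA sequence
#'
#' For each property, the sequence is mapped to the normalized values of
#' its L-1 overlapping dinucleotides \eqn{v_1, \dots, v_{L-1}} and reduced
#' to the lag-1 auto-covariance
#' \eqn{\frac{1}{L-2} \sum_j (v_j - \bar v)(v_{j+1} - \bar v)}.
#'
#' @param seq RNA residue string, length >= 3.
#' @param table Dinucleotide property matrix; defaults to the shipped
#'   22-property table.
#' @return A named numeric vector, one auto-covariance per property.
#' @export
encode_rna_physchem <- function(seq, table = default_rna_property_table()) {
  check_alphabet(seq, "rna", names(seq) %||% "<rna>")
  L <- nchar(seq)
  if (L < 3L) {
    rpi_stop("RNA sequence must have length >= 3 for dinucleotide auto-covariance",
             "rpifuse_sequence_too_short")
  }
  norm <- normalize_property(table)
  dinucs <- substring(seq, 1:(L - 1L), 2:L)
  idx <- match(dinucs, rownames(norm))
  vapply(seq_len(ncol(norm)), function(p) {
    v <- norm[idx, p]
    d <- v - mean(v)
    sum(d[-length(d)] * d[-1L]) / (L - 2L)
  }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(colnames(norm))
}

#' Physicochemical encoding of a protein sequence
#'
#' For each property, residues are mapped to normalized values
#' \eqn{v_1, \dots, v_L} and reduced to the first-tier sequence-order
#' correlation factor \eqn{\frac{1}{L-1} \sum_j (v_j - v_{j+1})^2}, the
#' pseudo amino-acid composition coupling term at rank 1.
#'
#' @param seq Protein residue string, length >= 2.
#' @param table Residue property matrix; defaults to the shipped 3-property
#'   table.
#' @return A named numeric vector, one correlation factor per property.
#' @export
encode_protein_physchem <- function(seq, table = default_protein_property_table()) {
  check_alphabet(seq, "protein", names(seq) %||% "<protein>")
  L <- nchar(seq)
  if (L < 2L) {
    rpi_stop("protein sequence must have length >= 2 for sequence-order factors",
             "rpifuse_sequence_too_short")
  }
  norm <- normalize_property(table)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  chars[chars == "U"] <- "C"   # selenocysteine uses the cysteine row
  idx <- match(chars, rownames(norm))
  vapply(seq_len(ncol(norm)), function(p) {
    v <- norm[idx, p]
    mean(diff(v)^2)
  }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(colnames(norm))
}

#' Fuse RNA and protein physicochemical vectors
#'
#' @param rna_vec Numeric vector of length 22.
#' @param prot_vec Numeric vector of length 3.
#' @return The RNA-first concatenation, length 25.
#' @export
fuse_physchem_block <- function(rna_vec, prot_vec) {
  check_fuse_dims(rna_vec, 22L, prot_vec, 3L)
  out <- c(rna_vec, prot_vec)
  names(out) <- c(paste0("rna_pc_", gsub(" ", "_", RNA_PROPERTY_NAMES)),
                  paste0("prot_pc_", PROTEIN_PROPERTY_NAMES))
  out
}
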