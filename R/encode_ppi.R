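# PPI features. The protein-protein interaction graph is summarised as a
# symmetric score matrix over a reference set of at most 400 proteins
# (unit diagonal, missing edges 0). Each reference protein's score row is
# projected onto the leading 100 principal axes of the matrix; proteins
# outside the reference set (or absent from the graph altogether) are
# represented by the all-zero 100-vector.

#' Build a PPI score matrix from an edge list
#'
#' The reference set is the first `reference_cap` proteins by descending
#' degree (ties broken by id); the matrix is filled from the edges, with
#' missing entries 0 and a unit diagonal.
#'
#' @param edges Data frame from [read_ppi_edges()] (both orientations
#'   present).
#' @param reference_cap Maximum side of the matrix (default 400).
#' @return A symmetric numeric matrix with protein ids as dimnames.
#' @export
build_ppi_matrix <- function(edges, reference_cap = 400L) {
  ids <- unique(c(edges$protein_a, edges$protein_b))
  if (length(ids) == 0L) {
    return(matrix(numeric(0), 0L, 0L))
  }
  degree <- table(factor(edges$protein_a[edges$protein_a != edges$protein_b],
                         levels = ids))
  ord <- order(-as.numeric(degree), ids)
  ref <- ids[ord][seq_len(min(reference_cap, length(ids)))]
  m <- matrix(0, length(ref), length(ref), dimnames = list(ref, ref))
  keep <- edges$protein_a %in% ref & edges$protein_b %in% ref
  e <- edges[keep, , drop = FALSE]
  m[cbind(e$protein_a, e$protein_b)] <- e$score
  diag(m) <- 1.0
  m
}

#' Fit a principal-component projection of the PPI matrix
#'
#' Rows are mean-centred and projected onto the top
#' `min(n_components, side, rank)` principal axes; projected vectors are
#' zero-padded to exactly `n_components`. The sign of each axis is fixed by
#' making its largest-magnitude loading positive, so refits on identical
#' input are bit-identical.
#'
#' @param m Square symmetric PPI matrix from [build_ppi_matrix()].
#' @param n_components Output dimensionality (default 100).
#' @return An object of class `ppi_projection` with elements `components`
#'   (loadings, side x n_kept), `center`, `per_protein` (id-named matrix,
#'   rows of length `n_components`) and `n_components`.
#' @export
fit_ppi_projection <- function(m, n_components = 100L) {
  side <- nrow(m)
  if (side == 0L) {
    return(structure(list(components = matrix(numeric(0), 0L, 0L),
                          center = numeric(0),
                          per_protein = matrix(numeric(0), 0L, n_components),
                          n_components = n_components),
                     class = "ppi_projection"))
  }
  pca <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  keep <- seq_len(min(n_components, ncol(pca$rotation)))
  rot <- pca$rotation[, keep, drop = FALSE]
  # deterministic sign: largest-magnitude loading of each axis positive
  flip <- vapply(seq_len(ncol(rot)), function(j) {
    sign(rot[which.max(abs(rot[, j])), j])
  }, numeric(1))
  rot <- sweep(rot, 2L, flip, "*")
  scores <- pca$x[, keep, drop = FALSE]
  scores <- sweep(scores, 2L, flip, "*")
  per_protein <- matrix(0, side, n_components,
                        dimnames = list(rownames(m), NULL))
  per_protein[, seq_len(ncol(scores))] <- scores
  structure(list(components = rot, center = pca$center,
                 per_protein = per_protein, n_components = n_components),
            class = "ppi_projection")
}

#' Per-protein PPI feature vector
#'
#' Returns the protein's projected score row, or the all-zero vector (with
#' a warning) for proteins outside the fitted reference set - the standard
#' fallback for proteins whose interactions are unknown.
#'
#' @param proj A `ppi_projection` from [fit_ppi_projection()].
#' @param protein_id Protein identifier.
#' @param quiet Suppress the unknown-id warning (used in bulk encoding,
#'   where the zero-vector rate is reported once).
#' @return A numeric vector of length `proj$n_components`.
#' @export
lookup_ppi <- function(proj, protein_id, quiet = FALSE) {
  if (protein_id %in% rownames(proj$per_protein)) {
    return(proj$per_protein[protein_id, ])
  }
  if (!quiet) {
    rpi_warn(sprintf("no PPI information for protein '%s'; using zero vector",
                     protein_id),
             "rpifuse_missing_ppi")
  }
  numeric(proj$n_components)
}
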