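# Pipeline glue: per-pair feature assembly across the four blocks, and an
# end-to-end encode -> select -> train -> evaluate run on a held-out split.

BLOCK_NAMES <- c("sequence", "structure", "physchem", "ppi")

#' Assemble per-pair feature blocks
#'
#' Encodes every unique molecule once (sequence k-mers, averaged structure
#' coefficients, physicochemical scalars), fits the PPI projection from
#' the edge list (unless one is supplied), and assembles one row per pair
#' for each enabled feature block. Pre-selection block widths are 739
#' (sequence), 40 (structure), 25 (physchem) and 100 (ppi).
#'
#' @param ds Dataset list (see [simulate_rpi_data()] / [load_dataset()]):
#'   `rna_seqs`, `protein_seqs`, `rna_structs`, `protein_structs`,
#'   `ppi_edges`, `pairs`.
#' @param blocks Feature families to encode (any non-empty subset of
#'   `sequence`, `structure`, `physchem`, `ppi`).
#' @param rna_table,protein_table Physicochemical property tables.
#' @param projection Optional pre-fitted [fit_ppi_projection()] result
#'   (e.g. the training-time projection when encoding new pairs).
#' @return A list with `blocks` (named list of matrices, rows = pairs),
#'   `y` (label factor or `NULL`), `pairs`, and `projection`.
#' @export
encode_pairs <- function(ds, blocks = BLOCK_NAMES,
                         rna_table = default_rna_property_table(),
                         protein_table = default_protein_property_table(),
                         projection = NULL) {
  if (length(blocks) == 0L) {
    rpi_stop("at least one feature family must be enabled",
             "rpifuse_config_error")
  }
  blocks <- match.arg(blocks, BLOCK_NAMES, several.ok = TRUE)
  pairs <- assemble_pairs(ds$pairs, ds$rna_seqs, ds$protein_seqs)
  rna_ids <- unique(pairs$rna_id)
  prot_ids <- unique(pairs$protein_id)
  out <- list()

  if ("sequence" %in% blocks) {
    rna_enc <- vapply(ds$rna_seqs[rna_ids], encode_rna_ik, numeric(340))
    prot_enc <- vapply(ds$protein_seqs[prot_ids], encode_protein_ict,
                       numeric(399))
    m <- cbind(t(rna_enc)[pairs$rna_id, , drop = FALSE],
               t(prot_enc)[pairs$protein_id, , drop = FALSE])
    out$sequence <- m
  }
  if ("structure" %in% blocks) {
    rna_coef <- vapply(rna_ids, function(id) {
      encode_structure(ds$rna_structs$symbols[ds$rna_structs$id == id], "rna")
    }, numeric(20))
    prot_coef <- vapply(prot_ids, function(id) {
      encode_structure(ds$protein_structs$symbols[ds$protein_structs$id == id],
                       "protein")
    }, numeric(20))
    m <- cbind(t(rna_coef)[pairs$rna_id, , drop = FALSE],
               t(prot_coef)[pairs$protein_id, , drop = FALSE])
    colnames(m) <- c(paste0("rna_struct_", 1:20), paste0("prot_struct_", 1:20))
    out$structure <- m
  }
  if ("physchem" %in% blocks) {
    rna_pc <- vapply(ds$rna_seqs[rna_ids], encode_rna_physchem,
                     numeric(ncol(rna_table)), table = rna_table)
    prot_pc <- vapply(ds$protein_seqs[prot_ids], encode_protein_physchem,
                      numeric(ncol(protein_table)), table = protein_table)
    m <- cbind(t(rna_pc)[pairs$rna_id, , drop = FALSE],
               t(prot_pc)[pairs$protein_id, , drop = FALSE])
    colnames(m) <- c(paste0("rna_pc_", gsub(" ", "_", colnames(rna_table))),
                     paste0("prot_pc_", colnames(protein_table)))
    out$physchem <- m
  }
  if ("ppi" %in% blocks) {
    if (is.null(projection)) {
      projection <- fit_ppi_projection(build_ppi_matrix(ds$ppi_edges))
    }
    m <- t(vapply(pairs$protein_id, lookup_ppi, numeric(projection$n_components),
                  proj = projection, quiet = TRUE))
    colnames(m) <- paste0("ppi_pc_", seq_len(ncol(m)))
    zero_rate <- mean(!pairs$protein_id %in% rownames(projection$per_protein))
    if (zero_rate > 0) {
      message(sprintf("ppi block: %.1f%% of pairs use the zero fallback vector",
                      100 * zero_rate))
    }
    out$ppi <- m
  }
  rn <- paste(pairs$rna_id, pairs$protein_id, sep = ":")
  out <- lapply(out, function(m) { rownames(m) <- rn; m })
  list(blocks = out, y = ds$pairs$label, pairs = pairs,
       projection = projection)
}

#' End-to-end pipeline on a held-out split
#'
#' Encodes the dataset, splits the pairs into stratified train / test
#' portions, fits the Gini-importance selection masks and the network on
#' the training portion only, and reports held-out metrics.
#'
#' @param ds Dataset list with a labelled `pairs` table.
#' @param config A [model_config()].
#' @param retain_fraction_seq,retain_fraction_other Retained fractions for
#'   the sequence block and for the remaining blocks.
#' @param holdout_fraction Fraction of pairs (per class) held out.
#' @param n_trees Forest size for the selector.
#' @param blocks Feature families to use.
#' @param seed Seed for the split and the selector; network training uses
#'   `config$seed`.
#' @return A list with `metrics` (a `metric_report`), `predictions`,
#'   `model`, `masks`, `projection`, and the `test_index` used.
#' @export
rpi_pipeline <- function(ds, config = model_config(),
                         retain_fraction_seq = 0.8,
                         retain_fraction_other = 0.8,
                         holdout_fraction = 0.2,
                         n_trees = 500L,
                         blocks = BLOCK_NAMES,
                         seed = 1L) {
  enc <- encode_pairs(ds, blocks = blocks)
  y01 <- as_y01(enc$y)
  set.seed(seed)
  test_idx <- integer(0)
  for (cls in c(0L, 1L)) {
    members <- which(y01 == cls)
    test_idx <- c(test_idx, sample(members,
                                   max(1L, floor(length(members) *
                                                   holdout_fraction))))
  }
  tr <- setdiff(seq_along(y01), test_idx)

  masks <- lapply(names(enc$blocks), function(bn) {
    frac <- if (identical(bn, "sequence")) retain_fraction_seq
            else retain_fraction_other
    imp <- gini_importance(enc$blocks[[bn]][tr, , drop = FALSE], y01[tr],
                           n_trees = n_trees, seed = seed)
    select_block(imp, frac, block_name = bn)
  })
  names(masks) <- names(enc$blocks)

  Xtr <- mapply(function(m, mk) apply_mask(m[tr, , drop = FALSE], mk),
                enc$blocks, masks, SIMPLIFY = FALSE)
  Xte <- mapply(function(m, mk) apply_mask(m[test_idx, , drop = FALSE], mk),
                enc$blocks, masks, SIMPLIFY = FALSE)
  model <- fit_rpi_cnn(Xtr, y01[tr], config)
  pred <- predict(model, Xte)
  metrics <- classification_metrics(y01[test_idx], pred$score)
  list(metrics = metrics, predictions = pred, model = model, masks = masks,
       projection = enc$projection, test_index = test_idx)
}
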