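# Secondary-structure encoding. Structure strings are digitized
# (dot-bracket: "." -> 0, "(" or ")" -> 1; protein classes: C -> 0,
# E -> 1, H -> 2) and compressed with a type-II discrete cosine transform,
# keeping the first 20 coefficients per molecule regardless of length.
# The half-sample-shifted cosine kernel makes unequal-length structures
# comparable on a fixed 20-dimensional scale.

#' Digitize a secondary-structure string
#'
#' RNA dot-bracket symbols map `.` to 0 and either bracket to 1 (only
#' paired/unpaired status is retained); protein classes map `C`, `E`, `H`
#' to 0, 1, 2.
#'
#' @param symbols A structure string.
#' @param kind `"rna"` or `"protein"`.
#' @return An integer vector, one value per position.
#' @export
digitize_structure <- function(symbols, kind = c("rna", "protein")) {
  kind <- match.arg(kind)
  chars <- strsplit(symbols, "", fixed = TRUE)[[1]]
  map <- if (kind == "rna") c("." = 0L, "(" = 1L, ")" = 1L)
         else c(C = 0L, E = 1L, H = 2L)
  vals <- map[chars]
  if (anyNA(vals) || length(vals) == 0L) {
    bad <- unique(chars[!chars %in% names(map)])
    rpi_stop(sprintf("unknown %s structure symbol(s): %s", kind,
                     paste(bad, collapse = " ")),
             "rpifuse_symbol_error")
  }
  unname(vals)
}

#' Cosine-series compression of a numeric structure series
#'
#' Computes the first `n_coeffs` coefficients
#' \deqn{X_i = \sqrt{2/l} \sum_{n=0}^{l-1} x_n
#'   \cos\left[\frac{\pi}{l}\left(n+\tfrac12\right)\left(i+\tfrac12\right)\right]}
#' for \eqn{i = 0, \dots, n_{coeffs}-1}, where \eqn{l} is the series length
#' (the half-sample-shifted type-II cosine kernel). Series shorter than
#' `n_coeffs` still yield `n_coeffs` coefficients; the input is never
#' padded.
#'
#' @param series Numeric vector (a digitized structure).
#' @param n_coeffs Number of leading coefficients to keep (default 20).
#' @return A numeric vector of length `n_coeffs`.
#' @export
cosine_transform <- function(series, n_coeffs = 20L) {
  l <- length(series)
  if (l < 1L) rpi_stop("empty structure series", "rpifuse_empty_series")
  n <- seq_len(l) - 1L
  i <- seq_len(n_coeffs) - 1L
  kernel <- cos(outer(i + 0.5, n + 0.5) * (pi / l))   # n_coeffs x l
  sqrt(2 / l) * as.numeric(kernel %*% series)
}

#' Encode one structure string as 20 cosine coefficients
#'
#' Convenience wrapper: [digitize_structure()] followed by
#' [cosine_transform()]. When several predicted structures are supplied for
#' the same molecule, encode each and average the coefficient vectors.
#'
#' @inheritParams digitize_structure
#' @param n_coeffs Number of coefficients (default 20).
#' @return A numeric vector of length `n_coeffs`.
#' @export
encode_structure <- function(symbols, kind = c("rna", "protein"), n_coeffs = 20L) {
  kind <- match.arg(kind)
  if (length(symbols) > 1L) {
    return(rowMeans(vapply(symbols, encode_structure, numeric(n_coeffs),
                           kind = kind, n_coeffs = n_coeffs)))
  }
  cosine_transform(digitize_structure(symbols, kind), n_coeffs)
}

#' Fuse RNA and protein structure coefficients
#'
#' @param rna_coeffs,prot_coeffs Numeric vectors of length 20.
#' @return The RNA-first concatenation, length 40.
#' @export
fuse_structure_block <- function(rna_coeffs, prot_coeffs) {
  check_fuse_dims(rna_coeffs, 20L, prot_coeffs, 20L)
  out <- c(rna_coeffs, prot_coeffs)
  names(out) <- c(paste0("rna_struct_", 1:20), paste0("prot_struct_", 1:20))
  out
}
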