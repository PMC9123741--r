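#' @name aaindex-properties
#' @title Amino-acid property tables and derived property scales
#'
#' @description
#' Numeric per-residue property tables are taken from the AAindex catalogue
#' shipped with the seqinr package and standardised (z-scored over the 20
#' standard residues) before use, the usual convention for correlation-type
#' descriptors. A small number of accessions are used by name in the
#' default feature set: DAYM780201 (relative mutability), BIGC670101
#' (residue volume), ARGP820101 (hydrophobicity) and HOPT810101
#' (hydrophilicity, Hopp-Woods). The full catalogue (all complete tables)
#' backs the wide autocorrelation block and the principal-component property
#' scales.
NULL

# Complete AAindex tables as a 20 x P matrix (rows in AA20 order), cached.
aaindex_matrix <- function() {
  if (!is.null(.xt_cache$aaindex_matrix)) return(.xt_cache$aaindex_matrix)
  env <- new.env()
  utils::data("aaindex", package = "seqinr", envir = env)
  idx <- env$aaindex
  vals <- vapply(idx, function(a) {
    v <- a$I
    v[match(names(AA3), names(v))]
  }, numeric(20))
  rownames(vals) <- unname(AA3[names(AA3)])
  keep <- colSums(is.na(vals)) == 0L & apply(vals, 2L, sd) > 0
  vals <- vals[AA20, keep, drop = FALSE]
  .xt_cache$aaindex_matrix <- vals
  vals
}

#' Fetch an amino-acid property table by AAindex accession
#'
#' @param accession AAindex accession, e.g. `"DAYM780201"`.
#' @param standardize z-score the 20 values (population standard deviation,
#'   i.e. divide by `sqrt(mean((v - mean(v))^2))`), the convention of
#'   pseudo-amino-acid composition descriptors. Default `TRUE`.
#' @return list of class `xt_property` with fields `accession`, `values`
#'   (named 20-vector in fixed alphabet order) and `standardized`.
#' @export
property_table <- function(accession, standardize = TRUE) {
  m <- aaindex_matrix()
  if (!accession %in% colnames(m)) {
    stop("unknown or incomplete AAindex accession: ", accession)
  }
  v <- m[, accession]
  if (standardize) v <- standardize_property(v)
  structure(list(accession = accession, values = v,
                 standardized = standardize),
            class = "xt_property")
}

#' Standardise a 20-residue property vector
#' @param v named numeric vector over the 20 standard residues.
#' @return z-scored vector (mean 0, population sd 1 over the 20 values).
#' @export
standardize_property <- function(v) {
  stopifnot(length(v) == 20L)
  s <- sqrt(mean((v - mean(v))^2))
  if (s == 0) stop("constant property table cannot be standardised")
  (v - mean(v)) / s
}

#' All complete AAindex accessions
#' @return character vector of accessions with all 20 values present.
#' @export
aaindex_accessions <- function() colnames(aaindex_matrix())

#' Principal-component property scales
#'
#' A principal-component reduction of the full standardised AAindex block
#' (20 residues x ~530 properties) to `k` orthogonal per-residue scores,
#' used by the auto-cross covariance descriptor ("scl" features). Scores are
#' centred over the 20 residues and scaled to unit population variance;
#' component signs are fixed deterministically (the residue with the largest
#' absolute score gets a positive score).
#'
#' @param k number of components (default 5).
#' @return 20 x `k` numeric matrix, rows named by residue.
#' @export
property_scales <- function(k = 5L) {
  key <- paste0("scales", k)
  if (!is.null(.xt_cache[[key]])) return(.xt_cache[[key]])
  m <- aaindex_matrix()
  mz <- scale(m)  # z-score each property over the 20 residues
  p <- prcomp(mz, center = TRUE, scale. = FALSE)
  if (k > ncol(p$x)) stop("k exceeds available components")
  sc <- p$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(sc[, j]))
    if (sc[i, j] < 0) sc[, j] <- -sc[, j]
    sc[, j] <- sc[, j] - mean(sc[, j])
    sc[, j] <- sc[, j] / sqrt(mean(sc[, j]^2))
  }
  colnames(sc) <- paste0("scl", seq_len(k))
  .xt_cache[[key]] <- sc
  sc
}
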