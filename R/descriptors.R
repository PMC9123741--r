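#' @name descriptors
#' @title Alignment-free sequence descriptors
#'
#' @description
#' Numeric descriptors computed from a residue string alone: amino-acid,
#' dipeptide and tripeptide compositions; k-mer counts (the GFV tripeptide is
#' tracked by default); normalised Moreau-Broto, Moran and Geary
#' autocorrelation of AAindex properties; Chou's amphiphilic pseudo-amino-acid
#' composition ("Pc" features); and auto-cross covariance of
#' principal-component property scales ("scl<i>.<j>lag.<d>" features).
#'
#' Ambiguous residues (`X`, after B/Z/U/O mapping) carry no property value:
#' they are excluded from composition numerators and denominators, and any
#' lagged product involving an `X` position is dropped from both the sum and
#' its denominator.
NULL

res_index <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1L]], AA20)
}

#' Amino-acid composition
#' @param seq residue string (uppercase, 20-letter alphabet plus `X`).
#' @return named 20-vector of fractions summing to 1 (`X` excluded).
#' @export
aac <- function(seq) {
  idx <- res_index(seq)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) stop("sequence contains no standard residues")
  tab <- tabulate(idx, nbins = 20L)
  setNames(tab / length(idx), AA20)
}

#' Count overlapping occurrences of a k-mer
#' @param seq residue string; `kmer` shorter query string.
#' @param kmer k-mer to count.
#' @return integer count of (possibly overlapping) occurrences.
#' @export
kmer_count <- function(seq, kmer) {
  k <- nchar(kmer)
  if (k < 1L || k > nchar(seq)) stop("kmer length must be in [1, sequence length]")
  starts <- seq_len(nchar(seq) - k + 1L)
  sum(substring(seq, starts, starts + k - 1L) == kmer)
}

kmer_composition <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) stop("sequence shorter than k = ", k)
  starts <- seq_len(L - k + 1L)
  words <- substring(seq, starts, starts + k - 1L)
  words <- words[!grepl("X", words, fixed = TRUE)]
  all_words <- apply(do.call(expand.grid,
                             rev(rep(list(AA20), k))), 1L,
                     paste0, collapse = "")
  cnt <- table(factor(words, levels = all_words))
  setNames(as.numeric(cnt) / (L - k + 1L), all_words)
}

#' Dipeptide composition
#' @param seq residue string.
#' @return named 400-vector; counts divided by `L - 1`. Sums to 1 for
#'   `X`-free sequences.
#' @export
dipeptide_composition <- function(seq) kmer_composition(seq, 2L)

#' Tripeptide composition
#' @param seq residue string.
#' @return named 8000-vector; counts divided by `L - 2`. Feature names are
#'   the raw 3-mers (e.g. `"GFV"`).
#' @export
tripeptide_composition <- function(seq) kmer_composition(seq, 3L)

prop_values <- function(prop) {
  if (inherits(prop, "xt_property")) {
    if (!isTRUE(prop$standardized)) stop("property table must be standardised")
    prop$values
  } else {
    stopifnot(is.numeric(prop), length(prop) == 20L)
    prop[AA20]
  }
}

lagged_mean <- function(p, d) {
  # mean of p[i] * p[i+d] over pairs where both values are defined
  a <- p[seq_len(length(p) - d)]
  b <- p[(d + 1L):length(p)]
  prod <- a * b
  ok <- !is.na(prod)
  if (!any(ok)) return(0)
  sum(prod[ok]) / sum(ok)
}

#' Normalised Moreau-Broto autocorrelation
#'
#' `ATS_d = (1/(L - d)) * sum_i P(r_i) P(r_(i+d))` for a standardised
#' property `P`; pairs touching an `X` position are skipped (and removed
#' from the denominator).
#'
#' @param seq residue string.
#' @param prop `xt_property` (standardised) or named standardised 20-vector.
#' @param d lag, `1 <= d < L`.
#' @return scalar descriptor value.
#' @export
moreau_broto <- function(seq, prop, d) {
  v <- prop_values(prop)
  idx <- res_index(seq)
  L <- nchar(seq)
  if (d >= L || d < 1L) stop("lag d must satisfy 1 <= d < sequence length")
  lagged_mean(v[idx], d)
}

#' Moran autocorrelation
#' @inheritParams moreau_broto
#' @return scalar; lagged covariance of centred property values divided by
#'   their variance.
#' @export
moran <- function(seq, prop, d) {
  v <- prop_values(prop)
  idx <- res_index(seq)
  if (d >= nchar(seq) || d < 1L) stop("lag d must satisfy 1 <= d < sequence length")
  p <- v[idx]
  m <- mean(p, na.rm = TRUE)
  vv <- mean((p - m)^2, na.rm = TRUE)
  if (vv == 0) return(0)
  lagged_mean(p - m, d) / vv
}

#' Geary autocorrelation
#' @inheritParams moreau_broto
#' @return scalar; half the mean squared lagged difference divided by the
#'   (n-1)-denominator variance.
#' @export
geary <- function(seq, prop, d) {
  v <- prop_values(prop)
  idx <- res_index(seq)
  if (d >= nchar(seq) || d < 1L) stop("lag d must satisfy 1 <= d < sequence length")
  p <- v[idx]
  n <- sum(!is.na(p))
  if (n < 2L) return(0)
  dd <- (p[seq_len(length(p) - d)] - p[(d + 1L):length(p)])^2
  ok <- !is.na(dd)
  if (!any(ok)) return(0)
  num <- sum(dd[ok]) / (2 * sum(ok))
  den <- sum((p - mean(p, na.rm = TRUE))^2, na.rm = TRUE) / (n - 1L)
  if (den == 0) return(0)
  num / den
}

#' Amphiphilic pseudo-amino-acid composition (APAAC)
#'
#' Chou's amphiphilic pseudo-composition: the 20 composition terms plus
#' `2 * lambda` sequence-order terms `tau`, where `tau_(2j-1)` is the lag-j
#' hydrophobicity correlation and `tau_(2j)` the lag-j hydrophilicity
#' correlation. Entry `a` of the first block is
#' `f_a / (1 + w * sum(tau))`; entry `20 + j` is `w * tau_j / (1 + w *
#' sum(tau))`. With `lambda = 0` the descriptor reduces to [aac()].
#'
#' @param seq residue string.
#' @param lambda number of correlation lags (`0 <= lambda < L`).
#' @param weight weight `w` of the sequence-order terms (default 0.05).
#' @param h1,h2 standardised hydrophobicity / hydrophilicity tables
#'   (defaults: AAindex ARGP820101 and HOPT810101).
#' @return named numeric vector of length `20 + 2 * lambda`; names `Pc1.<AA>`
#'   and `Pc2.<Hydrophobicity|Hydrophilicity>.<j>`.
#' @export
apaac <- function(seq, lambda = 30L, weight = 0.05,
                  h1 = property_table("ARGP820101"),
                  h2 = property_table("HOPT810101")) {
  L <- nchar(seq)
  if (lambda >= L) stop("lambda must be smaller than the sequence length")
  if (weight <= 0) stop("weight must be positive")
  f <- aac(seq)
  if (lambda == 0L) {
    return(setNames(as.numeric(f), paste0("Pc1.", AA20)))
  }
  p1 <- prop_values(h1)[res_index(seq)]
  p2 <- prop_values(h2)[res_index(seq)]
  tau <- numeric(2L * lambda)
  for (j in seq_len(lambda)) {
    tau[2L * j - 1L] <- lagged_mean(p1, j)
    tau[2L * j] <- lagged_mean(p2, j)
  }
  denom <- 1 + weight * sum(tau)
  out <- c(f / denom, weight * tau / denom)
  names(out) <- c(paste0("Pc1.", AA20),
                  paste0("Pc2.",
                         rep(c("Hydrophobicity", "Hydrophilicity"), lambda),
                         ".", rep(seq_len(lambda), each = 2L)))
  out
}

#' Auto-cross covariance of property scales
#'
#' `ACC_(i,j)(d) = (1/(L - d)) * sum_t s_i(t) s_j(t + d)` for per-residue
#' scale scores `s` (centred per component over the 20 residues), components
#' `i, j <= k` and lags `d = 1..acc_lag`. Feature `i = 5, j = 2, d = 5` is
#' named `"scl5.2lag.5"`.
#'
#' @param seq residue string.
#' @param scales 20 x k numeric matrix of per-residue scores (default
#'   [property_scales()] with k = 5).
#' @param acc_lag maximum lag (`< L`).
#' @return named numeric vector of length `k * k * acc_lag`.
#' @export
scales_acc <- function(seq, scales = property_scales(5L), acc_lag = 13L) {
  L <- nchar(seq)
  if (acc_lag >= L) stop("acc_lag must be smaller than the sequence length")
  k <- ncol(scales)
  idx <- res_index(seq)
  S <- scales[idx, , drop = FALSE]
  out <- numeric(0)
  nm <- character(0)
  for (i in seq_len(k)) for (j in seq_len(k)) for (d in seq_len(acc_lag)) {
    out <- c(out, lagged_mean_pair(S[, i], S[, j], d))
    nm <- c(nm, sprintf("scl%d.%dlag.%d", i, j, d))
  }
  setNames(out, nm)
}

lagged_mean_pair <- function(p, q, d) {
  a <- p[seq_len(length(p) - d)]
  b <- q[(d + 1L):length(q)]
  prod <- a * b
  ok <- !is.na(prod)
  if (!any(ok)) return(0)
  sum(prod[ok]) / sum(ok)
}

# ---- configuration ---------------------------------------------------------

#' Descriptor configuration
#'
#' Defaults reproduce the scale of the full feature inventory (several tens
#' of thousands of named features): 30 autocorrelation lags over every
#' complete AAindex table with three autocorrelation types, tripeptide and
#' dipeptide compositions, APAAC with lambda = 30, and 5 property scales
#' with 13 auto-cross covariance lags.
#'
#' @param lags maximum autocorrelation lag.
#' @param lambda APAAC lambda.
#' @param weight APAAC weight w.
#' @param n_components number of property scales k.
#' @param acc_lag maximum scales auto-cross covariance lag.
#' @param autocorr_accessions AAindex accessions for the autocorrelation
#'   block, or `"all"` for every complete table.
#' @param autocorr_types subset of `c("MBroto", "Moran", "Geary")`.
#' @param include_aac,include_dipeptide,include_tripeptide block switches.
#' @param kmers k-mers counted as explicit features (default `"GFV"`).
#' @return list of class `xt_descriptor_config`.
#' @export
descriptor_config <- function(lags = 30L, lambda = 30L, weight = 0.05,
                              n_components = 5L, acc_lag = 13L,
                              autocorr_accessions = "all",
                              autocorr_types = c("MBroto", "Moran", "Geary"),
                              include_aac = TRUE, include_dipeptide = TRUE,
                              include_tripeptide = TRUE, kmers = "GFV") {
  stopifnot(lags >= 1L, lambda >= 0L, weight > 0, n_components >= 1L,
            acc_lag >= 1L)
  autocorr_types <- match.arg(autocorr_types,
                              c("MBroto", "Moran", "Geary"),
                              several.ok = TRUE)
  structure(list(lags = as.integer(lags), lambda = as.integer(lambda),
                 weight = weight, n_components = as.integer(n_components),
                 acc_lag = as.integer(acc_lag),
                 autocorr_accessions = autocorr_accessions,
                 autocorr_types = autocorr_types,
                 include_aac = include_aac,
                 include_dipeptide = include_dipeptide,
                 include_tripeptide = include_tripeptide,
                 kmers = kmers),
            class = "xt_descriptor_config")
}

# Vectorised autocorrelation over a block of properties: Pm is a 20 x P
# z-scored matrix; returns named vector over types x accessions x lags.
autocorr_block <- function(seq, Pm, lags, types) {
  idx <- res_index(seq)
  L <- length(idx)
  if (lags >= L) stop("autocorrelation lag exceeds sequence length")
  V <- Pm[idx, , drop = FALSE]
  P <- ncol(Pm)
  acc <- colnames(Pm)
  out <- list()
  if ("Moran" %in% types || "Geary" %in% types) {
    mbar <- colMeans(V, na.rm = TRUE)
    C <- sweep(V, 2L, mbar)
    varp <- colMeans(C * C, na.rm = TRUE)           # population variance
    n <- colSums(!is.na(V))
    vars1 <- colSums(C * C, na.rm = TRUE) / pmax(n - 1L, 1L)
  }
  for (ty in types) {
    m <- matrix(0, nrow = lags, ncol = P)
    for (d in seq_len(lags)) {
      i1 <- seq_len(L - d); i2 <- (d + 1L):L
      if (ty == "MBroto") {
        prod <- V[i1, , drop = FALSE] * V[i2, , drop = FALSE]
        cnt <- colSums(!is.na(prod))
        val <- colSums(prod, na.rm = TRUE) / pmax(cnt, 1L)
        val[cnt == 0L] <- 0
      } else if (ty == "Moran") {
        prod <- C[i1, , drop = FALSE] * C[i2, , drop = FALSE]
        cnt <- colSums(!is.na(prod))
        val <- colSums(prod, na.rm = TRUE) / pmax(cnt, 1L)
        val <- ifelse(varp > 0, val / varp, 0)
        val[cnt == 0L] <- 0
      } else {
        dif <- (V[i1, , drop = FALSE] - V[i2, , drop = FALSE])^2
        cnt <- colSums(!is.na(dif))
        num <- colSums(dif, na.rm = TRUE) / (2 * pmax(cnt, 1L))
        val <- ifelse(vars1 > 0, num / vars1, 0)
        val[cnt == 0L] <- 0
      }
      m[d, ] <- val
    }
    dimnames(m) <- list(NULL, acc)
    v <- as.numeric(m)
    names(v) <- paste0(ty, ".", rep(acc, each = lags), ".lag.",
                       rep(seq_len(lags), P))
    out[[ty]] <- v
  }
  unlist(unname(out))
}

# ---- full extraction -------------------------------------------------------

#' Extract the full named feature matrix for a dataset
#'
#' Concatenates the feature blocks in a fixed order: composition (amino
#' acid, dipeptide, tripeptide), k-mer counts, AAindex autocorrelation,
#' APAAC, property-scale auto-cross covariance, then — when the profile
#' inputs are supplied — PROSITE signature features, PSSM summary features
#' and the profile-HMM log-odds score(s) over the annotated regions.
#'
#' @param dataset an `xt_dataset` or `xt_sequences`.
#' @param config an [descriptor_config()] object.
#' @param msa optional `xt_msa` of known positives (profile source).
#' @param regions optional `xt_regions` on the MSA reference row.
#' @param patterns optional named list of PROSITE pattern strings or
#'   compiled [compile_prosite()] objects.
#' @param alpha Laplace pseudocount for PSSM/HMM construction.
#' @return numeric matrix (class `xt_features`), rows = sequence ids,
#'   columns = named features; identical inputs give bitwise-identical
#'   output.
#' @export
extract_all <- function(dataset, config = descriptor_config(),
                        msa = NULL, regions = NULL, patterns = NULL,
                        alpha = 1) {
  records <- if (inherits(dataset, "xt_dataset")) dataset$records else dataset
  stopifnot(inherits(records, "xt_sequences"))
  cfg <- config

  Pm <- NULL
  if (length(cfg$autocorr_types)) {
    Pm <- aaindex_matrix()
    if (!identical(cfg$autocorr_accessions, "all")) {
      missing <- setdiff(cfg$autocorr_accessions, colnames(Pm))
      if (length(missing)) stop("unknown AAindex accession(s): ",
                                paste(missing, collapse = ", "))
      Pm <- Pm[, cfg$autocorr_accessions, drop = FALSE]
    }
    Pm <- apply(Pm, 2L, standardize_property)
    rownames(Pm) <- AA20
  }
  scales <- property_scales(cfg$n_components)
  h1 <- property_table("ARGP820101")
  h2 <- property_table("HOPT810101")

  compiled <- NULL
  if (!is.null(patterns)) {
    compiled <- lapply(patterns, function(p)
      if (inherits(p, "xt_prosite")) p else compile_prosite(p))
    if (is.null(names(compiled)) || any(!nzchar(names(compiled)))) {
      names(compiled) <- paste0("P", seq_along(compiled))
    }
  }

  pssm <- NULL; hmms <- NULL
  if (!is.null(msa)) {
    if (is.null(regions)) stop("regions must accompany the positives MSA")
    cols_by_kind <- lapply(split(seq_len(nrow(regions$regions)),
                                 regions$regions$kind),
                           function(i) map_regions_to_columns(
                             msa, xt_regions(regions$reference_id,
                                             regions$regions[i, , drop = FALSE])))
    all_cols <- sort(unique(unlist(cols_by_kind)))
    pssm <- build_pssm(msa, all_cols, alpha = alpha)
    hmms <- lapply(cols_by_kind, function(cc)
      build_profile_hmm(msa, cc, alpha = alpha))
  }

  one <- function(id, seq) {
    blocks <- list()
    if (cfg$include_aac) blocks$aac <- aac(seq)
    if (cfg$include_dipeptide) blocks$dipep <- dipeptide_composition(seq)
    if (cfg$include_tripeptide) blocks$tripep <- tripeptide_composition(seq)
    if (length(cfg$kmers)) {
      blocks$kmer <- setNames(vapply(cfg$kmers, function(k)
        as.numeric(kmer_count(seq, k)), numeric(1)),
        paste0("count.", cfg$kmers))
    }
    if (!is.null(Pm)) {
      blocks$autocorr <- autocorr_block(seq, Pm, cfg$lags, cfg$autocorr_types)
    }
    blocks$apaac <- apaac(seq, cfg$lambda, cfg$weight, h1, h2)
    blocks$scales <- scales_acc(seq, scales, cfg$acc_lag)
    if (!is.null(compiled)) {
      blocks$prosite <- prosite_features(seq, compiled)
    }
    if (!is.null(pssm)) {
      blocks$pssm <- pssm_features(seq, pssm)
      blocks$hmm <- setNames(vapply(hmms, function(h) hmm_score(h, seq),
                                    numeric(1)),
                             paste0("hmm.", names(hmms)))
    }
    v <- unlist(blocks, use.names = FALSE)
    names(v) <- unlist(lapply(blocks, names), use.names = FALSE)
    v
  }

  rows <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    rows[[i]] <- tryCatch(one(records$id[[i]], records$residues[[i]]),
                          error = function(e)
                            stop("sequence '", records$id[[i]], "': ",
                                 conditionMessage(e), call. = FALSE))
  }
  nm <- names(rows[[1L]])
  if (anyDuplicated(nm)) stop("internal error: duplicate feature names")
  mat <- do.call(rbind, rows)
  rownames(mat) <- records$id
  colnames(mat) <- nm
  class(mat) <- c("xt_features", class(mat))
  mat
}
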