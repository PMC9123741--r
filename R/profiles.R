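#' @name profiles
#' @title Position-specific profiles: PSSM and profile HMM
#'
#' @description
#' Profiles are built from the gapped alignment of known xylose transporters,
#' restricted to alignment columns that carry the annotated non-cytoplasmic
#' domains and putative sugar binding sites of the reference sequence. Two
#' profile types are provided: a position-specific scoring matrix (per-column
#' residue log2-odds with Laplace pseudocounts) whose summary statistics
#' become 23 features per query, and a Krogh-style profile hidden Markov
#' model whose forward-algorithm log2-odds score is the custom HMM feature —
#' the single most informative feature of the classifier.
#'
#' All scores are log base 2 (bits).
NULL

uniform_background <- function() setNames(rep(1 / 20, 20L), AA20)

# ---- region -> column mapping ----------------------------------------------

#' Map reference-sequence regions to alignment columns
#'
#' For each annotated residue of the (ungapped) reference sequence, returns
#' the alignment column that holds it. Reference gap columns are never
#' selected.
#'
#' @param msa `xt_msa` containing the reference row.
#' @param ann `xt_regions` whose `reference_id` names a row of `msa`.
#' @return sorted unique integer vector of alignment column indices.
#' @export
map_regions_to_columns <- function(msa, ann) {
  if (!ann$reference_id %in% msa$ids) {
    stop("reference row '", ann$reference_id, "' missing from alignment")
  }
  row <- strsplit(msa$aligned[[ann$reference_id]], "", fixed = TRUE)[[1L]]
  residue_cols <- which(row != "-")
  reflen <- length(residue_cols)
  if (any(ann$regions$end > reflen)) {
    stop("region exceeds ungapped reference length (", reflen, ")")
  }
  cols <- unlist(lapply(seq_len(nrow(ann$regions)), function(i) {
    residue_cols[ann$regions$start[[i]]:ann$regions$end[[i]]]
  }))
  sort(unique(cols))
}

# ---- PSSM ------------------------------------------------------------------

#' Build a position-specific scoring matrix from alignment columns
#'
#' Column probabilities are `(count_a + alpha) / (n_nongap + 20 * alpha)`
#' with gaps (and ambiguous `X`) excluded from the counts; log-odds are
#' `log2(p / q)` against the background `q`.
#'
#' @param msa `xt_msa`.
#' @param columns alignment column indices to retain (e.g. from
#'   [map_regions_to_columns()]).
#' @param alpha Laplace pseudocount (default 1).
#' @param q background residue frequencies (default uniform).
#' @return list of class `xt_pssm`: `width`, `columns`, `probs` (20 x width),
#'   `log_odds`, `consensus`, `q`, `alpha`.
#' @export
build_pssm <- function(msa, columns, alpha = 1, q = uniform_background()) {
  stopifnot(length(columns) >= 1L, alpha >= 0)
  columns <- sort(unique(as.integer(columns)))
  if (any(columns < 1L | columns > msa$width)) stop("column index out of range")
  q <- q[AA20]
  chars <- do.call(rbind, strsplit(msa$aligned, "", fixed = TRUE))
  sub <- chars[, columns, drop = FALSE]
  probs <- matrix(0, nrow = 20L, ncol = length(columns),
                  dimnames = list(AA20, NULL))
  for (j in seq_along(columns)) {
    col <- sub[, j]
    cnt <- tabulate(match(col, AA20), nbins = 20L)
    n <- sum(cnt)
    if (n == 0L && alpha == 0) {
      stop("alignment column ", columns[[j]],
           " has no residues and alpha = 0")
    }
    probs[, j] <- (cnt + alpha) / (n + 20 * alpha)
  }
  log_odds <- log2(probs / q)
  consensus <- paste0(AA20[apply(probs, 2L, which.max)], collapse = "")
  structure(list(width = length(columns), columns = columns, probs = probs,
                 log_odds = log_odds, consensus = consensus,
                 q = q, alpha = alpha),
            class = "xt_pssm")
}

#' PSSM summary features for a query sequence
#'
#' The query is aligned globally-in-profile/locally-in-query to the profile
#' consensus (BLOSUM62, gap open 10 / extend 1); every aligned query residue
#' takes the log-odds of its letter at that profile column. Summary: 20
#' per-residue-class mean scores, the overall mean, the maximum, and the
#' fraction of profile columns covered by a query residue (23 features).
#'
#' @param seq residue string.
#' @param pssm `xt_pssm`.
#' @return named numeric vector of 23 features (`pssm.mean.<AA>`,
#'   `pssm.mean`, `pssm.max`, `pssm.coverage`).
#' @export
pssm_features <- function(seq, pssm) {
  if (!nzchar(seq)) stop("empty query sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pssm$consensus), Biostrings::AAString(seq),
    substitutionMatrix = blosum62(), gapOpening = 10, gapExtension = 1,
    type = "global-local")
  pc <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  sc <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  k <- 0L
  scores <- numeric(0)
  letters_seen <- character(0)
  covered <- 0L
  for (i in seq_along(pc)) {
    if (pc[[i]] != "-") k <- k + 1L
    if (pc[[i]] != "-" && sc[[i]] != "-") {
      if (sc[[i]] %in% AA20) {
        covered <- covered + 1L
        scores <- c(scores, pssm$log_odds[sc[[i]], k])
        letters_seen <- c(letters_seen, sc[[i]])
      }
    }
  }
  if (length(scores) == 0L) stop("query has no alignable overlap with profile")
  cls <- vapply(AA20, function(a) {
    s <- scores[letters_seen == a]
    if (length(s)) mean(s) else 0
  }, numeric(1))
  c(setNames(cls, paste0("pssm.mean.", AA20)),
    pssm.mean = mean(scores), pssm.max = max(scores),
    pssm.coverage = covered / pssm$width)
}

blosum62 <- function() {
  if (is.null(.xt_cache$blosum62)) {
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    .xt_cache$blosum62 <- env$BLOSUM62
  }
  .xt_cache$blosum62
}

# ---- profile HMM -----------------------------------------------------------

#' Build a Krogh-style profile HMM from alignment columns
#'
#' Selected columns with at least `occupancy` non-gap fraction become match
#' states; the remaining selected columns feed the insert state that follows
#' the preceding match state. Emission and transition probabilities are
#' estimated from the per-row state paths with Laplace pseudocount `alpha`;
#' insert states emit the background distribution `q`. States from an
#' unobserved source are given uniform transitions over their allowed
#' destinations when `alpha = 0`.
#'
#' The first and last insert states (`I_0`, `I_m`) act as *flanking* states:
#' a whole-protein query traverses them for every residue outside the
#' modelled domain, so their self-transition probability is set analytically
#' to `flank_loop` (the remaining mass follows the estimated distribution
#' over the other destinations) rather than estimated from the domain
#' alignment, which contains no flank observations. This keeps the
#' forward log-odds score nearly independent of how much sequence flanks
#' the domain. Set `flank_loop = NULL` to estimate all transitions from the
#' alignment alone.
#'
#' @param msa `xt_msa`.
#' @param columns alignment columns (from [map_regions_to_columns()]).
#' @param alpha Laplace pseudocount (default 1).
#' @param q background frequencies over the model alphabet.
#' @param occupancy match-column occupancy threshold (default 0.5).
#' @param alphabet model alphabet (default the 20 amino acids).
#' @param flank_loop self-transition probability of the flanking insert
#'   states (default 0.99, suited to flanks of a few hundred residues), or
#'   `NULL` for count-based estimates only.
#' @return list of class `xt_hmm`; see source for slot layout.
#' @export
build_profile_hmm <- function(msa, columns, alpha = 1,
                              q = uniform_background(), occupancy = 0.5,
                              alphabet = AA20, flank_loop = 0.99) {
  stopifnot(length(columns) >= 1L, alpha >= 0)
  columns <- sort(unique(as.integer(columns)))
  if (any(columns < 1L | columns > msa$width)) stop("column index out of range")
  q <- q[alphabet]
  stopifnot(!any(is.na(q)), abs(sum(q) - 1) < 1e-9)
  A <- length(alphabet)
  chars <- do.call(rbind, strsplit(msa$aligned, "", fixed = TRUE))
  sub <- chars[, columns, drop = FALSE]
  occ <- colMeans(sub != "-")
  is_match <- occ >= occupancy
  m <- sum(is_match)
  if (m == 0L) stop("no column meets the match-state occupancy rule")

  emis <- matrix(alpha, nrow = A, ncol = m, dimnames = list(alphabet, NULL))
  # transition counts; rows j = 0..m index the source state M_j / I_j / D_j,
  # columns the destination type (M_{j+1} or E, I_j, D_{j+1})
  cM <- matrix(0, m + 1L, 3L, dimnames = list(NULL, c("M", "I", "D")))
  cI <- matrix(0, m + 1L, 3L, dimnames = list(NULL, c("M", "I", "D")))
  cD <- matrix(0, m + 1L, 3L, dimnames = list(NULL, c("M", "I", "D")))

  match_no <- cumsum(is_match)
  for (r in seq_len(nrow(sub))) {
    prev <- c("M", 0L)  # begin state B = M_0
    for (jcol in seq_along(columns)) {
      ch <- sub[r, jcol]
      if (is_match[[jcol]]) {
        k <- match_no[[jcol]]
        if (ch == "-") {
          st <- c("D", k)
        } else {
          st <- c("M", k)
          if (ch %in% alphabet) emis[ch, k] <- emis[ch, k] + 1
        }
      } else {
        if (ch == "-") next
        st <- c("I", match_no[[jcol]])
      }
      from <- prev[[1L]]; fj <- as.integer(prev[[2L]])
      dest <- st[[1L]]
      if (from == "M") cM[fj + 1L, dest] <- cM[fj + 1L, dest] + 1
      if (from == "I") cI[fj + 1L, dest] <- cI[fj + 1L, dest] + 1
      if (from == "D") cD[fj + 1L, dest] <- cD[fj + 1L, dest] + 1
      prev <- st
    }
    # transition into the end state, recorded in the "M" column of row m + 1
    from <- prev[[1L]]; fj <- as.integer(prev[[2L]])
    if (from == "M") cM[fj + 1L, "M"] <- cM[fj + 1L, "M"] + 1
    if (from == "I") cI[fj + 1L, "M"] <- cI[fj + 1L, "M"] + 1
    if (from == "D") cD[fj + 1L, "M"] <- cD[fj + 1L, "M"] + 1
  }

  emis <- sweep(emis, 2L, colSums(emis), "/")
  norm_trans <- function(cnt, is_delete) {
    p <- matrix(0, nrow(cnt), 3L, dimnames = dimnames(cnt))
    for (j in seq_len(nrow(cnt))) {
      jj <- j - 1L                      # source index
      if (is_delete && (jj < 1L || jj > m)) { p[j, ] <- NA; next }
      allowed <- c(TRUE, TRUE, jj < m)  # no D_(m+1); row m+1 is M_m/I_m -> E
      x <- cnt[j, ] + alpha * allowed
      x[!allowed] <- 0
      if (sum(x) == 0) x <- as.numeric(allowed) / sum(allowed)
      p[j, ] <- x / sum(x)
    }
    p
  }
  tI <- norm_trans(cI, FALSE)
  if (!is.null(flank_loop)) {
    stopifnot(flank_loop > 0, flank_loop < 1)
    for (r in c(1L, m + 1L)) {      # sources I_0 and I_m
      rest <- tI[r, c("M", "D")]
      rest <- if (sum(rest) > 0) rest / sum(rest) else c(M = 1, D = 0)
      tI[r, "I"] <- flank_loop
      tI[r, c("M", "D")] <- (1 - flank_loop) * rest
    }
  }
  structure(list(m = m, alphabet = alphabet, q = q, alpha = alpha,
                 occupancy = occupancy, columns = columns,
                 match_columns = columns[is_match],
                 flank_loop = flank_loop,
                 emissions = emis,
                 tM = norm_trans(cM, FALSE),
                 tI = tI,
                 tD = norm_trans(cD, TRUE)),
            class = "xt_hmm")
}

#' @export
print.xt_hmm <- function(x, ...) {
  cat("Profile HMM:", x$m, "match states over", length(x$columns),
      "alignment columns (alpha =", x$alpha, ")\n")
  invisible(x)
}

# Delete-state chain: given the probability mass g[k] entering D_k from the
# current M/I layer, propagate along D_k -> D_(k+1) (probabilities dd[k],
# k = 1..m-1). Closed form via prefix products when numerically safe,
# sequential fallback otherwise.
delete_chain <- function(g, dd) {
  m <- length(g)
  if (m == 1L) return(g)
  cp <- cumprod(c(1, dd))          # cp[k] = prod of dd up to k-1
  if (all(dd > 0) && cp[[m]] > 1e-280) {
    cp * cumsum(g / cp)
  } else {
    out <- numeric(m)
    out[[1L]] <- g[[1L]]
    for (k in 2L:m) out[[k]] <- g[[k]] + out[[k - 1L]] * dd[[k - 1L]]
    out
  }
}

#' Forward-algorithm log-odds score of a sequence under a profile HMM
#'
#' Computes `log2 P(seq | hmm) - log2 P(seq | background)` by the forward
#' algorithm (sum over all state paths, computed in scaled probability
#' space), in bits. Residues outside the model alphabet (i.e. `X`)
#' contribute probability 1 under both models. Poor matches give low
#' (negative) scores, never errors.
#'
#' @param hmm `xt_hmm`.
#' @param seq residue string (non-empty).
#' @return scalar score in bits.
#' @export
hmm_score <- function(hmm, seq) {
  stopifnot(nzchar(seq))
  x <- strsplit(seq, "", fixed = TRUE)[[1L]]
  idx <- match(x, hmm$alphabet)
  L <- length(x)
  m <- hmm$m
  # transition-prob vectors; source-state index j lives in row j + 1
  tMM <- hmm$tM[, "M"]; tMI <- hmm$tM[, "I"]; tMD <- hmm$tM[, "D"]
  tIM <- hmm$tI[, "M"]; tII <- hmm$tI[, "I"]; tID <- hmm$tI[, "D"]
  tDM <- hmm$tD[, "M"]; tDI <- hmm$tD[, "I"]; tDD <- hmm$tD[, "D"]
  dd <- if (m > 1L) tDD[2L:m] else numeric(0)  # D_k -> D_(k+1)
  # emission probability of observation i under the match states (m-vector)
  # and under the background; X rows emit 1 under both models
  EM <- matrix(1, nrow = L, ncol = m)
  known <- !is.na(idx)
  if (any(known)) EM[known, ] <- hmm$emissions[idx[known], , drop = FALSE]
  bg <- ifelse(known, hmm$q[idx], 1)

  # vector index j + 1 holds state M_j / I_j; FD[k] holds D_k
  FM <- c(1, rep(0, m))
  FI <- rep(0, m + 1L)
  g0 <- c(FM[[1L]] * tMD[[1L]], rep(0, m - 1L))
  FD <- delete_chain(g0, dd)
  logscale <- 0

  jm <- seq_len(m)
  for (i in seq_len(L)) {
    prevM <- FM; prevI <- FI; prevD <- FD
    inM <- prevM[jm] * tMM[jm] + prevI[jm] * tIM[jm] +
      c(0, if (m > 1L) prevD[seq_len(m - 1L)] * tDM[1L + seq_len(m - 1L)])
    FM <- c(0, EM[i, ] * inM)
    FI <- bg[[i]] * (prevM * tMI + prevI * tII +
                       c(0, prevD * tDI[1L + jm]))
    g <- FM[jm] * tMD[jm] + FI[jm] * tID[jm]
    FD <- delete_chain(g, dd)
    s <- max(FM, FI, FD)
    if (s > 0 && is.finite(s)) {
      FM <- FM / s; FI <- FI / s; FD <- FD / s
      logscale <- logscale + log(s)
    }
  }
  pend <- FM[[m + 1L]] * tMM[[m + 1L]] + FI[[m + 1L]] * tIM[[m + 1L]] +
    FD[[m]] * tDM[[m + 1L]]
  logp <- log(pend) + logscale
  lognull <- sum(log(bg))
  as.numeric((logp - lognull) / log(2))
}

# ---- serialization ---------------------------------------------------------

#' Write a profile HMM (or PSSM) to versioned JSON
#' @param x `xt_hmm` or `xt_pssm`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(x, path) {
  kind <- if (inherits(x, "xt_hmm")) "hmm" else if (inherits(x, "xt_pssm"))
    "pssm" else stop("not a profile object")
  obj <- lapply(unclass(x), function(el)
    if (is.matrix(el)) list(.matrix = TRUE, dim = dim(el),
                            dimnames = dimnames(el), data = as.numeric(el))
    else el)
  jsonlite::write_json(list(format = "xtclass-profile", version = 1L,
                            kind = kind, payload = obj),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a profile HMM or PSSM written by [write_profile()]
#' @param path JSON file.
#' @return `xt_hmm` or `xt_pssm`.
#' @export
read_profile <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "xtclass-profile") || obj$version != 1L) {
    stop("not a version-1 xtclass profile file")
  }
  payload <- lapply(obj$payload, function(el) {
    if (is.list(el) && isTRUE(el$.matrix)) {
      m <- matrix(el$data, nrow = el$dim[[1L]], ncol = el$dim[[2L]])
      dimnames(m) <- el$dimnames
      m
    } else el
  })
  if (!is.null(payload$q)) payload$q <- unlist(payload$q)
  class(payload) <- if (obj$kind == "hmm") "xt_hmm" else "xt_pssm"
  payload
}

# ---- precomputed ASCII PSSM ingestion --------------------------------------

#' Read a PSI-BLAST style ASCII PSSM file
#'
#' Parses the conventional per-protein ASCII matrix (one row per sequence
#' position: index, residue, then 20 log-odds columns headed by the residue
#' letters). Only the log-odds block is used.
#'
#' @param path ASCII PSSM file.
#' @return list of class `xt_pssm_ascii` with `residues` (the protein's own
#'   sequence) and `log_odds` (L x 20 matrix, columns in file order).
#' @export
read_pssm_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^\\s*[A-Z](\\s+[A-Z]){19}", lines)[1L]
  if (is.na(hdr)) stop("no PSSM header row of residue letters found")
  letters20 <- strsplit(trimws(lines[[hdr]]), "\\s+")[[1L]][1:20]
  rows <- list(); res <- character(0)
  for (ln in lines[(hdr + 1L):length(lines)]) {
    tok <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(tok) < 22L || is.na(suppressWarnings(as.integer(tok[[1L]]))))
      next
    res <- c(res, tok[[2L]])
    rows[[length(rows) + 1L]] <- as.numeric(tok[3:22])
  }
  if (!length(rows)) stop("no PSSM data rows found")
  lo <- do.call(rbind, rows)
  colnames(lo) <- letters20
  structure(list(residues = res, log_odds = lo), class = "xt_pssm_ascii")
}

#' Summary features from a precomputed per-protein PSSM
#'
#' The self-score of each position (the log-odds of the protein's own
#' residue) is summarised the same way as [pssm_features()]: 20
#' per-residue-class means, overall mean, max, and coverage (here the
#' fraction of positions with a standard residue).
#'
#' @param x `xt_pssm_ascii` from [read_pssm_ascii()].
#' @return named numeric vector of 23 features.
#' @export
pssm_ascii_features <- function(x) {
  keep <- x$residues %in% AA20 & x$residues %in% colnames(x$log_odds)
  if (!any(keep)) stop("PSSM contains no standard residues")
  scores <- x$log_odds[cbind(which(keep), match(x$residues[keep],
                                                colnames(x$log_odds)))]
  letters_seen <- x$residues[keep]
  cls <- vapply(AA20, function(a) {
    s <- scores[letters_seen == a]
    if (length(s)) mean(s) else 0
  }, numeric(1))
  c(setNames(cls, paste0("pssm.mean.", AA20)),
    pssm.mean = mean(scores), pssm.max = max(scores),
    pssm.coverage = mean(keep))
}
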