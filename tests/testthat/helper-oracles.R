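# Shared fixtures and independent oracles used across the test files.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_seq <- function(n, alphabet = AA) {
  paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}

toy_property <- function(values) {
  v <- setNames(rep(0, 20L), AA)
  v[names(values)] <- values
  structure(list(accession = "toy", values = v, standardized = TRUE),
            class = "xt_property")
}

# Brute-force forward probability: explicit enumeration of every state path
# through the profile that emits the sequence. Independent of the DP code.
enum_forward <- function(hmm, seq) {
  x <- strsplit(seq, "", fixed = TRUE)[[1L]]
  m <- hmm$m
  total <- 0
  rec <- function(type, j, i, p) {
    tmat <- switch(type, M = hmm$tM, I = hmm$tI, D = hmm$tD)
    row <- tmat[j + 1L, ]
    if (j == m) {
      if (i == length(x)) total <<- total + p * row[["M"]]
    } else {
      if (i < length(x)) {
        pe <- hmm$emissions[x[[i + 1L]], j + 1L]
        if (pe > 0 && row[["M"]] > 0) rec("M", j + 1L, i + 1L,
                                          p * row[["M"]] * pe)
      }
      if (row[["D"]] > 0) rec("D", j + 1L, i, p * row[["D"]])
    }
    if (i < length(x) && row[["I"]] > 0) {
      rec("I", j, i + 1L, p * row[["I"]] * hmm$q[[x[[i + 1L]]]])
    }
  }
  rec("M", 0L, 0L, 1)
  unname(total)
}

# Forward probability of `seq` from its bit score (undoes the null model).
forward_prob <- function(hmm, seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  2^hmm_score(hmm, seq) * prod(hmm$q[chars])
}

# Global affine-gap alignment oracle: plain three-matrix DP written
# independently of Biostrings (gap open 10, extend 1 means first gap
# position costs 10 + 1 = 11 under Biostrings' convention).
nw_identity_oracle <- function(a, b, sub, gap_open = 10, gap_ext = 1) {
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  open <- gap_open + gap_ext
  M <- matrix(NEG, n + 1L, m + 1L)   # match/mismatch state, plus traceback
  X <- matrix(NEG, n + 1L, m + 1L)   # gap in b (vertical)
  Y <- matrix(NEG, n + 1L, m + 1L)   # gap in a (horizontal)
  M[1L, 1L] <- 0
  for (i in 2L:(n + 1L)) X[i, 1L] <- -open - (i - 2L) * gap_ext
  for (j in 2L:(m + 1L)) Y[1L, j] <- -open - (j - 2L) * gap_ext
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      s <- sub[av[[i - 1L]], bv[[j - 1L]]]
      M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                     Y[i - 1L, j - 1L]) + s
      X[i, j] <- max(M[i - 1L, j] - open, X[i - 1L, j] - gap_ext,
                     Y[i - 1L, j] - open)
      Y[i, j] <- max(M[i, j - 1L] - open, Y[i, j - 1L] - gap_ext,
                     X[i, j - 1L] - open)
    }
  }
  # traceback for identical aligned positions, greedy over best state
  ident <- 0L; i <- n + 1L; j <- m + 1L
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  while (i > 1L || j > 1L) {
    if (state == 1L && i > 1L && j > 1L) {
      if (av[[i - 1L]] == bv[[j - 1L]]) ident <- ident + 1L
      s <- sub[av[[i - 1L]], bv[[j - 1L]]]
      prev <- c(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
      state <- which.max(prev)
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L && i > 1L) {
      prev <- c(M[i - 1L, j] - open, X[i - 1L, j] - gap_ext,
                Y[i - 1L, j] - open)
      state <- which.max(prev)
      i <- i - 1L
    } else {
      prev <- c(M[i, j - 1L] - open, Y[i, j - 1L] - gap_ext,
                X[i, j - 1L] - open)
      state <- c(1L, 3L, 2L)[which.max(prev)]
      j <- j - 1L
    }
  }
  ident / min(n, m)
}

blosum62_matrix <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}

# Pair-counting AUC oracle.
auc_oracle <- function(scores, labels) {
  pos <- which(labels == 1L); neg <- which(labels == 0L)
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (scores[[p]] > scores[[n]]) 1
      else if (scores[[p]] == scores[[n]]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Exhaustive step-integral average precision oracle.
ap_oracle <- function(scores, labels) {
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L) return(NA_real_)
  thr <- sort(unique(scores), decreasing = TRUE)
  ap <- 0; prev_rec <- 0
  for (t in thr) {
    sel <- scores >= t
    prec <- sum(labels[sel] == 1L) / sum(sel)
    rec <- sum(labels[sel] == 1L) / n_pos
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

# Compact labelled dataset for I/O and clustering tests.
make_tiny_dataset <- function(seed = 1L, n_pos = 4L, n_neg = 10L, len = 60L) {
  xtclass:::with_seed(seed, {
    ids <- c(sprintf("p%02d", seq_len(n_pos)), sprintf("n%02d", seq_len(n_neg)))
    seqs <- replicate(n_pos + n_neg, rand_seq(len))
    recs <- xt_sequences(ids, seqs)
    labels <- setNames(c(rep(1L, n_pos), rep(0L, n_neg)), ids)
    suppressMessages(xt_dataset(recs, labels))
  })
}

lean_descriptor <- function() {
  descriptor_config(autocorr_accessions = c("DAYM780201", "BIGC670101"),
                    autocorr_types = "MBroto", include_tripeptide = FALSE)
}
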