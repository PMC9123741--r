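#' @name imbalance
#' @title Class-imbalance resampling: SMOTE, ENN and their combination
#'
#' @description
#' Resamplers implemented from their definitions. SMOTE synthesises minority
#' samples by interpolating between a minority sample and one of its k
#' nearest minority neighbours; edited nearest neighbours (ENN) removes any
#' sample whose label disagrees with the majority of its k nearest
#' neighbours; SMOTE+ENN applies both in sequence — the combination used for
#' the final model. Random duplication oversampling is kept as a baseline.
#'
#' Neighbour searches use Euclidean distance on the raw feature scale by
#' default (set `standardize = TRUE` in [resample_config()] to z-score
#' internally first); returned samples are always on the original scale.
#' Distance ties are broken by sample index, and every method is
#' deterministic given `seed`. Resampling is meant for training data only —
#' never apply it to evaluation data.
NULL

#' Resampling configuration
#'
#' @param method one of `"random"`, `"smote"`, `"smote_enn"`, or `"none"`.
#' @param k_smote neighbours used for SMOTE synthesis (default 5).
#' @param k_enn neighbours used for ENN editing (default 3).
#' @param seed integer RNG seed.
#' @param target_ratio minority/majority ratio after oversampling, in
#'   (0, 1] (default 1).
#' @param standardize z-score features (fitted on the input) before
#'   neighbour computations. Default `FALSE`: raw Euclidean distance, the
#'   convention of the reference resamplers. With many uninformative
#'   descriptors, z-scoring makes distances concentrate on noise dimensions
#'   and ENN can then edit away entire classes; see the methods vignette.
#' @return list of class `xt_resample_config`.
#' @export
resample_config <- function(method = c("smote_enn", "smote", "random", "none"),
                            k_smote = 5L, k_enn = 3L, seed = 1L,
                            target_ratio = 1.0, standardize = FALSE) {
  method <- match.arg(method)
  stopifnot(k_smote >= 1L, k_enn >= 1L,
            target_ratio > 0, target_ratio <= 1)
  structure(list(method = method, k_smote = as.integer(k_smote),
                 k_enn = as.integer(k_enn), seed = as.integer(seed),
                 target_ratio = target_ratio,
                 standardize = isTRUE(standardize)),
            class = "xt_resample_config")
}

resample_space <- function(X, cfg) {
  if (isTRUE(cfg$standardize)) zscore_apply(X, zscore_fit(X)) else X
}

zscore_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(mu = mu, sd = sdv)
}
zscore_apply <- function(X, z) sweep(sweep(X, 2L, z$mu), 2L, z$sd, "/")

# k nearest neighbour indices of row i among candidate rows `pool`
# (self excluded by the caller); ties broken by ascending index.
knn_idx <- function(D, i, pool, k) {
  o <- order(D[i, pool], pool)
  pool[o[seq_len(k)]]
}

minority_label <- function(y) {
  tab <- table(factor(y, levels = c(0L, 1L)))
  if (tab[["1"]] <= tab[["0"]]) 1L else 0L
}

#' SMOTE oversampling
#'
#' Each synthetic row is `x + u * (x_nn - x)` with `u ~ Uniform(0, 1)` and
#' `x_nn` one of the `k_smote` nearest minority neighbours of `x`; base
#' samples are cycled in index order until the minority count reaches
#' `target_ratio * majority`. Synthetic rows are named `syn.<i>`.
#'
#' @param X numeric feature matrix with row names.
#' @param y 0/1 integer labels (same length as `nrow(X)`).
#' @param cfg [resample_config()].
#' @return list with resampled `X` and `y`.
#' @export
smote <- function(X, y, cfg = resample_config("smote")) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  minc <- minority_label(y)
  mi <- which(y == minc)
  if (length(mi) < 2L) stop("SMOTE needs at least 2 minority samples")
  if (cfg$k_smote >= length(mi)) {
    stop("k_smote must be smaller than the minority count (",
         length(mi), ")")
  }
  n_target <- round(cfg$target_ratio * sum(y != minc))
  n_syn <- n_target - length(mi)
  if (n_syn <= 0L) return(list(X = X, y = y))
  Z <- resample_space(X, cfg)
  Dm <- as.matrix(dist(Z[mi, , drop = FALSE]))
  syn <- with_seed(cfg$seed, {
    base <- rep_len(seq_along(mi), n_syn)
    rows <- lapply(seq_len(n_syn), function(s) {
      b <- base[[s]]
      nn_local <- knn_idx(Dm, b, setdiff(seq_along(mi), b), cfg$k_smote)
      nb <- nn_local[[sample.int(cfg$k_smote, 1L)]]
      u <- runif(1L)
      X[mi[[b]], ] + u * (X[mi[[nb]], ] - X[mi[[b]], ])
    })
    matrix(unlist(rows), nrow = n_syn, byrow = TRUE)
  })
  rownames(syn) <- paste0("syn.", seq_len(n_syn))
  colnames(syn) <- colnames(X)
  X2 <- rbind(X, syn)
  y2 <- c(y, rep(minc, n_syn))
  list(X = X2, y = y2)
}

#' Edited nearest neighbours cleaning
#'
#' Removes every sample (either class) whose label differs from the strict
#' majority label of its `k_enn` nearest neighbours, self excluded; all
#' neighbourhoods are computed on the original input in one pass. With an
#' even `k_enn`, a tie keeps the sample.
#'
#' @inheritParams smote
#' @return list with cleaned `X` and `y` (original rows only, order kept).
#' @export
enn_clean <- function(X, y, cfg = resample_config("smote_enn")) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  n <- nrow(X)
  if (n < cfg$k_enn + 1L) stop("need more than k_enn samples for ENN")
  Z <- resample_space(X, cfg)
  D <- as.matrix(dist(Z))
  remove <- vapply(seq_len(n), function(i) {
    nn <- knn_idx(D, i, setdiff(seq_len(n), i), cfg$k_enn)
    disagree <- sum(y[nn] != y[[i]])
    disagree * 2L > cfg$k_enn
  }, logical(1))
  list(X = X[!remove, , drop = FALSE], y = y[!remove])
}

#' Random duplication oversampling
#' @inheritParams smote
#' @return list with resampled `X` and `y`; added rows are copies of
#'   minority rows, named `dup.<i>`.
#' @export
random_oversample <- function(X, y, cfg = resample_config("random")) {
  minc <- minority_label(y)
  mi <- which(y == minc)
  n_syn <- round(cfg$target_ratio * sum(y != minc)) - length(mi)
  if (n_syn <= 0L) return(list(X = X, y = y))
  pick <- with_seed(cfg$seed, sample(mi, n_syn, replace = TRUE))
  dup <- X[pick, , drop = FALSE]
  rownames(dup) <- paste0("dup.", seq_len(n_syn))
  list(X = rbind(X, dup), y = c(y, rep(minc, n_syn)))
}

#' Dispatch a resampling method
#'
#' `smote_enn` runs [smote()] then [enn_clean()]. Class counts before and
#' after are reported.
#'
#' @inheritParams smote
#' @return list with resampled `X` and `y`.
#' @export
resample <- function(X, y, cfg) {
  apply_resample(X, y, cfg)
}

apply_resample <- function(X, y, cfg) {
  before <- table(factor(y, levels = c(0L, 1L)))
  out <- switch(cfg$method,
    none = list(X = X, y = y),
    random = random_oversample(X, y, cfg),
    smote = smote(X, y, cfg),
    smote_enn = {
      s <- smote(X, y, cfg)
      enn_clean(s$X, s$y, cfg)
    })
  after <- table(factor(out$y, levels = c(0L, 1L)))
  logmsg("resample (", cfg$method, "): ",
         before[["1"]], "/", before[["0"]], " -> ",
         after[["1"]], "/", after[["0"]], " (pos/neg)")
  out
}
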