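#' @name learn
#' @title Training: split, feature elimination, fitting, calibration
#'
#' @description
#' The learning stage around a gradient-boosted tree learner: a stratified
#' 70/30 train/test split, recursive feature elimination with
#' cross-validation (RFECV) using the learner's own importance ranking,
#' model fitting with imbalance-aware resampling applied to the training
#' data only, a full metric suite, and decision-threshold recalibration —
#' the default deployment threshold is 0.98, trading recall for
#' near-nullified false positives.
#'
#' The learner is a contract (fit / probability prediction / per-feature
#' importance); boosting itself is delegated to xgboost.
NULL

#' Split configuration
#' @param train_fraction fraction of samples in the training split
#'   (default 0.7).
#' @param stratified preserve class proportions (default `TRUE`).
#' @param seed RNG seed.
#' @return list of class `xt_split_config`.
#' @export
split_config <- function(train_fraction = 0.7, stratified = TRUE, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  structure(list(train_fraction = train_fraction, stratified = stratified,
                 seed = as.integer(seed)),
            class = "xt_split_config")
}

#' Stratified train/test split
#'
#' @param X feature matrix with row names; `y` named or plain 0/1 labels.
#' @param y 0/1 integer labels aligned with `X` rows.
#' @param cfg [split_config()].
#' @return list with `train = list(X, y)` and `test = list(X, y)`; per-class
#'   training fractions are within one sample of `train_fraction`.
#' @export
split_dataset <- function(X, y, cfg = split_config()) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  idx_tr <- with_seed(cfg$seed, {
    if (cfg$stratified) {
      unlist(lapply(c(0L, 1L), function(cl) {
        ii <- which(y == cl)
        if (length(ii) < 2L) {
          stop("class ", cl, " has fewer than 2 samples; cannot stratify")
        }
        n_tr <- floor(cfg$train_fraction * length(ii) + 0.5)
        n_tr <- min(max(n_tr, 1L), length(ii) - 1L)
        sample(ii, n_tr)
      }))
    } else {
      n_tr <- floor(cfg$train_fraction * length(y) + 0.5)
      sample(seq_along(y), n_tr)
    }
  })
  idx_tr <- sort(idx_tr)
  idx_te <- setdiff(seq_along(y), idx_tr)
  list(train = list(X = X[idx_tr, , drop = FALSE], y = y[idx_tr]),
       test = list(X = X[idx_te, , drop = FALSE], y = y[idx_te]))
}

# ---- learner contract ------------------------------------------------------

#' Gradient-boosted tree learner contract
#'
#' Wraps xgboost behind the three-method contract the pipeline requires:
#' `fit(X, y, seed)`, `predict_prob(model, X)`, and `importance(model,
#' feature_names)` (gain per feature, 0 for unused features). Training is
#' single-threaded for bitwise reproducibility.
#'
#' @param nrounds boosting rounds.
#' @param max_depth tree depth.
#' @param eta learning rate.
#' @param colsample_bytree fraction of features sampled per tree (default
#'   0.5). Subsampling keeps the early trees from riding on a single
#'   feature when several separate the training data equally well, which
#'   matters for probability ranking once gradients saturate.
#' @param ... further xgboost params (e.g. `subsample`).
#' @return list of class `xt_learner`.
#' @export
xgb_learner <- function(nrounds = 80L, max_depth = 4L, eta = 0.3,
                        colsample_bytree = 0.5, ...) {
  params <- list(objective = "binary:logistic", max_depth = max_depth,
                 eta = eta, colsample_bytree = colsample_bytree,
                 nthread = 1L, ...)
  structure(list(
    name = "xgboost",
    params = c(params, nrounds = nrounds),
    fit = function(X, y, seed = 1L) {
      dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1L)
      xgboost::xgb.train(params = c(params, seed = as.integer(seed)),
                         data = dtrain, nrounds = nrounds, verbose = 0)
    },
    predict_prob = function(model, X) {
      as.numeric(stats::predict(model,
                                xgboost::xgb.DMatrix(X, nthread = 1L)))
    },
    importance = function(model, feature_names) {
      imp <- setNames(rep(0, length(feature_names)), feature_names)
      tab <- tryCatch(xgboost::xgb.importance(model = model),
                      error = function(e) NULL)
      if (!is.null(tab) && nrow(tab)) {
        imp[tab$Feature] <- tab$Gain
      }
      imp
    }),
    class = "xt_learner")
}

# ---- RFECV -----------------------------------------------------------------

feature_count_schedule <- function(p, step, min_features = 1L) {
  min_features <- min(min_features, p)
  sizes <- p
  while (p > min_features) {
    drop <- if (step < 1) max(1L, ceiling(step * p)) else min(step, p - 1L)
    p <- max(min_features, p - drop)
    sizes <- c(sizes, p)
  }
  as.integer(sizes)
}

stratified_folds <- function(y, folds, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      ii <- sample(which(y == cl))
      fold[ii] <- rep_len(seq_len(folds), length(ii))
    }
  })
  fold
}

# one elimination pass: returns validation score at each schedule size
# (and, if keep_sets, the surviving feature set at each size)
rfe_pass <- function(Xtr, ytr, Xval, yval, learner, sizes, metric_fun, seed) {
  feats <- colnames(Xtr)
  scores <- numeric(length(sizes))
  sets <- vector("list", length(sizes))
  for (s in seq_along(sizes)) {
    if (length(feats) > sizes[[s]]) {
      stop("internal: schedule mismatch")
    }
    model <- learner$fit(Xtr[, feats, drop = FALSE], ytr, seed = seed)
    if (!is.null(Xval)) {
      prob <- learner$predict_prob(model, Xval[, feats, drop = FALSE])
      scores[[s]] <- metric_fun(prob, yval)
    }
    sets[[s]] <- feats
    if (s < length(sizes)) {
      imp <- learner$importance(model, feats)
      keep_n <- sizes[[s + 1L]]
      # ties: earliest column dropped first (stable ascending-importance
      # elimination), so later feature blocks survive zero-gain ties
      ord <- order(-imp, -seq_along(imp))
      feats <- feats[sort(ord[seq_len(keep_n)])]
    }
  }
  list(scores = scores, sets = sets)
}

#' Recursive feature elimination with cross-validation
#'
#' Within each stratified fold (resampling applied to the fold's training
#' part only), features are iteratively dropped by ascending learner
#' importance while the validation metric is recorded at each feature
#' count. The selected size is the smallest count whose mean cross-fold
#' score is within one standard error of the best; a final elimination pass
#' on the full training split names the selected set.
#'
#' @param X training feature matrix; `y` 0/1 labels.
#' @param y 0/1 integer labels.
#' @param learner an [xgb_learner()]-style contract.
#' @param step features dropped per round: an integer, or a fraction in
#'   (0, 1) meaning `ceiling(step * remaining)`.
#' @param folds stratified CV folds (default 5).
#' @param metric `"average_precision"` or `"roc_auc"`.
#' @param resample optional [resample_config()] applied within folds.
#' @param min_features smallest model size the elimination may reach
#'   (default 1). A floor keeps the booster's probability scale fine
#'   enough for high-threshold calibration.
#' @param seed RNG seed.
#' @return list of class `xt_rfecv`: `selected` (feature names), `ranking`
#'   (all features, best first: elimination order of the final pass),
#'   `sizes`, `mean_scores`, `se_scores`, `metric`, `n_selected`.
#' @export
rfecv <- function(X, y, learner = xgb_learner(), step = 1L, folds = 5L,
                  metric = c("average_precision", "roc_auc"),
                  resample = NULL, min_features = 1L, seed = 1L) {
  stopifnot(is.matrix(X), nrow(X) == length(y), folds >= 2L, step > 0,
            min_features >= 1L)
  metric <- match.arg(metric)
  metric_fun <- switch(metric, average_precision = average_precision,
                       roc_auc = roc_auc)
  sizes <- feature_count_schedule(ncol(X), step, min_features)
  fold <- stratified_folds(y, folds, seed)
  score_mat <- matrix(NA_real_, nrow = folds, ncol = length(sizes))
  for (f in seq_len(folds)) {
    tr <- fold != f; va <- fold == f
    if (length(unique(y[va])) < 2L) {
      stop("validation fold ", f, " contains a single class; ",
           "reduce folds or rebalance")
    }
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    if (!is.null(resample)) {
      rs <- apply_resample(Xtr, ytr, resample)
      Xtr <- rs$X; ytr <- rs$y
    }
    pass <- rfe_pass(Xtr, ytr, X[va, , drop = FALSE], y[va],
                     learner, sizes, metric_fun, seed = seed + f)
    score_mat[f, ] <- pass$scores
  }
  mean_scores <- colMeans(score_mat)
  se_scores <- apply(score_mat, 2L, sd) / sqrt(folds)
  best <- which.max(mean_scores)
  ok <- which(mean_scores >= mean_scores[[best]] - se_scores[[best]])
  sel_idx <- ok[which.min(sizes[ok])]
  n_selected <- sizes[[sel_idx]]

  Xfull <- X; yfull <- y
  if (!is.null(resample)) {
    rs <- apply_resample(Xfull, yfull, resample)
    Xfull <- rs$X; yfull <- rs$y
  }
  final <- rfe_pass(Xfull, yfull, NULL, NULL, learner, sizes, metric_fun,
                    seed = seed)
  selected <- final$sets[[sel_idx]]
  # ranking: features ordered by how long they survived the final pass
  ranking <- final$sets[[length(sizes)]]
  for (s in rev(seq_len(length(sizes) - 1L))) {
    ranking <- c(ranking, setdiff(final$sets[[s]], ranking))
  }
  structure(list(selected = selected, ranking = ranking, sizes = sizes,
                 mean_scores = mean_scores, se_scores = se_scores,
                 score_matrix = score_mat, metric = metric,
                 n_selected = n_selected),
            class = "xt_rfecv")
}

#' @export
print.xt_rfecv <- function(x, ...) {
  cat("RFECV (", x$metric, "): selected", x$n_selected, "of",
      max(x$sizes), "features\n")
  invisible(x)
}

# ---- model bundle ----------------------------------------------------------

#' Fit a model bundle on selected features
#'
#' Resamples the training split (per `resample`), fits the learner on the
#' selected features, and stores the normalised importance table (gain
#' fractions summing to 1). The decision threshold starts at 0.5 (Model 1)
#' until [calibrate_threshold()] raises it.
#'
#' @param X training feature matrix; `y` 0/1 labels.
#' @param y 0/1 integer labels.
#' @param features selected feature names (subset of `colnames(X)`).
#' @param learner learner contract.
#' @param resample optional [resample_config()].
#' @param seed RNG seed.
#' @param top_n rows of the importance table to report when printing
#'   (default 13, the compact report size).
#' @return list of class `xt_model`.
#' @export
fit_model <- function(X, y, features = colnames(X), learner = xgb_learner(),
                      resample = NULL, seed = 1L, top_n = 13L) {
  missing <- setdiff(features, colnames(X))
  if (length(missing)) stop("missing feature(s): ",
                            paste(head(missing, 5L), collapse = ", "))
  Xs <- X[, features, drop = FALSE]
  ys <- y
  if (!is.null(resample)) {
    rs <- apply_resample(Xs, ys, resample)
    Xs <- rs$X; ys <- rs$y
  }
  if (length(unique(ys)) < 2L) stop("single-class training data after resampling")
  model <- learner$fit(Xs, ys, seed = seed)
  imp <- learner$importance(model, features)
  imp <- if (sum(imp) > 0) imp / sum(imp) else imp
  imp_tab <- data.frame(feature = names(sort(imp, decreasing = TRUE)),
                        gain_fraction = as.numeric(sort(imp, decreasing = TRUE)),
                        stringsAsFactors = FALSE)
  structure(list(
    learner = learner, model = model,
    raw = xgboost::xgb.save.raw(model),
    features = features, threshold = 0.5,
    importance = imp_tab, top_n = as.integer(top_n),
    metadata = list(seed = as.integer(seed),
                    class_counts = c(pos = sum(y == 1L), neg = sum(y == 0L)),
                    resample = if (is.null(resample)) NULL else unclass(resample),
                    learner_params = learner$params)),
    class = "xt_model")
}

#' @export
print.xt_model <- function(x, ...) {
  cat("xtclass model:", length(x$features), "features, threshold",
      x$threshold, "\n")
  cat("Top", min(x$top_n, nrow(x$importance)), "features by gain fraction:\n")
  print(head(x$importance, x$top_n), row.names = FALSE)
  invisible(x)
}

#' Evaluate a model bundle on a test set
#' @param model `xt_model`.
#' @param X test feature matrix; `y` its 0/1 labels.
#' @param y 0/1 integer labels.
#' @return [metrics_report()] at the bundle's threshold.
#' @export
evaluate_model <- function(model, X, y) {
  stopifnot(nrow(X) > 0L)
  prob <- model$learner$predict_prob(model$model,
                                     X[, model$features, drop = FALSE])
  metrics_report(prob, y, model$threshold)
}

#' Recalibrate the decision threshold
#'
#' `fixed` mode sets the threshold verbatim (the deployment default is
#' 0.98); `precision_floor` mode sweeps the unique predicted probabilities
#' on a validation set and picks the lowest threshold whose precision
#' reaches the floor. The returned bundle carries a Model-1 (0.5) vs
#' Model-2 (new threshold) metric comparison in `$comparison` when
#' validation data are given.
#'
#' @param model `xt_model`.
#' @param X,y optional validation features/labels (required for
#'   `precision_floor` and for the comparison report).
#' @param mode `"fixed"` or `"precision_floor"`.
#' @param value the fixed threshold, or the precision floor.
#' @return `xt_model` with updated `threshold` (and `comparison`).
#' @export
calibrate_threshold <- function(model, X = NULL, y = NULL,
                                mode = c("fixed", "precision_floor"),
                                value = 0.98) {
  mode <- match.arg(mode)
  prob <- NULL
  if (!is.null(X)) {
    prob <- model$learner$predict_prob(model$model,
                                       X[, model$features, drop = FALSE])
  }
  if (mode == "fixed") {
    stopifnot(value > 0, value <= 1)
    new_thr <- value
  } else {
    if (is.null(prob)) stop("precision_floor mode needs validation data")
    if (length(unique(y)) < 2L) stop("validation data needs both classes")
    cand <- sort(unique(prob))
    prec <- vapply(cand, function(t) {
      sel <- prob >= t
      if (!any(sel)) return(NA_real_)
      sum(y[sel] == 1L) / sum(sel)
    }, numeric(1))
    ok <- which(!is.na(prec) & prec >= value)
    if (!length(ok)) {
      stop("precision floor ", value, " unattainable; best achievable is ",
           format(max(prec, na.rm = TRUE), digits = 4))
    }
    new_thr <- cand[[min(ok)]]
  }
  model$threshold <- new_thr
  if (!is.null(prob) && !is.null(y)) {
    model$comparison <- list(model1 = metrics_report(prob, y, 0.5),
                             model2 = metrics_report(prob, y, new_thr))
  }
  model
}

#' Predict xylose-transport capacity for candidate sequences
#'
#' @param object `xt_model`.
#' @param X candidate feature matrix containing all selected features.
#' @param ... unused.
#' @return data frame with `id`, `probability`, `class` (1 when
#'   `probability >= threshold`) and `near_miss` (`TRUE` when the
#'   probability falls within 0.05 below the threshold).
#' @export
predict.xt_model <- function(object, X, ...) {
  missing <- setdiff(object$features, colnames(X))
  if (length(missing)) {
    stop("candidate matrix lacks feature(s): ",
         paste(head(missing, 5L), collapse = ", "))
  }
  prob <- object$learner$predict_prob(object$model,
                                      X[, object$features, drop = FALSE])
  data.frame(id = rownames(X),
             probability = prob,
             class = as.integer(prob >= object$threshold),
             near_miss = prob >= object$threshold - 0.05 &
               prob < object$threshold,
             stringsAsFactors = FALSE)
}

# ---- serialization ---------------------------------------------------------

#' Write a model bundle to versioned JSON
#' @param model `xt_model`; `path` output file.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  obj <- list(format = "xtclass-model", version = 1L,
              booster_raw = jsonlite::base64_enc(as.raw(model$raw)),
              features = model$features,
              threshold = model$threshold,
              importance = model$importance,
              top_n = model$top_n,
              learner_params = model$learner$params,
              metadata = model$metadata)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a model bundle written by [write_model()]
#' @param path JSON file.
#' @return `xt_model` whose predictions are bitwise identical to the saved
#'   bundle's.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "xtclass-model") || obj$version != 1L) {
    stop("not a version-1 xtclass model file")
  }
  if (is.null(obj$threshold)) stop("model file is missing the threshold")
  raw <- jsonlite::base64_dec(obj$booster_raw)
  booster <- xgboost::xgb.load.raw(raw)
  params <- obj$learner_params
  learner <- xgb_learner(nrounds = params$nrounds,
                         max_depth = params$max_depth, eta = params$eta,
                         colsample_bytree = params$colsample_bytree)
  structure(list(learner = learner, model = booster, raw = raw,
                 features = obj$features, threshold = obj$threshold,
                 importance = obj$importance, top_n = obj$top_n,
                 metadata = obj$metadata),
            class = "xt_model")
}
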