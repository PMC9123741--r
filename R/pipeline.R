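#' @name pipeline
#' @title End-to-end reproducible runs
#'
#' @description
#' Orchestrates the full workflow in the standard order — redundancy
#' clustering, feature extraction, stratified 70/30 split, RFECV feature
#' selection, model fitting with resampling, threshold recalibration,
#' evaluation and prediction — writing every artefact (model, metrics,
#' predictions, manifest, log) into a run directory. A rerun with the same
#' configuration and seed reproduces the predictions file bitwise.
NULL

#' Pipeline run configuration
#'
#' Every default is recorded in the run manifest so that unstated choices
#' remain visible in outputs. In-memory objects may be passed instead of
#' paths via [run_pipeline()]'s `data` argument.
#'
#' @param fasta,labels,msa,regions input file paths (optional when `data`
#'   objects are passed to [run_pipeline()]).
#' @param out_dir run directory.
#' @param descriptor [descriptor_config()].
#' @param resample [resample_config()].
#' @param split [split_config()].
#' @param learner [xgb_learner()].
#' @param cluster run the redundancy-removal stage (default `TRUE`).
#' @param cluster_threshold identity threshold for clustering.
#' @param rfecv_step,rfecv_folds RFECV elimination step and fold count.
#' @param rfecv_min_features smallest model size the elimination may reach
#'   (default 13, the compact model size this method reports; also keeps
#'   the booster's probability scale fine-grained near the 0.98 cut).
#' @param threshold_mode `"fixed"` or `"precision_floor"`.
#' @param threshold_value fixed threshold (default 0.98) or precision floor.
#' @param patterns optional named list of PROSITE pattern strings.
#' @param seed global seed propagated to every stochastic stage.
#' @return list of class `xt_run_config`.
#' @export
run_config <- function(fasta = NULL, labels = NULL, msa = NULL,
                       regions = NULL, out_dir = tempfile("xtclass_run_"),
                       descriptor = descriptor_config(),
                       resample = resample_config("smote_enn"),
                       split = split_config(),
                       learner = xgb_learner(),
                       cluster = TRUE, cluster_threshold = 0.8,
                       rfecv_step = 0.5, rfecv_folds = 5L,
                       rfecv_min_features = 13L,
                       threshold_mode = "fixed", threshold_value = 0.98,
                       patterns = NULL, seed = 1L) {
  structure(list(fasta = fasta, labels = labels, msa = msa,
                 regions = regions, out_dir = out_dir,
                 descriptor = descriptor, resample = resample,
                 split = split, learner = learner,
                 cluster = cluster, cluster_threshold = cluster_threshold,
                 rfecv_step = rfecv_step, rfecv_folds = as.integer(rfecv_folds),
                 rfecv_min_features = as.integer(rfecv_min_features),
                 threshold_mode = threshold_mode,
                 threshold_value = threshold_value,
                 patterns = patterns, seed = as.integer(seed)),
            class = "xt_run_config")
}

config_manifest <- function(config) {
  cfg <- unclass(config)
  cfg$learner <- config$learner$params
  cfg$descriptor <- unclass(config$descriptor)
  cfg$resample <- unclass(config$resample)
  cfg$split <- unclass(config$split)
  cfg
}

#' Run the full pipeline
#'
#' Stages in order: load/validate inputs, redundancy clustering (known
#' positives protected), feature extraction, stratified split, RFECV,
#' final fit with resampling, threshold recalibration, evaluation at both
#' the default and recalibrated thresholds, prediction on the held-out
#' test set. Artefacts written to the run directory: `model.json`,
#' `metrics.json`, `predictions.tsv`, `manifest.json`, `log.txt`.
#'
#' @param config [run_config()].
#' @param data optional in-memory inputs: a list with `dataset`
#'   (`xt_dataset`), `msa`, `regions` (e.g. an `xt_synth` object), used
#'   instead of the configured file paths.
#' @return list of class `xt_run`: `model`, `rfecv`, `metrics` (model1 +
#'   model2), `predictions`, `manifest`, `dir`.
#' @export
run_pipeline <- function(config, data = NULL) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "log.txt")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  manifest <- list(config = config_manifest(config),
                   config_hash = config_hash(config_manifest(config)),
                   stages = list())
  t_all <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    writeLines(paste0("[", name, "] start"), log_con)
    res <- tryCatch(expr, error = function(e) {
      writeLines(paste0("[", name, "] ERROR: ", conditionMessage(e)), log_con)
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(config$out_dir,
                                               "manifest.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    el <- proc.time()[["elapsed"]] - t0
    manifest$stages[[name]] <<- list(status = "ok",
                                     seconds = round(el, 3))
    writeLines(sprintf("[%s] done (%.2fs)", name, el), log_con)
    res
  }

  inputs <- stage("load", {
    if (!is.null(data)) {
      list(dataset = data$dataset, msa = data$msa, regions = data$regions)
    } else {
      for (p in c(config$fasta, config$labels, config$msa, config$regions)) {
        if (!file.exists(p)) stop("input file not found: ", p)
      }
      recs <- read_fasta(config$fasta)
      list(dataset = load_labels(config$labels, recs),
           msa = read_fasta(config$msa, gapped = TRUE),
           regions = read_regions(config$regions))
    }
  })
  if (is.null(inputs$msa$reference_id)) {
    inputs$msa$reference_id <- inputs$regions$reference_id
  }
  dataset <- inputs$dataset
  manifest$n_input <- nrow(dataset$records)

  if (isTRUE(config$cluster)) {
    dataset <- stage("cluster", {
      protected <- names(dataset$labels)[dataset$labels == 1L]
      cl <- greedy_cluster(dataset, threshold = config$cluster_threshold,
                           protected = protected)
      manifest$n_clustered <- length(cl$kept)
      cluster_filter(dataset, cl)
    })
  } else {
    manifest$n_clustered <- nrow(dataset$records)
  }
  manifest$class_counts <- c(pos = unname(sum(dataset$labels == 1L)),
                             neg = unname(sum(dataset$labels == 0L)))

  features <- stage("extract", {
    extract_all(dataset, config$descriptor, msa = inputs$msa,
                regions = inputs$regions, patterns = config$patterns)
  })
  manifest$n_features <- ncol(features)

  sp <- stage("split", {
    cfg <- config$split
    cfg$seed <- config$seed
    split_dataset(features, dataset$labels[rownames(features)], cfg)
  })

  rcfg <- config$resample
  rcfg$seed <- config$seed
  sel <- stage("select", {
    rfecv(sp$train$X, sp$train$y, learner = config$learner,
          step = config$rfecv_step, folds = config$rfecv_folds,
          metric = "average_precision", resample = rcfg,
          min_features = config$rfecv_min_features,
          seed = config$seed)
  })
  manifest$n_selected <- sel$n_selected
  manifest$selected_features <- sel$selected

  model <- stage("fit", {
    fit_model(sp$train$X, sp$train$y, features = sel$selected,
              learner = config$learner, resample = rcfg,
              seed = config$seed)
  })

  model <- stage("calibrate", {
    calibrate_threshold(model, sp$test$X, sp$test$y,
                        mode = config$threshold_mode,
                        value = config$threshold_value)
  })

  metrics <- stage("evaluate", {
    prob <- model$learner$predict_prob(model$model,
                                       sp$test$X[, model$features,
                                                 drop = FALSE])
    list(model1 = metrics_report(prob, sp$test$y, 0.5),
         model2 = metrics_report(prob, sp$test$y, model$threshold))
  })

  predictions <- stage("predict", {
    stats::predict(model, sp$test$X)
  })

  stage("write", {
    write_model(model, file.path(config$out_dir, "model.json"))
    utils::write.table(predictions,
                       file.path(config$out_dir, "predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    strip_curves <- function(m) {
      m$roc <- NULL; m$pr <- NULL; unclass(m)
    }
    jsonlite::write_json(list(model1 = strip_curves(metrics$model1),
                              model2 = strip_curves(metrics$model2)),
                         file.path(config$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    invisible(NULL)
  })

  manifest$seconds_total <- round(proc.time()[["elapsed"]] - t_all, 3)
  manifest$seed <- config$seed
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  structure(list(model = model, rfecv = sel, metrics = metrics,
                 predictions = predictions, manifest = manifest,
                 features = features, split = sp, dir = config$out_dir),
            class = "xt_run")
}

#' @export
print.xt_run <- function(x, ...) {
  cat("xtclass run:", x$manifest$n_input, "sequences ->",
      x$manifest$n_clustered, "after clustering;",
      x$manifest$n_features, "features;",
      x$manifest$n_selected, "selected\n")
  cat("held-out metrics (recalibrated threshold):\n")
  print(x$metrics$model2)
  invisible(x)
}

#' Screen candidate sequences against a trained model
#'
#' Extracts features for the candidates exactly as for training (same
#' descriptor configuration, same profile inputs) and predicts each
#' candidate's probability of being a xylose transporter, sorted descending.
#'
#' @param model `xt_model` or path to a `model.json`.
#' @param candidates `xt_sequences` or path to a candidate FASTA.
#' @param msa,regions the known-positives alignment and region annotation
#'   used at training time.
#' @param descriptor the training [descriptor_config()].
#' @param patterns the training PROSITE patterns (if any).
#' @return data frame with `id`, `probability`, `class`, `near_miss`,
#'   sorted by descending probability; empty input gives an empty table
#'   with a warning.
#' @export
screen_candidates <- function(model, candidates, msa, regions,
                              descriptor = descriptor_config(),
                              patterns = NULL) {
  if (is.character(model)) model <- read_model(model)
  if (is.character(candidates)) candidates <- read_fasta(candidates)
  if (nrow(candidates) == 0L) {
    warning("no candidate sequences supplied")
    return(data.frame(id = character(0), probability = numeric(0),
                      class = integer(0), near_miss = logical(0)))
  }
  feats <- extract_all(candidates, descriptor, msa = msa, regions = regions,
                       patterns = patterns)
  missing <- setdiff(model$features, colnames(feats))
  if (length(missing)) {
    stop("feature-schema mismatch: extraction lacks ",
         paste(head(missing, 5L), collapse = ", "))
  }
  out <- stats::predict(model, feats)
  out[order(-out$probability, out$id), , drop = FALSE]
}
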