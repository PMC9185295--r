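#' Full pipeline configuration
#'
#' Bundles the flow solver, stacking, PCANet+ layer, SVM and evaluation
#' settings. Layer-1 filter depth is determined at training time by the
#' stacking window (`2T` channels).
#'
#' @param flow a [flow_config()].
#' @param T stacking window length (default 5).
#' @param s stacking step; `NULL` for the default `(T-1)/2`.
#' @param layers list of [layer_config()]s (two by default).
#' @param svm_C linear-SVM regularization constant.
#' @param standardize standardize features from train-fold statistics.
#' @param aggregate clip-level aggregation of per-tensor features,
#'   `"mean"` or `"sum"`.
#' @param target_size clip resize target `c(height, width)`.
#' @param cache_dir directory for the per-clip `.flo` flow cache, or `NULL`
#'   to disable caching.
#' @param seed integer seed recorded with results (the pipeline itself is
#'   deterministic).
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(flow = flow_config(), T = 5L, s = NULL,
                            layers = list(layer_config(7L, 32L),
                                          layer_config(9L, 16L)),
                            svm_C = 1, standardize = TRUE,
                            aggregate = c("mean", "sum"),
                            target_size = c(170L, 139L), cache_dir = NULL,
                            seed = 1L) {
  aggregate <- match.arg(aggregate)
  structure(list(flow = flow, T = as.integer(T),
                 s = if (is.null(s)) NULL else as.integer(s),
                 layers = layers, svm_C = svm_C, standardize = standardize,
                 aggregate = aggregate,
                 target_size = as.integer(target_size),
                 cache_dir = cache_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Shipped pipeline presets
#'
#' `"smic-best"` and `"casme2-best"` are the best-performing network
#' geometries for the two reference corpora (T = 5; 170 x 139 inputs;
#' layer filters (7x7x10)x32 / (9x9x32)x16 and (7x7x10)x16 / (7x7x16)x32
#' respectively, stride-1 3x3 mean pooling). `"synthetic-small"` is a
#' reduced geometry for the bundled synthetic data (64 x 64 frames, T = 3,
#' two layers of eight 5x5 filters).
#'
#' @param name preset name.
#' @return a [pipeline_config()].
#' @export
preset_config <- function(name = c("smic-best", "casme2-best",
                                   "synthetic-small")) {
  name <- match.arg(name)
  switch(name,
    "smic-best" = pipeline_config(
      T = 5L, layers = list(layer_config(7L, 32L), layer_config(9L, 16L))),
    "casme2-best" = pipeline_config(
      T = 5L, layers = list(layer_config(7L, 16L), layer_config(7L, 32L))),
    "synthetic-small" = pipeline_config(
      T = 3L, layers = list(layer_config(5L, 8L), layer_config(5L, 8L)),
      target_size = c(64L, 64L)))
}

#' Write / read a pipeline configuration as YAML
#'
#' The YAML round-trip is faithful: `read_pipeline_config(
#' write_pipeline_config(cfg, path))` reconstructs an identical
#' configuration.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns the `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  fl <- config$flow
  out <- list(
    flow = list(alpha = fl$alpha, beta = fl$beta,
                basis_size = fl$basis_size,
                pyramid_levels = fl$pyramid_levels,
                iterations_per_level = fl$iterations_per_level,
                outer_iterations = fl$outer_iterations,
                backend = fl$backend, eps_data = fl$eps_data,
                eps_tv = fl$eps_tv),
    stacking = list(T = config$T, s = config$s),
    layers = lapply(config$layers, function(cf)
      list(k = cf$k, D = cf$D, pool_size = cf$pool_size,
           pool_stride = cf$pool_stride, pad = cf$pad,
           F_lambda = cf$F_lambda, blocks = as.list(cf$blocks))),
    svm = list(C = config$svm_C, standardize = config$standardize),
    eval = list(aggregate = config$aggregate, seed = config$seed),
    io = list(target_size = as.list(config$target_size),
              cache_dir = config$cache_dir))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  fl <- y$flow %||% list()
  flow <- flow_config(
    alpha = fl$alpha %||% 10, beta = fl$beta %||% 1,
    basis_size = fl$basis_size,
    pyramid_levels = fl$pyramid_levels %||% 3L,
    iterations_per_level = fl$iterations_per_level %||% 50L,
    outer_iterations = fl$outer_iterations %||% 5L,
    backend = fl$backend %||% "trajectory",
    eps_data = fl$eps_data %||% 1e-3, eps_tv = fl$eps_tv %||% 1e-3)
  layers <- lapply(y$layers, function(cf)
    layer_config(k = cf$k, D = cf$D, pool_size = cf$pool_size %||% 3L,
                 pool_stride = cf$pool_stride %||% 1L,
                 pad = cf$pad %||% ((cf$k - 1L) %/% 2L),
                 F_lambda = cf$F_lambda %||% 8L,
                 blocks = unlist(cf$blocks %||% c(2L, 2L))))
  pipeline_config(flow = flow, T = y$stacking$T %||% 5L, s = y$stacking$s,
                  layers = layers, svm_C = y$svm$C %||% 1,
                  standardize = y$svm$standardize %||% TRUE,
                  aggregate = y$eval$aggregate %||% "mean",
                  target_size = unlist(y$io$target_size %||% c(170L, 139L)),
                  cache_dir = y$io$cache_dir, seed = y$eval$seed %||% 1L)
}

# Flow for one clip, via the .flo cache when a cache dir is configured.
clip_flow_cached <- function(clip, config) {
  cache <- config$cache_dir
  Lf <- dim(clip$frames)[3] - 1L
  if (!is.null(cache)) {
    dir.create(cache, recursive = TRUE, showWarnings = FALSE)
    files <- file.path(cache, sprintf("%s_%d.flo", clip$clip_id,
                                      seq_len(Lf)))
    if (all(file.exists(files))) {
      first <- read_flo(files[1])
      if (all(dim(first$u) == dim(clip$frames)[1:2])) {
        U <- array(0, dim = c(dim(first$u), Lf))
        V <- array(0, dim = c(dim(first$u), Lf))
        U[, , 1] <- first$u; V[, , 1] <- first$v
        for (t in seq_len(Lf)[-1]) {
          fl <- read_flo(files[t])
          U[, , t] <- fl$u; V[, , t] <- fl$v
        }
        return(structure(list(U = U, V = V, reference_index = 0L,
                              clip_id = clip$clip_id),
                         class = "flow_sequence"))
      }
    }
  }
  flow <- estimate_flow_sequence(clip, config$flow)
  if (!is.null(cache)) {
    for (t in seq_len(Lf)) {
      write_flo(list(u = flow$U[, , t], v = flow$V[, , t]),
                file.path(cache, sprintf("%s_%d.flo", clip$clip_id, t)))
    }
  }
  flow
}

#' Run the full recognition pipeline under LOSO evaluation
#'
#' Loads every clip of the manifest, estimates (or loads from cache) its
#' flow sequence, stacks it into multi-channel tensors, and then runs
#' leave-one-subject-out evaluation: for each fold a PCANet+ filter bank is
#' trained on the training subjects' tensors only, clip-level features are
#' aggregated from the per-tensor encodings, and a linear SVM predicts the
#' held-out subject's clips. Per-fold predictions are pooled into one
#' confusion matrix from which the metrics are computed.
#'
#' @param config a [pipeline_config()].
#' @param manifest path to a manifest CSV or a `dataset_index`.
#' @param verbose log per-stage progress to stderr.
#' @return a results list with `folds` (per-fold subjects, truth and
#'   predictions), `confusion`, `metrics`, `class_names` and `config`.
#' @export
run_pipeline <- function(config, manifest, verbose = FALSE) {
  index <- if (inherits(manifest, "dataset_index")) manifest
           else read_manifest(manifest)
  entries <- index$entries
  say <- function(...) if (verbose) message(sprintf(...))

  say("loading %d clips", nrow(entries))
  clips <- list()
  for (i in seq_len(nrow(entries))) {
    e <- entries[i, ]
    clips[[e$clip_id]] <- tryCatch(
      load_clip(e$path, target_size = config$target_size,
                clip_id = e$clip_id, subject_id = e$subject,
                label = e$label),
      error = function(err) stop("stage clip_io, clip '", e$clip_id, "': ",
                                 conditionMessage(err), call. = FALSE))
  }

  say("estimating flow (%s backend)", config$flow$backend)
  feats_per_clip <- list()
  tensors_per_clip <- list()
  for (id in names(clips)) {
    flow <- tryCatch(clip_flow_cached(clips[[id]], config),
                     error = function(err)
                       stop("stage optical_flow, clip '", id, "': ",
                            conditionMessage(err), call. = FALSE))
    stacked <- tryCatch(stack_flow_sequence(flow, config$T, config$s),
                        error = function(err)
                          stop("stage stacking, clip '", id, "': ",
                               conditionMessage(err), call. = FALSE))
    tensors_per_clip[[id]] <- stacked$tensors
  }

  folds <- loso_split(index)
  say("evaluating %d LOSO folds", length(folds))
  labels <- stats::setNames(as.character(entries$label), entries$clip_id)
  fold_results <- list()
  all_truth <- character(0); all_pred <- character(0)
  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    train_tensors <- unlist(tensors_per_clip[fold$train], recursive = FALSE)
    bank <- tryCatch(
      train_filter_bank(train_tensors, config$layers,
                        fold_id = fold$subject),
      error = function(err) stop("stage pcanet_plus, fold '", fold$subject,
                                 "': ", conditionMessage(err), call. = FALSE))
    feat_of <- function(id) aggregate_clip_feature(
      lapply(tensors_per_clip[[id]], forward_features, bank = bank),
      mode = config$aggregate)
    train_x <- do.call(rbind, lapply(fold$train, feat_of))
    test_x <- do.call(rbind, lapply(fold$test, feat_of))
    pred <- tryCatch(
      fit_predict_linear_svm(train_x, labels[fold$train], test_x,
                             C = config$svm_C,
                             standardize = config$standardize),
      error = function(err) stop("stage classify_eval, fold '",
                                 fold$subject, "': ", conditionMessage(err),
                                 call. = FALSE))
    fold_results[[fi]] <- list(subject = fold$subject,
                               clip_id = fold$test,
                               truth = unname(labels[fold$test]),
                               predicted = pred)
    all_truth <- c(all_truth, labels[fold$test])
    all_pred <- c(all_pred, pred)
    say("  fold %d/%d (%s): %d/%d correct", fi, length(folds),
        fold$subject, sum(pred == labels[fold$test]), length(pred))
  }
  cm <- confusion_matrix(all_truth, all_pred, index$class_names)
  list(folds = fold_results, confusion = cm,
       metrics = compute_metrics(cm), class_names = index$class_names,
       config = config)
}

#' Write pipeline results as JSON
#'
#' @param results the list returned by [run_pipeline()].
#' @param path output JSON file.
#' @export
write_results_json <- function(results, path) {
  out <- list(
    class_names = results$class_names,
    folds = lapply(results$folds, function(f)
      f[c("subject", "clip_id", "truth", "predicted")]),
    confusion = unclass(results$confusion),
    metrics = results$metrics[c("accuracy", "macro_f1", "macro_recall",
                                "macro_precision")])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Sweep the stacking window length
#'
#' Reruns the pipeline for each window length `T` (sharing the flow cache,
#' which does not depend on `T`) and collects the pooled metrics, one row
#' per configuration.
#'
#' @param config base [pipeline_config()].
#' @param manifest manifest path or `dataset_index`.
#' @param T_values integer vector of window lengths.
#' @param verbose log progress.
#' @return data frame with columns `T`, `accuracy`, `macro_f1`,
#'   `macro_recall`.
#' @export
sweep_stacking <- function(config, manifest, T_values = c(1L, 3L, 5L, 7L),
                           verbose = FALSE) {
  if (is.null(config$cache_dir))
    config$cache_dir <- file.path(tempfile("flowcache"), "flo")
  rows <- lapply(T_values, function(T) {
    cfg <- config
    cfg$T <- as.integer(T)
    cfg$s <- NULL
    res <- run_pipeline(cfg, manifest, verbose = verbose)
    data.frame(T = T, accuracy = res$metrics$accuracy,
               macro_f1 = res$metrics$macro_f1,
               macro_recall = res$metrics$macro_recall)
  })
  do.call(rbind, rows)
}

#' Sweep filter geometry
#'
#' Reruns the pipeline for each row of a `[k1, D1, k2, D2]` grid.
#'
#' @param config base [pipeline_config()].
#' @param manifest manifest path or `dataset_index`.
#' @param grid data frame with columns `k1`, `D1`, `k2`, `D2`.
#' @param verbose log progress.
#' @return `grid` with appended metric columns.
#' @export
sweep_filters <- function(config, manifest, grid, verbose = FALSE) {
  if (is.null(config$cache_dir))
    config$cache_dir <- file.path(tempfile("flowcache"), "flo")
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    cfg <- config
    cfg$layers <- list(layer_config(g$k1, g$D1), layer_config(g$k2, g$D2))
    res <- run_pipeline(cfg, manifest, verbose = verbose)
    cbind(g, data.frame(accuracy = res$metrics$accuracy,
                        macro_f1 = res$metrics$macro_f1,
                        macro_recall = res$metrics$macro_recall))
  })
  do.call(rbind, rows)
}
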