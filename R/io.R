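# Dataset folder reader, run configuration, experiment orchestration --------

#' Load a class-folder image dataset
#'
#' Expects `root/<class>/...` with exactly two class folders; a folder whose
#' name contains "fracture" but not "non" is the positive class (label 1).
#' Every decodable PNG/JPEG/PNM image is read, resized to the target size
#' and replicated to 3 channels; undecodable files are skipped with a
#' logged warning (mirroring the upstream exclusion of unreadable files).
#'
#' @param root Dataset root directory.
#' @param size Target image size (height = width).
#' @return List with `images` (list of arrays), `labels` (1 = fracture),
#'   `files`, `classes`.
#' @export
load_dataset <- function(root, size = 128L) {
  if (!dir.exists(root)) stop("dataset root does not exist: ", root)
  class_dirs <- list.dirs(root, recursive = FALSE)
  if (length(class_dirs) == 0L) stop("no class folders under ", root)
  cls <- basename(class_dirs)
  positive <- grepl("fracture", cls, ignore.case = TRUE) &
    !grepl("non", cls, ignore.case = TRUE)
  if (sum(positive) != 1L && length(class_dirs) == 2L) {
    positive <- c(TRUE, FALSE)   # fall back: first folder is positive
  }
  images <- list(); labels <- integer(0); files <- character(0)
  for (i in seq_along(class_dirs)) {
    fs <- list.files(class_dirs[i],
                     pattern = "\\.(png|jpe?g|ppm|pgm)$",
                     ignore.case = TRUE, full.names = TRUE)
    if (length(fs) == 0L) {
      stop("class folder '", cls[i], "' contains no images")
    }
    for (f in fs) {
      img <- tryCatch(read_image(f), error = function(e) NULL)
      if (is.null(img)) {
        warning("skipping undecodable image: ", f)
        next
      }
      if (!all(dim(img)[1:2] == size)) img <- resize_image(img, size)
      images[[length(images) + 1L]] <- img
      labels <- c(labels, as.integer(positive[i]))
      files <- c(files, f)
    }
  }
  list(images = images, labels = labels, files = files, classes = cls)
}

RUN_CONFIG_KEYS <- c("data", "out", "method", "wavelet", "ranges", "backbone",
                     "dense_units", "dropout", "subbands", "learning_rate",
                     "batch_size", "max_epochs", "patience", "fractions",
                     "seed", "threshold", "log_level")

#' Experiment run configuration
#'
#' One field per ablation axis: decomposition method, wavelet family,
#' backbone, subband subset, plus training and split settings.  Round-trips
#' losslessly through YAML; unknown keys are rejected.
#'
#' @param data,out Dataset root and run output directory.
#' @param method,wavelet,ranges Decomposition settings.
#' @param backbone,dense_units,dropout Branch settings.
#' @param subbands Subband subset.
#' @param learning_rate,batch_size,max_epochs,patience,seed Training
#'   settings.
#' @param fractions Hold-out split fractions.
#' @param threshold Decision threshold.
#' @param log_level "info" or "quiet".
#' @return List of class `run_config`.
#' @export
run_config <- function(data = NULL, out = NULL, method = "dwt2",
                       wavelet = "haar",
                       ranges = default_eigentriple_ranges(),
                       backbone = "tiny", dense_units = c(256L, 128L),
                       dropout = c(0.3, 0.3), subbands = SUBBAND_NAMES,
                       learning_rate = 0.001, batch_size = 32L,
                       max_epochs = 50L, patience = 5L,
                       fractions = c(train = 0.72, validation = 0.08,
                                     test = 0.20),
                       seed = 0L, threshold = 0.5, log_level = "info") {
  cfg <- structure(list(data = data, out = out, method = method,
                        wavelet = wavelet, ranges = ranges,
                        backbone = backbone,
                        dense_units = as.integer(dense_units),
                        dropout = dropout, subbands = subbands,
                        learning_rate = learning_rate,
                        batch_size = as.integer(batch_size),
                        max_epochs = as.integer(max_epochs),
                        patience = as.integer(patience),
                        fractions = fractions, seed = as.integer(seed),
                        threshold = threshold, log_level = log_level),
                   class = "run_config")
  # constructor-level validation via the module constructors
  branch_config(backbone, TRUE, cfg$dense_units, cfg$dropout)
  train_config(learning_rate, batch_size, max_epochs, patience, seed,
               subbands)
  split_spec(fractions, seed)
  match.arg(method, c("dwt2", "swt2", "svd"))
  wavelet_spec(wavelet)
  cfg
}

#' Save / load a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `load_config` returns the validated `run_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$ranges <- lapply(x$ranges, as.integer)
  x$fractions <- as.list(x$fractions)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  x <- yaml::read_yaml(path)
  unknown <- setdiff(names(x), RUN_CONFIG_KEYS)
  if (length(unknown) > 0L) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  x$fractions <- unlist(x$fractions)
  do.call(run_config, x)
}

run_log <- function(config, logfile, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                 sprintf(...))
  if (!identical(config$log_level, "quiet")) message(msg)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE)
  invisible(NULL)
}

#' Run a full experiment from a configuration
#'
#' resize -> decompose -> train -> evaluate, writing all artefacts
#' (config copy, per-epoch history, metrics JSON, ROC/PR curve CSVs,
#' trained weights, log) into the run directory.  Identical configuration
#' and seed give identical metrics.  If the run directory already contains
#' a `metrics.json` and `resume = TRUE`, the run is a no-op.
#'
#' @param config A [run_config()] with `data` and `out` set.
#' @param resume Skip work if the run is already complete.
#' @return Invisibly, a list with `model`, `history`, `metrics`, `split`.
#' @export
run_experiment <- function(config, resume = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$data) || is.null(config$out)) {
    stop("config$data and config$out are required")
  }
  metrics_path <- file.path(config$out, "metrics.json")
  if (resume && file.exists(metrics_path)) {
    return(invisible(list(metrics = jsonlite::read_json(metrics_path))))
  }
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(config$out, "run.log")
  cat("", file = logfile)
  save_config(config, file.path(config$out, "config.yaml"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[stage: ", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  run_log(config, logfile, "loading dataset from %s", config$data)
  ds <- stage("load", load_dataset(config$data))
  run_log(config, logfile, "%d images (%d fracture)", length(ds$images),
          sum(ds$labels))

  sp <- split_spec(config$fractions, config$seed)
  split <- stage("split", stratified_split(ds$labels, sp))
  pick <- function(idx) list(images = ds$images[idx],
                             labels = ds$labels[idx])

  run_log(config, logfile, "building %s/%s model, subbands %s",
          config$method, config$wavelet,
          paste(config$subbands, collapse = ","))
  model <- stage("build", build_model(
    branch_config(config$backbone, TRUE, config$dense_units, config$dropout),
    subbands = config$subbands, method = config$method,
    spec = wavelet_spec(config$wavelet), ranges = config$ranges,
    seed = config$seed))
  tc <- train_config(config$learning_rate, config$batch_size,
                     config$max_epochs, config$patience, config$seed,
                     config$subbands)
  run_log(config, logfile, "training (max %d epochs, patience %d)",
          tc$max_epochs, tc$patience)
  fit <- stage("train", train_model(model, pick(split$train),
                                    pick(split$validation), tc))
  utils::write.csv(fit$history, file.path(config$out, "history.csv"),
                   row.names = FALSE)

  run_log(config, logfile, "evaluating on %d test images",
          length(split$test))
  test <- pick(split$test)
  pred <- stage("evaluate", predict_model(fit$model, test$images,
                                          config$threshold))
  metrics <- compute_metrics(test$labels, pred$probabilities,
                             config$threshold)
  curves <- roc_pr_curves(test$labels, pred$probabilities)
  utils::write.csv(curves$roc, file.path(config$out, "roc.csv"),
                   row.names = FALSE)
  utils::write.csv(curves$pr, file.path(config$out, "pr.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = config$seed,
         n_train = length(split$train), n_val = length(split$validation),
         n_test = length(split$test),
         confusion = as.list(metrics$confusion),
         accuracy = metrics$accuracy, precision = metrics$precision,
         recall = metrics$recall, f1 = metrics$f1, kappa = metrics$kappa,
         auroc = metrics$auroc, auprc = metrics$auprc),
    metrics_path, auto_unbox = TRUE, digits = NA)
  save_model(fit$model, config$out)
  run_log(config, logfile, "done: accuracy %.4f", metrics$accuracy)
  invisible(list(model = fit$model, history = fit$history,
                 metrics = metrics, split = split))
}

#' Persist / restore a trained model
#'
#' Weights go into `weights.rds`; a YAML sidecar (`model.yaml`) records the
#' branch configuration, subbands and decomposition settings so prediction
#' is self-describing.
#'
#' @param model A `wavefrac_model`.
#' @param dir Run directory.
#' @return `load_model` returns the model.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(dir, "weights.rds"))
  yaml::write_yaml(
    list(backbone = model$branches[[1]]$config$backbone_id,
         subbands = model$subbands,
         dense_units = model$branches[[1]]$config$dense_units,
         dropout = model$branches[[1]]$config$dropout,
         decomposition = list(method = model$decomposition$method,
                              family = model$decomposition$family),
         input_shape = model$input_shape,
         seed = model$seed, trained = model$trained),
    file.path(dir, "model.yaml"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  path <- file.path(dir, "weights.rds")
  if (!file.exists(path)) stop("no saved model under ", dir)
  readRDS(path)
}
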