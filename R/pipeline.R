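#' Dataset sources for an experiment
#'
#' An experiment reads its windows either from the bundled simulator or
#' from a dataset directory written by [write_dataset()].
#'
#' @param n_fall,n_adl simulated window counts per class.
#' @param sim a [sim_config()].
#' @return a source description for [experiment_config()].
#' @export
simulate_source <- function(n_fall, n_adl, sim = sim_config()) {
  list(type = "simulate", n_fall = as.integer(n_fall),
       n_adl = as.integer(n_adl), sim = sim)
}

#' @rdname simulate_source
#' @param path dataset directory containing `manifest.json`.
#' @export
manifest_source <- function(path) list(type = "manifest", path = path)

#' Assemble a full experiment configuration
#'
#' Describes one end-to-end run: data source, augmentation plan, train/test
#' split, network variant and training recipe. A single top-level `seed`
#' fans out deterministically to the per-stage seeds (simulation,
#' augmentation, split, training), so one integer reproduces the whole run.
#'
#' @param source from [simulate_source()] or [manifest_source()].
#' @param plan an [augment_plan()] (use `augment_plan(0, 0)` for a no-DA arm).
#' @param split_fraction training fraction in (0, 1), default 0.8.
#' @param variant network variant, see [build_stack()].
#' @param train a [train_config()].
#' @param seed optional top-level seed overriding all stage seeds.
#' @param output_dir optional directory for `report.json`, the model
#'   checkpoint and the run log.
#' @return object of class `"experiment_config"`.
#' @export
experiment_config <- function(source, plan = augment_plan(0L, 0L),
                              split_fraction = 0.8,
                              variant = c("CNN-3B3Conv", "CNN-3Conv",
                                          "CNN-1Conv"),
                              train = train_config(), seed = NULL,
                              output_dir = NULL) {
  variant <- match.arg(variant)
  if (!(split_fraction > 0 && split_fraction < 1))
    fallcnn_error("bad_argument", "split_fraction must be in (0, 1)")
  cfg <- list(source = source, plan = plan, split_fraction = split_fraction,
              variant = variant, train = train, seed = seed,
              output_dir = output_dir)
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    # small additive offsets keep every derived seed a valid 32-bit integer
    if (cfg$source$type == "simulate") cfg$source$sim$seed <- seed + 1001L
    cfg$plan$seed <- seed + 2002L
    cfg$split_seed <- seed + 3003L
    cfg$train$seed <- seed + 4004L
  } else {
    cfg$split_seed <- 1L
  }
  structure(cfg, class = "experiment_config")
}

#' Run one experiment end-to-end
#'
#' Executes the stage sequence exactly once: load or simulate windows,
#' augment with random rotations, split 80/20 (or as configured), fit the
#' min-max normalizer on the training split and apply it to both splits,
#' train the network, evaluate on the held-out test split. Every derived
#' count and seed is recorded in the report so the run can be reproduced.
#'
#' @param cfg an [experiment_config()].
#' @return object of class `"experiment_report"`: list with `metrics` (a
#'   [metrics_report()]), `counts` (originals per class, augmented total,
#'   train/test sizes), `seeds`, `history` (training curve), `model` (the
#'   fitted [fall_cnn()]) and `config`.
#' @export
run_experiment <- function(cfg) {
  if (!inherits(cfg, "experiment_config"))
    fallcnn_error("bad_argument", "cfg must come from experiment_config()")
  data <- switch(cfg$source$type,
    simulate = gen_dataset(cfg$source$sim, cfg$source$n_fall, cfg$source$n_adl),
    manifest = read_dataset(cfg$source$path),
    fallcnn_error("bad_argument", sprintf("unknown source type '%s'",
                                          cfg$source$type))
  )
  counts <- list(n_fall_original = unname(data$class_counts[["fall"]]),
                 n_adl_original = unname(data$class_counts[["adl"]]))

  augmented <- augment_dataset(data, cfg$plan)
  counts$n_augmented <- length(augmented$windows)
  counts$n_fall_augmented <- unname(augmented$class_counts[["fall"]])
  counts$n_adl_augmented <- unname(augmented$class_counts[["adl"]])

  parts <- split_dataset(augmented, cfg$split_fraction, cfg$split_seed)
  counts$n_train <- length(parts$train$windows)
  counts$n_test <- length(parts$test$windows)

  normalizer <- fit_min_max(parts$train)
  train_norm <- apply_min_max(parts$train, normalizer)
  test_norm <- apply_min_max(parts$test, normalizer)

  model <- fall_cnn(train_norm, cfg$variant, config = cfg$train,
                    normalizer = normalizer)
  pred <- predict(model, test_norm, normalize = FALSE)
  metrics <- metrics_report(dataset_labels(parts$test), pred$label)

  seeds <- list(simulation = if (cfg$source$type == "simulate")
                  cfg$source$sim$seed else NA,
                augmentation = cfg$plan$seed,
                split = cfg$split_seed,
                training = cfg$train$seed)

  report <- structure(list(metrics = metrics, counts = counts, seeds = seeds,
                           history = model$history, model = model,
                           config = cfg),
                      class = "experiment_report")
  if (!is.null(cfg$output_dir)) write_report(report, cfg$output_dir)
  report
}

report_json <- function(report) {
  m <- report$metrics
  list(
    variant = report$config$variant,
    metrics = list(accuracy = as.numeric(m$accuracy),
                   precision = as.numeric(m$precision),
                   sensitivity = as.numeric(m$sensitivity),
                   specificity = as.numeric(m$specificity),
                   mcc = as.numeric(m$mcc)),
    confusion = as.list(unclass(m$counts)),
    counts = report$counts,
    seeds = report$seeds,
    history = report$history
  )
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_json(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  save_fall_cnn(report$model, file.path(dir, "model.json"))
  log_lines <- c(
    sprintf("variant: %s", report$config$variant),
    sprintf("seeds: simulation=%s augmentation=%s split=%s training=%s",
            report$seeds$simulation, report$seeds$augmentation,
            report$seeds$split, report$seeds$training),
    sprintf("counts: originals fall=%d adl=%d; augmented=%d; train=%d test=%d",
            report$counts$n_fall_original, report$counts$n_adl_original,
            report$counts$n_augmented, report$counts$n_train,
            report$counts$n_test))
  writeLines(log_lines, file.path(dir, "run.log"))
  invisible(dir)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("Experiment: %s, originals %d fall / %d adl -> %d augmented -> %d train / %d test\n",
              x$config$variant, x$counts$n_fall_original,
              x$counts$n_adl_original, x$counts$n_augmented,
              x$counts$n_train, x$counts$n_test))
  print(x$metrics)
  invisible(x)
}

report_metrics <- function(x) {
  if (inherits(x, "experiment_report")) x <- x$metrics
  if (!inherits(x, "metrics_report"))
    fallcnn_error("bad_argument", "expected an experiment or metrics report")
  x
}

#' Compare two experiment arms side by side
#'
#' Formats the five metrics of two runs (e.g. with and without data
#' augmentation) the way the published result tables present them: rates as
#' percentages with two decimals, MCC with four decimals.
#'
#' @param report_a,report_b `experiment_report` or `metrics_report` objects.
#' @param labels column labels for the two arms.
#' @return data.frame with columns `metric`, one formatted column per arm,
#'   and a numeric `diff` (arm A minus arm B, on the raw scale).
#' @export
compare_arms <- function(report_a, report_b, labels = c("A", "B")) {
  a <- report_metrics(report_a)
  b <- report_metrics(report_b)
  ms <- c("accuracy", "precision", "sensitivity", "specificity", "mcc")
  out <- data.frame(
    metric = ms,
    a = vapply(ms, function(m) fmt_metric(m, a[[m]]), character(1)),
    b = vapply(ms, function(m) fmt_metric(m, b[[m]]), character(1)),
    diff = vapply(ms, function(m) as.numeric(a[[m]]) - as.numeric(b[[m]]),
                  numeric(1)),
    row.names = NULL)
  names(out)[2:3] <- labels
  out
}

#' Save and load fitted models
#'
#' The checkpoint is a single JSON file holding the architecture (variant
#' and input length), training configuration, history, normalizer and full
#' precision weights.
#'
#' @param model a fitted [fall_cnn()].
#' @param path checkpoint file path.
#' @return `path` (save) or the restored `fall_cnn` object (load).
#' @export
save_fall_cnn <- function(model, path) {
  ser <- list(
    variant = model$stack$variant,
    input_length = model$stack$input_length,
    config = unclass(model$config),
    history = model$history,
    normalizer = if (!is.null(model$normalizer)) unclass(model$normalizer),
    weights = lapply(model$weights, function(w) {
      if (is.null(w)) return(NULL)
      list(dim = dim(w$W), W = as.vector(w$W), b = as.vector(w$b))
    })
  )
  # 17 significant digits: lossless round-trip for IEEE doubles
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname save_fall_cnn
#' @export
load_fall_cnn <- function(path) {
  if (!file.exists(path))
    fallcnn_error("missing_file", sprintf("no checkpoint at %s", path))
  ser <- jsonlite::read_json(path, simplifyVector = FALSE)
  stack <- build_stack(ser$variant, ser$input_length)
  weights <- lapply(ser$weights, function(w) {
    if (is.null(w) || length(w) == 0L) return(NULL)
    d <- unlist(w$dim)
    list(W = matrix(unlist(w$W), d[[1L]], d[[2L]]), b = as.numeric(unlist(w$b)))
  })
  normalizer <- if (!is.null(ser$normalizer))
    structure(list(min = as.numeric(unlist(ser$normalizer$min)),
                   max = as.numeric(unlist(ser$normalizer$max)),
                   degenerate = as.logical(unlist(ser$normalizer$degenerate))),
              class = "minmax_normalizer")
  hist <- if (length(ser$history))
    do.call(rbind, lapply(ser$history, function(r) as.data.frame(r)))
  else data.frame(epoch = integer(), loss = numeric(), accuracy = numeric())
  cfgl <- ser$config
  config <- train_config(cfgl$learning_rate, cfgl$momentum, cfgl$decay,
                         cfgl$nesterov, cfgl$epochs, cfgl$batch_size,
                         cfgl$seed)
  structure(list(stack = stack, weights = weights, config = config,
                 history = hist,
                 normalizer = normalizer, call = NULL),
            class = "fall_cnn")
}
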