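#' Construct a single accelerometer window
#'
#' A window is the classifier's unit of input: a fixed-length `L x 3` matrix
#' of acceleration components (x, y, z), carrying a class label and a
#' provenance tag.
#'
#' @param values numeric matrix with 3 columns (acceleration x, y, z) and at
#'   least one row; all values must be finite.
#' @param label one of `"fall"`, `"adl"`, `"unlabeled"`.
#' @param origin free-text provenance (e.g. `"trace12:500"`, `"synthetic"`,
#'   `"augmented:synthetic"`).
#' @return the matrix with class `"accel_window"` and attributes `label`,
#'   `origin`.
#' @export
accel_window <- function(values, label = "unlabeled", origin = "user") {
  values <- as.matrix(values)
  if (ncol(values) != 3L)
    fallcnn_error("bad_window", "window must have exactly 3 columns (x, y, z)")
  if (nrow(values) < 1L)
    fallcnn_error("bad_window", "window must have at least one row")
  if (!all(is.finite(values)))
    fallcnn_error("bad_window", "window contains non-finite values")
  label <- match.arg(label, c("fall", "adl", "unlabeled"))
  dimnames(values) <- NULL
  structure(values, label = label, origin = as.character(origin),
            class = c("accel_window", "matrix", "array"))
}

window_label <- function(w) attr(w, "label") %||% "unlabeled"
window_origin <- function(w) attr(w, "origin") %||% "user"
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bundle labeled windows into a dataset
#'
#' @param windows list of [accel_window()] objects, all of the same length.
#' @return an object of class `"accel_dataset"`: a list with elements
#'   `windows`, `window_length` and `class_counts` (named vector
#'   `c(fall=, adl=)`).
#' @export
accel_dataset <- function(windows) {
  if (length(windows) == 0L)
    fallcnn_error("empty_dataset", "dataset must contain at least one window")
  lens <- vapply(windows, nrow, integer(1))
  if (length(unique(lens)) != 1L)
    fallcnn_error("bad_window", "all windows must share the same length")
  labels <- vapply(windows, window_label, character(1))
  structure(list(
    windows = windows,
    window_length = lens[[1L]],
    class_counts = c(fall = sum(labels == "fall"), adl = sum(labels == "adl"))
  ), class = "accel_dataset")
}

#' @export
print.accel_dataset <- function(x, ...) {
  cat(sprintf("<accel_dataset> %d windows of %d x 3 (%d fall, %d adl)\n",
              length(x$windows), x$window_length,
              x$class_counts[["fall"]], x$class_counts[["adl"]]))
  invisible(x)
}

#' @export
length.accel_dataset <- function(x) length(x$windows)

dataset_labels <- function(dataset)
  vapply(dataset$windows, window_label, character(1))

# Stack a dataset into a B x L x 3 array for the network code.
dataset_array <- function(dataset) {
  B <- length(dataset$windows)
  L <- dataset$window_length
  a <- array(0, dim = c(B, L, 3L))
  for (i in seq_len(B)) a[i, , ] <- dataset$windows[[i]]
  a
}

#' Read a triaxial accelerometer trace from a delimited text file
#'
#' Expects one row per sample with a time/index column and three acceleration
#' columns; an optional integer label column marks fall samples (1) versus
#' activities of daily living (0). Units may be m/s^2 or g; values are used
#' as-is (downstream min-max normalization removes the scale).
#'
#' @param path path to a CSV file with a header row.
#' @param columns named character vector mapping the roles `t`, `x`, `y`, `z`
#'   (and optionally `label`) to column names in the file.
#' @param source_id provenance tag stored on the trace; defaults to the file
#'   path.
#' @return an `accel_trace`: a data.frame with columns `t`, `ax`, `ay`, `az`
#'   and (if present in the file) `label`, ordered as in the file.
#' @export
read_accel_csv <- function(path,
                           columns = c(t = "t", x = "x", y = "y", z = "z",
                                       label = "label"),
                           source_id = path) {
  if (!file.exists(path))
    fallcnn_error("missing_file", sprintf("file does not exist: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L)
    fallcnn_error("empty_trace", sprintf("no samples in %s", path))
  need <- c("t", "x", "y", "z")
  for (role in need) {
    nm <- columns[[role]]
    if (is.null(nm) || !nm %in% names(raw))
      fallcnn_error("missing_column",
                    sprintf("required column '%s' (role %s) not found", nm, role))
  }
  num <- function(role) {
    v <- suppressWarnings(as.numeric(raw[[columns[[role]]]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      fallcnn_error("non_numeric",
                    sprintf("non-numeric value in column '%s' at row %d",
                            columns[[role]], bad[[1L]]))
    v
  }
  trace <- data.frame(t = num("t"), ax = num("x"), ay = num("y"), az = num("z"))
  lab_col <- columns["label"]
  if (!is.na(lab_col) && lab_col %in% names(raw)) {
    lv <- suppressWarnings(as.integer(raw[[lab_col]]))
    if (any(is.na(lv) | !(lv %in% c(0L, 1L))))
      fallcnn_error("non_numeric", "label column must contain only 0 (adl) or 1 (fall)")
    trace$label <- lv
  }
  attr(trace, "source_id") <- source_id
  class(trace) <- c("accel_trace", "data.frame")
  trace
}

#' Write an accelerometer trace to CSV
#'
#' Inverse of [read_accel_csv()] with default column names.
#'
#' @param trace an `accel_trace` (or data.frame with columns `t`, `ax`, `ay`,
#'   `az` and optional `label`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(trace, path) {
  out <- data.frame(t = trace$t, x = trace$ax, y = trace$ay, z = trace$az)
  if (!is.null(trace$label)) out$label <- trace$label
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Segment a trace into fixed-length windows
#'
#' Cuts contiguous slices of `length` samples starting at offsets
#' 0, `stride`, 2*`stride`, ...; a trailing slice shorter than `length` is
#' discarded (never padded). With the default `stride = length` windows do
#' not overlap.
#'
#' @param trace an `accel_trace`.
#' @param length window length L (rows per window); typical choices are 500,
#'   118 or 25 depending on the sensor.
#' @param stride offset between consecutive window starts; defaults to
#'   `length` (non-overlapping).
#' @param label optional fixed label for every window; if `NULL` and the
#'   trace carries a `label` column, a window is labeled `"fall"` when any of
#'   its samples is marked 1, else `"adl"`; otherwise `"unlabeled"`.
#' @return list of [accel_window()]s (possibly empty for a short trace).
#' @export
segment_windows <- function(trace, length, stride = length, label = NULL) {
  L <- as.integer(length); s <- as.integer(stride)
  if (L < 1L || s < 1L)
    fallcnn_error("bad_argument", "length and stride must be positive integers")
  n <- nrow(trace)
  if (n < L) return(list())
  starts <- seq.int(1L, n - L + 1L, by = s)
  src <- attr(trace, "source_id") %||% "trace"
  lapply(starts, function(i) {
    rows <- i:(i + L - 1L)
    lab <- label
    if (is.null(lab)) {
      lab <- if (!is.null(trace$label)) {
        if (any(trace$label[rows] == 1L)) "fall" else "adl"
      } else "unlabeled"
    }
    accel_window(cbind(trace$ax[rows], trace$ay[rows], trace$az[rows]),
                 label = lab, origin = sprintf("%s:%d", src, i - 1L))
  })
}

#' Fit per-channel min-max normalization parameters
#'
#' Scans every sample of every window in the (training) dataset and records
#' the minimum and maximum of each of the three acceleration channels.
#' Fitting on the training split only, then applying to both splits, avoids
#' test-set leakage.
#'
#' @param train an `accel_dataset`.
#' @return an object of class `"minmax_normalizer"` with fields `min`, `max`
#'   (length-3 numeric) and `degenerate` (length-3 logical, `TRUE` where a
#'   channel is constant).
#' @export
fit_min_max <- function(train) {
  if (!inherits(train, "accel_dataset") || length(train$windows) == 0L)
    fallcnn_error("empty_dataset", "cannot fit normalizer on an empty dataset")
  mins <- rep(Inf, 3); maxs <- rep(-Inf, 3)
  for (w in train$windows) {
    mins <- pmin(mins, apply(w, 2L, min))
    maxs <- pmax(maxs, apply(w, 2L, max))
  }
  structure(list(min = mins, max = maxs, degenerate = mins == maxs),
            class = "minmax_normalizer")
}

#' Apply min-max normalization to a dataset
#'
#' Maps each value to `(v - min) / (max - min)` per channel. Values from the
#' fitting set land in `[0, 1]`; values from other sets (e.g. a test split)
#' may fall outside and are deliberately not clipped. A degenerate channel
#' (`min == max`) maps to all zeros.
#'
#' @param dataset an `accel_dataset`.
#' @param params a `"minmax_normalizer"` from [fit_min_max()].
#' @return the normalized `accel_dataset` (labels and origins preserved).
#' @export
apply_min_max <- function(dataset, params) {
  if (!inherits(params, "minmax_normalizer"))
    fallcnn_error("bad_argument", "params must come from fit_min_max()")
  rng <- params$max - params$min
  rng[params$degenerate] <- 1  # degenerate channel: (v - min) = 0 everywhere
  ws <- lapply(dataset$windows, function(w) {
    v <- sweep(sweep(unclass(w), 2L, params$min, "-"), 2L, rng, "/")
    v[, params$degenerate] <- 0
    accel_window(v, label = window_label(w), origin = window_origin(w))
  })
  accel_dataset(ws)
}

#' Invert min-max normalization
#'
#' @param dataset a normalized `accel_dataset`.
#' @param params the `"minmax_normalizer"` used to normalize it.
#' @return the dataset on the original scale.
#' @export
invert_min_max <- function(dataset, params) {
  rng <- params$max - params$min
  ws <- lapply(dataset$windows, function(w) {
    v <- sweep(sweep(unclass(w), 2L, rng, "*"), 2L, params$min, "+")
    accel_window(v, label = window_label(w), origin = window_origin(w))
  })
  accel_dataset(ws)
}

#' Split a dataset into train and test partitions
#'
#' Windows are shuffled with a seeded generator, then partitioned: the first
#' `round(train_fraction * N)` (half-away-from-zero rounding) go to the
#' training set, the remainder to the test set.
#'
#' @param dataset an `accel_dataset`.
#' @param train_fraction proportion in (0, 1); the canonical protocol uses 0.8.
#' @param seed integer seed controlling the shuffle.
#' @return list with elements `train` and `test`, both `accel_dataset`s,
#'   disjoint, whose union is the input.
#' @export
split_dataset <- function(dataset, train_fraction = 0.8, seed = 1L) {
  if (!(train_fraction > 0 && train_fraction < 1))
    fallcnn_error("bad_argument", "train_fraction must be in (0, 1)")
  N <- length(dataset$windows)
  if (N == 0L) fallcnn_error("empty_dataset", "cannot split an empty dataset")
  perm <- with_seed(seed, sample.int(N))
  n_train <- floor(train_fraction * N + 0.5)
  n_train <- max(1L, min(N - 1L, as.integer(n_train)))
  list(train = accel_dataset(dataset$windows[perm[seq_len(n_train)]]),
       test  = accel_dataset(dataset$windows[perm[(n_train + 1L):N]]))
}

#' Write a dataset as per-window CSVs plus a JSON manifest
#'
#' The on-disk layout is a directory holding one `window_NNNNNN.csv` per
#' window (header `x,y,z`) and a `manifest.json` recording `window_length`,
#' `class_counts` and per-window `file`, `label`, `origin`.
#'
#' @param dataset an `accel_dataset`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(dataset$windows)
  files <- sprintf("window_%06d.csv", seq_len(n))
  for (i in seq_len(n)) {
    w <- dataset$windows[[i]]
    utils::write.csv(data.frame(x = w[, 1], y = w[, 2], z = w[, 3]),
                     file.path(dir, files[[i]]), row.names = FALSE)
  }
  manifest <- list(
    window_length = dataset$window_length,
    class_counts = as.list(dataset$class_counts),
    windows = lapply(seq_len(n), function(i) list(
      file = files[[i]],
      label = window_label(dataset$windows[[i]]),
      origin = window_origin(dataset$windows[[i]])
    ))
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing `manifest.json` and the window CSVs.
#' @return an `accel_dataset`.
#' @export
read_dataset <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path))
    fallcnn_error("missing_file", sprintf("no manifest.json in %s", dir))
  manifest <- jsonlite::read_json(path)
  ws <- lapply(manifest$windows, function(rec) {
    m <- as.matrix(utils::read.csv(file.path(dir, rec$file)))
    accel_window(m, label = rec$label, origin = rec$origin)
  })
  accel_dataset(ws)
}
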