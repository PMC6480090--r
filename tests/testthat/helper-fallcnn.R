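# Shared fixtures and independent oracles, all built in code at test time.

make_trace <- function(n, seed = 1) {
  set.seed(seed)
  structure(data.frame(t = seq_len(n), ax = rnorm(n), ay = rnorm(n),
                       az = rnorm(n)),
            source_id = "fixture", class = c("accel_trace", "data.frame"))
}

# dataset of n tiny windows with given labels (length L, constant-free values)
make_dataset <- function(labels, L = 8L, seed = 1) {
  set.seed(seed)
  accel_dataset(lapply(seq_along(labels), function(i) {
    accel_window(matrix(rnorm(L * 3), L, 3), label = labels[[i]],
                 origin = sprintf("fixture:%d", i))
  }))
}

# independent brute-force metric recomputation from a 2x2 table
brute_metrics <- function(tp, fp, tn, fn) {
  den_mcc <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(
    accuracy = (tp + tn) / (tp + fp + tn + fn),
    precision = if (tp + fp == 0) 0 else tp / (tp + fp),
    sensitivity = if (tp + fn == 0) 0 else tp / (tp + fn),
    specificity = if (tn + fp == 0) 0 else tn / (tn + fp),
    mcc = if (den_mcc == 0) 0 else (tp * tn - fp * fn) / den_mcc
  )
}

# direct sliding-dot-product 1D convolution (valid, stride 1): the slow
# reference the vectorized engine is checked against
brute_conv1d <- function(x, W, b, kernel) {
  # x: L x C; W: (kernel*C) x F with rows ordered channel-major, tap within
  L <- nrow(x); C <- ncol(x); F <- ncol(W)
  Lout <- L - kernel + 1L
  out <- matrix(0, Lout, F)
  for (t in seq_len(Lout)) {
    patch <- numeric(kernel * C)
    for (c in seq_len(C))
      for (j in seq_len(kernel))
        patch[(c - 1L) * kernel + j] <- x[t + j - 1L, c]
    out[t, ] <- patch %*% W + b
  }
  out
}

rotate_test_set <- function(dataset, seed) {
  fallcnn:::with_seed(seed, {
    accel_dataset(lapply(dataset$windows,
                         function(w) rotate_window(w, sample_rotation())))
  })
}
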