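## Internal feed-forward engine for the 1D CNNs.
##
## Sequence activations are stored as a (B * len) x channels matrix whose
## rows are ordered time-step-fastest within each sample (row = t + (b-1)*len);
## after the flatten layer activations become a plain B x features matrix.
## Convolutions are evaluated as matrix products on an im2col expansion with
## column order (channel-major, tap within channel), and the weight layout
## matches that order.

seq_matrix <- function(X) {
  # B x L x C array -> (B*L) x C matrix, rows time-fastest within sample
  d <- dim(X)
  matrix(aperm(X, c(2L, 1L, 3L)), nrow = d[[1L]] * d[[2L]], ncol = d[[3L]])
}

im2col_seq <- function(M, B, len, k) {
  ch <- ncol(M)
  Lout <- len - k + 1L
  Xcol <- matrix(0, B * Lout, k * ch)
  for (j in seq_len(k)) {
    idx <- as.vector(outer(j:(j + Lout - 1L), (seq_len(B) - 1L) * len, "+"))
    Xcol[, (seq_len(ch) - 1L) * k + j] <- M[idx, , drop = FALSE]
  }
  Xcol
}

col2im_seq <- function(dXcol, B, len, ch, k) {
  Lout <- len - k + 1L
  dM <- matrix(0, B * len, ch)
  for (j in seq_len(k)) {
    idx <- as.vector(outer(j:(j + Lout - 1L), (seq_len(B) - 1L) * len, "+"))
    dM[idx, ] <- dM[idx, , drop = FALSE] +
      dXcol[, (seq_len(ch) - 1L) * k + j, drop = FALSE]
  }
  dM
}

pool_indices <- function(B, len, pool) {
  Lp <- len %/% pool
  lapply(seq_len(pool), function(s) {
    as.vector(outer(seq.int(s, by = pool, length.out = Lp),
                    (seq_len(B) - 1L) * len, "+"))
  })
}

maxpool_forward <- function(M, B, len, pool) {
  idx <- pool_indices(B, len, pool)
  best <- M[idx[[1L]], , drop = FALSE]
  arg <- matrix(1L, nrow(best), ncol(best))
  for (s in seq_len(pool)[-1L]) {
    cand <- M[idx[[s]], , drop = FALSE]
    upd <- cand > best
    best[upd] <- cand[upd]
    arg[upd] <- s
  }
  list(out = best, arg = arg, idx = idx, len = len)
}

maxpool_backward <- function(dOut, cache, B, ch) {
  dM <- matrix(0, B * cache$len, ch)
  nr <- nrow(dOut)
  for (s in seq_along(cache$idx)) {
    sel <- which(cache$arg == s)
    if (!length(sel)) next
    rows_out <- (sel - 1L) %% nr + 1L
    cols <- (sel - 1L) %/% nr + 1L
    dM[cbind(cache$idx[[s]][rows_out], cols)] <- dOut[sel]
  }
  dM
}

flatten_forward <- function(M, B, len) {
  ch <- ncol(M)
  t(matrix(aperm(array(M, c(len, B, ch)), c(3L, 1L, 2L)), ch * len, B))
}

flatten_backward <- function(dX, B, len, ch) {
  matrix(aperm(array(t(dX), c(ch, len, B)), c(2L, 3L, 1L)), len * B, ch)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

glorot_uniform <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# Draw Glorot-uniform weights for every trainable layer, in layer order,
# from the current RNG stream. Conv weight rows follow the im2col column
# order (channel-major, tap within channel).
init_weights <- function(stack) {
  ch <- 3L
  len <- stack$input_length
  weights <- vector("list", length(stack$layers))
  for (i in seq_along(stack$layers)) {
    ly <- stack$layers[[i]]
    switch(ly$kind,
      conv1d = {
        nin <- ly$kernel * ch
        weights[[i]] <- list(
          W = glorot_uniform(nin, ly$filters, nin, ly$kernel * ly$filters),
          b = numeric(ly$filters))
        len <- len - ly$kernel + 1L
        ch <- ly$filters
      },
      maxpool = { len <- len %/% ly$pool },
      flatten = { ch <- len * ch },
      dense = {
        weights[[i]] <- list(
          W = glorot_uniform(ch, ly$units, ch, ly$units),
          b = numeric(ly$units))
        ch <- ly$units
      },
      NULL
    )
  }
  weights
}

# Forward pass over a B x L x 3 array. training = TRUE applies inverted
# dropout (masks drawn from the current RNG stream) and, with cache = TRUE,
# records everything the backward pass needs.
forward_pass <- function(stack, weights, X, training = FALSE, cache = FALSE) {
  B <- dim(X)[[1L]]
  len <- dim(X)[[2L]]
  M <- seq_matrix(X)
  flat <- FALSE
  caches <- if (cache) vector("list", length(stack$layers))
  for (i in seq_along(stack$layers)) {
    ly <- stack$layers[[i]]
    switch(ly$kind,
      conv1d = {
        Xcol <- im2col_seq(M, B, len, ly$kernel)
        Z <- sweep(Xcol %*% weights[[i]]$W, 2L, weights[[i]]$b, "+")
        if (cache) caches[[i]] <- list(Xcol = Xcol, Z = Z, len_in = len,
                                       ch_in = ncol(M))
        M <- Z * (Z > 0)
        len <- len - ly$kernel + 1L
      },
      maxpool = {
        mp <- maxpool_forward(M, B, len, ly$pool)
        if (cache) caches[[i]] <- mp[c("arg", "idx", "len")]
        M <- mp$out
        len <- len %/% ly$pool
      },
      dropout = {
        if (training) {
          keep <- 1 - ly$p
          mask <- matrix((stats::runif(length(M)) < keep) / keep,
                         nrow(M), ncol(M))
          if (cache) caches[[i]] <- list(mask = mask)
          M <- M * mask
        }
      },
      flatten = {
        if (cache) caches[[i]] <- list(len = len, ch = ncol(M))
        M <- flatten_forward(M, B, len)
        flat <- TRUE
      },
      dense = {
        Z <- sweep(M %*% weights[[i]]$W, 2L, weights[[i]]$b, "+")
        if (cache) caches[[i]] <- list(Xin = M, Z = Z)
        M <- switch(ly$activation,
                    relu = Z * (Z > 0),
                    softmax = softmax_rows(Z),
                    Z)
      }
    )
  }
  list(scores = M, caches = caches, B = B)
}

# Backward pass; dOut is the gradient of the loss w.r.t. the network output
# (post-softmax scores). Returns per-layer gradients including the L2 kernel
# penalty term for convolutions.
backward_pass <- function(stack, weights, fwd, dOut) {
  B <- fwd$B
  grads <- vector("list", length(stack$layers))
  d <- dOut
  for (i in rev(seq_along(stack$layers))) {
    ly <- stack$layers[[i]]
    cc <- fwd$caches[[i]]
    switch(ly$kind,
      dense = {
        dZ <- switch(ly$activation,
          relu = d * (cc$Z > 0),
          softmax = {
            P <- softmax_rows(cc$Z)
            P * (d - rowSums(d * P))
          },
          d)
        grads[[i]] <- list(W = crossprod(cc$Xin, dZ), b = colSums(dZ))
        d <- tcrossprod(dZ, weights[[i]]$W)
      },
      flatten = {
        d <- flatten_backward(d, B, cc$len, cc$ch)
      },
      dropout = {
        if (!is.null(cc)) d <- d * cc$mask
      },
      maxpool = {
        d <- maxpool_backward(d, cc, B, ncol(d))
      },
      conv1d = {
        dZ <- d * (cc$Z > 0)
        grads[[i]] <- list(W = crossprod(cc$Xcol, dZ) + 2 * ly$l2 * weights[[i]]$W,
                           b = colSums(dZ))
        dXcol <- tcrossprod(dZ, weights[[i]]$W)
        d <- col2im_seq(dXcol, B, cc$len_in, cc$ch_in, ly$kernel)
      }
    )
  }
  grads
}

l2_penalty <- function(stack, weights) {
  p <- 0
  for (i in seq_along(stack$layers)) {
    ly <- stack$layers[[i]]
    if (ly$kind == "conv1d") p <- p + ly$l2 * sum(weights[[i]]$W^2)
  }
  p
}
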