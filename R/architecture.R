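## Declarative layer stacks for the three network variants.
##
## All convolutions are 1D, stride 1, no padding ("valid"), 64 filters,
## ReLU activation, L2 kernel penalty 0.01. Block 1 uses kernel size 4,
## Block 2 kernel size 3. Each block ends with maxpooling (pool 3) and
## dropout (p = 0.35). Block 3 is three dense layers of 64, 32 and 2 units;
## the 2-unit output is read through a softmax as (adl, fall) scores.

layer_conv <- function(kernel) list(kind = "conv1d", filters = 64L,
                                    kernel = as.integer(kernel),
                                    activation = "relu", l2 = 0.01)
layer_pool <- function() list(kind = "maxpool", pool = 3L)
layer_drop <- function() list(kind = "dropout", p = 0.35)
layer_flat <- function() list(kind = "flatten")
layer_dense <- function(units, activation) list(kind = "dense",
                                                units = as.integer(units),
                                                activation = activation)

new_layer_stack <- function(variant, input_length, layers) {
  structure(list(variant = variant, input_length = as.integer(input_length),
                 layers = layers),
            class = "layer_stack")
}

#' Build one of the three fall-detection network variants
#'
#' * `CNN-3B3Conv`: Block 1 (3 convolutions, kernel 4; maxpool 3; dropout
#'   0.35), Block 2 (3 convolutions, kernel 3; maxpool 3; dropout 0.35),
#'   Block 3 (dense 64, 32, 2).
#' * `CNN-3Conv`: Block 1 with all three convolutions, then Block 3.
#' * `CNN-1Conv`: Block 1 reduced to a single convolution and maxpool, then
#'   Block 3.
#'
#' Every convolution has 64 filters, ReLU activation and an L2 kernel
#' penalty of 0.01; the final dense layer has 2 units scored by softmax
#' ("fall" vs "not fall").
#'
#' @param variant one of `"CNN-3B3Conv"`, `"CNN-3Conv"`, `"CNN-1Conv"`.
#' @param input_length window length L; must be long enough that every
#'   convolution and pooling step leaves at least one time step.
#' @return an object of class `"layer_stack"`.
#' @export
build_stack <- function(variant = c("CNN-3B3Conv", "CNN-3Conv", "CNN-1Conv"),
                        input_length) {
  variant <- match.arg(variant)
  block3 <- list(layer_flat(),
                 layer_dense(64L, "relu"),
                 layer_dense(32L, "relu"),
                 layer_dense(2L, "softmax"))
  layers <- switch(variant,
    "CNN-3B3Conv" = c(list(layer_conv(4L), layer_conv(4L), layer_conv(4L),
                           layer_pool(), layer_drop(),
                           layer_conv(3L), layer_conv(3L), layer_conv(3L),
                           layer_pool(), layer_drop()),
                      block3),
    "CNN-3Conv" = c(list(layer_conv(4L), layer_conv(4L), layer_conv(4L),
                         layer_pool(), layer_drop()),
                    block3),
    "CNN-1Conv" = c(list(layer_conv(4L), layer_pool(), layer_drop()),
                    block3)
  )
  stack <- new_layer_stack(variant, input_length, layers)
  propagate_shapes(stack)  # validates input_length; errors name the layer
  stack
}

#' Propagate tensor shapes through a layer stack
#'
#' With valid (no padding) convolutions of stride 1 the output length is
#' `in - kernel + 1`; maxpooling of size p gives `floor(in / p)`; the
#' flatten layer yields `length * channels` features.
#'
#' @param stack a `"layer_stack"`.
#' @return data.frame with one row per layer: `layer`, `kind`,
#'   `out_length` (NA after flatten), `out_units` (channels or dense units,
#'   i.e. the flattened size for the flatten layer).
#' @export
propagate_shapes <- function(stack) {
  len <- stack$input_length
  ch <- 3L
  flat <- NA_integer_
  rows <- lapply(seq_along(stack$layers), function(i) {
    ly <- stack$layers[[i]]
    switch(ly$kind,
      conv1d = {
        len <<- len - ly$kernel + 1L
        if (len < 1L)
          fallcnn_error("input_too_short",
                        sprintf("layer %d (conv1d, kernel %d) leaves length %d; input_length %d is too small for %s",
                                i, ly$kernel, len, stack$input_length, stack$variant))
        ch <<- ly$filters
      },
      maxpool = {
        len <<- len %/% ly$pool
        if (len < 1L)
          fallcnn_error("input_too_short",
                        sprintf("layer %d (maxpool, size %d) leaves length 0; input_length %d is too small for %s",
                                i, ly$pool, stack$input_length, stack$variant))
      },
      dropout = NULL,
      flatten = {
        flat <<- len * ch
        len <<- NA_integer_
        ch <<- flat
      },
      dense = {
        ch <<- ly$units
      },
      fallcnn_error("bad_argument", sprintf("unknown layer kind '%s'", ly$kind))
    )
    data.frame(layer = i, kind = ly$kind, out_length = len, out_units = ch)
  })
  out <- do.call(rbind, rows)
  attr(out, "flatten_size") <- flat
  out
}

#' Count trainable parameters of a stack
#'
#' Sums weight and bias counts: a convolution with k-taps, `c` input
#' channels and `f` filters holds `k*c*f + f` parameters; a dense layer of
#' `n` inputs and `u` units holds `n*u + u`.
#'
#' @param stack a `"layer_stack"`.
#' @return integer parameter count (0 for a stack with no trainable layers).
#' @export
count_parameters <- function(stack) {
  if (length(stack$layers) == 0L) return(0L)
  ch <- 3L
  total <- 0
  len <- stack$input_length
  for (ly in stack$layers) {
    switch(ly$kind,
      conv1d = {
        total <- total + ly$kernel * ch * ly$filters + ly$filters
        len <- len - ly$kernel + 1L
        ch <- ly$filters
      },
      maxpool = { len <- len %/% ly$pool },
      flatten = { ch <- len * ch },
      dense = {
        total <- total + ch * ly$units + ly$units
        ch <- ly$units
      },
      NULL
    )
  }
  as.integer(total)
}

#' @export
print.layer_stack <- function(x, ...) {
  shapes <- propagate_shapes(x)
  cat(sprintf("<layer_stack> %s, input %d x 3, %s parameters\n",
              x$variant, x$input_length,
              format(count_parameters(x), big.mark = ",")))
  for (i in seq_along(x$layers)) {
    ly <- x$layers[[i]]
    desc <- switch(ly$kind,
      conv1d = sprintf("conv1d  %d filters, kernel %d, %s, l2 %.2f",
                       ly$filters, ly$kernel, ly$activation, ly$l2),
      maxpool = sprintf("maxpool size %d", ly$pool),
      dropout = sprintf("dropout p %.2f", ly$p),
      flatten = "flatten",
      dense = sprintf("dense   %d units, %s", ly$units, ly$activation))
    dim <- if (is.na(shapes$out_length[[i]]))
      sprintf("-> %d", shapes$out_units[[i]])
    else sprintf("-> %d x %d", shapes$out_length[[i]], shapes$out_units[[i]])
    cat(sprintf("  %2d. %-45s %s\n", i, desc, dim))
  }
  invisible(x)
}
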