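#' Rotation angles for data augmentation
#'
#' Holds the (alpha, beta, gamma) angles, in radians, of one rigid rotation
#' about the x-, y- and z-axes used to generate an augmented copy of a
#' window.
#'
#' @param alpha,beta,gamma finite angles in radians about x, y and z.
#' @return object of class `"rotation_spec"`.
#' @export
rotation_spec <- function(alpha, beta, gamma) {
  a <- c(alpha, beta, gamma)
  if (length(a) != 3L || !all(is.finite(a)))
    fallcnn_error("bad_argument", "rotation angles must be three finite numbers")
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "rotation_spec")
}

#' Build the 3x3 rotation matrix for a rotation spec
#'
#' Uses right-handed, counter-clockwise-positive elementary rotations
#' composed as `R = Rz(gamma) %*% Ry(beta) %*% Rx(alpha)`. The composition
#' order and handedness are fixed so augmented datasets are reproducible.
#'
#' @param spec a [rotation_spec()], or the alpha angle if `beta`/`gamma` are
#'   given.
#' @param beta,gamma optional angles when calling with three scalars.
#' @return orthonormal 3x3 matrix with determinant +1.
#' @export
rotation_matrix <- function(spec, beta = NULL, gamma = NULL) {
  if (!inherits(spec, "rotation_spec")) spec <- rotation_spec(spec, beta, gamma)
  ca <- cos(spec$alpha); sa <- sin(spec$alpha)
  cb <- cos(spec$beta);  sb <- sin(spec$beta)
  cg <- cos(spec$gamma); sg <- sin(spec$gamma)
  Rx <- matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
  Ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3, 3)
  Rz <- matrix(c(cg, sg, 0, -sg, cg, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Rotate every acceleration vector of a window
#'
#' Applies one rigid rotation to the whole window: output row t equals
#' `R %*% a(t)`. The label is preserved (a rotated fall is still a fall);
#' the origin is marked `augmented:<parent origin>`.
#'
#' @param window an [accel_window()].
#' @param spec a [rotation_spec()].
#' @return the rotated `accel_window`.
#' @export
rotate_window <- function(window, spec) {
  if (ncol(window) != 3L)
    fallcnn_error("bad_window", "window must have 3 columns")
  R <- rotation_matrix(spec)
  accel_window(unclass(window) %*% t(R),
               label = window_label(window),
               origin = paste0("augmented:", window_origin(window)))
}

#' Draw a random rotation
#'
#' Each of the three angles is drawn independently and uniformly on
#' `[0, 2*pi)` from the current RNG stream (seed it with `set.seed()` or let
#' [augment_dataset()] manage seeding).
#'
#' @return a [rotation_spec()].
#' @export
sample_rotation <- function() {
  a <- stats::runif(3, 0, 2 * pi)
  rotation_spec(a[[1L]], a[[2L]], a[[3L]])
}

#' Define an augmentation plan
#'
#' @param copies_per_fall,copies_per_adl non-negative integers: how many
#'   independently rotated copies to generate per original window of each
#'   class.
#' @param seed integer seed making the generated rotations reproducible.
#' @param include_originals keep the original windows in the augmented
#'   dataset (default `TRUE`). The URFD-style preset sets this to `FALSE`:
#'   that protocol trains on the generated samples only (30 falls x 60 +
#'   40 ADL x 80 = 5000 samples).
#' @return object of class `"augment_plan"`.
#' @seealso [augment_preset()] for the named dataset presets.
#' @export
augment_plan <- function(copies_per_fall, copies_per_adl, seed = 1L,
                         include_originals = TRUE) {
  if (copies_per_fall < 0 || copies_per_adl < 0)
    fallcnn_error("bad_argument", "copy counts must be non-negative")
  structure(list(copies_per_fall = as.integer(copies_per_fall),
                 copies_per_adl = as.integer(copies_per_adl),
                 seed = as.integer(seed),
                 include_originals = isTRUE(include_originals)),
            class = "augment_plan")
}

#' Augmentation presets reproducing the published dataset arithmetic
#'
#' Three named plans, each derived from printed before/after dataset sizes:
#' * `"urfd"` — 60 copies per fall, 80 per ADL, originals excluded:
#'   30 falls and 40 ADLs yield 1800 + 3200 = 5000 samples.
#' * `"smartwatch"` — 5 copies per fall, none per ADL, originals kept:
#'   182 falls become 1092; 1088 ADLs stay 1088.
#' * `"notch"` — 4 copies per fall, none per ADL, originals kept:
#'   106 falls become 530; 568 ADLs stay 568.
#'
#' @param name one of `"urfd"`, `"smartwatch"`, `"notch"`.
#' @param seed integer seed for the rotations.
#' @return an [augment_plan()].
#' @export
augment_preset <- function(name = c("urfd", "smartwatch", "notch"), seed = 1L) {
  switch(match.arg(name),
    urfd = augment_plan(60L, 80L, seed, include_originals = FALSE),
    smartwatch = augment_plan(5L, 0L, seed),
    notch = augment_plan(4L, 0L, seed)
  )
}

#' Expand a dataset with randomly rotated copies
#'
#' For every original window, generates `copies_per_fall` (falls) or
#' `copies_per_adl` (ADLs) new windows, each rotated rigidly by an
#' independent random rotation (angles uniform on `[0, 2*pi)` per axis).
#' Rotation preserves per-sample vector norms, so the physical magnitude
#' signature of the signal is unchanged. Deterministic given `plan$seed`.
#'
#' @param dataset an `accel_dataset`.
#' @param plan an [augment_plan()].
#' @return the augmented `accel_dataset`; with `include_originals = TRUE`
#'   its size is `N + n_fall * copies_per_fall + n_adl * copies_per_adl`.
#' @export
augment_dataset <- function(dataset, plan) {
  if (!inherits(plan, "augment_plan"))
    fallcnn_error("bad_argument", "plan must come from augment_plan()")
  if (length(dataset$windows) == 0L)
    fallcnn_error("empty_dataset", "cannot augment an empty dataset")
  with_seed(plan$seed, {
    out <- if (plan$include_originals) dataset$windows else list()
    copies <- lapply(dataset$windows, function(w) {
      k <- switch(window_label(w),
                  fall = plan$copies_per_fall,
                  adl = plan$copies_per_adl,
                  0L)
      if (k == 0L) return(list())
      lapply(seq_len(k), function(j) rotate_window(w, sample_rotation()))
    })
    accel_dataset(c(out, unlist(copies, recursive = FALSE)))
  })
}
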