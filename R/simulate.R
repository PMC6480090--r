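#' Configuration for the synthetic fall/ADL signal simulator
#'
#' The simulator emulates the two window classes the classifier must
#' separate. An ADL (activity of daily living) window is a gravity baseline
#' plus periodic body motion; a fall window follows the standard
#' biomechanical signature — a near-weightless free-fall dip, an impact
#' spike, then post-fall rest near gravity. All magnitudes are in g.
#'
#' @param window_length rows per window (L >= 8 so all fall phases fit).
#' @param gravity baseline magnitude in g (default 1).
#' @param adl_osc_amplitude amplitude of the periodic ADL motion, in g.
#' @param adl_osc_period period of the ADL oscillation, in samples.
#' @param fall_freefall_floor magnitude approached during free fall, in g.
#' @param fall_impact_peak length-2 range (g) the impact spike is drawn from.
#' @param noise_sd standard deviation of additive per-axis Gaussian noise (g).
#' @param orient `"random"` draws a fresh gravity direction per window
#'   (default; gives the rotation-augmentation module meaningful work);
#'   `"fixed"` pins gravity to the z-axis, useful for stress tests of
#'   orientation robustness.
#' @param seed integer seed used by [gen_dataset()].
#' @return object of class `"sim_config"`.
#' @export
sim_config <- function(window_length = 25L, gravity = 1, adl_osc_amplitude = 0.4,
                       adl_osc_period = 10, fall_freefall_floor = 0.05,
                       fall_impact_peak = c(3, 6), noise_sd = 0.05,
                       orient = c("random", "fixed"), seed = 1L) {
  orient <- match.arg(orient)
  if (window_length < 8L)
    fallcnn_error("bad_argument", "window_length must be at least 8")
  if (!(fall_impact_peak[[1L]] > gravity && gravity > fall_freefall_floor &&
        fall_freefall_floor >= 0))
    fallcnn_error("bad_argument",
                  "need impact peak > gravity > freefall floor >= 0")
  if (noise_sd < 0 || adl_osc_amplitude < 0 || adl_osc_period <= 0)
    fallcnn_error("bad_argument", "noise, amplitude and period must be valid")
  structure(list(window_length = as.integer(window_length), gravity = gravity,
                 adl_osc_amplitude = adl_osc_amplitude,
                 adl_osc_period = adl_osc_period,
                 fall_freefall_floor = fall_freefall_floor,
                 fall_impact_peak = fall_impact_peak, noise_sd = noise_sd,
                 orient = orient, seed = as.integer(seed)),
            class = "sim_config")
}

random_direction <- function(cfg) {
  if (cfg$orient == "fixed") return(c(0, 0, 1))
  v <- stats::rnorm(3)
  while (sum(v^2) < 1e-12) v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

magnitude_to_window <- function(m, cfg, label) {
  m <- pmax(m, 0)
  u <- random_direction(cfg)
  v <- outer(m, u)
  if (cfg$noise_sd > 0)
    v <- v + matrix(stats::rnorm(length(v), 0, cfg$noise_sd), nrow(v), 3L)
  accel_window(v, label = label, origin = "synthetic")
}

#' Generate one synthetic ADL window
#'
#' Magnitude trace `gravity + A * sin(2*pi*t/period + phase)` with a random
#' phase, projected onto a per-window gravity direction, plus Gaussian
#' noise. Draws from the current RNG stream; seed it with `set.seed()` or
#' use [gen_dataset()].
#'
#' @param cfg a [sim_config()].
#' @return an [accel_window()] labeled `"adl"`.
#' @export
gen_adl_window <- function(cfg) {
  t <- seq_len(cfg$window_length)
  phase <- stats::runif(1, 0, 2 * pi)
  m <- cfg$gravity + cfg$adl_osc_amplitude *
    sin(2 * pi * t / cfg$adl_osc_period + phase)
  magnitude_to_window(m, cfg, "adl")
}

#' Generate one synthetic fall window
#'
#' Four phases with randomized boundaries: pre-fall ADL-like motion, a
#' free-fall descent toward `fall_freefall_floor`, a single impact spike
#' drawn uniformly from `fall_impact_peak`, and post-fall rest near
#' gravity. With `noise_sd = 0` the impact sample is the unique global
#' maximum of the magnitude trace.
#'
#' @param cfg a [sim_config()].
#' @return an [accel_window()] labeled `"fall"`.
#' @export
gen_fall_window <- function(cfg) {
  L <- cfg$window_length
  n_pre <- max(1L, as.integer(floor(L * stats::runif(1, 0.15, 0.30))))
  n_ff <- max(2L, as.integer(floor(L * stats::runif(1, 0.15, 0.25))))
  # one impact sample; guarantee at least one rest sample
  while (n_pre + n_ff + 2L > L) {
    if (n_pre > 1L) n_pre <- n_pre - 1L else n_ff <- n_ff - 1L
  }
  n_rest <- L - n_pre - n_ff - 1L
  phase <- stats::runif(1, 0, 2 * pi)
  pre <- cfg$gravity + 0.5 * cfg$adl_osc_amplitude *
    sin(2 * pi * seq_len(n_pre) / cfg$adl_osc_period + phase)
  ff <- seq(cfg$gravity, cfg$fall_freefall_floor, length.out = n_ff + 1L)[-1L]
  impact <- stats::runif(1, cfg$fall_impact_peak[[1L]], cfg$fall_impact_peak[[2L]])
  rest <- cfg$gravity + 0.1 * cfg$adl_osc_amplitude *
    exp(-seq_len(n_rest) / 4) * cos(seq_len(n_rest))
  magnitude_to_window(c(pre, ff, impact, rest), cfg, "fall")
}

#' Generate a labeled synthetic dataset
#'
#' Seeds the RNG from `cfg$seed`, generates `n_fall` fall and `n_adl` ADL
#' windows, and shuffles their order. Deterministic for a given config.
#'
#' @param cfg a [sim_config()].
#' @param n_fall,n_adl window counts per class (at least one in total).
#' @return an `accel_dataset` with `class_counts = c(fall = n_fall,
#'   adl = n_adl)`.
#' @export
gen_dataset <- function(cfg, n_fall, n_adl) {
  if (n_fall < 0 || n_adl < 0 || n_fall + n_adl < 1)
    fallcnn_error("bad_argument", "need non-negative counts, at least one window")
  with_seed(cfg$seed, {
    ws <- c(lapply(seq_len(n_fall), function(i) gen_fall_window(cfg)),
            lapply(seq_len(n_adl), function(i) gen_adl_window(cfg)))
    accel_dataset(ws[sample.int(length(ws))])
  })
}
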