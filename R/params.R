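#' Model parameters
#'
#' Constructs the full parameter set of the visual-system model.  Defaults are
#' the reference configuration: retina persistence over `n_p` frames, vDoG
#' standard deviations `(sigma_e, sigma_i = 2 sigma_e)`, FDSR time constants
#' `tau1 < tau2` (ms), correlator sampling distance `sd` with `n_c` correlated
#' cells per direction, dynamic delay bounds `tau_s_min`..`tau_s_max` (ms) and
#' the sigmoid scale `k`.  The inter-frame interval `tau_i` (ms) is derived
#' from `fps` so the temporal constants can never disagree with the frame rate.
#'
#' @param fps frame rate of the input sequence (frames/second).
#' @param n_p number of persistent frames in the retina layer (0, 1 or 2).
#' @param tau1,tau2 fast-depolarising and slow-repolarising time constants, ms;
#'   `tau1 < tau2`.
#' @param sigma_e excitatory (centre) Gaussian standard deviation, px.  The
#'   inhibitory surround uses `sigma_i = 2 * sigma_e` and twice the kernel
#'   radius; kernels are truncated at radius `round(sigma)` and deliberately
#'   not renormalised.
#' @param sd sampling distance between paired correlator cells, px.
#' @param n_c number of correlated neighbour cells per direction; the
#'   correlator distances are `sd, 2*sd, ..., n_c*sd`.
#' @param tau_s_min,tau_s_max bounds of the distance-dependent dynamic delay,
#'   ms.  The nearest pair gets `tau_s_max` (largest latency), the farthest
#'   `tau_s_min`.
#' @param k sigmoid scale coefficient, calibrated to unit-range luminance
#'   (see `luminance_scale`); changing the internal luminance range requires
#'   retuning `k`.
#' @param luminance_scale divisor applied to input frames before processing;
#'   the default 255 maps 8-bit grey levels onto the unit range the model is
#'   calibrated for.  Because the correlator is quadratic in luminance, the
#'   raw wide-field sums would otherwise sit about five orders of magnitude
#'   above the sigmoid's linear range and every output would rail to +/-1.
#' @param fdsr_recursive,delay_recursive if `TRUE` (default) the FDSR /
#'   correlator delay low-pass mixes the current sample with the previous
#'   *filtered* value (first-order IIR), so a 200 ms delay constant really
#'   spans ~6 frames of memory at 30 fps; `FALSE` mixes with the previous raw
#'   sample (a 2-tap FIR that can only look back one frame, which flattens
#'   the ensemble's speed-range tuning).
#' @param rectify_medulla if `TRUE` (default) the adapted medulla signals are
#'   half-wave rectified before entering the direction-selective layer, so
#'   the 2-Q correlators multiply same-polarity, non-negative channel signals
#'   (a negative ON value would act as an OFF signal inside the ON channel,
#'   and the slow-repolarising negative rebounds would otherwise dominate the
#'   correlation).
#' @param enable_vdog,enable_fdsr ablation switches: `enable_vdog = FALSE`
#'   passes the retina signal through unfiltered, `enable_fdsr = FALSE` sets
#'   the medulla signals equal to the rectified lamina signals.
#' @param mixed_sign_policy what the vDoG outputs where centre and surround
#'   responses disagree in sign: `"zero"` (default) or `"subtract"` (plain
#'   `Pe - Pi`).
#' @return an object of class `model_params` (a validated list, including the
#'   derived fields `tau_i`, `sigma_i` and `alpha1`/`alpha2`).
#' @examples
#' p <- model_params()
#' p$alpha1  # ~0.971: the fast trace follows increments almost instantly
#' @export
model_params <- function(fps = 30, n_p = 2, tau1 = 1, tau2 = 100,
                         sigma_e = 2, sd = 4, n_c = 4,
                         tau_s_min = 10, tau_s_max = 200, k = 0.01,
                         luminance_scale = 255,
                         fdsr_recursive = TRUE, delay_recursive = TRUE,
                         rectify_medulla = TRUE,
                         enable_vdog = TRUE, enable_fdsr = TRUE,
                         mixed_sign_policy = c("zero", "subtract")) {
  mixed_sign_policy <- match.arg(mixed_sign_policy)
  if (fps <= 0) stop("fps must be positive")
  if (n_p < 0 || n_p != round(n_p)) stop("n_p must be a non-negative integer")
  if (tau1 >= tau2) stop("tau1 must be smaller than tau2")
  if (tau1 <= 0 || tau2 <= 0) stop("time constants must be positive")
  if (sigma_e <= 0) stop("sigma_e must be positive")
  if (sd < 1 || sd != round(sd)) stop("sd must be a positive integer")
  if (n_c < 1 || n_c != round(n_c)) stop("n_c must be a positive integer")
  if (tau_s_min >= tau_s_max) stop("tau_s_min must be smaller than tau_s_max")
  if (tau_s_min <= 0) stop("delay bounds must be positive")
  if (k <= 0) stop("k must be positive")
  if (luminance_scale <= 0) stop("luminance_scale must be positive")

  tau_i <- 1000 / fps
  p <- list(
    fps = fps, tau_i = tau_i, n_p = as.integer(n_p),
    tau1 = tau1, tau2 = tau2,
    alpha1 = tau_i / (tau1 + tau_i),
    alpha2 = tau_i / (tau2 + tau_i),
    sigma_e = sigma_e, sigma_i = 2 * sigma_e,
    sd = as.integer(sd), n_c = as.integer(n_c),
    tau_s_min = tau_s_min, tau_s_max = tau_s_max,
    k = k, luminance_scale = luminance_scale,
    fdsr_recursive = isTRUE(fdsr_recursive),
    delay_recursive = isTRUE(delay_recursive),
    rectify_medulla = isTRUE(rectify_medulla),
    enable_vdog = isTRUE(enable_vdog),
    enable_fdsr = isTRUE(enable_fdsr),
    mixed_sign_policy = mixed_sign_policy
  )
  class(p) <- "model_params"
  p
}

#' @export
print.model_params <- function(x, ...) {
  cat("Motion-vision model parameters\n")
  cat(sprintf("  fps %g (tau_i %.3f ms); retina persistence n_p = %d\n",
              x$fps, x$tau_i, x$n_p))
  cat(sprintf("  vDoG sigma_e/sigma_i = %g/%g px (%s)\n",
              x$sigma_e, x$sigma_i,
              if (x$enable_vdog) "enabled" else "bypassed"))
  cat(sprintf("  FDSR tau1/tau2 = %g/%g ms -> alpha1/alpha2 = %.4f/%.4f (%s)\n",
              x$tau1, x$tau2, x$alpha1, x$alpha2,
              if (x$enable_fdsr) "enabled" else "bypassed"))
  cat(sprintf("  correlators: sd = %d px, n_c = %d, tau_s in [%g, %g] ms\n",
              x$sd, x$n_c, x$tau_s_min, x$tau_s_max))
  cat(sprintf("  sigmoid scale k = %g\n", x$k))
  invisible(x)
}

#' Retina persistence decay coefficients
#'
#' The brightness-change signal persists and decays over `n_p` frames with
#' coefficient `a_i = 1 / (1 + exp(i))` for the map `i` frames in the past.
#'
#' @param n_p number of persistent frames.
#' @return numeric vector of length `n_p` (empty when `n_p = 0`).
#' @export
decay_coefficients <- function(n_p) {
  if (n_p == 0) return(numeric(0))
  1 / (1 + exp(seq_len(n_p)))
}

#' Distance-dependent dynamic delay
#'
#' Correlator pairs at smaller sampling distance carry a larger latency, which
#' decreases linearly to `tau_s_min` at the largest distance:
#' `tau_s(i) = tau_s_max - (tau_s_max - tau_s_min) * (i - sd) / (sd*n_c - sd)`.
#' With a single correlator (`n_c = 1`) the only pair takes `tau_s_max`.
#'
#' @param i sampling distance in px; must lie on the lattice
#'   `sd, 2*sd, ..., n_c*sd`.
#' @param params a [model_params()] object.
#' @return delay in ms.
#' @export
dynamic_delay_tau <- function(i, params) {
  lattice <- params$sd * seq_len(params$n_c)
  if (!all(i %in% lattice))
    stop("sampling distance must be one of ", paste(lattice, collapse = ", "))
  if (params$n_c == 1L) return(rep(params$tau_s_max, length(i)))
  params$tau_s_max - (params$tau_s_max - params$tau_s_min) *
    (i - params$sd) / (params$sd * params$n_c - params$sd)
}
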