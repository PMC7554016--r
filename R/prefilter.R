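#' Retina state
#'
#' Initialises the photoreceptor layer so that the model output is exactly
#' zero on the first frame: the previous-frame buffer starts at the first
#' frame itself and the persistence history starts at zero.
#'
#' @param first_frame luminance matrix of the first frame.
#' @param params a [model_params()] object.
#' @return a `retina_state` list with fields `prev` and `history`.
#' @export
retina_state <- function(first_frame, params) {
  z <- matrix(0, nrow(first_frame), ncol(first_frame))
  structure(list(prev = first_frame,
                 history = rep(list(z), params$n_p)),
            class = "retina_state")
}

#' Photoreceptor temporal differencing with persistence
#'
#' Computes the motion signal
#' `P(t) = L(t) - L(t-1) + sum_i a_i P(t-i)` with decay coefficients
#' `a_i = 1/(1 + exp(i))` over the last `n_p` frames, so a brightness change
#' continues and decays for a short while.
#'
#' @param frame luminance matrix `R x C`.
#' @param state a [retina_state()].
#' @param params a [model_params()] object.
#' @return list with `P` (the motion-signal map) and the updated `state`.
#' @export
retina_step <- function(frame, state, params) {
  if (!all(dim(frame) == dim(state$prev)))
    stop("frame shape does not match the retina state")
  P <- frame - state$prev
  a <- decay_coefficients(params$n_p)
  for (i in seq_along(a)) P <- P + a[i] * state$history[[i]]
  if (params$n_p > 0)
    state$history <- c(list(P), state$history[-params$n_p])
  state$prev <- frame
  list(P = P, state = state)
}

vdog_kernels <- function(params) {
  re <- max(1L, round(params$sigma_e))
  ri <- max(1L, round(params$sigma_i))
  list(e = gaussian_kernel(params$sigma_e, re),
       i = gaussian_kernel(params$sigma_i, ri))
}

#' Variant difference-of-Gaussians (vDoG) centre-surround filter
#'
#' The motion signal is convolved with a narrow excitatory Gaussian
#' (`sigma_e`, truncated at radius `round(sigma_e)`) and a broad inhibitory
#' one (`sigma_i = 2 sigma_e`, twice the radius); both kernels keep their
#' analytic amplitude `exp(-(u^2+v^2)/(2 sigma^2)) / (2 pi sigma^2)` and are
#' not renormalised after truncation.  Borders are zero padded.  The output
#' keeps the magnitude of the centre-surround difference with polarity
#' selectivity: `|Pe - Pi|` where both responses are non-negative,
#' `-|Pe - Pi|` where both are negative, and (by default) zero where their
#' signs disagree, since an ambiguous polarity carries no reliable ON/OFF
#' label.
#'
#' @param P motion-signal matrix from [retina_step()].
#' @param params a [model_params()] object.
#' @return signed contrast map `LA`, same shape as `P`.
#' @export
vdog <- function(P, params) {
  kk <- vdog_kernels(params)
  Pe <- .cpp_conv2(P, kk$e, boundary = 0L)
  Pi <- .cpp_conv2(P, kk$i, boundary = 0L)
  d <- abs(Pe - Pi)
  if (params$mixed_sign_policy == "zero") {
    d * ((Pe >= 0) & (Pi >= 0)) - d * ((Pe < 0) & (Pi < 0))
  } else {
    sgn <- ((Pe >= 0) & (Pi >= 0)) - ((Pe < 0) & (Pi < 0))
    ifelse(sgn == 0, Pe - Pi, sgn * d)
  }
}

#' ON/OFF half-wave rectification
#'
#' Splits the signed contrast map into the parallel pathways: the ON map
#' keeps positive values, the OFF map keeps sign-inverted negative values,
#' so `L1 >= 0`, `L2 >= 0` and `L1 * L2 = 0` everywhere.
#'
#' @param LA signed contrast map from [vdog()].
#' @return list with matrices `L1` (ON) and `L2` (OFF).
#' @export
rectify <- function(LA) {
  list(L1 = pmax(LA, 0), L2 = -pmin(LA, 0))
}

#' FDSR adaptation state
#'
#' @param L1,L2 the first rectified ON/OFF maps; traces start at these maps
#'   so the adapted output is zero on the first frame.
#' @return an `adapt_state` list.
#' @export
adapt_state <- function(L1, L2) {
  structure(list(Lhat1 = L1, Lhat2 = L2, prev_L1 = L1, prev_L2 = L2),
            class = "adapt_state")
}

fdsr_channel <- function(L, prev_L, Lhat_prev, params) {
  delta <- L - prev_L
  alpha <- params$alpha2 + (params$alpha1 - params$alpha2) * (delta >= 0)
  base <- if (params$fdsr_recursive) Lhat_prev else prev_L
  alpha * L + (1 - alpha) * base
}

#' Fast-depolarising slow-repolarising (FDSR) adaptation
#'
#' Each pathway carries an asymmetric first-order trace: where the signal
#' rose since the previous frame the trace mixes with coefficient
#' `alpha1 = tau_i / (tau1 + tau_i)` (fast), where it fell with
#' `alpha2 = tau_i / (tau2 + tau_i)` (slow).  By default the trace mixes the
#' current sample with the previous raw sample (the literal printed form);
#' with `fdsr_recursive = TRUE` it mixes with its own previous value.  The
#' trace is subtracted from the signal, which suppresses any sustained
#' component — the medulla outputs `M1 = L1 - L1_hat`, `M2 = L2 - L2_hat`
#' respond to change and are signed.
#'
#' @param L1,L2 rectified ON/OFF maps.
#' @param state an [adapt_state()].
#' @param params a [model_params()] object.
#' @return list with `M1`, `M2` and the updated `state`.
#' @export
fdsr_step <- function(L1, L2, state, params) {
  Lhat1 <- fdsr_channel(L1, state$prev_L1, state$Lhat1, params)
  Lhat2 <- fdsr_channel(L2, state$prev_L2, state$Lhat2, params)
  state$Lhat1 <- Lhat1; state$Lhat2 <- Lhat2
  state$prev_L1 <- L1;  state$prev_L2 <- L2
  list(M1 = L1 - Lhat1, M2 = L2 - Lhat2, state = state)
}
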