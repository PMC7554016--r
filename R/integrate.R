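#' Wide-field LPTC pooling
#'
#' Each lobula-plate sub-layer sums the T4 and T5 maps of its preferred
#' direction over the whole field.
#'
#' @param T4,T5 direction-map lists from [t4_responses()] / [t5_responses()].
#' @return named numeric vector `c(r, l, d, u)`.
#' @export
pool_lptc <- function(T4, T5) {
  c(r = sum(T4$r) + sum(T5$r),
    l = sum(T4$l) + sum(T5$l),
    d = sum(T4$d) + sum(T5$d),
    u = sum(T4$u) + sum(T5$u))
}

#' LPi sign-inverting opponency
#'
#' Neighbouring sub-layers inhibit each other, yielding the opponent
#' horizontal and vertical sums `HS_raw = LP_r - LP_l`,
#' `VS_raw = LP_d - LP_u`.
#'
#' @param LP named vector from [pool_lptc()].
#' @return named vector `c(HS_raw, VS_raw)`.
#' @export
opponency <- function(LP) {
  c(HS_raw = unname(LP["r"] - LP["l"]), VS_raw = unname(LP["d"] - LP["u"]))
}

#' Sigmoid output activation
#'
#' Maps the raw opponent sum to a bounded membrane potential:
#' `f(x) = 2 sgn(x) ((1 + exp(-|x| / (C R k)))^{-1} - 1/2)`.
#' The function is odd and strictly increasing, with range `(-1, 1)`:
#' positive input maps into `[0, 1)`, negative into `(-1, 0]`.
#'
#' @param x raw sum (any numeric vector).
#' @param params a [model_params()] object.
#' @param C,R columns and rows of the visual field (the normaliser scales
#'   with field area).
#' @return activated values in `(-1, 1)`.
#' @export
activate <- function(x, params, C, R) {
  s <- C * R * params$k
  if (!is.finite(s) || s == 0) stop("C * R * k must be non-zero")
  2 * sign(x) * (1 / (1 + exp(-abs(x) / s)) - 0.5)
}

#' Run the full model on a frame sequence
#'
#' Streams the frames through the retina, lamina (vDoG + rectification +
#' FDSR), the T4/T5 correlator ensembles and the lobula-plate integration,
#' and returns the per-frame wide-field responses.  Under the initialisation
#' convention (all buffers seeded from the first frame) the first frame's
#' outputs are exactly zero.
#'
#' @param frames numeric array `R x C x T` (a `frame_seq` or plain array)
#'   with values on the 0--255 luminance scale.
#' @param params a [model_params()] object.
#' @param keep_maps if `TRUE`, per-frame intermediate maps (`P`, `LA`, `L1`,
#'   `L2`, `M1`, `M2`, `T4`, `T5`) are attached as attribute `"maps"` (memory
#'   heavy; intended for small diagnostic runs).
#' @return a `system_response` data.frame with one row per frame and columns
#'   `frame`, `time_ms`, `LP_r`, `LP_l`, `LP_d`, `LP_u`, `HS_raw`, `VS_raw`,
#'   `HS`, `VS`.
#' @examples
#' sp <- stimulus_spec(width = 80, height = 60, duration = 12,
#'                     target_size = c(10, 30), target_grey = 0,
#'                     target_velocity = 27)
#' resp <- run_model(render_stimulus(sp), model_params())
#' head(resp)
#' @export
run_model <- function(frames, params, keep_maps = FALSE) {
  stopifnot(length(dim(frames)) == 3)
  dims <- dim(frames)
  R <- dims[1]; C <- dims[2]; T <- dims[3]
  if (T < 1) stop("empty frame sequence")
  zero <- matrix(0, R, C)
  frames <- frames / params$luminance_scale
  out <- data.frame(frame = seq_len(T),
                    time_ms = (seq_len(T) - 1) * params$tau_i,
                    LP_r = 0, LP_l = 0, LP_d = 0, LP_u = 0,
                    HS_raw = 0, VS_raw = 0, HS = 0, VS = 0)
  maps <- if (keep_maps) vector("list", T) else NULL

  rs <- retina_state(frames[, , 1], params)
  as <- adapt_state(zero, zero)
  ds_on <- delay_state(zero, params)
  ds_off <- delay_state(zero, params)

  for (t in seq_len(T)) {
    if (t == 1L) {
      if (keep_maps)
        maps[[t]] <- list(P = zero, LA = zero, L1 = zero, L2 = zero,
                          M1 = zero, M2 = zero)
      next
    }
    st <- retina_step(frames[, , t], rs, params)
    rs <- st$state
    P <- st$P
    LA <- if (params$enable_vdog) vdog(P, params) else P
    rl <- rectify(LA)
    if (params$enable_fdsr) {
      fd <- fdsr_step(rl$L1, rl$L2, as, params)
      as <- fd$state
      M1 <- fd$M1; M2 <- fd$M2
    } else {
      M1 <- rl$L1; M2 <- rl$L2
    }
    if (params$rectify_medulla) {
      M1 <- pmax(M1, 0); M2 <- pmax(M2, 0)
    }
    d1 <- delay_step(M1, ds_on, params);  ds_on <- d1$state
    d2 <- delay_step(M2, ds_off, params); ds_off <- d2$state
    T4 <- t4_responses(M1, d1$Mhat, params)
    T5 <- t5_responses(M2, d2$Mhat, params)
    LP <- pool_lptc(T4, T5)
    opp <- opponency(LP)
    out$LP_r[t] <- LP["r"]; out$LP_l[t] <- LP["l"]
    out$LP_d[t] <- LP["d"]; out$LP_u[t] <- LP["u"]
    out$HS_raw[t] <- opp["HS_raw"]; out$VS_raw[t] <- opp["VS_raw"]
    out$HS[t] <- activate(opp["HS_raw"], params, C, R)
    out$VS[t] <- activate(opp["VS_raw"], params, C, R)
    if (keep_maps)
      maps[[t]] <- list(P = P, LA = LA, L1 = rl$L1, L2 = rl$L2,
                        M1 = M1, M2 = M2, T4 = T4, T5 = T5)
  }
  class(out) <- c("system_response", "data.frame")
  attr(out, "params") <- params
  attr(out, "field") <- c(C = C, R = R)
  if (keep_maps) attr(out, "maps") <- maps
  out
}

#' @export
print.system_response <- function(x, ...) {
  cat(sprintf("System response: %d frames, field %dx%d\n",
              nrow(x), attr(x, "field")["C"], attr(x, "field")["R"]))
  cat(sprintf("  HS median %.4g (range %.4g .. %.4g)\n",
              median(x$HS), min(x$HS), max(x$HS)))
  cat(sprintf("  VS median %.4g (range %.4g .. %.4g)\n",
              median(x$VS), min(x$VS), max(x$VS)))
  invisible(x)
}

#' Plot HS/VS time series
#' @param x a `system_response`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.system_response <- function(x, ...) {
  graphics::matplot(x$time_ms, cbind(x$HS, x$VS), type = "l", lty = 1,
                    col = c("firebrick", "steelblue"),
                    xlab = "time (ms)", ylab = "activated output", ...)
  graphics::abline(h = 0, col = "grey70")
  graphics::legend("topright", c("HS", "VS"), lty = 1, bty = "n",
                   col = c("firebrick", "steelblue"))
}

#' Summary statistics of a response over a frame window
#'
#' @param resp a `system_response`.
#' @param window integer frame indices (e.g. from [crossing_window()]);
#'   defaults to all frames after the first.
#' @return one-row data.frame with median/mean/variance of HS and VS.
#' @export
response_stats <- function(resp, window = NULL) {
  if (is.null(window)) window <- seq_len(nrow(resp))[-1]
  window <- window[window >= 1 & window <= nrow(resp)]
  data.frame(median_HS = median(resp$HS[window]),
             mean_HS = mean(resp$HS[window]),
             var_HS = var(resp$HS[window]),
             median_VS = median(resp$VS[window]),
             mean_VS = mean(resp$VS[window]),
             var_VS = var(resp$VS[window]))
}
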