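#' Single delayed map
#'
#' One step of the correlator delay: `Mhat(t) = a3 M(t) + (1 - a3) M(t-1)`
#' with `a3 = tau_i / (tau_i + tau_s)`.  `prev` is the previous raw map in the
#' literal (default) form or the previous delayed map when
#' `delay_recursive = TRUE`.
#'
#' @param M current medulla map.
#' @param prev previous map (raw or delayed, see above).
#' @param tau_s delay constant, ms.
#' @param params a [model_params()] object.
#' @return the delayed map.
#' @export
delay_map <- function(M, prev, tau_s, params) {
  a3 <- params$tau_i / (params$tau_i + tau_s)
  a3 * M + (1 - a3) * prev
}

#' Delay state for one channel
#'
#' Keeps one delayed trace per sampling distance, because the delay constant
#' depends on the distance of the correlator pair.
#'
#' @param first_M the first medulla map of the channel.
#' @param params a [model_params()] object.
#' @return a `delay_state` list with `prev` (last raw map) and `traces`
#'   (one delayed map per distance).
#' @export
delay_state <- function(first_M, params) {
  structure(list(prev = first_M,
                 traces = rep(list(first_M), params$n_c)),
            class = "delay_state")
}

#' Per-distance delayed maps
#'
#' Computes the ensemble of delayed medulla maps, one per sampling distance
#' `i = sd, 2 sd, ..., n_c sd`, each with its own [dynamic_delay_tau()]
#' constant (nearest pair slowest, farthest fastest).
#'
#' @param M current medulla map.
#' @param state a [delay_state()].
#' @param params a [model_params()] object.
#' @return list with `Mhat` (list of delayed maps, one per distance) and the
#'   updated `state`.
#' @export
delay_step <- function(M, state, params) {
  dists <- params$sd * seq_len(params$n_c)
  taus <- dynamic_delay_tau(dists, params)
  Mhat <- vector("list", params$n_c)
  for (j in seq_len(params$n_c)) {
    prev <- if (params$delay_recursive) state$traces[[j]] else state$prev
    Mhat[[j]] <- delay_map(M, prev, taus[j], params)
  }
  state$traces <- Mhat
  state$prev <- M
  list(Mhat = Mhat, state = state)
}

ds_maps <- function(M, Mhat, params) {
  dists <- as.integer(params$sd * seq_len(params$n_c))
  .cpp_ds_maps(M, Mhat, dists)
}

#' Direction-selective T4 (ON) responses
#'
#' Per-pixel ensembles of two-quadrant correlators: for each sampling
#' distance `i`, the delayed signal at the reference cell multiplies the
#' instantaneous signal at the partner cell `i` px away, and the four
#' cardinal maps sum over distances:
#' `T4_r(x,y) = sum_i Mhat1(x,y) * M1(x+i,y)`,
#' `T4_l(x,y) = sum_i Mhat1(x+i,y) * M1(x,y)`, and analogously down/up along
#' `y` (row 1 at top, so "down" is increasing row).  Partners outside the
#' field contribute nothing.
#'
#' @param M1 current ON medulla map.
#' @param Mhat1 list of per-distance delayed ON maps from [delay_step()].
#' @param params a [model_params()] object.
#' @return list of matrices `r`, `l`, `d`, `u`.
#' @export
t4_responses <- function(M1, Mhat1, params) ds_maps(M1, Mhat1, params)

#' Direction-selective T5 (OFF) responses
#'
#' Identical correlator contract to [t4_responses()], applied to the OFF
#' channel maps.
#'
#' @param M2 current OFF medulla map.
#' @param Mhat2 list of per-distance delayed OFF maps.
#' @param params a [model_params()] object.
#' @return list of matrices `r`, `l`, `d`, `u`.
#' @export
t5_responses <- function(M2, Mhat2, params) ds_maps(M2, Mhat2, params)
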