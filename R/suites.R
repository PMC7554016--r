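#' @title Scripted experiment suites
#' @description Each suite renders a deterministic stimulus grid, runs the
#'   model on every cell and returns a tidy results table with the response
#'   statistics taken over the crossing window (frames in which the target is
#'   fully inside the field).  Suites are pure functions of their arguments,
#'   so identical parameters and seeds reproduce identical tables.
#' @name suites
NULL

run_cell <- function(spec, params) {
  resp <- run_model(render_stimulus(spec), params)
  stats <- response_stats(resp, crossing_window(spec))
  stats
}

#' Cardinal-direction decoding suite
#'
#' Dark and white bars translate in the four cardinal directions over a
#' uniform mid-grey ground; the matching wide-field system should respond
#' with the direction's sign (right: +HS, left: -HS, down: +VS, up: -VS)
#' while the orthogonal system stays silent.  Bars moving vertically use the
#' transposed bar geometry so the long side stays perpendicular to motion.
#'
#' @param params a [model_params()] object.
#' @param greys named vector of target grey levels.
#' @param speed target angular speed, degrees/s.
#' @param width,height,duration field geometry and sequence length.
#' @param target_size bar size `c(w, h)` for horizontal motion.
#' @param background_grey uniform ground luminance.
#' @return data.frame, one row per (grey, direction).
#' @export
suite_cardinal_directions <- function(params = model_params(),
                                      greys = c(dark = 0, white = 255),
                                      speed = 27, width = 320, height = 180,
                                      duration = 60, target_size = c(25, 120),
                                      background_grey = 128) {
  grid <- expand.grid(grey = names(greys),
                      direction = c("r", "l", "d", "u"),
                      stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    dir <- grid$direction[i]
    axis <- if (dir %in% c("r", "l")) "horizontal" else "vertical"
    v <- if (dir %in% c("r", "d")) speed else -speed
    size <- if (axis == "horizontal") target_size else rev(target_size)
    spec <- stimulus_spec(width = width, height = height, duration = duration,
                          target_size = size, target_grey = greys[[grid$grey[i]]],
                          target_velocity = v, target_axis = axis,
                          background_grey = background_grey)
    st <- run_cell(spec, params)
    matched <- if (axis == "horizontal") st$median_HS else st$median_VS
    orthogonal <- if (axis == "horizontal") st$median_VS else st$median_HS
    out[[i]] <- cbind(grid[i, , drop = FALSE],
                      target_grey = greys[[grid$grey[i]]],
                      st, matched = matched, orthogonal = orthogonal)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Depth-motion suppression suite
#'
#' Centred dark and white discs approach (radius grows) or recede (radius
#' shrinks) over a uniform ground.  Expanding and contracting edges drive
#' opposite-direction correlators symmetrically, so both wide-field systems
#' should stay silent throughout.
#'
#' @param params a [model_params()] object.
#' @param greys named target grey levels.
#' @param radius_range disc radius at the start and end of the approach, px
#'   (reversed for recession).
#' @param width,height,duration field geometry and sequence length.
#' @param background_grey uniform ground luminance.
#' @return data.frame with the peak absolute HS and VS per run.
#' @export
suite_depth_motion <- function(params = model_params(),
                               greys = c(dark = 0, white = 255),
                               radius_range = c(5, 60),
                               width = 320, height = 180, duration = 90,
                               background_grey = 128) {
  grid <- expand.grid(grey = names(greys), motion = c("approach", "recede"),
                      stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    rr <- if (grid$motion[i] == "approach") radius_range else rev(radius_range)
    rate <- (rr[2] - rr[1]) / (duration - 1)  # px/frame
    spec <- stimulus_spec(width = width, height = height, duration = duration,
                          target_kind = "disc", target_axis = "depth",
                          target_grey = greys[[grid$grey[i]]],
                          target_velocity = rate * 0.25 * 30,
                          radius_start = rr[1],
                          background_grey = background_grey)
    resp <- run_model(render_stimulus(spec), params)
    out[[i]] <- cbind(grid[i, , drop = FALSE],
                      max_abs_HS = max(abs(resp$HS)),
                      max_abs_VS = max(abs(resp$VS)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

clutter_bar_spec <- function(target_speed, target_grey, background_speed,
                             texture_seed, width, height, duration,
                             target_size, target_kind = "bar") {
  margin <- ceiling(target_size[1] / 2) + 8
  stimulus_spec(width = width, height = height, duration = duration,
                target_kind = target_kind, target_size = target_size,
                target_grey = target_grey, target_velocity = target_speed,
                target_start = c(margin + 20, (height + 1) / 2),
                background_kind = "procedural_clutter",
                background_velocity = background_speed,
                texture_seed = texture_seed)
}

# RMS contrast between the target grey and the background band it sweeps,
# as a fraction of the full luminance range
band_contrast <- function(spec) {
  tex <- clutter_texture(spec$width, spec$height, spec$texture_seed)
  hh <- (spec$target_size[2] - 1) / 2
  cy <- (spec$height + 1) / 2
  rows <- max(1, floor(cy - hh)):min(spec$height, ceiling(cy + hh))
  sqrt(mean((spec$target_grey - tex[rows, ])^2)) / 255
}

#' Foreground-vs-clutter sweep
#'
#' The systematic grid: bars at three grey levels translate rightward at
#' three speeds while the cluttered background drifts leftward at five
#' speeds.  One row per cell with the crossing-window statistics and the
#' target/background RMS contrast.
#'
#' @param params a [model_params()] object.
#' @param target_speeds,target_greys,background_speeds grid axes
#'   (degrees/s, named grey levels, degrees/s).
#' @param texture_seed background texture seed.
#' @param width,height,duration field geometry and sequence length.
#' @param target_size bar size, px.
#' @return data.frame with `length(target_speeds) * length(target_greys) *
#'   length(background_speeds)` rows.
#' @export
suite_clutter_sweep <- function(params = model_params(),
                                target_speeds = c(9, 18, 27),
                                target_greys = c(white = 255, moderate = 190,
                                                 dark = 0),
                                background_speeds = c(-5, -10, -20, -30, -40),
                                texture_seed = 1L,
                                width = 700, height = 180, duration = 100,
                                target_size = c(25, 120)) {
  grid <- expand.grid(target_speed = target_speeds,
                      grey = names(target_greys),
                      background_speed = background_speeds,
                      stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    spec <- clutter_bar_spec(grid$target_speed[i],
                             target_greys[[grid$grey[i]]],
                             grid$background_speed[i], texture_seed,
                             width, height, duration, target_size)
    out[[i]] <- cbind(grid[i, , drop = FALSE],
                      target_grey = target_greys[[grid$grey[i]]],
                      contrast = band_contrast(spec),
                      run_cell(spec, params))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Correlator-ensemble size sweep
#'
#' Re-runs one clutter cell with different numbers of correlated cells per
#' direction, to expose the saturating gain of the ensemble.
#'
#' @param params base [model_params()]; `n_c` is overridden per run.
#' @param n_c_values ensemble sizes to test.
#' @param target_speed,target_grey,background_speed the fixed cell.
#' @param texture_seed,width,height,duration,target_size as in
#'   [suite_clutter_sweep()].
#' @return data.frame, one row per `n_c`.
#' @export
suite_nc_sweep <- function(params = model_params(),
                           n_c_values = c(1, 2, 4, 8),
                           target_speed = 18, target_grey = 190,
                           background_speed = -20, texture_seed = 1L,
                           width = 700, height = 180, duration = 100,
                           target_size = c(25, 120)) {
  spec <- clutter_bar_spec(target_speed, target_grey, background_speed,
                           texture_seed, width, height, duration, target_size)
  frames <- render_stimulus(spec)
  w <- crossing_window(spec)
  out <- vector("list", length(n_c_values))
  for (i in seq_along(n_c_values)) {
    p <- params
    p$n_c <- as.integer(n_c_values[i])
    resp <- run_model(frames, p)
    out[[i]] <- cbind(data.frame(n_c = n_c_values[i]),
                      response_stats(resp, w))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pre-filter ablation suite
#'
#' Pairs full-model runs with runs in which both the vDoG and the FDSR are
#' bypassed, on identical stimuli, and reports the fraction of crossing
#' frames whose HS sign agrees with the ground-truth (rightward) direction.
#'
#' @param params a [model_params()] object (the "full" arm; the ablated arm
#'   copies it with `enable_vdog = enable_fdsr = FALSE`).
#' @param target_speed target speed, degrees/s.
#' @param target_greys named grey levels.
#' @param background_speed background speed, degrees/s.
#' @param texture_seed,width,height,duration,target_size as in
#'   [suite_clutter_sweep()].
#' @return data.frame with two rows (full/ablated) per grey level.
#' @export
suite_ablation <- function(params = model_params(), target_speed = 27,
                           target_greys = c(white = 255, moderate = 190,
                                            dark = 0),
                           background_speed = -20, texture_seed = 1L,
                           width = 700, height = 180, duration = 100,
                           target_size = c(25, 120)) {
  ablated <- params
  ablated$enable_vdog <- FALSE
  ablated$enable_fdsr <- FALSE
  out <- list()
  for (g in names(target_greys)) {
    spec <- clutter_bar_spec(target_speed, target_greys[[g]], background_speed,
                             texture_seed, width, height, duration, target_size)
    frames <- render_stimulus(spec)
    w <- crossing_window(spec)
    w <- w[w > 1]  # first frame is identically zero by initialisation
    for (arm in c("full", "ablated")) {
      p <- if (arm == "full") params else ablated
      resp <- run_model(frames, p)
      out[[length(out) + 1]] <-
        cbind(data.frame(grey = g, target_grey = target_greys[[g]],
                         arm = arm,
                         frac_correct_sign = mean(resp$HS[w] > 0)),
              response_stats(resp, w))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Target-size preference suite
#'
#' White squares of increasing side length translate rightward against a
#' fast leftward background; the wide-field systems prefer larger targets.
#'
#' @param params a [model_params()] object.
#' @param sizes square side lengths, px.
#' @param target_speed,target_grey,background_speed cell parameters.
#' @param texture_seed,width,height,duration as in [suite_clutter_sweep()].
#' @return data.frame, one row per size.
#' @export
suite_size_sweep <- function(params = model_params(),
                             sizes = c(10, 25, 50, 100),
                             target_speed = 27, target_grey = 255,
                             background_speed = -40, texture_seed = 1L,
                             width = 700, height = 180, duration = 100) {
  out <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    s <- sizes[i]
    spec <- clutter_bar_spec(target_speed, target_grey, background_speed,
                             texture_seed, width, height, duration,
                             c(s, s), target_kind = "square")
    out[[i]] <- cbind(data.frame(size = s), run_cell(spec, params))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' High-speed background suite
#'
#' The white bar translates rightward while the background drifts leftward
#' at very high speeds.  This regime is expected-degraded: the HS sign
#' should survive, but vertical-system suppression is not guaranteed.
#'
#' @param params a [model_params()] object.
#' @param background_speeds background speeds, degrees/s.
#' @param target_speed,target_grey cell parameters.
#' @param texture_seed,width,height,duration,target_size as in
#'   [suite_clutter_sweep()].
#' @return data.frame, one row per background speed.
#' @export
suite_highspeed_background <- function(params = model_params(),
                                       background_speeds = c(-50, -100, -200),
                                       target_speed = 27, target_grey = 255,
                                       texture_seed = 1L,
                                       width = 700, height = 180,
                                       duration = 100,
                                       target_size = c(25, 120)) {
  out <- vector("list", length(background_speeds))
  for (i in seq_along(background_speeds)) {
    spec <- clutter_bar_spec(target_speed, target_grey, background_speeds[i],
                             texture_seed, width, height, duration, target_size)
    out[[i]] <- cbind(data.frame(background_speed = background_speeds[i]),
                      run_cell(spec, params))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
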