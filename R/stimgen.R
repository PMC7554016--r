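#' Declare a synthetic visual stimulus
#'
#' A `stimulus_spec` describes one deterministic grey-scale sequence: a target
#' (bar, square or disc) over a uniform or procedurally cluttered background.
#' All velocities are angular (degrees/s) and are converted to pixels/frame
#' through the single calibration scalar `degrees_per_pixel` and the frame
#' rate, so the centroid moves `target_velocity / (degrees_per_pixel * fps)`
#' px per frame along the stated axis.  The depth axis scales the disc radius
#' instead of translating it.
#'
#' @param width,height field size in pixels (columns, rows).
#' @param fps frame rate, frames/second.
#' @param degrees_per_pixel angular subtense of one pixel, degrees.
#' @param duration number of frames.
#' @param target_kind `"bar"`, `"square"`, `"disc"` or `"none"`.
#' @param target_size `c(w, h)` in px (bars/squares).
#' @param target_grey target luminance in `[0, 255]`.
#' @param target_velocity signed angular velocity, degrees/s.  For the depth
#'   axis this is the radius growth rate (degrees/s of angular radius;
#'   positive = approach).
#' @param target_axis `"horizontal"`, `"vertical"` or `"depth"`.
#' @param target_start centre of the target at frame 1, `c(x, y)` px
#'   (1-based, x = column). `NULL` centres vertically and starts at a margin
#'   on the side the target moves away from.
#' @param radius_start disc radius at frame 1, px (depth axis).
#' @param background_kind `"uniform"` or `"procedural_clutter"`.
#' @param background_grey uniform background luminance in `[0, 255]`.
#' @param background_velocity signed horizontal angular velocity of the
#'   cluttered background, degrees/s.
#' @param texture_seed integer seed for the procedural texture; identical
#'   (spec, seed) pairs give bit-identical sequences.
#' @return an object of class `stimulus_spec`.
#' @seealso [render_stimulus()]
#' @export
stimulus_spec <- function(width = 320, height = 180, fps = 30,
                          degrees_per_pixel = 0.25, duration = 60,
                          target_kind = c("bar", "square", "disc", "none"),
                          target_size = c(25, 120), target_grey = 255,
                          target_velocity = 0,
                          target_axis = c("horizontal", "vertical", "depth"),
                          target_start = NULL, radius_start = 5,
                          background_kind = c("uniform", "procedural_clutter"),
                          background_grey = 128, background_velocity = 0,
                          texture_seed = 1L) {
  target_kind <- match.arg(target_kind)
  target_axis <- match.arg(target_axis)
  background_kind <- match.arg(background_kind)
  if (fps <= 0) stop("fps must be positive")
  if (duration < 1) stop("duration must be at least one frame")
  if (degrees_per_pixel <= 0) stop("degrees_per_pixel must be positive")
  if (target_grey < 0 || target_grey > 255 ||
      background_grey < 0 || background_grey > 255)
    stop("grey levels must lie in [0, 255]")
  if (target_kind %in% c("bar", "square")) {
    if (target_axis == "depth") stop("bars/squares translate; use a disc for depth")
    if (any(target_size < 1)) stop("target_size must be positive")
    if (target_size[1] > width || target_size[2] > height)
      stop("target larger than the visual field")
    if (target_kind == "square" && target_size[1] != target_size[2])
      stop("a square target needs equal width and height")
  }
  if (target_kind == "disc" && target_axis != "depth")
    stop("disc targets move in depth")
  spec <- list(width = as.integer(width), height = as.integer(height),
               fps = fps, degrees_per_pixel = degrees_per_pixel,
               duration = as.integer(duration),
               target_kind = target_kind, target_size = target_size,
               target_grey = target_grey, target_velocity = target_velocity,
               target_axis = target_axis, target_start = target_start,
               radius_start = radius_start,
               background_kind = background_kind,
               background_grey = background_grey,
               background_velocity = background_velocity,
               texture_seed = as.integer(texture_seed))
  class(spec) <- "stimulus_spec"
  spec
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf("Stimulus: %s on %s background, %dx%d px, %d frames @ %g fps\n",
              x$target_kind, x$background_kind, x$width, x$height,
              x$duration, x$fps))
  if (x$target_kind != "none")
    cat(sprintf("  target grey %g, velocity %+g deg/s (%s axis)\n",
                x$target_grey, x$target_velocity, x$target_axis))
  if (x$background_kind == "procedural_clutter")
    cat(sprintf("  background velocity %+g deg/s, texture seed %d\n",
                x$background_velocity, x$texture_seed))
  invisible(x)
}

#' Pixels per frame of an angular velocity
#' @param velocity angular velocity, degrees/s.
#' @param spec a [stimulus_spec()].
#' @return displacement in px/frame.
#' @export
px_per_frame <- function(velocity, spec) {
  velocity / (spec$degrees_per_pixel * spec$fps)
}

#' Unrounded target-centre trajectory
#'
#' @param spec a [stimulus_spec()].
#' @return data.frame with columns `frame`, `x`, `y` (px, 1-based) and, for
#'   depth stimuli, `radius`.
#' @export
target_centre <- function(spec) {
  t <- seq_len(spec$duration) - 1L
  start <- spec$target_start
  if (spec$target_axis == "depth") {
    cx <- (spec$width + 1) / 2
    cy <- (spec$height + 1) / 2
    rate <- px_per_frame(spec$target_velocity, spec)
    return(data.frame(frame = t + 1L, x = cx, y = cy,
                      radius = spec$radius_start + rate * t))
  }
  v <- px_per_frame(spec$target_velocity, spec)
  if (is.null(start)) {
    margin_x <- ceiling(spec$target_size[1] / 2) + 8
    margin_y <- ceiling(spec$target_size[2] / 2) + 8
    start <- c(
      if (spec$target_axis == "horizontal" && v < 0) spec$width - margin_x
      else if (spec$target_axis == "horizontal") margin_x
      else (spec$width + 1) / 2,
      if (spec$target_axis == "vertical" && v < 0) spec$height - margin_y
      else if (spec$target_axis == "vertical") margin_y
      else (spec$height + 1) / 2)
  }
  x <- start[1] + if (spec$target_axis == "horizontal") v * t else 0
  y <- start[2] + if (spec$target_axis == "vertical") v * t else 0
  data.frame(frame = t + 1L, x = x, y = y)
}

#' Frames in which the target lies fully inside the field
#'
#' Response statistics in the experiment suites are taken over this
#' "crossing window".
#'
#' @param spec a [stimulus_spec()].
#' @return integer vector of frame indices.
#' @export
crossing_window <- function(spec) {
  traj <- target_centre(spec)
  if (spec$target_kind == "none") return(traj$frame)
  if (spec$target_axis == "depth") {
    r <- traj$radius
    inside <- (traj$x - r >= 1) & (traj$x + r <= spec$width) &
      (traj$y - r >= 1) & (traj$y + r <= spec$height)
    return(traj$frame[inside])
  }
  hw <- (spec$target_size[1] - 1) / 2
  hh <- (spec$target_size[2] - 1) / 2
  inside <- (round2(traj$x) - floor(hw) >= 1) &
    (round2(traj$x) + ceiling(hw) <= spec$width) &
    (round2(traj$y) - floor(hh) >= 1) &
    (round2(traj$y) + ceiling(hh) <= spec$height)
  traj$frame[inside]
}

# round half up; symmetric behaviour under mirroring is handled by choosing
# non-tie positions in the mirror tests
round2 <- function(x) floor(x + 0.5)

# texture cache: identical (seed, size) pairs are regenerated identically, so
# repeated suite cells reuse the texture instead of re-smoothing the noise
.texture_cache <- new.env(parent = emptyenv())

gaussian_kernel <- function(sigma, radius) {
  u <- -radius:radius
  g <- exp(-outer(u^2, u^2, "+") / (2 * sigma^2)) / (2 * pi * sigma^2)
  g
}

#' Procedural cluttered texture
#'
#' A seeded stand-in for the natural scenes used as moving backgrounds,
#' built from the standard image-formation model: a reflectance pattern with
#' a natural-image power-law amplitude spectrum (`~1/f^1.4`, so energy is
#' dominated by broad structure with sparse fine detail) is multiplied by a
#' smooth illumination field with sparse dark pockets (dappled light, so
#' shadowed regions are both dark and low-contrast), and finally smoothed by
#' a ~2 px Gaussian, the antialiasing a large photograph picks up when it is
#' downscaled to the stimulus raster.  The FFT construction makes the
#' texture periodic, so the scrolled background wraps seamlessly.  The
#' returned texture is continuous-valued in `[0, 255]`; quantisation to grey
#' levels happens per rendered frame.
#'
#' @param width,height texture size, px.
#' @param texture_seed integer seed.
#' @return numeric matrix `height x width` with values in `[0, 255]`.
#' @export
clutter_texture <- function(width, height, texture_seed) {
  key <- sprintf("%d_%d_%d", width, height, texture_seed)
  if (!is.null(.texture_cache[[key]])) return(.texture_cache[[key]])
  seed_keep <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(seed_keep)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", seed_keep, envir = globalenv())
  })
  set.seed(texture_seed)
  freq_axis <- function(n) {
    c(0:(n %/% 2), if (n > 1) -rev(seq_len(ceiling(n / 2) - 1))) / n
  }
  f2 <- outer(freq_axis(height)^2, freq_axis(width)^2, "+")
  amp <- 1 / (sqrt(f2) + 1 / max(width, height))^1.4
  noise <- matrix(rnorm(width * height), height, width)
  tex <- Re(stats::fft(stats::fft(noise) * amp, inverse = TRUE)) /
    (width * height)
  tex <- (tex - min(tex)) / (max(tex) - min(tex))
  refl <- 0.55 + 0.45 * tex
  illum <- .cpp_conv2(matrix(rnorm(width * height), height, width),
                      gaussian_kernel(16, 24), boundary = 1L)
  illum <- (illum - min(illum)) / (max(illum) - min(illum))
  illum <- 0.2 + 0.8 * illum^0.7
  lum <- 255 * refl * illum
  aa <- gaussian_kernel(2, 6)
  lum <- .cpp_conv2(lum, aa, boundary = 1L) / sum(aa)
  out <- pmin(pmax(lum, 0), 255)
  .texture_cache[[key]] <- out
  out
}

#' Render a scrolling cluttered background
#'
#' The texture scrolls horizontally by
#' `background_velocity / (degrees_per_pixel * fps)` px/frame with periodic
#' wrap, so arbitrarily long sequences come from a finite texture.  Motion
#' is sub-pixel: fractional offsets are resolved by linear interpolation
#' between neighbouring texture columns (the way an OpenGL-textured display
#' pipeline scrolls an image), and each frame is then quantised to integer
#' grey levels.
#'
#' @inheritParams clutter_texture
#' @param background_velocity signed horizontal velocity, degrees/s.
#' @param degrees_per_pixel,fps angular calibration and frame rate.
#' @param duration number of frames.
#' @return a `frame_seq` array, `height x width x duration`.
#' @export
render_clutter_background <- function(width, height, texture_seed,
                                      background_velocity, degrees_per_pixel,
                                      fps, duration) {
  tex <- clutter_texture(width, height, texture_seed)
  dx <- background_velocity / (degrees_per_pixel * fps)
  frames <- array(0, dim = c(height, width, duration))
  for (t in seq_len(duration)) {
    s <- dx * (t - 1L)
    s0 <- floor(s)
    fpart <- s - s0
    i1 <- ((seq_len(width) - 1L - s0) %% width) + 1L
    i2 <- ((seq_len(width) - 2L - s0) %% width) + 1L
    frames[, , t] <- round2((1 - fpart) * tex[, i1] + fpart * tex[, i2])
  }
  frames
}

draw_rect <- function(frame, cx, cy, w, h, grey) {
  hw <- (w - 1) / 2
  hh <- (h - 1) / 2
  c1 <- round2(cx) - floor(hw); c2 <- round2(cx) + ceiling(hw)
  r1 <- round2(cy) - floor(hh); r2 <- round2(cy) + ceiling(hh)
  c1 <- max(1L, c1); c2 <- min(ncol(frame), c2)
  r1 <- max(1L, r1); r2 <- min(nrow(frame), r2)
  if (c1 <= c2 && r1 <= r2) frame[r1:r2, c1:c2] <- grey
  frame
}

draw_disc <- function(frame, cx, cy, radius, grey) {
  dx2 <- (seq_len(ncol(frame)) - cx)^2
  dy2 <- (seq_len(nrow(frame)) - cy)^2
  mask <- outer(dy2, dx2, "+") <= radius^2
  frame[mask] <- grey
  frame
}

#' Render a stimulus specification into a frame sequence
#'
#' Produces exactly `duration` frames of `height x width` luminance values in
#' `[0, 255]`.  Target pixels replace background pixels; sub-pixel positions
#' are rounded to the nearest pixel (hard edges, no anti-aliasing).  Identical
#' `(spec, texture_seed)` pairs produce bit-identical output.
#'
#' @param spec a [stimulus_spec()].
#' @return a numeric array `height x width x duration` of class `frame_seq`,
#'   with the spec attached as attribute `"spec"`.
#' @examples
#' sp <- stimulus_spec(duration = 10, target_velocity = 27, target_grey = 0)
#' frames <- render_stimulus(sp)
#' dim(frames)
#' @export
render_stimulus <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  R <- spec$height; C <- spec$width; T <- spec$duration
  if (spec$background_kind == "procedural_clutter") {
    frames <- render_clutter_background(C, R, spec$texture_seed,
                                        spec$background_velocity,
                                        spec$degrees_per_pixel, spec$fps, T)
  } else {
    frames <- array(spec$background_grey, dim = c(R, C, T))
  }
  if (spec$target_kind != "none") {
    traj <- target_centre(spec)
    if (spec$target_kind == "disc") {
      rmax <- min(C, R) / 2
      if (any(traj$radius > rmax)) {
        warning("disc radius clamped to half the field")
        traj$radius <- pmin(traj$radius, rmax)
      }
      traj$radius <- pmax(traj$radius, 0)
      for (t in seq_len(T))
        frames[, , t] <- draw_disc(frames[, , t], traj$x[t], traj$y[t],
                                   traj$radius[t], spec$target_grey)
    } else {
      for (t in seq_len(T))
        frames[, , t] <- draw_rect(frames[, , t], traj$x[t], traj$y[t],
                                   spec$target_size[1], spec$target_size[2],
                                   spec$target_grey)
    }
  }
  structure(frames, spec = spec, class = c("frame_seq", "array"))
}

#' Mirror a frame sequence
#' @param frames a `frame_seq` array.
#' @param axis `"horizontal"` (flip columns) or `"vertical"` (flip rows).
#' @return flipped array of the same shape.
#' @export
mirror_frames <- function(frames, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  out <- if (axis == "horizontal") frames[, dim(frames)[2]:1, , drop = FALSE]
         else frames[dim(frames)[1]:1, , , drop = FALSE]
  attributes(out)$dim <- dim(frames)
  structure(out, spec = attr(frames, "spec"), class = c("frame_seq", "array"))
}
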