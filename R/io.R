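#' Write a frame sequence as numbered greyscale PNGs
#'
#' @param frames a `frame_seq` array (values 0--255).
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix; files are `prefix_000001.png`, ...
#' @return invisibly, the written file paths.
#' @export
write_frames_png <- function(frames, dir, prefix = "frame") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  T <- dim(frames)[3]
  paths <- file.path(dir, sprintf("%s_%06d.png", prefix, seq_len(T)))
  for (t in seq_len(T))
    png::writePNG(frames[, , t] / 255, paths[t])
  invisible(paths)
}

#' Read a directory of greyscale PNGs as a frame sequence
#'
#' Files are read in lexical order; colour images are averaged to a single
#' channel.  Values are returned on the 0--255 scale.
#'
#' @param dir directory containing `.png` files.
#' @return a `frame_seq` array `R x C x T`.
#' @export
read_frames_png <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no PNG frames found in ", dir)
  first <- png::readPNG(files[1])
  if (length(dim(first)) == 3) first <- rowMeans(first, dims = 2)
  frames <- array(0, dim = c(nrow(first), ncol(first), length(files)))
  frames[, , 1] <- first * 255
  for (t in seq_along(files)[-1]) {
    img <- png::readPNG(files[t])
    if (length(dim(img)) == 3) img <- rowMeans(img, dims = 2)
    if (!all(dim(img) == dim(first)))
      stop("frame ", files[t], " has a different shape")
    frames[, , t] <- img * 255
  }
  structure(frames, class = c("frame_seq", "array"))
}

#' Write the per-frame response table as CSV
#' @param resp a `system_response`.
#' @param path output path.
#' @export
write_response_csv <- function(resp, path) {
  write.csv(as.data.frame(resp), path, row.names = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records every parameter actually used, the stimulus description and the
#' seed, so a run can be reproduced exactly.
#'
#' @param path output path.
#' @param params a [model_params()] object.
#' @param spec optional [stimulus_spec()].
#' @param seed optional integer seed.
#' @export
write_run_manifest <- function(path, params, spec = NULL, seed = NULL) {
  manifest <- list(
    package = "flyvis",
    version = as.character(utils::packageVersion("flyvis")),
    params = unclass(params),
    stimulus = if (!is.null(spec)) unclass(spec),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' Serialise / load a stimulus specification
#'
#' The on-disk format is a YAML mapping of the [stimulus_spec()] fields.
#'
#' @param spec a [stimulus_spec()].
#' @param path file path.
#' @export
write_stimulus_config <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_stimulus_config
#' @return `read_stimulus_config()` returns a validated [stimulus_spec()].
#' @export
read_stimulus_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(stimulus_spec))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown stimulus fields: ", paste(unknown, collapse = ", "))
  if (!is.null(vals$target_size)) vals$target_size <- unlist(vals$target_size)
  if (!is.null(vals$target_start)) vals$target_start <- unlist(vals$target_start)
  do.call(stimulus_spec, vals)
}

#' Dump intermediate layer maps for inspection
#'
#' Writes each stored map of a `run_model(..., keep_maps = TRUE)` result as
#' a normalised greyscale PNG heat map and, optionally, a raw text grid.
#'
#' @param resp a `system_response` carrying a `"maps"` attribute.
#' @param dir output directory.
#' @param frames which frame indices to dump (default: all stored).
#' @param text also write raw values as whitespace-separated text grids.
#' @export
write_layer_dumps <- function(resp, dir, frames = NULL, text = FALSE) {
  maps <- attr(resp, "maps")
  if (is.null(maps)) stop("response was not run with keep_maps = TRUE")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(frames)) frames <- seq_along(maps)
  norm01 <- function(m) {
    rng <- range(m)
    if (diff(rng) == 0) matrix(0, nrow(m), ncol(m))
    else (m - rng[1]) / diff(rng)
  }
  for (t in frames) {
    layer <- maps[[t]]
    flat <- list(P = layer$P, LA = layer$LA, L1 = layer$L1, L2 = layer$L2,
                 M1 = layer$M1, M2 = layer$M2)
    if (!is.null(layer$T4))
      for (d in names(layer$T4)) {
        flat[[paste0("T4_", d)]] <- layer$T4[[d]]
        flat[[paste0("T5_", d)]] <- layer$T5[[d]]
      }
    for (nm in names(flat)) {
      base <- file.path(dir, sprintf("%s_%06d", nm, t))
      png::writePNG(norm01(flat[[nm]]), paste0(base, ".png"))
      if (text)
        utils::write.table(flat[[nm]], paste0(base, ".txt"),
                           row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(dir)
}
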