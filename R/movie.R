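#' Render a synthetic two-channel single-molecule movie
#'
#' Generates an [image_stack()] of diffraction-limited spots with known
#' ground truth for end-to-end testing of the trace-extraction pipeline.
#' Far-red frames show the immobilized molecules at their reference
#' positions; orange frames show per-frame intensities (binding or FRET
#' signal) at the transform-mapped positions. Stage drift shifts both
#' channels. PSFs are symmetric Gaussians integrated over pixels; counts
#' carry the Gaussian camera-noise model of [photophysics()]. Spots whose
#' center falls outside the frame are dropped with a warning.
#'
#' @param spots list of spots, each a list with `x`, `y` (reference-channel
#'   coordinates), `farred` (far-red intensity; default
#'   `photo$total_intensity`) and `orange` (scalar or per-orange-frame
#'   intensity vector).
#' @param frame_shape `c(nrow, ncol)` in pixels.
#' @param channel_tags channel per frame (`"orange"` / `"farred"`).
#' @param psf_sigma_px PSF width (px).
#' @param transform optional [estimate_transform()]-style
#'   `affine_transform` mapping reference to orange-channel coordinates;
#'   identity when `NULL`.
#' @param drift_path optional n_frames x 2 matrix of (dx, dy) stage drift.
#' @param photo a [photophysics()] supplying background and noise.
#' @param seed integer seed or `NULL`.
#' @return List with `stack` (an `image_stack`) and `registry` (data.frame
#'   of ground-truth spot ids and positions).
#' @export
render_movie <- function(spots, frame_shape = c(64, 64), channel_tags,
                         psf_sigma_px = 1.1, transform = NULL,
                         drift_path = NULL, photo = photophysics(),
                         seed = NULL) {
  n_frames <- length(channel_tags)
  nr <- frame_shape[1]; nc <- frame_shape[2]
  if (is.null(drift_path)) drift_path <- matrix(0, n_frames, 2)
  orange_idx <- cumsum(channel_tags == "orange")
  with_seed(seed, {
    frames <- array(0, c(nr, nc, n_frames))
    dropped <- FALSE
    for (f in seq_len(n_frames)) {
      img <- matrix(0, nr, nc)
      for (sp in spots) {
        if (channel_tags[f] == "farred") {
          p <- c(sp$x, sp$y)
          inten <- if (is.null(sp$farred)) photo$total_intensity else
            sp$farred
        } else {
          p <- if (is.null(transform)) c(sp$x, sp$y) else
            as.numeric(apply_transform(transform, rbind(c(sp$x, sp$y))))
          o <- sp$orange
          inten <- if (is.null(o)) photo$total_intensity else
            if (length(o) == 1) o else o[orange_idx[f]]
        }
        p <- p + drift_path[f, ]
        if (p[1] < 0 || p[1] > nc - 1 || p[2] < 0 || p[2] > nr - 1) {
          dropped <- TRUE
          next
        }
        if (inten <= 0) next
        w <- ceiling(5 * psf_sigma_px)
        cols <- max(0, floor(p[1]) - w):min(nc - 1, ceiling(p[1]) + w)
        rows <- max(0, floor(p[2]) - w):min(nr - 1, ceiling(p[2]) + w)
        px <- pnorm((cols + 0.5 - p[1]) / psf_sigma_px) -
          pnorm((cols - 0.5 - p[1]) / psf_sigma_px)
        py <- pnorm((rows + 0.5 - p[2]) / psf_sigma_px) -
          pnorm((rows - 0.5 - p[2]) / psf_sigma_px)
        img[rows + 1, cols + 1] <- img[rows + 1, cols + 1] +
          inten * outer(py, px)
      }
      v <- photo$excess_noise_factor * img + photo$background_sd^2
      img <- img + photo$background_mean
      if (any(v > 0))
        img <- img + matrix(stats::rnorm(nr * nc, 0, sqrt(v)), nr, nc)
      frames[, , f] <- img
    }
    if (dropped) warning("spot(s) outside the frame were dropped")
    registry <- data.frame(
      id = seq_along(spots),
      x = vapply(spots, `[[`, 0, "x"),
      y = vapply(spots, `[[`, 0, "y"))
    list(stack = image_stack(frames, channel_tags), registry = registry)
  })
}

#' Write an image stack as multi-page TIFF files
#'
#' One 32-bit float TIFF per channel plus a JSON sidecar with the channel
#' tags, per-channel intensity scale (TIFF floats are stored normalized to
#' \[0, 1\]) and pixel size, so [read_movie()] restores the stack exactly.
#'
#' @param stack an [image_stack()].
#' @param prefix output path prefix; files are
#'   `<prefix>_<channel>.tif` and `<prefix>_meta.json`.
#' @return Invisibly, the sidecar path.
#' @export
write_movie <- function(stack, prefix) {
  stopifnot(inherits(stack, "image_stack"))
  chans <- unique(stack$channel)
  scales <- list()
  for (ch in chans) {
    idx <- which(stack$channel == ch)
    mx <- max(stack$frames[, , idx, drop = FALSE], 1e-12)
    scales[[ch]] <- mx
    pages <- lapply(idx, function(i) pmax(stack$frames[, , i], 0) / mx)
    tiff::writeTIFF(pages, paste0(prefix, "_", ch, ".tif"),
                    bits.per.sample = 32L)
  }
  meta <- list(channel = stack$channel, scale = scales,
               pixel_size_nm = stack$pixel_size_nm)
  path <- paste0(prefix, "_meta.json")
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_movie()]
#'
#' @param prefix the path prefix used when writing.
#' @return An [image_stack()].
#' @export
read_movie <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  channel <- meta$channel
  frames <- NULL
  for (ch in unique(channel)) {
    pages <- tiff::readTIFF(paste0(prefix, "_", ch, ".tif"), all = TRUE)
    if (is.null(frames)) {
      d <- dim(pages[[1]])
      frames <- array(0, c(d[1], d[2], length(channel)))
    }
    idx <- which(channel == ch)
    for (k in seq_along(idx))
      frames[, , idx[k]] <- pages[[k]] * meta$scale[[ch]]
  }
  image_stack(frames, channel, meta$pixel_size_nm)
}

#' Write a trace as CSV with a ground-truth JSON sidecar
#'
#' Long format with columns `frame`, `time_s`, `channel`, `counts`. For a
#' `fret_trace` the channels are `donor`, `acceptor` and `alex`; for a
#' `binding_trace` a single `orange` channel. When the trace carries
#' simulation ground truth, a `<path>.json` sidecar stores it.
#'
#' @param trace a `fret_trace` or `binding_trace`.
#' @param path output CSV path.
#' @param sidecar write the ground-truth sidecar if available.
#' @return Invisibly, `path`.
#' @export
write_trace_csv <- function(trace, path, sidecar = TRUE) {
  if (inherits(trace, "fret_trace")) {
    df <- rbind(
      data.frame(frame = seq_along(trace$time_s), time_s = trace$time_s,
                 channel = "donor", counts = trace$donor),
      data.frame(frame = seq_along(trace$time_s), time_s = trace$time_s,
                 channel = "acceptor", counts = trace$acceptor))
    if (length(trace$alex_time_s) > 0)
      df <- rbind(df, data.frame(frame = seq_along(trace$alex_time_s),
                                 time_s = trace$alex_time_s,
                                 channel = "alex", counts = trace$alex))
    truth <- list(type = "fret_trace", beta = trace$beta,
                  gamma = trace$gamma,
                  frame_interval = trace$frame_interval, t_on = trace$t_on,
                  bleach_time_donor = trace$bleach_time_donor,
                  bleach_time_acceptor = trace$bleach_time_acceptor,
                  seed = trace$seed)
  } else if (inherits(trace, "binding_trace")) {
    df <- data.frame(frame = seq_along(trace$time_s),
                     time_s = trace$time_s, channel = "orange",
                     counts = trace$counts)
    truth <- list(type = "binding_trace", frame_time = trace$frame_time,
                  seed = trace$seed,
                  truth = as.data.frame(trace$truth))
  } else stop("unsupported trace type")
  utils::write.csv(df, path, row.names = FALSE)
  if (sidecar)
    jsonlite::write_json(truth, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' Read a FRET trace CSV written by [write_trace_csv()]
#'
#' @param path CSV path; a `<path>.json` sidecar is used when present.
#' @param beta,gamma correction coefficients if no sidecar is available.
#' @return A `fret_trace`.
#' @export
read_fret_trace_csv <- function(path, beta = 0.071, gamma = 0.463) {
  df <- utils::read.csv(path)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side,
                                                     simplifyVector = TRUE)
    else NULL
  d <- df[df$channel == "donor", ]
  a <- df[df$channel == "acceptor", ]
  al <- df[df$channel == "alex", ]
  dt <- if (!is.null(meta)) meta$frame_interval else
    stats::median(diff(d$time_s))
  structure(list(time_s = d$time_s, donor = d$counts, acceptor = a$counts,
                 alex_time_s = al$time_s, alex = al$counts,
                 beta = if (!is.null(meta)) meta$beta else beta,
                 gamma = if (!is.null(meta)) meta$gamma else gamma,
                 frame_interval = dt,
                 t_on = if (!is.null(meta)) meta$t_on else dt,
                 bleach_time_donor = if (!is.null(meta))
                   meta$bleach_time_donor else NULL,
                 bleach_time_acceptor = if (!is.null(meta))
                   meta$bleach_time_acceptor else NULL,
                 photo = NULL, seed = NULL),
            class = "fret_trace")
}
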