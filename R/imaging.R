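#' Two-channel image stack
#'
#' Container for a multi-frame movie: a `nrow x ncol x nframes` array of
#' counts with a channel tag per frame. Coordinates throughout the package
#' are 0-based with the pixel-center convention: pixel `(i, j)` (row i,
#' column j, both 0-based) covers `[i - 0.5, i + 0.5] x [j - 0.5, j + 0.5]`
#' and spot positions are `(x, y) = (column, row)`.
#'
#' @param frames 3-D numeric array (row x col x frame).
#' @param channel character vector of channel tags, one per frame.
#' @param pixel_size_nm physical pixel size (metadata only).
#' @return An `image_stack`.
#' @export
image_stack <- function(frames, channel, pixel_size_nm = 160) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] >= 1,
            length(channel) == dim(frames)[3])
  structure(list(frames = frames, channel = as.character(channel),
                 pixel_size_nm = pixel_size_nm),
            class = "image_stack")
}

#' Morphological (rolling-ball-style) background subtraction
#'
#' Estimates the smooth background of every frame by grayscale opening with
#' a disc of the given radius and subtracts it. The radius must exceed the
#' PSF width so that diffraction-limited spots are removed from the
#' background estimate rather than eroded into it.
#'
#' @param stack an [image_stack()] (or a single matrix).
#' @param radius_px disc radius in pixels.
#' @param psf_sigma_px assumed PSF width; a radius at or below it triggers a
#'   warning.
#' @return Background-subtracted stack (or matrix).
#' @export
subtract_background <- function(stack, radius_px = 10, psf_sigma_px = 1.2) {
  if (radius_px <= 2 * psf_sigma_px)
    warning("background radius <= PSF width: spots will be eroded")
  brush <- EBImage::makeBrush(2 * floor(radius_px) + 1, shape = "disc")
  sub1 <- function(m) {
    rng <- range(m)
    if (rng[2] - rng[1] < .Machine$double.eps) return(m - m[1])
    # EBImage grayscale morphology expects intensities in [0, 1]
    sc <- (m - rng[1]) / (rng[2] - rng[1])
    bg <- EBImage::opening(sc, brush) * (rng[2] - rng[1]) + rng[1]
    m - bg
  }
  if (is.matrix(stack)) return(sub1(stack))
  stopifnot(inherits(stack, "image_stack"))
  out <- stack
  for (i in seq_len(dim(stack$frames)[3]))
    out$frames[, , i] <- sub1(stack$frames[, , i])
  out
}

#' Fit a symmetric 2-D Gaussian to a spot
#'
#' Least-squares fit of a pixel-integrated symmetric Gaussian plus constant
#' offset within a square window around a seed position. The model
#' integrates the PSF over each pixel (matching the rendering convention),
#' so noiseless rendered spots are recovered exactly.
#'
#' @param frame numeric matrix.
#' @param x,y seed position (0-based pixel-center coordinates).
#' @param window_px half-width of the fit window in pixels.
#' @param psf_range admissible sigma range; a fitted sigma outside it sets
#'   `fit_ok = FALSE`.
#' @return List with `x`, `y`, `amplitude` (total integrated counts),
#'   `sigma`, `offset`, `fit_ok`, `rss`.
#' @export
fit_spot_gaussian <- function(frame, x, y, window_px = 4,
                              psf_range = c(0.5, 3)) {
  nr <- nrow(frame); nc <- ncol(frame)
  xi <- round(x); yi <- round(y)
  rows <- (yi - window_px):(yi + window_px)
  cols <- (xi - window_px):(xi + window_px)
  if (any(rows < 0) || any(cols < 0) || any(rows > nr - 1) ||
      any(cols > nc - 1))
    return(list(x = x, y = y, amplitude = NA_real_, sigma = NA_real_,
                offset = NA_real_, fit_ok = FALSE, rss = NA_real_))
  z <- frame[rows + 1, cols + 1]
  model <- function(par) {
    px <- pnorm((cols + 0.5 - par[2]) / par[4]) -
      pnorm((cols - 0.5 - par[2]) / par[4])
    py <- pnorm((rows + 0.5 - par[3]) / par[4]) -
      pnorm((rows - 0.5 - par[3]) / par[4])
    par[1] * outer(py, px) + par[5]
  }
  obj <- function(par) sum((z - model(par))^2)
  a0 <- max(sum(z - min(z)), .Machine$double.eps)
  start <- c(a0, x, y, 1.2, min(z))
  fit <- try(stats::optim(start, obj, method = "L-BFGS-B",
                          lower = c(0, min(cols), min(rows), 0.2, -Inf),
                          upper = c(Inf, max(cols), max(rows), 8, Inf)),
             silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(x = x, y = y, amplitude = NA_real_, sigma = NA_real_,
                offset = NA_real_, fit_ok = FALSE, rss = NA_real_))
  p <- fit$par
  resid_sd <- sqrt(fit$value / max(length(z) - 5, 1))
  peak <- p[1] / (2 * pi * p[4]^2)   # approximate peak height
  ok <- fit$convergence == 0 &&
    p[4] >= psf_range[1] && p[4] <= psf_range[2] &&
    peak > 3 * resid_sd + sqrt(.Machine$double.eps) * (abs(mean(z)) + 1)
  list(x = p[2], y = p[3], amplitude = p[1], sigma = p[4], offset = p[5],
       fit_ok = ok, rss = fit$value)
}

#' Detect diffraction-limited spots in a frame
#'
#' Local-maxima detection above a robust noise threshold, non-maximum
#' suppression at a minimum separation, and Gaussian refinement. Candidates
#' whose fitted PSF width exceeds `psf_max` (clusters, aggregates) or whose
#' fit fails are rejected.
#'
#' @param frame background-subtracted numeric matrix.
#' @param min_separation_px minimum spot separation for non-maximum
#'   suppression.
#' @param threshold_sd detection threshold in robust background SDs.
#' @param psf_max maximum admissible fitted sigma (px).
#' @param window_px Gaussian-fit window half-width.
#' @return data.frame with `x`, `y`, `amplitude`, `sigma` per accepted spot.
#' @export
detect_spots <- function(frame, min_separation_px = 4, threshold_sd = 5,
                         psf_max = 2.5, window_px = 4) {
  med <- stats::median(frame)
  sdr <- stats::mad(frame)
  thr <- med + threshold_sd * sdr
  nr <- nrow(frame); nc <- ncol(frame)
  # strict local maxima in a 3x3 neighborhood, away from the border
  inner <- frame[2:(nr - 1), 2:(nc - 1)]
  ismax <- inner > thr
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ismax <- ismax & (inner >= frame[2:(nr - 1) + di, 2:(nc - 1) + dj])
  }
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(x = numeric(0), y = numeric(0),
                      amplitude = numeric(0), sigma = numeric(0)))
  cand <- data.frame(y = idx[, 1], x = idx[, 2])     # back to 0-based
  cand$val <- frame[cbind(idx[, 1] + 1, idx[, 2] + 1)]
  cand <- cand[order(-cand$val), ]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      j <- (i + 1):nrow(cand)
      d2 <- (cand$x[j] - cand$x[i])^2 + (cand$y[j] - cand$y[i])^2
      keep[j][d2 < min_separation_px^2] <- FALSE
    }
  }
  cand <- cand[keep, ]
  out <- lapply(seq_len(nrow(cand)), function(i) {
    f <- fit_spot_gaussian(frame, cand$x[i], cand$y[i], window_px,
                           psf_range = c(0.5, psf_max))
    if (!isTRUE(f$fit_ok)) return(NULL)
    data.frame(x = f$x, y = f$y, amplitude = f$amplitude, sigma = f$sigma)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(x = numeric(0), y = numeric(0),
                      amplitude = numeric(0), sigma = numeric(0))
  out
}

#' Estimate an affine channel-registration transform
#'
#' Least-squares 2-D affine transform mapping source-channel to
#' target-channel pixel coordinates from matched control points (typically
#' 4-6 fiducial peaks visible in both channels).
#'
#' @param src_points,dst_points n x 2 matrices of (x, y) coordinates,
#'   n >= 3, not collinear.
#' @return An `affine_transform`: 2 x 3 coefficient matrix with attribute
#'   `residual_rms`.
#' @export
estimate_transform <- function(src_points, dst_points) {
  src <- as.matrix(src_points); dst <- as.matrix(dst_points)
  stopifnot(ncol(src) == 2, ncol(dst) == 2, nrow(src) == nrow(dst))
  if (nrow(src) < 3) stop("need >= 3 point pairs")
  X <- cbind(1, src)
  if (qr(X)$rank < 3) stop("control points are collinear")
  cf <- qr.solve(X, dst)           # 3 x 2: rows (intercept, x, y)
  M <- rbind(c(cf[2, 1], cf[3, 1], cf[1, 1]),
             c(cf[2, 2], cf[3, 2], cf[1, 2]))
  if (abs(det(M[, 1:2])) < 1e-12) stop("transform linear part is singular")
  pred <- X %*% cf
  rms <- sqrt(mean((dst - pred)^2))
  structure(M, class = "affine_transform", residual_rms = rms)
}

#' Apply an affine transform to points
#'
#' @param transform an `affine_transform` (2 x 3 matrix).
#' @param points n x 2 matrix of (x, y).
#' @return n x 2 matrix of mapped coordinates.
#' @export
apply_transform <- function(transform, points) {
  p <- as.matrix(points)
  if (ncol(p) != 2) stop("points must be n x 2")
  t(transform[, 1:2] %*% t(p) + transform[, 3])
}

# Sub-pixel shift between two frames by cross-correlation: returns (dx, dy)
# such that frame b is frame a translated by (dx, dy).
xcorr_shift <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  cc <- Re(stats::fft(stats::fft(b) * Conj(stats::fft(a)), inverse = TRUE))
  nr <- nrow(a); nc <- ncol(a)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  wrap <- function(i, n) if (i - 1 > n / 2) i - 1 - n else i - 1
  dy <- wrap(pk[1], nr); dx <- wrap(pk[2], nc)
  # parabolic sub-pixel refinement on each axis
  g <- function(i, j) cc[((i - 1) %% nr) + 1, ((j - 1) %% nc) + 1]
  ref <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (abs(den) < .Machine$double.eps) 0 else 0.5 * (cm - cp) / den
  }
  dy <- dy + ref(g(pk[1] - 1, pk[2]), g(pk[1], pk[2]), g(pk[1] + 1, pk[2]))
  dx <- dx + ref(g(pk[1], pk[2] - 1), g(pk[1], pk[2]), g(pk[1], pk[2] + 1))
  c(dx = dx, dy = dy)
}

#' Estimate stage drift from reference-channel frames
#'
#' Computes the field translation of every reference-channel frame relative
#' to the first one by image cross-correlation, then linearly interpolates
#' the offsets across the intervening frames of the other channel(s). The
#' returned per-frame offsets are added to spot positions at extraction
#' time.
#'
#' @param stack an [image_stack()].
#' @param reference_channel channel tag of the fiducial (e.g. far-red)
#'   frames.
#' @return n_frames x 2 matrix of `(dx, dy)` offsets.
#' @export
correct_drift <- function(stack, reference_channel = "farred") {
  stopifnot(inherits(stack, "image_stack"))
  ref_idx <- which(stack$channel == reference_channel)
  if (length(ref_idx) < 2) stop("need >= 2 reference frames")
  anchor <- stack$frames[, , ref_idx[1]]
  if (stats::sd(anchor) == 0) stop("featureless reference frame")
  offs <- t(vapply(ref_idx, function(i) {
    fr <- stack$frames[, , i]
    if (stats::sd(fr) == 0) {
      warning("featureless reference frame; carrying previous offset")
      return(c(NA_real_, NA_real_))
    }
    xcorr_shift(anchor, fr)
  }, numeric(2)))
  # carry previous offset over featureless frames
  for (k in seq_len(nrow(offs))) {
    if (anyNA(offs[k, ]))
      offs[k, ] <- if (k == 1) c(0, 0) else offs[k - 1, ]
  }
  n <- dim(stack$frames)[3]
  dx <- stats::approx(ref_idx, offs[, 1], xout = seq_len(n), rule = 2)$y
  dy <- stats::approx(ref_idx, offs[, 2], xout = seq_len(n), rule = 2)$y
  cbind(dx = dx, dy = dy)
}

#' Extract aperture-summed intensity traces
#'
#' For each position, sums per frame the pixels whose centers lie within
#' `radius_px` of the (drift-corrected) position. Positions whose aperture
#' extends beyond the frame are flagged edge-clipped. With
#' `local_background = "annulus"` the median pixel value in an annulus
#' between `radius_px + 1` and `radius_px + 4` is subtracted per aperture
#' pixel, removing any residual offset left by background subtraction
#' (standard aperture photometry).
#'
#' @param stack an [image_stack()].
#' @param positions n x 2 matrix of (x, y) spot positions.
#' @param radius_px aperture radius (px); 0 selects the single nearest
#'   pixel.
#' @param offsets optional n_frames x 2 drift offsets from
#'   [correct_drift()].
#' @param channel channel tag of frames to extract; `NULL` for all frames.
#' @param local_background `"none"` (plain sum) or `"annulus"`.
#' @return Matrix (frames x positions) of summed counts, with attributes
#'   `edge_clipped` (logical per position), `frame_index` and `npix`
#'   (aperture pixel count per position and frame average).
#' @export
extract_traces <- function(stack, positions, radius_px = 2, offsets = NULL,
                           channel = NULL,
                           local_background = c("none", "annulus")) {
  local_background <- match.arg(local_background)
  stopifnot(inherits(stack, "image_stack"))
  pos <- as.matrix(positions)
  nr <- dim(stack$frames)[1]; nc <- dim(stack$frames)[2]
  n_all <- dim(stack$frames)[3]
  fidx <- if (is.null(channel)) seq_len(n_all) else
    which(stack$channel == channel)
  if (is.null(offsets)) offsets <- matrix(0, n_all, 2)
  out <- matrix(NA_real_, length(fidx), nrow(pos))
  clipped <- rep(FALSE, nrow(pos))
  for (fi in seq_along(fidx)) {
    f <- fidx[fi]
    fr <- stack$frames[, , f]
    for (p in seq_len(nrow(pos))) {
      cx <- pos[p, 1] + offsets[f, 1]
      cy <- pos[p, 2] + offsets[f, 2]
      cols <- floor(cx - radius_px):ceiling(cx + radius_px)
      rows <- floor(cy - radius_px):ceiling(cy + radius_px)
      grid <- expand.grid(r = rows, c = cols)
      grid <- grid[(grid$r - cy)^2 + (grid$c - cx)^2 <= radius_px^2 +
                     1e-9, , drop = FALSE]
      if (nrow(grid) == 0) {   # radius 0 between pixels: nearest pixel
        grid <- data.frame(r = round(cy), c = round(cx))
      }
      inside <- grid$r >= 0 & grid$r <= nr - 1 & grid$c >= 0 &
        grid$c <= nc - 1
      if (!all(inside)) clipped[p] <- TRUE
      g <- grid[inside, , drop = FALSE]
      val <- sum(fr[cbind(g$r + 1, g$c + 1)])
      if (local_background == "annulus") {
        r_out <- radius_px + 4
        acols <- floor(cx - r_out):ceiling(cx + r_out)
        arows <- floor(cy - r_out):ceiling(cy + r_out)
        ag <- expand.grid(r = arows, c = acols)
        d2 <- (ag$r - cy)^2 + (ag$c - cx)^2
        ag <- ag[d2 > (radius_px + 1)^2 & d2 <= r_out^2 &
                   ag$r >= 0 & ag$r <= nr - 1 & ag$c >= 0 &
                   ag$c <= nc - 1, , drop = FALSE]
        if (nrow(ag) > 0)
          val <- val - nrow(g) *
            stats::median(fr[cbind(ag$r + 1, ag$c + 1)])
      }
      out[fi, p] <- val
    }
  }
  attr(out, "edge_clipped") <- clipped
  attr(out, "frame_index") <- fidx
  out
}

#' Chung-Kennedy edge-preserving nonlinear filter
#'
#' Forward-backward nonlinear filter for single-molecule intensity traces:
#' at each sample the outputs of a trailing and a leading running mean of
#' length `window` are combined with weights proportional to the inverse
#' local variance raised to `p_exponent`. Plateaus are averaged while steps
#' are preserved, because the window that straddles a transition has a large
#' local variance and is down-weighted.
#'
#' @param trace numeric vector, longer than `2 * window`.
#' @param window running-mean length in samples (>= 2).
#' @param p_exponent variance-weighting exponent.
#' @return Filtered vector of the same length.
#' @export
ck_filter <- function(trace, window = 8, p_exponent = 2) {
  n <- length(trace)
  stopifnot(window >= 2)
  if (n <= 2 * window) stop("trace must be longer than 2 * window")
  cs <- c(0, cumsum(trace)); cs2 <- c(0, cumsum(trace^2))
  stat <- function(lo, hi) {
    m <- hi - lo + 1
    s <- cs[hi + 1] - cs[lo]
    s2 <- cs2[hi + 1] - cs2[lo]
    mean <- s / m
    v <- ifelse(m > 1, pmax(0, (s2 - m * mean^2) / (m - 1)), 0)
    list(mean = mean, var = v)
  }
  t <- seq_len(n)
  f <- stat(pmax(1, t - window + 1), t)       # trailing, includes current
  b <- stat(t, pmin(n, t + window - 1))       # leading, includes current
  tol <- 1e-9 * stats::var(trace)
  vf <- f$var; vb <- b$var
  wf <- ifelse(vf <= tol, Inf, vf^(-p_exponent))
  wb <- ifelse(vb <= tol, Inf, vb^(-p_exponent))
  out <- numeric(n)
  both_inf <- is.infinite(wf) & is.infinite(wb)
  fi <- is.infinite(wf) & !both_inf
  bi <- is.infinite(wb) & !both_inf
  fin <- !(both_inf | fi | bi)
  out[both_inf] <- 0.5 * (f$mean[both_inf] + b$mean[both_inf])
  out[fi] <- f$mean[fi]
  out[bi] <- b$mean[bi]
  out[fin] <- (wf[fin] * f$mean[fin] + wb[fin] * b$mean[fin]) /
    (wf[fin] + wb[fin])
  out
}
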