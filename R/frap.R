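#' Double-normalize a FRAP curve
#'
#' Divides the bleached-ROI intensity by the unbleached reference ROI to
#' remove acquisition photobleaching, then rescales affinely so the
#' pre-bleach mean maps to 1 and the first post-bleach point maps to 0.
#' Frames where the reference is non-positive are dropped with a warning.
#'
#' @param curve a `frap_curve` (fields `t`, `bleach_roi`,
#'   `reference_roi`; pre-bleach frames have `t < 0`).
#' @return The curve with fields `normalized` and `t` (possibly reduced)
#'   added.
#' @export
frap_normalize <- function(curve) {
  stopifnot(inherits(curve, "frap_curve") || is.list(curve))
  t <- curve$t
  if (!any(t < 0)) stop("no pre-bleach frames")
  if (!any(t >= 0)) stop("no post-bleach frames")
  ok <- curve$reference_roi > 0
  if (!all(ok)) {
    warning("dropping ", sum(!ok), " frame(s) with non-positive reference")
    t <- t[ok]
  }
  r <- curve$bleach_roi[ok] / curve$reference_roi[ok]
  pre <- mean(r[t < 0])
  first_post <- r[which(t >= 0)[1]]
  if (abs(pre - first_post) < .Machine$double.eps)
    stop("degenerate normalization: no bleach depth")
  out <- curve
  out$t <- t
  out$normalized <- (r - first_post) / (pre - first_post)
  class(out) <- unique(c("frap_curve", class(curve)))
  out
}

#' Average FRAP curves with a standard-error band
#'
#' Normalizes each curve if needed, resamples all curves onto the time base
#' of the first by linear interpolation, and reports the pointwise mean and
#' SEM.
#'
#' @param curves list of `frap_curve` objects.
#' @return A `frap_mean_curve`: `t`, `mean`, `sem` (`NA` with a single
#'   curve), `n`.
#' @export
average_curves <- function(curves) {
  stopifnot(length(curves) >= 1)
  curves <- lapply(curves, function(cv)
    if (is.null(cv$normalized)) frap_normalize(cv) else cv)
  t0 <- curves[[1]]$t
  vals <- vapply(curves, function(cv)
    stats::approx(cv$t, cv$normalized, xout = t0, rule = 2)$y,
    numeric(length(t0)))
  vals <- matrix(vals, nrow = length(t0))
  structure(list(t = t0, mean = rowMeans(vals),
                 sem = if (ncol(vals) > 1)
                   apply(vals, 1, stats::sd) / sqrt(ncol(vals))
                 else rep(NA_real_, length(t0)),
                 n = ncol(vals)),
            class = "frap_mean_curve")
}

#' Fit exponential recovery with an immobile fraction
#'
#' Least-squares fit of `R(t) = M (1 - exp(-t / tau))` to the post-bleach
#' portion of a normalized recovery curve. The immobile fraction is defined
#' from the fitted plateau, `1 - M`, rather than from the last measured
#' point, which matters when the recovery time constant is comparable to
#' the observation window. A fitted `M > 1.05` triggers a warning that the
#' normalization is suspect.
#'
#' @param curve a `frap_mean_curve` from [average_curves()] or a
#'   normalized `frap_curve`.
#' @param double_exponential fit `M1 (1 - exp(-t/tau1)) + M2 (1 -
#'   exp(-t/tau2))` instead (off by default; the single-lifetime model is
#'   the standard readout).
#' @return A `frap_fit`: `tau` (s), `mobile_amplitude`,
#'   `immobile_fraction`, `se` (named standard errors), `rss`. For the
#'   double-exponential model `tau` and `mobile_amplitude` have length 2
#'   and the immobile fraction is `1 - sum(M)`.
#' @export
fit_recovery <- function(curve, double_exponential = FALSE) {
  t <- curve$t
  y <- if (!is.null(curve$mean)) curve$mean else curve$normalized
  post <- t >= 0
  t <- t[post]; y <- y[post]
  if (length(t) < 3) stop("need >= 3 post-bleach frames")
  if (!double_exponential) {
    m0 <- min(max(mean(utils::tail(y, max(3, length(y) %/% 10))), 0.1),
              1.2)
    fit <- minpack.lm::nlsLM(y ~ M * (1 - exp(-t / tau)),
                             data = data.frame(t = t, y = y),
                             start = list(M = m0, tau = max(t) / 3),
                             lower = c(0, 1e-9),
                             control = minpack.lm::nls.lm.control(
                               maxiter = 500))
    cf <- stats::coef(fit)
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) c(M = NA_real_, tau = NA_real_))
    if (cf["M"] > 1.05)
      warning("fitted mobile amplitude > 1.05: normalization suspect")
    structure(list(tau = unname(cf["tau"]),
                   mobile_amplitude = unname(cf["M"]),
                   immobile_fraction = 1 - unname(cf["M"]),
                   se = c(M = unname(se["M"]), tau = unname(se["tau"])),
                   rss = sum(stats::resid(fit)^2)),
              class = "frap_fit")
  } else {
    fit <- minpack.lm::nlsLM(
      y ~ M1 * (1 - exp(-t / tau1)) + M2 * (1 - exp(-t / tau2)),
      data = data.frame(t = t, y = y),
      start = list(M1 = 0.3, M2 = 0.3, tau1 = max(t) / 10,
                   tau2 = max(t)),
      lower = c(0, 0, 1e-9, 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    cf <- stats::coef(fit)
    ord <- order(c(cf["tau1"], cf["tau2"]))
    taus <- unname(c(cf["tau1"], cf["tau2"])[ord])
    Ms <- unname(c(cf["M1"], cf["M2"])[ord])
    structure(list(tau = taus, mobile_amplitude = Ms,
                   immobile_fraction = 1 - sum(Ms), se = NULL,
                   rss = sum(stats::resid(fit)^2)),
              class = "frap_fit")
  }
}
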