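#' Event timeline of alternating bright/dark segments
#'
#' Gap-free ordered segments of a colocalization binding trace. Bright
#' segments are bound intervals (`t_bright`), dark segments unbound
#' intervals (`t_dark`). First and last segments are censored (their true
#' duration extends beyond the observation window); segments suspected of
#' overlapping multiple binding events can be flagged excluded.
#'
#' @param state character vector of `"bright"` / `"dark"`, alternating.
#' @param start_s segment start times (s).
#' @param duration_s segment durations (s), > 0.
#' @param censored logical per segment; default censors the first and last.
#' @param excluded logical per segment; default all `FALSE`.
#' @return An `event_timeline` data.frame.
#' @export
event_timeline <- function(state, start_s, duration_s, censored = NULL,
                           excluded = NULL) {
  n <- length(state)
  stopifnot(length(start_s) == n, length(duration_s) == n, n >= 1,
            all(duration_s > 0), all(state %in% c("bright", "dark")))
  if (n > 1) {
    if (any(state[-1] == state[-n])) stop("segments must alternate")
    if (any(abs(start_s[-1] - (start_s[-n] + duration_s[-n])) > 1e-6))
      stop("timeline must be gap-free")
  }
  if (is.null(censored)) {
    censored <- rep(FALSE, n); censored[c(1, n)] <- TRUE
  }
  if (is.null(excluded)) excluded <- rep(FALSE, n)
  structure(data.frame(state = state, start_s = start_s,
                       duration_s = duration_s, censored = censored,
                       excluded = excluded),
            class = c("event_timeline", "data.frame"))
}

#' Detect binding events by thresholding
#'
#' Chung-Kennedy-filters the trace, marks frames above `threshold`
#' (default: background mean + 3 SD) as bright, drops bright runs shorter
#' than `min_frames` (single-frame crossings are indistinguishable from
#' noise), and assembles the alternating timeline. Bright segments whose
#' plateau exceeds `overlap_factor` times the single-molecule unit
#' intensity (the median bright plateau) are flagged excluded as
#' overlapping multiple binding events; first and last segments are
#' censored.
#'
#' @param trace a `binding_trace` from [simulate_binding_trace()], or a
#'   numeric vector (then `frame_time` is required).
#' @param threshold intensity threshold; `NULL` uses
#'   `background_mean + 3 * background_sd`.
#' @param min_frames minimum bright-run length in frames.
#' @param background_mean,background_sd background statistics; default
#'   robust estimates (median / MAD) from the filtered trace.
#' @param overlap_factor plateau multiple of the unit intensity above which
#'   a segment is flagged as overlapping events.
#' @param frame_time frame interval (s) for numeric input.
#' @param ck_window Chung-Kennedy window (frames); 0 skips filtering.
#' @return An [event_timeline()].
#' @export
detect_events <- function(trace, threshold = NULL, min_frames = 2,
                          background_mean = NULL, background_sd = NULL,
                          overlap_factor = 1.8, frame_time = NULL,
                          ck_window = 8) {
  if (inherits(trace, "binding_trace")) {
    x <- trace$counts
    frame_time <- trace$frame_time
    if (is.null(background_mean)) background_mean <-
      trace$photo$background_mean
    if (is.null(background_sd)) background_sd <- trace$photo$background_sd
  } else {
    x <- as.numeric(trace)
    if (is.null(frame_time)) stop("frame_time required for numeric input")
  }
  xf <- if (ck_window >= 2 && length(x) > 2 * ck_window)
    ck_filter(x, ck_window) else x
  if (is.null(background_mean)) background_mean <- stats::median(xf)
  if (is.null(background_sd)) background_sd <- stats::mad(xf)
  if (is.null(threshold)) threshold <- background_mean + 3 * background_sd
  if (threshold <= background_mean)
    stop("threshold must exceed the background mean")
  bright <- xf > threshold
  r <- rle(bright)
  # bright runs shorter than min_frames are noise: relabel as dark
  r$values[r$values & r$lengths < min_frames] <- FALSE
  x2 <- inverse.rle(r)
  r <- rle(x2)
  n_seg <- length(r$lengths)
  ends <- cumsum(r$lengths)
  starts_f <- c(1, utils::head(ends, -1) + 1)
  state <- ifelse(r$values, "bright", "dark")
  tl <- event_timeline(state = state,
                       start_s = (starts_f - 1) * frame_time,
                       duration_s = r$lengths * frame_time)
  plateaus <- rep(NA_real_, n_seg)
  for (i in which(state == "bright"))
    plateaus[i] <- mean(x[starts_f[i]:ends[i]]) - background_mean
  unit <- stats::median(plateaus, na.rm = TRUE)
  if (is.finite(unit) && unit > 0)
    tl$excluded <- !is.na(plateaus) & plateaus > overlap_factor * unit
  tl
}

#' Dwell durations usable for survival analysis
#'
#' Extracts the durations of the requested state from a timeline, dropping
#' censored boundary segments and overlap-excluded segments.
#'
#' @param timeline an [event_timeline()].
#' @param state `"bright"` (residence times) or `"dark"` (waiting times).
#' @return Numeric vector of durations (s).
#' @export
dwell_times <- function(timeline, state = "bright") {
  stopifnot(inherits(timeline, "event_timeline"))
  sel <- timeline$state == state & !timeline$censored & !timeline$excluded
  timeline$duration_s[sel]
}

#' Empirical survival curve of dwell times
#'
#' Complementary cumulative distribution: the fraction of dwells with
#' duration >= t, evaluated at the observed durations. Censored dwells are
#' excluded from the curve but counted in the report.
#'
#' @param durations dwell durations (s).
#' @param censored optional logical vector; censored dwells are dropped.
#' @return A `survival_curve`: sorted `t`, non-increasing `s` in \[0, 1\],
#'   `n`, `n_censored`.
#' @export
survival_curve <- function(durations, censored = NULL) {
  if (is.null(censored)) censored <- rep(FALSE, length(durations))
  d <- sort(durations[!censored])
  n <- length(d)
  if (n < 1) stop("no uncensored dwells")
  structure(list(t = d, s = (n - seq_len(n) + 1) / n, n = n,
                 n_censored = sum(censored)),
            class = "survival_curve")
}

# multi-start bi-exponential least squares on (t, s)
biexp_ls <- function(t, s) {
  med <- stats::median(t)
  m1 <- mean(t[t <= med]); m2 <- mean(t[t > med])
  if (!is.finite(m2) || m2 <= m1) m2 <- 2 * m1
  starts <- list(c(t1 = 0.5 * m1, t2 = 2 * m2),
                 c(t1 = m1, t2 = m2),
                 c(t1 = 0.2 * m1, t2 = 4 * m2))
  best <- NULL
  for (st in starts) {
    fit <- try(minpack.lm::nlsLM(
      s ~ A1 * exp(-t / t1) + A2 * exp(-t / t2),
      data = data.frame(t = t, s = s),
      start = list(A1 = 0.5, A2 = 0.5, t1 = unname(st["t1"]),
                   t2 = unname(st["t2"])),
      lower = c(0, 0, 1e-6, 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 300)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  best
}

#' Bi-exponential residence-time fit
#'
#' Least-squares fit of `A1 exp(-t/tau1) + A2 exp(-t/tau2)` to a dwell-time
#' survival curve, with non-negative amplitudes and `tau1 < tau2` enforced
#' by post-hoc ordering. Multi-start initialization (time constants seeded
#' from the sample mean split at the median) avoids the classic
#' bi-exponential local minima. The fit collapses to a flagged
#' mono-exponential when the two time constants are degenerate
#' (`tau2 / tau1 < 1.5`) or when the second component does not earn its
#' keep (either component below 5 percent amplitude, or less than a 5
#' percent residual improvement over the mono-exponential fit).
#'
#' @param curve a [survival_curve()] of bright times (>= 50 dwells
#'   recommended).
#' @return A `biexp_fit`: `A1`, `A2`, `tau_off_1`, `tau_off_2`,
#'   `fractions` (relative amplitudes), `collapsed`, `rss`, `se` (named
#'   standard errors when available).
#' @export
fit_biexp <- function(curve) {
  stopifnot(inherits(curve, "survival_curve"))
  t <- curve$t; s <- curve$s
  best <- biexp_ls(t, s)
  mono <- fit_monoexp(curve)
  collapse <- is.null(best)
  if (!collapse) {
    cf <- stats::coef(best$fit)
    taus <- sort(c(cf["t1"], cf["t2"]))
    fr <- c(cf["A1"], cf["A2"]) / sum(cf["A1"], cf["A2"])
    collapse <- taus[2] / taus[1] < 1.5 || min(fr) < 0.05 ||
      best$rss > 0.95 * mono$rss
  }
  if (collapse) {
    return(structure(list(A1 = mono$A, A2 = 0,
                          tau_off_1 = 1 / mono$k_on_app,
                          tau_off_2 = NA_real_, fractions = c(1, 0),
                          collapsed = TRUE, rss = mono$rss,
                          se = NULL), class = "biexp_fit"))
  }
  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) NULL)
  ord <- order(c(cf["t1"], cf["t2"]))
  A <- c(cf["A1"], cf["A2"])[ord]
  taus <- c(cf["t1"], cf["t2"])[ord]
  structure(list(A1 = unname(A[1]), A2 = unname(A[2]),
                 tau_off_1 = unname(taus[1]), tau_off_2 = unname(taus[2]),
                 fractions = unname(A / sum(A)), collapsed = FALSE,
                 rss = best$rss, se = se),
            class = "biexp_fit")
}

#' Mono-exponential fit of a survival curve
#'
#' Least-squares fit of `A exp(-t * k)`. Applied to dark-time survival
#' curves, `k` is the apparent on-rate constant. Wald confidence limits
#' from the fit covariance are reported and are necessarily wide for small
#' samples.
#'
#' @param curve a [survival_curve()].
#' @return A `monoexp_fit`: `A`, `k_on_app` (1/s), `se`, `ci` (95 percent
#'   Wald interval for k), `rss`.
#' @export
fit_monoexp <- function(curve) {
  stopifnot(inherits(curve, "survival_curve"))
  t <- curve$t; s <- curve$s
  k0 <- 1 / max(mean(t), 1e-9)
  fit <- minpack.lm::nlsLM(s ~ A * exp(-t * k),
                           data = data.frame(t = t, s = s),
                           start = list(A = 1, k = k0),
                           lower = c(0, 1e-12),
                           control = minpack.lm::nls.lm.control(maxiter =
                                                                  300))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(A = NA_real_, k = NA_real_))
  # sampling error of the rate itself dominates for small n: k-hat of an
  # exponential sample has relative SE 1/sqrt(n)
  k_se <- max(se["k"], unname(cf["k"]) / sqrt(curve$n), na.rm = TRUE)
  structure(list(A = unname(cf["A"]), k_on_app = unname(cf["k"]),
                 se = c(A = unname(se["A"]), k = k_se),
                 ci = unname(cf["k"]) + c(-1.96, 1.96) * k_se,
                 rss = sum(stats::resid(fit)^2)),
            class = "monoexp_fit")
}

#' Summarize residence-time fits across conditions
#'
#' Aggregates replicate bi-exponential fits per condition (mean and SD of
#' the time constants and of the slow-component fraction) and compares the
#' specific residence time `tau_off_2` between all condition pairs with
#' two-tailed unpaired t-tests.
#'
#' @param fits named list: one entry per condition, each a list of
#'   `biexp_fit` replicates (>= 2 recommended; with a single replicate the
#'   SD is reported as `NA`).
#' @return data.frame of per-condition summaries with attribute
#'   `p_values`, a symmetric matrix of pairwise t-test p-values on
#'   `tau_off_2` (`NA` where either condition has < 2 replicates).
#' @export
summarize_conditions <- function(fits) {
  stopifnot(is.list(fits), !is.null(names(fits)))
  g <- function(cond, what) vapply(fits[[cond]], function(f)
    switch(what, tau1 = f$tau_off_1, tau2 = f$tau_off_2,
           frac2 = f$fractions[2]), numeric(1))
  conds <- names(fits)
  sumr <- do.call(rbind, lapply(conds, function(cn) {
    t1 <- g(cn, "tau1"); t2 <- g(cn, "tau2"); f2 <- g(cn, "frac2")
    sd_or_na <- function(v) if (length(v) > 1) stats::sd(v) else NA_real_
    data.frame(condition = cn, n_reps = length(t1),
               tau1_mean = mean(t1), tau1_sd = sd_or_na(t1),
               tau2_mean = mean(t2), tau2_sd = sd_or_na(t2),
               frac2_mean = mean(f2), frac2_sd = sd_or_na(f2))
  }))
  p <- matrix(NA_real_, length(conds), length(conds),
              dimnames = list(conds, conds))
  for (i in seq_along(conds)) for (j in seq_along(conds)) {
    if (i >= j) next
    a <- g(conds[i], "tau2"); b <- g(conds[j], "tau2")
    if (length(a) > 1 && length(b) > 1)
      p[i, j] <- p[j, i] <- stats::t.test(a, b, var.equal = FALSE)$p.value
  }
  attr(sumr, "p_values") <- p
  sumr
}
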