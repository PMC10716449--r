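#' Corrected FRET efficiency
#'
#' Computes the per-frame FRET efficiency from donor and acceptor channel
#' intensities with bleed-through and detection-sensitivity corrections:
#' `E = (F_A - beta * F_D) / ((F_A - beta * F_D) + gamma * F_D)`, where
#' `beta` is the fraction of donor emission bleeding into the acceptor
#' channel and `gamma` the acceptor/donor detection-sensitivity ratio. The
#' defaults are the Cy3B/Alexa647 calibration values used throughout the
#' package. Frames with a zero denominator return `NA` and are excluded
#' from histograms.
#'
#' @param f_d,f_a donor and acceptor (FRET channel) counts, same length.
#' @param beta bleed-through coefficient, >= 0.
#' @param gamma detection-sensitivity ratio, > 0.
#' @return Numeric vector of efficiencies.
#' @export
compute_efret <- function(f_d, f_a, beta = 0.071, gamma = 0.463) {
  stopifnot(beta >= 0, gamma > 0, length(f_d) == length(f_a))
  num <- f_a - beta * f_d
  den <- num + gamma * f_d
  e <- num / den
  e[abs(den) < .Machine$double.eps] <- NA_real_
  e
}

# background level for a trace: explicit argument, simulated ground truth,
# or zero
trace_background <- function(trace, background = NULL) {
  if (!is.null(background)) return(background)
  if (!is.null(trace$photo)) trace$photo$background_mean else 0
}

# total intensity channel: F_D + (F_A - beta F_D) / gamma equals the full
# molecular brightness I at every frame regardless of the FRET state, so it
# steps only when the donor bleaches - the one channel where bleach
# detection is immune to conformational dynamics
total_channel <- function(trace, background = 0) {
  d <- trace$donor - background
  a <- trace$acceptor - background
  d + (a - trace$beta * d) / trace$gamma
}

# sensitized-emission channel I * E: zero (at background) from the first
# bleach event onward, whichever dye dies first
acorr_channel <- function(trace, background = 0) {
  d <- trace$donor - background
  a <- trace$acceptor - background
  (a - trace$beta * d) / trace$gamma
}

# first frame index from which a channel stays at zero: the terminal dark
# onset, robust to fluctuations earlier in the trace. Inf when the channel
# never goes permanently dark. A channel dark throughout returns Inf too:
# with no observable transition there is no bleach EVENT - the molecule may
# simply be zero-FRET, and acceptor presence is the ALEX check's job.
terminal_zero_onset <- function(x, ck_window = 8) {
  n <- length(x)
  xf <- if (n > 2 * ck_window) ck_filter(x, ck_window) else x
  sigma <- stats::mad(diff(x)) / sqrt(2)
  thr <- 4 * sigma + 1e-9 * (max(abs(xf)) + 1)
  above <- xf > thr
  if (!any(above)) return(Inf)
  last_above <- max(which(above))
  if (last_above >= n) Inf else last_above + 1L
}

# frames of a fret_trace before the first bleach event (ground truth when
# simulated, detected otherwise)
prebleach_index <- function(trace, background = NULL) {
  tb <- suppressWarnings(min(trace$bleach_time_donor,
                             trace$bleach_time_acceptor, Inf, na.rm = TRUE))
  if (is.finite(tb)) return(which(trace$time_s + trace$t_on <= tb))
  bg <- trace_background(trace, background)
  tot <- total_channel(trace, bg)
  steps <- detect_bleach_steps(tot)
  k_d <- if (nrow(steps)) steps$index[1] else Inf
  k_a <- terminal_zero_onset(acorr_channel(trace, bg))
  first <- min(k_d, k_a, length(trace$donor) + 1)
  seq_len(first - 1L)
}

#' Estimate bleed-through and detection-sensitivity corrections
#'
#' `beta` is estimated from donor-only traces as the mean ratio of
#' acceptor-channel to donor-channel signal. `gamma` is estimated from
#' traces containing a single acceptor-bleach step as the mean ratio of the
#' drop in the bleed-corrected acceptor channel to the anticorrelated rise
#' in the donor channel across the step; traces without a usable step are
#' dropped from the gamma estimate.
#'
#' @param donor_only_traces list of `fret_trace` objects with no acceptor.
#' @param bleach_traces list of `fret_trace` objects containing one
#'   acceptor-bleach step.
#' @param background background level subtracted from both channels
#'   (counts).
#' @return List with `beta` and `gamma`.
#' @export
estimate_corrections <- function(donor_only_traces, bleach_traces,
                                 background = 0) {
  betas <- vapply(donor_only_traces, function(tr) {
    # donor-only molecules: only the donor channel can show a bleach step
    d_steps <- detect_bleach_steps(tr$donor)
    last <- if (nrow(d_steps)) d_steps$index[1] - 1L else length(tr$donor)
    idx <- seq_len(last)
    if (length(idx) < 2) return(NA_real_)
    mean(tr$acceptor[idx] - background) / mean(tr$donor[idx] - background)
  }, numeric(1))
  beta <- mean(betas, na.rm = TRUE)
  gammas <- vapply(bleach_traces, function(tr) {
    steps <- detect_bleach_steps(tr$acceptor)
    if (nrow(steps) != 1) return(NA_real_)
    k <- steps$index[1]
    n <- length(tr$acceptor)
    pre <- max(1, k - 50):(k - 1)
    post <- k:min(n, k + 50)
    if (length(pre) < 2 || length(post) < 2) return(NA_real_)
    fa_c <- (tr$acceptor - background) - beta * (tr$donor - background)
    d_a <- mean(fa_c[pre]) - mean(fa_c[post])
    d_d <- mean(tr$donor[post]) - mean(tr$donor[pre])
    if (d_d <= 0) return(NA_real_)
    d_a / d_d
  }, numeric(1))
  list(beta = beta, gamma = mean(gammas, na.rm = TRUE))
}

#' Detect single-step photobleaching events in a channel
#'
#' Change-point detection for irreversible single-step bleaching: the frame
#' split that minimizes the two-plateau residual sum of squares is accepted
#' as a step when the level drop is downward and exceeds
#' `min_step_sd` robust noise SDs; each side is then searched once more, so
#' up to two steps (two dyes) are reported.
#'
#' @param x channel intensity vector (Chung-Kennedy filtering is not
#'   required but sharpens localization on noisy traces).
#' @param min_step_sd significance threshold in noise SDs.
#' @return data.frame with `index` (first frame of the lower plateau) and
#'   `size` (level drop), ordered by index; zero rows when no step is
#'   found.
#' @export
detect_bleach_steps <- function(x, min_step_sd = 4) {
  sigma <- stats::mad(diff(x)) / sqrt(2)
  find1 <- function(lo, hi) {
    n <- hi - lo + 1
    if (n < 4) return(NULL)
    y <- x[lo:hi]
    cs <- cumsum(y); cs2 <- cumsum(y^2)
    tot <- cs[n]
    k <- seq_len(n - 1)
    m1 <- cs[k] / k
    m2 <- (tot - cs[k]) / (n - k)
    sse <- (cs2[n]) - (k * m1^2 + (n - k) * m2^2)
    j <- which.min(sse)
    drop <- m1[j] - m2[j]
    if (drop <= 0) return(NULL)
    thr <- min_step_sd * sigma +
      sqrt(.Machine$double.eps) * (abs(m1[j]) + abs(m2[j]) + 1)
    if (drop <= thr) return(NULL)
    data.frame(index = lo + j, size = drop)
  }
  s1 <- find1(1, length(x))
  if (is.null(s1)) return(data.frame(index = integer(0), size = numeric(0)))
  # a one-frame margin keeps the partial frame straddling the bleach
  # instant from registering as a second step
  left <- find1(1, s1$index - 2)
  right <- find1(s1$index + 1, length(x))
  out <- rbind(left, s1, right)
  out[order(out$index), , drop = FALSE]
}

#' ALEX single-dye validation
#'
#' Uses the direct-excitation (ALEX) acceptor frames and the donor channel
#' to verify that the molecule carries exactly one donor and one acceptor:
#' the donor channel must show exactly one bleach step, and the ALEX signal
#' must start above background with at most one bleach step (absence, extra
#' dyes or clustered molecules fail).
#'
#' @param trace a `fret_trace` with ALEX frames.
#' @param background background level (counts); defaults to the trace's
#'   simulated background when available.
#' @return `TRUE` (pass) or `FALSE` with attribute `reason`.
#' @export
validate_alex <- function(trace, background = NULL) {
  background <- trace_background(trace, background)
  fail <- function(reason) structure(FALSE, reason = reason)
  if (length(trace$alex) < 3) return(fail("no ALEX frames"))
  # donor bleaching is detected on the total-intensity channel, which is
  # flat under FRET dynamics and steps only when the donor dies
  d_steps <- detect_bleach_steps(total_channel(trace, background))
  if (nrow(d_steps) != 1) return(fail("donor step count != 1"))
  alex <- trace$alex - background
  sig <- stats::mad(diff(alex)) / sqrt(2)
  head_lvl <- mean(alex[seq_len(min(3, length(alex)))])
  if (head_lvl <= 5 * sig + sqrt(.Machine$double.eps))
    return(fail("no acceptor under direct excitation"))
  a_steps <- detect_bleach_steps(alex)
  if (nrow(a_steps) > 1) return(fail("acceptor step count > 1"))
  TRUE
}

#' Trace selection for smFRET analysis
#'
#' Applies the selection criteria for usable single-molecule FRET traces:
#' (1) initial total fluorescence (donor plus gamma-corrected acceptor)
#' above `min_counts` over baseline; (2) at least `min_pre_bleach_s`
#' seconds before the first bleach event; (3) a single bleach event per
#' channel, with (3a) an anticorrelated donor rise to the pre-bleach total
#' when the acceptor bleaches first, or (3b) a persistent direct-excitation
#' acceptor signal when the donor bleaches first; plus the ALEX single-dye
#' check.
#'
#' @param trace a `fret_trace`.
#' @param min_counts minimum initial total fluorescence over baseline.
#' @param min_pre_bleach_s minimum observation time before the first bleach
#'   (s).
#' @param background baseline level (counts); defaults to the simulated
#'   background when available.
#' @return A `selection_result`: list with `status`
#'   (`"accepted"`/`"rejected"`) and `reason` (`NA` when accepted).
#' @export
apply_selection <- function(trace, min_counts = 2000, min_pre_bleach_s = 5,
                            background = NULL) {
  background <- trace_background(trace, background)
  res <- function(status, reason = NA_character_)
    structure(list(status = status, reason = reason),
              class = "selection_result")
  d <- trace$donor - background
  total <- total_channel(trace, background)
  head_idx <- seq_len(min(10, length(total)))
  init_total <- mean(total[head_idx])
  if (init_total <= min_counts) return(res("rejected", "intensity"))

  # donor bleaching is read off the total-intensity channel (flat under
  # FRET dynamics, steps only at donor bleach); acceptor loss is the
  # terminal onset of zero sensitized emission
  d_steps <- detect_bleach_steps(total)
  if (nrow(d_steps) > 1) return(res("rejected", "multi-step"))
  t_d <- if (nrow(d_steps)) trace$time_s[d_steps$index[1]] else Inf
  acorr <- acorr_channel(trace, background)
  k_a <- terminal_zero_onset(acorr)
  t_a <- if (is.finite(k_a)) trace$time_s[k_a] else Inf
  if (!is.finite(t_d) && !is.finite(t_a))
    return(res("rejected", "multi-step"))   # no bleach event observed
  if (min(t_d, t_a) < min_pre_bleach_s)
    return(res("rejected", "pre-bleach-duration"))

  av <- validate_alex(trace, background = background)
  if (!isTRUE(av)) return(res("rejected", "alex-dye-count"))

  if (t_a < t_d) {
    # acceptor first: donor must rise to the pre-bleach total level
    end <- if (is.finite(t_d)) d_steps$index[1] - 1L else length(d)
    post <- seq_len(end)
    post <- post[trace$time_s[post] > t_a]
    if (length(post) < 2 ||
        abs(mean(d[post]) - init_total) > 0.25 * init_total)
      return(res("rejected", "anticorrelation"))
  } else {
    # donor first: acceptor must still respond to direct excitation in
    # the ALEX frames right after the donor bleach
    alex <- trace$alex - background
    post <- utils::head(which(trace$alex_time_s > t_d), 3)
    sig <- stats::mad(diff(alex)) / sqrt(2)
    if (length(post) < 1 ||
        mean(alex[post]) <= 5 * sig + sqrt(.Machine$double.eps))
      return(res("rejected", "alex-dye-count"))
  }
  res("accepted")
}

#' Build an averaged FRET-efficiency histogram
#'
#' Histograms per-frame efficiencies with a fixed bin width over
#' `[-0.1, 1.1]` (accommodating noise-driven excursions outside `[0, 1]`).
#' Each trace longer than `min_length_s` contributes a histogram normalized
#' to its own total counts; traces are averaged with equal weight, and when
#' several independent repeats are supplied the per-bin mean and SD across
#' repeats are reported.
#'
#' @param traces either a list of traces / numeric efficiency vectors (one
#'   repeat), or a list of such lists (independent repeats).
#' @param bin bin width.
#' @param min_length_s minimum trace length (s) to contribute; applies to
#'   `fret_trace` inputs.
#' @return An `efret_histogram`: `bin_edges`, `mid`, `mean_density`,
#'   `sd_density`, `n_traces`, `n_repeats`.
#' @export
build_histogram <- function(traces, bin = 0.02, min_length_s = 5) {
  edges <- seq(-0.1, 1.1, by = bin)
  is_repeat_list <- length(traces) > 0 && is.list(traces[[1]]) &&
    !inherits(traces[[1]], "fret_trace")
  repeats <- if (is_repeat_list) traces else list(traces)
  trace_e <- function(tr) {
    if (inherits(tr, "fret_trace")) {
      idx <- prebleach_index(tr)
      if (length(idx) * tr$frame_interval <= min_length_s) return(NULL)
      bg <- trace_background(tr)
      e <- compute_efret(tr$donor[idx] - bg, tr$acceptor[idx] - bg,
                         tr$beta, tr$gamma)
    } else e <- as.numeric(tr)
    e <- e[!is.na(e) & e >= edges[1] & e < edges[length(edges)]]
    if (length(e) == 0) NULL else e
  }
  rep_density <- function(trs) {
    hs <- lapply(trs, function(tr) {
      e <- trace_e(tr)
      if (is.null(e)) return(NULL)
      h <- graphics::hist(e, breaks = edges, plot = FALSE,
                          right = FALSE)$counts
      h / sum(h)
    })
    hs <- Filter(Negate(is.null), hs)
    if (length(hs) == 0) return(NULL)
    list(density = Reduce(`+`, hs) / length(hs), n = length(hs))
  }
  per_rep <- Filter(Negate(is.null), lapply(repeats, rep_density))
  if (length(per_rep) == 0) stop("no usable traces")
  dmat <- do.call(rbind, lapply(per_rep, `[[`, "density"))
  structure(list(bin_edges = edges,
                 mid = edges[-length(edges)] + bin / 2,
                 mean_density = colMeans(dmat),
                 sd_density = if (nrow(dmat) > 1) apply(dmat, 2, stats::sd)
                   else rep(NA_real_, ncol(dmat)),
                 n_traces = sum(vapply(per_rep, `[[`, 0, "n")),
                 n_repeats = nrow(dmat)),
            class = "efret_histogram")
}

# sum of unnormalized Gaussian components A_i * exp(-((x - c_i)/s_i)^2)
mixture_value <- function(x, components) {
  rowSums(vapply(seq_len(nrow(components)), function(i)
    components$A[i] * exp(-((x - components$c[i]) / components$sigma[i])^2),
    numeric(length(x))))
}

#' Fit a Gaussian mixture to a FRET histogram
#'
#' Least-squares fit of `sum_i A_i * exp(-((x - c_i) / sigma_i)^2)` to the
#' mean histogram density. Note the exponent carries no factor 1/2, so
#' `sigma_i` differs from a standard deviation by sqrt(2); the value of the
#' fitted curve at `x = c_i` for an isolated component equals `A_i`.
#' Components are reported sorted by center. When `k = NULL`, 2 and 3
#' components are tried and the larger model is kept only if it improves
#' the residual sum of squares by at least 5 percent.
#'
#' @param hist an [build_histogram()] result.
#' @param k number of components (1-3), or `NULL` for automatic 2-vs-3
#'   selection.
#' @return A `gaussian_mixture`: data.frame `components` (A, c, sigma),
#'   `k`, `goodness` (residual sum of squares), `converged`.
#' @export
fit_mixture <- function(hist, k = 2) {
  stopifnot(inherits(hist, "efret_histogram"))
  x <- hist$mid; y <- hist$mean_density
  fit_k <- function(k) {
    # initialize centers at the k strongest well-separated local maxima,
    # widths from the local second moment around each peak
    sm <- stats::filter(y, rep(1 / 5, 5), sides = 2)
    sm[is.na(sm)] <- 0
    ord <- order(-sm)
    centers <- numeric(0)
    for (i in ord) {
      if (length(centers) == k) break
      if (all(abs(x[i] - centers) > 0.08)) centers <- c(centers, x[i])
    }
    # fewer separated maxima than components: shoulder the extras next to
    # the strongest peak, where the gradient is well conditioned
    off <- 0.08
    while (length(centers) < k) {
      centers <- c(centers, min(max(centers[1] + off, -0.1), 1.1))
      off <- -off * 1.5
    }
    local_sigma <- vapply(centers, function(cc) {
      w <- abs(x - cc) <= 0.1
      if (sum(y[w]) <= 0) return(0.05)
      v <- sum(y[w] * (x[w] - cc)^2) / sum(y[w])
      min(max(sqrt(2 * v), 0.02), 0.3)
    }, numeric(1))
    a0 <- pmax(y[vapply(centers, function(cc) which.min(abs(x - cc)),
                        1L)], 0.05 * max(y), 1e-4)
    form <- paste0("A", 1:k, " * exp(-((x - c", 1:k, ") / s", 1:k, ")^2)",
                   collapse = " + ")
    attempt <- function(cs, ss) {
      start <- c(A = a0, c = cs, s = ss)
      names(start) <- c(paste0("A", 1:k), paste0("c", 1:k),
                        paste0("s", 1:k))
      try(minpack.lm::nlsLM(
        stats::as.formula(paste("y ~", form)),
        data = data.frame(x = x, y = y), start = start,
        lower = c(rep(0, k), rep(-0.1, k), rep(0.005, k)),
        upper = c(rep(Inf, k), rep(1.1, k), rep(0.8, k)),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
        silent = TRUE)
    }
    fit <- attempt(centers, local_sigma)
    tries <- 0
    while (inherits(fit, "try-error") && tries < 4) {
      tries <- tries + 1
      jit_c <- pmin(pmax(centers + stats::rnorm(k, 0, 0.03), -0.1), 1.1)
      fit <- attempt(jit_c, pmax(local_sigma * stats::runif(k, 0.5, 2),
                                 0.01))
    }
    fit
  }
  pick <- function(fit, k) {
    cf <- stats::coef(fit)
    comp <- data.frame(A = cf[paste0("A", 1:k)],
                       c = cf[paste0("c", 1:k)],
                       sigma = cf[paste0("s", 1:k)])
    comp <- comp[order(comp$c), ]
    rownames(comp) <- NULL
    structure(list(components = comp, k = k,
                   goodness = sum(stats::resid(fit)^2), converged = TRUE),
              class = "gaussian_mixture")
  }
  ks <- if (is.null(k)) c(2, 3) else k
  stopifnot(all(ks %in% 1:3))
  fits <- lapply(ks, fit_k)
  ok <- !vapply(fits, inherits, TRUE, "try-error")
  if (!any(ok))
    return(structure(list(components = NULL, k = ks[1], goodness = NA_real_,
                          converged = FALSE), class = "gaussian_mixture"))
  fits <- fits[ok]; ks <- ks[ok]
  if (length(fits) == 1) return(pick(fits[[1]], ks[1]))
  rss <- vapply(fits, function(f) sum(stats::resid(f)^2), 0)
  use <- if (rss[2] < 0.95 * rss[1]) 2 else 1
  pick(fits[[use]], ks[use])
}

#' Classify a trace as dynamic or static high/low FRET
#'
#' A trace is "dynamic" when donor and acceptor show anticorrelated
#' intensity fluctuations: in at least one window of `window_s` seconds the
#' donor-acceptor Pearson correlation is below `r_threshold` while the
#' filtered donor fluctuation amplitude exceeds `amp_factor` times the shot
#' noise SD (estimated from frame-to-frame differences). Otherwise the
#' trace is static and split at a mean efficiency of `center_threshold`
#' into `static_high` / `static_low`.
#'
#' @param trace an accepted `fret_trace`.
#' @param center_threshold efficiency split between low and high FRET.
#' @param window_s correlation window length (s).
#' @param r_threshold Pearson correlation threshold (negative).
#' @param amp_factor required fluctuation amplitude in noise SDs.
#' @return One of `"dynamic"`, `"static_high"`, `"static_low"`.
#' @export
classify_trace <- function(trace, center_threshold = 0.2, window_s = 2,
                           r_threshold = -0.3, amp_factor = 3) {
  idx <- prebleach_index(trace)
  bg <- trace_background(trace)
  d <- trace$donor[idx] - bg; a <- trace$acceptor[idx] - bg
  n <- length(d)
  nw <- max(4L, round(window_s / trace$frame_interval))
  sig_d <- stats::mad(diff(d)) / sqrt(2)
  dyn <- FALSE
  if (n >= nw && n > 2 * 8) {
    df <- ck_filter(d, window = min(8, floor((n - 1) / 2)))
    starts <- seq(1, n - nw + 1, by = max(1L, nw %/% 2))
    for (s0 in starts) {
      w <- s0:(s0 + nw - 1)
      if (stats::sd(d[w]) == 0 || stats::sd(a[w]) == 0) next
      r <- stats::cor(d[w], a[w])
      amp <- max(df[w]) - min(df[w])
      if (r < r_threshold && amp > amp_factor * sig_d) { dyn <- TRUE; break }
    }
  }
  if (dyn) return("dynamic")
  e <- compute_efret(d, a, trace$beta, trace$gamma)
  if (mean(e, na.rm = TRUE) > center_threshold) "static_high" else
    "static_low"
}

#' Donor-acceptor cross-correlation relaxation analysis
#'
#' For every gated trace (mean efficiency above `gate`, excluding the
#' zero-FRET population) the normalized cross-covariance
#' `CC(tau) = <dF_D(t) dF_A(t + tau)> / (sigma_D sigma_A)` is computed on
#' mean-subtracted channels up to the first bleach event. Channel means are
#' taken across the gated ensemble rather than per trace: subtracting each
#' trace's own short-window mean biases the estimated decay time downward
#' by a term of order `tau_R / T`, whereas the trace-specific static term
#' left by ensemble-mean subtraction is lag-independent and is absorbed by
#' the fit offset. Per-lag values
#' are averaged across traces with their SEM, and a single exponential
#' `CC(tau) = -a exp(-tau / tau_R) + offset` is fitted, whose decay time
#' `tau_R` reports the conformational exchange relaxation time. A fitted
#' `tau_R` below two frame intervals is flagged unresolvable.
#'
#' @param traces list of `fret_trace` objects.
#' @param gate minimum mean efficiency for inclusion.
#' @param max_lag_s largest lag (s).
#' @param min_traces minimum number of gated traces required.
#' @return A `cross_corr_fit`: `lags` (s), `cc`, `sem`, `tau_R`,
#'   `amplitude`, `offset`, `n_traces`, `converged`, `resolvable`.
#' @export
cross_correlate <- function(traces, gate = 0.2, max_lag_s = 10,
                            min_traces = 10) {
  dt <- traces[[1]]$frame_interval
  K <- max(2L, round(max_lag_s / dt))
  gated <- Filter(Negate(is.null), lapply(traces, function(tr) {
    idx <- prebleach_index(tr)
    if (length(idx) < K + 10) return(NULL)
    bg <- trace_background(tr)
    d <- tr$donor[idx] - bg; a <- tr$acceptor[idx] - bg
    e <- compute_efret(d, a, tr$beta, tr$gamma)
    if (mean(e, na.rm = TRUE) <= gate) return(NULL)
    list(d = d, a = a)
  }))
  if (length(gated) < min_traces)
    stop("fewer than ", min_traces, " gated traces")
  m_d <- mean(unlist(lapply(gated, `[[`, "d")))
  m_a <- mean(unlist(lapply(gated, `[[`, "a")))
  per <- Filter(Negate(is.null), lapply(gated, function(g) {
    dd <- g$d - m_d; da <- g$a - m_a
    sdd <- sqrt(mean(dd^2)); sda <- sqrt(mean(da^2))
    if (sdd == 0 || sda == 0) return(NULL)
    n <- length(dd)
    vapply(seq_len(K), function(k)
      sum(dd[1:(n - k)] * da[(1 + k):n]) / ((n - k) * sdd * sda),
      numeric(1))
  }))
  if (length(per) < min_traces)
    stop("fewer than ", min_traces, " gated traces")
  m <- do.call(rbind, per)
  cc <- colMeans(m)
  sem <- apply(m, 2, stats::sd) / sqrt(nrow(m))
  lags <- seq_len(K) * dt
  c0 <- mean(utils::tail(cc, max(3, K %/% 5)))
  a0 <- max(c0 - cc[1], 1e-4)
  fit <- try(minpack.lm::nlsLM(
    cc ~ -a * exp(-lags / tau) + off,
    data = data.frame(cc = cc, lags = lags),
    start = list(a = a0, tau = max_lag_s / 5, off = c0),
    lower = c(0, dt / 10, -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  out <- list(lags = lags, cc = cc, sem = sem, n_traces = nrow(m))
  if (inherits(fit, "try-error")) {
    out <- c(out, list(tau_R = NA_real_, amplitude = 0, offset = c0,
                       converged = FALSE, resolvable = FALSE))
  } else {
    cf <- stats::coef(fit)
    out <- c(out, list(tau_R = unname(cf["tau"]),
                       amplitude = unname(cf["a"]),
                       offset = unname(cf["off"]), converged = TRUE,
                       resolvable = unname(cf["tau"]) >= 2 * dt))
  }
  structure(out, class = "cross_corr_fit")
}
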