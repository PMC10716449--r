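#' Simulate a continuous-time Markov state path (Gillespie)
#'
#' Draws a trajectory of conformational states from a kinetic scheme using
#' the Gillespie algorithm. The initial state is drawn from the stationary
#' distribution unless `init_state` is given, reflecting molecules observed
#' at steady state.
#'
#' @param scheme a [kinetic_scheme()].
#' @param duration trajectory length (s), > 0.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param init_state optional fixed initial state index.
#' @return A `state_path`: list with `times` (segment start times, first 0),
#'   `states` (state index per segment), `duration`, and `efret` (per-segment
#'   mean efficiency).
#' @export
simulate_ctmc <- function(scheme, duration, seed = NULL, init_state = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"), duration > 0)
  n <- length(scheme$state_labels)
  R <- scheme$rates
  diag(R) <- 0
  with_seed(seed, {
    s <- if (is.null(init_state)) {
      if (n == 1L) 1L else sample.int(n, 1, prob = stationary_distribution(scheme))
    } else as.integer(init_state)
    times <- 0
    states <- s
    t_now <- 0
    repeat {
      exit <- sum(R[s, ])
      if (exit <= 0) break            # absorbing state: stays forever
      t_now <- t_now + stats::rexp(1, exit)
      if (t_now >= duration) break
      s <- sample.int(n, 1, prob = R[s, ])
      times <- c(times, t_now)
      states <- c(states, s)
    }
    structure(list(times = times, states = states, duration = duration,
                   efret = scheme$efret_means[states]),
              class = "state_path")
  })
}

#' FRET efficiency from donor-acceptor distance
#'
#' Standard Foerster relation `E = 1 / (1 + (r / r0)^6)`, used to map
#' structural distances onto simulator state efficiencies.
#'
#' @param r dye-dye distance (any unit, same as `r0`), >= 0.
#' @param r0 Foerster radius, > 0.
#' @return Efficiency in (0, 1\].
#' @export
efret_from_distance <- function(r, r0) {
  if (any(r0 <= 0)) stop("r0 must be > 0")
  if (any(r < 0)) stop("r must be >= 0")
  1 / (1 + (r / r0)^6)
}

# Cumulative integral of the piecewise-constant efficiency path, evaluated at
# arbitrary times by linear interpolation (exact, since the integral is
# piecewise linear).
path_cumint <- function(path) {
  brk <- c(path$times, path$duration)
  vals <- path$efret
  ci <- c(0, cumsum(vals * diff(brk)))
  function(t) {
    t <- pmin(pmax(t, 0), path$duration)
    stats::approx(brk, ci, xout = t, rule = 2)$y
  }
}

#' Render a FRET intensity trace from a state path
#'
#' Converts a conformational trajectory into per-frame donor and acceptor
#' counts under an illumination schedule. Per instant the noiseless rendering
#' is `F_D = I * (1 - E)` and `F_A = gamma * I * E + beta * F_D`, so that the
#' corrected-efficiency formula with the same `beta`, `gamma` inverts the
#' renderer exactly. Efficiency is time-averaged over each integration
#' window, since 100-ms frames straddle state jumps. Bleach times are drawn
#' exponentially; after donor bleach both FRET channels fall to background,
#' after acceptor bleach the acceptor channel falls and the donor rises to
#' the full intensity `I`. Far-red frames in the schedule report direct
#' acceptor excitation (ALEX check frames), nonzero until acceptor bleach.
#'
#' @param path a `state_path` from [simulate_ctmc()].
#' @param photo a [photophysics()] object.
#' @param sched an [illumination_schedule()].
#' @param beta donor bleed-through coefficient, >= 0.
#' @param gamma acceptor/donor detection-sensitivity ratio, > 0.
#' @param seed integer seed or `NULL`.
#' @return A `fret_trace` with per-frame times, donor/acceptor counts, ALEX
#'   counts and times, true frame-averaged efficiencies, and ground-truth
#'   bleach times.
#' @export
render_fret_trace <- function(path, photo, sched, beta = 0.071,
                              gamma = 0.463, seed = NULL) {
  stopifnot(inherits(path, "state_path"), inherits(photo, "photophysics"),
            inherits(sched, "illumination_schedule"), beta >= 0, gamma > 0)
  starts <- sched$frame_starts
  tags <- sched$frame_tags
  if (sched$duration > path$duration + 1e-12) {
    warning("illumination schedule longer than state path; truncating frames")
    keep <- starts + sched$t_on <= path$duration + 1e-12
    starts <- starts[keep]; tags <- tags[keep]
  }
  I <- photo$total_intensity
  cum_e <- path_cumint(path)
  with_seed(seed, {
    td <- if (photo$bleach_rate_donor == 0) Inf else
      if (is.infinite(photo$bleach_rate_donor)) 0 else
        stats::rexp(1, photo$bleach_rate_donor)
    ta <- if (photo$bleach_rate_acceptor == 0) Inf else
      if (is.infinite(photo$bleach_rate_acceptor)) 0 else
        stats::rexp(1, photo$bleach_rate_acceptor)

    orange <- tags == "orange"
    a <- starts; b <- starts + sched$t_on
    both_end <- pmin(b, ta, td)
    t_both <- pmax(0, both_end - a)
    int_e <- pmax(0, cum_e(pmax(a, pmin(both_end, b))) - cum_e(a))
    # donor-only stretch exists when acceptor bleaches before donor
    t_donly <- if (ta < td) pmax(0, pmin(b, td) - pmax(a, ta)) else
      rep(0, length(a))
    f_d <- I * ((t_both - int_e) + t_donly) / sched$t_on
    f_a <- gamma * I * int_e / sched$t_on + beta * f_d
    alex <- I * pmax(0, pmin(b, ta) - a) / sched$t_on

    add_noise <- function(x) {
      v <- photo$excess_noise_factor * pmax(x, 0) + photo$background_sd^2
      out <- x + photo$background_mean
      pos <- v > 0
      if (any(pos))
        out[pos] <- out[pos] + stats::rnorm(sum(pos), 0, sqrt(v[pos]))
      out
    }
    donor <- add_noise(f_d[orange])
    acceptor <- add_noise(f_a[orange])
    alex_a <- add_noise(alex[!orange])

    # true efficiency averaged over each full integration window
    e_frame <- (cum_e(b) - cum_e(a)) / sched$t_on

    structure(list(time_s = starts[orange],
                  donor = donor, acceptor = acceptor,
                  alex_time_s = starts[!orange], alex = alex_a,
                  beta = beta, gamma = gamma,
                  frame_interval = sched$frame_interval,
                  t_on = sched$t_on,
                  true_efret = e_frame[orange],
                  bleach_time_donor = td, bleach_time_acceptor = ta,
                  path = path, photo = photo, seed = seed),
              class = "fret_trace")
  })
}

#' Draw residence times from an exponential mixture
#'
#' Each dwell is drawn by first choosing a mixture component with
#' probability `fractions[i]`, then drawing an exponential with mean
#' `taus[i]` - the generative inverse of a bi-exponential residence-time
#' fit.
#'
#' @param n number of dwells, >= 1.
#' @param params a [binding_params()].
#' @param seed integer seed or `NULL`.
#' @return Numeric vector of `n` durations (s).
#' @export
simulate_dwell_times <- function(n, params, seed = NULL) {
  stopifnot(inherits(params, "binding_params"))
  if (n < 1) stop("n must be >= 1")
  with_seed(seed, {
    comp <- sample.int(length(params$taus), n, replace = TRUE,
                       prob = params$fractions)
    stats::rexp(n, rate = 1) * params$taus[comp]
  })
}

#' Simulate a colocalization binding trace
#'
#' Generates an alternating dark/bright timeline (dark intervals exponential
#' with rate `k_on_app`; bright intervals from the residence-time mixture)
#' and renders it to framewise counts: each frame reports the unit intensity
#' times the fraction of the integration window spent bound, plus camera
#' noise. The ground-truth timeline is returned alongside.
#'
#' @param duration trace length (s); should exceed several mean dwells.
#' @param params a [binding_params()].
#' @param frame_time frame interval (s).
#' @param photo a [photophysics()]; `total_intensity` is the bound-state
#'   unit intensity.
#' @param seed integer seed or `NULL`.
#' @return A `binding_trace`: list with `time_s`, `counts`, `frame_time`,
#'   `photo`, and `truth` (an [event_timeline()]).
#' @export
simulate_binding_trace <- function(duration, params, frame_time = 0.1003,
                                   photo = photophysics(), seed = NULL) {
  stopifnot(inherits(params, "binding_params"), duration > 0, frame_time > 0)
  if (frame_time >= min(params$taus))
    warning("frame_time >= shortest tau: discretization will censor events")
  with_seed(seed, {
    segs <- list(); t_now <- 0; state <- "dark"
    while (t_now < duration) {
      len <- if (state == "dark") {
        if (params$k_on_app == 0) Inf else stats::rexp(1, params$k_on_app)
      } else {
        simulate_dwell_times(1, params)
      }
      len <- min(len, duration - t_now)
      segs[[length(segs) + 1L]] <- list(state = state, start = t_now,
                                        duration = len)
      t_now <- t_now + len
      state <- if (state == "dark") "bright" else "dark"
    }
    truth <- event_timeline(
      state = vapply(segs, `[[`, "", "state"),
      start_s = vapply(segs, `[[`, 0, "start"),
      duration_s = vapply(segs, `[[`, 0, "duration"))

    n_frames <- floor(duration / frame_time)
    a <- (seq_len(n_frames) - 1) * frame_time
    b <- a + frame_time
    # fraction of each frame spent bright, via the cumulative bright time
    brk <- c(truth$start_s, duration)
    is_bright <- as.numeric(truth$state == "bright")
    ci <- c(0, cumsum(is_bright * diff(brk)))
    cum_bright <- function(t) stats::approx(brk, ci, xout = pmin(pmax(t, 0),
                                            duration), rule = 2)$y
    frac <- (cum_bright(b) - cum_bright(a)) / frame_time
    clean <- photo$total_intensity * frac
    v <- photo$excess_noise_factor * clean + photo$background_sd^2
    counts <- clean + photo$background_mean
    pos <- v > 0
    if (any(pos)) counts[pos] <- counts[pos] +
      stats::rnorm(sum(pos), 0, sqrt(v[pos]))
    structure(list(time_s = a, counts = counts, frame_time = frame_time,
                   photo = photo, truth = truth, seed = seed),
              class = "binding_trace")
  })
}

#' Simulate FRAP recovery curves
#'
#' Generates raw bleached-ROI and unbleached reference-ROI intensity series.
#' On the normalized scale the ground-truth recovery is
#' `R(t) = (1 - immobile_fraction) * (1 - exp(-t / tau))`; the raw bleached
#' ROI additionally carries the bleach drop and acquisition photobleaching,
#' and the reference ROI decays with `acquisition_bleach_rate` only, so that
#' [frap_normalize()] recovers `R(t)` exactly in the noiseless limit.
#'
#' @param params a [frap_params()].
#' @param n_curves number of curves (e.g. bleached centromeres).
#' @param n_pre pre-bleach frames, >= 1.
#' @param n_post post-bleach frames, >= 2 (first frame is t = 0, the bleach
#'   floor).
#' @param seed integer seed or `NULL`.
#' @return List of `frap_curve` objects with fields `t` (s, bleach at 0),
#'   `bleach_roi`, `reference_roi`, and the generating `params`.
#' @export
simulate_frap_curves <- function(params, n_curves = 20, n_pre = 5,
                                 n_post = 200, seed = NULL) {
  stopifnot(inherits(params, "frap_params"), n_pre >= 1, n_post >= 2)
  dt <- params$frame_interval
  t_pre <- -rev(seq_len(n_pre)) * dt
  t_post <- (seq_len(n_post) - 1) * dt
  t_all <- c(t_pre, t_post)
  elapsed <- t_all - t_all[1]
  I0 <- 100
  with_seed(seed, {
    lapply(seq_len(n_curves), function(i) {
      R <- (1 - params$immobile_fraction) * (1 - exp(-t_post / params$tau))
      base <- c(rep(1, n_pre), (1 - params$bleach_depth) +
                  params$bleach_depth * R)
      decay <- exp(-params$acquisition_bleach_rate * elapsed)
      bleach <- I0 * base * decay
      ref <- I0 * decay
      if (params$noise_sd > 0) {
        bleach <- bleach + stats::rnorm(length(t_all), 0, params$noise_sd * I0)
        ref <- ref + stats::rnorm(length(t_all), 0, params$noise_sd * I0)
      }
      structure(list(t = t_all, bleach_roi = bleach, reference_roi = ref,
                     params = params),
                class = "frap_curve")
    })
  })
}
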