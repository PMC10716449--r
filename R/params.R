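#' Kinetic scheme for conformational dynamics
#'
#' Defines a continuous-time Markov model of chromatin conformational states,
#' each with a mean FRET efficiency. The off-diagonal entries of `rates` are
#' transition rates in 1/s; the diagonal is ignored. A symmetric two-state
#' scheme with exchange rates `k12 = k21 = k` has relaxation time
#' `tau_R = 1/(k12 + k21)`, the quantity reported by donor-acceptor
#' cross-correlation analysis.
#'
#' @param state_labels character vector of state names.
#' @param efret_means numeric vector of true FRET efficiencies in \[0, 1\],
#'   one per state.
#' @param rates square numeric matrix of transition rates (1/s); entry
#'   `[i, j]` is the rate from state i to state j. Diagonal ignored.
#' @return An object of class `kinetic_scheme`.
#' @examples
#' two_state_scheme(0.1, 0.5, k12 = 0.296, k21 = 0.296)
#' @export
kinetic_scheme <- function(state_labels, efret_means, rates) {
  n <- length(state_labels)
  stopifnot(n >= 1, length(efret_means) == n)
  if (any(efret_means < 0 | efret_means > 1))
    stop("efret_means must lie in [0, 1]")
  rates <- as.matrix(rates)
  if (!all(dim(rates) == c(n, n)))
    stop("rates must be a ", n, "x", n, " matrix")
  off <- rates; diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal rates must be >= 0")
  structure(list(state_labels = as.character(state_labels),
                 efret_means = as.numeric(efret_means),
                 rates = rates),
            class = "kinetic_scheme")
}

#' Symmetric or asymmetric two-state scheme
#'
#' Convenience constructor for the open/compacted two-state model.
#'
#' @param e_low,e_high mean FRET efficiencies of the two states.
#' @param k12 rate from state 1 to 2 (1/s).
#' @param k21 rate from state 2 to 1 (1/s); default `k12`.
#' @return A `kinetic_scheme` with two states.
#' @export
two_state_scheme <- function(e_low = 0.1, e_high = 0.5, k12 = 0.296,
                             k21 = k12) {
  kinetic_scheme(c("open", "compact"), c(e_low, e_high),
                 matrix(c(0, k12, k21, 0), 2, 2, byrow = TRUE))
}

#' Analytic relaxation time of a two-state scheme
#'
#' @param scheme a two-state `kinetic_scheme`.
#' @return `1 / (k12 + k21)` in seconds.
#' @export
relaxation_time <- function(scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            length(scheme$state_labels) == 2L)
  1 / (scheme$rates[1, 2] + scheme$rates[2, 1])
}

#' Stationary distribution of a kinetic scheme
#'
#' Solves `pi Q = 0` with `sum(pi) = 1` for the generator built from the
#' off-diagonal rates. States with no exit and no entry share mass uniformly
#' within their communicating structure via the least-squares solution.
#'
#' @param scheme a `kinetic_scheme`.
#' @return numeric vector of stationary probabilities.
#' @export
stationary_distribution <- function(scheme) {
  n <- length(scheme$state_labels)
  if (n == 1L) return(1)
  Q <- scheme$rates
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  p <- as.numeric(qr.solve(A, b))
  p[p < 0 & p > -1e-12] <- 0
  p / sum(p)
}

#' Camera illumination schedule
#'
#' Frame timing and channel interleaving of a TIRF acquisition. The default
#' mirrors a typical alternating acquisition: 100 ms integration, 0.3 ms
#' inter-frame gap, cycles of 99 orange frames followed by 1 far-red frame,
#' repeated 40 times.
#'
#' @param t_on camera integration time per frame (s).
#' @param t_off inter-frame gap (s).
#' @param cycle character vector of channel tags, one per frame of the cycle.
#' @param n_repeats number of cycle repeats.
#' @return An `illumination_schedule` with derived frame start times and tags.
#' @export
illumination_schedule <- function(t_on = 0.1, t_off = 3e-4,
                                  cycle = c(rep("orange", 99), "farred"),
                                  n_repeats = 40) {
  stopifnot(t_on > 0, t_off >= 0, length(cycle) >= 1, n_repeats >= 1)
  tags <- rep(cycle, n_repeats)
  n <- length(tags)
  starts <- (seq_len(n) - 1) * (t_on + t_off)
  structure(list(t_on = t_on, t_off = t_off, cycle = cycle,
                 n_repeats = n_repeats, frame_tags = tags,
                 frame_starts = starts,
                 frame_interval = t_on + t_off,
                 duration = n * (t_on + t_off)),
            class = "illumination_schedule")
}

#' Dye photophysics and camera noise parameters
#'
#' `total_intensity` is the mean detected counts per frame for an unbleached
#' molecule. Camera noise is approximated as Gaussian with variance
#' `excess_noise_factor * signal + background_sd^2`, an EM-CCD-style model
#' adequate at the count levels the selection criteria require (thousands of
#' counts). Bleaching is single-step and irreversible with exponential times;
#' an infinite rate means the dye is pre-bleached.
#'
#' @param total_intensity mean counts/frame for an unbleached molecule.
#' @param bleach_rate_donor,bleach_rate_acceptor bleach rates (1/s); 0
#'   disables bleaching, `Inf` pre-bleaches the dye.
#' @param background_mean,background_sd background level and read-noise SD
#'   (counts).
#' @param excess_noise_factor multiplicative excess-noise factor applied to
#'   the signal-dependent variance (dimensionless).
#' @return A `photophysics` parameter object.
#' @export
photophysics <- function(total_intensity = 3000,
                         bleach_rate_donor = 0,
                         bleach_rate_acceptor = 0,
                         background_mean = 0, background_sd = 0,
                         excess_noise_factor = 0) {
  stopifnot(total_intensity > 0, bleach_rate_donor >= 0,
            bleach_rate_acceptor >= 0, background_sd >= 0,
            excess_noise_factor >= 0)
  structure(list(total_intensity = total_intensity,
                 bleach_rate_donor = bleach_rate_donor,
                 bleach_rate_acceptor = bleach_rate_acceptor,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 excess_noise_factor = excess_noise_factor),
            class = "photophysics")
}

#' Binding-kinetics parameters
#'
#' Generative model of a colocalization timeline: dark (unbound) intervals are
#' exponential with apparent on-rate `k_on_app`; bright (bound) intervals are
#' drawn from a mixture of exponentials with amplitudes `fractions` and
#' residence-time constants `taus` (ascending), the generative inverse of a
#' bi-exponential residence-time fit.
#'
#' @param k_on_app apparent on-rate (1/s).
#' @param fractions mixture weights, summing to 1.
#' @param taus residence-time constants (s), strictly positive and strictly
#'   increasing.
#' @return A `binding_params` object.
#' @export
binding_params <- function(k_on_app = 0.02, fractions = c(0.5, 0.5),
                           taus = c(6.9, 61)) {
  stopifnot(k_on_app >= 0, length(fractions) == length(taus))
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (any(taus <= 0) || any(diff(taus) <= 0))
    stop("taus must be strictly positive and strictly increasing")
  structure(list(k_on_app = k_on_app, fractions = as.numeric(fractions),
                 taus = as.numeric(taus)),
            class = "binding_params")
}

#' FRAP generative parameters
#'
#' Recovery on the normalized scale is
#' `R(t) = (1 - immobile_fraction) * (1 - exp(-t / tau))`. The raw bleached
#' region of interest (ROI) carries a bleach drop of depth `bleach_depth`;
#' an unbleached reference ROI decays with `acquisition_bleach_rate`, the
#' photobleaching induced by imaging itself, which double normalization must
#' remove. Defaults put 200 post-bleach frames at 7.3 s spacing, i.e. a
#' roughly 24-minute observation window with a 5-frame pre-bleach baseline.
#'
#' @param tau recovery time constant (s).
#' @param immobile_fraction fraction of signal that never recovers, in
#'   \[0, 1\].
#' @param bleach_depth fraction of the signal removed by the bleach pulse,
#'   in (0, 1\].
#' @param frame_interval time between frames (s).
#' @param acquisition_bleach_rate imaging-induced bleach rate (1/s) applied
#'   to both ROIs.
#' @param noise_sd Gaussian noise SD as a fraction of the pre-bleach
#'   intensity.
#' @return A `frap_params` object.
#' @export
frap_params <- function(tau = 971, immobile_fraction = 0.43,
                        bleach_depth = 0.8, frame_interval = 7.3,
                        acquisition_bleach_rate = 2e-4, noise_sd = 0.03) {
  stopifnot(tau > 0, immobile_fraction >= 0, immobile_fraction <= 1,
            bleach_depth > 0, bleach_depth <= 1, frame_interval > 0,
            acquisition_bleach_rate >= 0, noise_sd >= 0)
  structure(list(tau = tau, immobile_fraction = immobile_fraction,
                 bleach_depth = bleach_depth,
                 frame_interval = frame_interval,
                 acquisition_bleach_rate = acquisition_bleach_rate,
                 noise_sd = noise_sd),
            class = "frap_params")
}

# Run code with a locally set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}
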