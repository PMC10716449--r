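# shared fixtures, all built in code

# orange-only schedule of n frames at the standard 100 ms / 0.3 ms timing
orange_schedule <- function(n_frames) {
  illumination_schedule(t_on = 0.1, t_off = 3e-4,
                        cycle = rep("orange", n_frames), n_repeats = 1)
}

# standard ALEX acquisition: cycles of 99 orange + 1 far-red frame
alex_schedule <- function(n_repeats = 20) {
  illumination_schedule(n_repeats = n_repeats)
}

# static single-state scheme at a fixed efficiency
static_scheme <- function(e) kinetic_scheme("s", e, matrix(0, 1, 1))

# camera model with realistic counts and noise
noisy_photo <- function(total_intensity = 3000, bleach_d = 0, bleach_a = 0)
  photophysics(total_intensity, bleach_rate_donor = bleach_d,
               bleach_rate_acceptor = bleach_a, background_mean = 100,
               background_sd = 30, excess_noise_factor = 1)

# render one trace from a scheme under a schedule
sim_trace <- function(scheme, sched, photo, seed, beta = 0.071,
                      gamma = 0.463) {
  path <- simulate_ctmc(scheme, sched$duration + 1, seed = seed)
  render_fret_trace(path, photo, sched, beta = beta, gamma = gamma,
                    seed = seed + 7e5)
}

# widely separated spot grid for movie fixtures
spot_grid <- function(n, lim = c(10, 110), per_row = 5, farred = 5000,
                      orange = 3000) {
  xs <- rep(seq(lim[1], lim[2], length.out = per_row),
            ceiling(n / per_row))[1:n]
  ys <- rep(seq(lim[1], lim[2], length.out = ceiling(n / per_row)),
            each = per_row)[1:n]
  lapply(seq_len(n), function(i)
    list(x = xs[i], y = ys[i], farred = farred, orange = orange))
}
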