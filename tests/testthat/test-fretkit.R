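test_that("corrected efficiency formula hits its anchor values", {
  expect_equal(compute_efret(1000, 0.071 * 1000), 0)
  expect_equal(compute_efret(0, 800), 1)
  expect_equal(compute_efret(1000, 571), 500 / 963, tolerance = 1e-12)
  expect_true(is.na(compute_efret(0, 0)))
})

test_that("beta and gamma are recovered from calibration traces", {
  sched <- alex_schedule(20)
  donor_only <- lapply(1:15, function(i)
    sim_trace(static_scheme(0), sched, noisy_photo(), seed = i))
  bleach <- lapply(1:25, function(i)
    sim_trace(static_scheme(0.5), sched,
              noisy_photo(bleach_a = 0.02), seed = 100 + i))
  est <- estimate_corrections(donor_only, bleach, background = 100)
  expect_equal(est$beta, 0.071, tolerance = 0.005 / 0.071)
  expect_equal(est$gamma, 0.463, tolerance = 0.02 / 0.463)
  # zero bleed-through rendering estimates near zero
  d0 <- lapply(1:15, function(i)
    sim_trace(static_scheme(0), sched, noisy_photo(), seed = 200 + i,
              beta = 0))
  expect_lt(abs(estimate_corrections(d0, bleach,
                                     background = 100)$beta), 0.005)
})

test_that("bleach-step detection locates single and double steps", {
  set.seed(1)
  one <- c(rep(1000, 300), rep(10, 200)) + stats::rnorm(500, 0, 30)
  s <- detect_bleach_steps(one)
  expect_equal(nrow(s), 1)
  expect_lt(abs(s$index - 301), 2)
  expect_equal(nrow(detect_bleach_steps(stats::rnorm(500, 1000, 30))), 0)
  two <- c(rep(2000, 200), rep(1000, 200), rep(10, 100)) +
    stats::rnorm(500, 0, 30)
  expect_equal(detect_bleach_steps(two)$index, c(201, 401), tolerance = 2)
})

test_that("ALEX validation passes 1D/1A and fails wrong dye counts", {
  sched <- alex_schedule(20)
  ph <- noisy_photo(bleach_d = 0.015, bleach_a = 0.015)
  # a compliant fixture must keep both dyes alive past the first
  # direct-excitation frame (10 s into the 99-orange/1-far-red cycle)
  tr <- NULL
  for (s in 40:80) {
    cand <- sim_trace(static_scheme(0.5), sched, ph, seed = s)
    if (min(cand$bleach_time_donor, cand$bleach_time_acceptor) > 15 &&
        max(cand$bleach_time_donor, cand$bleach_time_acceptor) < 180) {
      tr <- cand
      break
    }
  }
  expect_true(isTRUE(validate_alex(tr)))
  # acceptor absent
  tr_na <- sim_trace(static_scheme(0.5), sched,
                     noisy_photo(bleach_d = 0.015, bleach_a = Inf),
                     seed = 43)
  expect_false(isTRUE(validate_alex(tr_na)))
  # two donors: summed trace has double intensity and two donor steps
  t1 <- sim_trace(static_scheme(0.5), sched, ph, seed = 44)
  t2 <- sim_trace(static_scheme(0.5), sched, ph, seed = 45)
  tt <- t1
  tt$donor <- t1$donor + t2$donor - 100
  tt$acceptor <- t1$acceptor + t2$acceptor - 100
  tt$alex <- t1$alex + t2$alex - 100
  tt$bleach_time_donor <- NULL; tt$bleach_time_acceptor <- NULL
  expect_false(isTRUE(validate_alex(tt)))
})

test_that("trace selection applies the intensity and duration criteria", {
  sched <- alex_schedule(20)
  ph <- noisy_photo(bleach_d = 0.015, bleach_a = 0.015)
  ok <- 0
  for (i in 1:12) {
    tr <- sim_trace(static_scheme(0.5), sched, ph, seed = 300 + i)
    first <- min(tr$bleach_time_donor, tr$bleach_time_acceptor)
    s <- apply_selection(tr)
    if (first > 5 && first < 190 && s$status == "accepted") ok <- ok + 1
    if (first < 4.5 && min(tr$bleach_time_donor,
                           tr$bleach_time_acceptor) > 0)
      expect_equal(s$reason, "pre-bleach-duration")
  }
  expect_gte(ok, 6)
  # dim molecule: initial total 1500 counts
  dim_tr <- sim_trace(static_scheme(0.5), sched,
                      photophysics(1500, bleach_rate_donor = 0.015,
                                   bleach_rate_acceptor = 0.015,
                                   background_mean = 100,
                                   background_sd = 30,
                                   excess_noise_factor = 1), seed = 7)
  expect_equal(apply_selection(dim_tr)$reason, "intensity")
})

test_that("histograms are per-trace normalized and conserve mass", {
  h1 <- build_histogram(list(rep(0.50, 200)), min_length_s = 0)
  expect_equal(sum(h1$mean_density), 1, tolerance = 1e-9)
  expect_equal(h1$mean_density[h1$mid > 0.50 & h1$mid < 0.52], 1)
  # equal per-trace weight despite unequal lengths
  h2 <- build_histogram(list(rep(0.11, 1000), rep(0.51, 10)),
                        min_length_s = 0)
  expect_equal(h2$mean_density[h2$mid > 0.10 & h2$mid < 0.12], 0.5)
  expect_equal(h2$mean_density[h2$mid > 0.50 & h2$mid < 0.52], 0.5)
  # mode lands at the generating center
  set.seed(8)
  e <- stats::rnorm(1e4, 0.44, 0.07)
  h3 <- build_histogram(split(e, rep(1:20, each = 500)), min_length_s = 0)
  expect_lt(abs(h3$mid[which.max(h3$mean_density)] - 0.44), 0.021)
  expect_equal(sum(h3$mean_density), 1, tolerance = 1e-9)
})

test_that("repeat averaging reports SD and ignores empty repeats", {
  r1 <- list(rep(0.3, 100), rep(0.32, 100))
  r2 <- list(rep(0.3, 100))
  h <- build_histogram(list(r1, r2), min_length_s = 0)
  expect_equal(h$n_repeats, 2)
  h_with_empty <- build_histogram(list(r1, r2, list()), min_length_s = 0)
  expect_equal(h_with_empty$mean_density, h$mean_density)
})

test_that("mixture fit recovers isolated and paired components", {
  edges <- seq(-0.1, 1.1, by = 0.02)
  mid <- edges[-length(edges)] + 0.01
  base <- build_histogram(list(rep(0.5, 100)), min_length_s = 0)
  # single printed-form component, fitted with k = 2
  base$mean_density <- exp(-((mid - 0.57) / 0.1)^2)
  fm <- fit_mixture(base, k = 2)
  main <- which.max(fm$components$A)
  expect_equal(fm$components$c[main], 0.57, tolerance = 0.01 / 0.57)
  expect_lt(min(fm$components$A), 0.01)
  # value at the center of an isolated component equals its amplitude
  expect_equal(fm$components$A[main] *
                 exp(-((0.57 - fm$components$c[main]) /
                         fm$components$sigma[main])^2),
               fm$components$A[main], tolerance = 1e-6)
  # two well-separated components from sampled data
  for (s in 1:5) {
    set.seed(400 + s)
    e <- c(stats::rnorm(5000, 0.05, 0.04), stats::rnorm(5000, 0.57, 0.07))
    h <- build_histogram(split(e, rep(1:20, 500)), min_length_s = 0)
    f2 <- fit_mixture(h, k = 2)
    expect_lt(abs(f2$components$c[1] - 0.05), 0.02)
    expect_lt(abs(f2$components$c[2] - 0.57), 0.02)
  }
})

test_that("traces sort into dynamic and static high/low classes", {
  sched <- orange_schedule(598)
  ph <- noisy_photo()
  expect_equal(classify_trace(sim_trace(static_scheme(0.5), sched, ph,
                                        seed = 1)), "static_high")
  expect_equal(classify_trace(sim_trace(static_scheme(0.05), sched, ph,
                                        seed = 2)), "static_low")
  sch <- two_state_scheme(0.1, 0.5, k12 = 1 / (2 * 1.7))
  cl <- vapply(1:100, function(i)
    classify_trace(sim_trace(sch, sched, ph, seed = 500 + i)),
    character(1))
  expect_gte(mean(cl == "dynamic"), 0.9)
})

test_that("classification is monotone in the FRET contrast", {
  sched <- orange_schedule(598)
  ph <- noisy_photo()
  frac_dyn <- function(de) {
    sch <- two_state_scheme(0.1, 0.1 + de, k12 = 1 / (2 * 1.7))
    mean(vapply(1:40, function(i)
      classify_trace(sim_trace(sch, sched, ph, seed = 700 + i)),
      character(1)) == "dynamic")
  }
  f <- vapply(c(0.05, 0.2, 0.4), frac_dyn, numeric(1))
  expect_true(all(diff(f) >= 0))
})

test_that("static traces with independent noise show no cross-correlation", {
  sched <- orange_schedule(598)
  traces <- lapply(1:30, function(i)
    sim_trace(static_scheme(0.5), sched, noisy_photo(), seed = 800 + i))
  cc <- cross_correlate(traces, gate = 0.2, max_lag_s = 5)
  expect_lt(max(abs(cc$cc)), 0.05)
  expect_lt(cc$amplitude, 0.05)
})

test_that("sub-frame relaxation times are flagged unresolvable", {
  sch <- two_state_scheme(0.1, 0.5, k12 = 1 / (2 * 0.05))
  sched <- orange_schedule(598)
  traces <- lapply(1:40, function(i)
    sim_trace(sch, sched, noisy_photo(), seed = 900 + i))
  cc <- cross_correlate(traces, gate = 0.2, max_lag_s = 5)
  expect_false(isTRUE(cc$resolvable) && cc$amplitude > 0.1)
})
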