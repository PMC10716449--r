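test_that("background subtraction removes constant offsets and keeps zeros", {
  m <- matrix(250, 40, 40)
  expect_lt(max(abs(subtract_background(m, 8))), 1)
  z <- matrix(0, 40, 40)
  expect_equal(subtract_background(z, 8), z)
})

test_that("spot amplitude survives subtraction of a tilted-plane background", {
  mv <- render_movie(list(list(x = 20, y = 22, orange = 4000)), c(48, 48),
                     "orange", psf_sigma_px = 1.1,
                     photo = photophysics(4000), seed = 1)
  plane <- outer(seq(0, 30, length.out = 48), seq(0, 20, length.out = 48),
                 `+`)
  fr <- mv$stack$frames[, , 1] + plane + 50
  sub <- subtract_background(fr, 8)
  f <- fit_spot_gaussian(sub, 20, 22)
  expect_true(f$fit_ok)
  expect_equal(f$amplitude, 4000, tolerance = 0.05)
})

test_that("Gaussian fit localizes a noiseless spot to 1e-3 px", {
  mv <- render_movie(list(list(x = 14.37, y = 9.81, orange = 2000)),
                     c(32, 32), "orange", psf_sigma_px = 1.2,
                     photo = photophysics(2000), seed = 1)
  f <- fit_spot_gaussian(mv$stack$frames[, , 1], 14, 10)
  expect_lt(abs(f$x - 14.37), 1e-3)
  expect_lt(abs(f$y - 9.81), 1e-3)
  expect_equal(f$sigma, 1.2, tolerance = 1e-3)
})

test_that("a flat window yields fit_ok = FALSE, off-frame windows reject", {
  fr <- matrix(100, 32, 32)
  expect_false(fit_spot_gaussian(fr, 15, 15)$fit_ok)
  expect_false(fit_spot_gaussian(fr, 1, 1)$fit_ok)
})

test_that("localization error stays below 0.1 px RMS at SNR 10", {
  ph <- photophysics(3000, background_mean = 100, background_sd = 30,
                     excess_noise_factor = 1)
  errs <- vapply(1:50, function(i) {
    mv <- render_movie(list(list(x = 15.3, y = 16.7, orange = 3000)),
                       c(32, 32), "orange", psf_sigma_px = 1.1,
                       photo = ph, seed = 100 + i)
    f <- fit_spot_gaussian(subtract_background(mv$stack$frames[, , 1], 8),
                           15, 17)
    sqrt((f$x - 15.3)^2 + (f$y - 16.7)^2)
  }, numeric(1))
  expect_lt(sqrt(mean(errs^2)), 0.1 * sqrt(2))
})

test_that("spot detection finds all spots with no false positives", {
  ph <- photophysics(5000, background_mean = 200, background_sd = 30,
                     excess_noise_factor = 1)
  spots <- spot_grid(20)
  for (i in 1:10) {
    mv <- render_movie(spots, c(120, 120), "farred", psf_sigma_px = 1.1,
                       photo = ph, seed = 200 + i)
    det <- detect_spots(subtract_background(mv$stack$frames[, , 1], 8),
                        min_separation_px = 4, threshold_sd = 5)
    expect_equal(nrow(det), 20)
    # every detection matches a true spot within 0.5 px
    d <- vapply(seq_len(nrow(det)), function(k)
      min(sqrt((det$x[k] - mv$registry$x)^2 +
                 (det$y[k] - mv$registry$y)^2)), numeric(1))
    expect_lt(max(d), 0.5)
  }
})

test_that("blank noise frames yield at most rare false positives", {
  n_fp <- 0
  for (i in 1:20) {
    set.seed(300 + i)
    fr <- matrix(stats::rnorm(120^2, 0, 30), 120, 120)
    n_fp <- n_fp + nrow(detect_spots(fr, 4, threshold_sd = 5))
  }
  expect_lte(n_fp / 20, 0.1)
})

test_that("two spots 8 sigma apart are both recovered accurately", {
  sp <- list(list(x = 30, y = 30, orange = 3000),
             list(x = 30 + 8 * 1.1, y = 30, orange = 3000))
  ph <- photophysics(3000, background_mean = 100, background_sd = 25,
                     excess_noise_factor = 1)
  mv <- render_movie(sp, c(64, 64), "orange", psf_sigma_px = 1.1,
                     photo = ph, seed = 5)
  det <- detect_spots(subtract_background(mv$stack$frames[, , 1], 8), 4, 5)
  expect_equal(nrow(det), 2)
  errs <- vapply(1:2, function(k)
    min(sqrt((det$x - sp[[k]]$x)^2 + (det$y - sp[[k]]$y)^2)), numeric(1))
  expect_lt(max(errs), 0.2)
})

test_that("affine registration is exact on exact data and honest on noise", {
  src <- cbind(c(5, 40, 12, 33, 20, 8), c(7, 9, 35, 30, 18, 25))
  tf_id <- estimate_transform(src, src)
  expect_equal(unclass(tf_id)[, 1:2], diag(2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_lt(attr(tf_id, "residual_rms"), 1e-12)
  th <- 1 * pi / 180
  M <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  dst <- t(M %*% t(src)) + matrix(c(3.2, -1.7), 6, 2, byrow = TRUE)
  tf <- estimate_transform(src, dst)
  expect_equal(unclass(tf), cbind(M, c(3.2, -1.7)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(apply_transform(tf, src), dst, tolerance = 1e-9,
               ignore_attr = TRUE)
  set.seed(1)
  dst_j <- dst + matrix(stats::rnorm(12, 0, 0.1), 6, 2)
  expect_equal(attr(estimate_transform(src, dst_j), "residual_rms"), 0.1,
               tolerance = 0.6)
  expect_error(estimate_transform(src[1:2, ], dst[1:2, ]), ">= 3")
  col <- cbind(1:5, 2 * (1:5))
  expect_error(estimate_transform(col, col), "collinear")
})

test_that("drift estimation recovers zero, linear and step drift", {
  ph <- photophysics(5000, background_mean = 200, background_sd = 25,
                     excess_noise_factor = 1)
  spots <- spot_grid(12)
  tags <- rep(c(rep("orange", 9), "farred"), 10)
  # zero drift
  mv0 <- render_movie(spots, c(120, 120), tags, photo = ph, seed = 31)
  off0 <- correct_drift(mv0$stack)
  expect_lt(max(abs(off0)), 0.075)
  # linear drift 0.05 px/frame in x
  dr <- cbind(0.05 * (0:99), 0)
  mv1 <- render_movie(spots, c(120, 120), tags, drift_path = dr,
                      photo = ph, seed = 32)
  off1 <- correct_drift(mv1$stack)
  ref1 <- which(tags == "farred")[1]
  slope <- stats::coef(stats::lm(off1[ref1:100, 1] ~ seq(ref1, 100)))[2]
  expect_equal(unname(slope), 0.05, tolerance = 0.1)
  expect_lt(max(abs(off1[, 2])), 0.1)
  # 2 px step between cycles 5 and 6
  drs <- cbind(c(rep(0, 50), rep(2, 50)), 0)
  mv2 <- render_movie(spots, c(120, 120), tags, drift_path = drs,
                      photo = ph, seed = 33)
  off2 <- correct_drift(mv2$stack)
  ref_idx <- which(tags == "farred")
  at_refs <- off2[ref_idx, 1]
  expect_lt(max(abs(at_refs - (drs[ref_idx, 1] - drs[ref_idx[1], 1]))),
            0.3)
})

test_that("aperture extraction matches the rendering within pixelation", {
  mv <- render_movie(list(list(x = 20, y = 24, orange = 3000)), c(48, 48),
                     "orange", psf_sigma_px = 1.0,
                     photo = photophysics(3000), seed = 1)
  tr <- extract_traces(mv$stack, cbind(20, 24), radius_px = 3)
  # analytic in-aperture counts from the pixel-integrated PSF
  grid <- expand.grid(r = 17:31, c = 13:27)
  grid <- grid[(grid$r - 24)^2 + (grid$c - 20)^2 <= 9 + 1e-9, ]
  px <- pnorm((grid$c + 0.5 - 20)) - pnorm((grid$c - 0.5 - 20))
  py <- pnorm((grid$r + 0.5 - 24)) - pnorm((grid$r - 0.5 - 24))
  expect_equal(tr[1, 1], 3000 * sum(px * py), tolerance = 0.02)
})

test_that("empty-field extraction sums the background and flags edges", {
  ph <- photophysics(1000, background_mean = 50, background_sd = 5)
  mv <- render_movie(list(), c(40, 40), rep("orange", 20), photo = ph,
                     seed = 2)
  tr <- extract_traces(mv$stack, cbind(20, 20), radius_px = 2)
  npix <- sum((rep(-2:2, 5))^2 + (rep(-2:2, each = 5))^2 <= 4)
  expect_equal(mean(tr), npix * 50, tolerance = 0.05)
  # radius 0: a single pixel
  tr0 <- extract_traces(mv$stack, cbind(20, 20), radius_px = 0)
  expect_equal(mean(tr0), 50, tolerance = 0.2)
  tre <- extract_traces(mv$stack, cbind(1, 20), radius_px = 3)
  expect_true(attr(tre, "edge_clipped")[1])
})

test_that("Chung-Kennedy filter preserves steps and suppresses noise", {
  expect_equal(ck_filter(rep(7, 100), 8), rep(7, 100))
  step <- c(rep(0, 50), rep(1000, 50))
  fs <- ck_filter(step, 8, 2)
  expect_lt(max(abs(fs - step)), 1000 * 0.01)   # no overshoot, sharp edge
  set.seed(4)
  x <- stats::rnorm(1000)
  expect_lt(stats::var(ck_filter(x, 8, 2)), 0.25 * stats::var(x))
  # idempotent on noiseless piecewise-constant traces
  pc <- c(rep(100, 40), rep(600, 40), rep(50, 40))
  f1 <- ck_filter(pc, 8)
  expect_equal(ck_filter(f1, 8), f1)
  expect_error(ck_filter(1:10, 8), "longer")
})

test_that("render/detect/extract pipeline recovers molecules end to end", {
  ph <- photophysics(5000, background_mean = 200, background_sd = 30,
                     excess_noise_factor = 1)
  spots <- spot_grid(20)
  tags <- rep(c(rep("orange", 9), "farred"), 10)
  mv <- render_movie(spots, c(120, 120), tags, psf_sigma_px = 1.1,
                     photo = ph, seed = 41)
  st <- subtract_background(mv$stack, 8)
  det <- detect_spots(st$frames[, , which(tags == "farred")[1]], 4, 5)
  expect_gte(nrow(det), 19)                      # >= 95 percent recovered
  tr <- extract_traces(st, as.matrix(det[, c("x", "y")]), radius_px = 3,
                       channel = "orange", local_background = "annulus")
  capture <- 1 - exp(-9 / (2 * 1.1^2))
  expect_lt(max(abs(colMeans(tr) / (3000 * capture) - 1)), 0.1)
})
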