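mk_stack <- function(frames, px = 32.25, dt = 2.4) {
  arr <- array(unlist(frames), dim = c(nrow(frames[[1]]), ncol(frames[[1]]),
                                       length(frames)))
  image_stack(arr, px, dt)
}

test_that("histogram-matching bleach correction restores scaled frames", {
  set.seed(1)
  f0 <- matrix(runif(900, 50, 500), 30, 30)
  st <- mk_stack(list(f0, f0, 0.5 * f0, f0 * 0 + 3))
  bc <- bleach_correct(st)
  expect_equal(bc$frames[, , 2], f0)                       # identical frame
  expect_equal(bc$frames[, , 3], f0, tolerance = 1e-12)    # rank-exact undo
  expect_equal(bc$frames[, , 4], f0 * 0 + 3)               # constant: identity
  # quantile agreement after correction of a nonlinear distortion
  st2 <- mk_stack(list(f0, sqrt(f0) * 10))
  bc2 <- bleach_correct(st2)
  q0 <- quantile(f0, probs = seq(0.01, 0.99, length.out = 256))
  q1 <- quantile(bc2$frames[, , 2], probs = seq(0.01, 0.99, length.out = 256))
  expect_lt(max(abs(q0 - q1)), diff(range(f0)) / 256)
})

test_that("signal extraction is exact on constant stacks and linear in intensity", {
  st <- mk_stack(list(matrix(7, 40, 40), matrix(7, 40, 40), matrix(7, 40, 40)))
  cs <- core_set(data.frame(id = 1:2, x_nm = c(400, 800), y_nm = c(400, 800)))
  sig <- extract_signals(st, cs)
  expect_true(all(sig$signals == 7))
  st2 <- st; st2$frames <- st2$frames * 2
  expect_equal(extract_signals(st2, cs)$signals, 2 * sig$signals)
  expect_error(extract_signals(st, cs, radius_nm = 1), "no pixel centers")
})

test_that("extracted signals track the generator's truth signals", {
  lay <- manual_layout(1500, 1500, radius_nm = 100, base_intensity = 100,
                       field_size_nm = c(3000, 3000))
  o <- osc_spec(noise_sd_fraction = 0, n_frames = 40)
  mv <- simulate_movie(lay, o, noise = NULL, seed = 2)
  sig <- extract_signals(mv$stack, core_table(lay))
  expect_gt(cor(sig$signals[1, ], mv$truth$signals[1, ]), 0.99)
})

test_that("pairwise synchrony matches analytic correlations and affine invariance", {
  tt <- seq(0, 159, by = 2.4)
  s1 <- sin(2 * pi * tt / 40)
  sm <- structure(list(ids = 1:3, x_nm = c(0, 500, 1000), y_nm = c(0, 0, 0),
                       signals = rbind(s1, s1, -s1), dt_s = 2.4),
                  class = "signal_matrix")
  syn <- pairwise_synchrony(sm, detrend = FALSE)
  expect_equal(syn$pearson_r[syn$core_i == 1 & syn$core_j == 2], 1, tolerance = 1e-12)
  expect_equal(syn$pearson_r[syn$core_i == 1 & syn$core_j == 3], -1, tolerance = 1e-12)
  expect_equal(syn$distance_nm, c(500, 1000, 500))
  # per-core gain/offset leaves r unchanged
  sm2 <- sm; sm2$signals <- sm$signals * c(3, 0.5, 10) + c(100, -40, 7)
  expect_equal(pairwise_synchrony(sm2, detrend = FALSE)$pearson_r,
               syn$pearson_r, tolerance = 1e-9)
  # zero-variance signals are excluded and counted
  sm3 <- sm; sm3$signals[2, ] <- 5
  syn3 <- pairwise_synchrony(sm3, detrend = FALSE)
  expect_equal(attr(syn3, "n_excluded"), 2)
  expect_equal(nrow(syn3), 1)
})

test_that("synchrony curve recovers an exponential half-decay", {
  set.seed(3)
  d <- runif(4000, 0, 5000)
  lambda <- 800
  tab <- structure(data.frame(core_i = 1, core_j = 2, distance_nm = d,
                              pearson_r = exp(-d / lambda)),
                   class = c("synchrony_table", "data.frame"))
  sc <- synchrony_curve(tab, bin_width_nm = 100)
  expect_lt(abs(sc$half_decay_nm - lambda * log(2)), 100)
  # flat curve at r = 1: no half-decay
  tab1 <- tab; tab1$pearson_r <- 1
  expect_true(is.na(synchrony_curve(tab1, 100)$half_decay_nm))
})

test_that("spectra satisfy Parseval and isolate planted tones", {
  tt <- (0:166) * 2.4
  x <- 3 * sin(2 * pi * 0.04 * tt + 1)
  sp <- signal_spectrum(x, 2.4)
  expect_equal(length(sp$magnitude), 84)
  top <- order(sp$magnitude, decreasing = TRUE)
  expect_lt(abs(sp$frequency_hz[top[1]] - 0.04), 1 / (167 * 2.4))
  expect_gt(sp$magnitude[top[1]], 10 * max(sp$magnitude[-top[1:2]]))
  # constant signal: all magnitudes vanish after detrending
  expect_true(all(signal_spectrum(rep(5, 32), 1)$magnitude < 1e-9))
  # Parseval for the detrended signal
  y <- rnorm(64)
  spy <- signal_spectrum(y, 1, detrend = FALSE)
  full <- Mod(fft(y - mean(y)))
  expect_equal(sum(full^2) / 64, sum((y - mean(y))^2), tolerance = 1e-6)
})

test_that("natural frequencies are scale-invariant relative detections", {
  tt <- (0:166) * 2.4
  set.seed(4)
  x <- 1 + 0.3 * sin(2 * pi * 0.04 * tt + 1) + rnorm(167, 0, 0.05)
  f1 <- natural_frequencies(signal_spectrum(x, 2.4))
  f2 <- natural_frequencies(signal_spectrum(1000 * x, 2.4))
  expect_equal(f1, f2)
  expect_equal(length(f1), 1)
  expect_lt(abs(f1 - 0.04), 1 / (167 * 2.4))
})

test_that("unsmoothed rate movies telescope exactly", {
  set.seed(5)
  frames <- lapply(1:6, function(i) matrix(runif(400, 0, 100), 20, 20))
  st <- mk_stack(frames)
  rm0 <- rate_movie(st, gaussian_radius_nm = 0, temporal_window = 1)
  total <- apply(rm0$rates, c(1, 2), sum)
  expect_equal(total, frames[[6]] - frames[[1]], tolerance = 1e-9)
  # static stack: all-zero rates even with smoothing
  sts <- mk_stack(lapply(1:4, function(i) frames[[1]]))
  expect_true(all(rate_movie(sts)$rates == 0))
})

test_that("planted growth and decay discs are segmented with correct sign", {
  set.seed(6)
  H <- 80; W <- 80; px <- 32.25
  disc <- function(r0, c0, rad) {
    outer(1:H, 1:W, function(r, c) (r - r0)^2 + (c - c0)^2 <= rad^2)
  }
  g <- disc(25, 20, 6); d <- disc(55, 60, 6)
  frames <- lapply(0:3, function(t)
    matrix(rnorm(H * W, 50, 0.5), H, W) + t * (10 * g - 10 * d))
  st <- mk_stack(frames, px = px)
  rm <- rate_movie(st, gaussian_radius_nm = 0, temporal_window = 1)
  seg <- segment_rate_clusters(rm, z_thresh = 3, min_area_um2 = 0.02)
  fr1 <- seg$regions[seg$regions$frame == 1, ]
  expect_equal(sum(fr1$class == "growing"), 1)
  expect_equal(sum(fr1$class == "decreasing"), 1)
  grow <- fr1[fr1$class == "growing", ]
  expect_lt(abs(grow$centroid_x_nm - (20 - 1) * px), 2 * px)
  expect_lt(abs(grow$centroid_y_nm - (25 - 1) * px), 2 * px)
  # zero rate map: nothing segmented
  rm0 <- rm; rm0$rates[] <- 0
  expect_equal(nrow(segment_rate_clusters(rm0)$regions), 0)
})

test_that("kymographs have one row per pixel step and track signals", {
  lay <- manual_layout(1500, 1500, radius_nm = 100, base_intensity = 100,
                       field_size_nm = c(3000, 3000))
  mv <- simulate_movie(lay, osc_spec(noise_sd_fraction = 0, n_frames = 30),
                       noise = NULL, seed = 7)
  pl <- rbind(c(500, 1500), c(2500, 1500))    # horizontal line through the core
  ky <- kymograph(mv$stack, pl, width_nm = 100)
  expect_equal(nrow(ky$pixels), floor(2000 / mv$stack$pixel_size_nm) + 1)
  expect_equal(ncol(ky$pixels), 30)
  row_core <- which.min(abs(seq(0, 2000, by = mv$stack$pixel_size_nm) - 1000))
  expect_gt(cor(ky$pixels[row_core, ], mv$truth$signals[1, ]), 0.99)
  # static stack: identical columns
  sts <- mk_stack(lapply(1:3, function(i) mv$stack$frames[, , 1]))
  kys <- kymograph(sts, pl)
  expect_equal(kys$pixels[, 1], kys$pixels[, 3])
  expect_error(kymograph(mv$stack, rbind(c(100, 100), c(100, 100))), "degenerate")
})
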