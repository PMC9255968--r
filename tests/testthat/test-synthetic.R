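test_that("layouts are deterministic in the seed and respect the hard core", {
  p <- layout_params(field_size_nm = c(6000, 6000), n_islets = 5,
                     islet_radius_nm = 600, cores_per_islet_mean = 6,
                     hard_core_nm = 250, seed = 11)
  a <- make_layout(p)
  b <- make_layout(p)
  expect_identical(a, b)
  expect_gt(nrow(a$cores), 0)
  # brute-force all-pairs separation oracle
  d <- as.matrix(dist(cbind(a$cores$x_nm, a$cores$y_nm)))
  diag(d) <- Inf
  expect_gte(min(d), 250)
  # every core belongs to exactly one existing islet and lies in the field
  expect_true(all(a$cores$islet_id %in% a$islets$islet_id))
  expect_true(all(a$cores$x_nm >= 0 & a$cores$x_nm <= 6000 &
                  a$cores$y_nm >= 0 & a$cores$y_nm <= 6000))
})

test_that("empty and infeasible layouts are handled explicitly", {
  p0 <- layout_params(n_islets = 0, seed = 1)
  lay <- make_layout(p0)
  expect_equal(nrow(lay$cores), 0)
  expect_equal(nrow(lay$islets), 0)
  expect_error(make_layout(layout_params(field_size_nm = c(2000, 2000),
                                         n_islets = 10, islet_radius_nm = 900,
                                         cores_per_islet_mean = 20,
                                         hard_core_nm = 400, seed = 1)),
               "unsatisfiable density")
  expect_error(layout_params(hard_core_nm = 2000, islet_radius_nm = 500),
               "hard_core_nm")
})

test_that("rendering an empty layout gives pure background", {
  lay <- make_layout(layout_params(n_islets = 0, field_size_nm = c(3000, 3000),
                                   seed = 2))
  img <- render_frame(lay, noise = NULL, background = 50)
  expect_true(all(img$pixels == 50))
  img_n <- render_frame(lay, noise = noise_model(poisson = TRUE, read_sd = 5),
                        background = 50)
  expect_lt(abs(mean(img_n$pixels) - 50), 1)
})

test_that("a noise-free spot has its peak at the core and analytic mass", {
  lay <- manual_layout(2000.0, 2000.0, radius_nm = 100, base_intensity = 80)
  img <- render_frame(lay, noise = NULL, background = 10)
  am <- which(img$pixels == max(img$pixels), arr.ind = TRUE)
  px <- img$pixel_size_nm
  expect_equal(unname((am[1, 2] - 1) * px), 2000, tolerance = px / 2)
  expect_equal(unname((am[1, 1] - 1) * px), 2000, tolerance = px / 2)
  mass <- sum(img$pixels - 10)
  analytic <- 80 * 2 * pi * 100^2 / px^2
  expect_equal(mass, analytic, tolerance = 0.01)
})

test_that("rendered mass is linear in base intensity", {
  lay1 <- manual_layout(c(1200, 2800), c(1500, 2500), base_intensity = 50)
  lay2 <- lay1
  lay2$cores$base_intensity <- 100
  i1 <- render_frame(lay1, noise = NULL, background = 0)
  i2 <- render_frame(lay2, noise = NULL, background = 0)
  expect_equal(sum(i2$pixels) / sum(i1$pixels), 2, tolerance = 1e-9)
})

test_that("movie truth follows the phase model", {
  lay <- make_layout(layout_params(field_size_nm = c(6000, 6000), n_islets = 4,
                                   islet_radius_nm = 400, cores_per_islet_mean = 4,
                                   hard_core_nm = 250, seed = 3))
  # zero amplitude, zero noise: every frame identical
  o0 <- osc_spec(components = data.frame(frequency_hz = 0.04, amplitude = 0),
                 noise_sd_fraction = 0, n_frames = 5)
  mv0 <- simulate_movie(lay, o0, noise = NULL, seed = 1)
  expect_equal(mv0$stack$frames[, , 1], mv0$stack$frames[, , 5])
  # global phases, one component: all truth signals perfectly correlated
  og <- osc_spec(components = data.frame(frequency_hz = 0.04, amplitude = 0.3),
                 phase_model = "global", noise_sd_fraction = 0, n_frames = 20)
  mvg <- simulate_movie(lay, og, noise = NULL, seed = 1)
  cc <- cor(t(mvg$truth$signals))
  expect_true(all(abs(cc - 1) < 1e-12))
  # determinism of the full movie
  mvg2 <- simulate_movie(lay, og, noise = NULL, seed = 1)
  expect_identical(mvg$stack$frames, mvg2$stack$frames)
})

test_that("independent phases leave mean signed truth correlation near zero", {
  lay <- make_layout(layout_params(field_size_nm = c(20000, 20000), n_islets = 40,
                                   islet_radius_nm = 400, cores_per_islet_mean = 5,
                                   hard_core_nm = 250, seed = 5))
  oi <- osc_spec(phase_model = "independent", noise_sd_fraction = 0)
  mv <- simulate_movie(lay, oi, noise = NULL, seed = 5,
                       pixel_size_nm = 200)   # coarse render; truth is the target
  cc <- cor(t(mv$truth$signals))
  expect_gt(nrow(mv$truth$signals), 150)
  expect_lt(abs(mean(cc[upper.tri(cc)])), 0.1)
})

test_that("simulated localization heights follow the protein spec", {
  lay <- make_layout(layout_params(seed = 4))
  # degenerate precision and no slope: z collapses onto the mean
  pr0 <- protein_spec("test", "core_centered", axial_mean_nm = 100,
                      localization_precision_nm = 1e-9)
  l0 <- simulate_localizations(lay, pr0, 200, seed = 1)
  expect_true(all(abs(l0$z_nm - 100) < 1e-6))
  # paxillin-like cloud: median recovered within 1 nm at n = 5000
  pr <- protein_spec("paxillin", "ring_at_offset_nm", axial_mean_nm = 139,
                     localization_precision_nm = 15)
  l1 <- simulate_localizations(lay, pr, 5000, seed = 2)
  expect_lt(abs(median(l1$z_nm) - 139), 1)
  # core-centered clouds sit closer to cores than 300 nm rings
  prc <- protein_spec("core", "core_centered", lateral_sd_nm = 100)
  prr <- protein_spec("ring", "ring_at_offset_nm", offset_nm = 300,
                      lateral_sd_nm = 30)
  lc <- simulate_localizations(lay, prc, 1000, seed = 3)
  lr <- simulate_localizations(lay, prr, 1000, seed = 3)
  nn_dist <- function(l) {
    sapply(seq_len(nrow(l)), function(k)
      min(sqrt((lay$cores$x_nm - l$x_nm[k])^2 + (lay$cores$y_nm - l$y_nm[k])^2)))
  }
  expect_lt(mean(nn_dist(lc)), mean(nn_dist(lr)))
})

test_that("ground-truth manifests round-trip", {
  lay <- make_layout(layout_params(n_islets = 4, field_size_nm = c(5000, 5000),
                                   seed = 9))
  dir <- withr::local_tempdir()
  write_layout(lay, dir)
  lay2 <- read_layout(dir)
  expect_equal(lay2$cores, lay$cores, tolerance = 1e-12)
  expect_equal(lay2$islets, lay$islets, tolerance = 1e-12)
  expect_equal(unclass(lay2$params), unclass(lay$params), tolerance = 1e-12)
})

test_that("calibrated TIFF round-trips preserve intensities and calibration", {
  img <- image2d(matrix(runif(400, 10, 500), 20, 20), 32.25, "actin")
  f <- withr::local_tempfile(fileext = ".tif")
  write_image_tiff(img, f)
  img2 <- read_image_tiff(f)
  expect_equal(img2$pixels, img$pixels, tolerance = 1e-6)
  expect_equal(img2$pixel_size_nm, 32.25)
  expect_equal(img2$channel, "actin")
  st <- image_stack(array(runif(20 * 20 * 3, 0, 900), c(20, 20, 3)), 64.5, 2.4)
  fs <- withr::local_tempfile(fileext = ".tif")
  write_stack_tiff(st, fs)
  st2 <- read_stack_tiff(fs)
  expect_equal(st2$frames, st$frames, tolerance = 1e-6)
  expect_equal(st2$dt_s, 2.4)
})
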