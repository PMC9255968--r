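test_that("belt angle follows the principal axis of the neighborhood", {
  xs <- seq(0, 3000, by = 300)
  horiz <- core_set(data.frame(id = seq_along(xs), x_nm = xs, y_nm = 0 * xs))
  ba <- local_belt_angle(horiz, neighborhood_radius_nm = 2000)
  expect_true(all(abs(ba$angle_deg) < 1e-6))
  expect_false(any(ba$low_confidence))
  th <- 30
  rot <- core_set(data.frame(id = seq_along(xs),
                             x_nm = xs * cos(th * pi / 180),
                             y_nm = xs * sin(th * pi / 180)))
  ba30 <- local_belt_angle(rot, neighborhood_radius_nm = 2000)
  expect_true(all(abs(ba30$angle_deg - 30) < 1))
  # equivariance mod 180: rotating by 75 degrees shifts all angles by 75
  th2 <- 75 * pi / 180
  rot2 <- core_set(data.frame(id = seq_along(xs),
                              x_nm = xs * cos(th * pi / 180 + th2),
                              y_nm = xs * sin(th * pi / 180 + th2)))
  ba2 <- local_belt_angle(rot2, neighborhood_radius_nm = 2000)
  expect_true(all(abs(((ba2$angle_deg - ba30$angle_deg - 75) %% 180 + 90) %% 180 - 90) < 1))
})

# belt of cores along x with a ring marker; returns images + cores
belt_fixture <- function(ring_offset_nm = 300, noise = NULL) {
  x <- seq(1500, 6500, by = 500)
  lay <- manual_layout(x, rep(2000, length(x)), radius_nm = 100,
                       base_intensity = 100, field_size_nm = c(8000, 4000))
  actin <- render_frame(lay, noise = noise, background = 10)
  marker <- render_frame(lay, protein_spec("vinculin", "ring_at_offset_nm",
                                           offset_nm = ring_offset_nm,
                                           lateral_sd_nm = 50),
                         noise = noise, background = 10)
  list(lay = lay, actin = actin, edge = edge_transform(actin), marker = marker,
       cores = core_table(lay))
}

test_that("line profiles are centered on cores and channel-faithful", {
  fx <- belt_fixture()
  pr <- extract_line_profiles(fx$actin, fx$edge, fx$actin, fx$cores,
                              angles_deg = rep(0, nrow(fx$cores)))
  # marker channel fed with the actin image: identical profiles
  a <- pr[pr$channel == "actin", ]
  m <- pr[pr$channel == "marker", ]
  expect_equal(a$intensity, m$intensity)
  # center sample equals the width-averaged intensity at the centroid
  ctr <- a[a$position_nm == 0 & a$orientation == "longitudinal" & a$core_id == 6, ]
  ps <- radial_profiles(fx$actin, c(fx$cores$x_nm[6], fx$cores$y_nm[6]),
                        length_nm = 100)
  expect_equal(ctr$intensity, ps$intensity[1, 1], tolerance = 1e-9)
})

test_that("ring markers produce flanking peaks around the actin core", {
  fx <- belt_fixture(ring_offset_nm = 300)
  pr <- extract_line_profiles(fx$actin, fx$edge, fx$marker, fx$cores,
                              angles_deg = rep(0, nrow(fx$cores)))
  m6 <- pr[pr$channel == "marker" & pr$core_id == 6 &
           pr$orientation == "transverse", ]
  m6 <- m6[order(m6$position_nm), ]
  pk_left <- m6$position_nm[which.max(m6$intensity[m6$position_nm < 0])]
  right <- m6[m6$position_nm > 0, ]
  pk_right <- right$position_nm[which.max(right$intensity)]
  expect_lt(abs(abs(pk_left) - 300), 70)
  expect_lt(abs(pk_right - 300), 70)
})

test_that("cores clipped by the border are excluded and counted", {
  lay <- manual_layout(c(300, 2000), c(2000, 2000), radius_nm = 100)
  actin <- render_frame(lay, noise = NULL, background = 10)
  pr <- extract_line_profiles(actin, edge_transform(actin), actin,
                              core_table(lay), angles_deg = c(0, 0))
  expect_equal(attr(pr, "n_clipped"), 1)
  expect_equal(unique(pr$core_id), 2)
})

test_that("normalized pooled profiles are invariant to intensity scaling", {
  fx <- belt_fixture()
  pr <- extract_line_profiles(fx$actin, fx$edge, fx$marker, fx$cores,
                              angles_deg = rep(0, nrow(fx$cores)))
  np <- normalize_and_pool(pr)
  expect_true(all(np$intensity >= 0 & np$intensity <= 1, na.rm = TRUE))
  # doubling all image intensities changes nothing
  dbl <- function(img) image2d(img$pixels * 2, img$pixel_size_nm, img$channel)
  pr2 <- extract_line_profiles(dbl(fx$actin), dbl(fx$edge), dbl(fx$marker),
                               fx$cores, angles_deg = rep(0, nrow(fx$cores)))
  np2 <- normalize_and_pool(pr2)
  expect_equal(np2$intensity, np$intensity, tolerance = 1e-9)
  expect_equal(attr(np2, "median_radius_nm"), attr(np, "median_radius_nm"),
               tolerance = 1e-9)
})

test_that("pooled actin half-width sits at the Gaussian half-maximum ratio", {
  # cores with radii 80/100/120: the edge-estimated unit is the spot sigma,
  # so the actin half-maximum falls near sqrt(2 ln 2) = 1.18 units
  x <- seq(2000, 8000, by = 1500)
  lay <- manual_layout(x, rep(2500, length(x)),
                       radius_nm = rep(c(80, 100, 120), length.out = length(x)),
                       base_intensity = 100, field_size_nm = c(10000, 5000))
  actin <- render_frame(lay, noise = NULL, background = 0)
  pr <- extract_line_profiles(actin, edge_transform(actin), actin,
                              core_table(lay), angles_deg = rep(0, length(x)))
  np <- normalize_and_pool(pr, pool_orientations = TRUE)
  a <- np[np$channel == "actin", ]
  a <- a[order(a$position_units), ]
  pos <- a$position_units[a$position_units >= 0 & !is.na(a$intensity)]
  val <- a$intensity[a$position_units >= 0 & !is.na(a$intensity)]
  half_width <- pos[min(which(val <= 0.5))]
  expect_lt(abs(half_width - sqrt(2 * log(2))), 0.35)
})

test_that("profile extraction is consistent under a 90-degree rotation", {
  fx <- belt_fixture()
  rot90 <- function(img) image2d(t(img$pixels)[ncol(img$pixels):1, ],
                                 img$pixel_size_nm, img$channel)
  H_nm <- (nrow(fx$actin$pixels) - 1) * fx$actin$pixel_size_nm
  cores_rot <- core_set(data.frame(id = fx$cores$id,
                                   x_nm = H_nm - fx$cores$y_nm,
                                   y_nm = fx$cores$x_nm))
  pr <- extract_line_profiles(fx$actin, fx$edge, fx$marker, fx$cores,
                              angles_deg = rep(0, nrow(fx$cores)))
  pr_rot <- extract_line_profiles(rot90(fx$actin), rot90(fx$edge),
                                  rot90(fx$marker), cores_rot,
                                  angles_deg = rep(90, nrow(fx$cores)))
  common <- intersect(unique(pr$core_id), unique(pr_rot$core_id))
  a <- pr[pr$core_id %in% common & pr$orientation == "longitudinal" &
          pr$channel == "actin", ]
  b <- pr_rot[pr_rot$core_id %in% common & pr_rot$orientation == "longitudinal" &
              pr_rot$channel == "actin", ]
  expect_equal(nrow(a), nrow(b))
  expect_lt(max(abs(a$intensity - b$intensity)), 0.02 * max(a$intensity))
})

test_that("actin-marker correlation recovers planted per-core intensities", {
  fx <- belt_fixture()
  cm <- core_marker_correlation(fx$actin, fx$actin, fx$cores)
  expect_equal(cm$pearson_r, 1, tolerance = 1e-12)
  flat <- image2d(matrix(5, nrow(fx$actin$pixels), ncol(fx$actin$pixels)),
                  fx$actin$pixel_size_nm)
  expect_true(is.na(core_marker_correlation(fx$actin, flat, fx$cores)$pearson_r))
  # planted correlated intensities, isolated cores, noise-free imaging
  set.seed(8)
  n <- 24
  gx <- rep(seq(2500, 17500, length.out = 6), 4)
  gy <- rep(seq(2500, 14000, length.out = 4), each = 6)
  base <- rnorm(n, 100, 15)
  mbase <- 0.8 * base + 0.6 * rnorm(n, 0, 15) + 20
  la <- manual_layout(gx, gy, radius_nm = 100, base_intensity = base,
                      field_size_nm = c(20000, 16500))
  lm <- manual_layout(gx, gy, radius_nm = 100, base_intensity = mbase,
                      field_size_nm = c(20000, 16500))
  ia <- render_frame(la, noise = NULL, background = 10)
  im <- render_frame(lm, noise = NULL, background = 10)
  got <- core_marker_correlation(ia, im, core_table(la))$pearson_r
  expect_lt(abs(got - cor(base, mbase)), 0.05)
})

test_that("islet segmentation recovers planted top-hat rings", {
  px <- 32.25
  H <- 250; W <- 250
  xg <- outer(rep(1, H), (1:W - 1) * px)
  yg <- outer((1:H - 1) * px, rep(1, W))
  ring <- function(cx, cy, r_in, r_out) {
    d <- sqrt((xg - cx)^2 + (yg - cy)^2)
    d >= r_in & d <= r_out
  }
  m <- 100 * (ring(2000, 2000, 700, 900) | ring(5500, 5500, 900, 1100))
  adh <- image2d(m, px)
  cs <- core_set(data.frame(
    id = 1:10,
    x_nm = c(1800, 2000, 2200, 5100, 5300, 5500, 5700, 5900, 5500, 5500),
    y_nm = c(2000, 2200, 1900, 5500, 5500, 5100, 5700, 5500, 5900, 5300)))
  seg <- segment_islets(adh, cs, min_area_um2 = 0.2)
  expect_equal(nrow(seg$islets), 2)
  expect_setequal(seg$islets$n_cores, c(3, 7))
  a_small <- seg$islets$area_um2[seg$islets$n_cores == 3]
  a_big <- seg$islets$area_um2[seg$islets$n_cores == 7]
  expect_lt(abs(a_small - pi * 0.7^2) / (pi * 0.7^2), 0.1)
  expect_lt(abs(a_big - pi * 0.9^2) / (pi * 0.9^2), 0.1)
  expect_lte(sum(seg$islets$n_cores), nrow(cs))
  # no adhesion signal: zero islets
  seg0 <- segment_islets(image2d(matrix(0, H, W), px), cs)
  expect_equal(nrow(seg0$islets), 0)
})
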