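test_that("spots are detected with subpixel accuracy at high SNR", {
  spots <- data.frame(nucleus = c(1, 1, 2, 2, 3),
                      r = c(0.2, 0.7, 0.4, 0.85, 0.55),
                      azimuth = c(0.3, 2.5, 1.2, 4.4, 5.5))
  sp <- phantom_spec(n_nuclei = 3, spots = spots, seed = 19,
                     spot_amplitude = 400,
                     noise = list(photon_scale = 1, sigma = 4))
  ph <- generate_fish_phantom(sp)
  det <- detect_spots(ph$field, "fish", ph$truth$nuclei, snr_min = 3)
  expect_equal(nrow(det), 5)
  for (k in seq_len(nrow(det))) {
    err <- min(sqrt((ph$truth$spots$y_um - det$y_um[k])^2 +
                      (ph$truth$spots$x_um - det$x_um[k])^2))
    expect_lte(err, 0.5 * 0.2)   # 0.5 px at 0.2 um/px
  }
})

test_that("a blank channel yields an empty SpotSet", {
  ph <- generate_nucleus_phantom(
    phantom_spec(n_nuclei = 1, seed = 3, noise = noiseless))
  f <- ph$field
  f$channels$fish <- array(5, dim = f$dim)
  det <- detect_spots(f, "fish", ph$truth$nuclei)
  expect_equal(nrow(det), 0)
})

test_that("spots outside all nuclei are discarded", {
  img <- array(10, c(120, 120))
  nucm <- disk_mask(120, 30, 60, 60)
  img[nucm] <- 60
  fish <- array(10, c(120, 120))
  yy <- matrix(seq_len(120) - 0.5, 120, 120); xx <- t(yy)
  fish <- fish + 300 * exp(-((yy - 60)^2 + (xx - 60)^2) / (2 * 1.5^2)) +
    300 * exp(-((yy - 15)^2 + (xx - 110)^2) / (2 * 1.5^2))  # outside
  f <- image_field(list(dna = img, fish = fish), 0.2)
  nuc <- label_map(nucm * 1L)
  det <- detect_spots(f, "fish", nuc)
  expect_equal(nrow(det), 1)
  expect_equal(det$nucleus_id, 1L)
})

test_that("relative radial position matches disk geometry", {
  mask <- disk_mask(240, 100)          # R = 100 px
  px <- 0.1
  ctr <- c(120, 120) * px
  expect_equal(relative_radial_position(ctr, mask, NULL, px), 0)
  r40 <- relative_radial_position(c(120, 120 + 40) * px, mask, NULL, px)
  expect_equal(r40, 0.40, tolerance = 0.02)
  rb <- relative_radial_position(c(120, 120 + 99.4) * px, mask, NULL, px)
  expect_equal(rb, 1, tolerance = 0.02)
  expect_error(
    relative_radial_position(c(120, 232) * px, mask, NULL, px),
    "outside")
})

test_that("relative position is invariant under uniform scaling", {
  mask <- disk_mask(160, 60, 70, 90)
  spot <- c(70, 90 + 33)
  r1 <- relative_radial_position(spot * 0.1, mask, NULL, 0.1)
  r2 <- relative_radial_position(spot * 0.5, mask, NULL, 0.5)
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("phantom spots are recovered at their target relative positions", {
  spots <- data.frame(nucleus = 1, r = c(0.1, 0.3, 0.5, 0.7, 0.9),
                      azimuth = c(0.5, 1.7, 2.9, 4.1, 5.3))
  sp <- phantom_spec(field_shape = c(260, 260), n_nuclei = 1,
                     nucleus_radii = c(10, 12), pixel_size = 0.2,
                     spots = spots, seed = 23, noise = noiseless)
  ph <- generate_fish_phantom(sp)      # r_eq >= 50 px
  p <- ph$truth$partitions[[1]]
  for (k in seq_len(nrow(spots))) {
    r <- relative_radial_position(
      unlist(ph$truth$spots[k, c("y_um", "x_um")]), p$full, p$centroid,
      0.2)
    expect_lte(abs(r - spots$r[k]), 0.03)
  }
})

test_that("distance to the nearest focus follows the distance map", {
  n <- 150; px <- 0.2
  # focus: disk of radius 2 um at the center
  fmask <- disk_mask(n, 2 / px)
  foci <- label_map(fmask * 1L)
  ctr <- c(n / 2, n / 2) * px
  expect_equal(distance_to_nearest_focus(ctr, foci, px), 0)
  # spot 5 um from the center: distance D - r = 3 um
  spot <- ctr + c(0, 5)
  expect_equal(distance_to_nearest_focus(spot, foci, px), 3,
               tolerance = 2 * px)
  # two foci: min of the single-focus distances
  fmask2 <- fmask | disk_mask(n, 1 / px, 20, 20)
  both <- label_map((fmask * 1L) + (disk_mask(n, 1 / px, 20, 20) & !fmask) * 2L)
  d_both <- distance_to_nearest_focus(spot, both, px)
  d1 <- distance_to_nearest_focus(spot, label_map(fmask * 1L), px)
  d2 <- distance_to_nearest_focus(
    spot, label_map(disk_mask(n, 1 / px, 20, 20) * 1L), px)
  expect_equal(d_both, min(d1, d2), tolerance = 1e-12)
  # no foci at all: metric absent
  expect_warning(
    d <- distance_to_nearest_focus(spot, label_map(array(0L, c(n, n))), px),
    "no heterochromatic focus")
  expect_true(is.na(d))
})

test_that("distance map agrees with brute force on random configurations", {
  set.seed(99)
  px <- 0.25
  diag_px <- sqrt(2) * px
  for (i in 1:100) {
    n <- 40
    fmask <- matrix(runif(n * n) < 0.01, n, n)
    if (!any(fmask)) fmask[sample(n, 1), sample(n, 1)] <- TRUE
    spot <- runif(2, 1, n - 1) * px
    got <- distance_to_nearest_focus(spot, fmask, px)
    want <- oracle_min_dist(spot, fmask, px)
    expect_lte(abs(got - want), diag_px)
  }
})

test_that("position ECDFs are proper per-condition step functions", {
  one <- data.frame(relative_position = 0.5, condition = "a")
  e1 <- position_ecdf(one)
  expect_equal(e1$r, 0.5)
  expect_equal(e1$F, 1)
  dup <- data.frame(relative_position = c(0.2, 0.2, 0.7, 0.9, 0.9),
                    condition = "a")
  e2 <- position_ecdf(dup)
  expect_true(all(diff(e2$F) > 0))
  expect_equal(max(e2$F), 1)
  expect_equal(e2$F[e2$r == 0.2], 2 / 5)
})

test_that("area-uniform spots in a disk reproduce the F(r) = r^2 law", {
  # place 2000 points uniformly over a disk nucleus and measure r
  mask <- disk_mask(220, 100)
  px <- 0.1
  set.seed(12)
  n <- 2000
  rho <- sqrt(runif(n)) * 98.5   # keep off the boundary pixels
  phi <- runif(n, 0, 2 * pi)
  pts <- cbind(110 + rho * sin(phi), 110 + rho * cos(phi)) * px
  ctr <- colMeans(nucquant:::pixel_centers(dim(mask), c(px, px),
                                           which = which(mask)))
  r <- vapply(seq_len(n), function(k)
    relative_radial_position(pts[k, ], mask, ctr, px), 0)
  ks <- max(abs(vapply(sort(r), function(q) mean(r <= q), 0) - sort(r)^2))
  expect_lte(ks, 0.05)
})
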