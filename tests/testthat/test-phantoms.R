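test_that("marker signal splits between band and interior exactly as specified", {
  for (fp in c(1, 0.5)) {
    ph <- generate_nucleus_phantom(
      phantom_spec(n_nuclei = 2, peripheral_fraction = fp, seed = 11,
                   noise = noiseless))
    for (p in ph$truth$partitions) {
      mk <- ph$field$channels$marker
      got <- sum(mk[p$band]) / sum(mk[p$full])
      # band mask comes from the same partition op, so recovery is exact
      expect_equal(got, fp, tolerance = 1e-10)
    }
  }
})

test_that("noiseless marker channel conserves the per-nucleus total", {
  sp <- phantom_spec(n_nuclei = 3, peripheral_fraction = 0.35, seed = 2,
                     noise = noiseless, marker_level = 80)
  ph <- generate_nucleus_phantom(sp)
  mk <- ph$field$channels$marker
  for (p in ph$truth$partitions)
    expect_equal(sum(mk[p$full]), 80 * sum(p$full), tolerance = 1e-9)
})

test_that("same spec and seed give bit-identical phantoms", {
  sp <- phantom_spec(n_nuclei = 2, seed = 33)
  a <- generate_nucleus_phantom(sp)
  b <- generate_nucleus_phantom(sp)
  expect_identical(a$field$channels, b$field$channels)
  expect_identical(a$truth$nuclei$labels, b$truth$nuclei$labels)
})

test_that("noise stream is independent of the geometry stream", {
  sp1 <- phantom_spec(n_nuclei = 2, seed = 33, noise_seed = 1L)
  sp2 <- phantom_spec(n_nuclei = 2, seed = 33, noise_seed = 2L)
  a <- generate_nucleus_phantom(sp1)
  b <- generate_nucleus_phantom(sp2)
  expect_identical(a$truth$nuclei$labels, b$truth$nuclei$labels)
  expect_false(identical(a$field$channels$dna, b$field$channels$dna))
})

test_that("spec invariants are enforced", {
  expect_error(phantom_spec(peripheral_fraction = 1.2), "\\[0, 1\\]")
  expect_error(phantom_spec(focus_radius = -1), "positive")
  expect_error(phantom_spec(focus_gain = 0.5), "gains")
  expect_error(phantom_spec(spots = data.frame(nucleus = 1, r = 1.4,
                                               azimuth = 0)),
               "\\[0, 1\\]")
  expect_error(phantom_spec(n_nuclei = 2,
                            spots = data.frame(nucleus = 3, r = 0.5,
                                               azimuth = 0)),
               "must exist")
  # nuclei that cannot fit without overlap
  expect_error(generate_nucleus_phantom(
    phantom_spec(field_shape = c(64, 64), n_nuclei = 6,
                 nucleus_radii = c(5, 5), pixel_size = 0.2, seed = 1)),
    "placement failure")
})

test_that("FISH spots land at their analytic ground-truth positions", {
  # r* = 0 sits at the centroid; on a circular nucleus r* = 0.5 sits at
  # half the radius from the centroid
  sp <- phantom_spec(field_shape = c(200, 200), n_nuclei = 1,
                     nucleus_radii = c(10, 10), pixel_size = 0.2,
                     spots = data.frame(nucleus = c(1, 1), r = c(0, 0.5),
                                        azimuth = c(0, 2)),
                     seed = 8, noise = noiseless)
  ph <- generate_fish_phantom(sp)
  expect_equal(nrow(ph$truth$spots), 2)
  p <- ph$truth$partitions[[1]]
  d0 <- sqrt(sum((unlist(ph$truth$spots[1, c("y_um", "x_um")]) -
                    p$centroid)^2))
  d5 <- sqrt(sum((unlist(ph$truth$spots[2, c("y_um", "x_um")]) -
                    p$centroid)^2))
  expect_lt(d0, 0.2)          # at the centroid (within one pixel)
  expect_equal(d5, 5, tolerance = 0.05)  # half of the 10 um radius
})

test_that("adhesion phantom ground truth matches the requested geometry", {
  sp <- phantom_spec(field_shape = c(256, 256), n_nuclei = 1,
                     n_adhesions = 12, adhesion_radius = 1,
                     seed = 5, noise = noiseless)
  ph <- generate_adhesion_phantom(sp)
  expect_equal(ph$truth$adhesions$n, 12)
  expect_equal(nrow(ph$truth$adhesion_table), 12)
  # pixel-counted punctum area vs analytic pi r^2 (radius 5 px)
  expect_equal(mean(ph$truth$adhesion_table$area_um2), pi * 1^2,
               tolerance = 0.05)
  # zero-adhesion phantom: adhesion channel has no puncta above cytoplasm
  sp0 <- phantom_spec(field_shape = c(128, 128), n_nuclei = 1,
                      n_adhesions = 0, cell_radius = 8, seed = 5,
                      noise = noiseless)
  ph0 <- generate_adhesion_phantom(sp0)
  inside <- ph0$truth$cells$labels > 0
  expect_equal(diff(range(ph0$field$channels$adhesion[inside])), 0)
})

test_that("two-condition experiments are reproducible and labeled", {
  ctrl <- phantom_spec(n_nuclei = 2, peripheral_fraction = 0.6)
  pert <- phantom_spec(n_nuclei = 2, peripheral_fraction = 0.3)
  expect_error(generate_two_condition_experiment(ctrl, pert, 0), "at least 1")
  a <- generate_two_condition_experiment(ctrl, pert, 2, seed = 77)
  b <- generate_two_condition_experiment(ctrl, pert, 2, seed = 77)
  expect_identical(lapply(a, function(x) x$field$channels),
                   lapply(b, function(x) x$field$channels))
  expect_equal(vapply(a, `[[`, "", "condition"),
               rep(c("control", "perturbed"), each = 2))
  # identical specs in both conditions: true f_p identical (null case)
  nullex <- generate_two_condition_experiment(ctrl, ctrl, 2, seed = 3)
  fps <- vapply(nullex, function(x) unique(x$truth$nuclei_table$f_p), 0)
  expect_true(all(fps == 0.6))
})
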