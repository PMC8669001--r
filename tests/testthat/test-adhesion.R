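test_that("DoG band-pass removes DC, is linear, and peaks at puncta", {
  f <- image_field(list(adhesion = array(7, c(64, 64))), 0.2)
  expect_lt(max(abs(dog_bandpass(f))), 1e-10)
  expect_error(dog_bandpass(f, sigma_low = 1, sigma_high = 0.5),
               "sigma_low < sigma_high")
  set.seed(5)
  i1 <- matrix(runif(64 * 64), 64, 64)
  i2 <- matrix(runif(64 * 64), 64, 64)
  fa <- image_field(list(adhesion = i1), 0.2)
  fb <- image_field(list(adhesion = i2), 0.2)
  fab <- image_field(list(adhesion = 2 * i1 + 3 * i2), 0.2)
  expect_equal(dog_bandpass(fab),
               2 * dog_bandpass(fa) + 3 * dog_bandpass(fb),
               tolerance = 1e-9)
  # single punctum with radius inside the pass band: positive central peak
  img <- array(10, c(80, 80))
  img[disk_mask(80, 3, 40, 40)] <- 100
  resp <- dog_bandpass(image_field(list(adhesion = img), 0.2))
  expect_equal(unname(which(resp == max(resp), arr.ind = TRUE)[1, ]),
               c(40, 40), tolerance = 1)
  expect_gt(resp[40, 40], 0)
})

test_that("adhesion counts are recovered exactly on noiseless phantoms", {
  sp <- phantom_spec(field_shape = c(300, 300), n_nuclei = 2, seed = 21,
                     n_adhesions = 12, noise = noiseless)
  ph <- generate_adhesion_phantom(sp)
  cells <- segment_cells(ph$field)
  expect_equal(cells$n, 2)
  seg <- segment_adhesions(dog_bandpass(ph$field), cells,
                           pixel_size = 0.2)
  expect_equal(as.integer(table(seg$adhesions$host)), rep(12L, 2))
})

test_that("punctum areas are recovered within 20% at moderate SNR", {
  for (r in c(0.8, 1.0)) {   # 4 and 5 px
    sp <- phantom_spec(field_shape = c(300, 300), n_nuclei = 1, seed = 22,
                       n_adhesions = 10, adhesion_radius = r,
                       noise = list(photon_scale = 0, sigma = 40))
    ph <- generate_adhesion_phantom(sp)   # amplitude 200, SNR 5
    cells <- segment_cells(ph$field)
    seg <- segment_adhesions(dog_bandpass(ph$field), cells,
                             pixel_size = 0.2)
    expect_equal(nrow(seg$records), 10)
    expect_lte(abs(mean(seg$records$area_um2) / (pi * r^2) - 1), 0.2)
  }
})

test_that("blank fields and zero-variance cells yield zero adhesions", {
  img <- array(10, c(120, 120))
  img[disk_mask(120, 40)] <- 110
  f <- image_field(list(body = img, adhesion = array(5, c(120, 120))), 0.2)
  cells <- segment_cells(f)
  seg <- segment_adhesions(dog_bandpass(f), cells, pixel_size = 0.2)
  expect_equal(seg$adhesions$n, 0)
  expect_equal(nrow(seg$records), 0)
})

test_that("raising the threshold multiplier shrinks the adhesion pixel set", {
  # the above-threshold pixel set is nested as k grows; counts are
  # non-increasing once puncta are isolated (merged puncta can split)
  sp <- phantom_spec(field_shape = c(256, 256), n_nuclei = 1, seed = 31,
                     n_adhesions = 8, noise = list(photon_scale = 1,
                                                   sigma = 10))
  ph <- generate_adhesion_phantom(sp)
  cells <- segment_cells(ph$field)
  filt <- dog_bandpass(ph$field)
  prev <- NULL
  for (k in c(0.5, 1, 1.5, 2.5, 4, 6)) {
    cur <- segment_adhesions(filt, cells, k, pixel_size = 0.2,
                             min_area = 0)$adhesions$labels > 0
    if (!is.null(prev)) expect_true(all(prev[cur]))
    prev <- cur
  }
  # two isolated puncta: counts non-increasing across thresholds
  img <- array(50, c(120, 120))
  img[disk_mask(120, 4, 40, 40)] <- 250
  img[disk_mask(120, 4, 80, 80)] <- 250
  cellm <- label_map(disk_mask(120, 55, 60, 60) * 1L)
  filt2 <- dog_bandpass(image_field(list(adhesion = img), 0.2))
  counts <- vapply(c(0.5, 1, 1.5, 2.5, 4, 6), function(k)
    nrow(segment_adhesions(filt2, cellm, k, pixel_size = 0.2)$records), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("every adhesion lies inside exactly one cell", {
  sp <- phantom_spec(field_shape = c(300, 300), n_nuclei = 2, seed = 41,
                     n_adhesions = 10)
  ph <- generate_adhesion_phantom(sp)
  cells <- segment_cells(ph$field)
  seg <- segment_adhesions(dog_bandpass(ph$field), cells,
                           pixel_size = 0.2)
  for (id in seq_len(seg$adhesions$n)) {
    sel <- seg$adhesions$labels == id
    owners <- unique(cells$labels[sel])
    expect_length(owners, 1)
    expect_gt(owners, 0)
  }
})

test_that("per-cell summaries count, total and bound correctly", {
  sp <- phantom_spec(field_shape = c(300, 300), n_nuclei = 2, seed = 21,
                     n_adhesions = 12, noise = noiseless)
  ph <- generate_adhesion_phantom(sp)
  cells <- segment_cells(ph$field)
  seg <- segment_adhesions(dog_bandpass(ph$field), cells,
                           pixel_size = 0.2)
  summ <- summarize_cells(seg$records, cells, 0.2)
  expect_equal(sum(summ$adhesion_count), nrow(seg$records))
  expect_true(all(summ$spreading_area_um2 >=
                    summ$total_adhesion_area_um2))
  # a cell with no adhesions still yields a valid all-zero row
  empty <- summarize_cells(seg$records[0, ], cells, 0.2)
  expect_equal(empty$adhesion_count, c(0L, 0L))
  expect_equal(empty$total_adhesion_area_um2, c(0, 0))
  expect_gt(min(empty$spreading_area_um2), 300)
})

test_that("a perturbed condition with fewer/smaller adhesions ranks lower", {
  ctrl <- phantom_spec(field_shape = c(300, 300), n_nuclei = 2,
                       n_adhesions = 15, adhesion_radius = 0.8,
                       cell_radius = 10)
  pert <- phantom_spec(field_shape = c(300, 300), n_nuclei = 2,
                       n_adhesions = 5, adhesion_radius = 0.6,
                       cell_radius = 8)
  ds <- generate_two_condition_experiment(ctrl, pert, 2, seed = 55,
                                          kind = "adhesion")
  summ <- do.call(rbind, lapply(ds, function(d) {
    cells <- segment_cells(d$field)
    seg <- segment_adhesions(dog_bandpass(d$field), cells,
                             pixel_size = 0.2)
    summarize_cells(seg$records, cells, 0.2, condition = d$condition)
  }))
  med <- function(v, cond) median(v[summ$condition == cond])
  expect_lt(med(summ$adhesion_count, "perturbed"),
            med(summ$adhesion_count, "control"))
  expect_lt(med(summ$total_adhesion_area_um2, "perturbed"),
            med(summ$total_adhesion_area_um2, "control"))
  expect_lt(med(summ$spreading_area_um2, "perturbed"),
            med(summ$spreading_area_um2, "control"))
})
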