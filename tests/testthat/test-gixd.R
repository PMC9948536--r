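test_that("Bragg peak fitting recovers positions on clean and noisy profiles", {
  # single noise-free peak
  lat <- index_hexagonal(1.50)
  g <- gen_gixd(lat)
  fit <- fit_bragg_peaks(g$profile$qxy_A1, g$profile$intensity, 1)
  expect_lt(abs(fit$qxy_A1 - 1.50), 1e-4)
  expect_false(fit$weak)
  # flat profile: no peaks
  flat <- fit_bragg_peaks(seq(1.2, 1.8, length.out = 300), rep(4, 300), 2)
  expect_equal(nrow(flat), 0)
  # three overlapping peaks at 2% noise
  lat3 <- lattice2d(4.9, 5.3, 112, tilt = 15, azimuth = 40)
  g3 <- gen_gixd(lat3, noise_frac = 0.02, seed = 17)
  fit3 <- fit_bragg_peaks(g3$profile$qxy_A1, g3$profile$intensity, 3)
  truth_q <- sort(g3$truth$peaks$qxy_A1)
  expect_lt(max(abs(fit3$qxy_A1 - truth_q)), 2e-3)
})

test_that("hexagonal indexing follows the closed-form geometry", {
  lat <- index_hexagonal(1.4894)
  d <- 2 * pi / 1.4894
  expect_equal(lat$a, 2 * d / sqrt(3), tolerance = 1e-12)
  expect_equal(lat$area_chain_A2, sqrt(3) / 2 * lat$a^2, tolerance = 1e-12)
  expect_equal(lat$area_molecule_A2, 2 * lat$area_chain_A2)
  expect_equal(index_hexagonal(1.5)$area_chain_A2, 20.26, tolerance = 1e-3)
  expect_equal(lat$tilt, 0)
  expect_equal(lat$cell_class, "hexagonal")
  # {10}, {01}, {11bar} d spacings are degenerate by construction
  pk <- lattice_peaks(lat)
  expect_lt(diff(range(pk$qxy_A1)), 1e-10)
  expect_error(index_hexagonal(1.5, qz = 0.3), "tilted")
})

test_that("oblique indexing round-trips hexagonal, distorted and oblique truth cells", {
  cells <- list(
    hex = c(4.9, 4.9, 120, 0, 0),
    distorted_nn = c(4.9, 4.9, 118, 12, (180 - 118) / 2),
    oblique = c(4.9, 5.3, 112, 15, 40),
    oblique2 = c(4.55, 4.9, 117, 9, 20)
  )
  for (nm in names(cells)) {
    tr <- cells[[nm]]
    lat <- lattice2d(tr[1], tr[2], tr[3], tr[4], tr[5])
    pk <- lattice_peaks(lat)
    rec <- index_oblique(pk$qxy_A1, pk$qz_A1)
    expect_lt(abs(rec$a - tr[1]) / tr[1], 1e-6)
    expect_lt(abs(rec$b - tr[2]) / tr[2], 1e-6)
    expect_lt(abs(rec$gamma - tr[3]) / tr[3], 1e-6)
    expect_lt(abs(rec$tilt - tr[4]), 1e-4)
    # oracle identity: projected area times cos(tilt) equals chain cross-section
    expect_equal(rec$cross_section_A2,
                 rec$area_chain_A2 * cos(rec$tilt * pi / 180), tolerance = 1e-12)
  }
})

test_that("oblique indexing agrees with hexagonal indexing in the degenerate limit", {
  q <- 1.4894
  hex <- index_hexagonal(q)
  obl <- index_oblique(rep(q, 3), rep(0, 3))
  expect_equal(obl$a, hex$a, tolerance = 1e-9)
  expect_equal(obl$gamma, 120, tolerance = 1e-9)
  expect_equal(obl$tilt, 0, tolerance = 1e-9)
  expect_equal(obl$area_molecule_A2, hex$area_molecule_A2, tolerance = 1e-9)
})

test_that("an inconsistent rod-maximum triple raises an indexing failure", {
  lat <- lattice2d(4.9, 5.3, 112, tilt = 15, azimuth = 40)
  pk <- lattice_peaks(lat)
  bad_qz <- c(0.5, 0.01, 0.5)  # no tilt vector reproduces this pattern
  expect_error(index_oblique(pk$qxy_A1, bad_qz, qz_res_tol = 1e-4),
               "indexing failure")
})

test_that("the tilt-area relation is the cosine projection", {
  expect_equal(tilt_area_relation(21.1, 0), 21.1)
  expect_equal(acos(20.55 / 21.1) * 180 / pi, 13.1, tolerance = 0.05)
  expect_equal(tilt_area_relation(21.1, acos(20.55 / 21.1) * 180 / pi), 20.55,
               tolerance = 1e-9)
  tilts <- seq(0, 60, by = 10)
  areas <- vapply(tilts, function(t) tilt_area_relation(21, t), numeric(1))
  expect_true(all(diff(areas) < 0))
  expect_error(tilt_area_relation(21, 95), "tilt")
})

test_that("peak-count dispatch duplicates the degenerate reflection for 2-peak cells", {
  lat <- lattice2d(4.9, 4.9, 118, tilt = 12, azimuth = (180 - 118) / 2)
  g <- gen_gixd(lat)
  fit <- fit_bragg_peaks(g$profile$qxy_A1, g$profile$intensity, 2)
  qz <- vapply(g$rods, function(r) rod_maximum(r$qz_A1, r$intensity), numeric(1))
  o <- order(g$truth$peaks$qxy_A1)
  rec <- index_peaks(fit, qz[o])
  expect_lt(abs(rec$a - 4.9), 1e-3)
  expect_lt(abs(rec$gamma - 118), 0.05)
  expect_lt(abs(rec$tilt - 12), 0.1)
})

test_that("full fit-then-index round trip meets the noise-free and noisy targets", {
  lat <- lattice2d(4.9, 5.3, 112, tilt = 15, azimuth = 40)
  # noise-free: 1e-4 relative on all cell parameters
  g <- gen_gixd(lat)
  fit <- fit_bragg_peaks(g$profile$qxy_A1, g$profile$intensity, 3)
  qz <- vapply(g$rods, function(r) rod_maximum(r$qz_A1, r$intensity), numeric(1))
  o <- order(g$truth$peaks$qxy_A1)
  rec <- index_oblique(fit$qxy_A1, qz[o])
  expect_lt(abs(rec$a - lat$a) / lat$a, 1e-4)
  expect_lt(abs(rec$b - lat$b) / lat$b, 1e-4)
  expect_lt(abs(rec$gamma - lat$gamma) / lat$gamma, 1e-4)
  expect_lt(abs(rec$tilt - lat$tilt) / lat$tilt, 1e-4)
  # 2% noise: tilt within 0.5 degrees
  gn <- gen_gixd(lat, noise_frac = 0.02, seed = 5)
  fitn <- fit_bragg_peaks(gn$profile$qxy_A1, gn$profile$intensity, 3)
  qzn <- vapply(gn$rods, function(r) rod_maximum(r$qz_A1, r$intensity), numeric(1))
  recn <- index_oblique(fitn$qxy_A1, qzn[o])
  expect_lt(abs(recn$tilt - 15), 0.5)
})

test_that("areas stay positive and per-molecule doubling holds for any valid cell", {
  set.seed(33)
  for (i in 1:25) {
    lat <- lattice2d(runif(1, 4, 6), runif(1, 4, 6), runif(1, 95, 130),
                     tilt = runif(1, 0, 35), azimuth = runif(1, 0, 180))
    expect_gt(lat$area_chain_A2, 0)
    expect_equal(lat$area_molecule_A2, 2 * lat$area_chain_A2)
    expect_lte(lat$cross_section_A2, lat$area_chain_A2)
  }
})
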