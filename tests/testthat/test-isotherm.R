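test_that("compressibility modulus reproduces the analytic value on a linear isotherm", {
  A <- seq(50, 30, length.out = 60)
  iso <- isotherm(A, 141 - 2.5 * A)
  cm <- compressibility_modulus(iso)
  cs_at_40 <- stats::approx(cm$area_A2, cm$cs_inv_mN_m, xout = 40)$y
  expect_equal(cs_at_40, 100, tolerance = 1e-6)
  # constant pressure: zero modulus everywhere
  flat <- isotherm(A, rep(20, length(A)))
  expect_true(all(abs(compressibility_modulus(flat)$cs_inv_mN_m) < 1e-10))
  expect_error(compressibility_modulus(isotherm(c(50, 40), c(1, 2))), "at least 5")
})

test_that("compressibility modulus tracks an analytic derivative within 1% interior error", {
  A <- seq(70, 40, length.out = 300)
  Pi <- 60 * exp(-(A - 40) / 8)
  iso <- isotherm(A, Pi)
  cm <- compressibility_modulus(iso)
  truth <- cm$area_A2 * (60 / 8) * exp(-(cm$area_A2 - 40) / 8)
  interior <- cm$area_A2 > 42 & cm$area_A2 < 68
  rel <- abs(cm$cs_inv_mN_m[interior] - truth[interior]) / truth[interior]
  expect_lt(max(rel), 0.01)
})

test_that("limiting area is the abscissa intercept of the solid branch", {
  A <- seq(49, 41, length.out = 50)
  iso <- isotherm(A, 500 - 10 * A)
  expect_equal(limiting_area(iso, c(10, 80)), 50, tolerance = 1e-9)
  # sub-window invariance on an exact line
  expect_equal(limiting_area(iso, c(30, 60)), 50, tolerance = 1e-9)
  expect_error(limiting_area(isotherm(A, rep(10, 50) + 1e-12 * A), c(9, 11)),
               "degenerate")
})

test_that("phase features are recovered from generator truth and absent on a line", {
  g <- gen_isotherm(plateau_Pi = 20, kink_Pi = 35)
  f <- detect_phase_features(g$isotherm)
  expect_true(f$plateau_found)
  expect_lt(abs(f$plateau_pressure - 20), 0.5)
  expect_true(f$kink_found)
  expect_lt(abs(f$kink_pressure - 35), 0.5)
  lin <- isotherm(seq(60, 40, length.out = 120), seq(0, 50, length.out = 120))
  fl <- detect_phase_features(lin)
  expect_false(fl$plateau_found)
  expect_false(fl$kink_found)
})

test_that("feature pressures fall monotonically across a composition series built that way", {
  plateaus <- c(22, 18, 14)
  kinks <- c(38, 33, 28)
  got_p <- got_k <- numeric(0)
  for (i in seq_along(plateaus)) {
    g <- gen_isotherm(plateau_Pi = plateaus[i], kink_Pi = kinks[i])
    f <- detect_phase_features(g$isotherm)
    got_p <- c(got_p, f$plateau_pressure)
    got_k <- c(got_k, f$kink_pressure)
  }
  expect_true(all(diff(got_p) < 0))
  expect_true(all(diff(got_k) < 0))
})

test_that("excess area follows its defining arithmetic", {
  expect_equal(excess_area(40, 1, 40, 99), 0)
  expect_equal(excess_area(42, 0.5, 40, 42), 1)
  for (x in seq(0, 1, by = 0.25)) {
    expect_equal(excess_area(x * 40 + (1 - x) * 42, x, 40, 42), 0)
  }
  expect_error(excess_area(40, 1.2, 40, 40), "x1")
})

test_that("excess Gibbs energy matches the closed form for constant excess area", {
  fam <- gen_isotherm_family(x2_values = 0.5,
                             A_exc_fn = function(x2, Pi) 1)
  g <- excess_gibbs(fam$isotherms[["0.5"]], fam$isotherms[["0"]],
                    fam$isotherms[["1"]], Pi_target = 47)
  expect_equal(g, 6.02214076e23 * 1e-23 * 47, tolerance = 1e-6)
  # linear in the excess area
  fam2 <- gen_isotherm_family(x2_values = 0.5,
                              A_exc_fn = function(x2, Pi) 2)
  g2 <- excess_gibbs(fam2$isotherms[["0.5"]], fam2$isotherms[["0"]],
                     fam2$isotherms[["1"]], Pi_target = 47)
  expect_equal(g2, 2 * g, tolerance = 1e-9)
  # identical components: zero at any composition
  same <- gen_isotherm_family(x2_values = 0.3,
                              pure2 = list(A0 = 90, Ainf = 40, tau = 18))
  expect_equal(excess_gibbs(same$isotherms[["0.3"]], same$isotherms[["0"]],
                            same$isotherms[["1"]], 47), 0, tolerance = 1e-9)
  expect_error(excess_gibbs(fam$isotherms[["0.5"]], fam$isotherms[["0"]],
                            fam$isotherms[["1"]], 99), "target pressure")
})

test_that("excess Gibbs energy is stable under grid refinement on smooth input", {
  fam <- gen_isotherm_family(x2_values = 0.5,
                             A_exc_fn = function(x2, Pi) 1.5 * exp(-Pi / 30))
  args <- list(fam$isotherms[["0.5"]], fam$isotherms[["0"]], fam$isotherms[["1"]], 47)
  g_coarse <- do.call(excess_gibbs, c(args, n_grid = 236L))
  g_fine <- do.call(excess_gibbs, c(args, n_grid = 471L))
  expect_lt(abs(g_fine - g_coarse) / abs(g_fine), 0.001)
})

test_that("ideal mixing term is RT(x ln x + ...) with the 0 log 0 convention", {
  expect_equal(mixing_gibbs(0, 292.15, 0)$ideal, 0)
  expect_equal(mixing_gibbs(1, 292.15, 5)$ideal, 0)
  m <- mixing_gibbs(0.5, 292.15, 0)
  expect_equal(m$ideal, 8.314462618 * 292.15 * log(0.5), tolerance = 1e-12)
  m2 <- mixing_gibbs(0.3, 300, 400)
  expect_equal(m2$total, m2$ideal + 400)
  expect_lt(m2$total, 0)  # excess smaller than |ideal|
})

test_that("isotherm CSV round-trips with composition and temperature metadata", {
  g <- gen_isotherm(x2 = 0.3, T_K = 292.15)
  path <- tempfile(fileext = ".csv")
  write_isotherm_csv(g$isotherm, path)
  back <- read_isotherm_csv(path)
  expect_equal(back$area, g$isotherm$area)
  expect_equal(back$pressure, g$isotherm$pressure)
  expect_equal(back$x2, 0.3)
  expect_equal(back$T_K, 292.15)
})
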