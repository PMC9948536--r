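test_that("transient integration matches the closed-form exponential charge", {
  t <- seq(0, 5, by = 0.001)
  ts <- transient_set(0.1, list(data.frame(time_s = t,
                                           current_uA_cm2 = 10 * exp(-t / 0.5))))
  q <- integrate_transients(ts)
  expect_equal(q$charge_uC_cm2, 5, tolerance = 0.005 / 5)
  expect_true(q$decayed)
  # zero current
  ts0 <- transient_set(0.1, list(data.frame(time_s = t, current_uA_cm2 = 0 * t)))
  expect_equal(integrate_transients(ts0)$charge_uC_cm2, 0)
  # linearity: summed transients sum their charges
  ts2 <- transient_set(0.1, list(data.frame(time_s = t,
                                            current_uA_cm2 = 10 * exp(-t / 0.5) +
                                              4 * exp(-t / 0.2))))
  q2 <- integrate_transients(ts2)
  tsb <- transient_set(0.1, list(data.frame(time_s = t,
                                            current_uA_cm2 = 4 * exp(-t / 0.2))))
  expect_equal(q2$charge_uC_cm2,
               q$charge_uC_cm2 + integrate_transients(tsb)$charge_uC_cm2)
  # non-decayed transient is flagged
  tshort <- seq(0, 0.2, by = 0.001)
  tsw <- transient_set(0.1, list(data.frame(time_s = tshort,
                                            current_uA_cm2 = 10 * exp(-tshort / 0.5))))
  expect_warning(qw <- integrate_transients(tsw), "not decayed")
  expect_false(qw$decayed)
})

test_that("charge integration is additive over sub-intervals of time", {
  t <- seq(0, 2, by = 0.002)
  j <- 8 * exp(-t / 0.3)
  trap <- function(tt, jj) sum(diff(tt) * (head(jj, -1) + tail(jj, -1)) / 2)
  cut <- t <= 1
  expect_equal(trap(t, j), trap(t[cut], j[cut]) + trap(t[!cut | t == 1], j[!cut | t == 1]),
               tolerance = 1e-12)
})

test_that("pzc anchoring zeroes the bare curve at the pzc and is idempotent", {
  g <- gen_transients(sigma_fn = sigma_bare_truth)
  rel <- integrate_transients(g$transients)
  bare <- anchor_to_pzc(rel, 0.315, "bare")
  at_pzc <- stats::approx(bare$potential_V, bare$sigma_uC_cm2, xout = 0.315)$y
  expect_equal(at_pzc, 0, tolerance = 1e-9)
  expect_equal(attr(bare, "offset"),
               -stats::approx(rel$potential_V[order(rel$potential_V)],
                              rel$charge_uC_cm2[order(rel$potential_V)],
                              xout = 0.315)$y)
  twice <- anchor_to_pzc(data.frame(potential_V = bare$potential_V,
                                    charge_uC_cm2 = bare$sigma_uC_cm2), 0.315)
  expect_equal(twice$sigma_uC_cm2, bare$sigma_uC_cm2)
  expect_warning(anchor_to_pzc(rel, 2, "bare"), "outside")
})

test_that("anchored film and bare curves recover the absolute generator truth", {
  gb <- gen_transients(sigma_fn = sigma_bare_truth)
  gf <- gen_transients()
  bare <- anchor_to_pzc(integrate_transients(gb$transients), 0.315, "bare")
  film <- anchor_to_pzc(integrate_transients(gf$transients), 0.315, "film",
                        offset = attr(bare, "offset"))
  err <- max(abs(stats::approx(film$potential_V, film$sigma_uC_cm2,
                               gf$truth$sigma$potential_V)$y -
                   gf$truth$sigma$sigma_uC_cm2))
  expect_lt(err, 0.001 * max(abs(gf$truth$sigma$sigma_uC_cm2)))
})

test_that("differential capacitance recovers linear and piecewise-linear slopes", {
  E <- seq(-0.2, 0.4, by = 0.05)
  lin <- structure(data.frame(potential_V = E, sigma_uC_cm2 = 20 * (E - 0.315)),
                   class = c("charge_curve", "data.frame"))
  cap <- differential_capacitance(lin)
  expect_equal(cap$capacitance_uF_cm2, rep(20, length(E)), tolerance = 1e-9)
  # plateau capacitances away from breakpoints
  gt <- gen_transients()
  crv <- anchor_to_pzc(integrate_transients(gt$transients), 0.315, "film")
  capf <- differential_capacitance(crv)
  inner <- capf$potential_V > -0.3 & capf$potential_V < 0.3
  expect_true(all(abs(capf$capacitance_uF_cm2[inner] - 6) < 0.01))
  expect_error(differential_capacitance(lin[1, , drop = FALSE]), "at least 3")
})

test_that("film capacitance is below bare capacitance for curves built that way", {
  gb <- gen_transients(sigma_fn = sigma_bare_truth)
  gf <- gen_transients()
  bare <- anchor_to_pzc(integrate_transients(gb$transients), 0.315, "bare")
  film <- anchor_to_pzc(integrate_transients(gf$transients), 0.315, "film",
                        offset = attr(bare, "offset"))
  sel <- function(cc) {
    cap <- differential_capacitance(cc)
    mean(cap$capacitance_uF_cm2[cap$potential_V > -0.2 & cap$potential_V < 0.3])
  }
  expect_lt(sel(film), sel(bare))
})

test_that("state steps are located within one 0.05 V grid step, noise-free and noisy", {
  gt <- gen_transients()
  crv <- anchor_to_pzc(integrate_transients(gt$transients), 0.315, "film")
  st <- detect_state_steps(crv)
  expect_length(st$boundaries_V, 2)
  expect_lt(abs(st$boundaries_V[1] - (-0.80)), 0.05 + 1e-9)
  expect_lt(abs(st$boundaries_V[2] - (-0.40)), 0.05 + 1e-9)
  expect_equal(st$regions, c("desorbed", "II", "I"))
  # stability under seeded gaussian charge noise (sigma 0.2 uC/cm2)
  for (seed in 1:5) {
    set.seed(seed)
    noisy <- crv
    noisy$sigma_uC_cm2 <- noisy$sigma_uC_cm2 + stats::rnorm(nrow(crv), sd = 0.2)
    stn <- detect_state_steps(noisy)
    expect_length(stn$boundaries_V, 2)
    expect_true(all(abs(stn$boundaries_V - c(-0.80, -0.40)) <= 0.05 + 1e-9))
  }
  # linear curve: single region
  E <- seq(-0.9, 0.4, by = 0.05)
  lin <- structure(data.frame(potential_V = E, sigma_uC_cm2 = 20 * (E - 0.315)),
                   class = c("charge_curve", "data.frame"))
  stl <- detect_state_steps(lin)
  expect_length(stl$boundaries_V, 0)
  expect_equal(stl$regions, "I")
})

test_that("candidate count is monotone non-increasing in the detection threshold", {
  gt <- gen_transients()
  crv <- anchor_to_pzc(integrate_transients(gt$transients), 0.315, "film")
  counts <- vapply(c(1e-9, 0.5, 2, 3, 8, 30),
                   function(th) length(detect_state_steps(crv, threshold = th)$candidates_V),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  # a vanishing threshold admits every grid interval as a candidate
  expect_equal(counts[1], nrow(crv) - 1)
})

test_that("film pressure integrates the area between charge curves with unit conversion", {
  E <- seq(-0.5, 0.5, by = 0.05)
  mk <- function(s) structure(data.frame(potential_V = E, sigma_uC_cm2 = s),
                              class = c("charge_curve", "data.frame"))
  bare <- mk(20 * (E - 0.315))
  film <- mk(20 * (E - 0.315) + 5)
  expect_equal(film_pressure(film, bare, c(-0.25, 0.25)), 25, tolerance = 1e-9)
  expect_equal(film_pressure(bare, bare, c(-0.25, 0.25)), 0)
  expect_equal(film_pressure(bare, film, c(-0.25, 0.25)),
               -film_pressure(film, bare, c(-0.25, 0.25)))
  expect_error(film_pressure(film, bare, c(-2, 2)), "cover")
})

test_that("film pressure on generator curves matches the analytic integral", {
  gb <- gen_transients(sigma_fn = sigma_bare_truth)
  gf <- gen_transients()
  bare <- anchor_to_pzc(integrate_transients(gb$transients), 0.315, "bare")
  film <- anchor_to_pzc(integrate_transients(gf$transients), 0.315, "film",
                        offset = attr(bare, "offset"))
  # analytic: both truths known; integrate their difference on a fine grid
  E <- seq(-0.3, 0.3, length.out = 2001)
  d <- sigma_film_truth(E) - sigma_bare_truth(E)
  analytic <- 10 * sum(diff(E) * (head(d, -1) + tail(d, -1)) / 2)
  got <- film_pressure(film, bare, c(-0.3, 0.3))
  expect_lt(abs(got - analytic) / abs(analytic), 0.005)
})

test_that("long-format transient CSV reads back into a transient set", {
  g <- gen_transients(potentials = c(0.1, 0.0), t_end = 0.1, dt = 0.01)
  df <- do.call(rbind, lapply(seq_along(g$transients$potential), function(i) {
    cbind(potential_V = g$transients$potential[i], g$transients$transients[[i]])
  }))
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  back <- read_transients_csv(path)
  expect_equal(back$potential, g$transients$potential)
  expect_equal(back$transients[[1]]$current_uA_cm2,
               g$transients$transients[[1]]$current_uA_cm2)
  bad <- df
  names(bad)[3] <- "current"
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_transients_csv(path), "current_uA_cm2")
})
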