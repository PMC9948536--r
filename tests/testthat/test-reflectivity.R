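test_that("zero contrast gives zero reflectivity; the bare interface is Fresnel", {
  q <- seq(0.01, 0.4, length.out = 50)
  none <- slab_stack(data.frame(sld = c(0, 0), thick = c(20, 10)),
                     backing_sld = 0, roughness = 3)
  expect_true(all(abeles_reflectivity(none, q) < 1e-25))
  bare <- slab_stack(NULL, backing_sld = 6.36)
  qc <- critical_q(6.36e-6)
  expect_equal(abeles_reflectivity(bare, 2 * qc),
               ((2 - sqrt(3)) / (2 + sqrt(3)))^2, tolerance = 1e-12)
  expect_equal(abeles_reflectivity(bare, q), fresnel_exact(q, 6.36),
               tolerance = 1e-12)
  expect_equal(parratt_reflectivity(bare, q), fresnel_exact(q, 6.36),
               tolerance = 1e-12)
  # total reflection below the critical edge
  expect_equal(abeles_reflectivity(bare, qc * 0.8), 1)
})

test_that("Abeles and Parratt routes agree to 1e-10 relative on random stacks", {
  set.seed(101)
  q <- exp(seq(log(0.008), log(0.6), length.out = 120))
  worst <- 0
  for (i in 1:100) {
    st <- random_stack()
    ra <- abeles_reflectivity(st, q)
    rp <- parratt_reflectivity(st, q)
    keep <- rp > 1e-280
    worst <- max(worst, max(abs(ra[keep] - rp[keep]) / rp[keep]))
  }
  expect_lt(worst, 1e-10)
})

test_that("reflectivity collapses to the Fresnel limit as slab thicknesses vanish", {
  q <- seq(0.02, 0.5, length.out = 80)
  st <- slab_stack(data.frame(sld = c(7, 2), thick = c(0, 0)),
                   backing_sld = 6.36, roughness = 0)
  expect_equal(abeles_reflectivity(st, q), fresnel_exact(q, 6.36),
               tolerance = 1e-10)
})

test_that("Kiessig fringe spacing equals 2 pi over the layer thickness", {
  d <- 120
  st <- slab_stack(data.frame(sld = 4, thick = d), backing_sld = 2,
                   roughness = 0)
  q <- seq(0.05, 0.4, length.out = 8000)
  lr <- log(parratt_reflectivity(st, q))
  imin <- which(diff(sign(diff(lr))) > 0) + 1L
  spacing <- mean(diff(q[imin]))
  expect_lt(abs(spacing - 2 * pi / d) / (2 * pi / d), 0.01)
})

test_that("resolution smearing is identity at zero, preserves the plateau, damps fringes", {
  st <- slab_stack(data.frame(sld = 4, thick = 120), backing_sld = 2,
                   roughness = 0)
  q <- seq(0.02, 0.3, length.out = 500)
  expect_equal(reflectivity_model(st, q, 0), parratt_reflectivity(st, q))
  # critical-edge plateau within 1%
  bare <- slab_stack(NULL, backing_sld = 6.36)
  qlow <- seq(0.005, 0.9 * critical_q(6.36e-6), length.out = 30)
  expect_gt(min(reflectivity_model(bare, qlow, 0.07)), 0.99)
  # fringe amplitude decreases monotonically with dq/q
  amp <- vapply(c(0, 0.03, 0.07, 0.12), function(dq) {
    r <- reflectivity_model(st, q, dq)
    diff(range(log(r[q > 0.1 & q < 0.2])))
  }, numeric(1))
  expect_true(all(diff(amp) < 0))
})

test_that("co-fitting at the truth gives essentially zero chi-square on noise-free data", {
  sim <- gen_reflectivity(noise_rel = 0)
  for (ct in names(sim$curves)) sim$curves[[ct]]$dR <- pmax(0.01 * sim$curves[[ct]]$R, 1e-12)
  tr <- sim$truth
  par_truth <- c(t_tail = tr$t_tail, t_head = tr$t_head,
                 rough = tr$roughness, phi = tr$phi)
  out <- fit_reflectivity_pair(sim, par0 = par_truth,
                               lower = par_truth - 1e-9,
                               upper = par_truth + 1e-9)
  expect_lt(out$fit$chisq, 1e-10)
})

test_that("a fixed-roughness grid scan is minimised at the generating roughness", {
  sim <- gen_reflectivity(roughness = 3.0, seed = 77)
  tr <- sim$truth
  build <- function(par, contrast) {
    sp <- tr$subphase[[contrast]]
    twoslab_monolayer(par[["t_tail"]], par[["t_head"]], par[["rough"]],
                      par[["phi"]], tr$b_tail, tr$V_tail, tr$b_head,
                      tr$V_head, sp$b_w, sp$V_w, sp$sld)$stack
  }
  chis <- vapply(c(2.0, 2.5, 3.0, 3.5, 4.0), function(rg) {
    p0 <- c(t_tail = 15, t_head = 9, rough = rg, phi = 0.2)
    cofit_contrasts(sim$curves, build, p0,
                    lower = c(10, 5, rg, 0), upper = c(22, 14, rg, 0.7))$chisq
  }, numeric(1))
  expect_equal(which.min(chis), 3L)
})

test_that("structural parameters are recovered from noisy two-contrast data", {
  sim <- gen_reflectivity(t_tail = 17, t_head = 9, roughness = 3.5, seed = 19)
  out <- fit_reflectivity_pair(sim)
  expect_lt(abs(out$fit$par[["t_tail"]] - 17) / 17, 0.02)
  expect_lt(abs(out$fit$par[["t_head"]] - 9) / 9, 0.05)
  expect_lt(abs(out$n_w - sim$truth$n_w), 0.2)
})

test_that("MCMC mode brackets the truth with its 95% intervals on a cheap case", {
  sim <- gen_reflectivity(seed = 4)
  out <- fit_reflectivity_pair(sim, mode = "mcmc", seed = 8,
                               n_walkers = 16, n_steps = 150)
  ci <- out$fit$ci95
  tr <- c(sim$truth$t_tail, sim$truth$t_head, sim$truth$roughness, sim$truth$phi)
  inside <- tr >= ci[1, ] & tr <= ci[2, ]
  expect_gte(sum(inside), 3)
  # determinism: same seed, same estimates
  out2 <- fit_reflectivity_pair(sim, mode = "mcmc", seed = 8,
                                n_walkers = 16, n_steps = 150)
  expect_identical(out$fit$par, out2$fit$par)
})

test_that("headgroup solvation algebra satisfies its volume balance exactly", {
  s <- headgroup_solvation(A = 42.5, t_h = 8.0, sld_head_obs = 3.454,
                           b_head_dry = 60, n_ex = 0, V_water = 30,
                           b_water = 19.145)
  expect_equal(s$n_w, 3.0, tolerance = 1e-3)
  expect_equal(s$V_dry, 250, tolerance = 0.1)
  expect_equal(s$V_solv, s$A * s$t_h)
  expect_equal(s$V_dry, s$V_solv - s$n_w * 30, tolerance = 1e-9)
  # dry layer: observed SLD equals b_head / V_solv
  sld_dry <- 10 * 60 / (42.5 * 8)
  s0 <- headgroup_solvation(42.5, 8, sld_dry, 60)
  expect_equal(s0$n_w, 0, tolerance = 1e-9)
  expect_equal(s0$V_dry, s0$V_solv)
  # one exchanged hydrogen raises the effective head scattering length
  s1 <- headgroup_solvation(42.5, 8, 3.454, 60, n_ex = 1, V_water = 30,
                            b_water = 19.145)
  expect_equal(s1$b_head_fm - s$b_head_fm, 10.41, tolerance = 1e-6)
  expect_lt(s1$n_w, s$n_w)
  expect_error(headgroup_solvation(42.5, 8, 0.1, 60), "unphysical")
})

test_that("X-ray solvation mirrors the neutron route and the two agree", {
  # constructed self-consistent system: A = 45, t_h = 8, n_w = 3
  A <- 45; t_h <- 8; n_w <- 3
  V_solv <- A * t_h
  # neutron (D2O): b_head 60 fm, water 19.145 fm / 30.13 A^3
  sld_n <- 10 * (60 + n_w * 19.145) / V_solv
  sn <- headgroup_solvation(A, t_h, sld_n, 60)
  # X-ray: 180 electrons head, 10 electrons / 29.96 A^3 water
  re <- 2.8179403
  sld_x <- 10 * (180 * re + n_w * 10 * re) / V_solv
  sx <- xray_solvation(A, t_h, sld_x, 180)
  expect_equal(sn$n_w, 3, tolerance = 1e-9)
  expect_equal(sx$n_w, 3, tolerance = 1e-9)
  expect_lt(abs(sn$n_w - sx$n_w), 0.1)
  # dry-layer identity
  sx0 <- xray_solvation(A, t_h, 10 * 180 * re / V_solv, 180)
  expect_equal(sx0$n_w, 0, tolerance = 1e-9)
  # with one H/D exchange in D2O, the neutron route still matches X-ray
  sld_n1 <- 10 * (60 + 10.41 + n_w * 19.145) / V_solv
  sn1 <- headgroup_solvation(A, t_h, sld_n1, 60, n_ex = 1)
  expect_lt(abs(sn1$n_w - sx$n_w), 0.1)
})

test_that("shared-roughness stacks enforce their constraint", {
  st <- slab_stack(data.frame(sld = c(7, 3), thick = c(16, 8)),
                   backing_sld = 6.36, roughness = 3)
  expect_true(st$shared_roughness)
  expect_equal(st$roughness, rep(3, 3))
  expect_error(slab_stack(data.frame(sld = 1, thick = 5), 6, roughness = c(1, 2, 3)),
               "per interface")
  expect_error(slab_stack(data.frame(sld = 1, thick = -5), 6), "non-negative")
})
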