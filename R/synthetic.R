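# Ground-truth-known synthetic data for every analysis stage. Each
# generator is deterministic for a given seed and returns the data together
# with the generating truth, so round-trip recovery is checkable without
# any experimental input.

#' Synthetic surface pressure-area isotherm with phase structure
#'
#' Piecewise-smooth compression isotherm with a liquid-expanded branch, a
#' coexistence plateau, a liquid-condensed branch ending in a kink, and a
#' steep solid branch whose zero-pressure extrapolation hits a prescribed
#' limiting area. Defaults mimic gel-phase dimyristoyl phospholipids near
#' 19 C (plateau near 20 mN/m, kink near 35 mN/m, limiting area 40 A^2,
#' maximum pressure above 47 mN/m).
#'
#' @param x2 Mole fraction of component 2.
#' @param T_K Temperature, K (default 292.15).
#' @param plateau_Pi Coexistence plateau pressure, mN/m.
#' @param kink_Pi Condensed-to-solid kink pressure, mN/m.
#' @param A_lim Limiting area (solid-branch abscissa intercept), A^2.
#' @param solid_slope Solid-branch |dPi/dA|, mN/m per A^2 (default 25).
#' @param A_max,A_lift,A_plateau_end Large-area geometry, A^2.
#' @param n Points (default 400).
#' @param noise_sd Gaussian pressure noise, mN/m (default 0).
#' @param seed RNG seed (required when `noise_sd > 0`).
#' @return list with `isotherm` (an [isotherm()]) and `truth`.
#' @export
gen_isotherm <- function(x2 = 0, T_K = 292.15, plateau_Pi = 20, kink_Pi = 35,
                         A_lim = 40, solid_slope = 25, A_max = 95,
                         A_lift = 85, A_plateau_end = 48, n = 400L,
                         noise_sd = 0, seed = NULL) {
  if (noise_sd > 0 && is.null(seed)) stop("seed required for noisy output")
  A_k <- A_lim - kink_Pi / solid_slope
  A_min <- A_k - (70 - kink_Pi) / solid_slope  # run solid branch up to ~70 mN/m
  stopifnot(A_min < A_k, A_k < A_plateau_end, A_plateau_end < A_lift)
  # plateau start: where the liquid-expanded branch meets plateau_Pi
  A_plateau_start <- A_lift - (A_lift - A_plateau_end) * 0.55
  area <- seq(A_max, A_min, length.out = n)
  pressure <- vapply(area, function(a) {
    if (a >= A_lift) {
      0
    } else if (a >= A_plateau_start) {
      plateau_Pi * ((A_lift - a) / (A_lift - A_plateau_start))^2
    } else if (a >= A_plateau_end) {
      plateau_Pi
    } else if (a >= A_k) {
      plateau_Pi + (kink_Pi - plateau_Pi) * (A_plateau_end - a) / (A_plateau_end - A_k)
    } else {
      kink_Pi + solid_slope * (A_k - a)
    }
  }, numeric(1))
  if (noise_sd > 0) {
    set.seed(seed)
    pressure <- pressure + stats::rnorm(n, sd = noise_sd)
  }
  list(
    isotherm = isotherm(area, pressure, x2 = x2, T_K = T_K),
    truth = list(plateau_Pi = plateau_Pi, kink_Pi = kink_Pi, A_lim = A_lim,
                 solid_slope = solid_slope, A_kink = A_k)
  )
}

#' Synthetic binary composition family with prescribed excess area
#'
#' Plateau-free monotone isotherms A_i(Pi) = A_inf + (A_0 - A_inf)
#' exp(-Pi/tau) for the pure components; each mixture takes the
#' mole-fraction-weighted pure areas plus a prescribed excess area
#' A_exc(x2, Pi), so the mixing thermodynamics of the family is known in
#' closed form.
#'
#' @param x2_values Mixture compositions to generate (pure components 0 and
#'   1 are always included).
#' @param A_exc_fn Function `(x2, Pi) -> A_exc` in A^2 (default 0: ideal).
#' @param T_K Temperature, K.
#' @param Pi_max Maximum pressure, mN/m (default 60).
#' @param pure1,pure2 Lists with `A0`, `Ainf`, `tau` for the two pure
#'   components.
#' @param n Points per isotherm.
#' @return list with `isotherms` (named by x2) and `truth`.
#' @export
gen_isotherm_family <- function(x2_values = c(0.1, 0.3, 0.5, 0.7, 0.9),
                                A_exc_fn = function(x2, Pi) 0,
                                T_K = 292.15, Pi_max = 60,
                                pure1 = list(A0 = 90, Ainf = 40, tau = 18),
                                pure2 = list(A0 = 95, Ainf = 41, tau = 20),
                                n = 300L) {
  Pi <- seq(0, Pi_max, length.out = n)
  area_of <- function(p) p$Ainf + (p$A0 - p$Ainf) * exp(-Pi / p$tau)
  a1 <- area_of(pure1)
  a2 <- area_of(pure2)
  isos <- list(
    "0" = isotherm(a1, Pi, x2 = 0, T_K = T_K),
    "1" = isotherm(a2, Pi, x2 = 1, T_K = T_K)
  )
  for (x2 in x2_values) {
    a12 <- (1 - x2) * a1 + x2 * a2 + vapply(Pi, function(p) A_exc_fn(x2, p), numeric(1))
    isos[[as.character(x2)]] <- isotherm(a12, Pi, x2 = x2, T_K = T_K)
  }
  list(isotherms = isos,
       truth = list(A_exc_fn = A_exc_fn, pure1 = pure1, pure2 = pure2))
}

#' Piecewise-linear charge-density truth with adsorption-state steps
#'
#' sigma(E) for a film-covered electrode: capacitive segments separated by
#' charge jumps at the state-transition potentials, anchored so the curve
#' merges with a bare-electrode line below the desorption step.
#'
#' @param E Potentials, V.
#' @param pzc Bare-electrode potential of zero charge, V (default 0.315).
#' @param C_bare Bare capacitance, uF/cm^2 (default 20).
#' @param C_film Adsorbed-state capacitance, uF/cm^2 (default 6).
#' @param steps Transition potentials, V (default c(-0.40, -0.80)).
#' @param jumps Charge jumps at each step, uC/cm^2 (default c(-4, -5)).
#' @return sigma(E), uC/cm^2.
#' @export
sigma_film_truth <- function(E, pzc = 0.315, C_bare = 20, C_film = 6,
                             steps = c(-0.40, -0.80), jumps = c(-4, -5)) {
  steps <- sort(steps, decreasing = TRUE)
  sigma_des <- C_bare * (min(steps) - pzc)  # desorbed limb rejoins bare line
  vapply(E, function(e) {
    if (e <= min(steps)) {
      C_bare * (e - pzc)
    } else if (length(steps) > 1 && e <= steps[1]) {
      # cushioned state (region II): film slope, continuous up to step 1
      sigma_des - jumps[2] + C_film * (e - steps[2])
    } else {
      base <- sigma_des - jumps[2] + C_film * (steps[1] - steps[2])
      base - jumps[1] + C_film * (e - steps[1])
    }
  }, numeric(1))
}

#' Synthetic potential-step transient set with known charge curve
#'
#' One exponential-decay transient per potential whose time integral equals
#' the truth relative charge density at that potential (the absolute truth
#' minus its value at the desorption reference potential).
#'
#' @param sigma_fn Truth absolute charge density function sigma(E),
#'   uC/cm^2.
#' @param potentials Step potentials, V (default 0.44 down to -0.96 every
#'   0.05 V).
#' @param E_ref Desorption reference potential (default the most negative).
#' @param tau Transient decay constant, s (default 0.05).
#' @param t_end,dt Time window and sampling, s (defaults 1, 0.001).
#' @param noise_sd Gaussian current noise, uA/cm^2 (default 0).
#' @param seed RNG seed (required when `noise_sd > 0`).
#' @return list with `transients` (a [transient_set()]) and `truth`
#'   (data.frame `potential_V`, `sigma_uC_cm2`, plus `E_ref`).
#' @export
gen_transients <- function(sigma_fn = sigma_film_truth,
                           potentials = seq(0.44, -0.96, by = -0.05),
                           E_ref = NULL, tau = 0.05, t_end = 1, dt = 0.001,
                           noise_sd = 0, seed = NULL) {
  if (noise_sd > 0 && is.null(seed)) stop("seed required for noisy output")
  if (is.null(E_ref)) E_ref <- min(potentials)
  sig <- vapply(potentials, sigma_fn, numeric(1))
  rel <- sig - sigma_fn(E_ref)
  tgrid <- seq(0, t_end, by = dt)
  if (noise_sd > 0) set.seed(seed)
  trs <- lapply(rel, function(r) {
    # truncation-corrected amplitude: integral over [0, t_end] equals r
    amp <- r / (tau * (1 - exp(-t_end / tau)))
    j <- amp * exp(-tgrid / tau)
    if (noise_sd > 0) j <- j + stats::rnorm(length(j), sd = noise_sd)
    data.frame(time_s = tgrid, current_uA_cm2 = j)
  })
  list(
    transients = transient_set(potentials, trs),
    truth = list(sigma = data.frame(potential_V = potentials, sigma_uC_cm2 = sig),
                 E_ref = E_ref, tau = tau)
  )
}

#' Synthetic infrared spectrum with known band model and chain tilt
#'
#' C-H region: six pseudo-Voigt bands on the conventional centres; the
#' methylene symmetric (~2850) and asymmetric (~2920) band areas are set
#' from a prescribed chain tilt through the metal-surface dipole relation
#' I = 3 cos^2(theta) I_iso, splitting the tilt equally between the two
#' dipoles (cos^2 theta_s = cos^2 theta_as = sin^2(tilt)/2). C=O region:
#' three bands whose free-carbonyl (~1740) share of the total area equals a
#' prescribed solvation fraction.
#'
#' @param region `"CH"` or `"CO"`.
#' @param tilt_deg Truth chain tilt, degrees (CH region).
#' @param solvation Truth free-carbonyl fraction (CO region).
#' @param iso_areas Isotropic reference areas for the methylene bands,
#'   named `nu_s`, `nu_as` (CH region).
#' @param eta Lorentzian fraction of all bands (default 0.3).
#' @param noise_frac Gaussian noise as a fraction of the signal maximum.
#' @param seed RNG seed (required when `noise_frac > 0`).
#' @param dx Grid spacing, cm^-1 (default 0.5).
#' @return list with `wavenumber`, `signal`, `truth` (band model, tilt or
#'   solvation fraction, iso areas).
#' @export
gen_ir_spectrum <- function(region = c("CH", "CO"), tilt_deg = 25,
                            solvation = 0.4,
                            iso_areas = c(nu_s = 8, nu_as = 15),
                            eta = 0.3, noise_frac = 0, seed = NULL,
                            dx = 0.5) {
  region <- match.arg(region)
  if (noise_frac > 0 && is.null(seed)) stop("seed required for noisy output")
  if (region == "CH") {
    cos2 <- sin(tilt_deg * pi / 180)^2 / 2
    a_s <- iso_areas[["nu_s"]] * 3 * cos2
    a_as <- iso_areas[["nu_as"]] * 3 * cos2
    centers <- c(2850, 2870, 2895, 2920, 2935, 2960)
    fwhm <- c(9.8, 10, 14, 16.3, 14, 12)
    areas <- c(a_s, 3.5, 1.5, a_as, 1.5, 4.5)
    truth_extra <- list(tilt_deg = tilt_deg, iso_areas = iso_areas)
    grid <- seq(2800, 3010, by = dx)
  } else {
    centers <- c(1710, 1728, 1740)
    total <- 10
    areas <- c((1 - solvation) * 0.45, (1 - solvation) * 0.55, solvation) * total
    fwhm <- c(18, 16, 12)
    truth_extra <- list(solvation = solvation)
    grid <- seq(1670, 1785, by = dx)
  }
  heights <- areas / peak_area(fwhm, rep(1, length(fwhm)), eta)
  model <- band_model(centers, fwhm, heights, eta, region = region)
  signal <- eval_band_model(model, grid)
  if (noise_frac > 0) {
    set.seed(seed)
    signal <- signal + stats::rnorm(length(grid), sd = noise_frac * max(signal))
  }
  list(wavenumber = grid, signal = signal,
       truth = c(list(model = model), truth_extra))
}

#' Synthetic grazing-incidence diffraction profile with known lattice
#'
#' Pseudo-Voigt Bragg peaks at the {1 0}, {0 1}, {1 -1} positions of a
#' truth [lattice2d()] (degenerate reflections merge and add intensity),
#' over a linear background, plus Gaussian rod profiles centred at the
#' tilt-relation q_z maxima.
#'
#' @param lat Truth [lattice2d()].
#' @param qxy_range,n_qxy In-plane grid (defaults 1.1-1.9 1/A, 600 points).
#' @param peak_fwhm,peak_height,eta Line-shape settings.
#' @param background Linear background intercept (default 5).
#' @param rod_fwhm Rod Gaussian FWHM, 1/A (default 0.25).
#' @param noise_frac Gaussian noise as a fraction of `peak_height`.
#' @param seed RNG seed (required when `noise_frac > 0`).
#' @return list with `profile` (qxy, intensity), `rods` (list per unique
#'   peak of qz, intensity), `truth` (lattice, merged peak table).
#' @export
gen_gixd <- function(lat, qxy_range = c(1.1, 1.9), n_qxy = 600L,
                     peak_fwhm = 0.012, peak_height = 100, eta = 0.3,
                     background = 5, rod_fwhm = 0.25,
                     noise_frac = 0, seed = NULL) {
  if (noise_frac > 0 && is.null(seed)) stop("seed required for noisy output")
  pk <- lattice_peaks(lat)
  # merge degenerate reflections
  merged <- list()
  for (i in seq_len(nrow(pk))) {
    hit <- FALSE
    for (j in seq_along(merged)) {
      if (abs(merged[[j]]$qxy - pk$qxy_A1[i]) < 5e-4 &&
          abs(merged[[j]]$qz - pk$qz_A1[i]) < 5e-3) {
        merged[[j]]$mult <- merged[[j]]$mult + 1L
        hit <- TRUE
        break
      }
    }
    if (!hit) merged[[length(merged) + 1L]] <-
        list(qxy = pk$qxy_A1[i], qz = pk$qz_A1[i], mult = 1L)
  }
  qxy <- seq(qxy_range[1], qxy_range[2], length.out = n_qxy)
  intensity <- rep(background, n_qxy)
  for (m in merged) {
    intensity <- intensity +
      pseudo_voigt(qxy, m$qxy, peak_fwhm, peak_height * m$mult, eta)
  }
  qz_grid <- seq(0, 1.2, length.out = 200L)
  if (noise_frac > 0) set.seed(seed)
  rods <- lapply(merged, function(m) {
    ri <- 1 + 50 * exp(-log(2) * ((qz_grid - m$qz) / (rod_fwhm / 2))^2)
    if (noise_frac > 0) ri <- ri + stats::rnorm(length(ri), sd = noise_frac * 50)
    data.frame(qz_A1 = qz_grid, intensity = ri)
  })
  if (noise_frac > 0) {
    intensity <- intensity + stats::rnorm(n_qxy, sd = noise_frac * peak_height)
  }
  truth_peaks <- do.call(rbind, lapply(merged, function(m) {
    data.frame(qxy_A1 = m$qxy, qz_A1 = m$qz, multiplicity = m$mult)
  }))
  list(profile = data.frame(qxy_A1 = qxy, intensity = intensity),
       rods = rods,
       truth = list(lattice = lat, peaks = truth_peaks))
}

#' Synthetic two-contrast reflectivity with known two-slab structure
#'
#' Builds the air / d-chain tails / solvated head / subphase truth stacks
#' for D2O and air-contrast-matched subphases from one structural
#' parameter set, applies constant-dq/q Gaussian smearing, and adds seeded
#' noise whose relative size can grow with q (counting-statistics-like) or
#' stay flat.
#'
#' @param t_tail,t_head,roughness Structural truth, A (defaults 16, 8, 3).
#' @param headgroup `"PE"` or `"PS"` fragment chemistry.
#' @param q Momentum-transfer grid (default 90 log-spaced points,
#'   0.018-0.5 1/A, the usual air-water range).
#' @param dq_over_q Resolution (default 0.07).
#' @param noise_rel Base relative noise (default 0.01).
#' @param noise_model `"counting"` (relative error doubling towards q_max)
#'   or `"flat"`.
#' @param contrasts Subset of `c("D2O", "ACMW")`.
#' @param seed RNG seed (required when `noise_rel > 0`).
#' @return list with `curves` (per contrast: `q`, `R`, `dR`, `dq_over_q`,
#'   `contrast`) and `truth` (parameters, per-contrast stacks, `A`, `phi`,
#'   `n_w`, and the D2O-route `solvation_result`).
#' @export
gen_reflectivity <- function(t_tail = 16, t_head = 8, roughness = 3,
                             headgroup = "PE",
                             q = exp(seq(log(0.018), log(0.5), length.out = 90L)),
                             dq_over_q = 0.07, noise_rel = 0.01,
                             noise_model = c("counting", "flat"),
                             contrasts = c("D2O", "ACMW"), seed = NULL) {
  noise_model <- match.arg(noise_model)
  if (noise_rel > 0 && is.null(seed)) stop("seed required for noisy output")
  frag <- lipid_fragments(deuterated = TRUE, headgroup = headgroup)
  wat <- water_materials()
  tab <- isotope_table()
  b_tail <- scattering_length(frag$tails, tab)
  b_head <- scattering_length(frag$head, tab)
  A <- frag$tails$volume / t_tail
  V_solv <- A * t_head
  phi <- 1 - frag$head$volume / V_solv
  if (phi < 0) stop("head slab thinner than the dry headgroup; increase t_head")
  subphase <- list(
    D2O = list(sld = sld(wat$D2O, tab), b_w = scattering_length(wat$D2O, tab),
               V_w = wat$D2O$volume),
    ACMW = list(sld = 0, b_w = 0, V_w = wat$H2O$volume)
  )
  if (noise_rel > 0) set.seed(seed)
  curves <- lapply(contrasts, function(ct) {
    sp <- subphase[[ct]]
    mdl <- twoslab_monolayer(t_tail, t_head, roughness, phi,
                             b_tail, frag$tails$volume, b_head,
                             frag$head$volume, sp$b_w, sp$V_w, sp$sld)
    Rtrue <- reflectivity_model(mdl$stack, q, dq_over_q)
    rel <- if (noise_model == "counting") {
      noise_rel * (1 + q / max(q))
    } else {
      rep(noise_rel, length(q))
    }
    dR <- pmax(rel * Rtrue, 1e-12)
    Robs <- if (noise_rel > 0) Rtrue + stats::rnorm(length(q), sd = dR) else Rtrue
    list(q = q, R = Robs, dR = dR, dq_over_q = dq_over_q,
         contrast = ct, stack = mdl$stack)
  })
  names(curves) <- contrasts
  n_w <- phi * V_solv / subphase$D2O$V_w
  sld_head_d2o <- 10 * (b_head + n_w * subphase$D2O$b_w) / V_solv
  solv <- headgroup_solvation(A, t_head, sld_head_d2o, b_head,
                              n_ex = 0, V_water = subphase$D2O$V_w,
                              b_water = subphase$D2O$b_w, table = tab)
  list(
    curves = curves,
    truth = list(t_tail = t_tail, t_head = t_head, roughness = roughness,
                 phi = phi, A = A, n_w = n_w, b_tail = b_tail,
                 b_head = b_head, V_tail = frag$tails$volume,
                 V_head = frag$head$volume, solvation = solv,
                 subphase = subphase)
  )
}

#' Fit a synthetic two-contrast pair with the two-slab model
#'
#' Convenience wrapper used by the recovery studies: co-fits the curves of
#' [gen_reflectivity()] for (t_tail, t_head, roughness, phi) with the
#' fragment scattering lengths held at their known values, then runs the
#' headgroup solvation calculation on the fitted D2O head SLD.
#'
#' @param sim Output of [gen_reflectivity()].
#' @param par0,lower,upper Start values and bounds for
#'   `c(t_tail, t_head, rough, phi)` (defaults cover the monolayer regime).
#' @param mode `"ls"` or `"mcmc"` (see [cofit_contrasts()]).
#' @param ... Passed to [cofit_contrasts()].
#' @return list with `fit`, `A`, `n_w`, `solvation`.
#' @export
fit_reflectivity_pair <- function(sim,
                                  par0 = c(t_tail = 15, t_head = 9,
                                           rough = 3.5, phi = 0.2),
                                  lower = c(10, 5, 1, 0),
                                  upper = c(22, 14, 8, 0.7),
                                  mode = "ls", ...) {
  tr <- sim$truth
  build <- function(par, contrast) {
    sp <- tr$subphase[[contrast]]
    twoslab_monolayer(par[["t_tail"]], par[["t_head"]], par[["rough"]],
                      par[["phi"]], tr$b_tail, tr$V_tail, tr$b_head,
                      tr$V_head, sp$b_w, sp$V_w, sp$sld)$stack
  }
  fit <- cofit_contrasts(sim$curves, build, par0, lower, upper, mode = mode, ...)
  p <- fit$par
  A <- tr$V_tail / p[["t_tail"]]
  V_solv <- A * p[["t_head"]]
  n_w <- p[["phi"]] * V_solv / tr$subphase$D2O$V_w
  sld_head <- 10 * (tr$b_head + n_w * tr$subphase$D2O$b_w) / V_solv
  solv <- headgroup_solvation(A, p[["t_head"]], sld_head, tr$b_head,
                              n_ex = 0, V_water = tr$subphase$D2O$V_w,
                              b_water = tr$subphase$D2O$b_w)
  list(fit = fit, A = A, n_w = n_w, solvation = solv)
}
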