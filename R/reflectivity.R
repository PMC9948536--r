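# Specular reflectometry: slab-model forward calculation (Abeles transfer
# matrix and, as an independent route, Parratt recursion), Nevot-Croce
# roughness, Gaussian resolution smearing, multi-contrast co-fitting of the
# two-slab lipid monolayer model, and the headgroup solvation calculation.

#' Construct a slab stack
#'
#' Ordered interfacial model: fronting medium (air), slabs top to bottom,
#' backing medium (subphase). With `n` slabs there are `n + 1` interfaces;
#' a scalar roughness applies to every interface (the shared-roughness
#' constraint used throughout the monolayer fits), or a vector of length
#' `n + 1` gives each interface its own value (top first).
#'
#' @param slabs data.frame with columns `sld` (1e-6 A^-2) and `thick` (A,
#'   non-negative), top slab first. Zero rows give a bare interface.
#' @param backing_sld Subphase SLD, 1e-6 A^-2.
#' @param fronting_sld Fronting SLD (default 0, air).
#' @param roughness Scalar (shared) or length `n + 1` vector, A, >= 0.
#' @return Object of class `slab_stack`.
#' @export
slab_stack <- function(slabs, backing_sld, fronting_sld = 0, roughness = 0) {
  if (is.null(slabs)) slabs <- data.frame(sld = numeric(0), thick = numeric(0))
  stopifnot(all(c("sld", "thick") %in% names(slabs)))
  if (any(slabs$thick < 0)) stop("slab thicknesses must be non-negative")
  n_int <- nrow(slabs) + 1L
  if (length(roughness) == 1L) {
    roughness <- rep(roughness, n_int)
    shared <- TRUE
  } else {
    if (length(roughness) != n_int) {
      stop("roughness must be scalar or one value per interface (", n_int, ")")
    }
    shared <- FALSE
  }
  if (any(roughness < 0)) stop("roughness must be non-negative")
  structure(
    list(slabs = slabs, backing_sld = backing_sld,
         fronting_sld = fronting_sld, roughness = roughness,
         shared_roughness = shared),
    class = "slab_stack"
  )
}

# Vertical wavevectors in every layer for momentum transfer q (vector).
# Returns a list of complex vectors, one per layer (fronting first).
.layer_kz <- function(stack, q) {
  rho <- c(stack$fronting_sld, stack$slabs$sld, stack$backing_sld) * 1e-6
  kz0_sq <- (q / 2)^2
  lapply(rho, function(r) {
    sqrt(as.complex(kz0_sq - 4 * pi * (r - rho[1])))
  })
}

#' Specular reflectivity by the Abeles transfer-matrix method
#'
#' Characteristic 2x2 matrices per layer with Nevot-Croce Gaussian
#' roughness factors on the interface Fresnel coefficients. For
#' absorption-free input, R is in \[0, 1\] and reaches 1 below the critical
#' edge of a positive-contrast backing.
#'
#' @param stack A [slab_stack()].
#' @param q Momentum transfer grid, inverse Angstrom (positive).
#' @return Reflectivity R(q), same length as `q`.
#' @export
abeles_reflectivity <- function(stack, q) {
  if (any(q <= 0)) stop("q must be positive")
  kz <- .layer_kz(stack, q)
  d <- c(0, stack$slabs$thick)  # phase thickness of layer above interface j
  nlay <- length(kz)
  sig <- stack$roughness
  M11 <- rep(1 + 0i, length(q)); M12 <- rep(0i, length(q))
  M21 <- rep(0i, length(q)); M22 <- rep(1 + 0i, length(q))
  for (j in seq_len(nlay - 1L)) {
    k1 <- kz[[j]]; k2 <- kz[[j + 1L]]
    r <- (k1 - k2) / (k1 + k2) * exp(-2 * k1 * k2 * sig[j]^2)
    beta <- if (j == 1L) rep(0i, length(q)) else 1i * k1 * d[j]
    e <- exp(beta)
    c11 <- e; c12 <- r * e
    c21 <- r / e; c22 <- 1 / e
    n11 <- M11 * c11 + M12 * c21
    n12 <- M11 * c12 + M12 * c22
    n21 <- M21 * c11 + M22 * c21
    n22 <- M21 * c12 + M22 * c22
    M11 <- n11; M12 <- n12; M21 <- n21; M22 <- n22
  }
  R <- Mod(M21 / M11)^2
  pmin(R, 1)
}

#' Specular reflectivity by Parratt recursion
#'
#' Bottom-up recursion over interfaces with the same Nevot-Croce roughness
#' factors as [abeles_reflectivity()]; the two routes are algebraically
#' equivalent and serve as mutual cross-checks.
#'
#' @inheritParams abeles_reflectivity
#' @return Reflectivity R(q).
#' @export
parratt_reflectivity <- function(stack, q) {
  if (any(q <= 0)) stop("q must be positive")
  kz <- .layer_kz(stack, q)
  d <- c(0, stack$slabs$thick, 0)
  nlay <- length(kz)
  sig <- stack$roughness
  RR <- rep(0i, length(q))
  for (j in seq(nlay - 1L, 1L)) {
    k1 <- kz[[j]]; k2 <- kz[[j + 1L]]
    r <- (k1 - k2) / (k1 + k2) * exp(-2 * k1 * k2 * sig[j]^2)
    phase <- exp(2i * k2 * d[j + 1L])
    RR <- (r + RR * phase) / (1 + r * RR * phase)
  }
  pmin(Mod(RR)^2, 1)
}

#' Apply Gaussian q-resolution smearing to a reflectivity model
#'
#' Convolution with a Gaussian of width sigma = (dq/q) q / 2.355 by
#' fixed-point quadrature (17 points over +/- 3.5 sigma), matching the
#' constant-dq/q resolution of time-of-flight reflectometers.
#'
#' @param q Momentum transfer grid.
#' @param reflect_fn Function of a q vector returning R.
#' @param dq_over_q Fractional FWHM resolution (e.g. 0.07); 0 is identity.
#' @param n_points Quadrature points (default 17).
#' @return Smeared R(q).
#' @export
smear_resolution <- function(q, reflect_fn, dq_over_q, n_points = 17L) {
  if (dq_over_q < 0) stop("dq/q must be non-negative")
  if (dq_over_q == 0) return(reflect_fn(q))
  x <- seq(-3.5, 3.5, length.out = n_points)
  w <- exp(-x^2 / 2)
  w <- w / sum(w)
  sigma <- dq_over_q / 2.355
  out <- numeric(length(q))
  for (i in seq_along(x)) {
    qi <- q * (1 + sigma * x[i])
    qi[qi <= 0] <- min(q) * 1e-3
    out <- out + w[i] * reflect_fn(qi)
  }
  out
}

#' Smeared slab-stack reflectivity
#'
#' @param stack A [slab_stack()].
#' @param q Momentum transfer grid.
#' @param dq_over_q Fractional resolution (default 0).
#' @param method `"abeles"` or `"parratt"`.
#' @return R(q).
#' @export
reflectivity_model <- function(stack, q, dq_over_q = 0,
                               method = c("abeles", "parratt")) {
  method <- match.arg(method)
  fn <- switch(method,
               abeles = function(qq) abeles_reflectivity(stack, qq),
               parratt = function(qq) parratt_reflectivity(stack, qq))
  smear_resolution(q, fn, dq_over_q)
}

#' Co-fit reflectivity curves from multiple contrasts
#'
#' Shared structural parameters across contrasts, contrast-specific SLDs
#' through a user-supplied stack builder. Least-squares mode uses
#' Levenberg-Marquardt on the dR-weighted residuals; MCMC mode runs a
#' seeded affine-invariant (stretch-move) ensemble around the same
#' likelihood and reports 95% credible intervals.
#'
#' @param curves List of curves; each a list with elements `q`, `R`, `dR`,
#'   `dq_over_q`, and `contrast` (passed to `build_stack`).
#' @param build_stack Function `(par, contrast) -> slab_stack`.
#' @param par0 Named numeric start values.
#' @param lower,upper Bounds (same length as `par0`).
#' @param mode `"ls"` or `"mcmc"`.
#' @param seed RNG seed (required for MCMC).
#' @param n_walkers,n_steps,burn_frac Ensemble settings (MCMC mode).
#' @return list with `par` (point estimates), `chisq`, `dof`,
#'   `reduced_chisq`, and in MCMC mode `ci95` (2.5/97.5 percentiles) and
#'   `samples`.
#' @export
cofit_contrasts <- function(curves, build_stack, par0, lower, upper,
                            mode = c("ls", "mcmc"), seed = 1L,
                            n_walkers = 32L, n_steps = 400L,
                            burn_frac = 0.3) {
  mode <- match.arg(mode)
  stopifnot(length(curves) >= 1, length(lower) == length(par0),
            length(upper) == length(par0))
  resid_fn <- function(par) {
    names(par) <- names(par0)
    unlist(lapply(curves, function(cv) {
      st <- build_stack(par, cv$contrast)
      (reflectivity_model(st, cv$q, cv$dq_over_q) - cv$R) / cv$dR
    }))
  }
  ndata <- sum(vapply(curves, function(cv) length(cv$q), integer(1)))
  dof <- ndata - length(par0)
  if (mode == "ls") {
    fit <- minpack.lm::nls.lm(par = par0, fn = resid_fn, lower = lower,
                              upper = upper,
                              control = minpack.lm::nls.lm.control(maxiter = 300))
    chisq <- sum(fit$fvec^2)
    jac <- fit$hessian
    if (!is.null(jac) && any(!is.finite(diag(jac)))) {
      warning("flat likelihood direction: parameter set may be unidentifiable")
    }
    est <- fit$par
    names(est) <- names(par0)
    return(list(par = est, chisq = chisq, dof = dof,
                reduced_chisq = chisq / max(dof, 1), mode = "ls",
                info = fit$info))
  }
  # affine-invariant stretch-move ensemble (Goodman & Weare)
  set.seed(seed)
  npar <- length(par0)
  log_post <- function(par) {
    if (any(par < lower) || any(par > upper)) return(-Inf)
    -0.5 * sum(resid_fn(par)^2)
  }
  walkers <- t(vapply(seq_len(n_walkers), function(i) {
    pmin(pmax(par0 * (1 + 0.01 * stats::rnorm(npar)), lower), upper)
  }, numeric(npar)))
  lp <- apply(walkers, 1, log_post)
  a_stretch <- 2
  keep <- list()
  for (step in seq_len(n_steps)) {
    for (i in seq_len(n_walkers)) {
      j <- sample(seq_len(n_walkers)[-i], 1)
      z <- ((a_stretch - 1) * stats::runif(1) + 1)^2 / a_stretch
      prop <- walkers[j, ] + z * (walkers[i, ] - walkers[j, ])
      lp_prop <- log_post(prop)
      if (log(stats::runif(1)) < (npar - 1) * log(z) + lp_prop - lp[i]) {
        walkers[i, ] <- prop
        lp[i] <- lp_prop
      }
    }
    if (step > burn_frac * n_steps) keep[[length(keep) + 1L]] <- walkers
  }
  samples <- do.call(rbind, keep)
  colnames(samples) <- names(par0)
  est <- apply(samples, 2, stats::median)
  ci <- apply(samples, 2, stats::quantile, probs = c(0.025, 0.975))
  chisq <- sum(resid_fn(est)^2)
  list(par = est, chisq = chisq, dof = dof,
       reduced_chisq = chisq / max(dof, 1),
       ci95 = ci, samples = samples, mode = "mcmc")
}

#' Headgroup solvation from a fitted neutron head-slab SLD
#'
#' The molecular area must be the same in the tail and head slabs, so the
#' solvated headgroup volume is V_solv = A t_h. Its scattering comes from
#' one dry headgroup (with `n_ex` labile hydrogens exchanged for deuterium)
#' plus n_w waters:
#' n_w = (rho_obs V_solv - b_head) / b_water, V_dry = V_solv - n_w V_water.
#'
#' @param A Area per molecule, A^2.
#' @param t_h Headgroup slab thickness, A.
#' @param sld_head_obs Fitted head-slab SLD, 1e-6 A^-2.
#' @param b_head_dry Dry (unexchanged) headgroup scattering length, fm.
#' @param n_ex Number of exchanged labile hydrogens (default 0).
#' @param V_water Water molecular volume, A^3 (default 30.13, D2O).
#' @param b_water Water scattering length, fm (default 19.145, D2O).
#' @param table Isotope table supplying b(D) - b(H) for the exchange.
#' @return list of class `solvation_result`: `A`, `t_h`, `V_solv`, `V_dry`,
#'   `n_w`, `n_ex`, `b_head_fm`.
#' @export
headgroup_solvation <- function(A, t_h, sld_head_obs, b_head_dry, n_ex = 0,
                                V_water = 30.13, b_water = 19.145,
                                table = isotope_table()) {
  if (A <= 0 || t_h <= 0) stop("area and thickness must be positive")
  if (b_water == 0) stop("b_water must be non-zero")
  V_solv <- A * t_h
  b_head <- b_head_dry + n_ex * (table[["D"]] - table[["H"]])
  # rho[1e-6 A^-2] * V[A^3] -> fm: x 0.1
  total_b_fm <- sld_head_obs * V_solv * 0.1
  n_w <- (total_b_fm - b_head) / b_water
  V_dry <- V_solv - n_w * V_water
  if (n_w < -1e-6 || V_dry <= 0) {
    stop(sprintf(
      "unphysical solvation solution: n_w = %.3f, V_dry = %.1f A^3", n_w, V_dry))
  }
  structure(
    list(A = A, t_h = t_h, V_solv = V_solv, V_dry = V_dry,
         n_w = max(n_w, 0), n_ex = n_ex, b_head_fm = b_head),
    class = "solvation_result"
  )
}

#' @export
print.solvation_result <- function(x, ...) {
  cat(sprintf(
    "<solvation> A = %.1f A^2  t_h = %.2f A  V_solv = %.1f  V_dry = %.1f A^3  n_w = %.2f (n_ex = %d)\n",
    x$A, x$t_h, x$V_solv, x$V_dry, x$n_w, as.integer(x$n_ex)))
  invisible(x)
}

#' Headgroup solvation from a fitted X-ray head-slab SLD
#'
#' Same algebra as [headgroup_solvation()] with electron-count scattering
#' lengths (electrons times the classical electron radius); X-rays see no
#' H/D exchange.
#'
#' @param A,t_h As in [headgroup_solvation()].
#' @param sld_head_obs Fitted head-slab X-ray SLD, 1e-6 A^-2.
#' @param electrons_head Dry headgroup electron count.
#' @param V_water Water molecular volume, A^3 (default 29.96).
#' @param electrons_water Water electron count (default 10).
#' @return A `solvation_result`.
#' @export
xray_solvation <- function(A, t_h, sld_head_obs, electrons_head,
                           V_water = 29.96, electrons_water = 10) {
  if (A <= 0 || t_h <= 0) stop("area and thickness must be positive")
  V_solv <- A * t_h
  b_head <- electrons_head * .r_e_fm
  b_water <- electrons_water * .r_e_fm
  total_b_fm <- sld_head_obs * V_solv * 0.1
  n_w <- (total_b_fm - b_head) / b_water
  V_dry <- V_solv - n_w * V_water
  if (n_w < -1e-6 || V_dry <= 0) {
    stop(sprintf(
      "unphysical solvation solution: n_w = %.3f, V_dry = %.1f A^3", n_w, V_dry))
  }
  structure(
    list(A = A, t_h = t_h, V_solv = V_solv, V_dry = V_dry,
         n_w = max(n_w, 0), n_ex = 0, b_head_fm = b_head),
    class = "solvation_result"
  )
}

#' Default lipid fragment materials for the two-slab monolayer model
#'
#' Nominal dimyristoyl (C14) fragments: the tail slab holds the two
#' hydrocarbon chains (perdeuterated variant for d-lipids); the head slab
#' holds the remainder including the ester carbonyls. Formulas and volumes
#' are plain fields and may be overridden; volumes follow common literature
#' values (tails 722 A^3, dry head 252 A^3).
#'
#' @param deuterated Use perdeuterated (d54) chains (default TRUE).
#' @param headgroup `"PE"` or `"PS"`.
#' @return Named list with materials `tails` and `head`.
#' @export
lipid_fragments <- function(deuterated = TRUE, headgroup = c("PE", "PS")) {
  headgroup <- match.arg(headgroup)
  tails <- if (deuterated) {
    material("d54 myristoyl chains", c(C = 26, D = 54), volume = 722,
             electrons = 26 * 6 + 54)
  } else {
    material("h54 myristoyl chains", c(C = 26, H = 54), volume = 722,
             electrons = 26 * 6 + 54)
  }
  head <- if (headgroup == "PE") {
    # glycerol backbone + 2 carbonyls + phosphoethanolamine
    material("PE head + carbonyls", c(C = 10, H = 18, N = 1, O = 8, P = 1),
             volume = 252, electrons = 10 * 6 + 18 + 7 + 8 * 8 + 15)
  } else {
    # phosphoserine analogue (sodium salt), one more carboxylate
    material("PS head + carbonyls", c(C = 11, H = 17, N = 1, O = 10, P = 1, Na = 1),
             volume = 252, electrons = 11 * 6 + 17 + 7 + 10 * 8 + 15 + 11)
  }
  list(tails = tails, head = head)
}

#' Two-slab monolayer stack from structural parameters
#'
#' Builds the air / tails / solvated head / subphase stack used in all the
#' monolayer fits. The area per molecule follows from the (fixed) tail
#' volume and the tail thickness, A = V_tail / t_tail; the head-slab SLD
#' mixes the dry headgroup with `n_w = phi A t_h / V_water` waters of the
#' contrast's subphase.
#'
#' @param t_tail,t_head Slab thicknesses, A.
#' @param roughness Shared interfacial roughness, A.
#' @param phi Head-slab solvent volume fraction in \[0, 1).
#' @param b_tail,V_tail Tail scattering length (fm) and volume (A^3).
#' @param b_head,V_head Dry head scattering length (fm) and volume (A^3)
#'   (V_head is informational; the head SLD uses phi directly).
#' @param b_water,V_water Subphase water scattering length (fm) and volume.
#' @param backing_sld Subphase SLD, 1e-6 A^-2.
#' @return list with the [slab_stack()] (`stack`), `A`, `n_w`.
#' @export
twoslab_monolayer <- function(t_tail, t_head, roughness, phi,
                              b_tail, V_tail, b_head, V_head,
                              b_water, V_water, backing_sld) {
  if (phi < 0 || phi >= 1) stop("phi must be in [0, 1)")
  A <- V_tail / t_tail
  n_w <- phi * A * t_head / V_water
  sld_tail <- 10 * b_tail / V_tail          # fm / A^3 -> 1e-6 A^-2
  sld_head <- 10 * (b_head + n_w * b_water) / (A * t_head)
  st <- slab_stack(
    data.frame(sld = c(sld_tail, sld_head), thick = c(t_tail, t_head)),
    backing_sld = backing_sld, fronting_sld = 0, roughness = roughness
  )
  list(stack = st, A = A, n_w = n_w)
}
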