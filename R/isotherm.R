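# Surface pressure-area isotherm mechanics and mixing thermodynamics for
# Langmuir monolayers.

R_GAS <- 8.314462618  # J mol^-1 K^-1
N_AVOGADRO <- 6.02214076e23

#' Construct an isotherm
#'
#' @param area Area per molecule, A^2/molecule, strictly monotone.
#' @param pressure Surface pressure Pi, mN/m, finite.
#' @param x2 Mole fraction of component 2 in a binary film, in \[0, 1\].
#' @param T_K Temperature in kelvin.
#' @return An object of class `isotherm` with the series sorted by
#'   decreasing area (compression order).
#' @export
isotherm <- function(area, pressure, x2 = 0, T_K = 292.15) {
  if (length(area) != length(pressure)) stop("area and pressure lengths differ")
  if (any(!is.finite(area)) || any(!is.finite(pressure))) {
    stop("isotherm series must be finite")
  }
  d <- diff(area)
  if (!(all(d > 0) || all(d < 0))) stop("area series must be strictly monotone")
  if (x2 < 0 || x2 > 1) stop("x2 must be in [0, 1]")
  o <- order(area, decreasing = TRUE)
  structure(
    list(area = area[o], pressure = pressure[o], x2 = x2, T_K = T_K),
    class = "isotherm"
  )
}

#' @export
print.isotherm <- function(x, ...) {
  cat(sprintf(
    "<isotherm> %d points, A %.1f-%.1f A^2, Pi %.1f-%.1f mN/m, x2 = %.2f, T = %.2f K\n",
    length(x$area), min(x$area), max(x$area),
    min(x$pressure), max(x$pressure), x$x2, x$T_K
  ))
  invisible(x)
}

#' Read an isotherm from CSV
#'
#' Expects columns `area_A2` and `pressure_mN_m`; metadata header lines
#' `# x2=<value>` and `# T_K=<value>` are honoured.
#'
#' @param path CSV file path.
#' @return An [isotherm()].
#' @export
read_isotherm_csv <- function(path) {
  hdr <- readLines(path, n = 20L)
  hdr <- hdr[startsWith(hdr, "#")]
  grab <- function(key, default) {
    m <- grep(paste0("^#\\s*", key, "\\s*="), hdr, value = TRUE)
    if (length(m)) as.numeric(sub(paste0("^#\\s*", key, "\\s*="), "", m[1])) else default
  }
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("area_A2", "pressure_mN_m") %in% names(df))) {
    stop("isotherm CSV needs columns 'area_A2' and 'pressure_mN_m' in ", path)
  }
  isotherm(df$area_A2, df$pressure_mN_m, x2 = grab("x2", 0), T_K = grab("T_K", 292.15))
}

#' Write an isotherm to CSV (round-trips with [read_isotherm_csv()])
#' @param iso An [isotherm()].
#' @param path Output file.
#' @export
write_isotherm_csv <- function(iso, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# x2=%.10g", iso$x2), sprintf("# T_K=%.10g", iso$T_K)), con)
  utils::write.csv(
    data.frame(area_A2 = iso$area, pressure_mN_m = iso$pressure),
    con, row.names = FALSE
  )
  invisible(path)
}

# Smoothed derivative dPi/dA on a uniform area grid (Savitzky-Golay).
# Returns list(area, pressure, dPi_dA) on the resampled grid.
.isotherm_derivative <- function(iso, sg_window = 11L, sg_order = 3L) {
  n <- length(iso$area)
  sg_window <- min(sg_window, if (n %% 2L == 1L) n else n - 1L)
  if (sg_window %% 2L == 0L) sg_window <- sg_window - 1L
  sg_window <- max(sg_window, sg_order + 2L + (sg_order %% 2L == 1L))
  if (sg_window %% 2L == 0L) sg_window <- sg_window + 1L
  # resample to uniform grid so the filter's fixed spacing applies
  a <- seq(max(iso$area), min(iso$area), length.out = max(n, 2L * sg_window))
  p <- stats::approx(iso$area, iso$pressure, xout = a)$y
  h <- a[2] - a[1]  # negative (compression order)
  dp <- signal::sgolayfilt(p, p = sg_order, n = sg_window, m = 1L) / h
  ps <- signal::sgolayfilt(p, p = sg_order, n = sg_window, m = 0L)
  list(area = a, pressure = ps, dPi_dA = dp)
}

#' Compressibility modulus along an isotherm
#'
#' In-plane elastic modulus Cs^-1 = -A dPi/dA, evaluated pointwise on a
#' Savitzky-Golay smoothed derivative. High values (several hundred mN/m)
#' indicate a solid monolayer phase.
#'
#' @param iso An [isotherm()] with at least 5 points.
#' @param sg_window Savitzky-Golay window length (odd; default 11).
#' @param sg_order Savitzky-Golay polynomial order (default 3).
#' @return data.frame with columns `area_A2`, `pressure_mN_m`, `cs_inv_mN_m`.
#' @export
compressibility_modulus <- function(iso, sg_window = 11L, sg_order = 3L) {
  if (length(iso$area) < 5L) stop("need at least 5 isotherm points")
  d <- .isotherm_derivative(iso, sg_window, sg_order)
  data.frame(
    area_A2 = d$area,
    pressure_mN_m = d$pressure,
    cs_inv_mN_m = -d$area * d$dPi_dA
  )
}

#' Limiting molecular area by solid-phase extrapolation
#'
#' Straight-line fit to the isotherm points inside a surface-pressure window
#' on the solid branch, extrapolated to zero pressure (the abscissa).
#'
#' @param iso An [isotherm()].
#' @param solid_phase_window Numeric length-2 pressure window (mN/m).
#' @return Limiting area in A^2/molecule.
#' @export
limiting_area <- function(iso, solid_phase_window) {
  w <- range(solid_phase_window)
  sel <- iso$pressure >= w[1] & iso$pressure <= w[2]
  if (sum(sel) < 3L) stop("solid-phase window contains fewer than 3 points")
  fit <- stats::lm(pressure ~ area, data = data.frame(
    area = iso$area[sel], pressure = iso$pressure[sel]
  ))
  slope <- stats::coef(fit)[["area"]]
  if (abs(slope) < 1e-8) stop("degenerate extrapolation: near-zero slope in window")
  -stats::coef(fit)[["(Intercept)"]] / slope
}

#' Locate plateau and kink features of an isotherm
#'
#' The plateau onset is the pressure at which, on compression (decreasing
#' area), the smoothed slope dPi/dA first falls below a tolerance fraction
#' of the isotherm's maximum slope magnitude — the liquid-expanded /
#' liquid-condensed coexistence plateau. The kink is the pressure of the
#' strongest curvature (second-derivative magnitude) between the plateau and
#' the solid branch — the condensed-to-solid transition.
#'
#' @param iso An [isotherm()].
#' @param plateau_tol Slope tolerance as a fraction of the maximum slope
#'   magnitude (default 0.02).
#' @param pressure_floor Plateau candidates must exceed this fraction of
#'   the maximum pressure (default 0.05), so the zero-pressure gas region
#'   before lift-off is not mistaken for the coexistence plateau.
#' @param sg_window,sg_order Savitzky-Golay settings (see
#'   [compressibility_modulus()]).
#' @return list with `plateau_found`, `plateau_pressure`, `kink_found`,
#'   `kink_pressure` (pressures in mN/m, NA when absent).
#' @export
detect_phase_features <- function(iso, plateau_tol = 0.02,
                                  pressure_floor = 0.05,
                                  sg_window = 11L, sg_order = 3L) {
  d <- .isotherm_derivative(iso, sg_window, sg_order)
  slope <- abs(d$dPi_dA)
  n <- length(slope)
  edge <- max(3L, ceiling(0.02 * n))  # SG endpoints are unreliable
  core <- seq(edge, n - edge)
  smax <- max(slope[core])
  out <- list(plateau_found = FALSE, plateau_pressure = NA_real_,
              kink_found = FALSE, kink_pressure = NA_real_)
  if (smax <= 0) return(out)
  # compression order = decreasing area = increasing index in d$area
  flat <- which(slope[core] < plateau_tol * smax &
                  d$pressure[core] > pressure_floor * max(d$pressure))
  if (length(flat) == 0L) return(out)
  i_plateau <- core[flat[1]]
  out$plateau_found <- TRUE
  out$plateau_pressure <- d$pressure[i_plateau]
  # kink: curvature extremum after the plateau region ends
  after <- which(slope > plateau_tol * smax * 3)
  after <- after[after > core[flat[length(flat)]]]
  if (length(after) == 0L) return(out)
  i0 <- after[1]
  curv <- abs(signal::sgolayfilt(d$pressure, p = 3, n = 11, m = 2L) /
                (d$area[2] - d$area[1])^2)
  seg <- seq(i0, n - edge)
  if (length(seg) < 3L) return(out)
  i_kink <- seg[which.max(curv[seg])]
  # refine: intersect straight-line fits on either side of the curvature
  # extremum (the smoothed pressure at the corner itself is biased)
  gap <- 5L
  span <- 25L
  lo <- seq(max(1L, i_kink - span), i_kink - gap)
  hi <- seq(i_kink + gap, min(n, i_kink + span))
  if (length(lo) >= 3L && length(hi) >= 3L) {
    f1 <- stats::lm.fit(cbind(1, d$area[lo]), d$pressure[lo])$coefficients
    f2 <- stats::lm.fit(cbind(1, d$area[hi]), d$pressure[hi])$coefficients
    if (abs(f1[2] - f2[2]) > 1e-10) {
      a_star <- (f2[1] - f1[1]) / (f1[2] - f2[2])
      p_star <- f1[1] + f1[2] * a_star
      if (a_star >= min(d$area[c(lo, hi)]) && a_star <= max(d$area[c(lo, hi)])) {
        out$kink_found <- TRUE
        out$kink_pressure <- unname(p_star)
        return(out)
      }
    }
  }
  out$kink_found <- TRUE
  out$kink_pressure <- d$pressure[i_kink]
  out
}

#' Excess area of mixing at one surface pressure
#'
#' Difference between the measured mixed-film area per molecule and the
#' mole-fraction-weighted areas of the pure components:
#' A_exc = A12 - (x1 A1 + x2 A2).
#'
#' @param A12 Mixed-film area per molecule, A^2.
#' @param x1 Mole fraction of component 1.
#' @param A1,A2 Pure-component areas per molecule at the same pressure, A^2.
#' @return Excess area in A^2/molecule.
#' @export
excess_area <- function(A12, x1, A1, A2) {
  if (x1 < 0 || x1 > 1) stop("x1 must be in [0, 1]")
  if (any(c(A12, A1, A2) <= 0)) stop("areas must be positive")
  A12 - (x1 * A1 + (1 - x1) * A2)
}

# Interpolate A(Pi) for one isotherm on a pressure grid; below the lowest
# measured pressure, hold the lowest-pressure area constant (documented
# lower-limit treatment of the excess-energy integral).
.area_on_pressure_grid <- function(iso, pi_grid) {
  o <- order(iso$pressure)
  p <- iso$pressure[o]
  a <- iso$area[o]
  # collapse plateau duplicates to keep approx() happy
  keep <- !duplicated(p)
  p <- p[keep]; a <- a[keep]
  out <- stats::approx(p, a, xout = pi_grid, rule = 1)$y
  out[pi_grid <= p[1]] <- a[1]
  out
}

#' Excess Gibbs energy of mixing from isotherms
#'
#' Trapezoid-rule integral of the excess area over surface pressure from 0
#' to `Pi_target`, converted to J/mol:
#' G_exc = N_A * integral(A_exc dPi). Pure-component and mixture areas are
#' interpolated onto a common pressure grid; below the lowest measured
#' pressure the integrand is held constant (ideal-gas-limit treatment).
#'
#' @param mixture,pure1,pure2 [isotherm()] objects; `mixture$x2` gives the
#'   composition (component 2 fraction).
#' @param Pi_target Upper integration limit, mN/m.
#' @param n_grid Number of pressure grid points (default 471).
#' @return G_exc in J/mol.
#' @export
excess_gibbs <- function(mixture, pure1, pure2, Pi_target, n_grid = 471L) {
  for (iso in list(mixture, pure1, pure2)) {
    if (max(iso$pressure) < Pi_target) {
      stop("isotherm does not reach the target pressure ", Pi_target, " mN/m")
    }
  }
  x2 <- mixture$x2
  x1 <- 1 - x2
  pi_grid <- seq(0, Pi_target, length.out = n_grid)
  a12 <- .area_on_pressure_grid(mixture, pi_grid)
  a1 <- .area_on_pressure_grid(pure1, pi_grid)
  a2 <- .area_on_pressure_grid(pure2, pi_grid)
  a_exc <- a12 - (x1 * a1 + x2 * a2)
  integral <- sum(diff(pi_grid) * (utils::head(a_exc, -1) + utils::tail(a_exc, -1)) / 2)
  # A^2 * mN/m = 1e-20 m^2 * 1e-3 N/m = 1e-23 J per molecule
  N_AVOGADRO * 1e-23 * integral
}

#' Ideal and total Gibbs energy of mixing
#'
#' Ideal term RT (x1 ln x1 + x2 ln x2) (with 0 ln 0 = 0), plus a supplied
#' excess term, giving the total Gibbs energy of mixing. The ideal term is
#' non-positive for any 0 < x1 < 1; a negative total indicates that the two
#' components mix.
#'
#' @param x1 Mole fraction of component 1, in \[0, 1\].
#' @param T_K Temperature, K.
#' @param G_exc Excess Gibbs energy, J/mol.
#' @return list with `ideal`, `excess`, `total` (J/mol).
#' @export
mixing_gibbs <- function(x1, T_K, G_exc) {
  if (x1 < 0 || x1 > 1) stop("x1 must be in [0, 1]")
  if (T_K <= 0) stop("temperature must be positive")
  x2 <- 1 - x1
  xlnx <- function(x) if (x <= 0) 0 else x * log(x)
  ideal <- R_GAS * T_K * (xlnx(x1) + xlnx(x2))
  list(ideal = ideal, excess = G_exc, total = ideal + G_exc)
}
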