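# Pseudo-Voigt band decomposition of infrared spectral regions, and the
# solvation-fraction and transition-dipole tilt analysis built on the fitted
# band areas. At a metal surface only the surface-normal electric field
# component is absorbed, so integrated band intensity relative to an
# isotropic (randomly oriented) reference encodes dipole orientation.

#' Pseudo-Voigt line profile
#'
#' Linear mixture of a Lorentzian and a Gaussian of common centre, height
#' and full width at half maximum: eta * L + (1 - eta) * G.
#'
#' @param x Abscissa (e.g. wavenumber, cm^-1).
#' @param center Peak centre.
#' @param fwhm Full width at half maximum (> 0).
#' @param height Peak height.
#' @param eta Lorentzian fraction in \[0, 1\].
#' @return Profile values at `x`.
#' @export
pseudo_voigt <- function(x, center, fwhm, height, eta = 0.5) {
  if (fwhm <= 0) stop("fwhm must be positive")
  if (eta < 0 || eta > 1) stop("eta must be in [0, 1]")
  u2 <- ((x - center) / (fwhm / 2))^2
  g <- exp(-log(2) * u2)
  l <- 1 / (1 + u2)
  height * (eta * l + (1 - eta) * g)
}

#' Construct a band model
#'
#' @param center,fwhm,height,eta Equal-length numeric vectors of peak
#'   parameters (see [pseudo_voigt()]).
#' @param baseline Length-2 numeric: intercept and slope of a linear
#'   baseline (default 0, 0).
#' @param region `"CH"` (six peaks conventional) or `"CO"` (three peaks).
#' @return Object of class `band_model`: data.frame of peaks with
#'   attributes `baseline` and `region`.
#' @export
band_model <- function(center, fwhm, height, eta = 0.5,
                       baseline = c(0, 0), region = c("CH", "CO")) {
  region <- match.arg(region)
  n <- length(center)
  eta <- rep_len(eta, n)
  if (any(fwhm <= 0)) stop("fwhm must be positive")
  if (any(eta < 0 | eta > 1)) stop("eta must be in [0, 1]")
  structure(
    data.frame(center = center, fwhm = rep_len(fwhm, n),
               height = rep_len(height, n), eta = eta),
    baseline = baseline, region = region,
    class = c("band_model", "data.frame")
  )
}

#' Evaluate a band model (all peaks plus baseline) on a grid
#' @param model A [band_model()].
#' @param x Wavenumber grid.
#' @return Numeric vector of model signal.
#' @export
eval_band_model <- function(model, x) {
  bl <- attr(model, "baseline")
  y <- bl[1] + bl[2] * (x - mean(x))
  for (i in seq_len(nrow(model))) {
    y <- y + pseudo_voigt(x, model$center[i], model$fwhm[i],
                          model$height[i], model$eta[i])
  }
  y
}

#' Closed-form area of a pseudo-Voigt peak
#'
#' eta * (pi/2) h w + (1 - eta) * h w (1/2) sqrt(pi / ln 2).
#'
#' @param fwhm,height,eta Peak parameters (vectors recycle).
#' @return Integrated peak area.
#' @export
peak_area <- function(fwhm, height, eta = 0.5) {
  if (any(fwhm <= 0)) stop("fwhm must be positive")
  g_area <- height * fwhm * 0.5 * sqrt(pi / log(2))
  l_area <- height * fwhm * pi / 2
  eta * l_area + (1 - eta) * g_area
}

#' Fit a band model to a spectrum
#'
#' Levenberg-Marquardt least squares over all peak centres, widths and
#' heights plus a linear baseline; the Lorentzian fractions eta are held at
#' their template values by default (set `fit_eta = TRUE` to free them).
#' Centre ordering of the template is preserved.
#'
#' @param wavenumber,signal Spectrum (monotone grid, finite signal).
#' @param template A [band_model()] providing initial values and the peak
#'   count (six for the C-H region, three for C=O, by convention).
#' @param fit_eta Free the mixing fractions (default FALSE).
#' @param center_window Allowed excursion of each centre from its template
#'   value, cm^-1 (default 10).
#' @return A fitted [band_model()] with attributes `rms` (residual RMS) and
#'   `convergence` (nls.lm info code).
#' @export
fit_bands <- function(wavenumber, signal, template, fit_eta = FALSE,
                      center_window = 10) {
  stopifnot(length(wavenumber) == length(signal))
  if (any(!is.finite(signal))) stop("signal must be finite")
  if (is.unsorted(wavenumber) && is.unsorted(rev(wavenumber))) {
    stop("wavenumber grid must be monotone")
  }
  if (any(template$center < min(wavenumber) | template$center > max(wavenumber))) {
    stop("template centres must lie inside the wavenumber grid")
  }
  np <- nrow(template)
  x0 <- c(template$center, log(template$fwhm), template$height,
          attr(template, "baseline"))
  if (fit_eta) x0 <- c(x0, stats::qlogis(pmin(pmax(template$eta, 1e-3), 1 - 1e-3)))
  unpack <- function(p) {
    ctr <- p[1:np]
    fw <- exp(p[(np + 1):(2 * np)])
    h <- p[(2 * np + 1):(3 * np)]
    bl <- p[(3 * np + 1):(3 * np + 2)]
    eta <- if (fit_eta) stats::plogis(p[(3 * np + 3):(4 * np + 2)]) else template$eta
    list(ctr = ctr, fw = fw, h = h, bl = bl, eta = eta)
  }
  resid_fn <- function(p) {
    q <- unpack(p)
    y <- q$bl[1] + q$bl[2] * (wavenumber - mean(wavenumber))
    for (i in seq_len(np)) {
      y <- y + pseudo_voigt(wavenumber, q$ctr[i], q$fw[i], q$h[i], q$eta[i])
    }
    y - signal
  }
  lo <- c(template$center - center_window, rep(-Inf, length(x0) - np))
  hi <- c(template$center + center_window, rep(Inf, length(x0) - np))
  fit <- minpack.lm::nls.lm(
    par = x0, fn = resid_fn, lower = lo, upper = hi,
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  if (fit$info == 0 || fit$info == 9) {
    stop("band fit did not converge (nls.lm info = ", fit$info,
         "); last RMS = ", signif(sqrt(mean(fit$fvec^2)), 4))
  }
  q <- unpack(fit$par)
  o <- order(q$ctr)
  out <- band_model(q$ctr[o], q$fw[o], q$h[o], q$eta[o],
                    baseline = q$bl, region = attr(template, "region"))
  attr(out, "rms") <- sqrt(mean(fit$fvec^2))
  attr(out, "convergence") <- fit$info
  out
}

#' Non-hydrogen-bonded fraction of ester carbonyls
#'
#' Ratio of the area of the ~1740 cm^-1 band (free C=O) to the total area
#' of all carbonyl components; the lower-wavenumber components arise from
#' hydrogen-bonded (solvated) carbonyls, so this fraction falls as the
#' ester region of a bilayer takes up water.
#'
#' @param co_model A fitted [band_model()] for the C=O region.
#' @param free_center Nominal centre of the free-carbonyl band (default
#'   1740 cm^-1); the nearest fitted peak is taken.
#' @return Fraction in \[0, 1\].
#' @export
solvation_fraction <- function(co_model, free_center = 1740) {
  areas <- peak_area(co_model$fwhm, co_model$height, co_model$eta)
  tot <- sum(areas)
  if (tot <= 0) stop("total carbonyl band area is zero; ratio undefined")
  i <- which.min(abs(co_model$center - free_center))
  areas[i] / tot
}

#' Transition-dipole angle from an intensity ratio
#'
#' At a metal surface the absorbed intensity scales as 3 cos^2(theta) times
#' the isotropic-reference intensity, so
#' theta = arccos(sqrt(I_exp / (3 I_iso))).
#'
#' @param I_exp Integrated experimental band intensity.
#' @param I_iso Integrated intensity of the same band in the simulated
#'   isotropic (randomly oriented) reference spectrum (> 0).
#' @param tol Tolerance above 3 for the ratio before erroring (default 0.02).
#' @return Dipole angle from the surface normal, degrees, in \[0, 90\].
#' @export
dipole_angle <- function(I_exp, I_iso, tol = 0.02) {
  if (I_iso <= 0) stop("isotropic reference intensity must be positive")
  ratio <- I_exp / I_iso
  if (ratio < 0) stop("negative intensity ratio")
  if (ratio > 3 + tol) {
    stop("unphysical intensity ratio ", signif(ratio, 4), " > 3")
  }
  ratio <- min(ratio, 3)
  acos(sqrt(ratio / 3)) * 180 / pi
}

#' Hydrocarbon chain tilt from the two methylene dipole angles
#'
#' The symmetric and asymmetric CH2 stretching dipoles and the chain axis
#' are mutually orthogonal, so their direction cosines satisfy
#' cos^2(theta_s) + cos^2(theta_as) + cos^2(theta_chain) = 1.
#'
#' @param theta_s,theta_as Dipole angles of the symmetric and asymmetric
#'   CH2 stretches, degrees from the surface normal.
#' @param tol Allowed excess of cos^2 sum over 1 before erroring; smaller
#'   excesses are clamped (default 0.02).
#' @return Chain tilt from the surface normal, degrees.
#' @export
chain_tilt <- function(theta_s, theta_as, tol = 0.02) {
  cs <- cos(theta_s * pi / 180)^2
  ca <- cos(theta_as * pi / 180)^2
  s <- cs + ca
  if (s > 1 + tol) {
    stop("inconsistent dipole angles: cos^2 sum = ", signif(s, 4), " > 1")
  }
  s <- min(s, 1)
  acos(sqrt(1 - s)) * 180 / pi
}

#' Standard six-band C-H region template
#'
#' Methylene symmetric (~2850) and asymmetric (~2920) stretches, methyl
#' symmetric (~2870) and asymmetric (~2960) stretches, and two Fermi
#' resonances (~2895, ~2935). Heights are placeholders for fitting.
#'
#' @param eta Lorentzian fraction (default 0.5).
#' @return A [band_model()].
#' @export
ch_template <- function(eta = 0.5) {
  band_model(
    center = c(2850, 2870, 2895, 2920, 2935, 2960),
    fwhm = c(10, 10, 14, 16, 14, 12),
    height = c(1, 0.4, 0.2, 1, 0.2, 0.4),
    eta = eta, region = "CH"
  )
}

#' Standard three-band C=O region template
#'
#' Free carbonyl (~1740) plus two hydrogen-bonded components (~1728, ~1710).
#'
#' @param eta Lorentzian fraction (default 0.5).
#' @return A [band_model()].
#' @export
co_template <- function(eta = 0.5) {
  band_model(
    center = c(1710, 1728, 1740),
    fwhm = c(18, 16, 12),
    height = c(0.3, 0.5, 0.8),
    eta = eta, region = "CO"
  )
}

#' Chain tilt from fitted C-H band areas
#'
#' Convenience wrapper for the full orientation analysis: take the fitted
#' areas of the methylene symmetric and asymmetric stretches, form ratios
#' against the isotropic reference areas, convert each to a dipole angle
#' and combine into the chain tilt. The methyl and Fermi-resonance bands
#' are fit components only and never enter the ratios.
#'
#' @param ch_model A fitted [band_model()] for the C-H region (six peaks).
#' @param iso_areas Named numeric with isotropic reference areas `nu_s`
#'   (~2850 band) and `nu_as` (~2920 band).
#' @return list with `theta_s`, `theta_as`, `theta_chain` (degrees) and the
#'   intensity ratios used.
#' @export
tilt_from_ch_fit <- function(ch_model, iso_areas) {
  stopifnot(all(c("nu_s", "nu_as") %in% names(iso_areas)))
  i_s <- which.min(abs(ch_model$center - 2850))
  i_as <- which.min(abs(ch_model$center - 2920))
  a_s <- peak_area(ch_model$fwhm[i_s], ch_model$height[i_s], ch_model$eta[i_s])
  a_as <- peak_area(ch_model$fwhm[i_as], ch_model$height[i_as], ch_model$eta[i_as])
  th_s <- dipole_angle(a_s, iso_areas[["nu_s"]])
  th_as <- dipole_angle(a_as, iso_areas[["nu_as"]])
  list(
    theta_s = th_s, theta_as = th_as,
    theta_chain = chain_tilt(th_s, th_as),
    ratio_s = a_s / iso_areas[["nu_s"]],
    ratio_as = a_as / iso_areas[["nu_as"]]
  )
}
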