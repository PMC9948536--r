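# Scattering-length / SLD bookkeeping and optical unit conversions shared by
# the scattering modules.

#' Product of Planck's constant and the speed of light, in keV * Angstrom
#' @keywords internal
.hc_kev_angstrom <- 12.39842

#' Classical electron radius in fm (X-ray scattering length per electron)
#' @keywords internal
.r_e_fm <- 2.8179403

#' Load a table of bound coherent neutron scattering lengths
#'
#' The package ships a small table (H, D, C, N, O, P, Na; Sears 1992 values,
#' in fm) used for all neutron scattering-length arithmetic. A user-supplied
#' CSV with columns `isotope`, `b_coh_fm` (comment lines starting `#`) may be
#' given to override it.
#'
#' @param path Optional path to a replacement CSV table.
#' @return An object of class `isotope_table`: a named numeric vector of
#'   scattering lengths in fm with a `source` attribute.
#' @examples
#' tab <- isotope_table()
#' tab[["D"]] - tab[["H"]]  # contrast gained per H/D exchange, fm
#' @export
isotope_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "isotopes.csv", package = "memlayer")
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("isotope", "b_coh_fm") %in% names(df))) {
    stop("isotope table must have columns 'isotope' and 'b_coh_fm'")
  }
  tab <- stats::setNames(as.numeric(df$b_coh_fm), df$isotope)
  if (!all(c("H", "D") %in% names(tab))) {
    stop("isotope table must contain both H and D")
  }
  if (tab[["D"]] - tab[["H"]] <= 0) {
    stop("isotope table invalid: b(D) - b(H) must be positive")
  }
  structure(tab, source = path, class = c("isotope_table", class(tab)))
}

#' Define a material by isotopic composition and molecular volume
#'
#' @param name Label for the material.
#' @param counts Named numeric vector of atom counts per formula unit, named
#'   by isotope label (e.g. `c(H = 2, O = 1)`); counts must be non-negative.
#' @param volume Molecular volume in cubic Angstrom; must be positive.
#' @param electrons Optional electron count per formula unit (for X-ray SLD).
#' @return An object of class `material`.
#' @examples
#' water <- material("H2O", c(H = 2, O = 1), volume = 29.96, electrons = 10)
#' @export
material <- function(name, counts, volume, electrons = NULL) {
  counts <- unlist(counts)
  if (length(counts) > 0 && (is.null(names(counts)) || any(!nzchar(names(counts))))) {
    stop("'counts' must be named by isotope")
  }
  if (any(counts < 0)) stop("atom counts must be non-negative")
  if (!is.numeric(volume) || length(volume) != 1 || volume <= 0) {
    stop("molecular volume must be a single positive number")
  }
  structure(
    list(name = name, counts = counts, volume = volume, electrons = electrons),
    class = "material"
  )
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s  V = %.2f A^3\n", x$name, x$volume))
  if (length(x$counts)) {
    cat("  ", paste(sprintf("%s:%g", names(x$counts), x$counts), collapse = " "), "\n")
  }
  invisible(x)
}

#' Read material definitions from a JSON config file
#'
#' The file holds an array of objects with fields `name`, `counts` (map from
#' isotope label to count), `volume`, and optionally `electrons`.
#'
#' @param path Path to the JSON file.
#' @return Named list of [material()] objects.
#' @export
read_materials <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  mats <- lapply(raw, function(m) {
    material(m$name, unlist(m$counts), m$volume,
             electrons = if (!is.null(m$electrons)) m$electrons else NULL)
  })
  stats::setNames(mats, vapply(mats, function(m) m$name, character(1)))
}

#' Convert photon energy to wavelength
#'
#' @param energy Photon energy in keV (positive).
#' @return Wavelength in Angstrom, lambda = hc / E with hc = 12.39842 keV A.
#' @examples
#' kev_to_angstrom(12.5)  # 0.9919 A
#' @export
kev_to_angstrom <- function(energy) {
  if (any(!is.finite(energy)) || any(energy <= 0)) {
    stop("photon energy must be positive")
  }
  .hc_kev_angstrom / energy
}

#' Brewster angle of an interface
#'
#' Angle of incidence at which p-polarised reflectivity vanishes,
#' arctan(n_transmitted / n_incident). For the air|water interface
#' (n about 1.334) this is about 53.1 degrees, the working angle of
#' Brewster-angle microscopy.
#'
#' @param n_incident Refractive index of the incident medium (positive).
#' @param n_transmitted Refractive index of the transmitting medium (positive).
#' @return Brewster angle in degrees.
#' @export
brewster_angle <- function(n_incident, n_transmitted) {
  if (n_incident <= 0 || n_transmitted <= 0) {
    stop("refractive indices must be positive")
  }
  atan2(n_transmitted, n_incident) * 180 / pi
}

#' Total bound coherent scattering length of a material
#'
#' @param mat A [material()].
#' @param table An [isotope_table()] (default the shipped one).
#' @return Sum over isotopes of count x b, in fm.
#' @export
scattering_length <- function(mat, table = isotope_table()) {
  if (length(mat$counts) == 0) return(0)
  missing <- setdiff(names(mat$counts), names(table))
  if (length(missing)) {
    stop("isotope(s) not in table: ", paste(missing, collapse = ", "))
  }
  sum(mat$counts * unclass(table)[names(mat$counts)])
}

#' Neutron scattering length density of a material
#'
#' @inheritParams scattering_length
#' @return SLD in units of 1e-6 per square Angstrom (1 fm = 1e-5 A).
#' @examples
#' d2o <- material("D2O", c(D = 2, O = 1), volume = 30.13)
#' sld(d2o)  # ~6.35
#' @export
sld <- function(mat, table = isotope_table()) {
  if (mat$volume <= 0) stop("molecular volume must be positive")
  b_fm <- scattering_length(mat, table)
  # b[fm] * 1e-5 A / V[A^3] -> A^-2; report in 1e-6 A^-2
  b_fm * 1e-5 / mat$volume * 1e6
}

#' X-ray scattering length density of a material
#'
#' Electron count times the classical electron radius, over the molecular
#' volume.
#'
#' @inheritParams scattering_length
#' @return X-ray SLD in units of 1e-6 per square Angstrom.
#' @export
xray_sld <- function(mat) {
  if (is.null(mat$electrons)) stop("material has no electron count")
  if (mat$volume <= 0) stop("molecular volume must be positive")
  mat$electrons * .r_e_fm * 1e-5 / mat$volume * 1e6
}

#' Air-contrast-matched water composition
#'
#' Volume fraction of D2O at which an H2O/D2O mixture has zero neutron SLD
#' (air-contrast-matched water, ACMW), solving
#' phi * rho_D2O + (1 - phi) * rho_H2O = 0.
#'
#' @param rho_d2o SLD of pure D2O (positive), 1e-6 A^-2.
#' @param rho_h2o SLD of pure H2O (negative), 1e-6 A^-2.
#' @return D2O volume fraction in (0, 1).
#' @examples
#' acmw_fraction(6.35, -0.56)  # about 0.08
#' @export
acmw_fraction <- function(rho_d2o, rho_h2o) {
  if (!(rho_d2o > 0 && rho_h2o < 0)) {
    stop("no zero-SLD mixture: need rho_d2o > 0 > rho_h2o")
  }
  -rho_h2o / (rho_d2o - rho_h2o)
}

#' Critical momentum transfer of total external reflection
#'
#' q_c = 4 sqrt(pi rho) for a subphase of SLD rho; below q_c the specular
#' reflectivity of an ideal interface is unity.
#'
#' @param rho_subphase Subphase SLD in absolute units (A^-2), non-negative.
#' @return q_c in inverse Angstrom; 0 (with a warning) for negative input.
#' @export
critical_q <- function(rho_subphase) {
  if (rho_subphase < 0) {
    warning("negative subphase SLD: no total-reflection edge; returning 0")
    return(0)
  }
  4 * sqrt(pi * rho_subphase)
}

#' Default water materials near 20 degrees C
#'
#' Molecular volumes 29.96 A^3 (H2O) and 30.13 A^3 (D2O); volumes are plain
#' fields and may be overridden for other temperatures.
#'
#' @return Named list with materials `H2O` and `D2O`.
#' @export
water_materials <- function() {
  list(
    H2O = material("H2O", c(H = 2, O = 1), volume = 29.96, electrons = 10),
    D2O = material("D2O", c(D = 2, O = 1), volume = 30.13, electrons = 10)
  )
}
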