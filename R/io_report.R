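# Text I/O for reflectivity curves (ORSO-style .ort dialect), spectrum and
# profile CSVs, provenance records for the analysis drivers, and the
# cross-technique consistency report.

#' Read a reflectivity curve from an ORSO-style text file
#'
#' Header lines start with `#`; data columns are q (1/A), R, dR and
#' optionally dq (FWHM q resolution, converted to a fractional dq/q).
#'
#' @param path File path.
#' @return list with `q`, `R`, `dR`, `dq_over_q` and any `# key: value`
#'   header fields as attribute `header`.
#' @export
read_ort <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  dat <- utils::read.table(text = lines[!grepl("^#|^\\s*$", lines)])
  if (ncol(dat) < 3) stop("expected at least 3 columns (q, R, dR) in ", path)
  dq_over_q <- if (ncol(dat) >= 4) stats::median(dat[[4]] / dat[[1]]) else 0
  kv <- hdr[grepl("^#\\s*\\S+\\s*:", hdr)]
  header <- if (length(kv)) {
    keys <- sub("^#\\s*([^:]+):.*$", "\\1", kv)
    vals <- trimws(sub("^#\\s*[^:]+:", "", kv))
    stats::setNames(as.list(vals), trimws(keys))
  } else list()
  structure(
    list(q = dat[[1]], R = dat[[2]], dR = dat[[3]], dq_over_q = dq_over_q),
    header = header
  )
}

#' Write a reflectivity curve to an ORSO-style text file
#'
#' @param curve list with `q`, `R`, `dR`, `dq_over_q`.
#' @param path Output path.
#' @param header Named list written as `# key: value` lines.
#' @export
write_ort <- function(curve, path, header = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# # ORSO reflectivity data file | 1.0 standard | YAML encoding | https://www.reflectometry.org/", con)
  for (k in names(header)) writeLines(sprintf("# %s: %s", k, header[[k]]), con)
  writeLines("# columns: [Qz (1/angstrom), R, sR, sQz (1/angstrom)]", con)
  dq <- curve$dq_over_q * curve$q
  utils::write.table(
    data.frame(q = curve$q, R = curve$R, dR = curve$dR, dq = dq),
    con, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read a spectrum CSV (`wavenumber_cm1`, `signal`)
#' @param path CSV path.
#' @return data.frame.
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  miss <- setdiff(c("wavenumber_cm1", "signal"), names(df))
  if (length(miss)) stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  df
}

#' Read a diffraction profile CSV (`qxy_A-1` or `qxy_A1`, `intensity`)
#' @param path CSV path.
#' @return data.frame with columns `qxy_A1`, `intensity`.
#' @export
read_gixd_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  qcol <- intersect(c("qxy_A-1", "qxy_A1"), names(df))
  if (!length(qcol) || !"intensity" %in% names(df)) {
    stop("profile CSV needs columns 'qxy_A-1' (or 'qxy_A1') and 'intensity' in ", path)
  }
  data.frame(qxy_A1 = df[[qcol[1]]], intensity = df$intensity)
}

#' Provenance record for an analysis output
#'
#' Every driver writes one of these next to its results so a run can be
#' reproduced: package version, R version, stage label, parameters and
#' seed.
#'
#' @param stage Stage label.
#' @param params Named list of parameters used.
#' @param seed RNG seed used (NA when the stage is deterministic).
#' @param path Optional JSON output path.
#' @return The record (invisibly when written to file).
#' @export
provenance_record <- function(stage, params = list(), seed = NA, path = NULL) {
  rec <- list(
    stage = stage,
    package = "memlayer",
    package_version = as.character(utils::packageVersion("memlayer")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    params = params
  )
  if (!is.null(path)) {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    return(invisible(rec))
  }
  rec
}

#' Cross-technique consistency report
#'
#' Checks that a diffraction-derived chain lattice and a reflectivity
#' two-slab fit describe the same monolayer: the tail-slab thickness
#' should match the chain length projected by the tilt
#' (L cos(tilt)), and the diffraction area per molecule should match the
#' area implied by the fit.
#'
#' @param lattice A [lattice2d()].
#' @param t_tail Fitted tail-slab thickness, A.
#' @param area_fit Fitted area per molecule, A^2.
#' @param chain_length Extended chain length, A.
#' @param thickness_tol Relative tolerance on thickness (default 0.1).
#' @param area_tol Relative tolerance on area (default 0.05).
#' @return list with the compared values, relative discrepancies and
#'   logical `flags` (empty character vector when consistent).
#' @export
consistency_report <- function(lattice, t_tail, area_fit, chain_length,
                               thickness_tol = 0.1, area_tol = 0.05) {
  t_expected <- chain_length * cos(lattice$tilt * pi / 180)
  d_thick <- abs(t_tail - t_expected) / t_expected
  d_area <- abs(area_fit - lattice$area_molecule_A2) / lattice$area_molecule_A2
  flags <- character(0)
  if (d_thick > thickness_tol) {
    flags <- c(flags, sprintf(
      "tail thickness %.2f A vs projected chain length %.2f A (%.1f%% off)",
      t_tail, t_expected, 100 * d_thick))
  }
  if (d_area > area_tol) {
    flags <- c(flags, sprintf(
      "fitted area %.2f A^2 vs diffraction area %.2f A^2 (%.1f%% off)",
      area_fit, lattice$area_molecule_A2, 100 * d_area))
  }
  list(
    t_tail = t_tail, t_expected = t_expected, rel_thickness = d_thick,
    area_fit = area_fit, area_gixd = lattice$area_molecule_A2,
    rel_area = d_area, consistent = length(flags) == 0L, flags = flags
  )
}
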