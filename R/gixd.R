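# Grazing-incidence diffraction analysis: Bragg-peak fitting in integrated
# I(q_xy) profiles and indexing to 2D unit cells of the hydrocarbon-chain
# lattice. One chain occupies one 2D cell; dimyristoyl lipids carry two
# chains, so area per molecule is twice the chain area.

#' Construct a 2D chain lattice
#'
#' @param a,b Cell edges, Angstrom.
#' @param gamma Cell angle, degrees (0 < gamma < 180).
#' @param tilt Chain tilt from the surface normal, degrees in \[0, 90).
#' @param azimuth Tilt azimuth, degrees from the a* direction, in \[0, 180).
#' @param chains_per_molecule Chains per lipid (default 2).
#' @return Object of class `lattice2d` with derived fields `area_chain_A2`
#'   (projected cell area per chain), `area_molecule_A2`,
#'   `cross_section_A2` (chain cross-section = projected area x cos tilt)
#'   and `cell_class` (hexagonal / distorted / oblique).
#' @export
lattice2d <- function(a, b, gamma, tilt = 0, azimuth = 0,
                      chains_per_molecule = 2) {
  if (a <= 0 || b <= 0) stop("cell edges must be positive")
  if (gamma <= 0 || gamma >= 180) stop("gamma must be in (0, 180) degrees")
  if (tilt < 0 || tilt >= 90) stop("tilt must be in [0, 90) degrees")
  area_xy <- a * b * sin(gamma * pi / 180)
  d <- .lattice_d_spacings(a, b, gamma)
  q <- sort(2 * pi / d)
  cls <- if (max(q) - min(q) < 1e-4 * mean(q)) "hexagonal"
         else if (min(diff(q)) < 1e-4 * mean(q)) "distorted"
         else "oblique"
  structure(
    list(a = a, b = b, gamma = gamma, tilt = tilt,
         azimuth = azimuth %% 180,
         area_chain_A2 = area_xy,
         area_molecule_A2 = chains_per_molecule * area_xy,
         cross_section_A2 = area_xy * cos(tilt * pi / 180),
         cell_class = cls),
    class = "lattice2d"
  )
}

#' @export
print.lattice2d <- function(x, ...) {
  cat(sprintf(
    "<lattice2d> %s  a = %.4f  b = %.4f A  gamma = %.3f deg  tilt = %.2f deg (az %.1f)\n",
    x$cell_class, x$a, x$b, x$gamma, x$tilt, x$azimuth
  ))
  cat(sprintf("  area/chain %.3f A^2  area/molecule %.3f A^2  cross-section %.3f A^2\n",
              x$area_chain_A2, x$area_molecule_A2, x$cross_section_A2))
  invisible(x)
}

# d spacings of the {1 0}, {0 1}, {1 -1} plane sets
.lattice_d_spacings <- function(a, b, gamma) {
  g <- gamma * pi / 180
  # reciprocal magnitudes: |a*| = 2 pi / (a sin g), |b*| = 2 pi / (b sin g),
  # |a* - b*| from gamma* = 180 - gamma
  qa <- 2 * pi / (a * sin(g))
  qb <- 2 * pi / (b * sin(g))
  cgs <- cos(pi - g)
  qab <- sqrt(qa^2 + qb^2 - 2 * qa * qb * cgs)
  2 * pi / c(qa, qb, qab)
}

#' Reciprocal-space peak positions of a tilted chain lattice
#'
#' Enumerates the {1 0}, {0 1} and {1 -1} reflections of a [lattice2d()],
#' with Bragg-rod maxima placed by the tilt relation
#' q_z = (G . u) tan(tilt) for in-plane reciprocal vector G and tilt
#' azimuth unit vector u (powder averaging makes the sign immaterial).
#'
#' @param lat A [lattice2d()].
#' @return data.frame with columns `h`, `k`, `qxy_A1`, `qz_A1`.
#' @export
lattice_peaks <- function(lat) {
  g <- lat$gamma * pi / 180
  qa <- 2 * pi / (lat$a * sin(g))
  qb <- 2 * pi / (lat$b * sin(g))
  gstar <- pi - g
  astar <- c(qa, 0)
  bstar <- c(qb * cos(gstar), qb * sin(gstar))
  hk <- rbind(c(1, 0), c(0, 1), c(1, -1))
  u <- c(cos(lat$azimuth * pi / 180), sin(lat$azimuth * pi / 180))
  tt <- tan(lat$tilt * pi / 180)
  out <- apply(hk, 1, function(m) {
    G <- m[1] * astar + m[2] * bstar
    c(qxy = sqrt(sum(G^2)), qz = abs(sum(G * u)) * tt)
  })
  data.frame(h = hk[, 1], k = hk[, 2],
             qxy_A1 = out["qxy", ], qz_A1 = out["qz", ])
}

#' Fit Bragg peaks in an integrated intensity profile
#'
#' Pseudo-Voigt peaks over a linear background, by Levenberg-Marquardt
#' least squares with initial positions at the strongest local maxima.
#' Profiles with no structure above the noise floor return zero peaks; a
#' fitted amplitude below `noise_mult` times the residual scale marks that
#' peak with a weak-feature flag.
#'
#' @param qxy,intensity Profile (monotone grid).
#' @param n_peaks Number of peaks to fit (1-3).
#' @param eta Lorentzian fraction of the line shape (default 0.3).
#' @param noise_mult Weak-feature multiplier (default 3).
#' @return data.frame with columns `qxy_A1`, `fwhm_A1`, `height`, `area`,
#'   `weak` plus attribute `background` (intercept, slope).
#' @export
fit_bragg_peaks <- function(qxy, intensity, n_peaks, eta = 0.3,
                            noise_mult = 3) {
  stopifnot(n_peaks %in% 1:3, length(qxy) == length(intensity))
  n <- length(qxy)
  # rough background: line through the profile's lower envelope
  bl <- stats::quantile(intensity, 0.2)
  resid0 <- intensity - bl
  noise <- stats::mad(diff(intensity)) / sqrt(2)
  if (max(resid0) < noise_mult * max(noise, 1e-12)) {
    out <- data.frame(qxy_A1 = numeric(0), fwhm_A1 = numeric(0),
                      height = numeric(0), area = numeric(0), weak = logical(0))
    attr(out, "background") <- c(bl, 0)
    return(out)
  }
  # initial centres: strongest separated local maxima of a smoothed profile
  k <- max(3L, 2L * floor(n / 80L) + 1L)
  sm <- stats::filter(intensity, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- intensity[is.na(sm)]
  cand <- which(diff(sign(diff(sm))) < 0) + 1L
  cand <- cand[order(sm[cand], decreasing = TRUE)]
  centers <- numeric(0)
  min_sep <- (max(qxy) - min(qxy)) / 30
  for (i in cand) {
    if (all(abs(qxy[i] - centers) > min_sep)) centers <- c(centers, qxy[i])
    if (length(centers) == n_peaks) break
  }
  while (length(centers) < n_peaks) {
    centers <- c(centers, mean(range(qxy)))
  }
  w0 <- rep(0.02, n_peaks)
  h0 <- pmax(stats::approx(qxy, intensity, xout = centers)$y - bl, noise)
  p0 <- c(centers, log(w0), h0, bl, 0)
  resid_fn <- function(p) {
    ctr <- p[1:n_peaks]
    fw <- exp(p[(n_peaks + 1):(2 * n_peaks)])
    h <- p[(2 * n_peaks + 1):(3 * n_peaks)]
    b <- p[3 * n_peaks + 1] + p[3 * n_peaks + 2] * (qxy - mean(qxy))
    y <- b
    for (i in seq_len(n_peaks)) y <- y + pseudo_voigt(qxy, ctr[i], fw[i], h[i], eta)
    y - intensity
  }
  fit <- minpack.lm::nls.lm(par = p0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  p <- fit$par
  ctr <- p[1:n_peaks]
  fw <- exp(p[(n_peaks + 1):(2 * n_peaks)])
  h <- p[(2 * n_peaks + 1):(3 * n_peaks)]
  rms <- sqrt(mean(fit$fvec^2))
  o <- order(ctr)
  out <- data.frame(
    qxy_A1 = ctr[o], fwhm_A1 = fw[o], height = h[o],
    area = peak_area(fw[o], h[o], eta),
    weak = h[o] < noise_mult * rms
  )
  attr(out, "background") <- p[3 * n_peaks + 1:2]
  out
}

#' Locate the maximum of a Bragg-rod profile
#'
#' Gaussian-plus-constant least-squares fit of I(q_z); the fitted centre,
#' clamped to q_z >= 0, is the rod maximum used by the tilt relations.
#'
#' @param qz,intensity Rod profile.
#' @return Rod maximum position, inverse Angstrom (>= 0).
#' @export
rod_maximum <- function(qz, intensity) {
  i0 <- which.max(intensity)
  p0 <- c(center = qz[i0], logw = log(0.2),
          h = max(intensity) - min(intensity), b = min(intensity))
  fn <- function(p) {
    p["b"] + p["h"] * exp(-log(2) * ((qz - p["center"]) / (exp(p["logw"]) / 2))^2) -
      intensity
  }
  fit <- minpack.lm::nls.lm(par = p0, fn = fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  max(0, unname(fit$par["center"]))
}

#' Index a single Bragg peak as a hexagonal chain lattice
#'
#' A single in-plane peak with its rod maximum at q_z = 0 means untilted
#' chains on a hexagonal net where the {1 1}, {1 0} and {0 1} d spacings
#' coincide: d = 2 pi / q_xy, a = 2 d / sqrt(3), area per chain
#' (sqrt(3)/2) a^2.
#'
#' @param qxy Peak position, inverse Angstrom.
#' @param qz Rod maximum (default 0); a value off zero beyond `qz_tol`
#'   raises an advisory error to use oblique indexing.
#' @param qz_tol Tolerance on the rod maximum (default 0.05).
#' @return A [lattice2d()] with `cell_class = "hexagonal"` and zero tilt.
#' @export
index_hexagonal <- function(qxy, qz = 0, qz_tol = 0.05) {
  if (qxy <= 0) stop("qxy must be positive")
  if (qz > qz_tol) {
    stop("rod maximum off zero (", signif(qz, 3),
         " 1/A): chains are tilted; use index_oblique")
  }
  d <- 2 * pi / qxy
  a <- 2 * d / sqrt(3)
  lattice2d(a, a, 120, tilt = 0, azimuth = 0)
}

#' Index three Bragg peaks as an oblique chain lattice with tilted chains
#'
#' Assigns the three (q_xy, q_z) peaks to the {1 0}, {0 1} and {1 -1}
#' reflections (degenerate peaks may be passed twice), reconstructs the
#' reciprocal and real cells, and solves the rod-maximum relations
#' q_z = |G . u| tan(tilt) for the tilt magnitude and azimuth by trying
#' the sign combinations of the powder-averaged rods. Among the valid
#' peak-label assignments the one minimising the cell area is kept
#' (lowest-index convention).
#'
#' @param qxy,qz Length-3 numeric vectors of peak positions and rod maxima.
#' @param qz_res_tol Residual tolerance (1/A) on the tilt solution
#'   (default 1e-3 + 2\% of max q_z).
#' @return A [lattice2d()].
#' @export
index_oblique <- function(qxy, qz = c(0, 0, 0), qz_res_tol = NULL) {
  stopifnot(length(qxy) == 3, length(qz) == 3)
  if (any(qxy <= 0)) stop("qxy must be positive")
  if (is.null(qz_res_tol)) qz_res_tol <- 1e-3 + 0.02 * max(qz)
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  best <- NULL
  for (r in seq_len(nrow(perms))) {
    pp <- perms[r, ]
    qa <- qxy[pp[1]]; qb <- qxy[pp[2]]; qab <- qxy[pp[3]]
    cgs <- (qa^2 + qb^2 - qab^2) / (2 * qa * qb)
    if (abs(cgs) >= 1) next
    gstar <- acos(cgs)
    astar <- c(qa, 0)
    bstar <- c(qb * cos(gstar), qb * sin(gstar))
    G <- rbind(astar, bstar, astar - bstar)
    qz3 <- qz[pp]
    # tilt vector v = tan(t) u from |G_i . v| = qz_i; try rod signs
    sol <- NULL
    for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
      rhs <- qz3 * c(1, s2, s3)
      v <- tryCatch(stats::lm.fit(G, rhs)$coefficients, error = function(e) NULL)
      if (is.null(v) || any(!is.finite(v))) next
      res <- max(abs(abs(G %*% v) - qz3))
      if (is.null(sol) || res < sol$res) sol <- list(v = v, res = res)
    }
    if (is.null(sol) || sol$res > qz_res_tol) next
    tilt <- atan(sqrt(sum(sol$v^2))) * 180 / pi
    # real-space basis in the frame with a* along x
    rot90 <- function(p) c(-p[2], p[1])
    A_vec <- 2 * pi * rot90(bstar) / sum(astar * rot90(bstar))
    B_vec <- 2 * pi * rot90(astar) / sum(bstar * rot90(astar))
    # Lagrange reduction to the canonical (shortest-vector) cell
    repeat {
      if (sum(B_vec^2) < sum(A_vec^2)) { tmp <- A_vec; A_vec <- B_vec; B_vec <- tmp }
      mu <- round(sum(A_vec * B_vec) / sum(A_vec * A_vec))
      if (mu == 0) break
      B_vec <- B_vec - mu * A_vec
    }
    a <- sqrt(sum(A_vec^2))
    b <- sqrt(sum(B_vec^2))
    cg <- sum(A_vec * B_vec) / (a * b)
    if (cg > 0) { B_vec <- -B_vec; cg <- -cg }  # obtuse-gamma convention
    gamma <- acos(pmin(pmax(cg, -1), 1)) * 180 / pi
    # azimuth of the tilt direction from the (reduced) a* direction
    az <- 0
    if (sum(sol$v^2) > 0) {
      astar_new <- rot90(B_vec)  # a* is perpendicular to B
      if (sum(astar_new * A_vec) < 0) astar_new <- -astar_new
      az <- ((atan2(sol$v[2], sol$v[1]) -
                atan2(astar_new[2], astar_new[1])) * 180 / pi) %% 180
    }
    lat <- lattice2d(a, b, gamma, tilt = tilt, azimuth = az)
    if (is.null(best) || lat$area_chain_A2 < best$area_chain_A2 - 1e-9) best <- lat
  }
  if (is.null(best)) {
    stop("indexing failure: no consistent cell/tilt solution for these peaks")
  }
  best
}

#' Index fitted peaks, choosing the cell type from the peak count
#'
#' One peak: hexagonal untilted. Two peaks: the stronger (degenerate) peak
#' is duplicated and the triple indexed as a distorted cell. Three peaks:
#' oblique indexing.
#'
#' @param peaks data.frame from [fit_bragg_peaks()].
#' @param qz Rod maxima for each peak (same order), default all zero.
#' @return A [lattice2d()].
#' @export
index_peaks <- function(peaks, qz = rep(0, nrow(peaks))) {
  n <- nrow(peaks)
  if (n == 0L) stop("no peaks to index")
  if (n == 1L) return(index_hexagonal(peaks$qxy_A1, qz[1]))
  if (n == 2L) {
    dup <- which.max(peaks$area)
    return(index_oblique(c(peaks$qxy_A1, peaks$qxy_A1[dup]),
                         c(qz, qz[dup])))
  }
  index_oblique(peaks$qxy_A1[1:3], qz[1:3])
}

#' Chain cross-section from projected area and tilt
#'
#' A0 = A_xy cos(tilt): the area a tilted chain projects onto the surface
#' shrinks back to its perpendicular cross-section.
#'
#' @param area_xy Projected (in-plane) area, A^2.
#' @param tilt Chain tilt, degrees in \[0, 90).
#' @return Cross-sectional area, A^2.
#' @export
tilt_area_relation <- function(area_xy, tilt) {
  if (tilt < 0 || tilt >= 90) stop("tilt must be in [0, 90) degrees")
  area_xy * cos(tilt * pi / 180)
}
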