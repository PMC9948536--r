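# Reduction of potential-step current transients to absolute charge-density
# curves for electrode-supported bilayers, and quantities derived from them.

#' Construct a set of potential-step current transients
#'
#' @param potential Numeric vector of step potentials (V vs reference), one
#'   per transient.
#' @param transients List (same length) of data.frames with columns `time_s`
#'   (strictly increasing from 0) and `current_uA_cm2`. Cathodic current is
#'   negative.
#' @return Object of class `transient_set`.
#' @export
transient_set <- function(potential, transients) {
  if (length(potential) != length(transients)) {
    stop("one transient per potential required")
  }
  for (tr in transients) {
    if (!all(c("time_s", "current_uA_cm2") %in% names(tr))) {
      stop("each transient needs columns 'time_s' and 'current_uA_cm2'")
    }
    if (tr$time_s[1] < 0 || any(diff(tr$time_s) <= 0)) {
      stop("transient time series must be strictly increasing from 0")
    }
  }
  structure(list(potential = potential, transients = transients),
            class = "transient_set")
}

#' Read transients from long-format CSV
#'
#' Columns `potential_V`, `time_s`, `current_uA_cm2`; rows grouped by
#' potential.
#'
#' @param path CSV file path.
#' @return A [transient_set()].
#' @export
read_transients_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("potential_V", "time_s", "current_uA_cm2")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  pots <- unique(df$potential_V)
  trs <- lapply(pots, function(p) {
    sub <- df[df$potential_V == p, c("time_s", "current_uA_cm2")]
    sub[order(sub$time_s), ]
  })
  transient_set(pots, trs)
}

#' Integrate current transients to relative charge densities
#'
#' Trapezoid integral of current density over time for each potential step;
#' transients whose final current has not decayed below `decay_floor` are
#' flagged rather than extrapolated.
#'
#' @param ts A [transient_set()].
#' @param decay_floor Absolute current (uA/cm^2) below which a transient is
#'   considered fully decayed (default 0.05).
#' @return data.frame with columns `potential_V`, `charge_uC_cm2`,
#'   `decayed` (logical flag).
#' @export
integrate_transients <- function(ts, decay_floor = 0.05) {
  out <- lapply(seq_along(ts$potential), function(i) {
    tr <- ts$transients[[i]]
    t <- tr$time_s
    j <- tr$current_uA_cm2
    q <- sum(diff(t) * (utils::head(j, -1) + utils::tail(j, -1)) / 2)
    decayed <- abs(j[length(j)]) <= decay_floor
    if (!decayed) {
      warning(sprintf("transient at %.3f V has not decayed below %.3g uA/cm2",
                      ts$potential[i], decay_floor))
    }
    data.frame(potential_V = ts$potential[i], charge_uC_cm2 = q, decayed = decayed)
  })
  do.call(rbind, out)
}

#' Anchor relative charge densities at the potential of zero charge
#'
#' Adds the constant offset that makes the bare-electrode curve pass through
#' zero charge at the pzc; the same offset applies to film-covered curves
#' measured against the same desorption reference.
#'
#' @param relative data.frame with `potential_V`, `charge_uC_cm2` (relative).
#' @param pzc Potential of zero charge (V); interpolation within the
#'   measured range, extrapolation triggers a warning.
#' @param label `"bare"` or `"film"`.
#' @param offset Optional explicit offset (uC/cm^2); when `NULL` (bare
#'   curves) it is computed as -sigma_rel(pzc).
#' @return Object of class `charge_curve`: data.frame `potential_V`,
#'   `sigma_uC_cm2` with attributes `label`, `pzc`, `offset`.
#' @export
anchor_to_pzc <- function(relative, pzc, label = "bare", offset = NULL) {
  o <- order(relative$potential_V)
  E <- relative$potential_V[o]
  q <- relative$charge_uC_cm2[o]
  if (is.null(offset)) {
    if (pzc < min(E) || pzc > max(E)) {
      warning("pzc outside the measured potential range; extrapolating")
      offset <- -stats::approx(E, q, xout = pzc, rule = 2)$y
    } else {
      offset <- -stats::approx(E, q, xout = pzc)$y
    }
  }
  structure(
    data.frame(potential_V = E, sigma_uC_cm2 = q + offset),
    label = label, pzc = pzc, offset = offset,
    class = c("charge_curve", "data.frame")
  )
}

#' Differential capacitance from a charge-density curve
#'
#' Local slope d(sigma)/dE by central finite differences on the measured
#' potential grid; for the adsorbed state this is the interfacial
#' capacitance.
#'
#' @param curve A `charge_curve` (or data.frame with `potential_V`,
#'   `sigma_uC_cm2`).
#' @return data.frame with `potential_V`, `capacitance_uF_cm2`.
#' @export
differential_capacitance <- function(curve) {
  E <- curve$potential_V
  s <- curve$sigma_uC_cm2
  n <- length(E)
  if (n < 3L) stop("need at least 3 points for a capacitance estimate")
  dc <- numeric(n)
  dc[1] <- (s[2] - s[1]) / (E[2] - E[1])
  dc[n] <- (s[n] - s[n - 1]) / (E[n] - E[n - 1])
  dc[2:(n - 1)] <- (s[3:n] - s[1:(n - 2)]) / (E[3:n] - E[1:(n - 2)])
  data.frame(potential_V = E, capacitance_uF_cm2 = dc)
}

#' Detect adsorption-state steps in a charge-density curve
#'
#' Steps in sigma(E) mark transitions between adsorption states of a
#' supported bilayer (directly adsorbed, electrolyte-cushioned, desorbed).
#' Boundaries are local maxima of |d(sigma)/dE| exceeding a threshold
#' multiple of the median slope magnitude.
#'
#' @param curve A `charge_curve`.
#' @param threshold Multiplier of the median |slope| defining candidate
#'   step intervals (default 3).
#' @param noise_mult Boundaries must additionally clear the median slope
#'   plus this many robust (MAD) slope deviations (default 5), so isolated
#'   noise spikes are not reported as state transitions.
#' @param max_run Longest run of consecutive above-threshold grid intervals
#'   still counted as one step (default 2); longer runs are steep
#'   capacitive branches, not steps.
#' @return list with `boundaries_V` (possibly empty, sorted ascending),
#'   `candidates_V` (all interval midpoints above the plain threshold) and
#'   `regions`: labels between boundaries, most negative first
#'   (`desorbed`, `II`, `I` as available).
#' @export
detect_state_steps <- function(curve, threshold = 3, noise_mult = 5,
                               max_run = 2L) {
  E <- curve$potential_V
  s <- curve$sigma_uC_cm2
  g <- abs(diff(s) / diff(E))  # slope of each grid interval
  mid <- (E[-length(E)] + E[-1]) / 2
  cand_thr <- threshold * stats::median(g)
  candidates <- mid[g > cand_thr]
  thr <- max(cand_thr, stats::median(g) + noise_mult * stats::mad(g))
  idx <- which(g > thr)
  bnd <- numeric(0)
  if (length(idx)) {
    grp <- cumsum(c(1, diff(idx) > 1))
    for (run in split(idx, grp)) {
      if (length(run) > max_run) {
        # extended steep branch: only an embedded, clearly sharper interval
        # (a step riding on the branch) counts
        if (max(g[run]) <= 2 * stats::median(g[run])) next
      }
      i <- run[which.max(g[run])]
      bnd <- c(bnd, (E[i] + E[i + 1L]) / 2)
    }
  }
  bnd <- sort(bnd)
  labels_all <- c("desorbed", "II", "I")
  k <- length(bnd)
  regions <- if (k == 0L) "I"
             else if (k < 3L) utils::tail(labels_all, k + 1L)
             else c(labels_all, paste0("region", seq_len(k - 2L)))
  list(boundaries_V = bnd, candidates_V = candidates, regions = regions)
}

#' Film pressure of an adsorbed layer from charge-density curves
#'
#' The free-energy lowering by the film is the area between the film-covered
#' and bare charge-density curves over a potential range:
#' Phi = integral(sigma_film - sigma_bare) dE, with
#' 1 uC V / cm^2 = 10 mN/m.
#'
#' @param film,bare `charge_curve` objects (interpolated onto a common
#'   grid over `E_range`).
#' @param E_range Length-2 potential interval (V).
#' @param n_grid Grid points for the integral (default 201).
#' @return Film pressure in mN/m.
#' @export
film_pressure <- function(film, bare, E_range, n_grid = 201L) {
  E_range <- range(E_range)
  for (cc in list(film, bare)) {
    if (min(cc$potential_V) > E_range[1] || max(cc$potential_V) < E_range[2]) {
      stop("charge curve does not cover the requested potential range")
    }
  }
  grid <- seq(E_range[1], E_range[2], length.out = n_grid)
  sf <- stats::approx(film$potential_V, film$sigma_uC_cm2, xout = grid)$y
  sb <- stats::approx(bare$potential_V, bare$sigma_uC_cm2, xout = grid)$y
  d <- sf - sb
  integral <- sum(diff(grid) * (utils::head(d, -1) + utils::tail(d, -1)) / 2)
  10 * integral
}

#' Write a charge curve to CSV
#' @param curve A `charge_curve`.
#' @param path Output file.
#' @export
write_charge_curve_csv <- function(curve, path) {
  utils::write.csv(
    data.frame(potential_V = curve$potential_V, sigma_uC_cm2 = curve$sigma_uC_cm2),
    path, row.names = FALSE
  )
  invisible(path)
}
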