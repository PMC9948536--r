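#!/usr/bin/env Rscript
# PM-IRRAS band analysis: decompose C-H region spectra generated at a
# series of chain tilts (emulating the response of a bilayer to surface
# charge), recover the tilt from the methylene dipole intensity ratios,
# and track the ester-carbonyl solvation fraction from C=O region spectra.

library(memlayer)

dir.create("results", showWarnings = FALSE)
seed <- 303L

## Chain tilt vs an applied-charge-like index: tilts rise towards negative
## charge then relax on desorption.
cat("== chain tilt from the C-H stretching region ==\n")
tilt_truth <- c(28, 30, 33, 36, 34, 29)
charge_idx <- seq(5, -20, length.out = length(tilt_truth))  # uC/cm2, nominal
rows <- list()
for (i in seq_along(tilt_truth)) {
  g <- gen_ir_spectrum("CH", tilt_deg = tilt_truth[i], noise_frac = 0.01,
                       seed = seed + i)
  fit <- fit_bands(g$wavenumber, g$signal, ch_template(eta = 0.3))
  res <- tilt_from_ch_fit(fit, g$truth$iso_areas)
  i_s <- which.min(abs(fit$center - 2850))
  i_as <- which.min(abs(fit$center - 2920))
  rows[[i]] <- data.frame(
    charge_uC_cm2 = charge_idx[i], tilt_truth_deg = tilt_truth[i],
    tilt_deg = res$theta_chain,
    nu_s_cm1 = fit$center[i_s], nu_as_cm1 = fit$center[i_as],
    fwhm_s_cm1 = fit$fwhm[i_s], fwhm_as_cm1 = fit$fwhm[i_as]
  )
  cat(sprintf("  charge %+5.1f: tilt %.1f deg (truth %.0f), nu_s %.1f, nu_as %.1f cm-1\n",
              charge_idx[i], res$theta_chain, tilt_truth[i],
              fit$center[i_s], fit$center[i_as]))
}
tilts <- do.call(rbind, rows)
write.csv(tilts, "results/pmirras_tilt.csv", row.names = FALSE)
stopifnot(max(abs(tilts$tilt_deg - tilts$tilt_truth_deg)) < 3)
cat("all tilts recovered within the 3 degree spectroscopic uncertainty\n")

## Carbonyl solvation: the free-C=O (1740 cm-1) share drops as water
## enters the ester region.
cat("\n== carbonyl solvation from the C=O stretching region ==\n")
solv_truth <- c(0.65, 0.55, 0.45, 0.35)
rows <- list()
for (i in seq_along(solv_truth)) {
  g <- gen_ir_spectrum("CO", solvation = solv_truth[i], noise_frac = 0.01,
                       seed = seed + 50 + i)
  fit <- fit_bands(g$wavenumber, g$signal, co_template(eta = 0.3))
  rows[[i]] <- data.frame(solvation_truth = solv_truth[i],
                          solvation = solvation_fraction(fit))
  cat(sprintf("  truth %.2f -> recovered %.3f\n", solv_truth[i],
              rows[[i]]$solvation))
}
solv <- do.call(rbind, rows)
write.csv(solv, "results/pmirras_solvation.csv", row.names = FALSE)

provenance_record("pmirras", params = list(noise_frac = 0.01, eta = 0.3),
                  seed = seed, path = "results/pmirras_provenance.json")
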