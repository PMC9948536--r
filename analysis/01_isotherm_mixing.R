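#!/usr/bin/env Rscript
# Monolayer mechanics and mixing thermodynamics of a binary phospholipid
# family. Generates a composition series with a small prescribed positive
# excess area (near-ideal mixing, as seen for PE/PS monolayers), then runs
# the full isotherm analysis: compressibility modulus, phase features,
# limiting area, excess area/Gibbs energy at 47 mN/m, and the total Gibbs
# energy of mixing.

library(memlayer)

dir.create("results", showWarnings = FALSE)
seed <- 101L
set.seed(seed)

## Phase-structured isotherms: plateau and kink pressures fall with x2,
## mimicking the PS-content trend.
cat("== phase features across the composition series ==\n")
feature_rows <- list()
for (x2 in c(0, 0.1, 0.5, 1)) {
  g <- gen_isotherm(x2 = x2, plateau_Pi = 22 - 8 * x2, kink_Pi = 38 - 10 * x2,
                    noise_sd = 0.05, seed = seed + round(100 * x2))
  f <- detect_phase_features(g$isotherm)
  cm <- compressibility_modulus(g$isotherm)
  a_lim <- limiting_area(g$isotherm, c(45, 65))
  feature_rows[[length(feature_rows) + 1L]] <- data.frame(
    x2 = x2, plateau_mN_m = f$plateau_pressure, kink_mN_m = f$kink_pressure,
    cs_inv_max_mN_m = max(cm$cs_inv_mN_m), A_lim_A2 = a_lim
  )
  cat(sprintf("  x2 = %.1f: plateau %.1f mN/m, kink %.1f mN/m, max Cs-1 %.0f mN/m, A_lim %.1f A2\n",
              x2, f$plateau_pressure, f$kink_pressure, max(cm$cs_inv_mN_m), a_lim))
}
features <- do.call(rbind, feature_rows)
write.csv(features, "results/isotherm_features.csv", row.names = FALSE)

## Mixing thermodynamics on a plateau-free family with a small positive
## excess area peaking at x2 = 0.5 (0.5 A^2), evaluated at 47 mN/m.
cat("\n== mixing thermodynamics at 47 mN/m ==\n")
a_exc_truth <- function(x2, Pi) 2 * x2 * (1 - x2) * exp(-Pi / 80)
fam <- gen_isotherm_family(x2_values = c(0.1, 0.3, 0.5, 0.7, 0.9),
                           A_exc_fn = a_exc_truth)
rows <- list()
for (x2 in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  iso <- fam$isotherms[[as.character(x2)]]
  gexc <- excess_gibbs(iso, fam$isotherms[["0"]], fam$isotherms[["1"]], 47)
  mg <- mixing_gibbs(1 - x2, iso$T_K, gexc)
  a47 <- sapply(list(iso, fam$isotherms[["0"]], fam$isotherms[["1"]]), function(s) {
    approx(s$pressure, s$area, xout = 47)$y
  })
  rows[[length(rows) + 1L]] <- data.frame(
    x2 = x2, A_exc_A2 = excess_area(a47[1], 1 - x2, a47[2], a47[3]),
    G_exc_J_mol = gexc, G_ideal_J_mol = mg$ideal, G_total_J_mol = mg$total
  )
  cat(sprintf("  x2 = %.1f: A_exc %.3f A2, G_exc %+.0f, ideal %+.0f, total %+.0f J/mol\n",
              x2, rows[[length(rows)]]$A_exc_A2, gexc, mg$ideal, mg$total))
}
mixing <- do.call(rbind, rows)
write.csv(mixing, "results/isotherm_mixing.csv", row.names = FALSE)
stopifnot(all(mixing$G_total_J_mol < 0))  # the components mix
cat("\nAll total mixing energies are negative: the two lipids mix.\n")

provenance_record("isotherm_mixing",
                  params = list(Pi_target = 47, A_exc_peak_A2 = 0.5),
                  seed = seed, path = "results/isotherm_mixing_provenance.json")
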