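# Shared fixtures built in code.

# A random absorption-free slab stack for forward-model cross-checks.
random_stack <- function(n_slabs = sample(1:5, 1)) {
  slab_stack(
    data.frame(sld = stats::runif(n_slabs, -2, 9),
               thick = stats::runif(n_slabs, 5, 80)),
    backing_sld = stats::runif(1, 1, 9.5),
    roughness = stats::runif(1, 0, 6)
  )
}

# Bare-electrode charge-density truth: single capacitance through the pzc.
sigma_bare_truth <- function(E, pzc = 0.315, C = 20) C * (E - pzc)

# Exact Fresnel reflectivity of a bare interface with backing SLD rho
# (1e-6 A^-2) at momentum transfer q — independent closed form.
fresnel_exact <- function(q, rho) {
  qc2 <- 16 * pi * rho * 1e-6
  kr <- sqrt(as.complex(q^2 - qc2))
  Mod((q - kr) / (q + kr))^2
}
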