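# Random parameter record with all fields drawn log-uniformly within a
# factor `spread` of the given preset's defaults (structural zeros stay 0).
random_params <- function(mode = "mutualism", spread = 10) {
  p <- preset_params(mode)
  for (nm in names(p)) {
    if (p[[nm]] > 0)
      p[[nm]] <- p[[nm]] * exp(runif(1, -log(spread), log(spread)))
  }
  validate <- phagetrade:::validate_params
  validate(p)
  structure(p, class = "community_params")
}

# Symmetric parameter record: invariant under the prey swap E <-> S.
random_symmetric_params <- function(mode = "mutualism", spread = 4) {
  p <- random_params(mode, spread)
  p$alpha_SE <- p$alpha_ES
  p$beta_SE <- p$beta_ES
  p$mu_S <- p$mu_E
  p$kappa_S <- p$kappa_E
  p$gamma_SG <- p$gamma_EG
  p$sigma_SG <- p$sigma_EG
  p$delta_S <- p$delta_E
  p
}

# Roots of the symmetric phage-free mutualism equilibrium condition
# x^2 - (1 - 2 delta/mu) x + 2 delta/mu ... at the Table defaults:
# x^2 - 0.94 x + 0.06 = 0.
mutualism_prey_roots <- function() {
  (0.94 + c(1, -1) * sqrt(0.94^2 - 4 * 0.06)) / 2
}
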