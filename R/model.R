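#' Community state
#'
#' A single time point of the four-species community. Densities are
#' dimensionless biomass and must be non-negative.
#'
#' @param E,S prey biomass.
#' @param G generalist phage biomass.
#' @param P specialist phage biomass.
#' @param t time (dimensionless), default 0.
#' @return Named numeric vector of class `community_state` with elements
#'   `E`, `S`, `G`, `P` and a `t` attribute.
#' @export
community_state <- function(E, S, G = 0, P = 0, t = 0) {
  x <- c(E = E, S = S, G = G, P = P)
  if (any(!is.finite(x))) stop("state components must be finite")
  if (any(x < 0)) stop("state components must be non-negative")
  structure(x, t = t, class = c("community_state", "numeric"))
}

state_vec <- function(state) {
  x <- unclass(state)
  if (is.null(names(x))) {
    if (length(x) != 4) stop("state must have 4 components E, S, G, P")
    names(x) <- c("E", "S", "G", "P")
  } else {
    x <- x[c("E", "S", "G", "P")]
    if (any(is.na(x))) stop("state must have named components E, S, G, P")
  }
  x
}

# Saturating mutualistic benefit bracket alpha*partner/(alpha*partner+kappa).
# kappa == 0 switches the bracket off (identically 1, including at the 0/0
# point where the partner is absent), recovering plain logistic competition.
sat_bracket <- function(alpha, partner, kappa) {
  if (kappa == 0) return(1)
  a <- alpha * partner
  a / (a + kappa)
}

#' Right-hand side of the community dynamics
#'
#' Time derivatives of the four species. Prey grow logistically toward the
#' shared carrying capacity `R`, modulated by the saturating mutualistic
#' benefit of the partner prey and reduced by the competitive pressure
#' `beta * partner`; they are lost to phage adsorption and intrinsic
#' death/dilution. Phage grow by burst-size-weighted adsorption on their
#' hosts and are lost to death/dilution:
#'
#' \deqn{dE/dt = \mu_E E \frac{\alpha_{ES} S}{\alpha_{ES} S + \kappa_E}
#'   (R - E - \beta_{ES} S) - \varsigma_{EG} G E - \delta_E E}
#' \deqn{dS/dt = \mu_S S \frac{\alpha_{SE} E}{\alpha_{SE} E + \kappa_S}
#'   (R - S - \beta_{SE} E) - \varsigma_{SP} P S - \varsigma_{SG} G S
#'   - \delta_S S}
#' \deqn{dG/dt = \gamma_{SG}\varsigma_{SG} G S +
#'   \gamma_{EG}\varsigma_{EG} G E - \delta_G G}
#' \deqn{dP/dt = \gamma_{SP}\varsigma_{SP} P S - \delta_P P}
#'
#' The logistic term is deliberately not clamped at zero: overshoot beyond
#' capacity yields negative per-capita growth, as in standard
#' Lotka-Volterra.
#'
#' @param state a [community_state()] or named numeric vector `E,S,G,P`.
#' @param params a [community_params()] record.
#' @return Named numeric derivative vector `(dE, dS, dG, dP)`.
#' @export
community_rhs <- function(state, params) {
  x <- state_vec(state)
  if (any(x < 0)) stop("negative state component (solver overshoot?)")
  rhs_raw(x, params)
}

# Unchecked core used inside the integrator (adaptive solvers may probe
# slightly negative states; the polynomial form is well-defined there).
rhs_raw <- function(x, p) {
  E <- x[[1L]]; S <- x[[2L]]; G <- x[[3L]]; P <- x[[4L]]
  brE <- sat_bracket(p$alpha_ES, S, p$kappa_E)
  brS <- sat_bracket(p$alpha_SE, E, p$kappa_S)
  dE <- p$mu_E * E * brE * (p$R - E - p$beta_ES * S) -
    p$sigma_EG * G * E - p$delta_E * E
  dS <- p$mu_S * S * brS * (p$R - S - p$beta_SE * E) -
    p$sigma_SP * P * S - p$sigma_SG * G * S - p$delta_S * S
  dG <- p$gamma_SG * p$sigma_SG * G * S +
    p$gamma_EG * p$sigma_EG * G * E - p$delta_G * G
  dP <- p$gamma_SP * p$sigma_SP * P * S - p$delta_P * P
  c(E = dE, S = dS, G = dG, P = dP)
}

#' Analytic Jacobian of the community dynamics
#'
#' Closed-form partial derivatives of [community_rhs()] with respect to the
#' four state variables. When `kappa = 0` the saturating bracket is the
#' constant 1 and its derivative vanishes.
#'
#' @inheritParams community_rhs
#' @return 4 x 4 numeric matrix, rows and columns ordered `E, S, G, P`.
#' @export
community_jacobian <- function(state, params) {
  x <- state_vec(state)
  p <- params
  E <- x[[1L]]; S <- x[[2L]]; G <- x[[3L]]; P <- x[[4L]]
  brE <- sat_bracket(p$alpha_ES, S, p$kappa_E)
  brS <- sat_bracket(p$alpha_SE, E, p$kappa_S)
  # d(bracket)/d(partner): alpha*kappa/(alpha*partner+kappa)^2, 0 when kappa=0
  dbrE <- if (p$kappa_E == 0) 0 else
    p$alpha_ES * p$kappa_E / (p$alpha_ES * S + p$kappa_E)^2
  dbrS <- if (p$kappa_S == 0) 0 else
    p$alpha_SE * p$kappa_S / (p$alpha_SE * E + p$kappa_S)^2
  J <- matrix(0, 4, 4, dimnames = list(c("E", "S", "G", "P"),
                                       c("E", "S", "G", "P")))
  J["E", "E"] <- p$mu_E * brE * (p$R - 2 * E - p$beta_ES * S) -
    p$sigma_EG * G - p$delta_E
  J["E", "S"] <- p$mu_E * E *
    (dbrE * (p$R - E - p$beta_ES * S) - brE * p$beta_ES)
  J["E", "G"] <- -p$sigma_EG * E
  J["S", "E"] <- p$mu_S * S *
    (dbrS * (p$R - S - p$beta_SE * E) - brS * p$beta_SE)
  J["S", "S"] <- p$mu_S * brS * (p$R - 2 * S - p$beta_SE * E) -
    p$sigma_SP * P - p$sigma_SG * G - p$delta_S
  J["S", "G"] <- -p$sigma_SG * S
  J["S", "P"] <- -p$sigma_SP * S
  J["G", "E"] <- p$gamma_EG * p$sigma_EG * G
  J["G", "S"] <- p$gamma_SG * p$sigma_SG * G
  J["G", "G"] <- p$gamma_SG * p$sigma_SG * S +
    p$gamma_EG * p$sigma_EG * E - p$delta_G
  J["P", "S"] <- p$gamma_SP * p$sigma_SP * P
  J["P", "P"] <- p$gamma_SP * p$sigma_SP * S - p$delta_P
  J
}
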