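#' Community parameter set
#'
#' Constructs the full rate/interaction parameter record of the four-species
#' community: two bacterial prey (`E`, `S`), a generalist phage `G` attacking
#' both, and a specialist phage `P` attacking only `S`. All quantities are
#' dimensionless (biomass, time); there is no unit-conversion layer.
#'
#' Prey interact either through resource competition (`beta_*` > 0,
#' `kappa_*` = 0) or obligate cross-feeding mutualism (`kappa_*` > 0,
#' `beta_*` = 0, benefit saturating with half-saturation `kappa`).
#' `gamma_EP` and `sigma_EP` describe a specialist attack on prey `E` that
#' the dynamics never use; they are stored for completeness and are inert.
#'
#' @param alpha_ES,alpha_SE mutualistic benefit of S on E / of E on S.
#' @param beta_ES,beta_SE competitive effect of S on E / of E on S.
#' @param mu_E,mu_S maximum intrinsic prey growth rates.
#' @param kappa_E,kappa_S half-saturation constants of the mutualistic
#'   benefit; 0 switches the saturating bracket off (competition).
#' @param R system carrying capacity.
#' @param gamma_EG,gamma_SG generalist burst sizes on E and S.
#' @param gamma_SP specialist burst size on S.
#' @param gamma_EP inert specialist burst size on E (never used by the
#'   dynamics).
#' @param sigma_EG,sigma_SG generalist attachment rates on E and S.
#' @param sigma_SP specialist attachment rate on S.
#' @param sigma_EP inert specialist attachment rate on E.
#' @param delta_E,delta_S,delta_G,delta_P intrinsic death/dilution rates.
#'
#' @return An object of class `community_params` (named list of scalars).
#' @seealso [preset_params()], [apply_cost()], [community_rhs()]
#' @export
community_params <- function(alpha_ES = 1, alpha_SE = 1,
                             beta_ES = 0, beta_SE = 0,
                             mu_E = 0.5, mu_S = 0.5,
                             kappa_E = 1, kappa_S = 1,
                             R = 1,
                             gamma_EG = 20, gamma_SG = 20,
                             gamma_SP = 20, gamma_EP = 20,
                             sigma_EG = 0.001, sigma_SG = 0.001,
                             sigma_SP = 0.001, sigma_EP = 0.001,
                             delta_E = 0.03, delta_S = 0.03,
                             delta_G = 0.03, delta_P = 0.03) {
  p <- list(alpha_ES = alpha_ES, alpha_SE = alpha_SE,
            beta_ES = beta_ES, beta_SE = beta_SE,
            mu_E = mu_E, mu_S = mu_S,
            kappa_E = kappa_E, kappa_S = kappa_S,
            R = R,
            gamma_EG = gamma_EG, gamma_SG = gamma_SG,
            gamma_SP = gamma_SP, gamma_EP = gamma_EP,
            sigma_EG = sigma_EG, sigma_SG = sigma_SG,
            sigma_SP = sigma_SP, sigma_EP = sigma_EP,
            delta_E = delta_E, delta_S = delta_S,
            delta_G = delta_G, delta_P = delta_P)
  validate_params(p)
  structure(p, class = "community_params")
}

param_fields <- function() {
  c("alpha_ES", "alpha_SE", "beta_ES", "beta_SE", "mu_E", "mu_S",
    "kappa_E", "kappa_S", "R", "gamma_EG", "gamma_SG", "gamma_SP",
    "gamma_EP", "sigma_EG", "sigma_SG", "sigma_SP", "sigma_EP",
    "delta_E", "delta_S", "delta_G", "delta_P")
}

validate_params <- function(p) {
  miss <- setdiff(param_fields(), names(p))
  if (length(miss) > 0)
    stop("missing parameter fields: ", paste(miss, collapse = ", "))
  vals <- unlist(p[param_fields()])
  if (any(!is.finite(vals)))
    stop("all parameters must be finite numbers")
  if (any(vals < 0))
    stop("all parameters must be non-negative; offending: ",
         paste(param_fields()[vals < 0], collapse = ", "))
  invisible(p)
}

#' @export
print.community_params <- function(x, ...) {
  mode <- interaction_mode_of(x)
  cat("community_params (", mode, "-like)\n", sep = "")
  v <- unlist(x[param_fields()])
  print(v)
  invisible(x)
}

# Infer the closest interaction mode; "mixed" when both channels are active.
interaction_mode_of <- function(p) {
  if (p$kappa_E == 0 && p$kappa_S == 0) return("competition")
  if (p$beta_ES == 0 && p$beta_SE == 0) return("mutualism")
  "mixed"
}

#' Default parameter presets for the two prey-interaction modes
#'
#' Returns the study-default parameterization for pure competition
#' (`kappa = 0`, `beta = 1`, `R = 2`) or pure obligate mutualism
#' (`kappa = 1`, `beta = 0`, `R = 1`). Shared defaults: growth `mu = 0.5`,
#' all burst sizes 20, all attachment rates 0.001, all death/dilution rates
#' 0.03, `alpha = 1`. The larger competition carrying capacity standardizes
#' total final prey biomass between the modes (obligate mutualism inflates
#' equilibrium biomass above `R`).
#'
#' @param mode `"competition"` or `"mutualism"`.
#' @return A [community_params()] record.
#' @examples
#' preset_params("competition")$R      # 2
#' preset_params("mutualism")$kappa_E  # 1
#' @export
preset_params <- function(mode = c("competition", "mutualism")) {
  mode <- match.arg(mode)
  if (mode == "competition") {
    community_params(beta_ES = 1, beta_SE = 1, kappa_E = 0, kappa_S = 0,
                     R = 2)
  } else {
    community_params(beta_ES = 0, beta_SE = 0, kappa_E = 1, kappa_S = 1,
                     R = 1)
  }
}

#' Impose a cost of generalism
#'
#' Rescales the specialist's advantage relative to the generalist baseline.
#' The cost is absolute with respect to the baseline, so composing two calls
#' keeps only the last ratio.
#'
#' * `"burst"`: specialist burst size `gamma_SP := ratio * gamma_SG`
#'   (generalist burst sizes unchanged).
#' * `"attachment"`: specialist attachment `sigma_SP := ratio * sigma_SG`.
#' * `"mortality"`: death/dilution baseline moves to 0.0067 for prey and the
#'   specialist, and the generalist's rate becomes `ratio * 0.0067` — the
#'   cost is carried by the generalist's higher intrinsic mortality.
#'
#' @param params a [community_params()] record.
#' @param cost_kind `"burst"`, `"attachment"` or `"mortality"`.
#' @param ratio positive scalar; 1 means parametrically identical phage
#'   (for `"mortality"`, equal mortality at the 0.0067 baseline).
#' @return A new `community_params` record; the input is not modified.
#' @examples
#' p <- apply_cost(preset_params("competition"), "burst", 5)
#' p$gamma_SP  # 100
#' @export
apply_cost <- function(params, cost_kind = c("burst", "attachment", "mortality"),
                       ratio) {
  cost_kind <- match.arg(cost_kind)
  stopifnot(is.numeric(ratio), length(ratio) == 1, is.finite(ratio), ratio > 0)
  p <- params
  if (cost_kind == "burst") {
    p$gamma_SP <- ratio * p$gamma_SG
  } else if (cost_kind == "attachment") {
    p$sigma_SP <- ratio * p$sigma_SG
  } else {
    p$delta_E <- p$delta_S <- p$delta_P <- 0.0067
    p$delta_G <- ratio * 0.0067
  }
  validate_params(p)
  structure(p, class = "community_params")
}

#' Read / write a parameter record as a flat config file
#'
#' The on-disk format is a flat key-value mapping whose keys are exactly the
#' field names of [community_params()]. YAML and JSON are supported; the
#' dialect is chosen from the file extension (`.yml`/`.yaml` vs `.json`).
#'
#' @param path file path.
#' @return `read_params()` returns a `community_params`;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  vals <- read_flat_config(path)
  do.call(community_params, vals[intersect(names(vals), param_fields())])
}

#' @param params a [community_params()] record.
#' @rdname read_params
#' @export
write_params <- function(params, path) {
  write_flat_config(unclass(params)[param_fields()], path)
}

read_flat_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config dialect: .", ext, " (use .yaml/.yml or .json)")
  }
}

write_flat_config <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    yaml::write_yaml(x, path)
  } else if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    stop("unsupported config dialect: .", ext, " (use .yaml/.yml or .json)")
  }
  invisible(path)
}
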