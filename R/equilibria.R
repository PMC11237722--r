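#' Enumerate fixed points of the community dynamics
#'
#' Finds non-negative roots of the right-hand side by solving, for each of
#' the 16 presence/absence subsets of `(E, S, G, P)`, the reduced algebraic
#' system with absent species pinned to 0. Each subset is attacked by damped
#' Newton iteration (analytic Jacobian) from a deterministic lattice of
#' starting points; converged roots are deduplicated at tolerance `dedup_tol`
#' and classified for stability via [classify_stability()]. The origin is
#' always included (residual exactly 0).
#'
#' In degenerate parameter regions the system can possess a continuum of
#' equilibria (e.g. a line of prey compositions under symmetric competition
#' with the generalist); distinct Newton starts then return several
#' representative points on the continuum, each classified `marginal`.
#'
#' @param params a [community_params()] record.
#' @param dedup_tol Euclidean tolerance for treating two roots as identical.
#' @param residual_tol acceptance threshold on max |rhs| at a root.
#' @return List of `fixed_point` objects; each has `state` (named vector),
#'   `presence` (logical vector over `E,S,G,P`), `eigenvalues` (4 complex),
#'   `stability` (`"stable"`, `"unstable"` or `"marginal"`) and `residual`.
#' @export
enumerate_fixed_points <- function(params, dedup_tol = 1e-6,
                                   residual_tol = 1e-9) {
  roots <- list(rep(0, 4))  # origin, always a fixed point
  Rhi <- max(params$R, 1)
  prey_lev <- c(0.05, 0.25, 0.6, 0.95, 1.3) * Rhi
  phage_lev <- c(1, 10, 40, 120)
  for (mask_id in 1:15) {
    present <- as.logical(bitwAnd(mask_id, c(1L, 2L, 4L, 8L)))
    levs <- list()
    for (i in which(present)) {
      levs[[length(levs) + 1L]] <- if (i <= 2) prey_lev else phage_lev
    }
    # guarantee >= 8 starts even for single-species subsets
    if (sum(present) == 1L)
      levs[[1L]] <- c(levs[[1L]], c(0.12, 0.45, 0.8) * Rhi * 60)
    starts <- as.matrix(expand.grid(levs))
    for (k in seq_len(nrow(starts))) {
      x0 <- rep(0, 4)
      x0[present] <- starts[k, ]
      root <- newton_subset(x0, present, params)
      if (is.null(root)) next
      if (max(abs(rhs_raw(root, params))) > residual_tol) next
      # root must respect the presence pattern it was solved under
      if (any(root[present] <= dedup_tol)) next
      dup <- any(vapply(roots, function(r) sqrt(sum((r - root)^2)) < dedup_tol,
                        logical(1)))
      if (!dup) roots[[length(roots) + 1L]] <- root
    }
  }
  lapply(roots, function(r) {
    fp <- structure(list(state = c(E = r[1], S = r[2], G = r[3], P = r[4]),
                         presence = c(E = r[1] > 0, S = r[2] > 0,
                                      G = r[3] > 0, P = r[4] > 0),
                         eigenvalues = NULL, stability = NA_character_,
                         residual = max(abs(rhs_raw(r, params)))),
                    class = "fixed_point")
    classify_stability(fp, params)
  })
}

# Damped Newton on the subsystem restricted to `present` coordinates.
newton_subset <- function(x0, present, params, max_iter = 60) {
  x <- x0
  idx <- which(present)
  fx <- rhs_raw(x, params)[idx]
  for (it in seq_len(max_iter)) {
    if (max(abs(fx)) < 1e-12) break
    J <- community_jacobian(x, params)[idx, idx, drop = FALSE]
    step <- try(solve(J, -fx), silent = TRUE)
    if (inherits(step, "try-error") || any(!is.finite(step))) return(NULL)
    lam <- 1
    repeat {
      xn <- x
      xn[idx] <- x[idx] + lam * step
      fn <- rhs_raw(xn, params)[idx]
      if (all(is.finite(fn)) &&
          (max(abs(fn)) < max(abs(fx)) || max(abs(fn)) < 1e-12)) break
      lam <- lam / 2
      if (lam < 1e-10) return(NULL)
    }
    x <- xn; fx <- fn
  }
  if (max(abs(fx)) >= 1e-12 && max(abs(fx)) >= 1e-10) return(NULL)
  if (any(x[idx] < -1e-8)) return(NULL)   # negative root: outside the orthant
  x[x < 0] <- 0
  x
}

#' Classify the local stability of a fixed point
#'
#' Fills in the eigenvalues of the analytic Jacobian of the full four-species
#' system at the point, and the stability label: `"unstable"` when some
#' eigenvalue real part exceeds `+eps`, `"stable"` when every real part is
#' below `-eps`, otherwise `"marginal"` (leading real part within `±eps`,
#' e.g. on a continuum of equilibria). Eigenvalues of absent species encode
#' invasion growth rates, so classification is always on the full 4x4
#' Jacobian.
#'
#' @param fp a `fixed_point` (residual must be below 1e-9).
#' @param params a [community_params()] record.
#' @param eps marginality half-width on eigenvalue real parts.
#' @return The `fixed_point` with `eigenvalues` and `stability` filled.
#' @export
classify_stability <- function(fp, params, eps = 1e-7) {
  stopifnot(inherits(fp, "fixed_point"))
  if (fp$residual >= 1e-9)
    stop("fixed point residual too large to classify: ", fp$residual)
  ev <- eigen(community_jacobian(fp$state, params),
              only.values = TRUE)$values
  re <- Re(ev)
  fp$eigenvalues <- ev
  fp$stability <- if (any(re > eps)) "unstable"
                  else if (all(re < -eps)) "stable"
                  else "marginal"
  fp
}

#' @export
print.fixed_point <- function(x, ...) {
  patt <- paste(ifelse(x$presence, c("E", "S", "G", "P"), "-"), collapse = "")
  cat(sprintf("fixed_point [%s] %s  max Re(eig) = %.3g  residual = %.2g\n",
              patt, x$stability, max(Re(x$eigenvalues)), x$residual))
  print(x$state)
  invisible(x)
}

#' Tabulate fixed points
#'
#' @param fps list of `fixed_point` objects from [enumerate_fixed_points()].
#' @return data.frame with columns `E,S,G,P`, `presence` (string like
#'   `"ES-P"`), `max_re_eig`, `stability`, `residual`.
#' @export
fixed_point_table <- function(fps) {
  do.call(rbind, lapply(fps, function(fp) {
    data.frame(E = fp$state[["E"]], S = fp$state[["S"]],
               G = fp$state[["G"]], P = fp$state[["P"]],
               presence = paste(ifelse(fp$presence, c("E", "S", "G", "P"),
                                       "-"), collapse = ""),
               max_re_eig = max(Re(fp$eigenvalues)),
               stability = fp$stability,
               residual = fp$residual)
  }))
}

#' @param path output CSV file.
#' @rdname fixed_point_table
#' @export
write_fixed_points <- function(fps, path) {
  utils::write.csv(fixed_point_table(fps), path, row.names = FALSE)
  invisible(path)
}

#' Analytic S* invasion criterion for the two phage
#'
#' Applies R*-resource theory with the shared prey `S` as the resource: each
#' phage needs a minimum equilibrium prey-S density for zero net growth.
#' With a generalist symmetric across prey (equal burst and attachment on
#' both hosts) and a common death/dilution rate `delta`,
#' \deqn{S_P^* = \delta / (\gamma_P \varsigma_P), \qquad
#'       S_G^* = \delta / (\gamma_G \varsigma_G) - E}
#' and the specialist excludes the generalist (`S_P* < S_G*`) iff
#' \deqn{\frac{\gamma_G \varsigma_G}{\gamma_P \varsigma_P} <
#'       1 - \frac{\gamma_G \varsigma_G E}{\delta}.}
#' Both forms are evaluated and cross-checked. The criterion requires a cost
#' of generalism: it can never hold when
#' `gamma_G*sigma_G >= gamma_P*sigma_P`.
#'
#' @param params a [community_params()] record satisfying the symmetry
#'   assumptions (`gamma_EG == gamma_SG`, `sigma_EG == sigma_SG`, all four
#'   `delta` equal) to within `1e-12`; asymmetric inputs are rejected.
#' @param E_level assumed density of the alternative prey `E` (>= 0).
#' @return Object of class `sstar_report`: list with `S_G_star`, `S_P_star`,
#'   `inequality_holds` and `E_level`.
#' @export
sstar_criterion <- function(params, E_level) {
  p <- params
  stopifnot(is.numeric(E_level), length(E_level) == 1, E_level >= 0)
  if (abs(p$gamma_EG - p$gamma_SG) > 1e-12 ||
      abs(p$sigma_EG - p$sigma_SG) > 1e-12)
    stop("S* criterion assumes the generalist has equal burst size and ",
         "attachment rate on both prey")
  ds <- c(p$delta_E, p$delta_S, p$delta_G, p$delta_P)
  if (diff(range(ds)) > 1e-12)
    stop("S* criterion assumes one common death/dilution rate for all ",
         "four species")
  delta <- p$delta_G
  gG <- p$gamma_SG * p$sigma_SG
  gP <- p$gamma_SP * p$sigma_SP
  S_P_star <- delta / gP
  S_G_star <- delta / gG - E_level
  holds <- S_P_star < S_G_star
  holds_ratio_form <- gG / gP < 1 - gG * E_level / delta
  if (!identical(holds, holds_ratio_form))
    stop("internal inconsistency between the S* comparison and its ",
         "ratio form")  # algebraically equivalent; guards regressions
  structure(list(S_G_star = S_G_star, S_P_star = S_P_star,
                 inequality_holds = holds, E_level = E_level),
            class = "sstar_report")
}

#' @export
print.sstar_report <- function(x, ...) {
  cat(sprintf("S* report at E = %g: S_P* = %g, S_G* = %g -> specialist %s\n",
              x$E_level, x$S_P_star, x$S_G_star,
              if (x$inequality_holds) "favored (S_P* < S_G*)"
              else "not favored"))
  invisible(x)
}

#' @param report an `sstar_report`.
#' @param path output JSON file.
#' @rdname sstar_criterion
#' @export
write_sstar <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Locate a cost-of-generalism threshold by bisection
#'
#' Bisects the cost ratio over `bracket` on one of two indicators:
#'
#' * `"only_stable_is_ESP"` — fixed-point battery: TRUE when no stable fixed
#'   point contains the generalist and the prey-pair + specialist
#'   coexistence point (`E>0, S>0, P>0, G=0`) is stable. Trivial extinction
#'   states with both prey absent are disregarded: under obligate mutualism
#'   the origin is unconditionally stable (per-capita growth tends to
#'   `-delta` as both prey vanish), so the literal "every stable point is
#'   E-S-P" can never hold there.
#' * `"density_crossing"` — forward simulation from all species at 0.1:
#'   TRUE when long-run specialist density exceeds the generalist's
#'   (window-averaged when the run does not converge pointwise).
#'
#' For `cost_kind` `"burst"` or `"attachment"` the ratio acts on a single
#' factor of the specialist's `gamma * sigma` product, so the returned
#' threshold is on the product scale and the two kinds are expected to
#' agree.
#'
#' @param mode `"competition"` or `"mutualism"`.
#' @param cost_kind passed to [apply_cost()].
#' @param criterion `"only_stable_is_ESP"` or `"density_crossing"`.
#' @param bracket length-2 ratio interval; the indicator must change truth
#'   value across it, otherwise an error identifies the constant side.
#' @param tol bisection tolerance on the ratio (default 5e-3).
#' @param ... further arguments to [run_to_steady_state()] (e.g. `t_max`)
#'   for the simulation indicator.
#' @return Threshold ratio (midpoint of the final bracket).
#' @export
find_cost_threshold <- function(mode = c("competition", "mutualism"),
                                cost_kind = c("burst", "attachment", "mortality"),
                                criterion = c("only_stable_is_ESP",
                                              "density_crossing"),
                                bracket = c(1, 6), tol = 5e-3, ...) {
  mode <- match.arg(mode)
  cost_kind <- match.arg(cost_kind)
  criterion <- match.arg(criterion)
  stopifnot(length(bracket) == 2, bracket[1] > 0, bracket[2] > bracket[1])
  base <- preset_params(mode)
  indicator <- function(ratio) {
    p <- apply_cost(base, cost_kind, ratio)
    if (criterion == "only_stable_is_ESP") {
      only_stable_is_esp(enumerate_fixed_points(p))
    } else {
      ss <- run_to_steady_state(p, ...)
      ss$final_state[["P"]] > ss$final_state[["G"]]
    }
  }
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- indicator(lo); f_hi <- indicator(hi)
  if (f_lo == f_hi)
    stop("indicator is constant (", f_lo, ") on both ends of the bracket [",
         lo, ", ", hi, "]")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (indicator(mid) == f_lo) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# TRUE when no stable fixed point contains the generalist and a stable
# E-S-specialist coexistence point exists. States with both prey absent
# (trivial extinction) are disregarded.
only_stable_is_esp <- function(fps) {
  nontrivial <- Filter(function(fp) fp$presence[["E"]] || fp$presence[["S"]],
                       fps)
  stable <- Filter(function(fp) fp$stability == "stable", nontrivial)
  if (length(stable) == 0) return(FALSE)
  g_free <- !vapply(stable, function(fp) fp$presence[["G"]], logical(1))
  esp <- vapply(stable, function(fp) {
    all(fp$presence == c(E = TRUE, S = TRUE, G = FALSE, P = TRUE))
  }, logical(1))
  all(g_free) && any(esp)
}
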