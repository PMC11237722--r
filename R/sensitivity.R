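#' Default sensitivity ranges
#'
#' Per-parameter intervals spanning +/-50% of each preset default, sampled
#' log-uniformly (all varied parameters are positive rates or scales). This
#' is a package convention, overridable by passing custom ranges. Structural
#' zeros of the mode are not varied (e.g. `beta` under mutualism). The four
#' death/dilution rates vary together as one chemostat-style parameter
#' `delta`; the two half-saturation constants vary together as `kappa`.
#'
#' @param mode `"competition"` or `"mutualism"`.
#' @return Named list of `c(lo, hi)` intervals.
#' @export
default_sensitivity_ranges <- function(mode = c("competition", "mutualism")) {
  mode <- match.arg(mode)
  p <- preset_params(mode)
  nm <- c("mu_E", "mu_S",
          if (mode == "competition") c("beta_ES", "beta_SE")
          else c("alpha_ES", "alpha_SE", "kappa"),
          "R", "gamma_EG", "gamma_SG", "gamma_SP",
          "sigma_EG", "sigma_SG", "sigma_SP", "delta")
  defaults <- vapply(nm, function(n) {
    switch(n, kappa = p$kappa_E, delta = p$delta_G, p[[n]])
  }, numeric(1))
  stats::setNames(lapply(defaults, function(d) c(0.5 * d, 1.5 * d)), nm)
}

#' Read / write a sensitivity range specification
#'
#' Flat config file (YAML or JSON by extension) mapping each parameter name
#' to its `[lo, hi]` interval, as consumed by [morris_screen()] and
#' [sobol_indices()].
#'
#' @param path config file path.
#' @return `read_ranges()`: named list of `c(lo, hi)` vectors.
#' @export
read_ranges <- function(path) {
  raw <- read_flat_config(path)
  out <- lapply(raw, function(r) {
    r <- as.numeric(unlist(r))
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2])
      stop("each range must be a finite [lo, hi] pair")
    r
  })
  out
}

#' @param ranges named list of `c(lo, hi)` intervals.
#' @rdname read_ranges
#' @export
write_ranges <- function(ranges, path) {
  write_flat_config(ranges, path)
}

# Named sensitivity values -> full parameter record. `delta` fans out to all
# four species, `kappa` to both half-saturation constants.
apply_named_values <- function(base, values) {
  p <- base
  for (n in names(values)) {
    v <- values[[n]]
    if (n == "delta") {
      p$delta_E <- p$delta_S <- p$delta_G <- p$delta_P <- v
    } else if (n == "kappa") {
      p$kappa_E <- p$kappa_S <- v
    } else if (n %in% param_fields()) {
      p[[n]] <- v
    } else {
      stop("unknown sensitivity parameter: ", n)
    }
  }
  p
}

#' Endpoint evaluator for sensitivity analysis
#'
#' Builds the model function mapped over sensitivity samples: integrate from
#' all species at 0.1 to a fixed horizon (default 2000 time units — a fixed
#' evaluation horizon rather than a full steady-state search, to keep
#' thousands of evaluations tractable) and report each phage's final
#' biomass.
#'
#' @param mode `"competition"` or `"mutualism"`.
#' @param t_eval evaluation horizon.
#' @param rtol,atol solver tolerances.
#' @return `function(values)` taking a named vector of sensitivity
#'   parameters and returning `c(final_G = ..., final_P = ...)`.
#' @export
make_endpoint_evaluator <- function(mode, t_eval = 2000,
                                    rtol = 1e-8, atol = 1e-12) {
  base <- preset_params(mode)
  function(values) {
    p <- apply_named_values(base, values)
    traj <- try(suppressWarnings(
      integrate_community(p, community_state(0.1, 0.1, 0.1, 0.1),
                          t_end = t_eval, step_out = 2,
                          rtol = rtol, atol = atol)), silent = TRUE)
    if (inherits(traj, "try-error") || !traj$converged)
      return(c(final_G = NA_real_, final_P = NA_real_))  # dropped upstream
    x <- traj$states[nrow(traj$states), ]
    c(final_G = x[["G"]], final_P = x[["P"]])
  }
}

# Map unit-hypercube coordinates to parameter values, log-uniformly.
# Degenerate ranges (lo == hi) map to the constant.
unit_to_range <- function(u, ranges) {
  vapply(seq_along(ranges), function(i) {
    r <- ranges[[i]]
    if (r[1] <= 0) stop("ranges must be positive for log-uniform sampling")
    if (r[1] == r[2]) return(r[1])
    exp(log(r[1]) + u[i] * (log(r[2]) - log(r[1])))
  }, numeric(1), USE.NAMES = FALSE) -> v
  stats::setNames(v, names(ranges))
}

run_model_samples <- function(U, ranges, model_fn) {
  out <- lapply(seq_len(nrow(U)), function(i) {
    y <- model_fn(unit_to_range(U[i, ], ranges))
    if (any(!is.finite(y))) rep(NA_real_, length(y)) else y
  })
  do.call(rbind, out)
}

#' Morris elementary-effects screening
#'
#' One-at-a-time screening of the endpoint phage biomass (or of a custom
#' model function). Each of `r` trajectories starts at a random point of a
#' `levels`-point grid on the unit hypercube and perturbs every parameter
#' once by `delta = levels / (2 (levels - 1))`; the elementary effect of a
#' parameter is the output change per unit step in scaled (log-range)
#' coordinates. Parameters are ranked by `mu_star` (mean absolute
#' elementary effect); `sigma` (their standard deviation) signals
#' interactions/nonlinearity.
#'
#' @param mode `"competition"` or `"mutualism"`.
#' @param ranges named list of positive `c(lo, hi)` intervals
#'   (default [default_sensitivity_ranges()]).
#' @param r number of trajectories (>= 10).
#' @param levels number of grid levels (even).
#' @param seed RNG seed (mandatory input; fixed default 0).
#' @param model_fn model evaluated per sample: `function(values)` returning
#'   a named numeric vector of outputs. Defaults to the fixed-horizon
#'   endpoint evaluator ([make_endpoint_evaluator()]).
#' @param t_eval evaluation horizon for the default evaluator.
#' @return Object of class `sensitivity_result` with a long-format `table`
#'   (`output`, `parameter`, `mu_star`, `sigma`), plus method metadata.
#'   Samples with non-finite model output are dropped (with a message).
#' @export
morris_screen <- function(mode = c("competition", "mutualism"),
                          ranges = NULL, r = 12, levels = 8, seed = 0,
                          model_fn = NULL, t_eval = 2000) {
  mode <- match.arg(mode)
  if (is.null(ranges)) ranges <- default_sensitivity_ranges(mode)
  stopifnot(r >= 10, levels >= 2)
  if (is.null(model_fn)) model_fn <- make_endpoint_evaluator(mode, t_eval)
  k <- length(ranges)
  delta <- levels / (2 * (levels - 1))
  grid_lo <- (seq_len(levels / 2) - 1) / (levels - 1)  # points with room for +delta
  set.seed(seed)
  ee <- list()  # per trajectory: k x n_out matrix of elementary effects
  n_dropped <- 0
  for (tr in seq_len(r)) {
    x <- grid_lo[sample.int(length(grid_lo), k, replace = TRUE)]
    dirs <- sample(c(-1, 1), k, replace = TRUE)
    # flip directions that would leave [0, 1]
    dirs <- ifelse(x + dirs * delta < 0 | x + dirs * delta > 1, -dirs, dirs)
    order_k <- sample.int(k)
    f_prev <- model_fn(unit_to_range(x, ranges))
    n_out <- length(f_prev)
    eff <- matrix(NA_real_, k, n_out,
                  dimnames = list(names(ranges), names(f_prev)))
    for (i in order_k) {
      x[i] <- x[i] + dirs[i] * delta
      f_new <- model_fn(unit_to_range(x, ranges))
      if (all(is.finite(f_new)) && all(is.finite(f_prev))) {
        eff[i, ] <- (f_new - f_prev) / (dirs[i] * delta)
      } else {
        n_dropped <- n_dropped + 1
      }
      f_prev <- f_new
    }
    ee[[tr]] <- eff
  }
  if (n_dropped > 0)
    message("morris_screen: dropped ", n_dropped,
            " elementary effects with non-finite model output")
  outputs <- colnames(ee[[1]])
  table <- do.call(rbind, lapply(outputs, function(o) {
    M <- vapply(ee, function(m) m[, o], numeric(k))  # k x r
    data.frame(output = o, parameter = names(ranges),
               mu_star = apply(M, 1, function(z) mean(abs(z), na.rm = TRUE)),
               sigma = apply(M, 1, stats::sd, na.rm = TRUE),
               row.names = NULL)
  }))
  structure(list(method = "morris", mode = mode, table = table,
                 outputs = outputs, r = r, levels = levels, seed = seed,
                 n_evals = r * (k + 1)),
            class = "sensitivity_result")
}

#' Sobol variance-based sensitivity indices
#'
#' Saltelli-style sampling (radial A/B/AB design) with the Saltelli-2010
#' first-order estimator and the Jansen total-order estimator, plus
#' percentile bootstrap confidence intervals over the base samples.
#'
#' @inheritParams morris_screen
#' @param n_base base sample size (>= 128; powers of two recommended).
#'   Total model evaluations: `n_base * (k + 2)`.
#' @param bootstrap number of bootstrap resamples for the CIs.
#' @return `sensitivity_result` with long-format `table` (`output`,
#'   `parameter`, `first_order`, `first_lo`, `first_hi`, `total_order`,
#'   `total_lo`, `total_hi`).
#' @export
sobol_indices <- function(mode = c("competition", "mutualism"),
                          ranges = NULL, n_base = 128, seed = 0,
                          bootstrap = 200, model_fn = NULL, t_eval = 2000) {
  mode <- match.arg(mode)
  if (is.null(ranges)) ranges <- default_sensitivity_ranges(mode)
  stopifnot(n_base >= 128)
  if (is.null(model_fn)) model_fn <- make_endpoint_evaluator(mode, t_eval)
  k <- length(ranges)
  set.seed(seed)
  A <- matrix(stats::runif(n_base * k), n_base, k)
  B <- matrix(stats::runif(n_base * k), n_base, k)
  fA <- run_model_samples(A, ranges, model_fn)
  fB <- run_model_samples(B, ranges, model_fn)
  fAB <- lapply(seq_len(k), function(i) {
    ABi <- A; ABi[, i] <- B[, i]
    run_model_samples(ABi, ranges, model_fn)
  })
  outputs <- colnames(fA)
  n_dropped <- sum(is.na(fA[, 1])) + sum(is.na(fB[, 1])) +
    sum(vapply(fAB, function(m) sum(is.na(m[, 1])), numeric(1)))
  if (n_dropped > 0)
    message("sobol_indices: ", n_dropped, " non-finite samples dropped")
  est <- function(a, b, abi, idx) {
    a <- a[idx]; b <- b[idx]; abi <- abi[idx]
    keep <- is.finite(a) & is.finite(b) & is.finite(abi)
    a <- a[keep]; b <- b[keep]; abi <- abi[keep]
    V <- stats::var(c(a, b))
    if (V == 0) return(c(first = 0, total = 0))
    c(first = mean(b * (abi - a)) / V,
      total = mean((a - abi)^2) / (2 * V))
  }
  table <- do.call(rbind, lapply(outputs, function(o) {
    do.call(rbind, lapply(seq_len(k), function(i) {
      full <- est(fA[, o], fB[, o], fAB[[i]][, o], seq_len(n_base))
      boot <- replicate(bootstrap, {
        idx <- sample.int(n_base, replace = TRUE)
        est(fA[, o], fB[, o], fAB[[i]][, o], idx)
      })
      qs_f <- stats::quantile(boot["first", ], c(0.025, 0.975), na.rm = TRUE)
      qs_t <- stats::quantile(boot["total", ], c(0.025, 0.975), na.rm = TRUE)
      data.frame(output = o, parameter = names(ranges)[i],
                 first_order = full[["first"]],
                 first_lo = qs_f[[1]], first_hi = qs_f[[2]],
                 total_order = full[["total"]],
                 total_lo = qs_t[[1]], total_hi = qs_t[[2]],
                 row.names = NULL)
    }))
  }))
  structure(list(method = "sobol", mode = mode, table = table,
                 outputs = outputs, n_base = n_base, seed = seed,
                 bootstrap = bootstrap, n_evals = n_base * (k + 2)),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("sensitivity_result: %s, mode = %s, %d model evaluations, seed %s\n",
              x$method, x$mode, x$n_evals, format(x$seed)))
  for (o in x$outputs) {
    tab <- x$table[x$table$output == o, ]
    key <- if (x$method == "morris") "mu_star" else "total_order"
    tab <- tab[order(-tab[[key]]), ]
    cat("top parameters for ", o, " (by ", key, "):\n", sep = "")
    print(utils::head(tab, 5), row.names = FALSE)
  }
  invisible(x)
}

#' Write a sensitivity result (long CSV + JSON metadata)
#' @param x a `sensitivity_result`.
#' @param path CSV output path; metadata goes to `<path>.meta.json`.
#' @export
write_sensitivity <- function(x, path) {
  utils::write.csv(x$table, path, row.names = FALSE)
  meta <- x[setdiff(names(x), "table")]
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
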