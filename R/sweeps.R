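#' Scenario battery: phage presence/absence end states
#'
#' Runs the four canonical phage treatments — no phage, specialist only,
#' generalist only, both phage — for one interaction mode and cost ratio.
#' Every present species starts at density 0.1, absent species at 0.
#'
#' @param mode `"competition"` or `"mutualism"`.
#' @param cost_ratio burst-size cost of generalism (1 = parametrically
#'   identical phage).
#' @param cost_kind passed to [apply_cost()] (default `"burst"`).
#' @param ... further arguments to [run_to_steady_state()].
#' @return data.frame with one row per scenario: end-state densities,
#'   prey fraction `E / (E + S)`, specialist relative abundance, and the
#'   convergence flag.
#' @export
scenario_battery <- function(mode = c("competition", "mutualism"),
                             cost_ratio = 1, cost_kind = "burst", ...) {
  mode <- match.arg(mode)
  p <- apply_cost(preset_params(mode), cost_kind, cost_ratio)
  scen <- list(no_phage = c(0.1, 0.1, 0, 0),
               specialist_only = c(0.1, 0.1, 0, 0.1),
               generalist_only = c(0.1, 0.1, 0.1, 0),
               both_phage = c(0.1, 0.1, 0.1, 0.1))
  rows <- lapply(names(scen), function(nm) {
    y0 <- scen[[nm]]
    ss <- run_to_steady_state(p, community_state(y0[1], y0[2], y0[3], y0[4]),
                              ...)
    x <- ss$final_state
    prey_tot <- x[["E"]] + x[["S"]]
    data.frame(scenario = nm, E = x[["E"]], S = x[["S"]],
               G = x[["G"]], P = x[["P"]],
               prey_fraction_E = if (prey_tot > 0) x[["E"]] / prey_tot
                                 else NA_real_,
               specialist_rel_abund = relative_specialist_abundance(ss),
               converged = ss$converged)
  })
  do.call(rbind, rows)
}

#' One-dimensional cost-of-generalism sweep
#'
#' Steady-state end states with both phage present (all species initialized
#' at 0.1) along a grid of cost ratios. Default grids follow the package
#' convention of 30 log-spaced ratios in `[1, 10]`.
#'
#' @inheritParams scenario_battery
#' @param cost_kind `"burst"`, `"attachment"` or `"mortality"`.
#' @param ratios positive increasing grid of cost ratios.
#' @param floor extinction floor used for the prey-excluded flags.
#' @param ... further arguments to [run_to_steady_state()].
#' @return Object of class `sweep_grid` (a data.frame): per cell the final
#'   densities, `specialist_rel_abund`, `converged`, and prey-exclusion
#'   flags `E_excluded` / `S_excluded`.
#' @export
sweep_cost <- function(mode = c("competition", "mutualism"),
                       cost_kind = c("burst", "attachment", "mortality"),
                       ratios = exp(seq(log(1), log(10), length.out = 30)),
                       floor = 1e-12, ...) {
  mode <- match.arg(mode)
  cost_kind <- match.arg(cost_kind)
  stopifnot(all(ratios > 0), !is.unsorted(ratios))
  base <- preset_params(mode)
  rows <- lapply(ratios, function(r) {
    ss <- run_to_steady_state(apply_cost(base, cost_kind, r), floor = floor,
                              ...)
    cbind(data.frame(cost_ratio = r), cell_summary(ss, floor))
  })
  grid <- do.call(rbind, rows)
  structure(grid, class = c("sweep_grid", "data.frame"),
            axis1 = "cost_ratio", axis2 = NULL,
            mode = mode, cost_kind = cost_kind)
}

cell_summary <- function(ss, floor) {
  x <- ss$final_state
  data.frame(E = x[["E"]], S = x[["S"]], G = x[["G"]], P = x[["P"]],
             specialist_rel_abund = relative_specialist_abundance(ss),
             converged = ss$converged,
             E_excluded = x[["E"]] < floor,
             S_excluded = x[["S"]] < floor)
}

#' Two-dimensional sweep: cost of generalism x prey asymmetry
#'
#' Crosses a cost-ratio grid with a prey-asymmetry grid. Asymmetry acts on
#' prey `E` relative to prey `S` held at its default:
#' * `"growth_rate"`: `mu_E = asymmetry * 0.5` (with `mu_S = 0.5`);
#' * `"interaction_coefficient"`: in competition `beta_ES = asymmetry`
#'   (with `beta_SE = 1`); in mutualism `alpha_ES = asymmetry` (with
#'   `alpha_SE = 1`).
#'
#' Besides the end-state exclusion flags, each cell records whether each
#' prey is *competitively* excluded — driven below the extinction floor in
#' the phage-free prey subsystem under the same asymmetry
#' (`E_comp_excluded` / `S_comp_excluded`). The two can differ: a prey that
#' loses the pure competition may persist in the full community through
#' predator-mediated release of its competitor. Mutualism cells in which
#' the prey pair cannot persist even without effective predation are
#' flagged `infeasible` (both prey below the extinction floor).
#'
#' @inheritParams sweep_cost
#' @param asymmetry_kind `"growth_rate"` or `"interaction_coefficient"`.
#' @param asymmetry positive grid of asymmetry multipliers for prey E.
#' @return `sweep_grid` data.frame with columns `cost_ratio`, `asymmetry`,
#'   cell summaries as in [sweep_cost()], and `infeasible`.
#' @export
sweep_cost_by_asymmetry <- function(mode = c("competition", "mutualism"),
                                    cost_kind = c("burst", "attachment",
                                                  "mortality"),
                                    ratios = exp(seq(log(1), log(10),
                                                     length.out = 30)),
                                    asymmetry_kind = c("growth_rate",
                                                       "interaction_coefficient"),
                                    asymmetry = exp(seq(log(0.25), log(4),
                                                        length.out = 30)),
                                    floor = 1e-12, ...) {
  mode <- match.arg(mode)
  cost_kind <- match.arg(cost_kind)
  asymmetry_kind <- match.arg(asymmetry_kind)
  stopifnot(all(ratios > 0), all(asymmetry > 0))
  base <- preset_params(mode)
  with_asym <- function(p, a) {
    if (asymmetry_kind == "growth_rate") {
      p$mu_E <- a * p$mu_S
    } else if (mode == "competition") {
      p$beta_ES <- a * p$beta_SE
    } else {
      p$alpha_ES <- a * p$alpha_SE
    }
    p
  }
  # phage-free prey outcome per asymmetry level (prey parameters do not
  # depend on the cost ratio; mortality costs re-base prey delta identically
  # at every ratio)
  prey_flags <- lapply(asymmetry, function(a) {
    p <- with_asym(apply_cost(base, cost_kind, ratios[1]), a)
    prey <- run_to_steady_state(p, community_state(0.1, 0.1, 0, 0),
                                floor = floor, ...)
    c(E = prey$final_state[["E"]] < floor,
      S = prey$final_state[["S"]] < floor)
  })
  names(prey_flags) <- as.character(asymmetry)
  cells <- expand.grid(cost_ratio = ratios, asymmetry = asymmetry,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    r <- cells$cost_ratio[i]; a <- cells$asymmetry[i]
    p <- with_asym(apply_cost(base, cost_kind, r), a)
    ss <- run_to_steady_state(p, floor = floor, ...)
    cs <- cell_summary(ss, floor)
    cs$infeasible <- cs$E_excluded && cs$S_excluded
    pf <- prey_flags[[as.character(a)]]
    cs$E_comp_excluded <- unname(pf[["E"]])
    cs$S_comp_excluded <- unname(pf[["S"]])
    cbind(cells[i, , drop = FALSE], cs)
  })
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  structure(grid, class = c("sweep_grid", "data.frame"),
            axis1 = "cost_ratio", axis2 = "asymmetry",
            mode = mode, cost_kind = cost_kind,
            asymmetry_kind = asymmetry_kind)
}

#' Write a sweep grid (long CSV + JSON metadata sidecar)
#'
#' @param grid a `sweep_grid`.
#' @param path CSV output path; metadata goes to `<path>.meta.json`.
#' @export
write_sweep <- function(grid, path) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE)
  meta <- list(axis1 = attr(grid, "axis1"), axis2 = attr(grid, "axis2"),
               mode = attr(grid, "mode"), cost_kind = attr(grid, "cost_kind"),
               asymmetry_kind = attr(grid, "asymmetry_kind"),
               n_cells = nrow(grid))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Heatmap of a two-dimensional sweep
#'
#' Renders specialist relative abundance over the cost x asymmetry plane
#' (base graphics `image`); non-converged cells are overplotted with dots,
#' infeasible cells in grey.
#'
#' @param grid a 2-D `sweep_grid` from [sweep_cost_by_asymmetry()].
#' @param ... passed to [graphics::image()].
#' @export
plot_sweep <- function(grid, ...) {
  if (is.null(attr(grid, "axis2")))
    stop("plot_sweep expects a 2-D sweep grid")
  xs <- sort(unique(grid$cost_ratio))
  ys <- sort(unique(grid$asymmetry))
  z <- matrix(NA_real_, length(xs), length(ys))
  z[cbind(match(grid$cost_ratio, xs), match(grid$asymmetry, ys))] <-
    grid$specialist_rel_abund
  graphics::image(xs, ys, z, xlab = "cost of generalism (ratio)",
                  ylab = paste("prey E asymmetry:",
                               attr(grid, "asymmetry_kind")),
                  zlim = c(0, 1),
                  col = grDevices::hcl.colors(25, "Blue-Yellow", rev = TRUE),
                  ...)
  bad <- grid[grid$infeasible | !grid$converged, , drop = FALSE]
  if (nrow(bad) > 0)
    graphics::points(bad$cost_ratio, bad$asymmetry, pch = 16, cex = 0.4,
                     col = ifelse(bad$infeasible, "grey50", "black"))
  invisible(grid)
}
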