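#' Run configuration
#'
#' Bundles the settings of a pipeline run into one serializable record.
#' Every field has the study default; [run_analysis()] writes the resolved
#' config next to its outputs so runs are reproducible bit-for-bit under a
#' fixed seed.
#'
#' @param analysis one of `"simulate"`, `"fixed_points"`, `"sstar"`,
#'   `"threshold"`, `"sweep"`, `"sensitivity"`, `"synth"`, `"reproduce"`.
#' @param mode `"competition"` or `"mutualism"`.
#' @param cost_kind,cost_ratio cost of generalism (see [apply_cost()]).
#' @param criterion threshold criterion (see [find_cost_threshold()]).
#' @param bracket threshold bisection bracket.
#' @param scenario phage treatment for `simulate`/`synth`.
#' @param t_max,tol,window steady-state solver settings.
#' @param ratios,asymmetry,asymmetry_kind sweep grids; `asymmetry = NULL`
#'   selects a 1-D sweep.
#' @param sens_method `"morris"` or `"sobol"`; `sens_r`, `sens_n_base` the
#'   corresponding sample sizes.
#' @param noise_cv,n_replicates synthetic-readout settings.
#' @param E_level assumed alternative-prey density for the S* report.
#' @param out_dir output directory.
#' @param seed RNG seed.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(analysis = "simulate",
                       mode = "mutualism",
                       cost_kind = "burst", cost_ratio = 1,
                       criterion = "density_crossing",
                       bracket = c(1, 6),
                       scenario = "both",
                       t_max = 1e5, tol = 1e-9, window = 100,
                       ratios = exp(seq(log(1), log(10), length.out = 30)),
                       asymmetry = NULL,
                       asymmetry_kind = "growth_rate",
                       sens_method = "morris", sens_r = 12,
                       sens_n_base = 128,
                       noise_cv = 0.1, n_replicates = 3,
                       E_level = 0.5,
                       out_dir = "phagetrade-out", seed = 0) {
  cfg <- as.list(environment())
  stopifnot(analysis %in% c("simulate", "fixed_points", "sstar", "threshold",
                            "sweep", "sensitivity", "synth", "reproduce"),
            mode %in% c("competition", "mutualism"))
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Keys not present fall back to the [run_config()] defaults; unknown keys
#' are rejected.
#'
#' @param path config file (`.yaml`/`.yml`/`.json`).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- read_flat_config(path)
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' @param cfg a `run_config`.
#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  write_flat_config(unclass(cfg), path)
}

#' Execute one configured analysis
#'
#' Dispatches on `cfg$analysis`, writes CSV/JSON artifacts under
#' `cfg$out_dir` (created if needed) together with the resolved
#' configuration (`config.yaml`), and returns the computed object
#' invisibly. Outputs are deterministic under a fixed seed.
#'
#' @param cfg a [run_config()].
#' @param quiet suppress progress messages.
#' @return The computed result object, invisibly.
#' @export
run_analysis <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  write_run_config(cfg, file.path(cfg$out_dir, "config.yaml"))
  set.seed(cfg$seed)
  params <- apply_cost(preset_params(cfg$mode), cfg$cost_kind, cfg$cost_ratio)
  res <- switch(
    cfg$analysis,
    simulate = {
      init <- switch(cfg$scenario,
                     none = community_state(0.1, 0.1, 0, 0),
                     specialist_only = community_state(0.1, 0.1, 0, 0.1),
                     generalist_only = community_state(0.1, 0.1, 0.1, 0),
                     both = community_state(0.1, 0.1, 0.1, 0.1))
      ss <- run_to_steady_state(params, init, tol = cfg$tol,
                                window = cfg$window, t_max = cfg$t_max)
      traj <- integrate_community(params, init,
                                  t_end = min(cfg$t_max, ss$t_reached))
      write_trajectory(traj, file.path(cfg$out_dir, "trajectory.csv"))
      write_steady_state(ss, file.path(cfg$out_dir, "steady_state.json"))
      say("steady state at t = ", ss$t_reached)
      ss
    },
    fixed_points = {
      fps <- enumerate_fixed_points(params)
      write_fixed_points(fps, file.path(cfg$out_dir, "fixed_points.csv"))
      say(length(fps), " fixed points")
      fps
    },
    sstar = {
      rep <- sstar_criterion(params, cfg$E_level)
      write_sstar(rep, file.path(cfg$out_dir, "sstar.json"))
      rep
    },
    threshold = {
      th <- find_cost_threshold(cfg$mode, cfg$cost_kind, cfg$criterion,
                                bracket = cfg$bracket, t_max = cfg$t_max)
      jsonlite::write_json(list(mode = cfg$mode, cost_kind = cfg$cost_kind,
                                criterion = cfg$criterion, threshold = th),
                           file.path(cfg$out_dir, "threshold.json"),
                           auto_unbox = TRUE, digits = NA)
      say("threshold ratio = ", signif(th, 4))
      th
    },
    sweep = {
      grid <- if (is.null(cfg$asymmetry)) {
        sweep_cost(cfg$mode, cfg$cost_kind, cfg$ratios, t_max = cfg$t_max)
      } else {
        sweep_cost_by_asymmetry(cfg$mode, cfg$cost_kind, cfg$ratios,
                                cfg$asymmetry_kind, cfg$asymmetry,
                                t_max = cfg$t_max)
      }
      write_sweep(grid, file.path(cfg$out_dir, "sweep.csv"))
      grid
    },
    sensitivity = {
      sens <- if (cfg$sens_method == "morris") {
        morris_screen(cfg$mode, r = cfg$sens_r, seed = cfg$seed)
      } else {
        sobol_indices(cfg$mode, n_base = cfg$sens_n_base, seed = cfg$seed)
      }
      write_sensitivity(sens, file.path(cfg$out_dir, "sensitivity.csv"))
      sens
    },
    synth = {
      ro <- simulate_readout(params, cfg$scenario, noise_cv = cfg$noise_cv,
                             n_replicates = cfg$n_replicates, seed = cfg$seed)
      write_readouts(ro, file.path(cfg$out_dir, "readouts.csv"))
      say("winner: ", classify_winner(ro))
      ro
    },
    reproduce = reproduce_battery(cfg, say)
  )
  invisible(res)
}

# The full battery behind the headline analyses: scenario end states in both
# modes at cost 1 and 5, the two mutualism thresholds, and the S* report.
reproduce_battery <- function(cfg, say) {
  out <- cfg$out_dir
  scen <- do.call(rbind, lapply(c("competition", "mutualism"), function(m) {
    do.call(rbind, lapply(c(1, 5), function(r) {
      cbind(mode = m, cost_ratio = r,
            scenario_battery(m, r, t_max = cfg$t_max))
    }))
  }))
  utils::write.csv(scen, file.path(out, "scenario_battery.csv"),
                   row.names = FALSE)
  say("scenario battery done")
  th_stab <- find_cost_threshold("mutualism", "burst", "only_stable_is_ESP",
                                 bracket = cfg$bracket)
  th_cross <- find_cost_threshold("mutualism", "burst", "density_crossing",
                                  bracket = cfg$bracket, t_max = cfg$t_max)
  say("thresholds: stability ", signif(th_stab, 4), ", crossing ",
      signif(th_cross, 4))
  sstar <- sstar_criterion(preset_params("mutualism"), cfg$E_level)
  no_phage <- scen[scen$scenario == "no_phage" & scen$cost_ratio == 1, ]
  summary <- list(
    stability_threshold_product_ratio = th_stab,
    density_crossing_burst_ratio = th_cross,
    prey_fraction_E_no_phage = stats::setNames(as.list(
      no_phage$prey_fraction_E), no_phage$mode),
    sstar = unclass(sstar))
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
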