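#' Synthetic plate-reader / plaque-assay readout
#'
#' Emulates the in-vitro observables of a phage competition assay from model
#' trajectories: species-resolved optical-density-like prey signals sampled
#' every 20 minutes over 48 hours (145 time points), and endpoint phage
#' titers (PFU/mL) censored at a lower limit of detection. Noise is
#' multiplicative lognormal with a configurable coefficient of variation —
#' a stand-in with the right (positive) support; the study itself reports no
#' noise model. The mapping from dimensionless model time to hours is a
#' declared configuration scale affecting only this readout layer, never the
#' dynamics.
#'
#' @param params a [community_params()] record.
#' @param scenario phage treatment: `"none"`, `"specialist_only"`,
#'   `"generalist_only"` or `"both"`.
#' @param biomass_to_od scale from prey biomass to OD-equivalent signal.
#' @param biomass_to_pfu scale from phage biomass to PFU/mL.
#' @param noise_cv coefficient of variation of the lognormal noise (>= 0).
#' @param n_replicates number of replicate readouts (differ only in their
#'   noise stream).
#' @param seed RNG seed.
#' @param lod lower limit of detection for titers (PFU/mL).
#' @param hours assay duration in hours.
#' @param step_min sampling interval in minutes.
#' @param time_scale model time units per hour.
#' @return List of `plate_readout` objects. Each holds `signals` (long
#'   data.frame: `replicate`, `time_h`, `channel` in `E`/`S`, `value`),
#'   `titers` (data.frame: `phage`, `initial`, `final`, `censored`),
#'   `lod`, `replicate`, `seed`. Censored finals carry `final = NA` with
#'   `censored = TRUE` — never 0 nor a fabricated positive reading.
#' @export
simulate_readout <- function(params, scenario = c("both", "none",
                                                  "specialist_only",
                                                  "generalist_only"),
                             biomass_to_od = 1, biomass_to_pfu = 1,
                             noise_cv = 0.1, n_replicates = 3, seed = 0,
                             lod = 500, hours = 48, step_min = 20,
                             time_scale = 1) {
  scenario <- match.arg(scenario)
  stopifnot(biomass_to_od > 0, biomass_to_pfu > 0, noise_cv >= 0,
            n_replicates >= 1)
  init <- switch(scenario,
                 none = community_state(0.1, 0.1, 0, 0),
                 specialist_only = community_state(0.1, 0.1, 0, 0.1),
                 generalist_only = community_state(0.1, 0.1, 0.1, 0),
                 both = community_state(0.1, 0.1, 0.1, 0.1))
  times_h <- seq(0, hours, by = step_min / 60)
  traj <- integrate_community(params, init, t_end = hours * time_scale,
                              step_out = step_min / 60 * time_scale)
  # sample the trajectory on the assay grid
  sel <- vapply(times_h * time_scale, function(t)
    which.min(abs(traj$times - t)), integer(1))
  prey <- traj$states[sel, c("E", "S"), drop = FALSE]
  final <- traj$states[nrow(traj$states), ]
  init_v <- state_vec(init)
  sdlog <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
  meanlog <- -sdlog^2 / 2  # unit-mean noise
  set.seed(seed)
  lapply(seq_len(n_replicates), function(rep_id) {
    noise <- function(n) if (sdlog == 0) rep(1, n)
                         else stats::rlnorm(n, meanlog, sdlog)
    signals <- data.frame(
      replicate = rep_id,
      time_h = rep(times_h, 2),
      channel = rep(c("E", "S"), each = length(times_h)),
      value = c(prey[, "E"], prey[, "S"]) * biomass_to_od *
        noise(2 * length(times_h)))
    raw <- c(generalist = final[["G"]], specialist = final[["P"]]) *
      biomass_to_pfu * noise(2)
    censored <- raw < lod
    titers <- data.frame(
      phage = c("generalist", "specialist"),
      initial = c(init_v[["G"]], init_v[["P"]]) * biomass_to_pfu,
      final = ifelse(censored, NA_real_, raw),
      censored = censored)
    structure(list(signals = signals, titers = titers, lod = lod,
                   replicate = rep_id, seed = seed),
              class = "plate_readout")
  })
}

#' @export
print.plate_readout <- function(x, ...) {
  cat(sprintf("plate_readout replicate %d: %d signal rows, LOD = %g PFU/mL\n",
              x$replicate, nrow(x$signals), x$lod))
  print(x$titers, row.names = FALSE)
  invisible(x)
}

#' Write plate readouts as tidy CSV
#'
#' Long format with columns `replicate`, `time_h`, `channel`, `value`,
#' `censored`. Prey channels (`E`, `S`) appear at every sampled time;
#' endpoint titer channels (`titer_generalist`, `titer_specialist`) appear
#' once at the final time with their censoring flag (`value` empty when
#' censored).
#'
#' @param readouts list of `plate_readout` objects.
#' @param path output CSV file.
#' @export
write_readouts <- function(readouts, path) {
  rows <- lapply(readouts, function(r) {
    sig <- cbind(r$signals, censored = FALSE)
    tit <- data.frame(replicate = r$replicate,
                      time_h = max(r$signals$time_h),
                      channel = paste0("titer_", r$titers$phage),
                      value = r$titers$final,
                      censored = r$titers$censored)
    rbind(sig, tit)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Natural-log fold change of a phage titer
#'
#' `ln(final / initial)`; zero means no net change in titer. When the final
#' titer is censored below the limit of detection the value returned is the
#' upper bound `ln(lod / initial)`, flagged as censored.
#'
#' @param final_titer final titer (PFU/mL), or `NA` when censored.
#' @param initial_titer starting titer (PFU/mL), > 0.
#' @param censored whether the final titer is below the LOD.
#' @param lod limit of detection (PFU/mL); used only for censored bounds.
#' @return List with `value` (signed magnitude, or the censored upper
#'   bound) and `censored` flag.
#' @export
ln_fold_change <- function(final_titer, initial_titer, censored = FALSE,
                           lod = 500) {
  stopifnot(initial_titer > 0)
  if (isTRUE(censored) || is.na(final_titer)) {
    list(value = log(lod / initial_titer), censored = TRUE)
  } else {
    list(value = log(final_titer / initial_titer), censored = FALSE)
  }
}

#' Classify the winning phage from replicate readouts
#'
#' Compares mean endpoint titers between the two phage. Censored titers are
#' handled by interval bounds: a censored replicate contributes `[0, lod]`
#' to its phage's mean interval. The call is `"generalist"` or
#' `"specialist"` only when one mean interval lies strictly above the
#' other's; overlapping intervals give `"tie"`, and `"both_below_LOD"` when
#' every replicate of both phage is censored.
#'
#' @param readouts non-empty list of `plate_readout` objects.
#' @return One of `"generalist"`, `"specialist"`, `"tie"`,
#'   `"both_below_LOD"`.
#' @export
classify_winner <- function(readouts) {
  stopifnot(length(readouts) >= 1)
  bounds <- function(phage) {
    per <- vapply(readouts, function(r) {
      row <- r$titers[r$titers$phage == phage, ]
      if (row$censored) c(0, r$lod) else rep(row$final, 2)
    }, numeric(2))
    rowMeans(per)  # c(lower, upper) of the mean titer
  }
  g <- bounds("generalist"); p <- bounds("specialist")
  all_cens <- all(vapply(readouts, function(r) all(r$titers$censored),
                         logical(1)))
  if (all_cens) return("both_below_LOD")
  if (g[1] > p[2]) return("generalist")
  if (p[1] > g[2]) return("specialist")
  "tie"
}
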