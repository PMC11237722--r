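#' Integrate the community dynamics
#'
#' Solves the four-species system with deSolve's adaptive, stiff-capable
#' LSODA solver. Any species whose density has fallen below the extinction
#' floor at an output sample is clamped to exactly 0 there and the
#' integration restarts from that sample, so a numerically extinct
#' population cannot resurge later; because every per-capita rate is
#' proportional to the species' own biomass, a clamped species then stays
#' at 0 exactly. Clamping thus acts at the output sampling resolution
#' (`step_out`).
#'
#' On an unrecoverable solver failure part-way through, the partial
#' trajectory collected so far is returned with `converged = FALSE`;
#' a non-finite state with no usable prefix is an error.
#'
#' @param params a [community_params()] record.
#' @param init a [community_state()] or named vector `E,S,G,P`; the study
#'   convention initializes every present species at 0.1.
#' @param t_end final time (> 0).
#' @param step_out output sampling interval (default 1 time unit).
#' @param rtol,atol solver tolerances.
#' @param floor extinction floor (default 1e-12).
#' @return An object of class `trajectory`: list with `times`, `states`
#'   (matrix with columns `E,S,G,P`), `params`, `converged` (solver
#'   completed the full time span) and `t_end` (time of last sample).
#' @export
integrate_community <- function(params, init = community_state(0.1, 0.1, 0.1, 0.1),
                                t_end, step_out = 1,
                                rtol = 1e-8, atol = 1e-12, floor = 1e-12) {
  stopifnot(t_end > 0, step_out > 0)
  y0 <- state_vec(init)
  if (any(y0 < 0)) stop("initial state must be non-negative")
  y0[y0 < floor] <- 0
  times <- seq(0, t_end, by = step_out)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  deriv <- function(t, y, p) list(rhs_raw(y, p))
  nm <- c("E", "S", "G", "P")
  collected <- matrix(y0, 1, 4, dimnames = list(NULL, nm))
  coll_times <- times[1]
  start_idx <- 1L
  y <- y0
  ok <- TRUE
  while (start_idx < length(times)) {
    seg_times <- times[start_idx:length(times)]
    alive <- y > 0
    out <- try(suppressWarnings(deSolve::lsoda(
      y = y, times = seg_times, func = deriv, parms = params,
      rtol = rtol, atol = atol, maxsteps = 50000)), silent = TRUE)
    if (inherits(out, "try-error") || nrow(out) < 2) { ok <- FALSE; break }
    st <- out[, nm, drop = FALSE]
    finite <- apply(is.finite(st), 1, all)
    if (!all(finite)) {
      last <- which(!finite)[1] - 1L
      if (last < 2 && nrow(collected) == 1)
        stop("non-finite state encountered in integration")
      if (last < 2) { ok <- FALSE; break }
      st <- st[seq_len(last), , drop = FALSE]
      out <- out[seq_len(last), , drop = FALSE]
      ok <- FALSE
    }
    st[, !alive] <- 0  # extinct species stay extinct (guard against drift)
    # first sample at which a living species has dropped below the floor
    hit <- which(apply(st[, alive, drop = FALSE] < floor, 1, any))
    hit <- hit[hit > 1][1]  # segment start is clamped already
    cut <- if (is.na(hit)) nrow(st) else hit
    st[st < floor] <- 0
    collected <- rbind(collected, st[2:cut, , drop = FALSE])
    coll_times <- c(coll_times, out[2:cut, "time"])
    y <- st[cut, ]
    start_idx <- start_idx + cut - 1L
    if (!ok || (is.na(hit) && nrow(out) < length(seg_times))) { ok <- FALSE; break }
  }
  structure(list(times = coll_times, states = collected, params = params,
                 converged = ok && coll_times[length(coll_times)] >= t_end,
                 t_end = coll_times[length(coll_times)]),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  n <- nrow(x$states)
  cat(sprintf("trajectory: %d samples over t = [%g, %g]%s\n",
              n, x$times[1], x$t_end,
              if (x$converged) "" else "  [solver stopped early]"))
  cat("final state:\n")
  print(x$states[n, ])
  invisible(x)
}

#' Write a trajectory as tidy CSV
#'
#' Columns `t, E, S, G, P`, one row per output sample.
#'
#' @param traj a `trajectory` from [integrate_community()].
#' @param path output file.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(t = traj$times, traj$states, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the community to steady state
#'
#' Integrates in chunks and declares pointwise convergence when the
#' max absolute per-species excursion across a trailing window falls below
#' `tol`. Systems on limit cycles never converge pointwise; those are
#' summarized by the time average over the trailing window
#' (`method = "window_average"`, `converged = FALSE`) so that downstream
#' sweeps can flag such cells.
#'
#' @inheritParams integrate_community
#' @param tol per-species change threshold for pointwise convergence.
#' @param window trailing window duration (time units).
#' @param t_max integration cap.
#' @param step_out sampling interval within the window.
#' @return Object of class `steady_state`: list with `final_state` (named
#'   vector `E,S,G,P`), `converged`, `method` (`"pointwise"` or
#'   `"window_average"`), `t_reached`, `max_residual` (max |rhs| at
#'   `final_state`, reported in all cases) and `params`.
#' @export
run_to_steady_state <- function(params, init = community_state(0.1, 0.1, 0.1, 0.1),
                                tol = 1e-9, window = 100, t_max = 1e5,
                                step_out = 1, rtol = 1e-8, atol = 1e-12,
                                floor = 1e-12) {
  stopifnot(tol > 0, window > 0, t_max > window)
  y <- state_vec(init)
  y[y < floor] <- 0
  t_now <- 0
  chunk <- max(window, 200)
  repeat {
    t_next <- min(t_now + chunk, t_max)
    traj <- integrate_community(params, y, t_end = t_next - t_now,
                                step_out = step_out, rtol = rtol,
                                atol = atol, floor = floor)
    n <- nrow(traj$states)
    y <- traj$states[n, ]
    t_now <- t_now + traj$t_end
    in_win <- traj$times > traj$t_end - window
    win <- traj$states[in_win, , drop = FALSE]
    drift <- max(apply(win, 2, function(z) diff(range(z))))
    if (drift < tol) {
      return(structure(list(final_state = y, converged = TRUE,
                            method = "pointwise", t_reached = t_now,
                            max_residual = max(abs(rhs_raw(y, params))),
                            params = params),
                       class = "steady_state"))
    }
    if (t_now >= t_max || !traj$converged) {
      avg <- colMeans(win)
      return(structure(list(final_state = avg, converged = FALSE,
                            method = "window_average", t_reached = t_now,
                            max_residual = max(abs(rhs_raw(avg, params))),
                            params = params),
                       class = "steady_state"))
    }
    # grow chunks to amortize solver start-up on slow approaches
    chunk <- min(chunk * 2, 25000)
  }
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("steady_state (%s, converged = %s) at t = %g\n",
              x$method, x$converged, x$t_reached))
  print(x$final_state)
  cat(sprintf("max |rhs| = %.3g\n", x$max_residual))
  invisible(x)
}

#' Write a steady-state result as a JSON record
#' @param result a `steady_state` object.
#' @param path output file.
#' @export
write_steady_state <- function(result, path) {
  rec <- list(final_state = as.list(result$final_state),
              converged = result$converged, method = result$method,
              t_reached = result$t_reached,
              max_residual = result$max_residual)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Relative abundance of the specialist phage
#'
#' Equilibrium specialist density divided by the summed equilibrium density
#' of both phage, `P / (P + G)`. Values above 0.5 mean the specialist is the
#' more abundant phage. When both phage are extinct the fraction is
#' undefined and `NA` is returned (an explicit marker, not a NaN from 0/0).
#'
#' @param result a `steady_state` object, or a named state vector.
#' @return Fraction in `[0, 1]`, or `NA` when `P + G == 0`.
#' @export
relative_specialist_abundance <- function(result) {
  x <- if (inherits(result, "steady_state")) result$final_state
       else state_vec(result)
  tot <- x[["P"]] + x[["G"]]
  if (tot == 0) return(NA_real_)
  unname(x[["P"]] / tot)
}
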