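# Quasi-steady-state diel simulation: one FBA solve per expression time
# point, chained into a trajectory; cumulated starch content; calibration
# of the export bounds against the +/-1 diel step target.

#' Diel schedule
#'
#' @param time_points_h simulation time points (default `0, 3, ..., 21`:
#'   one 24 h cycle on the 3 h microarray grid; the 24 h sample duplicates
#'   ZT0 and is not re-simulated).
#' @param light_window_h half-open interval during which lights are on
#'   (default `[0, 12)`).
#' @param dt_h grid spacing used for flux cumulation.
#' @return A `diel_schedule`.
#' @export
diel_schedule <- function(time_points_h = seq(0, 21, by = 3),
                          light_window_h = c(0, 12), dt_h = 3) {
  if (is.unsorted(time_points_h, strictly = TRUE))
    stop("time points must be strictly increasing")
  structure(list(time_points_h = as.numeric(time_points_h),
                 light_window_h = as.numeric(light_window_h),
                 dt_h = as.numeric(dt_h)),
            class = "diel_schedule")
}

#' Is a time point in the light phase?
#' @param schedule a `diel_schedule`.
#' @param t_h time in hours (taken modulo 24).
#' @return logical vector.
#' @export
is_light <- function(schedule, t_h) {
  tm <- t_h %% 24
  tm >= schedule$light_window_h[1] & tm < schedule$light_window_h[2]
}

#' Simulate one diel cycle as a chain of quasi-steady states
#'
#' At every schedule time point: the phase is set from the light window
#' (CO2 uptake and its objective weight on in the light, off in the dark),
#' reaction bounds are rescaled by the expression-derived activity
#' multipliers, and the flux balance problem is solved. Time points are
#' independent; only the cumulation step (see [cumulate_starch()]) links
#' them. Solver failures at single points are recorded and the run
#' continues.
#'
#' @param model a `starch_model`.
#' @param norm a `normalized_series`; its time grid must contain every
#'   schedule time point.
#' @param schedule a `diel_schedule`.
#' @param overrides named gene-value overrides passed to
#'   [reaction_activity()] (used by the perturbation scans).
#' @param minimize_total_flux logical; lexicographic flux tie-break.
#' @return A `diel_trajectory`: times, phase flags, solver status, the
#'   starch/maltose/glucose exchange fluxes, objective values and the full
#'   flux matrix (reactions x time points).
#' @export
simulate_cycle <- function(model, norm, schedule = diel_schedule(),
                           overrides = NULL, minimize_total_flux = TRUE) {
  stopifnot(inherits(norm, "normalized_series"))
  idx <- match(schedule$time_points_h, norm$time_points_h)
  if (anyNA(idx))
    stop("expression grid lacks schedule time point(s): ",
         paste(schedule$time_points_h[is.na(idx)], collapse = ", "))
  tp <- schedule$time_points_h
  nT <- length(tp)
  rx_ids <- model$reactions$id
  fluxes <- matrix(NA_real_, nrow = length(rx_ids), ncol = nT,
                   dimnames = list(rx_ids, paste0("ZT", tp)))
  status <- character(nT); objective <- rep(NA_real_, nT)
  light <- is_light(schedule, tp)
  for (k in seq_len(nT)) {
    m <- set_phase(model, light[k])
    mult <- reaction_activity(norm, m, idx[k], overrides)
    m <- apply_activity(m, mult)
    sol <- tryCatch(
      solve_fba(m, diel_objective(m, light[k]),
                minimize_total_flux = minimize_total_flux),
      error = function(e) list(status = paste("error:", conditionMessage(e)),
                               fluxes = numeric(0)))
    status[k] <- sol$status
    if (identical(sol$status, "optimal")) {
      fluxes[, k] <- sol$fluxes[rx_ids]
      objective[k] <- sol$objective_value
    }
  }
  structure(list(
    times_h = tp, light = light, status = status, objective = objective,
    starch_flux = fluxes["EX_STARCH", ],
    maltose_flux = fluxes["EX_MAL", ],
    glucose_flux = fluxes["EX_GLC", ],
    fluxes = fluxes, schedule = schedule),
    class = "diel_trajectory")
}

#' Cumulate starch exchange flux into a starch-content trajectory
#'
#' Left-rectangular Riemann cumulation on the schedule grid:
#' `content[k] = S0 + sum_{i<=k} flux(t_i) * dt`. Infeasible time points
#' contribute zero flux (and are flagged). The default `S0` is the
#' smallest value keeping the content non-negative over the cycle, since
#' the granule is never observed to deplete completely.
#'
#' @param traj a `diel_trajectory`.
#' @param S0 initial content (arbitrary units); `NULL` for the default.
#' @param rule `"left"` (default) or `"trapezoid"`.
#' @return A `starch_trajectory` with `times_h`, `content`, `S0`.
#' @export
cumulate_starch <- function(traj, S0 = NULL, rule = c("left", "trapezoid")) {
  rule <- match.arg(rule)
  flux <- traj$starch_flux
  flux[is.na(flux)] <- 0
  dt <- traj$schedule$dt_h
  inc <- flux * dt
  if (rule == "trapezoid" && length(flux) > 1L)
    inc[-1] <- dt * (utils::head(flux, -1) + utils::tail(flux, -1)) / 2
  cum <- cumsum(inc)
  if (is.null(S0)) S0 <- max(0, -min(cum, 0))
  structure(list(times_h = traj$times_h, content = S0 + cum, S0 = S0,
                 flagged_infeasible = traj$times_h[traj$status != "optimal"]),
            class = "starch_trajectory")
}

#' Multi-day starch content simulation
#'
#' Repeats the quasi-steady-state daily cycle `n_days` times, carrying the
#' cumulated content across days. Time points are still independent
#' steady states (no memory, no dilution term), so the daily flux pattern
#' is identical across days and only the content baseline drifts.
#'
#' @param model,norm,schedule,overrides as in [simulate_cycle()].
#' @param n_days number of days (>= 1).
#' @param S0 initial content; `NULL` keeps the whole trajectory >= 0.
#' @return A `starch_trajectory` spanning `n_days * 24` hours.
#' @export
simulate_days <- function(model, norm, schedule = diel_schedule(),
                          n_days = 1L, S0 = NULL, overrides = NULL) {
  if (n_days < 1L) stop("n_days must be >= 1")
  traj <- simulate_cycle(model, norm, schedule, overrides)
  flux <- traj$starch_flux
  flux[is.na(flux)] <- 0
  dt <- traj$schedule$dt_h
  flux_all <- rep(flux, n_days)
  times <- as.vector(vapply(seq_len(n_days) - 1L,
                            function(d) traj$times_h + 24 * d,
                            numeric(length(traj$times_h))))
  cum <- cumsum(flux_all * dt)
  if (is.null(S0)) S0 <- max(0, -min(cum, 0))
  structure(list(times_h = times, content = S0 + cum, S0 = S0,
                 flagged_infeasible =
                   times[rep(traj$status != "optimal", n_days)]),
            class = "starch_trajectory")
}

#' Calibrate the export bounds against the diel step target
#'
#' Grid search over (maltose, glucose) export upper bounds minimizing the
#' squared deviation of the saturated (all activity multipliers = 1)
#' light/dark starch exchange fluxes from a step target (+1 during the
#' light phase, -1 at night). Ties keep the earliest grid point, so the
#' result is deterministic for a fixed grid.
#'
#' The default grid spans `[0, 370]` x `[0, 245]` (below the
#' stoichiometric export capacities of 370 maltose and 740 glucose per
#' unit starch flux) and contains the shipped defaults (166.5, 122.45).
#'
#' @param model a `starch_model` (its CO2 bound and objective are kept).
#' @param target length-2 numeric: the light and dark target flux.
#' @param maltose_grid,glucose_grid candidate upper bounds.
#' @param schedule a `diel_schedule` (sets the light:dark point ratio).
#' @return A list with `maltose_ub`, `glucose_ub`, `residual` and the full
#'   `grid` data frame (columns `maltose_ub`, `glucose_ub`,
#'   `starch_light`, `starch_dark`, `residual`).
#' @export
calibrate_export_bounds <- function(model,
                                    target = c(light = 1, dark = -1),
                                    maltose_grid = seq(0, 370, by = 33.3),
                                    glucose_grid = seq(0, 244.9, by = 24.49),
                                    schedule = diel_schedule()) {
  if (!length(maltose_grid) || !length(glucose_grid))
    stop("empty calibration grid")
  if (length(target) != 2L) stop("target must be c(light, dark)")
  n_light <- sum(is_light(schedule, schedule$time_points_h))
  n_dark <- length(schedule$time_points_h) - n_light
  im <- .rx_index(model, "EX_MAL"); ig <- .rx_index(model, "EX_GLC")
  grid <- expand.grid(maltose_ub = maltose_grid, glucose_ub = glucose_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$starch_light <- NA_real_; grid$starch_dark <- NA_real_
  grid$residual <- NA_real_
  for (k in seq_len(nrow(grid))) {
    m <- model
    m$reactions$upper_bound[c(im, ig)] <-
      m$reactions$default_upper[c(im, ig)] <-
      c(grid$maltose_ub[k], grid$glucose_ub[k])
    sl <- solve_fba(set_phase(m, TRUE), minimize_total_flux = FALSE)
    sd <- solve_fba(set_phase(m, FALSE),
                    diel_objective(m, FALSE), minimize_total_flux = FALSE)
    fl <- if (sl$status == "optimal") sl$fluxes[["EX_STARCH"]] else NA_real_
    fd <- if (sd$status == "optimal") sd$fluxes[["EX_STARCH"]] else NA_real_
    grid$starch_light[k] <- fl; grid$starch_dark[k] <- fd
    grid$residual[k] <- n_light * (fl - target[1])^2 +
      n_dark * (fd - target[2])^2
  }
  best <- which.min(grid$residual)   # first minimum: deterministic
  list(maltose_ub = grid$maltose_ub[best], glucose_ub = grid$glucose_ub[best],
       residual = grid$residual[best], grid = grid)
}

# ---- printing / export ------------------------------------------------------

#' @export
print.diel_trajectory <- function(x, ...) {
  cat("Diel quasi-steady-state trajectory (", length(x$times_h),
      " time points )\n", sep = "")
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.diel_trajectory <- function(x, ...) {
  data.frame(time_h = x$times_h,
             phase = ifelse(x$light, "light", "dark"),
             starch_flux = unname(x$starch_flux),
             maltose_flux = unname(x$maltose_flux),
             glucose_flux = unname(x$glucose_flux),
             objective = x$objective, status = x$status,
             stringsAsFactors = FALSE)
}

#' @export
print.starch_trajectory <- function(x, ...) {
  cat("Starch content trajectory, S0 =", format(x$S0, digits = 4), "\n")
  print(data.frame(time_h = x$times_h, content = x$content),
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.starch_trajectory <- function(x, ...) {
  data.frame(time_h = x$times_h, content = x$content)
}

#' Write a trajectory as TSV
#' @param x a `diel_trajectory` or `starch_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Plot a diel flux or starch-content trajectory
#'
#' @param x a `diel_trajectory`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.diel_trajectory <- function(x, ...) {
  graphics::matplot(x$times_h,
                    cbind(x$starch_flux, x$maltose_flux / 166.5),
                    type = "b", pch = c(19, 1), lty = c(1, 2),
                    xlab = "time (h)", ylab = "flux (normalized units)",
                    ...)
  graphics::abline(v = x$schedule$light_window_h[2], col = "grey", lty = 3)
  graphics::abline(h = 0, col = "grey")
  graphics::legend("topright", c("starch exchange", "maltose export / 166.5"),
                   pch = c(19, 1), lty = c(1, 2), bty = "n")
  invisible(x)
}

#' @export
plot.starch_trajectory <- function(x, ...) {
  graphics::plot(x$times_h, x$content, type = "b", pch = 19,
                 xlab = "time (h)", ylab = "starch content (a.u.)", ...)
  invisible(x)
}
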