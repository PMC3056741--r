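# Flux balance analysis core: the diel objective, deterministic LP solves
# with a lexicographic minimum-total-flux tie-break, flux variability and
# robustness scans.

#' Diel objective function
#'
#' The weighted sum maximized at every quasi-steady state:
#' `Z = w_CO2 * CO2_uptake + 10468.135 * starch_exchange +
#'  963.325 * maltose_export + 650 * glucose_export`,
#' with `w_CO2 = 1` in the light phase and `0` in the dark (nightfall is
#' simulated by zeroing both the CO2 weight and the CO2 uptake bound).
#'
#' @param model a `starch_model`.
#' @param light logical phase flag.
#' @return Named numeric vector of weights over all reactions.
#' @export
diel_objective <- function(model, light = TRUE) {
  w <- stats::setNames(rep(0, nrow(model$reactions)), model$reactions$id)
  keep <- intersect(names(model$objective), names(w))
  if (length(keep) < length(model$objective))
    stop("objective references unknown reactions: ",
         paste(setdiff(names(model$objective), names(w)), collapse = ", "))
  w[keep] <- model$objective[keep]
  if (!light) w["EX_CO2"] <- 0
  w
}

#' Switch the model between light and dark phase
#'
#' Light: CO2 uptake open at its default bound and weighted 1 in the
#' objective. Dark: CO2 uptake bound and weight both 0. Nothing else
#' changes, and the operation is idempotent.
#'
#' @param model a `starch_model`.
#' @param light logical.
#' @return The model with phase applied; the phase objective is stored in
#'   `attr(model, "phase_objective")` and the flag in `attr(model, "light")`.
#' @export
set_phase <- function(model, light) {
  i <- match("EX_CO2", model$reactions$id)
  if (is.na(i)) stop("model has no CO2 uptake exchange (EX_CO2)")
  model$reactions$upper_bound[i] <-
    if (light) model$reactions$default_upper[i] else 0
  attr(model, "light") <- light
  attr(model, "phase_objective") <- diel_objective(model, light)
  model
}

.model_lp <- function(model) {
  list(S = stoichiometric_matrix(model),
       lb = model$reactions$lower_bound,
       ub = model$reactions$upper_bound,
       ids = model$reactions$id)
}

#' Solve the flux balance problem
#'
#' Maximizes the objective over `S v = 0`, `lb <= v <= ub`. Among the
#' (generally non-unique) optimal vertices, the reported solution is made
#' deterministic by a lexicographic second stage that minimizes total
#' absolute flux at the primary optimum, which removes futile cycles.
#'
#' @param model a `starch_model` (phase already applied via [set_phase()]
#'   or bounds set directly).
#' @param objective named weight vector as from [diel_objective()]; by
#'   default the light-phase diel objective.
#' @param minimize_total_flux logical; run the lexicographic second stage.
#' @param tol numerical tolerance for the optimum pin of the second stage.
#' @return An `fba_solution`: list with `status` (`optimal`, `infeasible`,
#'   `unbounded`), `objective_value`, and named `fluxes` (empty unless
#'   optimal).
#' @examples
#' mod <- set_phase(build_starch_model(), light = TRUE)
#' sol <- solve_fba(mod)
#' sol$fluxes["EX_STARCH"]
#' @export
solve_fba <- function(model, objective = NULL, minimize_total_flux = TRUE,
                      tol = 1e-9) {
  if (is.null(objective)) {
    objective <- attr(model, "phase_objective")
    if (is.null(objective)) objective <- diel_objective(model, light = TRUE)
  }
  lp <- .model_lp(model)
  w <- stats::setNames(rep(0, length(lp$ids)), lp$ids)
  bad <- setdiff(names(objective)[objective != 0], lp$ids)
  if (length(bad)) stop("objective references unknown reactions: ",
                        paste(bad, collapse = ", "))
  w[names(objective)] <- objective

  if (any(lp$lb > lp$ub)) {
    return(structure(list(status = "infeasible",
                          objective_value = NA_real_,
                          fluxes = numeric(0)), class = "fba_solution"))
  }
  m <- nrow(lp$S)
  r1 <- solve_lp(w, lp$S, rep(0, m), lp$lb, lp$ub, maximize = TRUE)
  if (r1$status != "optimal") {
    return(structure(list(status = r1$status, objective_value = NA_real_,
                          fluxes = numeric(0)), class = "fba_solution"))
  }
  v <- r1$x
  if (minimize_total_flux) {
    v <- .min_total_flux(lp, w, r1$objective, tol)
    if (is.null(v)) v <- r1$x   # pin infeasible at tolerance: keep stage 1
  }
  names(v) <- lp$ids
  structure(list(status = "optimal",
                 objective_value = sum(w * v),
                 fluxes = v),
            class = "fba_solution")
}

# Lexicographic stage 2: minimize sum(|v|) subject to the original
# constraints and w'v >= Z* - eps. Reversible columns are split v = p - q.
.min_total_flux <- function(lp, w, zstar, tol) {
  n <- length(lp$ids)
  rev <- lp$lb < 0
  nr <- sum(rev)
  S1 <- lp$S
  Sp <- S1[, rev, drop = FALSE]
  A <- cbind(S1, -Sp)                       # columns: all v (p-role), q for rev
  # pin row: w'v >= zstar - eps  ->  w'v - s = zstar - eps, s >= 0
  eps <- tol * max(1, abs(zstar))
  pin <- c(w, -w[rev])
  A <- rbind(A, c(pin))
  A <- cbind(A, c(rep(0, nrow(S1)), -1))    # slack column
  b <- c(rep(0, nrow(S1)), zstar - eps)
  lb2 <- c(pmax(lp$lb, 0), rep(0, nr), 0)
  ub2 <- c(lp$ub, -lp$lb[rev], Inf)
  ub2[ub2 < lb2] <- lb2[ub2 < lb2]
  cc <- c(rep(1, n + nr), 0)
  r <- solve_lp(cc, A, b, lb2, ub2, maximize = FALSE)
  if (r$status != "optimal") return(NULL)
  v <- r$x[seq_len(n)]
  v[rev] <- v[rev] - r$x[n + seq_len(nr)]
  v
}

#' @export
print.fba_solution <- function(x, ...) {
  cat("FBA solution:", x$status)
  if (x$status == "optimal") {
    cat("  Z =", format(x$objective_value, digits = 8), "\n")
    key <- intersect(c("EX_CO2", "EX_STARCH", "EX_MAL", "EX_GLC"),
                     names(x$fluxes))
    if (length(key)) {
      cat("  exchange fluxes:\n")
      for (k in key) cat(sprintf("    %-10s %12.6f\n", k, x$fluxes[k]))
    }
  } else cat("\n")
  invisible(x)
}

#' @export
as.data.frame.fba_solution <- function(x, ...) {
  data.frame(reaction = names(x$fluxes), flux = unname(x$fluxes),
             stringsAsFactors = FALSE)
}

#' Flux variability analysis
#'
#' For every reaction, the minimum and maximum flux it can carry while the
#' objective stays at or above `fraction` times its optimum.
#'
#' @param model a `starch_model`.
#' @param objective named weights (default: light diel objective).
#' @param fraction required fraction of the optimal objective, in (0, 1].
#' @return Data frame with columns `reaction`, `min_flux`, `max_flux`, or
#'   a structure with `status = "infeasible"` when the base problem is.
#' @export
flux_variability <- function(model, objective = NULL, fraction = 1.0) {
  if (!(is.numeric(fraction) && length(fraction) == 1L &&
        fraction > 0 && fraction <= 1))
    stop("fraction must lie in (0, 1]")
  base <- solve_fba(model, objective, minimize_total_flux = FALSE)
  if (base$status != "optimal")
    return(structure(list(status = base$status), class = "fva_result"))
  lp <- .model_lp(model)
  w <- stats::setNames(rep(0, length(lp$ids)), lp$ids)
  if (is.null(objective)) objective <- diel_objective(model, TRUE)
  w[names(objective)] <- objective
  zmin <- fraction * base$objective_value -
    1e-9 * max(1, abs(base$objective_value))
  # add row w'v - s = zmin with slack s in [0, Inf)
  A <- rbind(lp$S, w)
  A <- cbind(A, c(rep(0, nrow(lp$S)), -1))
  b <- c(rep(0, nrow(lp$S)), zmin)
  lb <- c(lp$lb, 0); ub <- c(lp$ub, Inf)
  n <- length(lp$ids)
  mn <- mx <- numeric(n)
  for (j in seq_len(n)) {
    e <- rep(0, n + 1); e[j] <- 1
    mx[j] <- solve_lp(e, A, b, lb, ub, maximize = TRUE)$objective
    mn[j] <- solve_lp(e, A, b, lb, ub, maximize = FALSE)$objective
  }
  structure(data.frame(reaction = lp$ids, min_flux = mn, max_flux = mx,
                       stringsAsFactors = FALSE),
            status = "optimal", class = c("fva_result", "data.frame"))
}

#' Robustness scan over one reaction's upper bound
#'
#' Re-solves the flux balance problem for each value of the scanned
#' reaction's upper bound, holding everything else fixed; reports the
#' optimal objective and the starch exchange flux per grid point. The
#' optimal objective is non-decreasing in the bound.
#'
#' @param model a `starch_model`.
#' @param objective named weights (default: light diel objective).
#' @param reaction_id reaction whose upper bound is scanned.
#' @param grid numeric vector of non-negative upper-bound values.
#' @return Data frame with columns `bound`, `status`, `objective_value`,
#'   `starch_flux`.
#' @export
robustness_scan <- function(model, objective = NULL, reaction_id, grid) {
  i <- .rx_index(model, reaction_id)
  if (any(grid < 0)) stop("grid values must be >= 0")
  out <- data.frame(bound = grid, status = NA_character_,
                    objective_value = NA_real_, starch_flux = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(grid)) {
    m2 <- model
    m2$reactions$upper_bound[i] <- grid[k]
    if (m2$reactions$lower_bound[i] > grid[k])
      m2$reactions$lower_bound[i] <- min(m2$reactions$lower_bound[i], grid[k])
    sol <- solve_fba(m2, objective, minimize_total_flux = FALSE)
    out$status[k] <- sol$status
    if (sol$status == "optimal") {
      out$objective_value[k] <- sol$objective_value
      out$starch_flux[k] <- sol$fluxes["EX_STARCH"]
    }
  }
  out
}

#' Export fluxes of a solution as TSV
#'
#' @param solution an `fba_solution`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fluxes_tsv <- function(solution, path) {
  utils::write.table(as.data.frame(solution), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
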