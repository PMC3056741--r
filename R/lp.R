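# Dense bounded-variable two-phase primal simplex.
#
# Solves   max/min  c'x   s.t.  A x = b,   lb <= x <= ub
# on the small dense problems that arise from the starch network
# (tens of rows, low hundreds of columns). Determinism matters more than
# raw speed here: entering variables are chosen by the most-negative
# reduced cost with smallest-index tie-breaks, the leaving row by the
# tightest ratio with smallest-index tie-breaks, and Bland's rule takes
# over if the objective stalls, so identical inputs always yield the
# identical vertex.

#' Solve a bounded-variable linear program
#'
#' A self-contained two-phase primal simplex over equality constraints and
#' variable bounds, the canonical form of a flux-balance problem
#' (`S v = 0`, `lb <= v <= ub`).
#'
#' @param obj numeric objective coefficients, length `n`.
#' @param A constraint matrix (`m x n`); may have zero rows.
#' @param b right-hand side, length `m`.
#' @param lb,ub variable bounds (recycled); `-Inf`/`Inf` allowed.
#' @param maximize logical; maximize (default) or minimize.
#' @param tol feasibility/optimality tolerance.
#' @param max_iter iteration cap across both phases.
#'
#' @return A list with elements `status` (one of `"optimal"`,
#'   `"infeasible"`, `"unbounded"`), `objective` and `x` (primal solution,
#'   `NA` unless optimal).
#' @keywords internal
#' @export
solve_lp <- function(obj, A, b, lb, ub, maximize = TRUE,
                     tol = 1e-9, max_iter = 20000L) {
  A <- as.matrix(A)
  n <- length(obj)
  m <- nrow(A)
  stopifnot(ncol(A) == n, length(b) == m)
  lb <- rep_len(as.numeric(lb), n)
  ub <- rep_len(as.numeric(ub), n)

  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n)))
  }
  # Clamp crossing bounds that agree within tolerance.
  mid <- lb > ub
  if (any(mid)) { v <- (lb[mid] + ub[mid]) / 2; lb[mid] <- v; ub[mid] <- v }

  cc <- if (maximize) -as.numeric(obj) else as.numeric(obj)

  if (m == 0L) {
    # Pure bound problem.
    x <- ifelse(cc < 0, ub, ifelse(cc > 0, lb, ifelse(is.finite(lb), pmax(lb, pmin(ub, 0)), 0)))
    if (any(!is.finite(x))) {
      return(list(status = "unbounded", objective = NA_real_,
                  x = rep(NA_real_, n)))
    }
    z <- sum(cc * x)
    return(list(status = "optimal",
                objective = if (maximize) -z else z, x = x))
  }

  # Start every structural variable at its finite bound nearest zero
  # (zero itself for free variables), then cover the residual with one
  # artificial per row so phase 1 starts from an identity basis.
  start_val <- function(l, u) {
    if (is.finite(l) && l > 0) l
    else if (is.finite(u) && u < 0) u
    else if (is.finite(l) && is.finite(u) && l <= 0 && u >= 0) 0
    else if (is.finite(l)) max(l, 0)
    else if (is.finite(u)) min(u, 0)
    else 0
  }
  x0 <- mapply(start_val, lb, ub)
  resid <- b - as.vector(A %*% x0)
  sgn <- ifelse(resid >= 0, 1, -1)

  Afull <- cbind(A, diag(sgn, nrow = m))
  lbf <- c(lb, rep(0, m))
  ubf <- c(ub, rep(Inf, m))
  ntot <- n + m
  art <- (n + 1L):ntot

  # State: basis (row -> column), nonbasic status vector:
  #   0 = basic, 1 = at lower bound, 2 = at upper bound, 3 = free at 0.
  basis <- art
  stat <- integer(ntot)
  stat[seq_len(n)] <- ifelse(x0 == lb & is.finite(lb), 1L,
                       ifelse(x0 == ub & is.finite(ub), 2L, 3L))
  stat[art] <- 0L
  xval <- c(x0, abs(resid))

  run_phase <- function(cost, basis, stat, xval, iter_left) {
    nloc <- length(cost)
    stall <- 0L
    bland <- FALSE
    zprev <- Inf
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > iter_left) return(list(code = "maxiter", basis = basis,
                                      stat = stat, xval = xval, iters = it))
      Bmat <- Afull[, basis, drop = FALSE]
      Blu <- tryCatch(solve(Bmat), error = function(e) NULL)
      if (is.null(Blu)) {
        # Singular basis should not happen (phase-1 identity start, pivot
        # checks below); abort defensively.
        return(list(code = "singular", basis = basis, stat = stat,
                    xval = xval, iters = it))
      }
      # Refresh basic values from the nonbasic ones for numerical hygiene.
      nb <- which(stat != 0L)
      rhs <- b - as.vector(Afull[, nb, drop = FALSE] %*% xval[nb])
      xval[basis] <- as.vector(Blu %*% rhs)

      y <- as.vector(crossprod(Blu, cost[basis]))
      d <- cost - as.vector(crossprod(Afull, y))  # reduced costs
      d[basis] <- 0

      cand_lo <- which(stat == 1L & d < -tol)
      cand_hi <- which(stat == 2L & d > tol)
      cand_fr <- which(stat == 3L & abs(d) > tol)
      if (length(cand_lo) + length(cand_hi) + length(cand_fr) == 0L) {
        return(list(code = "optimal", basis = basis, stat = stat,
                    xval = xval, iters = it))
      }
      if (bland) {
        j <- min(c(cand_lo, cand_hi, cand_fr))
      } else {
        allc <- c(cand_lo, cand_hi, cand_fr)
        score <- abs(d[allc])
        j <- allc[which(score == max(score))][1L]
      }
      dirn <- if (stat[j] == 1L || (stat[j] == 3L && d[j] < 0)) 1 else -1

      w <- as.vector(Blu %*% Afull[, j])
      # Max step before a basic variable or the entering variable itself
      # hits a bound.  x_B changes by -dirn * w * t as x_j += dirn * t.
      # Distance to the entering variable's own opposite bound, measured
      # from its current value (it may rest at 0 between its bounds).
      tmax <- if (dirn > 0) ubf[j] - xval[j] else xval[j] - lbf[j]
      if (!is.finite(tmax)) tmax <- Inf
      leave <- 0L
      leave_to <- 0L
      xb <- xval[basis]
      delta <- -dirn * w
      for (i in seq_len(m)) {
        di <- delta[i]
        if (di > tol) {
          cap <- (ubf[basis[i]] - xb[i]) / di
          to <- 2L
        } else if (di < -tol) {
          cap <- (lbf[basis[i]] - xb[i]) / di
          to <- 1L
        } else next
        if (cap < tmax - 1e-12) {
          tmax <- max(cap, 0)
          leave <- i
          leave_to <- to
        } else if (cap <= tmax + 1e-12 && leave != 0L &&
                   basis[i] < basis[leave]) {
          # Bland-compatible tie-break: smallest column index leaves.
          leave <- i
          leave_to <- to
        }
      }
      if (!is.finite(tmax)) {
        return(list(code = "unbounded", basis = basis, stat = stat,
                    xval = xval, iters = it))
      }
      xval[j] <- xval[j] + dirn * tmax
      xval[basis] <- xval[basis] + delta * tmax
      if (leave == 0L) {
        # Bound flip: entering variable moved to its opposite bound.
        stat[j] <- if (dirn > 0) 2L else 1L
        xval[j] <- if (dirn > 0) ubf[j] else lbf[j]
      } else {
        lv <- basis[leave]
        stat[lv] <- leave_to
        xval[lv] <- if (leave_to == 1L) lbf[lv] else ubf[lv]
        basis[leave] <- j
        stat[j] <- 0L
      }
      z <- sum(cost * xval)
      if (z < zprev - tol) { zprev <- z; stall <- 0L }
      else {
        stall <- stall + 1L
        if (stall > 2L * (nloc + m)) bland <- TRUE
      }
    }
  }

  # Phase 1: drive artificials to zero.
  c1 <- c(rep(0, n), rep(1, m))
  p1 <- run_phase(c1, basis, stat, xval, max_iter)
  if (p1$code == "maxiter" || p1$code == "singular") {
    stop("simplex failed to converge in phase 1 (", p1$code, ")")
  }
  if (p1$code == "unbounded") stop("phase-1 problem cannot be unbounded")
  feas <- sum(p1$xval[art])
  if (feas > 1e-7) {
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n)))
  }
  # Freeze artificials at zero for phase 2.
  ubf[art] <- 0
  # Basic artificials (degenerate at 0) are tolerated: their bounds are now
  # [0,0] so they can never move off zero.
  c2 <- c(cc, rep(0, m))
  p2 <- run_phase(c2, p1$basis, p1$stat, p1$xval, max_iter)
  if (p2$code == "maxiter" || p2$code == "singular") {
    stop("simplex failed to converge in phase 2 (", p2$code, ")")
  }
  if (p2$code == "unbounded") {
    return(list(status = "unbounded", objective = NA_real_,
                x = rep(NA_real_, n)))
  }
  x <- p2$xval[seq_len(n)]
  # Snap to bounds within tolerance.
  x <- pmin(pmax(x, lb), ub)
  z <- sum(cc * x)
  list(status = "optimal", objective = if (maximize) -z else z, x = x)
}

# Assign ubf/lbf into the closure of run_phase via environment: run_phase is
# defined inside solve_lp so it captures Afull, b, lbf, ubf, tol, m by
# lexical scope; note phase 2 sees the updated ubf because the freeze above
# happens before run_phase is called again.
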