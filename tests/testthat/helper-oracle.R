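# Independent LP oracle: brute-force enumeration of basic solutions
# (vertices) of  max c'x  s.t.  A x = b,  lb <= x <= ub.
# Exponential, so only for networks with <= 8 reactions; used to certify
# the package's simplex on small problems.

oracle_lp <- function(obj, A, b, lb, ub) {
  A <- as.matrix(A); m <- nrow(A); n <- ncol(A)
  lb <- rep_len(lb, n); ub <- rep_len(ub, n)
  stopifnot(n <= 10, all(is.finite(lb)), all(is.finite(ub)))
  best <- -Inf; bestx <- NULL
  feas_tol <- 1e-8
  check <- function(x) {
    if (any(x < lb - feas_tol) || any(x > ub + feas_tol)) return()
    if (m > 0 && max(abs(A %*% x - b)) > 1e-7) return()
    z <- sum(obj * x)
    if (z > best) { best <<- z; bestx <<- x }
  }
  if (m == 0L) {
    # vertices of the box
    grid <- expand.grid(rep(list(1:2), n))
    for (i in seq_len(nrow(grid)))
      check(ifelse(grid[i, ] == 1, lb, ub))
  } else {
    combs <- utils::combn(n, m)
    for (k in seq_len(ncol(combs))) {
      B <- combs[, k]
      AB <- A[, B, drop = FALSE]
      if (abs(det(AB)) < 1e-10) next
      N <- setdiff(seq_len(n), B)
      settings <- expand.grid(rep(list(1:2), length(N)))
      if (length(N) == 0L) settings <- data.frame(row.names = 1)
      for (i in seq_len(nrow(settings))) {
        x <- numeric(n)
        if (length(N))
          x[N] <- ifelse(settings[i, ] == 1, lb[N], ub[N])
        rhs <- b - if (length(N)) A[, N, drop = FALSE] %*% x[N] else 0
        x[B] <- solve(AB, rhs)
        check(x)
      }
    }
  }
  list(objective = best, x = bestx)
}

# A three-reaction chain: uptake -> conversion (bottleneck) -> export.
toy_chain_model <- function(conv_ub = 5) {
  A <- matrix(c(1, -1, 0,
                0, 1, -1), nrow = 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("uptake", "conv", "export")))
  list(S = A, lb = c(0, 0, 0), ub = c(10, conv_ub, 10),
       obj = c(0, 0, 1))
}

# Noise-free fixture + canonical model, shared across perturbation tests.
fixture_norm <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- normalize_expression(diel_expression_fixture(seed = 1,
                                                           noise_sd = 0))
    val
  }
})

canonical_model <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- build_starch_model()
    val
  }
})

saturated_phase_flux <- function(model, light, reaction = "EX_STARCH") {
  m <- set_phase(model, light)
  sol <- solve_fba(m, diel_objective(m, light))
  sol$fluxes[[reaction]]
}
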