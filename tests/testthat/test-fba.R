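# The LP core on the canonical model and on hand-checkable toys.

test_that("toy chain optimum equals the bottleneck bound", {
  toy <- toy_chain_model(conv_ub = 5)
  r <- solve_lp(toy$obj, toy$S, c(0, 0), toy$lb, toy$ub)
  expect_equal(r$objective, 5)
  want <- oracle_lp(toy$obj, toy$S, c(0, 0), toy$lb, toy$ub)
  expect_equal(r$objective, want$objective)
})

test_that("saturated light and dark optima give the symmetric diel step", {
  # Derived expectation, independent of the solver: the objective weights
  # per glucosyl residue are 963.325/2 (maltose) and 650 (glucose) versus
  # 10468.135/740 (starch), so both export bounds saturate first and
  # starch receives the residual carbon.  With the CO2 bound at
  # 2*(12*166.5 + 6*122.45) carbons, light = capacity - exports and
  # dark = -exports, i.e. +/- (12*166.5 + 6*122.45)/4440.
  step <- (12 * 166.5 + 6 * 122.45) / 4440
  mod <- canonical_model()
  sl <- saturated_phase_flux(mod, light = TRUE)
  sd_ <- saturated_phase_flux(mod, light = FALSE)
  expect_equal(sl, step, tolerance = 1e-6)
  expect_equal(sd_, -step, tolerance = 1e-6)
  # exports saturate in both phases
  m <- set_phase(mod, TRUE)
  sol <- solve_fba(m, diel_objective(m, TRUE))
  expect_equal(unname(sol$fluxes["EX_MAL"]), 166.5, tolerance = 1e-6)
  expect_equal(unname(sol$fluxes["EX_GLC"]), 122.45, tolerance = 1e-6)
})

test_that("optimal solutions are mass balanced and within bounds", {
  mod <- canonical_model()
  S <- stoichiometric_matrix(mod)
  for (light in c(TRUE, FALSE)) {
    m <- set_phase(mod, light)
    sol <- solve_fba(m, diel_objective(m, light))
    expect_identical(sol$status, "optimal")
    expect_lt(max(abs(S %*% sol$fluxes)), 1e-6)
    expect_true(all(sol$fluxes >= m$reactions$lower_bound - 1e-9))
    expect_true(all(sol$fluxes <= m$reactions$upper_bound + 1e-9))
  }
})

test_that("set_phase toggles only the CO2 uptake and is idempotent", {
  mod <- canonical_model()
  dark <- set_phase(mod, FALSE)
  i <- match("EX_CO2", mod$reactions$id)
  expect_identical(dark$reactions$upper_bound[i], 0)
  expect_identical(dark$reactions$upper_bound[-i],
                   mod$reactions$upper_bound[-i])
  expect_identical(attr(dark, "phase_objective")[["EX_CO2"]], 0)
  light2 <- set_phase(set_phase(mod, TRUE), TRUE)
  expect_identical(light2$reactions$upper_bound,
                   set_phase(mod, TRUE)$reactions$upper_bound)
  # dark forces zero CO2 flux in any optimal solution
  sol <- solve_fba(dark, diel_objective(dark, FALSE))
  expect_identical(unname(sol$fluxes["EX_CO2"]), 0)
  nox <- mod; nox$reactions <- mod$reactions[mod$reactions$id != "EX_CO2", ]
  expect_error(set_phase(nox, TRUE), "EX_CO2")
})

test_that("conflicting bounds yield infeasible status with empty fluxes", {
  mod <- canonical_model()
  i <- match("AGP", mod$reactions$id)
  mod$reactions$lower_bound[i] <- 5
  mod$reactions$upper_bound[i] <- 1
  sol <- solve_fba(mod, diel_objective(mod, TRUE))
  expect_identical(sol$status, "infeasible")
  expect_length(sol$fluxes, 0)
})

test_that("relaxing any single upper bound never decreases the optimum", {
  mod <- set_phase(canonical_model(), TRUE)
  w <- diel_objective(mod, TRUE)
  base <- solve_fba(mod, w, minimize_total_flux = FALSE)$objective_value
  set.seed(3)
  for (j in sample(nrow(mod$reactions), 8)) {
    m2 <- mod
    m2$reactions$upper_bound[j] <- m2$reactions$upper_bound[j] * 2
    z <- solve_fba(m2, w, minimize_total_flux = FALSE)$objective_value
    expect_gte(z + 1e-6 * max(1, abs(base)), base)
  }
})

test_that("scaling all objective weights leaves the flux pattern unchanged", {
  mod <- set_phase(canonical_model(), TRUE)
  w <- diel_objective(mod, TRUE)
  a <- solve_fba(mod, w)
  b <- solve_fba(mod, w * 7.5)
  expect_equal(a$fluxes, b$fluxes, tolerance = 1e-7)
  expect_equal(b$objective_value, 7.5 * a$objective_value, tolerance = 1e-7)
})

test_that("flux variability collapses to the optimum on a unique-vertex toy", {
  toy <- toy_chain_model(conv_ub = 5)
  mod <- list(metabolites = data.frame(id = c("A", "B")),
              reactions = data.frame(
                id = colnames(toy$S), name = colnames(toy$S), ec = "",
                lower_bound = toy$lb, upper_bound = toy$ub,
                default_lower = toy$lb, default_upper = toy$ub,
                reversible = FALSE, is_exchange = c(TRUE, FALSE, TRUE),
                stringsAsFactors = FALSE))
  mod$reactions$stoichiometry <- list(c(A = 1), c(A = -1, B = 1), c(B = -1))
  mod$reactions$gene_ids <- list(character(0), character(0), character(0))
  class(mod) <- "starch_model"
  res <- flux_variability(mod, objective = c(export = 1), fraction = 1)
  expect_equal(res$min_flux, rep(5, 3), tolerance = 1e-6)
  expect_equal(res$max_flux, rep(5, 3), tolerance = 1e-6)
  expect_error(flux_variability(mod, objective = c(export = 1), fraction = 0),
               "fraction")
})

test_that("parallel duplicate reactions get complementary variability ranges", {
  # A-uptake (ub 4) splits over two identical conversions, then export.
  S <- matrix(c(1, -1, -1, 0,
                0, 1, 1, -1), 2, 4, byrow = TRUE,
              dimnames = list(c("A", "B"), c("up", "c1", "c2", "ex")))
  mod <- list(metabolites = data.frame(id = c("A", "B")),
              reactions = data.frame(
                id = colnames(S), name = colnames(S), ec = "",
                lower_bound = 0, upper_bound = c(4, 10, 10, 10),
                default_lower = 0, default_upper = c(4, 10, 10, 10),
                reversible = FALSE, is_exchange = c(TRUE, FALSE, FALSE, TRUE),
                stringsAsFactors = FALSE))
  mod$reactions$stoichiometry <-
    list(c(A = 1), c(A = -1, B = 1), c(A = -1, B = 1), c(B = -1))
  mod$reactions$gene_ids <- rep(list(character(0)), 4)
  class(mod) <- "starch_model"
  res <- flux_variability(mod, objective = c(ex = 1), fraction = 1)
  # each duplicate can carry anything from 0 to the whole bottleneck
  expect_equal(res$min_flux[res$reaction %in% c("c1", "c2")], c(0, 0),
               tolerance = 1e-6)
  expect_equal(res$max_flux[res$reaction %in% c("c1", "c2")], c(4, 4),
               tolerance = 1e-6)
  # hand-enumerated: their sum is pinned to the bottleneck
  expect_equal(res$min_flux[res$reaction == "ex"], 4, tolerance = 1e-6)
})

test_that("robustness scan is monotone and saturates at the next constraint", {
  mod <- set_phase(canonical_model(), TRUE)
  grid <- seq(0, 1500, length.out = 6)
  res <- robustness_scan(mod, reaction_id = "AGP", grid = grid)
  expect_true(all(diff(res$objective_value) >= -1e-6))
  # scanning an unused reaction leaves the optimum constant
  res2 <- robustness_scan(mod, reaction_id = "SPHO_60LG",
                          grid = c(0, 5, 10))
  expect_lt(diff(range(res2$objective_value)), 1e-5 * res2$objective_value[1])
  # zero bound on the starch exchange forces zero starch flux
  res3 <- robustness_scan(mod, reaction_id = "EX_STARCH", grid = 0)
  expect_equal(res3$starch_flux, 0, tolerance = 1e-9)
  expect_error(robustness_scan(mod, reaction_id = "AGP", grid = -1), ">= 0")
})
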