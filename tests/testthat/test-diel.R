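# Quasi-steady-state diel chaining, cumulation and calibration.

test_that("saturated simulation gives the On-Off step: positive light, negative dark", {
  mod <- canonical_model()
  # all activity multipliers = 1 means default bounds in both phases
  for (t in seq(0, 21, 3)) {
    light <- t < 12
    s <- saturated_phase_flux(mod, light)
    if (light) expect_gt(s, 0) else expect_lt(s, 0)
  }
})

test_that("cumulation follows the rectangular rule and is linear", {
  traj <- structure(list(
    times_h = c(0, 3, 6), light = c(TRUE, TRUE, FALSE),
    status = rep("optimal", 3), starch_flux = c(1, 1, -1),
    schedule = diel_schedule(c(0, 3, 6))), class = "diel_trajectory")
  st <- cumulate_starch(traj, S0 = 0)
  expect_equal(st$content, c(3, 6, 3))
  # all-zero fluxes give a constant S0
  traj$starch_flux <- c(0, 0, 0)
  expect_equal(cumulate_starch(traj, S0 = 2)$content, rep(2, 3))
  # additive in S0, linear in the fluxes
  traj$starch_flux <- c(2, 2, -2)
  expect_equal(cumulate_starch(traj, S0 = 1)$content, 1 + 2 * c(3, 6, 3))
  # infeasible points contribute zero flux
  traj$starch_flux <- c(1, NA, 1); traj$status <- c("optimal", "infeasible", "optimal")
  st2 <- cumulate_starch(traj, S0 = 0)
  expect_equal(st2$content, c(3, 3, 6))
  expect_identical(st2$flagged_infeasible, 3)
})

test_that("default S0 keeps the content non-negative", {
  nm <- fixture_norm()
  st <- cumulate_starch(simulate_cycle(canonical_model(), nm))
  expect_gte(min(st$content), 0)
})

test_that("time points are independent steady states (no hidden coupling)", {
  mod <- canonical_model()
  nm <- fixture_norm()
  full <- simulate_cycle(mod, nm)
  # re-simulating an arbitrary subset of time points reproduces the entries
  sub <- simulate_cycle(mod, nm, diel_schedule(c(6, 15), dt_h = 3))
  expect_equal(sub$starch_flux[["ZT6"]], full$starch_flux[["ZT6"]])
  expect_equal(sub$starch_flux[["ZT15"]], full$starch_flux[["ZT15"]])
  expect_error(simulate_cycle(mod, nm, diel_schedule(c(0, 5))), "5")
})

test_that("multi-day simulation tiles the daily cycle and carries content", {
  mod <- canonical_model()
  nm <- fixture_norm()
  one <- cumulate_starch(simulate_cycle(mod, nm), S0 = 10)
  days <- simulate_days(mod, nm, n_days = 3, S0 = 10)
  expect_identical(length(days$content), 3L * length(one$content))
  expect_equal(days$content[seq_along(one$content)], one$content)
  drift <- days$content[16] - days$content[8]
  expect_equal(days$content[24] - days$content[16], drift, tolerance = 1e-9)
  expect_error(simulate_days(mod, nm, n_days = 0), "n_days")
})

test_that("a saturated symmetric step gives a flat multi-day baseline", {
  # the saturated daily fluxes cancel exactly (symmetric +/- step), so the
  # content at the end of every day returns to its start
  mod <- canonical_model()
  step <- vapply(seq(0, 21, 3), function(t)
    saturated_phase_flux(mod, t < 12), numeric(1))
  expect_lt(abs(sum(step)), 1e-5)
})

test_that("shipped export bounds are the optimum of the +/-1 step calibration", {
  mod <- canonical_model()
  cal <- calibrate_export_bounds(
    mod,
    maltose_grid = c(0, 83.25, 166.5, 249.75, 333),
    glucose_grid = c(0, 61.225, 122.45, 183.675))
  expect_identical(cal$maltose_ub, 166.5)
  expect_identical(cal$glucose_ub, 122.45)
  g <- cal$grid
  here <- g$maltose_ub == 166.5 & g$glucose_ub == 122.45
  expect_true(all(g$residual[here] <= g$residual + 1e-9))
  # returned bounds sit below the stoichiometric export capacities
  # (370 maltose, 740 glucose per unit starch flux)
  expect_lt(cal$maltose_ub, 370)
  expect_lt(cal$glucose_ub, 740)
  expect_error(calibrate_export_bounds(mod, maltose_grid = numeric(0)),
               "empty")
})
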