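# Expression ingestion, min-max scaling and the E-flux bound multipliers.

test_that("expression TSV round-trips and rejects malformed tables", {
  vals <- matrix(c(2, 4, 6, 5, 5, 5), nrow = 2, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), NULL))
  es <- expression_series(vals, c(0, 3, 6))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(es, path)
  back <- read_expression_table(path)
  expect_equal(back$values, es$values)
  expect_identical(back$time_points_h, c(0, 3, 6))

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tZT0\tZT3", "g1\t1\t2", "g1\t3\t4"), dup)
  expect_error(read_expression_table(dup), "duplicate")
  neg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tZT0\tZT3", "g1\t1\t-2"), neg)
  expect_error(read_expression_table(neg), "negative")
  mis <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tZT0\tZT3", "g1\t1\t", "g2\t1\t2"), mis)
  expect_error(read_expression_table(mis), "g1")
})

test_that("min-max scaling matches the closed form and handles constants", {
  es <- expression_series(
    matrix(c(2, 4, 6, 5, 5, 5), 2, byrow = TRUE,
           dimnames = list(c("g1", "g2"), NULL)), c(0, 3, 6))
  nm <- normalize_expression(es)
  expect_equal(unname(nm$values["g1", ]), c(0, 0.5, 1))
  expect_equal(unname(nm$values["g2", ]), c(1, 1, 1))   # constitutive
  # idempotent on already-normalized profiles
  nm2 <- normalize_expression(nm)
  expect_equal(nm2$values, nm$values)
  # max-scaling variant
  mx <- normalize_expression(es, method = "max")
  expect_equal(unname(mx$values["g1", ]), c(2, 4, 6) / 6)
})

test_that("reaction multipliers sum isozymes, floor missing genes, honor overrides", {
  mod <- canonical_model()
  vals <- matrix(c(0.3, 0.6, 0.4, 0.8), 2, byrow = TRUE,
                 dimnames = list(c("Ot03g00330", "Ot14g01140"), NULL))
  nm <- normalize_expression(expression_series(vals, c(0, 3)), "max")
  mult <- reaction_activity(nm, mod, t_index = 1L)
  # FBPase has exactly these two genes: additive rule
  expect_equal(unname(mult["FBPASE"]), 0.3 / 0.6 + 0.4 / 0.8)
  # three-gene reaction with none measured: 3 x 0.01
  expect_equal(unname(mult["AGP"]), 0.03)
  # reactions without genes (and non-transporter exchanges) stay at 1
  expect_identical(unname(mult[c("CBC", "PPA", "EX_CO2", "EX_STARCH")]),
                   rep(1, 4))
  # overrides replace a gene's contribution
  m2 <- reaction_activity(nm, mod, 1L, overrides = c(Ot03g00330 = 0.01))
  expect_equal(unname(m2["FBPASE"]), 0.01 + 0.5)
  expect_error(reaction_activity(nm, mod, 1L, overrides = c(NOPE = 1)),
               "unknown gene")
  expect_error(reaction_activity(nm, mod, 1L, overrides = c(Ot03g00330 = -1)),
               ">= 0")
  expect_error(reaction_activity(nm, mod, 99L), "t_index")
})

test_that("raising a gene value never lowers any multiplier (monotonicity)", {
  mod <- canonical_model()
  nm <- fixture_norm()
  base <- reaction_activity(nm, mod, 3L)
  for (g in c("Ot07g02930", "Ot03g03190", "Ot09g03160")) {
    up <- reaction_activity(nm, mod, 3L,
                            overrides = stats::setNames(2, g))
    expect_true(all(up >= base - 1e-12))
  }
})

test_that("apply_activity scales bounds from the current model symmetrically", {
  mod <- canonical_model()
  ones <- stats::setNames(rep(1, nrow(mod$reactions)), mod$reactions$id)
  expect_identical(apply_activity(mod, ones)$reactions$upper_bound,
                   mod$reactions$upper_bound)
  half <- ones; half["PGM"] <- 0.5; half["AGP"] <- 0; half["ALD"] <- 2
  m2 <- apply_activity(mod, half)
  i <- match(c("PGM", "AGP", "ALD"), mod$reactions$id)
  expect_equal(m2$reactions$upper_bound[i],
               mod$reactions$upper_bound[i] * c(0.5, 0, 2))
  # PGM is reversible: lower bound scales symmetrically
  expect_equal(m2$reactions$lower_bound[i[1]],
               mod$reactions$lower_bound[i[1]] * 0.5)
  # irreversible lower bounds stay put; original model untouched
  expect_identical(m2$reactions$lower_bound[i[2]], 0)
  expect_identical(mod$reactions$upper_bound[i[2]],
                   canonical_model()$reactions$upper_bound[i[2]])
  expect_error(apply_activity(mod, c(PGM = -0.2)), "negative")
})
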