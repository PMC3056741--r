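# Single-gene impact and deletion scans on the noise-free fixture.
# The deletion phenotypes are contrasts of the rhythmic expression pattern
# itself, so they are asserted on the deterministic (noise-free) fixture.

amp <- function(tr) diff(range(tr$starch_flux, na.rm = TRUE))

# reference for the impact scans: every gene pinned at maximum level (1.0)
all_max_trajectory <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      mod <- canonical_model()
      ov <- stats::setNames(rep(1, nrow(mod$gene_table)), mod$gene_table$orf)
      val <<- simulate_cycle(mod, fixture_norm(), overrides = ov)
    }
    val
  }
})

test_that("no-op perturbations reproduce the reference trajectories", {
  mod <- canonical_model()
  nm <- fixture_norm()
  # impact of a constitutively saturated gene = the all-genes-at-maximum run
  flat <- normalize_expression(expression_series(
    matrix(1, 1, 9, dimnames = list("Ot15g02630", NULL)), seq(0, 24, 3)))
  imp <- single_gene_impact(mod, flat, gene_id = "Ot15g02630")
  expect_equal(imp$starch_flux, all_max_trajectory()$starch_flux,
               tolerance = 1e-6)
  # deleting a floor-imputed gene is the identical override
  base <- simulate_cycle(mod, nm)
  del <- gene_deletion(mod, nm, gene_id = "Ot11g02290")
  expect_equal(del$starch_flux, base$starch_flux, tolerance = 1e-9)
  expect_error(gene_deletion(mod, nm, gene_id = "BOGUS"), "valid ids")
})

test_that("MEX1 deletion caps maltose export at 1% of its bound", {
  tr <- gene_deletion(canonical_model(), fixture_norm(),
                      gene_id = "Ot09g03160")
  expect_true(all(tr$maltose_flux <= 0.01 * 166.5 + 1e-9))
  # and starch production increases while degradation nearly vanishes
  base <- simulate_cycle(canonical_model(), fixture_norm())
  expect_gt(max(tr$starch_flux), max(base$starch_flux))
})

test_that("AGPase small-subunit deletion removes the oscillation", {
  mod <- canonical_model()
  nm <- fixture_norm()
  base <- simulate_cycle(mod, nm)
  del <- gene_deletion(mod, nm, gene_id = "Ot07g02930")
  expect_lt(amp(del), 0.1 * amp(base))
  # deleting an unexpressed large subunit leaves the pattern intact
  del2 <- gene_deletion(mod, nm, gene_id = "Ot07g03280")
  expect_equal(del2$starch_flux, base$starch_flux, tolerance = 1e-9)
})

test_that("aldolase fbaII deletion blocks light-phase starch synthesis", {
  mod <- canonical_model()
  nm <- fixture_norm()
  base <- simulate_cycle(mod, nm)
  del <- gene_deletion(mod, nm, gene_id = "Ot10g01490")
  light <- base$light
  expect_lte(max(pmax(del$starch_flux[light], 0)),
             0.01 * max(base$starch_flux[light]))
})

test_that("phosphoglucomutase deletion shifts starch flux toward degradation", {
  mod <- canonical_model()
  nm <- fixture_norm()
  base <- simulate_cycle(mod, nm)
  del <- gene_deletion(mod, nm, gene_id = "Ot15g02630")
  expect_lt(max(del$starch_flux), 0.01 * max(base$starch_flux))
  expect_lt(mean(del$starch_flux), mean(base$starch_flux))
})

test_that("impact scan: solely-owned rhythms reshape their phase of the pattern", {
  # Under the maximum-level baseline a gene's rhythm only binds where no
  # sister isozyme covers its reactions: GBSSI (sole granule amylose
  # route) reshapes the light phase, MEX1 (sole maltose exporter) the dark.
  mod <- canonical_model()
  nm <- fixture_norm()
  ref <- all_max_trajectory()$starch_flux
  light <- seq(0, 21, 3) < 12
  gbss <- single_gene_impact(mod, nm, gene_id = "Ot06g03200")
  expect_gt(max(abs(gbss$starch_flux[light] - ref[light])), 0.05)
  expect_lt(max(abs(gbss$starch_flux[!light] - ref[!light])), 1e-6)
  mex <- single_gene_impact(mod, nm, gene_id = "Ot09g03160")
  expect_gt(max(abs(mex$starch_flux[!light] - ref[!light])), 0.05)
})

test_that("deletion scan assembles gene x time matrices and records errors", {
  mod <- canonical_model()
  nm <- fixture_norm()
  genes <- c("Ot09g03160", "Ot07g02930", "Ot11g02290")
  scan <- deletion_scan(mod, nm, genes = genes)
  expect_identical(dim(scan$starch), c(3L, 8L))
  expect_identical(dim(scan$maltose), c(3L, 8L))
  expect_identical(rownames(scan$starch), genes)
  df <- as.data.frame(scan)
  expect_identical(nrow(df), 24L)
  empty <- deletion_scan(mod, nm, genes = character(0))
  expect_identical(dim(empty$starch), c(0L, 8L))
})

test_that("deletion replaces exactly the gene's contribution in the sum", {
  mod <- canonical_model()
  nm <- fixture_norm()
  for (g in c("Ot07g02930", "Ot03g03190")) {
    hit <- vapply(mod$reactions$gene_ids, function(gs) g %in% gs, logical(1))
    for (k in c(2L, 5L)) {
      v <- nm$values[g, k]
      base <- reaction_activity(nm, mod, k)
      del <- reaction_activity(nm, mod, k, overrides = stats::setNames(0.01, g))
      expect_equal(del[hit], base[hit] - v + 0.01, tolerance = 1e-12)
      expect_identical(del[!hit], base[!hit])
      # monotone harm whenever the profile sits at or above the floor
      if (v >= 0.01) expect_true(all(del[hit] <= base[hit] + 1e-12))
    }
  }
})

test_that("pattern-flattening genes sit on topological cut reactions", {
  mod <- canonical_model()
  nm <- fixture_norm()
  base <- simulate_cycle(mod, nm)
  candidates <- c("Ot07g02930", "Ot06g03200", "Ot15g02630", "Ot09g03160",
                  "Ot13g01510", "Ot03g03190", "Ot10g01490")
  flattening <- character(0)
  for (g in candidates) {
    if (amp(gene_deletion(mod, nm, gene_id = g)) < 0.1 * amp(base))
      flattening <- c(flattening, g)
  }
  blocking <- starch_blocking_genes(mod)
  expect_true(length(flattening) >= 1)
  expect_true(all(flattening %in% blocking))
})
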