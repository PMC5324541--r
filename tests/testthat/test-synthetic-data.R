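test_that("the synthetic tree matches the roster, is ultrametric, and pairs crops with their progenitors", {
  tree <- defaultTree()
  roster <- speciesRoster()
  expect_identical(ape::Ntip(tree), 17L)
  expect_setequal(tree$tip.label, roster$species)
  depths <- ape::node.depth.edgelength(tree)[1:17]
  expect_lt(diff(range(depths)), 1e-9)
  expect_equal(max(depths), 1)
  D <- ape::cophenetic.phylo(tree)
  for (p in unique(roster$pair)) {
    crop <- roster$species[roster$pair == p & roster$status == "crop"]
    prog <- roster$species[roster$pair == p & roster$status == "progenitor"]
    others <- setdiff(roster$species, c(crop, prog))
    expect_lt(max(D[crop, prog]), min(D[crop, others]))
  }
})

test_that("datasets are exactly reproducible from the seed and differ across seeds", {
  a <- simulateTraitTable(simConfig(seed = 42))
  b <- simulateTraitTable(simConfig(seed = 42))
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  d <- simulateTraitTable(simConfig(seed = 43))
  expect_false(isTRUE(all.equal(a$records$mass_grain, d$records$mass_grain)))
  g1 <- simulateGrowthSeries(simConfig(seed = 42))
  g2 <- simulateGrowthSeries(simConfig(seed = 42))
  expect_identical(g1$series, g2$series)
})

test_that("the replicate structure follows the two-experiment block design", {
  sim <- simulateTraitTable(simConfig(seed = 2))
  counts <- table(sim$records$species)
  roster <- speciesRoster()
  exp1_only <- roster$species[roster$pair %in% c("avena", "secale")]
  expect_true(all(counts[exp1_only] == 20))
  expect_true(all(counts[setdiff(roster$species, exp1_only)] == 30))
  expect_false(any(sim$records$experiment == 2 &
                     sim$records$species %in% exp1_only))
  expect_true(all(sim$records$block[sim$records$experiment == 1] %in% 1:20))
  expect_true(all(sim$records$block[sim$records$experiment == 2] %in% 21:30))
  # replicates divided approximately equally between accessions
  acc <- table(sim$records$accession[sim$records$species == "Hordeum_vulgare"])
  expect_identical(length(acc), 3L)
  expect_lte(max(acc) - min(acc), 1)
})

test_that("the truth record reconstructs every noiseless trait exactly", {
  sim <- simulateTraitTable(simConfig(seed = 6, noiseless = TRUE))
  tr <- sim$truth
  rec <- as.data.frame(sim$records)
  i <- match(rec$species, tr$species)
  expect_equal(rec$seed_mass_sown, tr$seed_mass_mg[i], tolerance = 1e-12)
  expect_equal(rec$biomass_total, tr$biomass[i], tolerance = 1e-12)
  expect_equal(rec$mass_grain,
               tr$biomass[i] * tr$ar[i] * (1 - tr$chaff[i]), tolerance = 1e-12)
  expect_equal(rec$duration_days, tr$duration[i], tolerance = 1e-12)
  # planted multipliers are exact at species level in noiseless mode
  m <- attr(tr, "multipliers")
  for (p in c("hordeum", "cicer")) {
    crop <- tr[tr$pair == p & tr$status == "crop", ]
    prog <- tr[tr$pair == p & tr$status == "progenitor", ][1, ]
    expect_equal(crop$seed_mass_mg / prog$seed_mass_mg, m$seed_mass)
    expect_equal(crop$biomass / prog$biomass, m$biomass)
    expect_equal(crop$chaff / prog$chaff, m$chaff)
  }
})

test_that("pulses carry no per-infructescence counts and cereals satisfy the packaging identity", {
  sim <- simulateTraitTable(simConfig(seed = 14))
  rec <- as.data.frame(sim$records)
  pulses <- rec[rec$family == "legume", ]
  expect_true(all(is.na(pulses$n_seeds_per_infructescence)))
  expect_true(all(is.na(pulses$n_infructescences)))
  cereals <- rec[rec$family == "grass", ]
  expect_equal(cereals$n_seeds_total,
               cereals$n_seeds_per_infructescence * cereals$n_infructescences,
               tolerance = 1e-12)
})

test_that("configurations that push proportions out of range are rejected up front", {
  expect_error(simConfig(multipliers = list(chaff = 3)), "\\(0, 1\\)")
  expect_error(simConfig(multipliers = list(chaff = -0.5)), "positive")
  expect_error(simConfig(baselines = list(grass = list(
    seed_mass_mg = 10, biomass = 20, ar = 0.9, chaff = 0.39,
    duration = 100, ns = 20, height = 100), legume = NULL),
    multipliers = list(ar = 1.5)), "allocation")
  expect_error(simConfig(growth = list(days = c(5, 12, 16, 20, 24, 28))),
               "day 8")
})

test_that("growth series follow the six-harvest design within days 8-28", {
  g <- simulateGrowthSeries(simConfig(seed = 4))
  expect_true(all(g$series$day >= 8 & g$series$day <= 28))
  per_species <- table(g$series$species)
  expect_true(all(per_species == 12))  # 6 harvests x 2 plants
  expect_identical(length(unique(g$series$day)), 6L)
  expect_true(all(g$series$block %in% 1:6))
  expect_true(all(g$series$mass > 0))
  # no planted status effect on growth parameters
  expect_identical(ncol(g$truth), 7L)
})

test_that("attenuated secondary domesticates shrink oat and rye effects only", {
  cfg <- simConfig(seed = 30, noiseless = TRUE, attenuate_secondary = TRUE)
  tr <- simulateTraitTable(cfg)$truth
  att <- tr[tr$pair == "avena", ]
  full <- tr[tr$pair == "hordeum", ]
  ratio_att <- att$seed_mass_mg[att$status == "crop"] /
    att$seed_mass_mg[att$status == "progenitor"]
  ratio_full <- full$seed_mass_mg[full$status == "crop"] /
    full$seed_mass_mg[full$status == "progenitor"]
  expect_equal(ratio_full, 1.9)
  expect_equal(ratio_att, 1.9^0.25, tolerance = 1e-12)
})

test_that("implied effects are consistent with the planted component multipliers", {
  cfg <- simConfig()
  ie <- impliedEffects(cfg)
  expect_equal(unname(ie["chaff_reduction_pct"]), 38)
  expect_equal(unname(ie["yield"]),
               1.4 * (1 - 0.39 * 0.62) / (1 - 0.39), tolerance = 1e-12)
  expect_equal(unname(ie["n_total"]), unname(ie["yield"]) / 1.9)
})
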