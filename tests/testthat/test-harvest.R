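test_that("capture scaling: factors applied, fallbacks, aquaculture untouched", {
  prod <- micro_production()
  fac <- data.table::data.table(
    country = c("X", "X", "Y"),
    year = c(2000L, 2000L, 1999L)[c(1, 3, 1)],  # X@2000, X@1999? see below
    factor = 1)
  # explicit table: X has 2000, Y only 1999
  fac <- data.table::data.table(country = c("X", "Y"),
                                year = c(2000L, 1999L),
                                factor = c(1.29, 1.10))
  out <- scale_wild_production(prod, fac)
  # capture row for X in 2000: exact factor 1.29
  expect_equal(out[country == "X" & source == "capture", weight], 10 * 1.29)
  # aquaculture rows never scaled
  expect_equal(out[source == "aquaculture", weight],
               prod[source == "aquaculture", weight])
  # Y has no factor for 2000 and 2000 is the global last year -> year mean
  expect_equal(out[country == "Y" & source == "capture", weight], 2 * 1.29)

  # beyond the last factor year each country reuses its last factor
  prod16 <- data.table::copy(prod); prod16$year <- 2016L
  out16 <- scale_wild_production(prod16, fac)
  expect_equal(out16[country == "X" & source == "capture", weight], 10 * 1.29)
  expect_equal(out16[country == "Y" & source == "capture", weight], 2 * 1.10)

  # all-ones factor table is the identity
  fac1 <- data.table::CJ(country = c("X", "Y"), year = 2000L)[, factor := 1]
  expect_equal(scale_wild_production(prod, fac1)$weight, prod$weight)

  # marine_only restricts scaling to marine capture
  outm <- scale_wild_production(prod, fac, marine_only = TRUE)
  expect_equal(outm[environment == "freshwater", weight],
               prod[environment == "freshwater", weight])
})

test_that("fallback chain selects the documented pool at each level", {
  conc <- micro_conc()
  # sA: 3 records > cutoff 1 -> species level
  pA <- resolve_pool("sA", conc)
  expect_equal(pA$level, "species")
  expect_false(pA$rescaled)
  expect_equal(pA$mean, mean(c(0.004, 0.006, 0.005)))
  expect_equal(sort(pA$members[[1]]), c(0.004, 0.005, 0.006))

  # sB: exactly 1 record -> order level, CV-rescaled around the species mean
  pB <- resolve_pool("sB", conc)
  expect_equal(pB$level, "order")
  expect_true(pB$rescaled)
  expect_equal(pB$mean, 0.004)
  ord <- conc[conc$order == "o1", value]
  expect_equal(pB$sd, 0.004 * sd(ord) / mean(ord))

  # hand-checked rescaling: single record 0.004, order CV 0.25 -> sd 0.001
  conc2 <- data.table::data.table(
    species = c("thin", "a", "a", "a"), order = "o1", group = "finfish",
    value = c(0.004, 0.006, 0.008, 0.010), basis = "wet",
    moisture = NA_real_, origin = "wild")
  cv <- sd(c(0.004, 0.006, 0.008, 0.010)) / mean(c(0.004, 0.006, 0.008, 0.010))
  pT <- resolve_pool("thin", conc2)
  expect_equal(pT$sd, 0.004 * cv)

  # species absent from the db -> group pool (e.g. cartilaginous finfish)
  pX <- resolve_pool("shark01", conc, order = "oX", group = "finfish")
  expect_equal(pX$level, "group")
  expect_equal(pX$mean, mean(conc$value[conc$group == "finfish"]))

  # other aquatic invertebrates -> whole-database mean
  pI <- resolve_pool("urchin01", conc, order = NA, group = "other_invertebrate")
  expect_equal(pI$level, "database")
  expect_equal(pI$mean, mean(conc$value))

  expect_error(resolve_pools(micro_production(), conc[0]), "empty")
})

test_that("fallback chain is total on generated worlds", {
  for (seed in c(1L, 12L)) {
    d <- tiny_world(seed = seed, thin_rate = 0.5)
    rows <- filter_budget_groups(d$production)
    pools <- resolve_pools(rows, d$concentration)
    expect_setequal(pools$species, unique(rows$species))
    expect_true(all(pools$level %in%
                      c("species", "order", "group", "database")))
    expect_true(all(pools$mean > 0))
    expect_true(all(pools$sd >= 0))
  }
})

test_that("P-harvest equals the brute-force sum and is additive", {
  conc <- micro_conc(); prod <- micro_production()
  pools <- resolve_pools(prod, conc)
  rec <- compute_p_harvest(prod, pools)
  # independent oracle: explicit loop over rows
  oracle <- 0
  for (i in seq_len(nrow(prod))) {
    m <- pools$mean[match(prod$species[i], pools$species)]
    oracle <- oracle + prod$weight[i] * m
  }
  expect_equal(sum(rec$p_harvest_tg), oracle, tolerance = 1e-15)

  # unit multiplication: W = 1 Tg, R = 0.005 -> 0.005 Tg P
  one <- data.table::data.table(year = 2000L, country = "X", species = "sA",
                                order = "o1", group = "finfish",
                                environment = "marine", source = "capture",
                                weight = 1)
  pool1 <- data.table::data.table(species = "sA", mean = 0.005)
  expect_equal(compute_p_harvest(one, pool1)$p_harvest_tg, 0.005)

  # additivity: global = sum over countries = sum over groups
  expect_equal(sum(rec$p_harvest_tg),
               sum(rec[, .(s = sum(p_harvest_tg)), by = country]$s))
  expect_equal(sum(rec$p_harvest_tg),
               sum(rec[, .(s = sum(p_harvest_tg)), by = group]$s))

  # monotonicity in weights and pool means
  up <- data.table::copy(prod); up$weight[1] <- up$weight[1] * 1.01
  expect_gt(sum(compute_p_harvest(up, pools)$p_harvest_tg),
            sum(rec$p_harvest_tg))

  # empty production -> zero rows
  expect_equal(nrow(compute_p_harvest(prod[0], pools)), 0L)

  # unresolved species is an error naming it
  expect_error(compute_p_harvest(prod, pools[species != "sD"]), "sD")
})

test_that("plants and mammals never enter the budget", {
  d <- tiny_world()
  pb <- point_budget(d$production, d$concentration, d$pue, d$scaling)
  expect_false(any(pb$records$group %in% c("aquatic_plant", "mammal")))
})
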