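test_that("taxonomy generation: counts, coverage, determinism", {
  tax <- generate_taxonomy(tiny_config())
  expect_equal(nrow(tax), 30L)
  expect_equal(length(unique(tax$order)), 8L)
  expect_setequal(unique(tax$group), c("finfish", "crustacean", "mollusk"))
  # every order nonempty and in exactly one group
  expect_true(all(table(tax$order) >= 1))
  expect_equal(nrow(unique(tax[, .(order, group)])),
               length(unique(tax$order)))

  # compilation-scale taxonomy
  big <- generate_taxonomy(synth_config(n_species = 224L, n_orders = 40L))
  expect_equal(nrow(big), 224L)
  expect_equal(length(unique(big$order)), 40L)

  expect_identical(generate_taxonomy(tiny_config()),
                   generate_taxonomy(tiny_config()))
  expect_error(synth_config(n_species = 5L, n_orders = 10L), "n_orders")
})

test_that("whole run is byte-identical under a fixed seed", {
  d1 <- tiny_world(seed = 77L)
  d2 <- tiny_world(seed = 77L)
  for (nm in c("taxonomy", "production", "concentration", "pue", "pre",
               "scaling"))
    expect_identical(d1[[nm]], d2[[nm]], label = nm)
  # byte-for-byte after serialization
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_table(d1$production, f1); write_table(d2$production, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_false(identical(d1$production, tiny_world(seed = 78L)$production))
})

test_that("concentration db: zero-variance limit and dry-basis flags", {
  cfg <- tiny_config(order_cv = 0, species_cv = 0, thin_rate = 0,
                     dry_frac = 0)
  tax <- generate_taxonomy(cfg)
  db <- generate_concentration_db(tax, cfg)
  expect_equal(db$value, unname(cfg$group_mean_conc[db$group]),
               tolerance = 1e-12)

  cfg2 <- tiny_config(dry_frac = 0.5, moisture_missing_rate = 0)
  db2 <- generate_concentration_db(generate_taxonomy(cfg2), cfg2)
  dry <- db2[basis == "dry"]
  expect_gt(nrow(dry), 0)
  expect_true(all(dry$moisture > 0 & dry$moisture < 1))
  # latent truth is emitted for every species with records
  expect_true(all(db2$species %in% attr(db2, "truth")$species))
})

test_that("concentration db: sample mean recovers the group mean (LLN)", {
  cfg <- synth_config(n_species = 300L, n_orders = 100L,
                      group_mean_conc = c(finfish = 0.006,
                                          crustacean = 0.004,
                                          mollusk = 0.002),
                      order_cv = 0.1, species_cv = 0.1, thin_rate = 0,
                      dry_frac = 0, records_lambda = 4, seed = 11L)
  db <- generate_concentration_db(generate_taxonomy(cfg), cfg)
  ff <- db[group == "finfish"]
  expect_gt(nrow(ff), 1000)
  # records cluster within orders; use order-level means for the SE
  om <- ff[, .(m = mean(value)), by = order]
  se <- stats::sd(om$m) / sqrt(nrow(om))
  expect_lt(abs(mean(om$m) - 0.006), 3 * se)
})

test_that("thin species exercise the 0- and 1-record branches", {
  cfg <- tiny_config(thin_rate = 0.5, seed = 3L)
  tax <- generate_taxonomy(cfg)
  db <- generate_concentration_db(tax, cfg)
  n_rec <- table(factor(db$species, levels = tax$species))
  expect_true(any(n_rec == 0))
  expect_true(any(n_rec == 1))
  expect_true(any(n_rec > 1))
})

test_that("production: trajectory shape, environments, excluded groups", {
  d <- tiny_world()
  prod <- filter_budget_groups(d$production)
  tot <- prod[, .(w = sum(weight)), keyby = .(year, source)]
  expect_true(all(prod$weight >= 0))
  expect_setequal(unique(prod$environment), c("freshwater", "marine"))
  expect_setequal(unique(d$production$group)[
    unique(d$production$group) %in% c("aquatic_plant", "mammal")],
    c("aquatic_plant", "mammal"))

  # aquaculture grows geometrically after takeoff (1980 default < range here)
  aq <- tot[source == "aquaculture"]
  expect_true(all(diff(aq$w) > 0))

  # single pre-takeoff year: aquaculture share below 5%
  cfg <- tiny_config(year_range = c(1950L, 1950L))
  p50 <- filter_budget_groups(generate_production(generate_taxonomy(cfg), cfg))
  sh <- p50[, sum(weight[source == "aquaculture"]) / sum(weight)]
  expect_lt(sh, 0.05)

  # subset monotonicity
  one <- prod[country == prod$country[1], sum(weight)]
  expect_lte(one, prod[, sum(weight)])
})

test_that("production: default world grows ~8x from 1950 to 2016", {
  cfg <- synth_config(seed = 2L)
  prod <- filter_budget_groups(generate_production(generate_taxonomy(cfg), cfg))
  tot <- prod[, .(w = sum(weight)), keyby = year]
  ratio <- tot[year == 2016, w] / tot[year == 1950, w]
  expect_lt(abs(ratio - 8) / 8, 0.2)
  # wild capture plateaus: last decade's growth is small
  wild <- prod[source == "capture", .(w = sum(weight)), keyby = year]
  late_growth <- wild[year == 2016, w] / wild[year == 2006, w]
  expect_lt(late_growth, 1.1)
})

test_that("PUE generator: bounds, skew, finfish above crustaceans", {
  for (seed in c(1L, 2L, 3L)) {
    cfg <- synth_config(pue_n = 200L, seed = seed)
    pue <- generate_pue_db(cfg)
    expect_true(all(pue$value >= 0.01 & pue$value <= 1.67))
    ff <- pue[grepl("finfish", group6), value]
    cr <- pue[grepl("crustacean", group6), value]
    expect_gt(median(ff), median(cr))
    expect_lt(stats::wilcox.test(ff, cr, alternative = "greater")$p.value,
              0.01)
    expect_gt(mean(ff), median(ff))   # right skew
  }
  # no data for freshwater mollusks by default
  expect_false("freshwater_mollusk" %in% generate_pue_db(synth_config())$group6)
  # degenerate spread collapses to the medians
  d0 <- generate_pue_db(synth_config(pue_sigma = 0, pue_n = 5L))
  med <- synth_config()$pue_median
  expect_equal(d0$value, unname(med[d0$group6]), tolerance = 1e-12)
})

test_that("PRE generator: bounds and finfish > crustacean", {
  pre <- generate_pre_db(synth_config())
  expect_true(all(pre$value > 0 & pre$value <= 1))
  expect_gt(median(pre[group == "finfish", value]),
            median(pre[group == "crustacean", value]))
})

test_that("scaling factors: endpoints, monotone yearly means, 2014 cutoff", {
  cfg <- synth_config(seed = 9L)
  fac <- generate_scaling_factors(config = cfg)
  ym <- fac[, .(m = mean(factor)), keyby = year]
  expect_equal(ym[year == 1950, m], 1.29, tolerance = 1e-9)
  expect_equal(ym[year == 2004, m], 1.06, tolerance = 1e-9)
  expect_true(all(diff(ym$m) <= 1e-12))           # non-increasing
  expect_true(all(fac$factor >= 1))
  expect_equal(max(fac$year), 2014L)              # nothing after last year
  # linear interpolation between the anchors
  expect_equal(ym[year == 1977, m], (1.29 + 1.06) / 2, tolerance = 1e-9)
})
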