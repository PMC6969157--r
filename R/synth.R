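# Seeded generators for the five input tables. The defaults state a world
# shaped like the global fishery record: wild capture growing from ~20 Tg in
# 1950 to a plateau near 92 Tg, aquaculture taking off around 1980 and
# reaching ~75 Tg by 2016, whole-body P concentrations varying by species
# within orders within three major groups, right-skewed PUE with finfish
# above crustaceans, and catch-reconstruction scaling factors declining from
# 1.29 (1950) to 1.06 (2004). Latent species concentrations are emitted as
# ground truth so parameter-recovery tests need no external data.

#' Configuration for the synthetic-data generators
#'
#' Returns the default generator configuration, optionally overridden. Every
#' generator is deterministic given the config (including `seed`): each table
#' uses its own derived seed (`seed + fixed offset`) so stages can be
#' regenerated independently.
#'
#' @param ... Named overrides of the defaults.
#' @return A list of class `synth_config`.
#'
#' @section Fields:
#' \describe{
#'   \item{n_species, n_orders, n_countries}{Taxonomy and reporting sizes
#'     (defaults 224 species / 40 orders, mirroring the scale of published
#'     whole-body P compilations, and 20 countries).}
#'   \item{year_range}{Inclusive years, default 1950:2016.}
#'   \item{group_mean_conc}{Wet-basis whole-body P mass fraction per major
#'     group (finfish 0.007, crustacean 0.004, mollusk 0.002).}
#'   \item{order_cv, species_cv}{Lognormal dispersion of order means around
#'     the group mean and of species means (and records) within orders.}
#'   \item{thin_rate}{Fraction of species given 0 or 1 concentration records
#'     (half each), exercising the fallback chain. Default 0.3.}
#'   \item{dry_frac, moisture_range, moisture_missing_rate}{Share of records
#'     reported on dry basis, their moisture range, and the share of those
#'     with unreported moisture (database-mean fallback).}
#'   \item{records_lambda}{Poisson mean of extra records for well-sampled
#'     species (count = 2 + Pois(lambda)).}
#'   \item{pue_median, pue_sigma, pue_n}{Per-group6 PUE medians (NA = no data
#'     for that group, exercising the freshwater-mollusk substitution),
#'     log-scale spread, entries per group.}
#'   \item{pre_median, pre_sigma, pre_n}{Feeding-experiment P-retention
#'     medians and counts per major group.}
#'   \item{wild_plateau_year, aquaculture_takeoff_year}{Trend shape years.}
#'   \item{wild_start, wild_plateau}{Global wild capture in Tg at the start
#'     year and at the plateau.}
#'   \item{aqua_takeoff_level, aqua_growth, aqua_pregrowth}{Aquaculture Tg at
#'     takeoff and exponential growth rates after/before it.}
#'   \item{scaling_start, scaling_end, scaling_end_year, last_scaling_year}{
#'     Mean scaling factor anchors (1.29 at the first year, 1.06 at 2004) and
#'     the last year factors are defined for (2014).}
#'   \item{seed}{Integer master seed.}
#' }
#' @export
synth_config <- function(...) {
  cfg <- list(
    n_species = 224L, n_orders = 40L, n_countries = 20L,
    year_range = c(1950L, 2016L),
    group_mean_conc = c(finfish = 0.007, crustacean = 0.004, mollusk = 0.002),
    order_cv = 0.25, species_cv = 0.15,
    thin_rate = 0.30, dry_frac = 0.25,
    moisture_range = c(0.65, 0.80), moisture_missing_rate = 0.3,
    records_lambda = 5,
    pue_median = c(freshwater_finfish = 0.20, marine_finfish = 0.22,
                   freshwater_crustacean = 0.12, marine_crustacean = 0.13,
                   freshwater_mollusk = NA_real_, marine_mollusk = 0.25),
    pue_sigma = 0.6, pue_n = 34L,
    pre_median = c(finfish = 0.40, crustacean = 0.18),
    pre_sigma = 0.45, pre_n = c(finfish = 250L, crustacean = 98L),
    wild_plateau_year = 1990L, aquaculture_takeoff_year = 1980L,
    wild_start = 19, wild_plateau = 92,
    aqua_takeoff_level = 2, aqua_growth = 0.10, aqua_pregrowth = 0.05,
    scaling_start = 1.29, scaling_end = 1.06, scaling_end_year = 2004L,
    last_scaling_year = 2014L,
    seed = 42L)
  over <- list(...)
  if (anyDuplicated(names(over)))
    stop("duplicated synth_config field(s): ",
         paste(unique(names(over)[duplicated(names(over))]), collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown synth_config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(cfg, over)
  # validation
  stopifnot(cfg$n_species >= 1, cfg$n_orders >= 1, cfg$n_countries >= 1)
  if (cfg$n_species < cfg$n_orders || cfg$n_orders < 3)
    stop("need n_species >= n_orders >= 3 (one order per major group)",
         call. = FALSE)
  if (length(cfg$year_range) != 2 || cfg$year_range[1] > cfg$year_range[2])
    stop("year_range must be a nonempty inclusive pair", call. = FALSE)
  frac_ok <- function(x) all(is.na(x) | (x > 0 & x <= 1))
  if (!frac_ok(cfg$group_mean_conc) || !frac_ok(cfg$pue_median) ||
      !frac_ok(cfg$pre_median))
    stop("concentration and efficiency parameters must lie in (0, 1]",
         call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "synth_config"
  cfg
}

# seed-stream splitting: one documented offset per generator
.synth_seed <- function(cfg, stage) {
  off <- c(taxonomy = 1L, concentration = 2L, production = 3L,
           pue = 4L, pre = 5L, scaling = 6L)
  set.seed(cfg$seed + off[[stage]])
}

.country_ids <- function(n) sprintf("C%02d", seq_len(n))

#' Generate a species / order / major-group taxonomy
#'
#' Orders are split among the three major groups with a finfish-heavy share
#' (finfish dominate both real production and concentration compilations);
#' species are assigned to orders with a right-skewed (Zipf-like) allocation
#' so some orders are large and some have a single species.
#'
#' @param config A [synth_config()].
#' @return `data.table` with columns `species`, `order`, `group`.
#' @export
generate_taxonomy <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  .synth_seed(config, "taxonomy")
  n_ord <- config$n_orders; n_sp <- config$n_species

  # at least one order per group; remaining orders finfish-heavy (70/15/15)
  extra <- n_ord - 3L
  n_ff  <- 1L + round(0.70 * extra)
  n_cr  <- 1L + round(0.15 * extra)
  n_mo  <- n_ord - n_ff - n_cr
  order_group <- rep(c("finfish", "crustacean", "mollusk"),
                     times = c(n_ff, n_cr, n_mo))
  orders <- sprintf("O%03d", seq_len(n_ord))

  # every order gets one species, the rest Zipf-weighted
  order_of_species <- orders
  if (n_sp > n_ord) {
    w <- 1 / seq_len(n_ord)
    order_of_species <- c(orders,
      sample(orders, n_sp - n_ord, replace = TRUE, prob = w))
  }
  dt <- data.table::data.table(
    species = sprintf("S%04d", seq_len(n_sp)),
    order   = order_of_species[seq_len(n_sp)])
  dt[, group := order_group[match(order, orders)]]
  data.table::setkey(dt, species)
  dt[]
}

#' Generate a whole-body P concentration database
#'
#' Latent species means are lognormal around lognormal order means around the
#' configured group means. Records are lognormal around the species mean with
#' the within-order dispersion (`species_cv`), so `order_cv = species_cv = 0`
#' collapses every record to its group mean. A `thin_rate` share of species
#' receives 0 or 1 records to exercise the order/group fallback chain, and a
#' `dry_frac` share is stored on dry basis (value inflated by 1/(1-moisture)),
#' some with unreported moisture.
#'
#' @param taxonomy Output of [generate_taxonomy()].
#' @param config A [synth_config()].
#' @return `data.table` in the `concentration` schema, with attribute
#'   `truth`: a table of latent per-species wet-basis means (`species`,
#'   `true_conc`).
#' @export
generate_concentration_db <- function(taxonomy, config = synth_config()) {
  stopifnot(inherits(config, "synth_config"), nrow(taxonomy) > 0)
  .synth_seed(config, "concentration")
  tax <- data.table::as.data.table(taxonomy)

  ords <- unique(tax$order)
  order_eff <- stats::setNames(
    stats::rlnorm(length(ords), -config$order_cv^2 / 2, config$order_cv), ords)
  sp_eff <- stats::rlnorm(nrow(tax), -config$species_cv^2 / 2, config$species_cv)
  truth <- tax[, .(species, order, group)]
  truth[, true_conc := config$group_mean_conc[group] *
                        order_eff[order] * sp_eff]

  # record counts: thin species get 0 or 1 (half each), others 2 + Poisson
  n_sp <- nrow(truth)
  thin <- stats::runif(n_sp) < config$thin_rate
  n_rec <- 2L + stats::rpois(n_sp, config$records_lambda)
  n_rec[thin] <- as.integer(stats::runif(sum(thin)) < 0.5)

  idx <- rep(seq_len(n_sp), n_rec)
  db <- truth[idx, .(species, order, group, true_conc)]
  db[, value := true_conc *
       stats::rlnorm(.N, -config$species_cv^2 / 2, config$species_cv)]
  db[, true_conc := NULL]
  db[, origin := sample(c("wild", "raised"), .N, replace = TRUE,
                        prob = c(0.25, 0.75))]
  db[, basis := "wet"]
  db[, moisture := NA_real_]
  dry <- stats::runif(nrow(db)) < config$dry_frac
  if (any(dry)) {
    m <- stats::runif(sum(dry), config$moisture_range[1], config$moisture_range[2])
    db[dry, `:=`(basis = "dry", value = value / (1 - m), moisture = m)]
    hide <- dry & stats::runif(nrow(db)) < config$moisture_missing_rate
    db[hide, moisture := NA_real_]
  }
  out <- db[, .(species, order, group, value, basis, moisture, origin)]
  data.table::setattr(out, "truth", truth[, .(species, true_conc)])
  out[]
}

# logistic wild-capture trajectory reaching ~98% of plateau at plateau year
.wild_total <- function(years, cfg) {
  y0 <- cfg$year_range[1]
  mid <- (y0 + cfg$wild_plateau_year) / 2
  tau <- max((cfg$wild_plateau_year - y0) / 8, 1)
  cfg$wild_start +
    (cfg$wild_plateau - cfg$wild_start) / (1 + exp(-(years - mid) / tau))
}

.aqua_total <- function(years, cfg) {
  t0 <- cfg$aquaculture_takeoff_year
  rate <- ifelse(years < t0, cfg$aqua_pregrowth, cfg$aqua_growth)
  cfg$aqua_takeoff_level * exp(rate * (years - t0))
}

#' Generate a fishery production table
#'
#' Wild capture follows a logistic curve plateauing after
#' `wild_plateau_year`; aquaculture is near-zero before the takeoff year and
#' grows geometrically after it. Production is concentrated: country shares
#' are geometric (a dominant producer holds roughly a third of output, as
#' China does in real aquaculture statistics) and species shares within each
#' group are Zipf-like (a few species such as the carps dominate). Each
#' species farms/lands in a small set of countries and one environment. Small
#' aquatic-plant and mammal rows are included so downstream exclusion filters
#' are exercised.
#'
#' @param taxonomy Output of [generate_taxonomy()].
#' @param config A [synth_config()].
#' @return `data.table` in the `production` schema (weights in Tg).
#' @export
generate_production <- function(taxonomy, config = synth_config()) {
  stopifnot(inherits(config, "synth_config"), nrow(taxonomy) > 0)
  .synth_seed(config, "production")
  tax <- data.table::as.data.table(taxonomy)
  years <- seq(config$year_range[1], config$year_range[2])
  countries <- .country_ids(config$n_countries)

  # per-species static attributes
  n_sp <- nrow(tax)
  sp <- tax[, .(species, order, group)]
  p_marine <- c(finfish = 0.55, crustacean = 0.5, mollusk = 0.8)
  sp[, environment := ifelse(stats::runif(.N) < p_marine[group],
                             "marine", "freshwater")]
  roles <- sample(c("capture", "aquaculture", "both"), n_sp, replace = TRUE,
                  prob = c(0.5, 0.2, 0.3))
  sp[, in_capture := roles != "aquaculture"]
  sp[, in_aqua    := roles != "capture"]
  # make sure both sources and both environments exist
  sp[1, `:=`(in_capture = TRUE, environment = "marine")]
  sp[min(.N, 2), `:=`(in_aqua = TRUE, environment = "freshwater")]
  # Zipf weights in random species order: a few species dominate
  sp[, base_share := sample(1 / seq_len(.N))]

  cshare_cap  <- 0.70 ^ seq_along(countries)
  cshare_aqua <- 0.55 ^ seq_along(countries)
  n_ctry <- pmin(1L + stats::rpois(n_sp, 1.5), length(countries))
  sp_ctry <- lapply(seq_len(n_sp), function(i)
    sample(countries, n_ctry[i], prob = cshare_cap))

  long <- sp[rep(seq_len(n_sp), n_ctry)]
  long[, country := unlist(sp_ctry)]
  long[, cw_cap  := cshare_cap[match(country, countries)]]
  long[, cw_aqua := cshare_aqua[match(country, countries)]]
  long[, noise := stats::rlnorm(.N, 0, 0.3)]

  make_source <- function(flag_col, cw_col, totals) {
    rows <- long[long[[flag_col]] == TRUE]
    rows[, w_raw := base_share * rows[[cw_col]] * noise]
    grid <- rows[rep(seq_len(.N), each = length(years))]
    grid[, year := rep(years, times = nrow(rows))]
    # mild year-to-year record noise, then normalize to the global trajectory
    grid[, w_raw := w_raw * stats::rlnorm(.N, 0, 0.10)]
    grid[, weight := w_raw * totals[match(year, years)] / sum(w_raw), by = year]
    grid[, .(year, country, species, order, group, environment, weight)]
  }
  cap  <- make_source("in_capture", "cw_cap",  .wild_total(years, config))
  cap[, source := "capture"]
  aq   <- make_source("in_aqua", "cw_aqua", .aqua_total(years, config))
  aq[, source := "aquaculture"]

  # excluded groups: seaweed farming and marine mammal harvest
  extras <- data.table::CJ(year = years, country = countries[1])
  extras <- rbind(
    extras[, .(year, country, species = "Xplant01", order = NA_character_,
               group = "aquatic_plant", environment = "marine",
               weight = 5 + 0.3 * (year - years[1]), source = "aquaculture")],
    extras[, .(year, country, species = "Xmammal01", order = NA_character_,
               group = "mammal", environment = "marine",
               weight = 0.5, source = "capture")])

  out <- rbind(cap, aq, extras, use.names = TRUE)
  data.table::setcolorder(out, c("year", "country", "species", "order",
                                 "group", "environment", "source", "weight"))
  data.table::setkey(out, year, country, species, source)
  out[]
}

# lognormal draws with median m, resampled into [lo, hi]
.trunc_lnorm <- function(n, m, sigma, lo, hi) {
  if (sigma == 0) return(rep(m, n))
  x <- stats::rlnorm(n, log(m), sigma)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rlnorm(length(bad), log(m), sigma)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

#' Generate a culture-system PUE database
#'
#' Right-skewed (lognormal) phosphorus-use-efficiency values per
#' environment-by-taxon group, truncated to the observed range of real
#' culture systems, 1--167%. Groups whose configured median is `NA`
#' (freshwater mollusks by default) get no entries, exercising the
#' marine-mollusk substitution rule downstream. Default medians put finfish
#' above crustaceans, the one robust contrast in published compilations.
#'
#' @param config A [synth_config()].
#' @return `data.table` in the `pue` schema.
#' @export
generate_pue_db <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  .synth_seed(config, "pue")
  med <- config$pue_median
  missing_keys <- setdiff(group6_keys(), names(med))
  if (length(missing_keys))
    stop("pue_median must name all six groups (use NA for no data): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  keys <- names(med)[!is.na(med)]
  out <- data.table::rbindlist(lapply(keys, function(k) {
    data.table::data.table(
      group6 = k,
      value  = .trunc_lnorm(config$pue_n, med[[k]], config$pue_sigma,
                            0.01, 1.67),
      system = sample(c("pond", "tank", "cage", "recirculating",
                        "flow-through"), config$pue_n, replace = TRUE),
      country = sample(.country_ids(config$n_countries), config$pue_n,
                       replace = TRUE))
  }))
  out[]
}

#' Generate a feeding-experiment P-retention (PRE) database
#'
#' Lognormal retention fractions truncated to (0, 1] per major group;
#' defaults give finfish a higher median than crustaceans, matching feeding
#' trials.
#'
#' @param config A [synth_config()].
#' @return `data.table` in the `pre` schema.
#' @export
generate_pre_db <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  .synth_seed(config, "pre")
  med <- config$pre_median
  out <- data.table::rbindlist(lapply(names(med), function(g) {
    n <- config$pre_n[[g]]
    data.table::data.table(
      group = g,
      value = .trunc_lnorm(n, med[[g]], config$pre_sigma, 1e-4, 1))
  }))
  out[]
}

#' Generate country-level catch-reconstruction scaling factors
#'
#' The cross-country mean factor interpolates linearly between
#' `scaling_start` at the first production year and `scaling_end` at
#' `scaling_end_year`, then holds constant through `last_scaling_year`
#' (default 2014) — reconstruction series end before the production record
#' does, so later years must reuse the last factor downstream. Country
#' offsets are fixed, small and sum to zero, so yearly means equal the
#' interpolated line exactly and all factors stay above 1.
#'
#' @param countries Character vector of country ids (default: the config's).
#' @param years Integer years to cover (default: first production year
#'   through `last_scaling_year`).
#' @param config A [synth_config()].
#' @return `data.table` in the `scaling` schema.
#' @export
generate_scaling_factors <- function(countries = NULL, years = NULL,
                                     config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  .synth_seed(config, "scaling")
  if (is.null(countries)) countries <- .country_ids(config$n_countries)
  if (is.null(years))
    years <- seq(config$year_range[1],
                 min(config$last_scaling_year, config$year_range[2]))
  y0 <- config$year_range[1]
  line <- function(y) {
    frac <- pmin(pmax((y - y0) / (config$scaling_end_year - y0), 0), 1)
    config$scaling_start + frac * (config$scaling_end - config$scaling_start)
  }
  nc <- length(countries)
  delta <- stats::runif(nc, -0.04, 0.04)
  delta <- delta - mean(delta)   # zero-sum: yearly mean == line(y)
  out <- data.table::CJ(country = countries, year = as.integer(years))
  out[, factor := line(year) + delta[match(country, countries)]]
  out[]
}

#' Generate all five synthetic input tables
#'
#' Runs every generator under one config, optionally writes the five CSVs,
#' the latent-truth table and a JSON manifest (seed, config, file hashes) to
#' `out_dir`.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return Named list: `taxonomy`, `production`, `concentration`, `pue`,
#'   `pre`, `scaling`, `truth`, and `config`.
#' @export
generate_all <- function(config = synth_config(), out_dir = NULL) {
  tax  <- generate_taxonomy(config)
  conc <- generate_concentration_db(tax, config)
  prod <- generate_production(tax, config)
  pue  <- generate_pue_db(config)
  pre  <- generate_pre_db(config)
  scal <- generate_scaling_factors(config = config)
  out <- list(taxonomy = tax, production = prod, concentration = conc,
              pue = pue, pre = pre, scaling = scal,
              truth = attr(conc, "truth"), config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(production = "production.csv", concentration = "concentration.csv",
               pue = "pue.csv", pre = "pre.csv", scaling = "scaling.csv",
               taxonomy = "taxonomy.csv", truth = "truth.csv")
    for (nm in names(paths))
      write_table(out[[nm]], file.path(out_dir, paths[[nm]]))
    write_manifest(file.path(out_dir, "manifest.json"),
                   inputs = stats::setNames(file.path(out_dir, paths), names(paths)),
                   config = unclass(config), seed = config$seed,
                   counts = lapply(out[names(paths)], nrow))
  }
  invisible(out)
}

#' Closed-form P-harvest from latent species concentrations
#'
#' The generator's ground truth: \eqn{\sum_i W_i \mu_i} per year, using the
#' latent species means the concentration records were drawn around. Used by
#' parameter-recovery tests.
#'
#' @param production Production table (budget groups only are counted).
#' @param truth Truth table from [generate_concentration_db()].
#' @return `data.table` with `year` and `p_harvest` (Tg P).
#' @export
true_p_harvest <- function(production, truth) {
  dt <- filter_budget_groups(production)
  tr <- data.table::as.data.table(truth)
  dt <- merge(dt, tr, by = "species", all.x = TRUE)
  if (anyNA(dt$true_conc))
    stop("species without latent truth: ",
         paste(unique(dt$species[is.na(dt$true_conc)]), collapse = ", "),
         call. = FALSE)
  dt[, .(p_harvest = sum(weight * true_conc)), keyby = year]
}
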