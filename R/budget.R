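# The assembled budget: deterministic point estimate and the Monte Carlo
# engine that propagates concentration, biomass and PUE uncertainty through
# stages 1-2, plus the IQR summariser.

#' Deterministic P budget (point estimate)
#'
#' Runs stages 1-2 once with central values: scaled capture, pool-mean
#' concentrations, group-median PUE. Used as the reference the zero-variance
#' Monte Carlo must collapse to, and emitted alongside replicate summaries
#' for debugging.
#'
#' @param production Production table.
#' @param conc Concentration table (normalized internally).
#' @param pue_db PUE table.
#' @param factors Scaling-factor table (`NULL` to skip scaling).
#' @param cutoff Fallback-chain cutoff, see [resolve_pools()].
#' @param marine_only Scale only marine capture, see
#'   [scale_wild_production()].
#' @return List of class `p_budget`: `budget` (per year x country
#'   `p_harvest`, `p_input`, `p_net`, Tg P), `records` (record-level
#'   harvest), `pools`, and `pue` (group medians).
#' @export
point_budget <- function(production, conc, pue_db, factors = NULL,
                         cutoff = 1L, marine_only = FALSE) {
  prod <- validate_table(production, "production")
  if (!is.null(factors))
    prod <- scale_wild_production(prod, factors, marine_only)
  rows <- filter_budget_groups(prod)
  pools <- resolve_pools(rows, conc, cutoff)
  rec <- compute_p_harvest(rows, pools)

  pue <- group_pue_all(pue_db)
  rec[, g6 := ifelse(source == "aquaculture",
                     group6_of(environment, group), NA_character_)]
  budget <- rec[, .(
      p_harvest = sum(p_harvest_tg),
      p_input   = sum(ifelse(is.na(g6), 0, p_harvest_tg / pue[g6]))),
    keyby = .(year, country)]
  budget[, p_net := p_harvest - p_input]
  structure(list(budget = budget, records = rec, pools = pools, pue = pue),
            class = "p_budget")
}

#' Monte Carlo configuration
#'
#' @param n_rep Number of replicates (default 1000).
#' @param cutoff Fallback-chain cutoff (default 1).
#' @param biomass_level Relative biomass uncertainty level, one of 0, 0.5, 1
#'   (total interval width as a fraction of the weight; 0.5 means +/-25%).
#' @param seed Integer seed governing the whole run.
#' @param marine_only Scale only marine capture rows.
#' @return List of class `mc_config`.
#' @export
mc_config <- function(n_rep = 1000L, cutoff = 1L, biomass_level = 0.5,
                      seed = 1L, marine_only = FALSE) {
  stopifnot(n_rep >= 1, cutoff >= 0, biomass_level >= 0)
  structure(list(n_rep = as.integer(n_rep), cutoff = as.integer(cutoff),
                 biomass_level = biomass_level, seed = as.integer(seed),
                 marine_only = marine_only),
            class = "mc_config")
}

#' Draw concentrations from a resolved pool
#'
#' Species-level and proxy pools are sampled uniformly from their member
#' values; rescaled pools (thin species) are sampled from a normal with the
#' species mean and the CV-rescaled standard deviation, truncated to
#' positive values by redrawing. Uses the current RNG state.
#'
#' @param pool One-row pool table from [resolve_pools()].
#' @param n Number of draws.
#' @return Numeric vector of wet-basis concentrations.
#' @export
draw_concentration <- function(pool, n = 1L) {
  pool <- data.table::as.data.table(pool)
  stopifnot(nrow(pool) == 1L)
  if (isTRUE(pool$rescaled)) {
    if (pool$sd == 0) return(rep(pool$mean, n))
    x <- stats::rnorm(n, pool$mean, pool$sd)
    bad <- which(x <= 0)
    while (length(bad)) {
      x[bad] <- stats::rnorm(length(bad), pool$mean, pool$sd)
      bad <- bad[x[bad] <= 0]
    }
    x
  } else {
    mem <- pool$members[[1]]
    mem[sample.int(length(mem), n, replace = TRUE)]
  }
}

#' Draw biomass within a relative uncertainty level
#'
#' Uniform on `[W (1 - level/2), W (1 + level/2)]`; `level = 0` returns the
#' weight exactly. Level 0.5 (+/-25%) corresponds to "very low confidence"
#' reporting and is the default for the headline budget.
#'
#' @param W Weights (Tg), vectorized.
#' @param level Total relative interval width (0, 0.5 or 1 in practice).
#' @return Numeric vector, same length as `W`.
#' @export
draw_biomass <- function(W, level = 0.5) {
  stopifnot(all(W >= 0), level >= 0)
  if (level == 0) return(W)
  W * stats::runif(length(W), 1 - level / 2, 1 + level / 2)
}

#' Draw a PUE value from a group's empirical pool
#'
#' One uniform draw from the group's compiled values (after the
#' freshwater-mollusk substitution); replicates use one draw per group, not
#' per record, since PUE enters the budget as a group-level parameter.
#'
#' @param pue_db PUE table.
#' @param key Key from [group6_keys()].
#' @param n Number of draws.
#' @return Numeric vector of PUE fractions.
#' @export
draw_pue <- function(pue_db, key, n = 1L) {
  vals <- .pue_pool(pue_db, key)
  vals[sample.int(length(vals), n, replace = TRUE)]
}

#' Run the Monte Carlo uncertainty propagation
#'
#' Each replicate applies fresh draws through stages 1-2: one concentration
#' draw per species (shared across countries and years within the
#' replicate), one biomass draw per production record, and one PUE draw per
#' six-group. Deterministic given `config$seed` and the inputs.
#'
#' @param production Production table.
#' @param conc Concentration table.
#' @param pue_db PUE table.
#' @param factors Scaling-factor table (`NULL` to skip scaling).
#' @param config An [mc_config()].
#' @return List of class `mc_budget`: `replicates` (long `data.table`:
#'   `replicate`, `year`, `country`, `p_harvest`, `p_input`, `p_net`),
#'   `point` (the deterministic [point_budget()]), and `config`.
#' @export
run_monte_carlo <- function(production, conc, pue_db, factors = NULL,
                            config = mc_config()) {
  stopifnot(inherits(config, "mc_config"))
  point <- point_budget(production, conc, pue_db, factors,
                        cutoff = config$cutoff,
                        marine_only = config$marine_only)
  rec <- point$records
  n_rep <- config$n_rep

  units <- unique(rec[, .(year, country)])
  data.table::setkey(units, year, country)
  units[, uid := .I]
  rec <- merge(rec, units, by = c("year", "country"), sort = FALSE)

  pools <- point$pools
  sp_ids <- pools$species
  rec[, sp_idx := match(species, sp_ids)]

  set.seed(config$seed)
  # one concentration draw per species per replicate
  C <- matrix(0, nrow = length(sp_ids), ncol = n_rep)
  for (i in seq_along(sp_ids)) C[i, ] <- draw_concentration(pools[i], n_rep)
  # one PUE draw per group per replicate
  keys <- group6_keys()
  P <- matrix(0, nrow = length(keys), ncol = n_rep,
              dimnames = list(keys, NULL))
  for (k in keys) P[k, ] <- draw_pue(pue_db, k, n_rep)

  W <- rec$weight
  uidx <- rec$uid
  aq <- which(!is.na(rec$g6))
  g6_idx <- match(rec$g6[aq], keys)
  uidx_aq <- uidx[aq]
  n_units <- nrow(units)

  PH <- matrix(0, n_units, n_rep)
  PI <- matrix(0, n_units, n_rep)
  for (r in seq_len(n_rep)) {
    w_r <- draw_biomass(W, config$biomass_level)
    p_rec <- w_r * C[rec$sp_idx, r]
    ph <- rowsum(p_rec, uidx)        # unit ids are 1..n_units, all present
    PH[, r] <- ph[, 1]
    if (length(aq)) {
      inp <- p_rec[aq] / P[g6_idx, r]
      pi_r <- rowsum(inp, uidx_aq)
      PI[as.integer(rownames(pi_r)), r] <- pi_r[, 1]
    }
  }

  reps <- data.table::data.table(
    replicate = rep(seq_len(n_rep), each = n_units),
    year      = rep(units$year, n_rep),
    country   = rep(units$country, n_rep),
    p_harvest = as.vector(PH),
    p_input   = as.vector(PI))
  reps[, p_net := p_harvest - p_input]
  structure(list(replicates = reps, point = point, config = config),
            class = "mc_budget")
}

#' Summarise Monte Carlo replicates as mean and interquartile range
#'
#' Replicate fluxes are aggregated to the requested unit within each
#' replicate, then summarised across replicates: the central value is the
#' replicate mean and the band is the IQR (25th and 75th percentiles,
#' linear-interpolation quantiles, R type 7). The skewed PUE pool makes
#' P-input right-skewed, so the mean may sit above the IQR midpoint; no
#' ordering between mean and quantiles is enforced.
#'
#' @param mc An `mc_budget` from [run_monte_carlo()], or its `replicates`
#'   table.
#' @param by Grouping columns, default `"year"` (global);
#'   `c("year","country")` for country resolution.
#' @return Long `data.table`: grouping columns, `flux` (`p_harvest`,
#'   `p_input`, `p_net`), `mean`, `q25`, `q75`.
#' @export
summarize_replicates <- function(mc, by = "year") {
  reps <- if (inherits(mc, "mc_budget")) mc$replicates else
    data.table::as.data.table(mc)
  agg <- reps[, .(p_harvest = sum(p_harvest), p_input = sum(p_input),
                  p_net = sum(p_net)),
              keyby = c("replicate", by)]
  long <- data.table::melt(agg, id.vars = c("replicate", by),
                           variable.name = "flux", value.name = "value",
                           variable.factor = FALSE)
  long[, .(mean = mean(value),
           q25 = unname(stats::quantile(value, 0.25, type = 7)),
           q75 = unname(stats::quantile(value, 0.75, type = 7))),
       keyby = c(by, "flux")]
}
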