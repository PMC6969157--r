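# Stage 1: P-harvest. Wild capture is rescaled with catch-reconstruction
# factors, every produced species is resolved to a whole-body P concentration
# pool through the hierarchical fallback chain, and harvested P is
# P_harvest = sum_i W_i * R_i over all produced species.

#' Scale wild capture with country-level reconstruction factors
#'
#' Reported wild capture understates true landings (unreported, artisanal and
#' subsistence catch), so capture rows are multiplied by country x year
#' scaling factors from a catch-reconstruction table. Aquaculture rows are
#' never scaled. Years beyond the last factor year reuse each country's last
#' available factor (reconstruction series end before the production record);
#' a (country, year) pair absent from the table falls back to that year's
#' cross-country mean factor.
#'
#' @param production Production table (`production` schema).
#' @param factors Scaling-factor table (`scaling` schema).
#' @param marine_only If `TRUE`, scale only marine capture rows (the
#'   reconstruction covers marine catch); default scales all capture.
#' @return Production with scaled capture weights.
#' @export
scale_wild_production <- function(production, factors, marine_only = FALSE) {
  prod <- data.table::copy(data.table::as.data.table(production))
  fac  <- data.table::as.data.table(factors)
  if (!nrow(fac)) return(prod)
  last_year <- max(fac$year)
  year_mean <- fac[, .(factor_mean = mean(factor)), keyby = year]
  last_fac  <- fac[, .SD[which.max(year)], by = country][
                    , .(country, factor_last = factor)]

  idx <- prod$source == "capture"
  if (marine_only) idx <- idx & prod$environment == "marine"
  rows <- prod[idx]
  rows[, lookup_year := pmin(year, last_year)]
  rows <- merge(rows, fac, by.x = c("country", "lookup_year"),
                by.y = c("country", "year"), all.x = TRUE, sort = FALSE)
  rows <- merge(rows, last_fac, by = "country", all.x = TRUE, sort = FALSE)
  rows <- merge(rows, year_mean, by.x = "lookup_year", by.y = "year",
                all.x = TRUE, sort = FALSE)
  # precedence: exact factor; beyond-range years use the country's last
  # factor; otherwise the year's cross-country mean
  rows[, f := factor]
  rows[is.na(f) & year > last_year, f := factor_last]
  rows[is.na(f), f := factor_mean]
  if (anyNA(rows$f))
    stop("no scaling factor resolvable for some capture rows (empty year?)",
         call. = FALSE)
  prod[idx, weight := weight * rows$f]
  prod[]
}

#' Resolve concentration pools for a set of produced species
#'
#' Implements the hierarchical fallback chain that assigns every produced
#' species a sampling pool of whole-body P concentrations:
#' \itemize{
#'   \item more records than `cutoff` at species level: the species' own
#'     records (`level = "species"`);
#'   \item 1..`cutoff` records: keep the species mean but widen the spread
#'     using the order-level coefficient of variation — normal sampling with
#'     `mean = species mean`, `sd = species mean * (order sd / order mean)`
#'     (`level = "order"`, `rescaled = TRUE`; falls through to the group or
#'     whole-database CV when the order pool is itself at or below the
#'     cutoff);
#'   \item no records: the order pool (`level = "order"`), else the major
#'     group pool (`level = "group"`);
#'   \item taxa outside finfish/crustacean/mollusk (other aquatic
#'     invertebrates): the whole-database pool (`level = "database"`).
#' }
#'
#' @param production Production table restricted to budget groups (species,
#'   order, group columns are used; order may be `NA`).
#' @param conc Concentration table; normalized to wet basis internally if
#'   needed.
#' @param cutoff Record-count cutoff below which higher taxonomic levels
#'   supply the spread (default 1).
#' @return A `data.table` of pools (class `concentration_pools`): `species`,
#'   `level`, `mean`, `sd`, `rescaled`, and `members` (list column of raw
#'   pool values; for rescaled pools the species' own records).
#' @export
resolve_pools <- function(production, conc, cutoff = 1L) {
  stopifnot(cutoff >= 0)
  conc <- data.table::as.data.table(conc)
  if (!nrow(conc)) stop("empty concentration database", call. = FALSE)
  if (any(conc$basis == "dry")) conc <- normalize_concentration(conc)

  prod <- data.table::as.data.table(production)
  need <- unique(prod[, .(species, order, group)])
  # production may lack order ids; recover them from the concentration db
  db_order <- conc[!is.na(order), .(order_db = order[1]), by = species]
  need <- merge(need, db_order, by = "species", all.x = TRUE, sort = FALSE)
  need[is.na(order), order := order_db]
  need[, order_db := NULL]

  sp_vals  <- split(conc$value, conc$species)
  ord_vals <- split(conc$value, conc$order)
  grp_vals <- split(conc$value, conc$group)
  all_vals <- conc$value
  all_cv   <- stats::sd(all_vals) / mean(all_vals)

  one_pool <- function(species, ord, grp) {
    v_sp <- sp_vals[[species]]
    n_sp <- length(v_sp)
    if (!is.na(grp) && !grp %in% GROUPS_MAJOR) {
      # other aquatic invertebrates: whole-database mean
      return(list(level = "database", mean = mean(all_vals),
                  sd = stats::sd(all_vals), rescaled = FALSE,
                  members = list(all_vals)))
    }
    v_ord <- if (!is.na(ord)) ord_vals[[ord]] else NULL
    v_grp <- if (!is.na(grp)) grp_vals[[grp]] else NULL
    if (n_sp > cutoff) {
      return(list(level = "species", mean = mean(v_sp), sd = stats::sd(v_sp),
                  rescaled = FALSE, members = list(v_sp)))
    }
    if (n_sp > 0) {
      # thin species: species mean, spread from the nearest informative level
      m <- mean(v_sp)
      if (length(v_ord) > cutoff)
        return(list(level = "order", mean = m,
                    sd = m * stats::sd(v_ord) / mean(v_ord),
                    rescaled = TRUE, members = list(v_sp)))
      if (length(v_grp) > cutoff)
        return(list(level = "group", mean = m,
                    sd = m * stats::sd(v_grp) / mean(v_grp),
                    rescaled = TRUE, members = list(v_sp)))
      return(list(level = "database", mean = m, sd = m * all_cv,
                  rescaled = TRUE, members = list(v_sp)))
    }
    # no species records: proxy pools
    if (length(v_ord) > cutoff)
      return(list(level = "order", mean = mean(v_ord), sd = stats::sd(v_ord),
                  rescaled = FALSE, members = list(v_ord)))
    if (length(v_grp) > cutoff)
      return(list(level = "group", mean = mean(v_grp), sd = stats::sd(v_grp),
                  rescaled = FALSE, members = list(v_grp)))
    list(level = "database", mean = mean(all_vals), sd = stats::sd(all_vals),
         rescaled = FALSE, members = list(all_vals))
  }

  pools <- need[, one_pool(species, order, group),
                by = .(species, order, group)]
  data.table::setattr(pools, "class",
                      c("concentration_pools", class(pools)))
  pools
}

#' Resolve the concentration pool for a single species
#'
#' Convenience wrapper around [resolve_pools()] for one species.
#'
#' @param species Species identifier.
#' @param conc Concentration table.
#' @param cutoff See [resolve_pools()].
#' @param order,group Taxonomy of the species if absent from `conc`.
#' @return One-row pool table.
#' @export
resolve_pool <- function(species, conc, cutoff = 1L,
                         order = NA_character_, group = NA_character_) {
  conc <- data.table::as.data.table(conc)
  if (is.na(order) || is.na(group)) {
    hit <- conc[conc$species == species]
    if (nrow(hit)) {
      if (is.na(order)) order <- hit$order[1]
      if (is.na(group)) group <- hit$group[1]
    }
  }
  fake <- data.table::data.table(species = species, order = order,
                                 group = group)
  resolve_pools(fake, conc, cutoff)
}

#' Compute P-harvest from production and resolved pools
#'
#' Point estimate of harvested P per record: live-weight production times the
#' pool mean concentration (\eqn{P = \sum_i W_i R_i}); pool means (not
#' medians) are used so small pools do not bias the central value. Aquatic
#' plants and mammals are dropped via [filter_budget_groups()]; discarded
#' fish never appear because production tables record landed/harvested
#' biomass only.
#'
#' @param production Production table.
#' @param pools Pools from [resolve_pools()].
#' @return Record-level `data.table` with grouping columns preserved and
#'   `p_harvest_tg = weight * mean` (Tg P).
#' @export
compute_p_harvest <- function(production, pools) {
  dt <- filter_budget_groups(production)
  pl <- data.table::as.data.table(pools)[, .(species, conc_mean = mean)]
  out <- merge(dt, pl, by = "species", all.x = TRUE, sort = FALSE)
  if (anyNA(out$conc_mean))
    stop("unresolved species (no concentration pool): ",
         paste(unique(out$species[is.na(out$conc_mean)]), collapse = ", "),
         call. = FALSE)
  out[, p_harvest_tg := weight * conc_mean]
  data.table::setcolorder(out, c("year", "country", "species", "order",
                                 "group", "environment", "source"))
  out[]
}
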