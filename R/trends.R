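# Aggregation to country/continent/global resolution, composition shares,
# and the two headline trend statistics: the peak of the landward P flux and
# the year P-net turns persistently negative.

#' Build or validate a country-to-continent region map
#'
#' A region map is a table with columns `country`, `continent`, and optional
#' `start_year` / `end_year` bounding the years a mapping is valid (so
#' dissolved entities can be reassigned, e.g. a union state mapped to one
#' region before its breakup and successor states mapped geographically
#' after). For synthetic country ids a deterministic round-robin assignment
#' over the five inhabited continents is produced.
#'
#' @param countries Character vector of country ids to cover.
#' @return `data.table` with `country`, `continent`, `start_year`,
#'   `end_year`.
#' @export
default_region_map <- function(countries) {
  continents <- c("Asia", "Africa", "Americas", "Europe", "Oceania")
  data.table::data.table(
    country = countries,
    continent = continents[(seq_along(countries) - 1L) %% 5L + 1L],
    start_year = NA_integer_, end_year = NA_integer_)
}

#' Aggregate a budget table to country, continent or global level
#'
#' Sums are exact, so global = sum of continents = sum of countries at
#' machine precision. Errors name any country the region map does not cover
#' (at the years it appears).
#'
#' @param budget Table with `year`, `country` and numeric flux columns
#'   (e.g. the `budget` element of [point_budget()], or Monte Carlo
#'   replicates — any extra grouping column such as `replicate` is kept).
#' @param region_map See [default_region_map()]. Required for
#'   `level = "continent"`.
#' @param level `"global"`, `"continent"` or `"country"`.
#' @return Aggregated `data.table`.
#' @export
aggregate_budget <- function(budget, region_map = NULL,
                             level = c("global", "continent", "country")) {
  level <- match.arg(level)
  dt <- data.table::as.data.table(budget)
  flux_cols <- intersect(c("p_harvest", "p_input", "p_net"), names(dt))
  extra <- intersect("replicate", names(dt))
  if (level == "country")
    return(dt[, lapply(.SD, sum), .SDcols = flux_cols,
              keyby = c(extra, "year", "country")])
  if (level == "global")
    return(dt[, lapply(.SD, sum), .SDcols = flux_cols,
              keyby = c(extra, "year")])

  rm <- data.table::as.data.table(region_map)
  if (!nrow(rm)) stop("a region map is required for continent aggregation",
                      call. = FALSE)
  if (!"start_year" %in% names(rm)) rm[, start_year := NA_integer_]
  if (!"end_year" %in% names(rm)) rm[, end_year := NA_integer_]
  dt <- merge(dt, rm, by = "country", all.x = TRUE,
              allow.cartesian = TRUE, sort = FALSE)
  dt <- dt[is.na(continent) |
             ((is.na(start_year) | year >= start_year) &
              (is.na(end_year)   | year <= end_year))]
  unmapped <- unique(dt$country[is.na(dt$continent)])
  if (length(unmapped))
    stop("countries missing from the region map: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  dt[, lapply(.SD, sum), .SDcols = flux_cols,
     keyby = c(extra, "year", "continent")]
}

#' Composition shares of P-harvest (or any flux) along a dimension
#'
#' Per year, the share of each category (e.g. `source`, `environment`,
#' `group`) in the total. Shares lie in [0,1] and sum to 1 within a year;
#' years with a zero denominator yield `NA` shares.
#'
#' @param records Record-level table, e.g. from [compute_p_harvest()].
#' @param dimension Column to decompose by.
#' @param value_col Numeric column to share out (default `p_harvest_tg`).
#' @return `data.table`: `year`, dimension, `value`, `share`.
#' @export
budget_shares <- function(records, dimension, value_col = "p_harvest_tg") {
  dt <- data.table::as.data.table(records)
  stopifnot(dimension %in% names(dt), value_col %in% names(dt))
  agg <- dt[, .(value = sum(.SD[[1]])), .SDcols = value_col,
            keyby = c("year", dimension)]
  agg[, total := sum(value), by = year]
  agg[, share := ifelse(total > 0, value / total, NA_real_)]
  agg[, total := NULL]
  agg[]
}

#' Peak of a per-year series
#'
#' Argmax with the earliest-year tie-break (deterministic).
#'
#' @param years Integer years.
#' @param values Series values, same length.
#' @return List with `year` and `value`.
#' @export
find_peak <- function(years, values) {
  stopifnot(length(years) == length(values), length(years) > 0)
  o <- order(years)
  years <- years[o]; values <- values[o]
  i <- which.max(values)   # first maximum = earliest year after sorting
  list(year = years[i], value = values[i])
}

#' First year of a persistently negative P-net
#'
#' The turning point is the first year from which the series stays below
#' zero through its end — robust to single-year sign flips. If the series
#' never turns persistently negative the crossing lies beyond the observed
#' range and `Inf` is returned (printed as e.g. `"> 2016"` by
#' [format_crossing_year()]).
#'
#' @param years Integer years.
#' @param values P-net series, same length.
#' @return Numeric year, or `Inf` if beyond range.
#' @export
find_zero_crossing <- function(years, values) {
  stopifnot(length(years) == length(values), length(years) > 0)
  o <- order(years)
  years <- years[o]; values <- values[o]
  neg_tail <- rev(cumprod(rev(values < 0)))  # 1 where negative through end
  i <- which(neg_tail == 1)
  if (length(i)) as.numeric(years[i[1]]) else Inf
}

#' Format a (possibly beyond-range) crossing year
#'
#' @param year Numeric year from [find_zero_crossing()].
#' @param end_year Last observed year, used for the beyond-range sentinel.
#' @return Character scalar, e.g. `"2004"` or `"> 2016"`.
#' @export
format_crossing_year <- function(year, end_year) {
  ifelse(is.infinite(year), paste0("> ", end_year), as.character(year))
}

#' Trend statistics with replicate IQRs
#'
#' Computes the P-net peak (year and value) and the zero-crossing year on
#' the replicate-mean global series, and the IQR of each statistic across
#' replicates (each replicate's own peak year / crossing year distribution).
#' Beyond-range crossings enter the quantiles as `Inf`, so an upper quartile
#' can itself be beyond range, matching how regional turning points are
#' reported.
#'
#' @param mc An `mc_budget` from [run_monte_carlo()].
#' @return `data.table`: `statistic`, `central`, `q25`, `q75`.
#' @export
trend_statistics <- function(mc) {
  stopifnot(inherits(mc, "mc_budget"))
  glob <- aggregate_budget(mc$replicates, level = "global")
  mean_series <- glob[, .(p_net = mean(p_net)), keyby = year]

  peak <- find_peak(mean_series$year, mean_series$p_net)
  crossing <- find_zero_crossing(mean_series$year, mean_series$p_net)

  per_rep <- glob[, .(
      peak_year  = find_peak(year, p_net)$year,
      peak_value = find_peak(year, p_net)$value,
      crossing   = find_zero_crossing(year, p_net)),
    by = replicate]
  q <- function(x, p) unname(stats::quantile(x, p, type = 7, names = FALSE))
  data.table::data.table(
    statistic = c("peak_year", "peak_value", "crossing_year"),
    central   = c(peak$year, peak$value, crossing),
    q25 = c(q(per_rep$peak_year, .25), q(per_rep$peak_value, .25),
            q(per_rep$crossing, .25)),
    q75 = c(q(per_rep$peak_year, .75), q(per_rep$peak_value, .75),
            q(per_rep$crossing, .75)))
}
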