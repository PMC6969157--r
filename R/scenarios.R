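# Forward scenarios: a single-point 2050 projection of the budget, the PUE
# required for a P-neutral fishery, and the weighted efficiency calculators
# that translate feeding-experiment retention percentiles into a whole-
# aquaculture PUE.

#' Scenario specification
#'
#' @param wild_window Inclusive year pair over which wild capture (and its
#'   harvested P) is averaged for the stable-wild assumption. Default
#'   2005-2014.
#' @param aquaculture_target Aquaculture live-weight production at the
#'   horizon, Tg. Default 140 (a published business-as-usual projection,
#'   about 2.3 times the 2010 level).
#' @param horizon Projection year, default 2050.
#' @param pue_assumption Global aquaculture PUE at the horizon as a
#'   fraction (default 0.20, the current production-weighted level), or
#'   `"solve-neutral"` to use exactly the PUE that makes P-net zero.
#' @param aquaculture_conc Harvested P per unit aquaculture live weight
#'   (Tg P / Tg). `NULL` (default) derives it from the history as the mean
#'   of aquaculture P-harvest / aquaculture production over `wild_window`.
#' @return List of class `scenario_spec`.
#' @export
scenario_spec <- function(wild_window = c(2005L, 2014L),
                          aquaculture_target = 140,
                          horizon = 2050L,
                          pue_assumption = 0.20,
                          aquaculture_conc = NULL) {
  stopifnot(length(wild_window) == 2, wild_window[1] <= wild_window[2],
            aquaculture_target > 0)
  if (!identical(pue_assumption, "solve-neutral"))
    stopifnot(is.numeric(pue_assumption), pue_assumption > 0)
  structure(list(wild_window = as.integer(wild_window),
                 aquaculture_target = aquaculture_target,
                 horizon = as.integer(horizon),
                 pue_assumption = pue_assumption,
                 aquaculture_conc = aquaculture_conc),
            class = "scenario_spec")
}

#' Per-year production and harvested-P history for scenario building
#'
#' Collapses a deterministic budget's record-level harvest into the per-year
#' quantities the projection needs. Wild production reflects any
#' catch-reconstruction scaling already applied.
#'
#' @param budget A `p_budget` from [point_budget()].
#' @return `data.table`: `year`, `wild_production`, `aqua_production` (Tg),
#'   `wild_p_harvest`, `aqua_p_harvest`, `p_input`, `p_net` (Tg P).
#' @export
budget_history <- function(budget) {
  stopifnot(inherits(budget, "p_budget"))
  rec <- budget$records
  hist <- rec[, .(
      wild_production = sum(weight[source == "capture"]),
      aqua_production = sum(weight[source == "aquaculture"]),
      wild_p_harvest  = sum(p_harvest_tg[source == "capture"]),
      aqua_p_harvest  = sum(p_harvest_tg[source == "aquaculture"])),
    keyby = year]
  glob <- budget$budget[, .(p_input = sum(p_input)), keyby = year]
  hist <- merge(hist, glob, by = "year")
  hist[, p_net := wild_p_harvest + aqua_p_harvest - p_input]
  hist[]
}

#' Project the P budget to the scenario horizon
#'
#' Single-point projection: wild capture (and its harvested P) stays at its
#' `wild_window` mean; aquaculture production reaches `aquaculture_target`
#' and its harvested P is `target * aquaculture_conc`; P-input is
#' aquaculture harvested P divided by the PUE assumption; P-net is total
#' P-harvest minus P-input. Linear in the aquaculture target at fixed
#' concentration and PUE.
#'
#' @param history Output of [budget_history()] (or any table with those
#'   columns) covering the wild window.
#' @param spec A [scenario_spec()].
#' @return List of class `p_scenario`: `horizon`, `wild_production`,
#'   `aqua_production`, `wild_p_harvest`, `aqua_p_harvest`, `p_harvest`,
#'   `p_input`, `p_net`, `pue`, `aquaculture_conc`.
#' @export
project_baseline <- function(history, spec = scenario_spec()) {
  stopifnot(inherits(spec, "scenario_spec"))
  h <- data.table::as.data.table(history)
  win <- h[year >= spec$wild_window[1] & year <= spec$wild_window[2]]
  if (!nrow(win))
    stop(sprintf("history does not cover the wild window %d-%d",
                 spec$wild_window[1], spec$wild_window[2]), call. = FALSE)
  wild_p <- mean(win$wild_p_harvest)
  wild_w <- mean(win$wild_production)
  conc <- spec$aquaculture_conc
  if (is.null(conc)) conc <- mean(win$aqua_p_harvest / win$aqua_production)
  aqua_p <- spec$aquaculture_target * conc
  total_p <- wild_p + aqua_p
  pue <- spec$pue_assumption
  if (identical(pue, "solve-neutral")) pue <- aqua_p / total_p
  p_input <- aqua_p / pue
  structure(list(horizon = spec$horizon,
                 wild_production = wild_w,
                 aqua_production = spec$aquaculture_target,
                 wild_p_harvest = wild_p, aqua_p_harvest = aqua_p,
                 p_harvest = total_p, p_input = p_input,
                 p_net = total_p - p_input,
                 pue = pue, aquaculture_conc = conc),
            class = "p_scenario")
}

#' PUE required for a P-neutral fishery
#'
#' P-net is zero when aquaculture P-input equals total P-harvest, i.e. when
#' the global aquaculture PUE equals aquaculture harvested P divided by
#' total harvested P — the unique fixed point of the baseline projection.
#' Accepts a `p_scenario`, or any list providing `p_harvest` (total) plus
#' either `aqua_p_harvest` or both `p_input` and `pue` (from which
#' aquaculture harvested P is `p_input * pue`).
#'
#' @param baseline Baseline scenario (see above).
#' @return Required PUE fraction.
#' @export
#' @examples
#' # a baseline with P-input 3.42 Tg at PUE 20% and total harvest 1.41 Tg
#' solve_neutral_pue(list(p_harvest = 1.41, p_input = 3.42, pue = 0.20))
solve_neutral_pue <- function(baseline) {
  aqua_p <- baseline$aqua_p_harvest
  if (is.null(aqua_p)) {
    if (is.null(baseline$p_input) || is.null(baseline$pue))
      stop("baseline must provide aqua_p_harvest, or p_input and pue",
           call. = FALSE)
    aqua_p <- baseline$p_input * baseline$pue
  }
  total <- baseline$p_harvest
  if (is.null(total) || total <= 0)
    stop("baseline total p_harvest must be positive", call. = FALSE)
  if (aqua_p <= 0)
    stop("baseline aquaculture harvested P must be positive", call. = FALSE)
  aqua_p / total
}

#' Production-weighted aggregate efficiency
#'
#' Combines group efficiencies (PUE or PRE) into one aquaculture-wide value
#' using harvested-P shares. Two schemes are exposed: `"arithmetic"`
#' (`sum(share * eff)`) matches how retention percentiles are usually
#' combined into a headline PUE; `"harmonic"`
#' (`1 / sum(share / eff)`) is what the group-wise input sum implies for a
#' single equivalent PUE. Arithmetic >= harmonic always (weighted AM-HM
#' inequality), so the arithmetic headline is the optimistic reading.
#'
#' @param shares Numeric weights summing to 1 (harvested-P shares).
#' @param efficiencies Positive fractions, same length.
#' @param scheme `"arithmetic"` or `"harmonic"`.
#' @param tol Tolerance on `sum(shares) - 1`.
#' @return Weighted efficiency fraction.
#' @export
#' @examples
#' weighted_pue(c(0.87, 0.13), c(0.52, 0.21))          # 0.4797
#' weighted_pue(c(0.87, 0.13), c(0.52, 0.21), "harmonic")
weighted_pue <- function(shares, efficiencies,
                         scheme = c("arithmetic", "harmonic"),
                         tol = 1e-6) {
  scheme <- match.arg(scheme)
  stopifnot(length(shares) == length(efficiencies))
  if (abs(sum(shares) - 1) > tol)
    stop(sprintf("shares must sum to 1 (got %.6f)", sum(shares)),
         call. = FALSE)
  if (any(efficiencies <= 0))
    stop("efficiencies must be positive", call. = FALSE)
  if (scheme == "arithmetic") sum(shares * efficiencies)
  else 1 / sum(shares / efficiencies)
}

#' Empirical efficiency percentiles
#'
#' Quantiles of a PRE or PUE pool with the same interpolation rule as the
#' replicate summaries (linear, R type 7).
#'
#' @param db PRE or PUE table (any table with a `value` column).
#' @param q Probabilities.
#' @param group Optional filter on the `group` (PRE) or `group6` (PUE)
#'   column.
#' @return Named numeric vector of quantiles.
#' @export
#' @examples
#' efficiency_percentiles(data.frame(value = c(.1, .2, .3, .4)), 0.5) # 0.25
efficiency_percentiles <- function(db, q, group = NULL) {
  dt <- data.table::as.data.table(db)
  if (!is.null(group)) {
    col <- if ("group" %in% names(dt)) "group" else "group6"
    keep <- dt[[col]] %in% group   # precompute: 'group' is also a column name
    dt <- dt[keep]
  }
  if (!nrow(dt)) stop("empty efficiency pool", call. = FALSE)
  stats::quantile(dt$value, q, type = 7)
}
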