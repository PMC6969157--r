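# Stage 2: P-input. Aquaculture harvested P is mapped into six
# environment x taxon groups and divided by each group's phosphorus-use
# efficiency: P_input = sum_j P_harvest_j / PUE_j. Wild capture needs no
# feed or fertilizer and contributes zero P-input.

#' Map an aquaculture record to its six-group PUE key
#'
#' Deterministic `environment x taxon` mapping (brackish records are already
#' folded into marine at I/O). Other aquatic invertebrates carry no PUE pool
#' of their own and are assigned a configurable taxon (finfish by default).
#'
#' @param environment `"freshwater"` or `"marine"` (vectorized).
#' @param group Major group of the record.
#' @param other_invertebrate_as Taxon whose PUE pool covers
#'   other-invertebrate aquaculture.
#' @return Character vector of keys from [group6_keys()].
#' @export
#' @examples
#' group6_of("freshwater", "finfish")
#' group6_of("marine", "other_invertebrate")
group6_of <- function(environment, group,
                      other_invertebrate_as = "finfish") {
  stopifnot(other_invertebrate_as %in% GROUPS_MAJOR)
  bad <- !environment %in% ENVIRONMENTS
  if (any(bad))
    stop("unknown environment: ", environment[bad][1], call. = FALSE)
  taxon <- ifelse(group == "other_invertebrate", other_invertebrate_as, group)
  bad <- !taxon %in% GROUPS_MAJOR
  if (any(bad))
    stop("no PUE group for taxon: ", taxon[bad][1], call. = FALSE)
  paste(environment, taxon, sep = "_")
}

# raw value pool for one group6 key, applying the mollusk substitution:
# no freshwater-mollusk systems have been measured, so the marine pool is
# used in their place
.pue_pool <- function(pue_db, key) {
  pue <- data.table::as.data.table(pue_db)
  vals <- pue$value[pue$group6 == key]
  if (!length(vals) && key == "freshwater_mollusk")
    vals <- pue$value[pue$group6 == "marine_mollusk"]
  if (!length(vals))
    stop("empty PUE pool for group '", key, "' (after substitution)",
         call. = FALSE)
  vals
}

#' Central PUE for a six-group key
#'
#' The PUE distribution is strongly right-skewed, so the median of the
#' group's pool is the central estimate; Monte Carlo replicates draw from
#' the pool instead (see [draw_pue()]). Freshwater mollusks use the marine
#' mollusk pool when they have no entries of their own.
#'
#' @param pue_db PUE table (`pue` schema).
#' @param key A key from [group6_keys()].
#' @param statistic `"median"` (central value) or `"draw"` (one random draw
#'   from the pool, for replicates).
#' @return PUE fraction.
#' @export
group_pue <- function(pue_db, key, statistic = c("median", "draw")) {
  statistic <- match.arg(statistic)
  vals <- .pue_pool(pue_db, key)
  if (statistic == "median") stats::median(vals)
  else vals[sample.int(length(vals), 1L)]
}

#' Compute P-input from aquaculture harvested P and group PUEs
#'
#' \eqn{P_{input} = \sum_j P_{harvest,j} / PUE_j} over the six groups.
#'
#' @param aqua_harvest Named numeric vector: harvested P (Tg) per group6
#'   key, or a table with columns `group6` and `p_harvest_tg`.
#' @param pue_by_group Named numeric vector of PUE fractions per group6 key.
#' @return List with `total` (Tg P) and `per_group` (named vector, Tg P).
#' @export
#' @examples
#' compute_p_input(c(freshwater_finfish = 0.684),
#'                 c(freshwater_finfish = 0.20))$total  # 3.42
compute_p_input <- function(aqua_harvest, pue_by_group) {
  if (is.data.frame(aqua_harvest)) {
    dt <- data.table::as.data.table(aqua_harvest)
    agg <- dt[, .(p = sum(p_harvest_tg)), by = group6]
    aqua_harvest <- stats::setNames(agg$p, agg$group6)
  }
  keys <- names(aqua_harvest)
  bad <- setdiff(keys, group6_keys())
  if (length(bad))
    stop("unknown group6 key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  pue <- pue_by_group[keys]
  if (anyNA(pue) || any(pue <= 0))
    stop("missing or non-positive PUE for group(s): ",
         paste(keys[is.na(pue) | pue <= 0], collapse = ", "), call. = FALSE)
  per <- aqua_harvest / pue
  list(total = sum(per), per_group = per)
}

#' Central PUE for every six-group key
#'
#' @param pue_db PUE table.
#' @param keys Keys to resolve (default all six).
#' @return Named numeric vector of group medians.
#' @export
group_pue_all <- function(pue_db, keys = group6_keys()) {
  stats::setNames(vapply(keys, function(k) group_pue(pue_db, k), numeric(1)),
                  keys)
}
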