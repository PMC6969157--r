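# Shared fixture builders. Everything is generated in code; no files.

# small but fully featured world: thin species, dry records, both sources
tiny_config <- function(seed = 101L, ...) {
  args <- utils::modifyList(
    list(n_species = 30L, n_orders = 8L, n_countries = 5L,
         year_range = c(1995L, 2006L), seed = seed),
    list(...))
  do.call(synth_config, args)
}

tiny_world <- function(seed = 101L, ...) {
  generate_all(tiny_config(seed = seed, ...))
}

# a world with every random dispersion switched off; the pipeline must
# collapse to closed-form sums on it
frozen_config <- function(seed = 5L, ...) {
  args <- utils::modifyList(
    list(n_species = 12L, n_orders = 4L, n_countries = 3L,
         year_range = c(2000L, 2003L),
         order_cv = 0, species_cv = 0, thin_rate = 0, dry_frac = 0,
         pue_sigma = 0, pue_n = 1L, seed = seed),
    list(...))
  do.call(synth_config, args)
}

# hand-built micro tables for arithmetic oracles
micro_conc <- function() {
  data.table::data.table(
    species = c("sA", "sA", "sA", "sB", "sC", "sC", "sD"),
    order   = c("o1", "o1", "o1", "o1", "o2", "o2", "o2"),
    group   = c("finfish", "finfish", "finfish", "finfish",
                "crustacean", "crustacean", "crustacean"),
    value   = c(0.004, 0.006, 0.005, 0.004, 0.003, 0.005, 0.004),
    basis   = "wet", moisture = NA_real_, origin = "wild")
}

micro_production <- function() {
  data.table::data.table(
    year = 2000L,
    country = c("X", "X", "Y", "Y"),
    species = c("sA", "sB", "sC", "sD"),
    order = c("o1", "o1", "o2", "o2"),
    group = c("finfish", "finfish", "crustacean", "crustacean"),
    environment = c("marine", "freshwater", "marine", "freshwater"),
    source = c("capture", "aquaculture", "capture", "aquaculture"),
    weight = c(10, 5, 2, 1))
}

micro_pue <- function() {
  data.table::data.table(
    group6 = rep(c("freshwater_finfish", "marine_finfish",
                   "freshwater_crustacean", "marine_crustacean",
                   "marine_mollusk"), each = 3),
    value = c(0.1, 0.2, 0.3,  0.15, 0.25, 0.35,
              0.05, 0.1, 0.15, 0.08, 0.12, 0.2,  0.2, 0.3, 0.4),
    system = "pond", country = "X")
}
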