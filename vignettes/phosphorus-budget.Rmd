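---
title: "The fishery phosphorus budget: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The fishery phosphorus budget: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fisheryP)
library(data.table)
```

## The model

`fisheryP` treats the global fishery as two opposing phosphorus fluxes
across the aquatic–land boundary.

**P-harvest** is the P mass leaving aquatic systems in harvested fish
biomass,

$$P_{\mathrm{hat}} = \sum_{i=1}^{n} W_i \, R_i ,$$

where \(W_i\) is live-weight production (Tg yr\(^{-1}\)) and \(R_i\) the
whole-body P mass fraction per live weight of species \(i\). Whole-body
concentration (bone included) is the right trait here — food-composition
tables for edible portions understate it badly, since the skeleton carries
most of a fish's P.

**P-input** is the P entering aquatic systems as aquaculture feed and
fertilizer. Direct bottom-up feed accounting is not feasible globally, so
the input is inferred from what came out: harvested P divided by the
culture-system-level phosphorus-use efficiency (PUE = harvested P / input
P), in six environment × taxon groups \(j\),

$$P_{\mathrm{inp}} = \sum_{j=1}^{6} P_{\mathrm{hat},j} / PUE_j .$$

**P-net** \(= P_{\mathrm{hat}} - P_{\mathrm{inp}}\) is the quantity of
interest: positive means the fishery returns P to land–human systems,
negative means fish production is a net P load on inland and coastal
waters.

Assumptions built into this accounting:

* Wild capture requires no external P input; only aquaculture rows enter
  \(P_{\mathrm{inp}}\).
* Discarded catch never appears: production records are landed/harvested
  biomass, and discards stay in the water.
* Aquatic plants (no substantial P input, low P content) and mammals are
  excluded from the budget; the readers accept and the filters drop them.
* PUE is time-invariant within a group: the compiled culture-system data
  show no detectable temporal trend, so one empirical pool serves all
  years.
* Brackish-water production is folded into marine throughout, matching how
  production statistics report it.

## Pipeline stages and their parameters

**1. Catch scaling.** Reported wild capture understates true landings, so
capture rows are multiplied by country × year reconstruction factors.
Factors end before the production record does (default last factor year
2014): later years reuse each country's last factor; missing (country,
year) pairs use that year's cross-country mean. A `marine_only` switch
restricts scaling to marine capture — the reconstruction databases cover
marine catch, but the default scales all capture rows, treating the factors
as a general under-reporting correction.

**2. Concentration resolution** (`resolve_pools()`, `cutoff`, default 1).
Each produced species gets a sampling pool:

| situation | pool | sampling |
|---|---|---|
| records > cutoff | the species' own records | uniform over members |
| 1..cutoff records | species mean, order CV | normal(mean, mean × order CV), truncated > 0 |
| no records | order pool (if > cutoff), else group pool | uniform over members |
| outside the three groups | whole database | uniform over members |

The CV-rescaling keeps the species-level average (so thin species are not
dragged to the order mean) while borrowing a realistic spread from the
order. When the order pool is itself at or below the cutoff, the same rule
falls through to the group and finally whole-database CV — the natural
extension of the order-level rule one level down. Budgets are insensitive
to the cutoff in the source analysis, and `cutoff` remains exposed for
sensitivity runs. Point estimates always use the pool **mean** (medians
would be biased in small pools).

**3. P-input.** Group PUE central values are **medians** — the PUE
distribution is strongly right-skewed, spanning roughly 1–167% (values
above 100% occur where systems mine P stored in sediments or unmeasured
inputs), and the median represents a typical system better than the mean.
Freshwater mollusks have no measured systems; the marine mollusk pool
substitutes. Other-invertebrate aquaculture is assigned to a configurable
PUE group (finfish by default) and logged.

**4. Monte Carlo** (`mc_config()`). Default 1000 replicates; each draws

* one concentration per species per replicate (shared across countries and
  years — the same species should not have independent chemistry in two
  places within one replicate),
* one biomass factor per production record, uniform on
  \([W(1-\ell/2),\, W(1+\ell/2)]\) with level \(\ell \in \{0, 0.5, 1\}\)
  (default 0.5, i.e. ±25%): the stated "50% uncertainty" names the total
  relative width of the interval, the distribution itself being unstated we
  choose the maximum-entropy uniform,
* one PUE per group per replicate, uniformly from the group's empirical
  pool — PUE is a group-level parameter, so drawing per record would
  artificially cancel its variance.

Replicate summaries report the **mean** and the **interquartile range**
(25th/75th percentiles). IQR rather than a wider band because the skewed
PUE pool makes extremes unstable under the limited pool sizes. Quantiles
use linear interpolation (R type 7) everywhere — with 1000 replicates the
interpolation rule is visible in the third decimal, so it is fixed and
documented, and `efficiency_percentiles()` uses the same rule.

**5. Trends.** Aggregations are plain sums, so global = Σ continents = Σ
countries to machine precision (tests assert ≤ 1e-13 relative, allowing
reordered summation). The peak is the earliest-year argmax (deterministic
tie-break). The zero crossing is the first year from which P-net stays
negative through the end of the series — a persistence definition, robust
to single-year noise; series that never turn return `Inf`, formatted as
"> last-year", since regional balances can stay positive throughout.
Replicate distributions of both statistics give their IQRs.

**6. Scenarios.** The baseline projection holds wild capture (and its
harvested P) at its window mean (default 2005–2014), grows aquaculture to a
target tonnage (default 140 Tg), converts it to P with a concentration
derived from the window (harvested P per tonne of aquaculture output,
overridable), and divides by the PUE assumption (default 20%). The
P-neutral PUE is closed-form: \(PUE^\* = P_{\mathrm{hat,aqua}} /
P_{\mathrm{hat,total}}\), the unique fixed point making P-net zero
(re-projection at \(PUE^\*\) yields |P-net| < 1e-12, tested).

`weighted_pue()` exposes **two** weighting schemes for turning group
efficiencies into one aquaculture-wide number. The arithmetic scheme
\(\sum_j s_j e_j\) matches how published retention percentiles are combined
into a headline PUE target; the harmonic scheme \(1/\sum_j (s_j/e_j)\) is
what the group-wise input sum actually implies for a single equivalent
PUE. Arithmetic ≥ harmonic always (weighted AM–HM inequality, property-
tested), so the arithmetic headline is the optimistic reading; both are
reported rather than silently choosing one.

## What the synthetic generator emulates — and what it does not

`generate_all()` produces the five input tables with the statistical
structure the analysis assumes:

* a three-level taxonomy (default 224 species in 40 orders, the scale of
  real whole-body P compilations) with finfish-heavy order allocation;
* concentrations lognormal around latent species means around order means
  around group means (defaults: finfish 0.7%, crustacean 0.4%, mollusk
  0.2% of wet weight — plausible wet-basis whole-body values that put the
  modern global harvest near 1 Tg P yr\(^{-1}\)); 30% of species are
  "thin" (0 or 1 records, half each) to exercise every fallback branch;
  25% of records are stored dry-basis, some with unreported moisture, to
  exercise the wet-basis conversion and its database-mean fallback;
* wild capture logistic (19 Tg at 1950, plateau ~92 Tg after 1990) and
  aquaculture near-exponential after a 1980 takeoff — the 2016/1950 total
  ratio lands near 8, as in the real record;
* production concentrated across countries (geometric shares; one dominant
  producer, as China dominates real aquaculture) and species (Zipf-like, as
  carps dominate farmed tonnage);
* right-skewed lognormal PUE truncated to [0.01, 1.67] with finfish medians
  above crustacean (the one robust contrast in compiled systems) and an
  empty freshwater-mollusk group so the substitution rule runs;
* scaling-factor yearly means interpolating 1.29 (first year) → 1.06
  (2004), held to 2014, with zero-sum country offsets.

The latent species means and the closed-form budget they imply
(`true_p_harvest()`) are emitted as ground truth.

Not emulated: real species/country identities, trade flows, reporting
revisions, correlated errors between countries, within-species temporal
trends in concentration, or any covariance between species' concentrations
(the sampling is independent, as in the source analysis). A green test on
synthetic data therefore establishes that the *machinery* is correct —
conservation, determinism, unbiasedness, calibration — not that any
particular published flux value is reproduced; the only published numbers
asserted are the closed-form worked examples (the 2050 baseline arithmetic
and the 48% weighted-retention PUE).

## Numerical choices and degenerate inputs

* **Truncation** of rescaled normal concentration draws at > 0 is by
  rejection (redraw); at observed CVs the rejected mass is negligible, so
  the mean shift is immaterial.
* **Zero-variance worlds** (all CVs 0, singleton PUE pools, biomass level
  0) collapse the Monte Carlo to the deterministic pipeline *exactly*;
  tests assert equality at 1e-14 and against hand-written
  \(\sum W R\) / \(\sum P/PUE\) oracles.
* **"Truth" in calibration tests** is the closed-form point budget (pool
  means), i.e. the quantity the Monte Carlo estimates. Against the
  generator's latent means the MC mean carries an irreducible
  finite-records bias, which is a property of any empirical-pool resampling
  scheme, not a defect of the implementation; the 3-standard-error and
  IQR-coverage checks are therefore run against the closed form.
* **Seeds.** Every generator consumes `seed + fixed offset` (documented in
  `synth_config()`), so single tables can be regenerated independently;
  `run_monte_carlo()` seeds once and draws in a fixed order (concentrations
  by species, PUE by group, then biomass by replicate). Identical seed and
  inputs give byte-identical outputs, tested via file hashes.
* **Empty/degenerate inputs**: empty production yields zero-row budgets;
  single replicates give mean = q25 = q75; singleton pools always return
  their value; a zero share denominator yields `NA` shares rather than
  `Inf`.

## Known limitations

* P-input inherits all structural uncertainty of the PUE pools; with pools
  of tens of entries per group the input IQR is wide and right-skewed, and
  extreme percentiles should not be trusted.
* The record-level budget holds concentration constant across ontogeny,
  season and origin (wild vs raised) within a species.
* The 2050 projection is a single-point snapshot, not a year-by-year path,
  and takes the aquaculture tonnage target as given.
* Continental assignment ships as a configurable mapping (with optional
  era splits for dissolved states); no authoritative mapping is bundled.
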