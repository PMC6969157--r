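# Schemas, CSV readers/writers, vocabulary enforcement and basis/unit
# normalization for the five input tables. Tg (1e6 tonnes) is the only mass
# unit past this boundary.

GROUPS_ALL    <- c("finfish", "crustacean", "mollusk", "other_invertebrate",
                   "aquatic_plant", "mammal")
GROUPS_BUDGET <- c("finfish", "crustacean", "mollusk", "other_invertebrate")
GROUPS_MAJOR  <- c("finfish", "crustacean", "mollusk")
ENVIRONMENTS  <- c("freshwater", "marine")
SOURCES       <- c("capture", "aquaculture")

#' Six environment-by-taxon PUE group keys
#'
#' The culture-system phosphorus-use-efficiency database is pooled into six
#' groups: \{freshwater, marine\} crossed with \{finfish, crustacean,
#' mollusk\}. All PUE lookups are indexed by these keys.
#'
#' @return Character vector of the six keys, e.g. `"freshwater_finfish"`.
#' @export
#' @examples
#' group6_keys()
group6_keys <- function() {
  as.vector(outer(ENVIRONMENTS, GROUPS_MAJOR, paste, sep = "_"))
}

# schema registry: column -> type, plus per-schema vocabularies and checks
.schemas <- list(
  production = list(
    columns  = c(year = "integer", country = "character",
                 species = "character", order = "character",
                 group = "character", environment = "character",
                 source = "character", weight = "numeric"),
    optional = c("order", "units"),
    vocab    = list(group = NULL,   # filled below (GROUPS_ALL)
                    environment = c("freshwater", "marine", "brackish"),
                    source = NULL)
  ),
  concentration = list(
    columns  = c(species = "character", order = "character",
                 group = "character", value = "numeric",
                 basis = "character", moisture = "numeric",
                 origin = "character"),
    optional = c("moisture", "origin"),
    vocab    = list(basis = c("wet", "dry"), origin = c("wild", "raised"))
  ),
  pue = list(
    columns  = c(group6 = "character", value = "numeric",
                 system = "character", country = "character"),
    optional = c("system", "country"),
    vocab    = list(group6 = NULL)   # filled below (group6_keys)
  ),
  pre = list(
    columns  = c(group = "character", value = "numeric"),
    optional = character(),
    vocab    = list(group = NULL)    # GROUPS_MAJOR
  ),
  scaling = list(
    columns  = c(country = "character", year = "integer", factor = "numeric"),
    optional = character(),
    vocab    = list()
  )
)
.schemas$production$vocab$group    <- GROUPS_ALL
.schemas$production$vocab$source   <- SOURCES
.schemas$pue$vocab$group6          <- group6_keys()
.schemas$pre$vocab$group           <- GROUPS_MAJOR

#' Validate a table against one of the five input schemas
#'
#' Checks required columns, coerces types, enforces closed vocabularies,
#' folds brackish environments into marine, and converts tonnes to Tg when a
#' `units` column says `"tonnes"`. Errors name the offending row and field.
#'
#' @param x A data.frame-like table.
#' @param schema One of `"production"`, `"concentration"`, `"pue"`, `"pre"`,
#'   `"scaling"`.
#' @return A validated `data.table`.
#' @export
validate_table <- function(x, schema = names(.schemas)) {
  schema <- match.arg(schema)
  sc <- .schemas[[schema]]
  dt <- data.table::as.data.table(x)

  required <- setdiff(names(sc$columns), sc$optional)
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols))
    stop(sprintf("%s table: missing required column(s): %s",
                 schema, paste(missing_cols, collapse = ", ")), call. = FALSE)

  for (col in intersect(names(sc$columns), names(dt))) {
    target <- sc$columns[[col]]
    dt[[col]] <- switch(target,
      integer   = as.integer(dt[[col]]),
      numeric   = as.numeric(dt[[col]]),
      character = as.character(dt[[col]]))
  }

  for (col in names(sc$vocab)) {
    if (!col %in% names(dt)) next
    ok <- is.na(dt[[col]]) | dt[[col]] %in% sc$vocab[[col]]
    if (!all(ok))
      stop(sprintf("%s table row %d: field '%s' has value '%s' outside {%s}",
                   schema, which(!ok)[1], col, dt[[col]][which(!ok)[1]],
                   paste(sc$vocab[[col]], collapse = ", ")), call. = FALSE)
  }

  if (schema == "production") {
    # brackish water reported with marine throughout
    dt[environment == "brackish", environment := "marine"]
    if ("units" %in% names(dt)) {
      tn <- !is.na(dt$units) & dt$units == "tonnes"
      dt[tn, weight := weight / 1e6]
      dt[, units := NULL]
    }
    bad <- which(is.na(dt$weight) | dt$weight < 0)
    if (length(bad))
      stop(sprintf("production table row %d: field 'weight' is negative or missing",
                   bad[1]), call. = FALSE)
  }
  if (schema == "concentration") {
    bad <- which(is.na(dt$value) | dt$value <= 0)
    if (length(bad))
      stop(sprintf("concentration table row %d: field 'value' must be > 0",
                   bad[1]), call. = FALSE)
    if ("moisture" %in% names(dt)) {
      bad <- which(!is.na(dt$moisture) & (dt$moisture <= 0 | dt$moisture >= 1))
      if (length(bad))
        stop(sprintf("concentration table row %d: field 'moisture' must be in (0,1)",
                     bad[1]), call. = FALSE)
    } else dt[, moisture := NA_real_]
  }
  if (schema == "pue") {
    bad <- which(is.na(dt$value) | dt$value <= 0 | dt$value > 1.67)
    if (length(bad))
      stop(sprintf("pue table row %d: field 'value' must be in (0, 1.67]",
                   bad[1]), call. = FALSE)
  }
  if (schema == "pre") {
    bad <- which(is.na(dt$value) | dt$value <= 0 | dt$value > 1)
    if (length(bad))
      stop(sprintf("pre table row %d: field 'value' must be in (0, 1]",
                   bad[1]), call. = FALSE)
  }
  if (schema == "scaling") {
    bad <- which(is.na(dt$factor) | dt$factor <= 0)
    if (length(bad))
      stop(sprintf("scaling table row %d: field 'factor' must be > 0",
                   bad[1]), call. = FALSE)
  }
  dt[]
}

#' Read and validate one of the five input tables from CSV
#'
#' @param path Path to a CSV file whose header matches the schema.
#' @param schema Schema name, see [validate_table()].
#' @return A validated `data.table`.
#' @export
read_table <- function(path, schema = names(.schemas)) {
  schema <- match.arg(schema)
  if (!file.exists(path))
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  dt <- tryCatch(
    data.table::fread(path, na.strings = c("", "NA")),
    error = function(e) stop(sprintf("failed to parse CSV '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE))
  validate_table(dt, schema)
}

#' Write a table to CSV
#'
#' Plain CSV writer used for all pipeline outputs; the inverse of
#' [read_table()] for the five input schemas (round-trip safe).
#'
#' @param x Table to write.
#' @param path Output path; parent directories are created.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(data.table::as.data.table(x), path)
  invisible(path)
}

#' Convert concentration values to wet (live-weight) basis
#'
#' Dry-basis whole-body P concentrations are converted with
#' `wet = dry * (1 - moisture)` using the record's own moisture content when
#' reported, otherwise the database-average moisture. Wet-basis values pass
#' through unchanged, so the operation is idempotent.
#'
#' @param value Numeric concentration (P mass fraction).
#' @param basis `"wet"` or `"dry"`, recycled.
#' @param moisture Record moisture fraction in (0,1), `NA` if unreported.
#' @param mean_moisture Fallback moisture (database average).
#' @return Wet-basis P mass fraction.
#' @export
#' @examples
#' to_wet_basis(0.02, "dry", moisture = 0.75)  # 0.005
to_wet_basis <- function(value, basis, moisture = NA_real_,
                         mean_moisture = NA_real_) {
  n <- length(value)
  basis <- rep_len(basis, n); moisture <- rep_len(moisture, n)
  m <- ifelse(is.na(moisture), mean_moisture, moisture)
  dry <- basis == "dry"
  if (any(dry & is.na(m)))
    stop("dry-basis record with no moisture and no mean_moisture available",
         call. = FALSE)
  out <- value
  out[dry] <- value[dry] * (1 - m[dry])
  out
}

#' Normalize a concentration table to wet basis
#'
#' Applies [to_wet_basis()] to every record. The database-average moisture
#' (mean of reported moisture values) supplies the fallback for dry-basis
#' records that lack their own; it is computed from the table itself because
#' upstream sources do not publish a canonical value.
#'
#' @param conc Concentration table (schema `"concentration"`).
#' @return The table with `value` on wet basis and `basis` set to `"wet"`.
#' @export
normalize_concentration <- function(conc) {
  conc <- validate_table(conc, "concentration")
  mm <- mean(conc$moisture, na.rm = TRUE)
  if (is.nan(mm)) mm <- NA_real_
  conc[, value := to_wet_basis(value, basis, moisture, mm)]
  conc[, basis := "wet"]
  bad <- which(conc$value <= 0 | conc$value >= 0.1)
  if (length(bad))
    stop(sprintf("concentration table row %d: wet-basis value %.4g outside (0, 0.1)",
                 bad[1], conc$value[bad[1]]), call. = FALSE)
  conc[]
}

#' Drop production groups that do not enter the P budget
#'
#' Aquatic plants and mammals are readable but excluded from the budget:
#' plant farming needs no substantial P input and mammal production is not
#' counted in harvested fish P.
#'
#' @param production Production table.
#' @return Production restricted to finfish, crustaceans, mollusks and other
#'   aquatic invertebrates.
#' @export
filter_budget_groups <- function(production) {
  dt <- data.table::as.data.table(production)
  dt[group %in% GROUPS_BUDGET]
}

#' Write a JSON run manifest
#'
#' Records input-file MD5 hashes, the configuration snapshot, seed, package
#' version, per-stage row counts and a timestamp — enough to reproduce a run
#' bit for bit.
#'
#' @param path Output path for the manifest JSON.
#' @param inputs Named character vector of input file paths (hashed).
#' @param config List; configuration snapshot.
#' @param seed Integer seed used for the run.
#' @param counts Named list/vector of row counts per stage.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, inputs = character(), config = list(),
                           seed = NA_integer_, counts = list()) {
  hashes <- if (length(inputs)) {
    h <- tools::md5sum(unname(unlist(inputs)))
    stats::setNames(as.list(unname(h)), names(inputs))
  } else list()
  manifest <- list(
    package   = "fisheryP",
    version   = as.character(utils::packageVersion("fisheryP")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed      = seed,
    inputs    = hashes,
    config    = config,
    row_counts = counts)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
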