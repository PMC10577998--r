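#' Column-role schema for a country panel
#'
#' Maps the roles the analysis needs to the column names of an input CSV.
#' Defaults are the canonical names used throughout the package (and
#' emitted by [simulate_country_panel()]).
#'
#' @param country,exposure_index,outcome_raw,baseline_outcome_log Column
#'   names for the identifier, continuous exposure index, raw outcome
#'   (age-standardized DALYs per 100,000) and log pre-exposure outcome.
#' @param confounders Named character vector mapping confounder roles to
#'   columns: socio-demographic index (`sdi`, 0-1), unemployment rate
#'   (percent of labour force), income-inequality top-10% share
#'   (`inequality`, 0-1), urbanization index (0-1).
#' @param precision Named character vector of precision covariates:
#'   childhood-sexual-abuse summary exposure value (`csa_sev`, 0-100),
#'   data-quality rating (`quality_stars`, integer 1-5), healthcare
#'   access and quality index (`haq`, 0-100).
#'
#' @return A named list of class `panel_schema`.
#' @export
panel_schema <- function(country = "country",
                         exposure_index = "exposure_index",
                         outcome_raw = "outcome_raw",
                         baseline_outcome_log = "baseline_outcome_log",
                         confounders = c(sdi = "sdi",
                                         unemployment = "unemployment",
                                         inequality = "inequality",
                                         urbanization = "urbanization"),
                         precision = c(csa_sev = "csa_sev",
                                       quality_stars = "quality_stars",
                                       haq = "haq")) {
  structure(list(country = country,
                 exposure_index = exposure_index,
                 outcome_raw = outcome_raw,
                 baseline_outcome_log = baseline_outcome_log,
                 confounders = confounders,
                 precision = precision),
            class = "panel_schema")
}

# flat role -> column map
.schema_map <- function(schema) {
  c(country = schema$country,
    exposure_index = schema$exposure_index,
    outcome_raw = schema$outcome_raw,
    baseline_outcome_log = schema$baseline_outcome_log,
    schema$confounders, schema$precision)
}

#' Default covariate set for the nuisance regressions
#'
#' Confounders, the log pre-exposure outcome and the precision covariates,
#' in the canonical column names.
#'
#' @return Character vector of column names.
#' @export
panel_covariates <- function() {
  c("sdi", "unemployment", "inequality", "urbanization",
    "baseline_outcome_log", "csa_sev", "quality_stars", "haq")
}

#' Read and validate a country-level panel from CSV
#'
#' Reads a UTF-8 CSV with a header row, renames columns to the canonical
#' roles via `schema`, validates that every required cell is numeric and
#' non-missing, and applies the data-quality filter. Rows with missing
#' required fields are dropped with an itemized warning naming each
#' country; rows below `min_quality_stars` are excluded and the exclusion
#' count reported.
#'
#' @param path Path to the CSV file.
#' @param schema A [panel_schema()] mapping roles to columns.
#' @param min_quality_stars Minimum data-quality rating retained
#'   (default 3, the published analytic threshold).
#'
#' @return A tibble with canonical column names; attributes
#'   `rejected_missing` (country ids dropped for missingness) and
#'   `rejected_quality` (ids dropped by the quality filter).
#' @export
read_country_panel <- function(path, schema = panel_schema(),
                               min_quality_stars = 3) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  stopifnot(inherits(schema, "panel_schema"))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  map <- .schema_map(schema)
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("Required column(s) missing from %s: %s",
                  path, paste(missing_cols, collapse = ", ")))
  }
  dat <- raw[, unname(map)]
  names(dat) <- names(map)
  dat <- tibble::as_tibble(dat)

  num_cols <- setdiff(names(map), "country")
  for (col in num_cols) {
    v <- dat[[col]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(coerced))
      if (length(bad) > 0) {
        abort(sprintf(
          "Non-numeric value(s) in column `%s` (source column `%s`) for row(s): %s",
          col, map[[col]], paste(dat$country[bad], collapse = ", ")
        ))
      }
      dat[[col]] <- coerced
    }
  }

  incomplete <- !complete.cases(dat)
  if (any(incomplete)) {
    report <- vapply(which(incomplete), function(i) {
      miss <- names(dat)[is.na(unlist(dat[i, ]))]
      sprintf("%s (missing: %s)", dat$country[i], paste(miss, collapse = ", "))
    }, character(1))
    warn(sprintf("Rejected %d row(s) with missing required fields:\n  %s",
                 sum(incomplete), paste(report, collapse = "\n  ")))
  }
  rejected_missing <- dat$country[incomplete]
  dat <- dat[!incomplete, ]

  low_quality <- dat$quality_stars < min_quality_stars
  rejected_quality <- dat$country[low_quality]
  if (any(low_quality)) {
    inform(sprintf("Excluded %d row(s) below %d quality stars.",
                   sum(low_quality), min_quality_stars))
  }
  dat <- dat[!low_quality, ]
  if (nrow(dat) == 0) abort("No rows retained after validation and filtering.")

  attr(dat, "rejected_missing") <- rejected_missing
  attr(dat, "rejected_quality") <- rejected_quality
  dat
}

#' Write a country panel to CSV in the canonical schema
#'
#' Inverse of [read_country_panel()] for panels already in canonical
#' column names; round-trips exactly.
#'
#' @param data Panel tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_country_panel <- function(data, path) {
  out <- data
  if ("exposure_level" %in% names(out)) {
    out$exposure_level <- as.character(out$exposure_level)
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' Log-transform the raw outcome
#'
#' Adds `outcome_log = log(outcome_raw)` (natural log), preserving the
#' raw column. Non-positive outcomes are an error naming the country.
#'
#' @param data Panel tibble with `outcome_raw`.
#' @param outcome_col Column holding the raw outcome.
#'
#' @return The panel with an `outcome_log` column.
#' @export
log_transform_outcome <- function(data, outcome_col = "outcome_raw") {
  data <- tibble::as_tibble(data)
  y <- data[[outcome_col]]
  if (is.null(y)) abort(sprintf("Column `%s` not found.", outcome_col))
  bad <- which(!(y > 0))
  if (length(bad) > 0) {
    who <- if ("country" %in% names(data)) data$country[bad] else
      paste("row", bad)
    abort(sprintf("Non-positive outcome for: %s", paste(who, collapse = ", ")))
  }
  data$outcome_log <- log(y)
  data
}

#' Remove outcome outliers by sample percentile
#'
#' Drops rows whose outcome is strictly below the `lower_pct` or strictly
#' above the `upper_pct` linear-interpolation sample percentile
#' (`stats::quantile()` type 7). Retained rows are untouched.
#'
#' @param data Panel tibble.
#' @param lower_pct,upper_pct Percentile bounds (defaults 1 and 99).
#' @param outcome_col Column used to compute the percentiles.
#'
#' @return The filtered panel; attribute `removed_outliers` lists dropped
#'   country ids.
#' @export
remove_outcome_outliers <- function(data, lower_pct = 1, upper_pct = 99,
                                    outcome_col = "outcome_raw") {
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) abort("Panel is empty.")
  if (!outcome_col %in% names(data)) {
    abort(sprintf("Column `%s` not found.", outcome_col))
  }
  if (!(lower_pct < upper_pct)) {
    abort("`lower_pct` must be strictly less than `upper_pct`.")
  }
  y <- data[[outcome_col]]
  qs <- quantile(y, probs = c(lower_pct, upper_pct) / 100,
                 type = 7, names = FALSE)
  drop <- y < qs[1] | y > qs[2]
  removed <- if ("country" %in% names(data)) data$country[drop] else
    which(drop)
  if (any(drop)) {
    inform(sprintf("Removed %d outlier row(s): %s", sum(drop),
                   paste(removed, collapse = ", ")))
  }
  out <- data[!drop, ]
  attr(out, "removed_outliers") <- removed
  out
}
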