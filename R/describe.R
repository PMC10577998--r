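#' Per-level descriptive statistics for a panel variable
#'
#' Mean, SD, median and IQR of a variable within each exposure level,
#' plus an overall row. With a single observation in a level the SD is
#' reported as missing.
#'
#' @param data Panel tibble with an `exposure_level` column.
#' @param variable Name of the variable to summarize.
#'
#' @return A tibble with one row per level plus `Overall`.
#' @export
describe_by_level <- function(data, variable) {
  data <- tibble::as_tibble(data)
  if (!variable %in% names(data)) {
    abort(sprintf("Unknown variable `%s`.", variable))
  }
  if (!"exposure_level" %in% names(data)) {
    abort("Panel has no `exposure_level` column.")
  }
  one <- function(v) {
    tibble::tibble(
      n = length(v),
      mean = mean(v),
      sd = if (length(v) > 1) sd(v) else NA_real_,
      median = median(v),
      iqr = IQR(v, type = 7)
    )
  }
  per <- data |>
    dplyr::group_by(.data$exposure_level) |>
    dplyr::reframe(one(.data[[variable]])) |>
    dplyr::rename(level = "exposure_level") |>
    dplyr::mutate(level = as.character(.data$level))
  overall <- dplyr::bind_cols(tibble::tibble(level = "Overall"),
                              one(data[[variable]]))
  dplyr::bind_rows(per, overall) |>
    dplyr::mutate(variable = variable, .before = 1)
}

#' One-way between-group ANOVA across exposure levels
#'
#' Classical between/within variance decomposition via
#' `stats::oneway.test(var.equal = TRUE)`.
#'
#' @param data Panel tibble with `exposure_level`.
#' @param variable Variable to test.
#'
#' @return A one-row tibble: `statistic` (F), `df_between`, `df_within`,
#'   `p.value`, `method`.
#' @export
level_anova <- function(data, variable) {
  data <- tibble::as_tibble(data)
  if (!variable %in% names(data)) {
    abort(sprintf("Unknown variable `%s`.", variable))
  }
  g <- droplevels(factor(data$exposure_level))
  if (nlevels(g) < 2) abort("At least two exposure levels are required.")
  sizes <- table(g)
  if (any(sizes < 2)) {
    abort(sprintf("Each group needs at least 2 observations; too few in: %s",
                  paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  v <- data[[variable]]
  ft <- oneway.test(v ~ g, var.equal = TRUE)
  tibble::tibble(
    variable = variable,
    statistic = unname(ft$statistic),
    df_between = unname(ft$parameter[1]),
    df_within = unname(ft$parameter[2]),
    p.value = unname(ft$p.value),
    method = "one-way ANOVA"
  )
}

#' Kruskal-Wallis rank-sum test across exposure levels
#'
#' Tie-corrected H statistic with a chi-square p-value via
#' `stats::kruskal.test()`. When every value is tied across all groups the
#' statistic is undefined; H = 0 and p = 1 are returned with a warning.
#'
#' @inheritParams level_anova
#'
#' @return A one-row tibble: `statistic` (H), `df`, `p.value`, `method`.
#' @export
level_kruskal <- function(data, variable) {
  data <- tibble::as_tibble(data)
  if (!variable %in% names(data)) {
    abort(sprintf("Unknown variable `%s`.", variable))
  }
  g <- droplevels(factor(data$exposure_level))
  if (nlevels(g) < 2) abort("At least two exposure levels are required.")
  v <- data[[variable]]
  if (length(unique(v)) == 1L) {
    warn("All values tied across groups; returning H = 0, p = 1.")
    return(tibble::tibble(variable = variable, statistic = 0,
                          df = nlevels(g) - 1, p.value = 1,
                          method = "Kruskal-Wallis rank sum test"))
  }
  kt <- kruskal.test(v, g)
  tibble::tibble(
    variable = variable,
    statistic = unname(kt$statistic),
    df = unname(kt$parameter),
    p.value = unname(kt$p.value),
    method = "Kruskal-Wallis rank sum test"
  )
}

#' Descriptive comparison table across exposure levels
#'
#' Combines [describe_by_level()] with the group-comparison tests into the
#' mean (SD) / median (IQR) + test-statistic layout used in descriptive
#' tables of level-structured analyses.
#'
#' @param data Panel tibble.
#' @param variables Character vector of variables to summarize.
#'
#' @return A list with `summary` (long per-level tibble) and `tests`
#'   (one row per variable: ANOVA F/p and Kruskal-Wallis H/p).
#' @export
descriptive_comparison <- function(data, variables) {
  summary <- purrr::map_dfr(variables, ~ describe_by_level(data, .x))
  tests <- purrr::map_dfr(variables, function(v) {
    a <- level_anova(data, v)
    k <- level_kruskal(data, v)
    tibble::tibble(variable = v,
                   anova_f = a$statistic, anova_p = a$p.value,
                   kruskal_h = k$statistic, kruskal_p = k$p.value)
  })
  list(summary = summary, tests = tests)
}
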