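#' Run the full targeted-learning study on a panel
#'
#' Orchestrates the complete analysis over the sensitivity grid: for each
#' outlier-removal setting the two nuisance ensembles are fit once
#' (outcome regression and exposure mechanism); for each trimming
#' percentile the stabilized ratios are trimmed, the targeting step is
#' run and contrasts plus positivity diagnostics are produced.
#'
#' @param panel Panel tibble with `outcome_log`, `exposure_level`, and the
#'   covariate columns.
#' @param covariates Covariate columns (default [panel_covariates()]).
#' @param learners Learner library (default the published five).
#' @param folds Cross-validation folds for the ensembles (default 10).
#' @param seed Integer seed; the whole run is deterministic given it.
#' @param trim_percentiles Trimming grid (default `c(99.9, 99, 97.5)`,
#'   the primary and two sensitivity settings).
#' @param outlier_removal Logical vector over the grid; `c(FALSE, TRUE)`
#'   runs both with and without removing rows outside the 1st-99th
#'   outcome percentiles (default `FALSE` only).
#' @param outcome_col Outcome column name (default `"outcome_log"`).
#'
#' @return An `ecotmle_study` object: `grid` (one row per cell with
#'   list-columns `contrasts`, `diagnostics`, `fit`), `sl_performance`,
#'   `config`.
#' @export
run_study <- function(panel, covariates = panel_covariates(),
                      learners = default_learners(), folds = 10,
                      seed = NULL, trim_percentiles = c(99.9, 99, 97.5),
                      outlier_removal = FALSE,
                      outcome_col = "outcome_log") {
  panel <- tibble::as_tibble(panel)
  if (!is.null(seed)) set.seed(seed)
  config <- list(covariates = covariates,
                 learners = .learner_names(learners), folds = folds,
                 seed = seed, trim_percentiles = trim_percentiles,
                 outlier_removal = outlier_removal,
                 outcome_col = outcome_col, n_input = nrow(panel))

  grid_rows <- list()
  perf_rows <- list()
  for (outliers in outlier_removal) {
    d <- if (outliers) {
      suppressMessages(remove_outcome_outliers(panel,
                                               outcome_col = outcome_col))
    } else panel
    d$outcome_log <- d[[outcome_col]]
    qf <- tryCatch(
      estimate_outcome_regression(d, covariates, learners, folds),
      error = function(e) abort(sprintf("Outcome-regression stage failed: %s",
                                        conditionMessage(e))))
    gf <- tryCatch(
      estimate_propensities(d, covariates, learners, folds),
      error = function(e) abort(sprintf("Exposure-mechanism stage failed: %s",
                                        conditionMessage(e))))
    perf_rows[[length(perf_rows) + 1]] <- tibble::tibble(
      outliers_removed = outliers,
      cv_r_squared = qf$model$performance,
      cv_macro_auc = gf$model$performance)
    for (trim in trim_percentiles) {
      w <- stabilize_and_trim(gf$g, d$exposure_level, trim)
      fit <- tryCatch(
        target_level_means(d, qf$Q, w),
        error = function(e) abort(sprintf("Targeting stage failed: %s",
                                          conditionMessage(e))))
      grid_rows[[length(grid_rows) + 1]] <- tibble::tibble(
        trim_percentile = trim,
        outliers_removed = outliers,
        n = nrow(d),
        contrasts = list(contrasts_vs_reference(fit)),
        diagnostics = list(weight_summary(w)),
        fit = list(fit))
    }
  }
  structure(list(grid = dplyr::bind_rows(grid_rows),
                 sl_performance = dplyr::bind_rows(perf_rows),
                 config = config),
            class = "ecotmle_study")
}

#' @export
print.ecotmle_study <- function(x, ...) {
  cat(sprintf("<ecotmle_study: %d grid cell(s), n = %d>\n",
              nrow(x$grid), x$config$n_input))
  print(contrast_table(x))
  invisible(x)
}

#' Master contrast table of a study
#'
#' Binds the per-cell contrast tables with their grid coordinates.
#'
#' @param study An `ecotmle_study`.
#' @return A tibble with `trim_percentile`, `outliers_removed` and the
#'   contrast columns.
#' @export
contrast_table <- function(study) {
  stopifnot(inherits(study, "ecotmle_study"))
  purrr::pmap_dfr(study$grid, function(trim_percentile, outliers_removed,
                                       n, contrasts, ...) {
    dplyr::bind_cols(tibble::tibble(trim_percentile = trim_percentile,
                                    outliers_removed = outliers_removed),
                     tidy(contrasts))
  })
}

#' @method tidy ecotmle_study
#' @export
tidy.ecotmle_study <- function(x, ...) contrast_table(x)

#' @method glance ecotmle_study
#' @export
glance.ecotmle_study <- function(x, ...) {
  diag <- purrr::map_dfr(seq_len(nrow(x$grid)), function(i) {
    d <- x$grid$diagnostics[[i]]
    overall <- d[d$level == "Overall", ]
    tibble::tibble(trim_percentile = x$grid$trim_percentile[i],
                   outliers_removed = x$grid$outliers_removed[i],
                   max_weight = overall$max_weight,
                   mean_weight = overall$mean_weight)
  })
  dplyr::left_join(diag, x$sl_performance, by = "outliers_removed")
}

#' Run the study across several outcome columns
#'
#' Fits the exposure mechanism once (the covariate set is shared) and
#' reuses its propensities for every outcome, then runs the outcome
#' regression, targeting and contrasts per outcome over the trimming
#' grid.
#'
#' @inheritParams run_study
#' @param outcome_cols Character vector of log-outcome columns.
#'
#' @return Named list of `ecotmle_study`-like bundles, one per outcome;
#'   each contains the shared propensity model.
#' @export
run_multi_outcome <- function(panel, outcome_cols,
                              covariates = panel_covariates(),
                              learners = default_learners(), folds = 10,
                              seed = NULL,
                              trim_percentiles = c(99.9, 99, 97.5)) {
  panel <- tibble::as_tibble(panel)
  missing_cols <- setdiff(outcome_cols, names(panel))
  if (length(missing_cols) > 0) {
    abort(sprintf("Outcome column(s) not found: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!is.null(seed)) set.seed(seed)
  gf <- estimate_propensities(panel, covariates, learners, folds)
  out <- list()
  for (oc in outcome_cols) {
    d <- panel
    d$outcome_log <- d[[oc]]
    qf <- estimate_outcome_regression(d, covariates, learners, folds)
    grid_rows <- list()
    for (trim in trim_percentiles) {
      w <- stabilize_and_trim(gf$g, d$exposure_level, trim)
      fit <- target_level_means(d, qf$Q, w)
      grid_rows[[length(grid_rows) + 1]] <- tibble::tibble(
        trim_percentile = trim, outliers_removed = FALSE, n = nrow(d),
        contrasts = list(contrasts_vs_reference(fit)),
        diagnostics = list(weight_summary(w)),
        fit = list(fit))
    }
    out[[oc]] <- structure(
      list(grid = dplyr::bind_rows(grid_rows),
           sl_performance = tibble::tibble(
             outliers_removed = FALSE,
             cv_r_squared = qf$model$performance,
             cv_macro_auc = gf$model$performance),
           config = list(outcome_col = oc, covariates = covariates,
                         folds = folds, seed = seed,
                         trim_percentiles = trim_percentiles,
                         n_input = nrow(panel)),
           propensity_model = gf$model),
      class = "ecotmle_study")
  }
  out
}

#' Export a study report to disk
#'
#' Writes the master contrast table and weight diagnostics as CSV, a JSON
#' summary (configuration + contrasts), and a forest-plot figure.
#'
#' @param study An `ecotmle_study`, or a named list of them (e.g. from
#'   [run_multi_outcome()]).
#' @param dir Output directory, created if needed.
#'
#' @return Invisibly, the paths written.
#' @export
export_report <- function(study, dir) {
  if (is.list(study) && !inherits(study, "ecotmle_study")) {
    if (length(study) == 0) {
      warn("Empty bundle list; writing an empty report.")
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      p <- file.path(dir, "contrasts.csv")
      readr::write_csv(tibble::tibble(), p)
      return(invisible(p))
    }
    return(invisible(unlist(purrr::imap(
      study, function(s, nm) export_report(s, file.path(dir, nm))))))
  }
  stopifnot(inherits(study, "ecotmle_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ct <- contrast_table(study)
  diag <- glance(study)
  p1 <- file.path(dir, "contrasts.csv")
  p2 <- file.path(dir, "diagnostics.csv")
  p3 <- file.path(dir, "summary.json")
  p4 <- file.path(dir, "forest.png")
  readr::write_csv(ct, p1)
  readr::write_csv(diag, p2)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(list(config = study$config, contrasts = ct,
                              diagnostics = diag),
                         p3, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  g <- autoplot(study)
  ggplot2::ggsave(p4, g, width = 8, height = 1.2 + nrow(ct) * 0.35,
                  dpi = 150)
  invisible(c(p1, p2, p3, p4))
}
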