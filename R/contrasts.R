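#' Marginal-structural-model contrasts against the reference level
#'
#' Expresses the targeted level means as mean log differences versus the
#' reference (lowest) level, with influence-curve Wald inference:
#' `beta_k = psi_k - psi_ref`, `se` from `sd(IC_k - IC_ref)/sqrt(n)`,
#' 95% CI `beta +/- 1.96 se`, normal two-sided p-values. Because the
#' outcome is a natural-log burden, `beta * 100` reads approximately as a
#' percent difference; the exact factor `exp(beta) - 1` is also reported.
#'
#' @param fit A `tmle_fit` from [target_level_means()].
#' @param reference Reference level name (default the lowest level).
#' @param conf.level Confidence level (default 0.95).
#'
#' @return A `msm_contrasts` tibble, highest level first: `level`,
#'   `estimate` (mean log difference), `std.error`, `conf.low`,
#'   `conf.high`, `p.value`, `percent_approx`, `percent_exact`. The
#'   reference mean is in attribute `reference_mean`.
#' @export
contrasts_vs_reference <- function(fit, reference = fit$levels[1],
                                   conf.level = 0.95) {
  stopifnot(inherits(fit, "tmle_fit"))
  if (!reference %in% fit$levels) {
    abort(sprintf("Reference level `%s` not among: %s",
                  reference, paste(fit$levels, collapse = ", ")))
  }
  others <- setdiff(fit$levels, reference)
  others <- rev(others)  # highest level first, the headline row on top
  z <- qnorm(1 - (1 - conf.level) / 2)
  rows <- purrr::map_dfr(others, function(k) {
    beta <- fit$psi[k] - fit$psi[reference]
    ic <- fit$IC[, k] - fit$IC[, reference]
    se <- sd(ic) / sqrt(fit$n)
    p <- if (se > 0) 2 * (1 - pnorm(abs(beta) / se)) else as.numeric(beta == 0)
    tibble::tibble(level = k, reference = reference,
                   estimate = unname(beta), std.error = se,
                   conf.low = unname(beta - z * se),
                   conf.high = unname(beta + z * se),
                   p.value = unname(p))
  })
  rows$percent_approx <- percent_reading(rows$estimate)
  rows$percent_exact <- (exp(rows$estimate) - 1) * 100
  attr(rows, "reference_mean") <- unname(fit$psi[reference])
  attr(rows, "trim_percentile") <- fit$trim_percentile
  class(rows) <- c("msm_contrasts", class(rows))
  rows
}

#' Fit the saturated marginal structural model by least squares
#'
#' Ordinary least squares of the targeted per-country counterfactual
#' predictions (stacked over levels) on dummy regressors for each
#' non-reference level. With a saturated design the coefficients equal
#' the differences of targeted level means, so this is an algebraic
#' cross-check of [contrasts_vs_reference()].
#'
#' @param predictions Long tibble with columns `level` (factor) and
#'   `prediction` (targeted prediction), one row per country per level,
#'   e.g. from stacking the `q_star` matrix of a `tmle_fit`.
#' @param reference Reference level (default the first factor level).
#'
#' @return Tibble of coefficients: `term`, `estimate`; the intercept is
#'   the reference-level mean.
#' @export
fit_saturated_msm <- function(predictions, reference = NULL) {
  predictions <- tibble::as_tibble(predictions)
  if (!all(c("level", "prediction") %in% names(predictions))) {
    abort("`predictions` needs columns `level` and `prediction`.")
  }
  lev <- factor(predictions$level)
  if (!is.null(reference)) lev <- stats::relevel(lev, ref = reference)
  X <- model.matrix(~ lev)
  if (qr(X)$rank < ncol(X)) abort("Rank-deficient dummy design.")
  fit <- lm.fit(X, predictions$prediction)
  est <- fit$coefficients
  names(est) <- c("(Intercept)", levels(lev)[-1])
  tibble::tibble(term = names(est), estimate = unname(est))
}

#' Helper: stack a targeted-prediction matrix into long form
#'
#' @param fit A `tmle_fit`.
#' @return Tibble with `country`, `level`, `prediction`.
#' @export
targeted_predictions <- function(fit) {
  stopifnot(inherits(fit, "tmle_fit"))
  qs <- fit$q_star
  tibble::tibble(
    country = rep(rownames(qs) %||% as.character(seq_len(nrow(qs))),
                  times = ncol(qs)),
    level = factor(rep(colnames(qs), each = nrow(qs)), levels = fit$levels),
    prediction = as.vector(qs)
  )
}

#' Percent reading of a mean log difference
#'
#' Renders a natural-log mean difference as the integer percent obtained
#' by multiplying by 100 (the small-effect approximation
#' `log(1 + d) ~ d`); e.g. 0.31 reads as "31%". Pair with the exact
#' factor `exp(beta) - 1` for large effects.
#'
#' @param beta Numeric vector of log differences.
#' @return Character vector like `"31%"`.
#' @export
#'
#' @examples
#' percent_reading(c(0.31, 0, 0.49))
percent_reading <- function(beta) {
  sprintf("%d%%", as.integer(round(beta * 100)))
}

#' @export
print.msm_contrasts <- function(x, ...) {
  cat(sprintf("<msm_contrasts: vs %s, reference mean %.3f, trim %gth pct>\n",
              x$reference[1], attr(x, "reference_mean"),
              attr(x, "trim_percentile") %||% NA))
  NextMethod()
}

#' @method tidy msm_contrasts
#' @export
tidy.msm_contrasts <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "msm_contrasts")
  out
}
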