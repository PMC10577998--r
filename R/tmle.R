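#' Counterfactual outcome regression over exposure levels
#'
#' Fits one pooled super-learner regression of the log outcome on the
#' covariates plus exposure-level dummies, then predicts for every row
#' with the dummies set to each level in turn, giving the n-by-K matrix
#' of counterfactual outcome predictions Q.
#'
#' @param panel Panel tibble with `outcome_log` and `exposure_level`.
#' @param covariates Character vector of covariate columns
#'   (default [panel_covariates()]).
#' @param learners Learner library (default the five published learners).
#' @param folds,seed Passed to [fit_super_learner()].
#'
#' @return A list with `Q` (n-by-K matrix, log-outcome scale, columns
#'   named by level) and `model` (the `super_learner` fit).
#' @export
estimate_outcome_regression <- function(panel,
                                        covariates = panel_covariates(),
                                        learners = default_learners(),
                                        folds = 10, seed = NULL) {
  panel <- tibble::as_tibble(panel)
  .check_panel_cols(panel, c(covariates, "outcome_log", "exposure_level"))
  lev <- levels(panel$exposure_level)
  x <- panel[, covariates, drop = FALSE]
  if (var(panel$outcome_log) == 0) {
    # constant outcome: the regression is trivial
    Q <- matrix(panel$outcome_log[1], nrow(panel), length(lev),
                dimnames = list(panel$country, lev))
    return(list(Q = Q, model = NULL))
  }
  dummies <- .level_dummies(panel$exposure_level)
  feats <- cbind(data.frame(x), dummies)
  model <- fit_super_learner(feats, panel$outcome_log, mode = "regression",
                             folds = folds, seed = seed, learners = learners)
  Q <- vapply(lev, function(k) {
    d_k <- .level_dummies(factor(rep(k, nrow(panel)), levels = lev))
    predict(model, cbind(data.frame(x), d_k))
  }, numeric(nrow(panel)))
  Q <- matrix(Q, nrow = nrow(panel), dimnames = list(panel$country, lev))
  list(Q = Q, model = model)
}

# K-1 dummy columns with the lowest level as reference
.level_dummies <- function(level) {
  lev <- levels(level)
  out <- vapply(lev[-1], function(k) as.numeric(level == k),
                numeric(length(level)))
  out <- matrix(out, nrow = length(level))
  colnames(out) <- paste0("level_", gsub("[^A-Za-z0-9]", "_", lev[-1]))
  data.frame(out)
}

.check_panel_cols <- function(panel, cols) {
  missing_cols <- setdiff(cols, names(panel))
  if (length(missing_cols) > 0) {
    abort(sprintf("Panel is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (anyNA(panel[, cols])) abort("Panel columns contain missing values.")
}

#' Exposure-mechanism (propensity) estimation
#'
#' Multiclass super-learner fit of the exposure level on the covariates.
#' Predicted probabilities are floored and renormalized so every row is a
#' proper distribution with no zero entries.
#'
#' @inheritParams estimate_outcome_regression
#' @param floor Lower bound applied to each probability before row
#'   renormalization (default `1e-6`).
#'
#' @return A list with `g` (n-by-K propensity matrix, rows summing to 1)
#'   and `model` (the `super_learner` fit).
#' @export
estimate_propensities <- function(panel, covariates = panel_covariates(),
                                  learners = default_learners(),
                                  folds = 10, seed = NULL, floor = 1e-6) {
  panel <- tibble::as_tibble(panel)
  .check_panel_cols(panel, c(covariates, "exposure_level"))
  x <- data.frame(panel[, covariates, drop = FALSE])
  model <- fit_super_learner(x, panel$exposure_level, mode = "multiclass",
                             folds = folds, seed = seed, learners = learners)
  g <- predict(model, x)
  g <- pmax(g, floor)
  g <- g / rowSums(g)
  rownames(g) <- panel$country
  list(g = g, model = model)
}

#' Stabilized, percentile-trimmed density ratios
#'
#' For each country i at its observed level `A_i = k`, the stabilized
#' ratio is `s_ik = p_k / g_ik`, where `p_k` is the empirical marginal
#' frequency of level k; all other cells are zero. Ratios above the
#' `trim_percentile` linear-interpolation sample quantile of the pooled
#' positive ratios (or per level when `per_level = TRUE`) are set to that
#' threshold.
#'
#' @param g n-by-K propensity matrix with rows summing to 1, columns
#'   named by level.
#' @param levels Observed exposure-level factor, one entry per row of `g`.
#' @param trim_percentile Trimming percentile in (0, 100]; 100 means no
#'   trimming (default 99.9, the primary published setting; 99 and 97.5
#'   are the sensitivity settings).
#' @param per_level Trim within each level column instead of pooling.
#'
#' @return A `nuisance_weights` object: `ratios`, `ratios_trimmed`
#'   (n-by-K), `marginals`, `trim_percentile`, `levels`.
#' @export
stabilize_and_trim <- function(g, levels, trim_percentile = 99.9,
                               per_level = FALSE) {
  g <- as.matrix(g)
  levels <- factor(levels, levels = colnames(g))
  if (anyNA(levels)) abort("`levels` contains values not among g's columns.")
  if (nrow(g) != length(levels)) abort("g and levels are not conformal.")
  if (any(abs(rowSums(g) - 1) > 1e-6) || any(g <= 0)) {
    abort("g rows must be positive and sum to 1.")
  }
  if (!(trim_percentile > 0 && trim_percentile <= 100)) {
    abort("`trim_percentile` must be in (0, 100].")
  }
  n <- nrow(g)
  K <- ncol(g)
  marginals <- as.numeric(table(levels)) / n
  names(marginals) <- colnames(g)
  A <- matrix(0, n, K, dimnames = dimnames(g))
  A[cbind(seq_len(n), as.integer(levels))] <- 1
  ratios <- A * matrix(marginals, n, K, byrow = TRUE) / g

  trimmed <- ratios
  if (trim_percentile < 100) {
    if (per_level) {
      for (k in seq_len(K)) {
        pos <- ratios[, k][ratios[, k] > 0]
        if (length(pos) == 0) next
        thr <- quantile(pos, trim_percentile / 100, type = 7, names = FALSE)
        trimmed[, k] <- pmin(ratios[, k], thr)
      }
    } else {
      pos <- ratios[ratios > 0]
      thr <- quantile(pos, trim_percentile / 100, type = 7, names = FALSE)
      trimmed <- pmin(ratios, thr)
    }
    trimmed <- trimmed * (ratios > 0)
  }
  structure(list(ratios = ratios, ratios_trimmed = trimmed,
                 marginals = marginals, trim_percentile = trim_percentile,
                 per_level = per_level, levels = levels),
            class = "nuisance_weights")
}

#' @export
print.nuisance_weights <- function(x, ...) {
  pos <- x$ratios_trimmed[x$ratios_trimmed > 0]
  cat(sprintf(
    "<nuisance_weights: n = %d, K = %d, trim = %gth pct (%s)>\n",
    nrow(x$ratios), ncol(x$ratios), x$trim_percentile,
    if (x$per_level) "per level" else "pooled"))
  cat(sprintf("  stabilized trimmed ratios: mean %.3f, max %.3f\n",
              mean(pos), max(pos)))
  invisible(x)
}

#' Targeted estimation of counterfactual level means
#'
#' The targeting (fluctuation) step of TMLE for a bounded continuous
#' outcome: the log outcome is min-max scaled to `[0, 1]`, the initial
#' predictions Q are scaled likewise and bounded into `[0.005, 0.995]`,
#' and for each level k an intercept-only logistic fluctuation with
#' offset `logit(Q)` is fit by weighted maximum likelihood, using the
#' trimmed stabilized ratios of the rows observed at level k as weights.
#' The targeted counterfactual mean is the sample average of the updated
#' predictions mapped back to the original scale. Influence-curve columns
#' use the trimmed, de-stabilized ratio (trimmed ratio divided by the
#' marginal level frequency), so standard errors are
#' `sd(IC_k) / sqrt(n)`.
#'
#' @param panel Panel tibble with `outcome_log` and `exposure_level`.
#' @param Q n-by-K counterfactual prediction matrix from
#'   [estimate_outcome_regression()].
#' @param weights A `nuisance_weights` object from [stabilize_and_trim()].
#' @param q_bounds Bounds applied to the scaled Q (default
#'   `c(0.005, 0.995)`) to keep the logit finite.
#'
#' @return A `tmle_fit` object: `psi` (targeted level means, log-outcome
#'   scale), `epsilon`, `se`, `IC` (n-by-K), `q_star` (targeted
#'   per-country predictions), `scale_bounds`, `marginals`, `n`.
#' @export
target_level_means <- function(panel, Q, weights,
                               q_bounds = c(0.005, 0.995)) {
  stopifnot(inherits(weights, "nuisance_weights"))
  panel <- tibble::as_tibble(panel)
  .check_panel_cols(panel, c("outcome_log", "exposure_level"))
  y <- panel$outcome_log
  Q <- as.matrix(Q)
  n <- nrow(Q)
  K <- ncol(Q)
  if (n != nrow(panel) || n != nrow(weights$ratios_trimmed)) {
    abort("panel, Q and weights are not conformal.")
  }
  lev <- colnames(Q)
  y_min <- min(y); y_max <- max(y)
  if (y_max <= y_min) abort("Degenerate outcome: no variation in y.")
  scale <- y_max - y_min
  ys <- (y - y_min) / scale
  Qs <- pmin(pmax((Q - y_min) / scale, q_bounds[1]), q_bounds[2])

  rt <- weights$ratios_trimmed
  a <- weights$levels
  epsilon <- numeric(K)
  q_star_s <- matrix(NA_real_, n, K, dimnames = dimnames(Q))
  for (k in seq_len(K)) {
    idx <- which(as.integer(a) == k)
    w_k <- rt[idx, k]
    if (length(idx) == 0 || sum(w_k) <= 0) {
      abort(sprintf("No observed weight at level `%s`.", lev[k]))
    }
    off <- qlogis(Qs[idx, k])
    fit <- suppressWarnings(
      glm(ys[idx] ~ 1 + offset(off), family = quasibinomial(),
          weights = w_k, control = list(epsilon = 1e-12, maxit = 100))
    )
    if (!fit$converged) {
      abort(sprintf(
        "Fluctuation did not converge at level `%s` (n = %d, sum w = %.3g).",
        lev[k], length(idx), sum(w_k)))
    }
    epsilon[k] <- coef(fit)[1]
    q_star_s[, k] <- plogis(qlogis(Qs[, k]) + epsilon[k])
  }
  q_star <- q_star_s * scale + y_min
  psi <- colMeans(q_star)

  marg <- weights$marginals
  IC <- matrix(0, n, K, dimnames = dimnames(Q))
  for (k in seq_len(K)) {
    h <- rt[, k] / marg[k]  # trimmed, de-stabilized clever covariate
    IC[, k] <- h * (y - q_star[, k]) + q_star[, k] - psi[k]
  }
  se <- apply(IC, 2, sd) / sqrt(n)

  structure(list(psi = psi, epsilon = setNames(epsilon, lev), se = se,
                 IC = IC, q_star = q_star, scale_bounds = c(y_min, y_max),
                 marginals = marg, n = n, levels = lev,
                 trim_percentile = weights$trim_percentile),
            class = "tmle_fit")
}

#' @export
print.tmle_fit <- function(x, ...) {
  cat(sprintf("<tmle_fit: %d levels, n = %d, trim = %gth pct>\n",
              length(x$psi), x$n, x$trim_percentile))
  print(tidy(x))
  invisible(x)
}

#' @method tidy tmle_fit
#' @export
tidy.tmle_fit <- function(x, conf.level = 0.95, ...) {
  z <- qnorm(1 - (1 - conf.level) / 2)
  tibble::tibble(level = x$levels,
                 estimate = unname(x$psi),
                 std.error = unname(x$se),
                 conf.low = unname(x$psi - z * x$se),
                 conf.high = unname(x$psi + z * x$se))
}

#' @method glance tmle_fit
#' @export
glance.tmle_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_levels = length(x$psi),
                 trim_percentile = x$trim_percentile,
                 y_min = x$scale_bounds[1], y_max = x$scale_bounds[2],
                 max_abs_ic_mean = max(abs(colMeans(x$IC))))
}

#' Export nuisance and targeting matrices for audit
#'
#' Writes Q, g, the stabilized/trimmed ratios and the influence curves as
#' CSV files with country identifiers as the first column.
#'
#' @param dir Output directory (created if needed).
#' @param country Character vector of row identifiers.
#' @param Q,g Optional matrices from the nuisance steps.
#' @param weights Optional `nuisance_weights` object.
#' @param fit Optional `tmle_fit` object.
#'
#' @return Invisibly, the paths written.
#' @export
export_nuisance_audit <- function(dir, country, Q = NULL, g = NULL,
                                  weights = NULL, fit = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(m, name) {
    df <- tibble::as_tibble(as.data.frame(m))
    df <- dplyr::bind_cols(tibble::tibble(country = country), df)
    p <- file.path(dir, paste0(name, ".csv"))
    readr::write_csv(df, p)
    p
  }
  if (!is.null(Q)) paths <- c(paths, wr(Q, "Q_counterfactual"))
  if (!is.null(g)) paths <- c(paths, wr(g, "g_propensity"))
  if (!is.null(weights)) {
    paths <- c(paths, wr(weights$ratios, "ratios_stabilized"),
               wr(weights$ratios_trimmed, "ratios_trimmed"))
  }
  if (!is.null(fit)) {
    paths <- c(paths, wr(fit$IC, "influence_curves"),
               wr(fit$q_star, "targeted_predictions"))
  }
  invisible(paths)
}
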