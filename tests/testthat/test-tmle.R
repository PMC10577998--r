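test_that("stabilized ratios are one when propensities equal the marginals", {
  p <- tiny_panel()
  g <- marginal_g(p$exposure_level)
  w <- stabilize_and_trim(g, p$exposure_level, 99.9)
  pos <- w$ratios[w$ratios > 0]
  expect_equal(unname(pos), rep(1, nrow(p)))
  expect_equal(w$ratios, w$ratios_trimmed)
  expect_equal(sum(w$marginals), 1)
})

test_that("ratio structure: zero off the observed cell, trimming contracts", {
  set.seed(9)
  n <- 40
  lev <- factor(sample(c("Low", "Mid-Low", "Mid-High", "High"), n, TRUE),
                levels = c("Low", "Mid-Low", "Mid-High", "High"))
  g <- matrix(rgamma(n * 4, 2), n, 4)
  g <- g / rowSums(g)
  colnames(g) <- levels(lev)
  w <- stabilize_and_trim(g, lev, 100)
  A <- outer(as.integer(lev), 1:4, "==")
  expect_true(all(w$ratios[!A] == 0))
  idx <- cbind(seq_len(n), as.integer(lev))
  expect_equal(unname(w$ratios[idx]),
               unname(w$marginals[as.integer(lev)] / g[idx]))
  # trim_percentile = 100 is the identity
  expect_identical(w$ratios, w$ratios_trimmed)
  # trimming never increases a ratio, and lower percentiles trim harder
  maxes <- vapply(c(99.9, 99, 97.5), function(tp) {
    wt <- stabilize_and_trim(g, lev, tp)
    expect_true(all(wt$ratios_trimmed <= wt$ratios + 1e-12))
    max(wt$ratios_trimmed)
  }, numeric(1))
  expect_true(all(diff(maxes) <= 1e-12))
})

test_that("the trimming threshold equals a direct quantile oracle", {
  # ten observed ratios engineered through a 2-level propensity matrix
  target <- c(1.1, 0.8, 2.0, 5.0, 1.4, 0.9, 3.2, 1.0, 1.2, 0.7)
  lev <- factor(rep(c("Low", "High"), 5), levels = c("Low", "High"))
  p_marg <- 0.5
  g <- matrix(0, 10, 2, dimnames = list(NULL, c("Low", "High")))
  g[cbind(1:10, as.integer(lev))] <- p_marg / target
  g[, 1][g[, 1] == 0] <- 1 - g[, 2][g[, 1] == 0]
  g[, 2][g[, 2] == 0] <- 1 - g[, 1][g[, 2] == 0]
  w <- stabilize_and_trim(g, lev, 90)
  thr_oracle <- quantile(target, 0.90, type = 7, names = FALSE)
  expect_equal(max(w$ratios_trimmed), thr_oracle, tolerance = 1e-12)
  expect_equal(sort(unique(pmin(target, thr_oracle))),
               sort(unique(w$ratios_trimmed[w$ratios_trimmed > 0])),
               tolerance = 1e-12)
  # per-level trimming uses within-column quantiles
  wpl <- stabilize_and_trim(g, lev, 80, per_level = TRUE)
  thr_low <- quantile(target[lev == "Low"], 0.8, type = 7, names = FALSE)
  expect_equal(max(wpl$ratios_trimmed[, "Low"]), thr_low, tolerance = 1e-12)
})

test_that("propensity validation rejects malformed inputs", {
  p <- tiny_panel()
  g <- marginal_g(p$exposure_level)
  expect_error(stabilize_and_trim(g, p$exposure_level, 0), "0, 100")
  expect_error(stabilize_and_trim(g[-1, ], p$exposure_level), "conformal")
  gbad <- g
  gbad[1, 1] <- gbad[1, 1] + 0.5
  expect_error(stabilize_and_trim(gbad, p$exposure_level), "sum to 1")
})

test_that("randomized exposure: targeted means equal per-level sample means", {
  # no confounding of the exposure and known marginal propensities
  cfg <- sim_config(n_countries = 400, seed = 77,
                    confounder_effects_on_exposure = c(
                      sdi = 0, unemployment = 0, inequality = 0,
                      urbanization = 0, baseline_outcome_log = 0))
  p <- simulate_country_panel(cfg)
  g <- marginal_g(p$exposure_level)
  rownames(g) <- p$country
  w <- stabilize_and_trim(g, p$exposure_level, 99.9)
  Q <- matrix(mean(p$outcome_log), nrow(p), 4,
              dimnames = list(p$country, levels(p$exposure_level)))
  fit <- target_level_means(p, Q, w)
  oracle <- ipw_level_means(p$outcome_log, p$exposure_level, w)
  sample_means <- tapply(p$outcome_log, p$exposure_level, mean)
  expect_equal(unname(fit$psi), unname(oracle), tolerance = 1e-6)
  expect_equal(unname(fit$psi), as.numeric(sample_means), tolerance = 1e-6)
})

test_that("influence curves solve the score equation and bounds hold", {
  p <- tiny_panel(n_per_level = 8, seed = 13)
  qf <- estimate_outcome_regression(p, covariates = c("x1", "x2"),
                                    learners = linear_only(), folds = 4,
                                    seed = 1)
  g <- marginal_g(p$exposure_level)
  w <- stabilize_and_trim(g, p$exposure_level, 99.9)
  fit <- target_level_means(p, qf$Q, w)
  expect_lt(max(abs(colMeans(fit$IC))), 1e-6)
  expect_true(all(fit$se > 0))
  expect_true(all(fit$psi >= fit$scale_bounds[1] &
                    fit$psi <= fit$scale_bounds[2]))
  expect_equal(unname(colMeans(fit$q_star)), unname(fit$psi))
})

test_that("targeted means are equivariant under affine outcome rescaling", {
  p <- tiny_panel(n_per_level = 8, seed = 17)
  qf <- estimate_outcome_regression(p, covariates = c("x1", "x2"),
                                    learners = linear_only(), folds = 4,
                                    seed = 2)
  g <- marginal_g(p$exposure_level)
  w <- stabilize_and_trim(g, p$exposure_level, 99.9)
  fit1 <- target_level_means(p, qf$Q, w)
  p2 <- p
  p2$outcome_log <- 2 * p$outcome_log + 3
  fit2 <- target_level_means(p2, 2 * qf$Q + 3, w)
  expect_equal(unname(fit2$psi), unname(2 * fit1$psi + 3), tolerance = 1e-8)
  expect_equal(unname(fit2$se), unname(2 * fit1$se), tolerance = 1e-8)
})

test_that("degenerate outcomes are rejected at the right stage", {
  p <- tiny_panel()
  p$outcome_log <- rep(4, nrow(p))
  qf <- estimate_outcome_regression(p, covariates = c("x1", "x2"),
                                    learners = linear_only(), folds = 4)
  # constant outcome short-circuits to a constant Q matrix
  expect_true(all(qf$Q == 4))
  g <- marginal_g(p$exposure_level)
  w <- stabilize_and_trim(g, p$exposure_level, 99.9)
  expect_error(target_level_means(p, qf$Q, w), "Degenerate outcome")
})

test_that("outcome regression recovers level offsets under a linear truth", {
  p <- simulate_country_panel(sim_config(n_countries = 2000, seed = 99))
  qf <- estimate_outcome_regression(p, learners = linear_only(),
                                    folds = 5, seed = 3)
  offsets <- colMeans(qf$Q) - mean(qf$Q[, "Low"])
  expect_equal(unname(offsets[-1]), c(0.13, 0.14, 0.31), tolerance = 0.05)

  p0 <- simulate_country_panel(sim_config(n_countries = 2000,
                                          scenario = "zero_effect",
                                          seed = 98))
  qf0 <- estimate_outcome_regression(p0, learners = linear_only(),
                                     folds = 5, seed = 4)
  expect_lt(max(abs(colMeans(qf0$Q) - mean(qf0$Q[, "Low"]))), 0.05)
})

test_that("propensities approach the marginals under randomized exposure", {
  cfg <- sim_config(n_countries = 2000, seed = 55,
                    confounder_effects_on_exposure = c(
                      sdi = 0, unemployment = 0, inequality = 0,
                      urbanization = 0, baseline_outcome_log = 0))
  p <- simulate_country_panel(cfg)
  gf <- estimate_propensities(p, learners = linear_only(), folds = 5,
                              seed = 5)
  expect_equal(unname(rowSums(gf$g)), rep(1, nrow(p)), tolerance = 1e-8)
  expect_true(all(gf$g > 0))
  marg <- as.numeric(table(p$exposure_level)) / nrow(p)
  # bulk convergence to the marginals; isolated leverage rows converge
  # more slowly, so the tail is judged at the 90th percentile
  dev <- abs(sweep(gf$g, 2, marg))
  expect_lt(mean(dev), 0.03)
  expect_lt(quantile(dev, 0.9, names = FALSE), 0.07)
})

test_that("nuisance audit export writes labelled CSV matrices", {
  p <- tiny_panel(n_per_level = 6, seed = 23)
  qf <- estimate_outcome_regression(p, covariates = c("x1", "x2"),
                                    learners = linear_only(), folds = 4,
                                    seed = 6)
  g <- marginal_g(p$exposure_level)
  w <- stabilize_and_trim(g, p$exposure_level, 99.9)
  fit <- target_level_means(p, qf$Q, w)
  dir <- withr::local_tempdir()
  paths <- export_nuisance_audit(dir, p$country, Q = qf$Q, g = g,
                                 weights = w, fit = fit)
  expect_length(paths, 6)
  expect_true(all(file.exists(paths)))
  q_back <- readr::read_csv(paths[1], show_col_types = FALSE)
  expect_equal(q_back$country, p$country)
  expect_equal(as.matrix(q_back[, -1]), unname(qf$Q), ignore_attr = TRUE)
})
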