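sim_xy <- function(n = 120, seed = 1, noise = 0.1) {
  set.seed(seed)
  x <- data.frame(a = rnorm(n), b = runif(n), c = rnorm(n))
  y <- 1 + 0.8 * x$a - 0.5 * x$b + rnorm(n, 0, noise)
  list(x = x, y = y)
}

sim_xclass <- function(n = 160, seed = 2) {
  set.seed(seed)
  x <- data.frame(a = rnorm(n), b = rnorm(n))
  lp <- cbind(0, 1.2 * x$a, -1 * x$a + x$b, 1.5 * x$b)
  pr <- exp(lp) / rowSums(exp(lp))
  cls <- apply(pr, 1, function(p) sample(4, 1, prob = p))
  y <- factor(c("Low", "Mid-Low", "Mid-High", "High")[cls],
              levels = c("Low", "Mid-Low", "Mid-High", "High"))
  list(x = x, y = y)
}

test_that("a single-learner library receives weight one", {
  d <- sim_xy()
  sl <- fit_super_learner(d$x, d$y, "regression", folds = 5, seed = 1,
                          learners = linear_only())
  expect_equal(unname(sl$weights), 1)
  expect_equal(names(sl$weights), "linear_main_effects")
})

test_that("meta-weights lie on the simplex and beat every vertex", {
  d <- sim_xy(noise = 0.3)
  sl <- fit_super_learner(d$x, d$y, "regression", folds = 5, seed = 3,
                          learners = list(learner_spec("linear_main_effects"),
                                          learner_spec("intercept_only"),
                                          learner_spec("mars")))
  expect_true(all(sl$weights >= 0))
  expect_equal(sum(sl$weights), 1, tolerance = 1e-8)
  # direct evaluation of the meta-objective on the out-of-fold matrix
  Z <- sl$oof
  obj <- function(w) mean((d$y - Z %*% w)^2)
  vertex_risks <- vapply(seq_len(ncol(Z)),
                         function(l) obj(as.numeric(seq_len(ncol(Z)) == l)),
                         numeric(1))
  expect_lte(obj(unname(sl$weights)), min(vertex_risks) + 1e-6)
  expect_equal(unname(vertex_risks), unname(sl$cv_risks), tolerance = 1e-12)
})

test_that("multiclass stack: proper probabilities, simplex, vertex optimality", {
  d <- sim_xclass()
  sl <- fit_super_learner(d$x, d$y, "multiclass", folds = 5, seed = 4,
                          learners = list(learner_spec("linear_main_effects"),
                                          learner_spec("intercept_only"),
                                          learner_spec("ordered_logit")))
  expect_true(all(sl$weights >= 0))
  expect_equal(sum(sl$weights), 1, tolerance = 1e-8)
  pr <- predict(sl, d$x)
  expect_equal(unname(rowSums(pr)), rep(1, nrow(pr)), tolerance = 1e-8)
  expect_true(all(pr >= 1e-7 & pr <= 1))
  # log-loss at the returned weights is no worse than any single learner
  P <- sl$oof
  yi <- cbind(seq_along(d$y), as.integer(d$y))
  loss <- function(w) {
    q <- 0
    for (l in seq_along(w)) q <- q + w[l] * P[, , l][yi]
    -mean(log(pmax(q, 1e-12)))
  }
  vertex <- vapply(seq_len(dim(P)[3]),
                   function(l) loss(as.numeric(seq_len(dim(P)[3]) == l)),
                   numeric(1))
  expect_lte(loss(unname(sl$weights)), min(vertex) + 1e-6)
})

test_that("ensemble predictions are convex combinations of base learners", {
  d <- sim_xy(noise = 0.4)
  learners <- list(learner_spec("linear_main_effects"),
                   learner_spec("intercept_only"))
  sl <- fit_super_learner(d$x, d$y, "regression", folds = 5, seed = 5,
                          learners = learners)
  base <- vapply(names(sl$weights),
                 function(nm) ecotmle:::.predict_learner(sl$fits[[nm]], d$x),
                 numeric(nrow(d$x)))
  ens <- predict(sl, d$x)
  expect_true(all(ens >= apply(base, 1, min) - 1e-10))
  expect_true(all(ens <= apply(base, 1, max) + 1e-10))
  expect_equal(ens, drop(base %*% sl$weights), tolerance = 1e-12)
})

test_that("a fixed seed reproduces folds, weights and predictions exactly", {
  d <- sim_xy()
  sl1 <- fit_super_learner(d$x, d$y, "regression", folds = 5, seed = 42,
                           learners = list(learner_spec("linear_main_effects"),
                                           learner_spec("random_forest",
                                                        n_trees = 50)))
  sl2 <- fit_super_learner(d$x, d$y, "regression", folds = 5, seed = 42,
                           learners = list(learner_spec("linear_main_effects"),
                                           learner_spec("random_forest",
                                                        n_trees = 50)))
  expect_identical(sl1$fold_id, sl2$fold_id)
  expect_identical(sl1$weights, sl2$weights)
  expect_equal(predict(sl1, d$x), predict(sl2, d$x), tolerance = 1e-12)
})

test_that("leave-one-out folds match a brute-force per-row refit oracle", {
  set.seed(42)
  x <- data.frame(a = rnorm(12), b = rnorm(12))
  y <- 1 + x$a - 0.5 * x$b + rnorm(12, 0, 0.1)
  sl <- fit_super_learner(x, y, "regression", folds = 12, seed = 7,
                          learners = linear_only())
  ord <- order(sl$fold_id)  # fold f holds exactly one row
  oracle <- vapply(seq_len(12), function(i) {
    f <- lm(y ~ a + b, data = cbind(x, y = y)[-i, ])
    unname(predict(f, x[i, ]))
  }, numeric(1))
  expect_equal(unname(sl$oof[, 1]), oracle, tolerance = 1e-10)
})

test_that("cross-validated performance metrics behave at their anchors", {
  d <- sim_xy(n = 60)
  sl <- fit_super_learner(d$x, d$y, "regression", folds = 5, seed = 9,
                          learners = linear_only())
  # perfect out-of-fold predictions give R^2 = 1, grand-mean gives ~0
  perfect <- sl
  perfect$oof <- matrix(d$y, ncol = 1,
                        dimnames = list(NULL, "linear_main_effects"))
  expect_equal(cv_performance(perfect), 1)
  null <- sl
  null$oof <- matrix(mean(d$y), length(d$y), 1,
                     dimnames = list(NULL, "linear_main_effects"))
  expect_equal(cv_performance(null), 0, tolerance = 1e-12)

  dc <- sim_xclass(n = 120, seed = 8)
  slc <- fit_super_learner(dc$x, dc$y, "multiclass", folds = 5, seed = 10,
                           learners = linear_only())
  sep <- slc
  # perfectly separating out-of-fold probabilities give macro AUC 1
  m <- matrix(1e-3, length(dc$y), 4, dimnames = list(NULL, levels(dc$y)))
  m[cbind(seq_along(dc$y), as.integer(dc$y))] <- 1
  sep$oof <- array(m / rowSums(m), dim = c(length(dc$y), 4, 1),
                   dimnames = list(NULL, levels(dc$y),
                                   "linear_main_effects"))
  expect_equal(cv_performance(sep), 1)
})

test_that("degenerate targets and infeasible folds raise specific errors", {
  d <- sim_xy(n = 40)
  expect_error(fit_super_learner(d$x, rep(2, 40), "regression", folds = 5,
                                 learners = linear_only()),
               "constant")
  y1 <- factor(c(rep("Low", 39), "High"), levels = c("Low", "High"))
  expect_error(fit_super_learner(d$x, y1, "multiclass", folds = 5,
                                 learners = linear_only()),
               "fewer")
  expect_error(fit_super_learner(d$x, d$y, "regression", folds = 41,
                                 learners = linear_only()),
               "folds")
  expect_error(learner_spec("gradient_boost"), "Unknown learner")
})

test_that("a failing learner is dropped and weights renormalize", {
  d <- sim_xy(n = 60)
  # ordered_logit cannot run in regression mode and fails on every fold
  expect_warning(
    sl <- fit_super_learner(d$x, d$y, "regression", folds = 5, seed = 6,
                            learners = list(
                              learner_spec("linear_main_effects"),
                              learner_spec("ordered_logit"))),
    "dropped")
  expect_equal(names(sl$weights), "linear_main_effects")
  expect_equal(sum(sl$weights), 1)
})

test_that("prediction validates the feature schema", {
  d <- sim_xy(n = 40)
  sl <- fit_super_learner(d$x, d$y, "regression", folds = 5, seed = 2,
                          learners = linear_only())
  expect_error(predict(sl, d$x[, c("a", "b")]), "c")
})
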