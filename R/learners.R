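#' Base-learner specification
#'
#' The stacking ensemble combines the following base learners, with
#' hyperparameters defaulting to the published settings: a linear model
#' with main effects only; forward stepwise regression by AIC; an
#' L1-regularized linear model (penalty chosen by inner cross-validation);
#' multivariate adaptive regression splines (maximum interaction
#' degree 2); and a random forest (500 trees, 2 candidate variables per
#' split, minimum node size 5 for regression and 1 for classification).
#' Two further learners are available for diagnostics and ordinal
#' exposures: `intercept_only` (marginal mean / class frequencies) and
#' `ordered_logit` (proportional-odds logistic regression, multiclass
#' only).
#'
#' @param name One of `"linear_main_effects"`, `"stepwise_forward"`,
#'   `"l1_linear"`, `"mars"`, `"random_forest"`, `"intercept_only"`,
#'   `"ordered_logit"`.
#' @param ... Hyperparameter overrides (e.g. `n_trees = 200`).
#'
#' @return A `learner_spec` object.
#' @export
learner_spec <- function(name, ...) {
  known <- c("linear_main_effects", "stepwise_forward", "l1_linear",
             "mars", "random_forest", "intercept_only", "ordered_logit")
  if (!name %in% known) {
    abort(sprintf("Unknown learner `%s`. Available: %s",
                  name, paste(known, collapse = ", ")))
  }
  defaults <- switch(
    name,
    mars = list(max_interaction_degree = 2, max_terms = 15, n_knots = 7),
    random_forest = list(n_trees = 500, vars_per_split = 2,
                         min_node_size_regression = 5,
                         min_node_size_classification = 1),
    l1_linear = list(inner_folds = 10, n_lambda = 100,
                     unpenalized_pattern = "^level_"),
    list()
  )
  hyper <- modifyList(defaults, list(...))
  structure(list(name = name, hyper = hyper), class = "learner_spec")
}

#' Default learner library
#'
#' The five published base learners with their printed hyperparameters.
#'
#' @return A list of [learner_spec()] objects.
#' @export
default_learners <- function() {
  lapply(c("linear_main_effects", "stepwise_forward", "l1_linear",
           "mars", "random_forest"), learner_spec)
}

.learner_names <- function(learners) {
  vapply(learners, function(l) l$name, character(1))
}

# ---- fitting -----------------------------------------------------------

# x: data.frame of numeric features; y: numeric (regression) or factor
.fit_learner <- function(spec, x, y, mode) {
  hp <- spec$hyper
  dat <- data.frame(x)
  fit <- switch(
    spec$name,
    linear_main_effects = if (mode == "regression") {
      lm(y ~ ., data = cbind(dat, y = y))
    } else {
      nnet::multinom(y ~ ., data = cbind(dat, y = y),
                     trace = FALSE, maxit = 300)
    },
    stepwise_forward = .fit_step_forward(dat, y, mode),
    l1_linear = .fit_l1(dat, y, mode, hp),
    mars = .fit_mars_learner(dat, y, mode, hp),
    random_forest = .fit_rf(dat, y, mode, hp),
    intercept_only = if (mode == "regression") {
      structure(list(mean = mean(y)), class = "ecotmle_const")
    } else {
      structure(list(probs = as.numeric(table(y) / length(y)),
                     levels = levels(y)), class = "ecotmle_const")
    },
    ordered_logit = {
      if (mode != "multiclass") abort("ordered_logit is multiclass-only.")
      MASS::polr(y ~ ., data = cbind(dat, y = factor(y, ordered = TRUE)),
                 method = "logistic", Hess = FALSE)
    }
  )
  structure(list(spec = spec, fit = fit, mode = mode,
                 levels = if (is.factor(y)) levels(y) else NULL,
                 features = names(dat)),
            class = "ecotmle_learner_fit")
}

.fit_step_forward <- function(dat, y, mode) {
  vars <- names(dat)
  if (mode == "regression") {
    d <- cbind(dat, y = y)
    null_fit <- lm(y ~ 1, data = d)
    full_scope <- as.formula(paste("~", paste(vars, collapse = " + ")))
    step(null_fit, scope = list(lower = ~1, upper = full_scope),
         direction = "forward", trace = 0)
  } else {
    # forward AIC over main effects with multinomial logistic fits
    d <- cbind(dat, y = y)
    selected <- character(0)
    fit_with <- function(v) {
      f <- if (length(v) == 0) y ~ 1 else
        as.formula(paste("y ~", paste(v, collapse = " + ")))
      nnet::multinom(f, data = d, trace = FALSE, maxit = 300)
    }
    current <- fit_with(selected)
    current_aic <- AIC(current)
    repeat {
      remaining <- setdiff(vars, selected)
      if (length(remaining) == 0) break
      trials <- lapply(remaining, function(v) fit_with(c(selected, v)))
      aics <- vapply(trials, AIC, numeric(1))
      k <- which.min(aics)
      if (aics[k] >= current_aic - 1e-8) break
      selected <- c(selected, remaining[k])
      current <- trials[[k]]
      current_aic <- aics[k]
    }
    current
  }
}

.fit_l1 <- function(dat, y, mode, hp) {
  xm <- as.matrix(dat)
  if (ncol(xm) < 2) {  # glmnet needs >= 2 columns
    return(if (mode == "regression") lm(y ~ ., data = cbind(dat, y = y))
           else nnet::multinom(y ~ ., data = cbind(dat, y = y),
                               trace = FALSE))
  }
  nf <- max(3, min(hp$inner_folds, floor(nrow(xm) / 3)))
  fam <- if (mode == "regression") "gaussian" else "multinomial"
  # exposure-indicator columns stay unpenalized: shrinking the exposure
  # terms of an outcome model attenuates the very contrast under study
  pf <- rep(1, ncol(xm))
  if (!is.null(hp$unpenalized_pattern)) {
    pf[grepl(hp$unpenalized_pattern, colnames(xm))] <- 0
  }
  glmnet::cv.glmnet(xm, y, family = fam, nfolds = nf,
                    nlambda = hp$n_lambda, standardize = TRUE,
                    penalty.factor = pf)
}

.fit_mars_learner <- function(dat, y, mode, hp) {
  xm <- as.matrix(dat)
  if (mode == "regression") {
    mars_fit(xm, y, degree = hp$max_interaction_degree,
             max_terms = hp$max_terms, n_knots = hp$n_knots)
  } else {
    # one-vs-rest regressions on class indicators
    fits <- lapply(levels(y), function(lv) {
      mars_fit(xm, as.numeric(y == lv), degree = hp$max_interaction_degree,
               max_terms = hp$max_terms, n_knots = hp$n_knots)
    })
    structure(list(fits = fits, levels = levels(y)), class = "ecotmle_ovr")
  }
}

.fit_rf <- function(dat, y, mode, hp) {
  seed <- sample.int(.Machine$integer.max, 1)
  if (mode == "regression") {
    ranger::ranger(x = dat, y = y, num.trees = hp$n_trees,
                   mtry = min(hp$vars_per_split, ncol(dat)),
                   min.node.size = hp$min_node_size_regression,
                   num.threads = 1, seed = seed)
  } else {
    ranger::ranger(x = dat, y = y, num.trees = hp$n_trees,
                   mtry = min(hp$vars_per_split, ncol(dat)),
                   min.node.size = hp$min_node_size_classification,
                   probability = TRUE, num.threads = 1, seed = seed)
  }
}

# ---- prediction --------------------------------------------------------

# returns numeric vector (regression) or n x K probability matrix with
# columns ordered as lfit$levels
.predict_learner <- function(lfit, newx) {
  dat <- data.frame(newx)[, lfit$features, drop = FALSE]
  fit <- lfit$fit
  K <- length(lfit$levels)
  out <- if (inherits(fit, "ecotmle_const")) {
    if (lfit$mode == "regression") rep(fit$mean, nrow(dat)) else
      matrix(fit$probs, nrow(dat), K, byrow = TRUE,
             dimnames = list(NULL, fit$levels))
  } else if (inherits(fit, "ecotmle_mars")) {
    predict(fit, dat)
  } else if (inherits(fit, "ecotmle_ovr")) {
    s <- vapply(fit$fits, function(f) pmax(predict(f, dat), 1e-6),
                numeric(nrow(dat)))
    s <- matrix(s, nrow = nrow(dat))
    colnames(s) <- fit$levels
    s / rowSums(s)
  } else if (inherits(fit, "cv.glmnet")) {
    pr <- predict(fit, newx = as.matrix(dat), s = "lambda.min",
                  type = "response")
    if (lfit$mode == "regression") drop(pr) else {
      m <- pr[, , 1, drop = TRUE]
      m <- matrix(m, nrow = nrow(dat),
                  dimnames = list(NULL, dimnames(pr)[[2]]))
      m
    }
  } else if (inherits(fit, "ranger")) {
    pr <- predict(fit, data = dat, num.threads = 1)$predictions
    pr
  } else if (inherits(fit, "multinom")) {
    pr <- predict(fit, newdata = dat, type = "probs")
    if (is.null(dim(pr))) {  # K == 2 returns P(second level)
      pr <- cbind(1 - pr, pr)
      colnames(pr) <- lfit$levels
    }
    pr
  } else if (inherits(fit, "polr")) {
    predict(fit, newdata = dat, type = "probs")
  } else if (inherits(fit, "lm")) {
    unname(predict(fit, newdata = dat))
  } else {
    abort("Unrecognized learner fit.")
  }

  if (lfit$mode == "multiclass") {
    m <- matrix(0, nrow(dat), K, dimnames = list(NULL, lfit$levels))
    out <- as.matrix(out)
    m[, colnames(out)] <- out
    m <- pmin(pmax(m, 1e-6), 1 - 1e-6)
    m / rowSums(m)
  } else {
    as.numeric(out)
  }
}
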