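#' Fit a cross-validated stacking ensemble (super learner)
#'
#' Stacks a library of base learners by minimizing cross-validated risk
#' (mean squared error for regression, multinomial log-loss for the
#' multiclass exposure mechanism) over the simplex of convex weights.
#' Out-of-fold predictions from a V-fold split are assembled for every
#' learner; the meta-weights minimize the cross-validated risk over the
#' simplex (non-negative least squares followed by simplex-projected
#' gradient refinement for regression; projected gradient descent on the
#' log-loss for multiclass); the base learners are then refit on the full
#' data. A learner that fails on any fold is dropped with a warning and
#' the remaining weights are renormalized.
#'
#' @param x Data frame of numeric features.
#' @param y Numeric response (regression) or factor (multiclass).
#' @param mode `"regression"` or `"multiclass"`.
#' @param folds Number of cross-validation folds (default 10), stratified
#'   by class in multiclass mode.
#' @param seed Optional integer seed; fixes fold assignment and all
#'   learner randomness.
#' @param learners List of [learner_spec()] objects; defaults to the five
#'   published base learners.
#'
#' @return A `super_learner` object with elements `weights` (named simplex
#'   vector), `cv_risks`, `oof` (out-of-fold predictions),
#'   `performance` (cross-validated R-squared or macro one-vs-rest AUC),
#'   `fold_id`, and the refit base learners.
#' @export
fit_super_learner <- function(x, y, mode = c("regression", "multiclass"),
                              folds = 10, seed = NULL,
                              learners = default_learners()) {
  mode <- match.arg(mode)
  x <- data.frame(x)
  n <- nrow(x)
  if (!is.null(seed)) set.seed(seed)
  if (folds < 2 || folds > n) {
    abort(sprintf("Need 2 <= folds <= n; got n = %d, folds = %d.", n, folds))
  }
  if (anyNA(x)) abort("Features contain missing values.")

  if (mode == "regression") {
    y <- as.numeric(y)
    if (var(y) == 0) abort("Degenerate target: outcome is constant.")
  } else {
    y <- droplevels(as.factor(y))
    counts <- table(y)
    if (length(counts) < 2) abort("Degenerate target: a single class.")
    if (any(counts < 2)) {
      abort(sprintf(
        "Class(es) with fewer than 2 observations (%s): use fewer folds or pool levels.",
        paste(names(counts)[counts < 2], collapse = ", ")))
    }
  }

  fold_id <- .assign_folds(y, folds, stratify = (mode == "multiclass"))
  if (mode == "multiclass") {
    for (f in unique(fold_id)) {
      if (nlevels(droplevels(y[fold_id != f])) < nlevels(y)) {
        abort("A class is absent from a training fold; use fewer folds.")
      }
    }
  }

  lnames <- .learner_names(learners)
  if (anyDuplicated(lnames)) abort("Duplicate learner names in the library.")
  L <- length(learners)
  K <- if (mode == "multiclass") nlevels(y) else 1L

  # out-of-fold predictions, learners that error anywhere are dropped
  oof <- array(NA_real_, dim = c(n, K, L),
               dimnames = list(NULL, if (K > 1) levels(y), lnames))
  failed <- rep(FALSE, L)
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f
    for (l in seq_len(L)) {
      if (failed[l]) next
      pred <- tryCatch({
        lf <- .fit_learner(learners[[l]], x[tr, , drop = FALSE], y[tr], mode)
        .predict_learner(lf, x[!tr, , drop = FALSE])
      }, error = function(e) e)
      if (inherits(pred, "error")) {
        failed[l] <- TRUE
        warn(sprintf("Learner `%s` failed on fold %d (%s); dropped.",
                     lnames[l], f, conditionMessage(pred)))
      } else {
        oof[!tr, , l] <- pred
      }
    }
  }
  if (all(failed)) abort("Every learner failed during cross-validation.")
  keep <- which(!failed)

  if (mode == "regression") {
    Z <- oof[, 1, keep, drop = FALSE]
    dim(Z) <- c(n, length(keep))
    colnames(Z) <- lnames[keep]
    cv_risks <- colMeans((Z - y)^2)
    w <- .meta_regression(Z, y)
    ens_oof <- drop(Z %*% w)
    performance <- 1 - sum((y - ens_oof)^2) / sum((y - mean(y))^2)
    oof_store <- Z
  } else {
    P <- oof[, , keep, drop = FALSE]
    yi <- cbind(seq_len(n), as.integer(y))
    cv_risks <- apply(P, 3, function(m) -mean(log(pmax(m[yi], 1e-12))))
    w <- .meta_multiclass(P, as.integer(y))
    ens_oof <- .combine_probs(P, w)
    performance <- .macro_auc(ens_oof, y)
    oof_store <- P
  }
  names(cv_risks) <- lnames[keep]
  names(w) <- lnames[keep]

  # refit kept learners on the full data
  fits <- list()
  for (l in keep) {
    ft <- tryCatch(.fit_learner(learners[[l]], x, y, mode),
                   error = function(e) e)
    if (inherits(ft, "error")) {
      warn(sprintf("Learner `%s` failed on the full data (%s); dropped.",
                   lnames[l], conditionMessage(ft)))
      w <- w[names(w) != lnames[l]]
      cv_risks <- cv_risks[names(cv_risks) != lnames[l]]
    } else {
      fits[[lnames[l]]] <- ft
    }
  }
  if (length(fits) == 0) abort("Every learner failed on the full data.")
  if (sum(w) <= 0) w[] <- 1 / length(w)
  w <- w / sum(w)

  structure(list(mode = mode, learners = learners[keep], fits = fits,
                 weights = w, cv_risks = cv_risks, fold_id = fold_id,
                 oof = oof_store, performance = performance,
                 y = y, levels = if (K > 1) levels(y),
                 features = names(x), n = n, folds = folds, seed = seed),
            class = "super_learner")
}

.assign_folds <- function(y, folds, stratify) {
  n <- length(y)
  fold_id <- integer(n)
  if (stratify) {
    for (lv in levels(y)) {
      idx <- which(y == lv)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  } else {
    fold_id <- sample(rep_len(seq_len(folds), n))
  }
  fold_id
}

# Euclidean projection onto the probability simplex (sort-based)
.project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (1 - css[rho]) / rho
  pmax(v + theta, 0)
}

# simplex-constrained least squares: NNLS warm start + projected gradient
.meta_regression <- function(Z, y, max_iter = 2000, tol = 1e-12) {
  L <- ncol(Z)
  if (L == 1) return(1)
  w <- tryCatch({
    nn <- pracma::lsqnonneg(Z, y)$x
    if (sum(nn) > 0) nn / sum(nn) else rep(1 / L, L)
  }, error = function(e) rep(1 / L, L))
  w <- .project_simplex(w)
  G <- crossprod(Z) / nrow(Z)
  b <- crossprod(Z, y) / nrow(Z)
  step <- 1 / max(2 * max(eigen(G, symmetric = TRUE,
                                only.values = TRUE)$values), 1e-12)
  obj <- function(w) mean((y - Z %*% w)^2)
  cur <- obj(w)
  for (it in seq_len(max_iter)) {
    grad <- 2 * (G %*% w - b)
    w_new <- .project_simplex(drop(w - step * grad))
    new <- obj(w_new)
    if (cur - new < tol && sqrt(sum((w_new - w)^2)) < 1e-10) {
      w <- w_new
      break
    }
    w <- w_new
    cur <- new
  }
  w
}

# simplex-projected gradient descent on multinomial log-loss
.meta_multiclass <- function(P, y_int, max_iter = 1000, tol = 1e-10) {
  n <- dim(P)[1]; L <- dim(P)[3]
  if (L == 1) return(1)
  # S[i, l] = P_l(i, y_i)
  S <- vapply(seq_len(L), function(l) P[, , l][cbind(seq_len(n), y_int)],
              numeric(n))
  S <- pmax(S, 1e-12)
  obj <- function(w) -mean(log(pmax(S %*% w, 1e-12)))
  w <- rep(1 / L, L)
  cur <- obj(w)
  step <- 1
  for (it in seq_len(max_iter)) {
    q <- pmax(drop(S %*% w), 1e-12)
    grad <- -colMeans(S / q)
    repeat {
      w_new <- .project_simplex(w - step * grad)
      new <- obj(w_new)
      if (new <= cur + 1e-14 || step < 1e-12) break
      step <- step / 2
    }
    if (cur - new < tol && sqrt(sum((w_new - w)^2)) < 1e-10) {
      w <- w_new
      break
    }
    w <- w_new
    cur <- new
    step <- min(step * 2, 10)
  }
  # a convex objective: guard that no vertex beats the solution
  vert <- apply(S, 2, function(s) -mean(log(s)))
  if (min(vert) < cur - 1e-10) {
    w <- as.numeric(seq_len(L) == which.min(vert))
  }
  w
}

.combine_probs <- function(P, w) {
  out <- matrix(0, dim(P)[1], dim(P)[2], dimnames = dimnames(P)[1:2])
  for (l in seq_along(w)) out <- out + w[l] * P[, , l]
  out
}

# macro-averaged one-vs-rest AUC with tie handling via average ranks
.macro_auc <- function(probs, y) {
  aucs <- vapply(seq_len(ncol(probs)), function(k) {
    pos <- as.integer(y) == k
    m <- sum(pos); nn <- sum(!pos)
    if (m == 0 || nn == 0) return(NA_real_)
    r <- rank(probs[, k])
    (sum(r[pos]) - m * (m + 1) / 2) / (m * nn)
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Predict from a fitted super learner
#'
#' @param object A `super_learner` fit.
#' @param newdata Data frame with the training feature columns.
#' @param ... Unused.
#'
#' @return Numeric vector (regression) or an n-by-K probability matrix
#'   with rows summing to 1, entries clipped to `[1e-6, 1 - 1e-6]` and
#'   renormalized (multiclass).
#' @export
predict.super_learner <- function(object, newdata, ...) {
  newdata <- data.frame(newdata)
  missing_cols <- setdiff(object$features, names(newdata))
  if (length(missing_cols) > 0) {
    abort(sprintf("newdata is missing feature column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  newdata <- newdata[, object$features, drop = FALSE]
  w <- object$weights
  if (object$mode == "regression") {
    preds <- vapply(names(w),
                    function(nm) .predict_learner(object$fits[[nm]], newdata),
                    numeric(nrow(newdata)))
    preds <- matrix(preds, nrow = nrow(newdata))
    drop(preds %*% w)
  } else {
    K <- length(object$levels)
    out <- matrix(0, nrow(newdata), K, dimnames = list(NULL, object$levels))
    for (nm in names(w)) {
      out <- out + w[nm] * .predict_learner(object$fits[[nm]], newdata)
    }
    out <- pmin(pmax(out, 1e-6), 1 - 1e-6)
    out / rowSums(out)
  }
}

#' Cross-validated performance of a super learner
#'
#' Computed from out-of-fold predictions only: cross-validated R-squared
#' (`1 - SSE/SST`) for regression, macro-averaged one-vs-rest AUC for
#' multiclass.
#'
#' @param model A `super_learner` fit.
#' @param target Target vector; defaults to the training target.
#'
#' @return A single numeric value.
#' @export
cv_performance <- function(model, target = model$y) {
  stopifnot(inherits(model, "super_learner"))
  w <- model$weights
  if (model$mode == "regression") {
    target <- as.numeric(target)
    if (length(target) != model$n) abort("Target length mismatch.")
    Z <- model$oof[, names(w), drop = FALSE]
    ens <- drop(Z %*% w)
    1 - sum((target - ens)^2) / sum((target - mean(target))^2)
  } else {
    target <- factor(target, levels = model$levels)
    if (length(target) != model$n || anyNA(target)) {
      abort("Target does not match the training classes.")
    }
    ens <- .combine_probs(model$oof[, , names(w), drop = FALSE], w)
    .macro_auc(ens, target)
  }
}

#' @export
print.super_learner <- function(x, ...) {
  cat(sprintf("<super_learner: %s, %d learners, %d folds, n = %d>\n",
              x$mode, length(x$weights), x$folds, x$n))
  print(round(x$weights, 4))
  metric <- if (x$mode == "regression") "CV R-squared" else "CV macro AUC"
  cat(sprintf("%s: %.4f\n", metric, x$performance))
  invisible(x)
}

#' @method tidy super_learner
#' @export
tidy.super_learner <- function(x, ...) {
  tibble::tibble(learner = names(x$weights),
                 weight = unname(x$weights),
                 cv_risk = unname(x$cv_risks[names(x$weights)]))
}

#' @method glance super_learner
#' @export
glance.super_learner <- function(x, ...) {
  tibble::tibble(mode = x$mode,
                 metric = if (x$mode == "regression") "cv_r_squared"
                          else "cv_macro_auc",
                 performance = x$performance,
                 n = x$n, folds = x$folds,
                 n_learners = length(x$weights))
}
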