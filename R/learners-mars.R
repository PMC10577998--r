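# Multivariate adaptive regression splines (MARS), compact implementation:
# forward selection of reflected hinge-function pairs with interaction
# degree <= `degree`, then backward pruning by generalized cross-validation.
# Terms are products of hinges h(x_v - t) / h(t - x_v); a variable appears
# at most once per term.

# a term is list(vars, signs, knots); the intercept is the empty term
.mars_basis_col <- function(x, term) {
  if (length(term$vars) == 0L) return(rep(1, nrow(x)))
  b <- rep(1, nrow(x))
  for (j in seq_along(term$vars)) {
    b <- b * pmax(term$signs[j] * (x[, term$vars[j]] - term$knots[j]), 0)
  }
  b
}

.mars_basis <- function(x, terms) {
  vapply(terms, .mars_basis_col, numeric(nrow(x)), x = x)
}

mars_fit <- function(x, y, degree = 2, max_terms = 15, n_knots = 7,
                     penalty = 3) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  p <- ncol(x)
  knots <- lapply(seq_len(p), function(j) {
    q <- unique(quantile(x[, j], probs = seq(0.1, 0.9, length.out = n_knots),
                         type = 7, names = FALSE))
    # interior knots only: a hinge at the boundary is collinear with linears
    q[q > min(x[, j]) & q < max(x[, j])]
  })

  terms <- list(list(vars = integer(), signs = numeric(), knots = numeric()))
  B <- matrix(1, n, 1)
  qrB <- qr(B)

  repeat {
    if (length(terms) + 2L > max_terms) break
    Qc <- qr.Q(qrB)
    r <- y - Qc %*% crossprod(Qc, y)
    rss0 <- sum(r^2)
    if (rss0 < 1e-10 * n) break

    # enumerate candidate (parent, var, knot) triples
    cand <- list()
    for (ip in seq_along(terms)) {
      parent <- terms[[ip]]
      if (length(parent$vars) >= degree) next
      for (v in setdiff(seq_len(p), parent$vars)) {
        for (t in knots[[v]]) {
          cand[[length(cand) + 1L]] <- c(ip, v, t)
        }
      }
    }
    if (length(cand) == 0) break
    cm <- do.call(rbind, cand)

    best <- list(red = 0, idx = NA)
    chunk <- 400L
    for (start in seq(1L, nrow(cm), by = chunk)) {
      sel <- start:min(start + chunk - 1L, nrow(cm))
      Bp <- B[, cm[sel, 1], drop = FALSE]
      Xv <- x[, cm[sel, 2], drop = FALSE]
      Tk <- matrix(cm[sel, 3], n, length(sel), byrow = TRUE)
      B1 <- Bp * pmax(Xv - Tk, 0)
      B2 <- Bp * pmax(Tk - Xv, 0)
      U1 <- B1 - Qc %*% crossprod(Qc, B1)
      U2 <- B2 - Qc %*% crossprod(Qc, B2)
      a11 <- colSums(U1 * U1); a22 <- colSums(U2 * U2)
      a12 <- colSums(U1 * U2)
      c1 <- drop(crossprod(U1, r)); c2 <- drop(crossprod(U2, r))
      det <- a11 * a22 - a12^2
      eps <- 1e-10 * n
      red_pair <- ifelse(det > eps * pmax(a11, a22, eps),
                         (a22 * c1^2 - 2 * a12 * c1 * c2 + a11 * c2^2) / det,
                         0)
      red_1 <- ifelse(a11 > eps, c1^2 / a11, 0)
      red_2 <- ifelse(a22 > eps, c2^2 / a22, 0)
      red <- pmax(red_pair, red_1, red_2)
      k <- which.max(red)
      if (red[k] > best$red) best <- list(red = red[k], idx = sel[k])
    }
    if (!is.finite(best$red) || best$red <= 1e-8 * rss0) break

    ip <- cm[best$idx, 1]; v <- cm[best$idx, 2]; t <- cm[best$idx, 3]
    parent <- terms[[ip]]
    for (s in c(1, -1)) {
      terms[[length(terms) + 1L]] <- list(vars = c(parent$vars, v),
                                          signs = c(parent$signs, s),
                                          knots = c(parent$knots, t))
    }
    B <- .mars_basis(x, terms)
    qrB <- qr(B)
    # drop numerically collinear additions
    if (qrB$rank < ncol(B)) {
      keep <- sort(qrB$pivot[seq_len(qrB$rank)])
      if (!1 %in% keep) keep <- c(1, keep[-length(keep)])
      terms <- terms[keep]
      B <- B[, keep, drop = FALSE]
      qrB <- qr(B)
    }
  }

  # backward pruning by GCV
  gcv <- function(rss, m) {
    cm_eff <- m + penalty * (m - 1) / 2
    if (cm_eff >= n) return(Inf)
    (rss / n) / (1 - cm_eff / n)^2
  }
  active <- seq_along(terms)
  fit_rss <- function(idx) {
    f <- lm.fit(.mars_basis(x, terms[idx]), y)
    sum(f$residuals^2)
  }
  best_sets <- list(active)
  best_gcvs <- gcv(fit_rss(active), length(active))
  cur <- active
  while (length(cur) > 1) {
    drops <- setdiff(cur, 1L)  # never drop the intercept
    rs <- vapply(drops, function(d) fit_rss(setdiff(cur, d)), numeric(1))
    d <- drops[which.min(rs)]
    cur <- setdiff(cur, d)
    best_sets[[length(best_sets) + 1L]] <- cur
    best_gcvs <- c(best_gcvs, gcv(min(rs), length(cur)))
  }
  final <- best_sets[[which.min(best_gcvs)]]
  terms <- terms[final]
  Bf <- .mars_basis(x, terms)
  cf <- lm.fit(Bf, y)$coefficients
  cf[is.na(cf)] <- 0

  structure(list(terms = terms, coefficients = cf, gcv = min(best_gcvs),
                 degree = degree, colnames = colnames(x)),
            class = "ecotmle_mars")
}

#' @export
predict.ecotmle_mars <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$colnames, drop = FALSE])
  storage.mode(x) <- "double"
  drop(.mars_basis(x, object$terms) %*% object$coefficients)
}
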