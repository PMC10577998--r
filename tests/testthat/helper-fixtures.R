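# lean learner library for simulation-heavy tests: the correct linear
# model plus the L1 fit (inner CV at its defaults)
lean_learners <- function() {
  list(learner_spec("linear_main_effects"), learner_spec("l1_linear"))
}

linear_only <- function() list(learner_spec("linear_main_effects"))
const_only <- function() list(learner_spec("intercept_only"))
ordered_logit_only <- function() list(learner_spec("ordered_logit"))

# deterministic toy panel: 4 observations per level, linear outcome
tiny_panel <- function(n_per_level = 4, seed = 11, noise_sd = 0.2) {
  set.seed(seed)
  n <- 4 * n_per_level
  lev <- factor(rep(c("Low", "Mid-Low", "Mid-High", "High"),
                    each = n_per_level),
                levels = c("Low", "Mid-Low", "Mid-High", "High"),
                ordered = TRUE)
  x1 <- rnorm(n)
  x2 <- runif(n)
  y <- 4 + 0.5 * x1 - 0.3 * x2 +
    c(0, 0.1, 0.2, 0.4)[as.integer(lev)] + rnorm(n, 0, noise_sd)
  tibble::tibble(country = sprintf("C%02d", seq_len(n)),
                 exposure_level = lev, x1 = x1, x2 = x2,
                 outcome_log = y)
}

# propensity matrix equal to the empirical marginals in every row
marginal_g <- function(levels) {
  lev <- levels(levels)
  p <- as.numeric(table(levels)) / length(levels)
  matrix(p, length(levels), length(lev), byrow = TRUE,
         dimnames = list(NULL, lev))
}

# direct Hajek (self-normalized) weighted mean per level, the IPW oracle
ipw_level_means <- function(y, levels, weights_obj) {
  s <- weights_obj$ratios
  vapply(seq_len(ncol(s)), function(k) sum(s[, k] * y) / sum(s[, k]),
         numeric(1))
}
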