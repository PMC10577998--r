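make_groups <- function(values, sizes = NULL) {
  lev <- c("Low", "Mid-Low", "Mid-High", "High")
  n <- length(values)
  g <- if (is.null(sizes)) rep(lev[1:3], length.out = n) else
    rep(lev[seq_along(sizes)], times = sizes)
  tibble::tibble(
    exposure_level = factor(g, levels = lev, ordered = TRUE),
    v = values)
}

test_that("descriptive table matches hand-computed statistics", {
  d <- make_groups(c(1, 2, 3, 4, 10, 12, 14, 16, 5, 5, 5, 5),
                   sizes = c(4, 4, 4))
  out <- describe_by_level(d, "v")
  low <- out[out$level == "Low", ]
  expect_equal(low$mean, 2.5)
  expect_equal(low$sd, sd(c(1, 2, 3, 4)))
  expect_equal(low$median, 2.5)
  mid <- out[out$level == "Mid-High", ]
  expect_equal(mid$mean, 5)
  expect_equal(mid$sd, 0)
  expect_equal(mid$iqr, 0)
  overall <- out[out$level == "Overall", ]
  expect_equal(overall$n, 12)
  expect_equal(overall$mean, mean(d$v))
})

test_that("single observation per level reports SD as missing", {
  d <- make_groups(c(1, 2, 3, 4), sizes = c(1, 1, 1, 1))
  out <- describe_by_level(d, "v")
  per <- out[out$level != "Overall", ]
  expect_true(all(is.na(per$sd)))
  expect_equal(per$mean, c(1, 2, 3, 4))
  expect_error(describe_by_level(d, "nope"), "nope")
})

test_that("one-way ANOVA agrees with the direct sums-of-squares formula", {
  d <- make_groups(c(3.1, 2.9, 3.4, 3.6, 5.0, 5.3, 4.7, 5.2,
                     7.9, 8.4, 8.1, 7.6), sizes = c(4, 4, 4))
  out <- level_anova(d, "v")
  # independent oracle: classical decomposition computed directly
  gm <- mean(d$v)
  per <- split(d$v, droplevels(d$exposure_level))
  ssb <- sum(vapply(per, function(v) length(v) * (mean(v) - gm)^2, 0))
  ssw <- sum(vapply(per, function(v) sum((v - mean(v))^2), 0))
  df1 <- length(per) - 1
  df2 <- length(d$v) - length(per)
  f_oracle <- (ssb / df1) / (ssw / df2)
  expect_equal(out$statistic, f_oracle, tolerance = 1e-12)
  expect_equal(out$df_between, df1)
  expect_equal(out$df_within, df2)
  expect_equal(out$p.value, pf(f_oracle, df1, df2, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("ANOVA edge cases: equal means, two-group t identity, group size", {
  # identical group means with positive within-variance
  d0 <- make_groups(c(1, 3, 1, 3, 1, 3), sizes = c(2, 2, 2))
  out0 <- level_anova(d0, "v")
  expect_equal(out0$statistic, 0)
  expect_equal(out0$p.value, 1)
  # two groups: F equals the square of the pooled-variance t statistic
  d2 <- make_groups(c(1.2, 0.8, 1.5, 3.3, 2.9, 3.8), sizes = c(3, 3))
  out2 <- level_anova(d2, "v")
  tt <- t.test(v ~ droplevels(exposure_level), data = d2, var.equal = TRUE)
  expect_equal(out2$statistic, unname(tt$statistic)^2, tolerance = 1e-12)
  # a group below two observations is rejected
  d1 <- make_groups(c(1, 2, 3), sizes = c(2, 1))
  expect_error(level_anova(d1, "v"), "at least 2")
})

test_that("Kruskal-Wallis matches a brute-force tie-corrected rank oracle", {
  d <- make_groups(c(1, 2, 2, 5, 7, 2, 5, 9, 9, 3, 1, 9),
                   sizes = c(4, 4, 4))
  out <- level_kruskal(d, "v")
  # brute-force H with tie correction
  r <- rank(d$v)
  n <- length(r)
  per <- split(r, droplevels(d$exposure_level))
  h <- 12 / (n * (n + 1)) *
    sum(vapply(per, function(ri) length(ri) * mean(ri)^2, 0)) - 3 * (n + 1)
  ties <- table(d$v)
  h <- h / (1 - sum(ties^3 - ties) / (n^3 - n))
  expect_equal(out$statistic, h, tolerance = 1e-12)
  expect_equal(out$p.value, 1 - pchisq(h, out$df), tolerance = 1e-12)
})

test_that("Kruskal-Wallis separation and degenerate ties", {
  # monotone separation: H attains the no-tie maximum for these group sizes
  d <- make_groups(c(1, 2, 10, 11, 20, 21), sizes = c(2, 2, 2))
  out <- level_kruskal(d, "v")
  # maximum achievable H over all assignments of ranks 1..6 to 3 pairs
  perms <- combn(6, 2, simplify = FALSE)
  hmax <- 0
  for (a in perms) {
    rest <- setdiff(1:6, a)
    for (b in combn(rest, 2, simplify = FALSE)) {
      cc <- setdiff(rest, b)
      h <- 12 / (6 * 7) * 2 * (mean(a)^2 + mean(b)^2 + mean(cc)^2) - 3 * 7
      hmax <- max(hmax, h)
    }
  }
  expect_equal(out$statistic, hmax, tolerance = 1e-12)
  # all values tied: H = 0, p = 1, warning
  dt <- make_groups(rep(4, 6), sizes = c(3, 3))
  expect_warning(outt <- level_kruskal(dt, "v"), "tied")
  expect_equal(outt$statistic, 0)
  expect_equal(outt$p.value, 1)
})

test_that("descriptive comparison assembles summaries and both tests", {
  p <- simulate_country_panel(n_countries = 87, seed = 31)
  dc <- descriptive_comparison(p, c("outcome_raw", "sdi"))
  expect_equal(nrow(dc$tests), 2)
  expect_true(all(dc$tests$anova_p >= 0 & dc$tests$anova_p <= 1))
  expect_true(all(dc$tests$kruskal_h >= 0))
  expect_equal(nrow(dc$summary), 2 * 5)
})
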