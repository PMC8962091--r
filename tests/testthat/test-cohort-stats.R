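test_that("descriptives choose presentation by normality", {
  set.seed(1)
  tab <- data.frame(normal = rnorm(200),
                    skewed = exp(rnorm(200, sd = 1.2)),
                    constant = rep(3, 200))
  d <- describe_cohort(tab)
  expect_equal(d$presentation[d$variable == "normal"], "mean_sd")
  expect_equal(d$presentation[d$variable == "skewed"], "median_iqr")
  expect_equal(d$presentation[d$variable == "constant"], "flagged")
  expect_equal(d$sd[d$variable == "constant"], 0)
  expect_equal(d$n, rep(200L, 3), ignore_attr = TRUE)
  # missing values are excluded and n reported
  tab$normal[1:20] <- NA
  expect_equal(describe_cohort(tab)$n[1], 180L)
})

test_that("correlate: identity, strength labels and error contracts", {
  x <- 1:10
  r <- correlate(x, x, method = "pearson")
  expect_equal(r$estimate, 1)
  expect_equal(r$label, "excellent")
  expect_equal(r$n, 10L)
  expect_error(correlate(x, rep(1, 10)), "zero variance")
  expect_error(correlate(1:2, 2:1), "3 complete pairs")

  # construct samples with exact sample correlation r0 to probe the bands
  make_r <- function(r0, n = 40) {
    set.seed(4)
    x <- scale(rnorm(n))[, 1]
    z <- scale(resid(lm(rnorm(n) ~ x)))[, 1]
    y <- r0 * x + sqrt(1 - r0^2) * z
    list(x = x, y = y)
  }
  for (case in list(c(0.2, "negligible"), c(0.35, "weak"),
                    c(0.5, "moderate"), c(0.69, "moderate"),
                    c(0.7, "strong"), c(0.9, "strong"),
                    c(0.95, "excellent"), c(-0.8, "strong"))) {
    d <- make_r(as.numeric(case[1]))
    r <- correlate(d$x, d$y, method = "pearson")
    expect_equal(r$estimate, as.numeric(case[1]), tolerance = 1e-10)
    expect_equal(r$label, case[2])
  }
})

test_that("auto method selection follows Shapiro-Wilk", {
  set.seed(2)
  xn <- rnorm(60); yn <- rnorm(60)
  expect_equal(correlate(xn, yn, "auto")$method, "pearson")
  ylog <- exp(rnorm(60, sd = 1.5))
  expect_equal(correlate(xn, ylog, "auto")$method, "spearman")
})

test_that("Spearman p at n = 6 matches exhaustive enumeration", {
  set.seed(10)
  for (rep in 1:5) {
    x <- sample(100, 6); y <- sample(100, 6)
    got <- correlate(x, y, method = "spearman")
    expect_equal(got$p, spearman_p_exhaustive(x, y), tolerance = 1e-10)
  }
})

test_that("Mann-Whitney p at n = 4 vs 4 matches exhaustive enumeration", {
  set.seed(11)
  for (rep in 1:5) {
    a <- sample(1000, 4); b <- sample(1000, 4)
    # the pairwise matrix of compare_segments always uses the U test
    res <- compare_segments(c(a, b), rep(c("g1", "g2"), each = 4))
    p_enum <- mann_whitney_p_exhaustive(a, b)
    expect_equal(unname(res$pairwise_raw["g1", "g2"]), p_enum,
                 tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis omnibus p matches its permutation distribution", {
  set.seed(12)
  vals <- c(rnorm(3, 0), rnorm(3, 0.5), rnorm(3, 1), rnorm(3, 0.2))
  grp <- rep(paste0("s", 1:4), each = 3)
  got <- compare_segments(vals, grp)
  expect_equal(got$omnibus_method, "exact")
  # independent Monte-Carlo permutation distribution of H
  h_of <- function(v) unname(stats::kruskal.test(v, grp)$statistic)
  h_obs <- h_of(vals)
  expect_equal(got$h_statistic, h_obs)
  nmc <- 20000
  hs <- vapply(seq_len(nmc), function(i) h_of(sample(vals)), 1)
  p_mc <- mean(hs >= h_obs - 1e-12)
  mc_se <- sqrt(max(p_mc * (1 - p_mc), 1e-6) / nmc)
  expect_lt(abs(got$omnibus_p - p_mc), 5 * mc_se + 1e-6)
})

test_that("segment comparison handles ties and localizes the shift", {
  v <- rep(5, 12)
  g <- rep(letters[1:4], each = 3)
  res <- compare_segments(v, g)
  expect_equal(res$h_statistic, 0)
  expect_equal(res$omnibus_p, 1)
  expect_true(all(res$pairwise_adjusted[upper.tri(res$pairwise_adjusted)]
                  == 1))

  # groups c and d clearly shifted apart
  set.seed(3)
  v2 <- c(rnorm(6, 0), rnorm(6, 0.2), rnorm(6, -8), rnorm(6, 8))
  g2 <- rep(letters[1:4], each = 6)
  res2 <- compare_segments(v2, g2)
  m <- res2$pairwise_adjusted
  expect_equal(unname(m["c", "d"]), min(m, na.rm = TRUE))
  expect_true(res2$significant["c", "d"])
  # Bonferroni: adjusted = min(1, raw * n_pairs), always >= raw
  expect_true(all(m >= res2$pairwise_raw, na.rm = TRUE))
  expect_equal(m, pmin(res2$pairwise_raw * res2$n_pairs, 1))
  # warning and exclusion for an undersized group
  expect_warning(compare_segments(c(v2, 1), c(g2, "tiny")), "n < 2")
})

test_that("group differences pick the test by normality", {
  set.seed(5)
  a <- rnorm(30); b <- rnorm(30, 0.2)
  res <- group_difference(c(a, b), rep(1:2, each = 30))
  expect_equal(res$test, "t")
  sk <- exp(rnorm(30, sd = 1.5))
  res2 <- group_difference(c(sk, sk * 2), rep(1:2, each = 30))
  expect_equal(res2$test, "mann_whitney")
  res3 <- group_difference(rep(4, 20), rep(1:2, each = 10))
  expect_equal(res3$p, 1)
  expect_error(group_difference(1:5, rep(1, 5)), "2 levels")
})

test_that("two-sample p-values are null-calibrated across seeds", {
  ps <- vapply(1:200, function(s) {
    set.seed(s)
    group_difference(rnorm(60), rep(1:2, each = 30))$p
  }, 1)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("correlation power at r = 0.5, n = 28 matches Fisher-z theory", {
  nrep <- 2000
  rej <- vapply(seq_len(nrep), function(s) {
    set.seed(s)
    x <- rnorm(28)
    y <- 0.5 * x + sqrt(1 - 0.25) * rnorm(28)
    correlate(x, y, method = "pearson")$p < 0.05
  }, TRUE)
  power_theory <- 1 - pnorm(qnorm(0.975) - atanh(0.5) * sqrt(28 - 3)) +
    pnorm(-qnorm(0.975) - atanh(0.5) * sqrt(28 - 3))
  expect_lt(abs(mean(rej) - power_theory), 0.03)
})

test_that("analyses are invariant to row permutation", {
  x <- generate_cohort(cohort_spec(n = 40, seed = 2))
  perm <- x[sample(nrow(x)), ]
  a <- correlate(x$ke_norm_flow, x$ct1, method = "pearson")
  b <- correlate(perm$ke_norm_flow, perm$ct1, method = "pearson")
  expect_equal(a$estimate, b$estimate)
  expect_equal(a$p, b$p)
  da <- describe_cohort(x, "peak_vo2")
  db <- describe_cohort(perm, "peak_vo2")
  expect_equal(da$mean, db$mean)
  expect_equal(da$shapiro_p, db$shapiro_p)
})

test_that("correlate_pairs returns the long-format report", {
  x <- generate_cohort(cohort_spec(n = 60, seed = 8))
  rep_df <- correlate_pairs(x, rbind(c("ke_norm_flow", "ct1"),
                                     c("el_norm_flow", "peak_vo2")))
  expect_equal(nrow(rep_df), 2L)
  expect_true(all(c("var_x", "var_y", "method", "n", "estimate", "p",
                    "label") %in% names(rep_df)))
  expect_equal(rep_df$n, c(60L, 60L))
})
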