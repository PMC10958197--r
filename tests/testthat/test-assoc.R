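test_that("trend test matches the textbook formula and handles edge cases", {
  # identical genotype proportions in both groups: no trend
  tab <- cbind(responder = c(30, 20, 10), non_responder = c(30, 20, 10))
  tt <- trend_test(tab)
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p, 1)

  # maximal trend
  tab2 <- cbind(responder = c(0, 0, 50), non_responder = c(50, 0, 0))
  tt2 <- trend_test(tab2)
  ora2 <- oracle_trend(tab2)
  expect_equal(tt2$statistic, ora2$statistic, tolerance = 1e-10)

  # printed cohort genotype counts for one panel SNP
  tab3 <- cbind(responder = c(157, 76, 16), non_responder = c(146, 56, 10))
  tt3 <- trend_test(tab3)
  ora3 <- oracle_trend(tab3)
  expect_equal(tt3$statistic, ora3$statistic, tolerance = 1e-10)
  expect_equal(tt3$p, ora3$p, tolerance = 1e-10)
  expect_equal(round(tt3$statistic, 4), 1.8385)
  expect_equal(round(tt3$p, 4), 0.1751)

  expect_error(trend_test(cbind(c(1, 2, 3), c(0, 0, 0))), "group totals")
})

test_that("trend statistic is invariant to reversing genotype scores", {
  set.seed(6)
  for (i in 1:20) {
    tab <- matrix(rpois(6, 30) + 1, 3, 2)
    a <- trend_test(tab)$statistic
    b <- trend_test(tab[3:1, ])$statistic
    expect_equal(a, b, tolerance = 1e-10)
  }
})

test_that("genotypic Fisher test agrees with complete enumeration", {
  expect_equal(fisher_exact_genotypic(cbind(c(1, 0, 0), c(0, 0, 1))),
               oracle_fisher_3x2(cbind(c(1, 0, 0), c(0, 0, 1))),
               tolerance = 1e-10)
  # identical columns: p = 1
  expect_equal(fisher_exact_genotypic(cbind(c(5, 3, 2), c(5, 3, 2))), 1)
  set.seed(12)
  for (i in 1:40) {
    n <- sample(6:40, 1)
    tab <- matrix(rmultinom(1, n, runif(6, 0.05, 1))[, 1], 3, 2)
    if (any(colSums(tab) == 0)) next
    p <- fisher_exact_genotypic(tab)
    expect_equal(p, oracle_fisher_3x2(tab), tolerance = 1e-7)
    expect_gt(p, 0); expect_lte(p, 1)
  }
  expect_error(fisher_exact_genotypic(matrix(1e5, 3, 2)), "enumeration_limit")
  expect_lte(fisher_exact_genotypic(matrix(50, 3, 2), monte_carlo = TRUE), 1)
})

test_that("allelic odds ratios match hand arithmetic with group-swap symmetry", {
  # allele table (10,10) vs (10,10): genotype counts 5 het + homs unused
  tab_null <- cbind(c(5, 0, 5), c(5, 0, 5))  # 10/10 vs 10/10 alleles
  expect_equal(allelic_odds_ratio(tab_null)$or, 1.0)

  # allele counts 20 vs 10 / 10 vs 20
  tab <- cbind(c(5, 0, 10), c(10, 0, 5))
  res <- allelic_odds_ratio(tab)
  expect_equal(res$or, 4.0)
  se <- sqrt(1 / 20 + 1 / 10 + 1 / 10 + 1 / 20)   # Woolf
  expect_equal(res$se, se)
  expect_equal(res$ci_low, exp(log(4) - 1.96 * se))
  expect_equal(res$ci_high, exp(log(4) + 1.96 * se))

  set.seed(20)
  for (i in 1:20) {
    t1 <- matrix(rpois(6, 20) + 1, 3, 2)
    a <- allelic_odds_ratio(t1)$or
    b <- allelic_odds_ratio(t1[, 2:1])$or
    expect_equal(a, 1 / b, tolerance = 1e-12)
  }

  # zero cells get the Haldane-Anscombe correction, flagged
  tz <- cbind(c(10, 0, 0), c(0, 0, 10))
  rz <- allelic_odds_ratio(tz)
  expect_true(attr(rz, "haldane"))
  expect_error(allelic_odds_ratio(cbind(c(0, 0, 0), c(1, 1, 1))), "alleles")
})

test_that("logistic fits are null-calibrated and recover a known odds ratio", {
  set.seed(31)
  n <- 5000
  prs <- rnorm(n, 6, 2)
  y <- rbinom(n, 1, 0.5)
  res <- fit_logistic(y, data.frame(score = prs))
  row <- res[res$predictor == "score", ]
  expect_gt(row$or, 0.94); expect_lt(row$or, 1.06)
  expect_gt(row$p, 0.01)
  expect_true(row$ci_low <= row$or && row$or <= row$ci_high)

  set.seed(32)
  n <- 2000
  prs <- rnorm(n, 6, 2)
  eta <- log(1.25) * (prs - mean(prs))
  y <- rbinom(n, 1, plogis(eta))
  res <- fit_logistic(y, data.frame(score = prs))
  row <- res[res$predictor == "score", ]
  expect_lt(abs(row$beta - log(1.25)), 3 * row$se)
})

test_that("perfect separation and degenerate outcomes raise errors", {
  set.seed(33)
  prs <- rnorm(100)
  y <- as.numeric(prs > median(prs))
  expect_error(fit_logistic(y, data.frame(score = prs)), "separation")
  expect_error(fit_logistic(rep(1, 50), data.frame(score = rnorm(50))), "both classes")
  expect_error(fit_logistic(c(NA, 0, 1), data.frame(score = rnorm(3))), "missing")
})

test_that("Wald intervals achieve nominal coverage on model-generated data", {
  set.seed(34)
  R <- 200; n <- 800
  hits <- 0
  for (r in seq_len(R)) {
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(0.2 + log(1.3) * x))
    res <- fit_logistic(y, data.frame(x = x))
    row <- res[res$predictor == "x", ]
    if (row$ci_low <= 1.3 && 1.3 <= row$ci_high) hits <- hits + 1
  }
  expect_gte(hits / R, 0.90)
  expect_lte(hits / R, 0.99)
})

test_that("univariate screening flags real effects and skips constants", {
  set.seed(35)
  n <- 600
  age <- runif(n, 18, 80)
  noise <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.2 - 0.03 * (age - mean(age))))
  out <- univariate_screen(data.frame(age = age, noise = noise,
                                      const = rep(1, n)), y)
  expect_true(out$flagged[out$covariate == "age"])
  expect_true(out$skipped[out$covariate == "const"])
  expect_false(out$skipped[out$covariate == "age"])
})

test_that("pure-noise covariates are flagged at the nominal rate", {
  set.seed(36)
  R <- 400; n <- 150
  hits <- 0
  for (r in seq_len(R)) {
    x <- rnorm(n); y <- rbinom(n, 1, 0.5)
    out <- univariate_screen(data.frame(x = x), y)
    if (out$flagged[1]) hits <- hits + 1
  }
  rate <- hits / R
  expect_lt(abs(rate - 0.05), 2 * sqrt(0.05 * 0.95 / R) + 0.01)
})

test_that("per-variant tables select tests sensibly and conserve counts", {
  set.seed(37)
  n <- 300
  d <- cbind(common = rbinom(n, 2, 0.4), rare = rbinom(n, 2, 0.03))
  gm <- make_gm(d)
  y <- rbinom(n, 1, 0.5) == 1
  out <- per_snp_association(gm, y)
  expect_equal(out$test[out$id == "common"], "trend")
  expect_equal(out$test[out$id == "rare"], "fisher")
  counts <- out[1, c("resp_00", "resp_01", "resp_02",
                     "non_00", "non_01", "non_02")]
  expect_equal(sum(unlist(counts)), n)
  expect_true(all(out$p_bonferroni >= out$p))
})
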