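# Cohort statistics layer.

test_that("pearson handles exact linear relations and guards input", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson(x, 2 * x + 1)$r, 1)
  expect_equal(pearson(c(1, 2, 3), c(6, 4, 2))$r, -1)
  expect_error(pearson(c(1, 2), c(1, 2)), "3")
  expect_error(pearson(x, rep(1, 5)), "variance")
  # listwise deletion reported
  res <- pearson(c(x, NA), c(2 * x, 3))
  expect_equal(res$n, 5)
  expect_equal(res$n_missing, 1)
})

test_that("pearson p-values and CI match the t and Fisher formulas", {
  withr::local_seed(14)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  res <- pearson(x, y)
  r <- cor(x, y)
  tt <- r * sqrt(38 / (1 - r^2))
  expect_equal(res$p, 2 * pt(-abs(tt), 38))
  expect_equal(res$ci,
               tanh(atanh(r) + c(-1, 1) * qnorm(0.975) / sqrt(37)))
})

test_that("simulated correlated cohorts recover the target r on average", {
  withr::local_seed(15)
  rs <- replicate(400, {
    z <- MASS::mvrnorm(73, c(0, 0),
                       matrix(c(1, -0.6, -0.6, 1), 2))
    pearson(z[, 1], z[, 2])$r
  })
  expect_equal(mean(rs), -0.6, tolerance = 0.02)
})

test_that("independent correlation comparison follows the Fisher formula", {
  expect_equal(compare_correlations_independent(0.4, 50, 0.4, 80)$z, 0)
  expect_equal(compare_correlations_independent(0.4, 50, 0.4, 80)$p, 1)
  res <- compare_correlations_independent(0.5, 73, 0.0, 73)
  expect_equal(res$z, atanh(0.5) / sqrt(2 / 70), tolerance = 1e-12)
  expect_equal(res$z, 3.2498, tolerance = 1e-4)
  expect_equal(res$p, 0.001154, tolerance = 1e-3)
  # antisymmetry
  a <- compare_correlations_independent(0.7, 40, 0.2, 60)
  b <- compare_correlations_independent(0.2, 60, 0.7, 40)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)
  expect_error(compare_correlations_independent(1, 10, 0.5, 10), "< 1")
})

test_that("dependent correlation comparison is zero under equality", {
  expect_equal(compare_correlations_dependent(0.5, 0.5, 0.3, 73)$t, 0)
  res <- compare_correlations_dependent(-0.665, -0.610, 0.8, 73)
  expect_true(res$p > 0 && res$p < 1)
})

test_that("two_sample_t matches stats::t.test on raw data", {
  withr::local_seed(16)
  x1 <- rnorm(30, 1, 2); x2 <- rnorm(20, 0, 1)
  for (variant in c("welch", "pooled")) {
    mine <- two_sample_t(x1, x2, variant)
    ref <- t.test(x1, x2, var.equal = variant == "pooled")
    expect_equal(mine$t, unname(ref$statistic))
    expect_equal(mine$df, unname(ref$parameter))
    expect_equal(mine$p, ref$p.value)
    expect_equal(mine$ci, unname(ref$conf.int), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  same <- two_sample_t(x1, x1)
  expect_equal(same$t, 0)
  expect_equal(mean(same$ci), 0)
})

test_that("pooled summary-form t equals the textbook formula", {
  m1 <- 10; s1 <- 2; n1 <- 25; m2 <- 9; s2 <- 2; n2 <- 25
  res <- two_sample_t(c(m1, s1, n1), c(m2, s2, n2), "pooled",
                      summary_input = TRUE)
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  expect_equal(res$t, (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2)),
               tolerance = 1e-12)
  expect_equal(res$df, 48)
})

test_that("summary-form input reproduces raw-data results", {
  withr::local_seed(17)
  x1 <- rnorm(40, 5, 3); x2 <- rnorm(25, 4, 2)
  raw <- two_sample_t(x1, x2)
  summ <- two_sample_t(c(mean(x1), sd(x1), 40), c(mean(x2), sd(x2), 25),
                       summary_input = TRUE)
  expect_equal(raw$t, summ$t)
  expect_equal(raw$ci, summ$ci)
})

test_that("logistic OR for a binary predictor equals the cross-product ratio", {
  withr::local_seed(18)
  for (i in 1:5) {
    x <- rbinom(120, 1, 0.4)
    y <- rbinom(120, 1, plogis(-0.5 + 1.2 * x))
    tab <- table(x, y)
    if (any(tab == 0)) next
    orr <- (tab["1", "1"] * tab["0", "0"]) / (tab["1", "0"] * tab["0", "1"])
    fit <- logistic_fit(y, matrix(x, dimnames = list(NULL, "x")))
    expect_equal(unname(fit$odds_ratios["x", "or"]), unname(orr),
                 tolerance = 1e-6)
  }
})

test_that("logistic fit flags degenerate designs", {
  y <- rep(c(0, 1), each = 10)
  expect_error(logistic_fit(y, matrix(1, 20, 1)), "rank")
  expect_error(logistic_fit(rep(1, 20), matrix(rnorm(20))), "both levels")
  x <- c(rnorm(10, -5), rnorm(10, 5))   # complete separation
  expect_warning(fit <- logistic_fit(y, matrix(x,
                                               dimnames = list(NULL, "x")),
                                     scale_percent = FALSE),
                 "separation")
  expect_true(fit$separation)
})

test_that("percent scaling turns fraction predictors into per-1% odds ratios", {
  withr::local_seed(19)
  fr <- runif(300, 0, 0.5)
  y <- rbinom(300, 1, plogis(-2 + 10 * fr))
  fit_frac <- logistic_fit(y, cbind(at = fr), scale_percent = FALSE)
  fit_pct <- logistic_fit(y, cbind(at = fr), scale_percent = TRUE)
  expect_equal(unname(fit_pct$coefficients["at"]),
               unname(fit_frac$coefficients["at"]) / 100)
})

test_that("null logistic CIs cover OR = 1 at the nominal rate", {
  withr::local_seed(20)
  covered <- vapply(1:500, function(i) {
    x <- rnorm(200)
    y <- rbinom(200, 1, 0.5)
    or <- logistic_fit(y, cbind(x = x), scale_percent = FALSE)$odds_ratios
    or["x", "lower"] <= 1 && or["x", "upper"] >= 1
  }, NA)
  expect_gte(mean(covered), 0.93)
})

test_that("roc_analysis reproduces hand-countable cases", {
  perfect <- roc_analysis(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_true(perfect$cutpoint > 3 && perfect$cutpoint <= 10)

  flat <- roc_analysis(rep(2, 8), rep(c(0, 1), 4))
  expect_equal(flat$auc, 0.5)

  expect_equal(roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_analysis(c(1, 3, 2, 4), c(0, 0, 1, 1))$auc, 0.75)
  expect_error(roc_analysis(1:4, rep(1, 4)), "both classes")
})

test_that("AUC equals exhaustive pair counting with ties at 1/2", {
  withr::local_seed(21)
  for (i in 1:25) {
    n <- sample(6:30, 1)
    score <- sample(1:8, n, replace = TRUE)   # heavy ties
    label <- rbinom(n, 1, 0.5)
    if (length(unique(label)) < 2) next
    pos <- score[label == 1]; neg <- score[label == 0]
    conc <- 0
    for (a in pos) for (b in neg)
      conc <- conc + (a > b) + 0.5 * (a == b)
    expect_equal(roc_analysis(score, label)$auc,
                 conc / (length(pos) * length(neg)))
  }
})

test_that("AUC and operating points agree with pROC", {
  skip_if_not_installed("pROC")
  withr::local_seed(22)
  score <- c(rnorm(40, 1), rnorm(30))
  label <- rep(c(1, 0), c(40, 30))
  mine <- roc_analysis(score, label)
  ref <- pROC::roc(label, score, direction = "<", quiet = TRUE)
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)))
  best <- pROC::coords(ref, "best", best.method = "youden",
                       transpose = FALSE)
  expect_equal(mine$sensitivity + mine$specificity,
               best$sensitivity + best$specificity, tolerance = 1e-9)
})

test_that("univariate_ols matches lm and rejects constant predictors", {
  x <- seq(0, 1, length.out = 20)
  res <- suppressWarnings(univariate_ols(3 * x, x))  # exact fit
  expect_equal(res$beta, 3)
  expect_lt(res$p, 1e-10)
  withr::local_seed(23)
  y <- rnorm(30); x2 <- rnorm(30)
  ref <- summary(lm(y ~ x2))
  mine <- univariate_ols(y, x2)
  expect_equal(mine$beta, unname(coef(lm(y ~ x2))[2]))
  expect_equal(mine$p, ref$coefficients[2, 4])
  expect_error(univariate_ols(y, rep(2, 30)), "variance")
})

test_that("null-regression p-values are uniform", {
  withr::local_seed(24)
  ps <- replicate(400, univariate_ols(rnorm(25), rnorm(25))$p)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("bonferroni multiplies and caps at 1", {
  expect_equal(bonferroni(c(0.01, 0.04)), c(0.02, 0.08))
  expect_equal(bonferroni(1), 1)
  expect_equal(bonferroni(0.3, m = 5), 1)
  expect_equal(bonferroni(c(0.001, 0.5), m = 10), c(0.01, 1))
  expect_error(bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("cohort_stats assembles a coherent report on simulated data", {
  co <- simulate_cohort(cohort_spec(seed = 42))
  rep <- cohort_stats(co)
  expect_s3_class(rep, "cohort_report")
  cors <- rep$correlations
  expect_true(all(cors$p_bonferroni >= cors$p))
  at_fev <- cors[cors$qct %in% c("prm_fsad", "laa_exp_856", "ati") &
                   cors$spirometry == "fev1_fvc", ]
  expect_true(all(at_fev$r < 0))
  gt <- rep$group_tests
  ei <- gt[gt$metric == "ei_ratio", ]
  expect_gt(ei$mean_diff, 0)
  for (m in rep$models) {
    expect_gt(m$roc$auc, 0.55)
    expect_gt(m$logistic$odds_ratios[2, "or"], 1)
  }
})
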