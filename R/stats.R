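# Cohort-level statistics: Pearson correlations with Fisher-transform
# CIs, correlation comparison (independent and dependent variants),
# two-sample t procedures accepting raw vectors or printed summary
# statistics, emphysema-adjusted logistic regression, ROC analysis with a
# Youden-optimal cut-point, and Bonferroni correction. Standard fits go
# through stats::cor.test / t.test / glm / lm; the ROC estimator
# (Mann-Whitney AUC with Hanley-McNeil SE) is implemented directly and
# cross-checked against pROC in the test suite.

#' Pearson correlation with Fisher-transform confidence interval
#'
#' Pairwise-complete Pearson correlation with the t-based two-sided
#' p-value and a 95% CI through Fisher's z transform. Rows with missing
#' values in either vector are dropped (listwise deletion) and the
#' retained sample size is reported.
#'
#' @param x,y Numeric vectors of equal length; at least 3 complete pairs
#'   with nonzero variance.
#' @param conf_level Confidence level, default 0.95.
#' @return List of class `correlation_result`: `r`, `n`, `p`, `ci`,
#'   `n_missing`.
#' @export
pearson <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  ok <- is.finite(x) & is.finite(y)
  n_missing <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson",
                        conf.level = conf_level)
  r <- unname(ct$estimate)
  ci <- if (abs(r) < 1) {
    zr <- atanh(r); se <- 1 / sqrt(n - 3)
    q <- stats::qnorm(1 - (1 - conf_level) / 2)
    tanh(c(zr - q * se, zr + q * se))
  } else c(r, r)
  structure(list(r = r, n = n, p = ct$p.value, ci = ci,
                 n_missing = n_missing),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d, p = %.4g, 95%% CI %.3f to %.3f)\n",
              x$r, x$n, x$p, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Compare two independent correlations (Fisher r-to-z)
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` with a
#' two-sided normal p-value. For correlations measured on the same
#' subjects and sharing a variable, use
#' [compare_correlations_dependent()].
#'
#' @param r1,r2 Correlations with `|r| < 1`.
#' @param n1,n2 Sample sizes, each > 3.
#' @return List with `z` and `p`.
#' @export
compare_correlations_independent <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("correlations must satisfy |r| < 1")
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Compare two dependent correlations sharing a variable (Steiger)
#'
#' Williams-Steiger test for H0: rho(x, y1) = rho(x, y2) measured on one
#' sample of size `n`, given also the correlation `r23` between the two
#' competing variables.
#'
#' @param r12,r13 The two correlations sharing variable x.
#' @param r23 Correlation between the competing variables.
#' @param n Common sample size (> 3).
#' @return List with `t`, `df` and two-sided `p`.
#' @export
compare_correlations_dependent <- function(r12, r13, r23, n) {
  if (any(abs(c(r12, r13, r23)) >= 1)) stop("|r| must be < 1")
  if (n <= 3) stop("'n' must exceed 3")
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  rbar <- (r12 + r13) / 2
  tt <- (r12 - r13) * sqrt((n - 1) * (1 + r23) /
                             (2 * detR * (n - 1) / (n - 3) +
                                rbar^2 * (1 - r23)^3))
  list(t = tt, df = n - 3,
       p = 2 * stats::pt(-abs(tt), n - 3))
}

#' Two-sample t-test from raw data or printed summaries
#'
#' Welch (default) or pooled-variance independent-samples comparison, with
#' the confidence interval of the mean difference. Accepts either raw
#' vectors or the summary form (mean, sd, n) per group, so comparisons can
#' be recomputed from a published table.
#'
#' @param x1,x2 Numeric vectors, or length-3 vectors `c(mean, sd, n)` when
#'   `summary_input = TRUE`.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @param summary_input Interpret `x1`, `x2` as (mean, sd, n) summaries.
#' @param conf_level Confidence level, default 0.95.
#' @return List with `t`, `df`, `p`, `mean_diff`, `ci`.
#' @export
two_sample_t <- function(x1, x2, variant = c("welch", "pooled"),
                         summary_input = FALSE, conf_level = 0.95) {
  variant <- match.arg(variant)
  if (summary_input) {
    m1 <- x1[1]; s1 <- x1[2]; n1 <- x1[3]
    m2 <- x2[1]; s2 <- x2[2]; n2 <- x2[3]
  } else {
    x1 <- x1[is.finite(x1)]; x2 <- x2[is.finite(x2)]
    m1 <- mean(x1); s1 <- stats::sd(x1); n1 <- length(x1)
    m2 <- mean(x2); s2 <- stats::sd(x2); n2 <- length(x2)
  }
  if (n1 < 2 || n2 < 2) stop("need at least 2 observations per group")
  diff <- m1 - m2
  if (variant == "welch") {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  tt <- diff / se
  q <- stats::qt(1 - (1 - conf_level) / 2, df)
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df),
       mean_diff = diff, ci = c(diff - q * se, diff + q * se))
}

#' Binary logistic regression with odds ratios
#'
#' Maximum-likelihood logistic fit (via IRLS as in `stats::glm`) of a
#' binary outcome on one or more predictors, reporting odds ratios per
#' 1-unit change. With `scale_percent = TRUE` predictors that are
#' fractions are expressed in percentage points (multiplied by 100), so an
#' air-trapping fraction's OR reads "per 1% of lung volume".
#'
#' @param outcome Binary vector (0/1, logical, or two-level factor).
#' @param predictors Numeric matrix or data frame, columns named.
#' @param scale_percent Express fraction-valued predictors (range within
#'   \[0, 1\]) in percentage points; default `TRUE`.
#' @return List of class `logistic_fit`: `coefficients`, `odds_ratios`
#'   (with 95% CI), `se`, `p`, `converged`, `separation`.
#' @export
logistic_fit <- function(outcome, predictors, scale_percent = TRUE) {
  if (is.factor(outcome)) outcome <- as.integer(outcome) - 1L
  outcome <- as.numeric(outcome)
  if (!all(outcome %in% c(0, 1))) stop("'outcome' must be binary")
  if (length(unique(outcome)) < 2) stop("'outcome' must have both levels")
  X <- as.matrix(predictors)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != length(outcome))
    stop("'outcome' and 'predictors' lengths differ")
  scaled <- logical(ncol(X))
  if (scale_percent) {
    for (j in seq_len(ncol(X))) {
      rng <- range(X[, j], na.rm = TRUE)
      if (rng[1] >= 0 && rng[2] <= 1 && length(unique(X[, j])) > 2) {
        X[, j] <- X[, j] * 100
        scaled[j] <- TRUE
      }
    }
  }
  if (qr(cbind(1, X))$rank < ncol(X) + 1)
    stop("rank-deficient design matrix (constant or collinear predictor)")
  dat <- data.frame(.y = outcome, X, check.names = FALSE)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  sm <- summary(fit)
  co <- stats::coef(fit)
  se <- sm$coefficients[, "Std. Error"]
  separation <- sep_warn || !fit$converged
  if (separation)
    warning("possible complete separation: coefficients diverging")
  q <- stats::qnorm(0.975)
  or_ci <- cbind(or = exp(co), lower = exp(co - q * se),
                 upper = exp(co + q * se))
  structure(list(coefficients = co, odds_ratios = or_ci, se = se,
                 p = sm$coefficients[, "Pr(>|z|)"],
                 converged = fit$converged, separation = separation,
                 scaled_to_percent = stats::setNames(scaled, colnames(X)),
                 model = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Binary logistic regression (odds ratios per 1-unit change",
      if (any(x$scaled_to_percent)) "; fractions per percentage point",
      ")\n", sep = "")
  tab <- cbind(x$odds_ratios, p = x$p)
  print(signif(tab[-1, , drop = FALSE], 4))
  invisible(x)
}

#' ROC analysis with Youden-optimal cut-point
#'
#' AUC by the Mann-Whitney (trapezoidal) estimator with ties counted 1/2,
#' standard error by Hanley-McNeil, 95% CI by normal approximation
#' (clipped to \[0, 1\]), and a p-value for H0: AUC = 0.5. The optimal
#' cut-point maximises Youden's J = sensitivity + specificity - 1 over the
#' rule `score >= c` is positive, taking the lowest such threshold on
#' ties.
#'
#' @param score Numeric predictor; higher values are assumed to indicate
#'   the positive class.
#' @param label Binary vector (0/1, logical, or two-level factor with the
#'   positive class last).
#' @return List of class `roc_result`: `auc`, `se`, `ci`, `p`, `cutpoint`,
#'   `sensitivity`, `specificity`, `curve` (data frame of all operating
#'   points), `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(score, label) {
  if (is.factor(label)) label <- as.integer(label) - 1L
  label <- as.numeric(label)
  ok <- is.finite(score) & is.finite(label)
  score <- score[ok]; label <- label[ok]
  if (!all(label %in% c(0, 1))) stop("'label' must be binary")
  pos <- score[label == 1]; neg <- score[label == 0]
  n1 <- length(pos); n0 <- length(neg)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  # Mann-Whitney AUC with ties counted 1/2, via midranks
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # Hanley-McNeil standard error
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  ci <- pmin(pmax(c(auc - 1.96 * se, auc + 1.96 * se), 0), 1)
  p <- if (se > 0) 2 * stats::pnorm(-abs((auc - 0.5) / se)) else
    as.numeric(auc == 0.5)
  # operating points over rule score >= c
  cand <- sort(unique(score))
  sens <- vapply(cand, function(c) mean(pos >= c), 0)
  spec <- vapply(cand, function(c) mean(neg < c), 0)
  j <- sens + spec - 1
  best <- which(j == max(j))[1]          # ties -> lowest threshold
  structure(list(auc = auc, se = se, ci = ci, p = p,
                 cutpoint = cand[best], sensitivity = sens[best],
                 specificity = spec[best],
                 curve = data.frame(threshold = cand, sensitivity = sens,
                                    specificity = spec),
                 n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (SE %.3f, 95%% CI %.2f-%.2f, p = %.4g)\n",
              x$auc, x$se, x$ci[1], x$ci[2], x$p))
  cat(sprintf("  Youden cut-point %.4g: sensitivity %.2f, specificity %.2f\n",
              x$cutpoint, x$sensitivity, x$specificity))
  invisible(x)
}

#' Plot an ROC curve
#'
#' @param x A `roc_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(1 - x$curve$specificity, x$curve$sensitivity,
                 type = "s", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "Sensitivity", ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  graphics::points(1 - x$specificity, x$sensitivity, pch = 19,
                   col = "red3")
  invisible(x)
}

#' Univariate least-squares regression
#'
#' Slope, standard error and t-test p-value of `y ~ x`.
#'
#' @param y,x Numeric vectors, at least 3 complete pairs; `x` must vary.
#' @return List with `beta`, `se`, `p`, `intercept`, `r_squared`, `n`.
#' @export
univariate_ols <- function(y, x) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0) stop("predictor has zero variance")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(beta = unname(stats::coef(fit)[2]),
       se = sm$coefficients[2, 2],
       p = sm$coefficients[2, 4],
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared, n = length(x))
}

#' Bonferroni correction
#'
#' `min(1, p * m)` elementwise; `m` defaults to the number of tests.
#'
#' @param pvals P-values in \[0, 1\].
#' @param m Number of comparisons, default `length(pvals)`.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]")
  if (m < length(pvals)) stop("'m' cannot be below the number of tests")
  stats::p.adjust(pvals, method = "bonferroni", n = m)
}
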