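test_that("logistic fit: closed-form intercept and oracle equivalence", {
  y <- c(rep(1, 12), rep(0, 8))
  fit <- fit_logistic(y)
  expect_equal(unname(fit$coefficients[1]), log(12 / 8), tolerance = 1e-8)

  # small fixtures against stock glm (an independent IRLS implementation)
  for (rep in 1:10) {
    set.seed(700 + rep)
    x <- rnorm(6)
    y6 <- c(0, 1, 0, 1, 1, 0)
    fit1 <- fit_logistic(y6, data.frame(x = x))
    if (fit1$separated) next
    ref <- glm(y6 ~ x, family = binomial)
    expect_equal(unname(fit1$coefficients), unname(coef(ref)),
                 tolerance = 1e-6)
    expect_equal(fit1$ll1, as.numeric(logLik(ref)), tolerance = 1e-6)
  }
  expect_error(fit_logistic(rep(1, 10)), "single class")
  expect_error(fit_logistic(rep(0:1, 5),
                            data.frame(a = 1:10, b = 2 * (1:10))),
               "rank")
})

test_that("separation is flagged, not reported as a clean fit", {
  y <- rep(0:1, each = 10)
  x <- c(rnorm(10, -3), rnorm(10, 3))   # complete separation
  fit <- fit_logistic(y, data.frame(x = x))
  expect_true(fit$separated)
  expect_true(all(is.na(fit$p)))
})

test_that("Nagelkerke R2: endpoints and plug-in arithmetic", {
  expect_equal(nagelkerke_r2(ll0 = -10, ll1 = -10, n = 20), 0)
  expect_equal(nagelkerke_r2(ll0 = -13.8629, ll1 = 0, n = 20), 1)
  # n = 20 balanced, ll1 = -10: R2_CS = 1 - exp(-0.38629) ~ 0.3205,
  # R2_N = 0.3205 / 0.75 ~ 0.4273
  r2 <- nagelkerke_r2(ll0 = -13.8629, ll1 = -10, n = 20)
  expect_equal(r2, (1 - exp(-0.38629)) / 0.75, tolerance = 1e-4)
  expect_equal(r2, 0.4273, tolerance = 1e-3)
  expect_error(nagelkerke_r2(ll0 = 0, ll1 = 0, n = 5), "degenerate")

  # agreement with an independent computation from glm deviances
  set.seed(71)
  y <- rbinom(40, 1, 0.5); x <- rnorm(40) + y
  fit <- fit_logistic(y, data.frame(x = x))
  ref <- glm(y ~ x, family = binomial)
  r2_ref <- (1 - exp((ref$deviance - ref$null.deviance) / 40)) /
    (1 - exp(-ref$null.deviance / 40))
  expect_equal(nagelkerke_r2(fit), r2_ref, tolerance = 1e-6)
})

test_that("chi-squared 2x2 reproduces printed cohort-table statistics", {
  # postmortem cohort: suicide 0/32 vs 19/12, smoking 4/26 vs 14/17,
  # race 16/16 vs 26/5; sex tables from both cohorts
  expect_equal(round(chi_square_2x2(0, 32, 19, 12)$statistic, 1), 28.1)
  expect_equal(round(chi_square_2x2(4, 26, 14, 17)$statistic, 1), 7.4)
  expect_equal(round(chi_square_2x2(16, 16, 26, 5)$statistic, 1), 8.1)
  expect_equal(round(chi_square_2x2(6, 14, 8, 12)$statistic, 1), 0.4)
  expect_equal(round(chi_square_2x2(19, 13, 15, 16)$statistic, 1), 0.8)
  expect_equal(chi_square_2x2(10, 10, 10, 10)$statistic, 0)
  # symmetry under row and column swaps
  s <- chi_square_2x2(3, 7, 9, 2)$statistic
  expect_equal(chi_square_2x2(9, 2, 3, 7)$statistic, s)
  expect_equal(chi_square_2x2(7, 3, 2, 9)$statistic, s)
  # matches stock chisq.test without continuity correction
  ref <- suppressWarnings(chisq.test(matrix(c(3, 9, 7, 2), 2), correct = FALSE))
  expect_equal(s, unname(ref$statistic))
  expect_error(chi_square_2x2(0, 0, 3, 4), "margin")
})

test_that("Mann-Whitney: conventions, extremes, permutation oracle", {
  ref <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ref$z, 0)
  expect_equal(ref$p, 1)
  # complete separation with nA = nB = 3: U = 9 (all b > a), maximal z
  sep <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$U, 9)
  expect_equal(sep$z, (9 - 4.5 - 0.5) / sqrt(3 * 3 * 7 / 12))  # maximal 3v3
  # sign convention: larger group-B values give positive z
  expect_gt(mann_whitney(rnorm(20), rnorm(20) + 3)$z, 0)
  # identical constant values across both groups
  flat <- mann_whitney(rep(2, 4), rep(2, 5))
  expect_equal(flat$p, 1)

  for (rep in 1:5) {
    set.seed(720 + rep)
    a <- sample(1:20, 8, replace = TRUE)
    b <- sample(3:22, 8, replace = TRUE)
    got <- mann_whitney(a, b)$p
    expect_lt(abs(got - oracle_mw_perm(a, b)), 0.02)
  }
})

test_that("score standardization is orthogonal to covariates", {
  set.seed(73)
  n <- 30
  covs <- data.frame(age = rnorm(n, 50, 10), sex = rbinom(n, 1, 0.5))
  s <- rnorm(n) + 0.5 * covs$age
  z <- standardize_scores(s, covs)
  expect_equal(mean(z), 0, tolerance = 1e-8)
  expect_equal(sd(z), 1, tolerance = 1e-8)
  expect_lt(abs(cor(z, covs$age)), 1e-8)
  expect_lt(abs(cor(z, covs$sex)), 1e-8)
  # intercept-only = plain z-score
  expect_equal(standardize_scores(s), as.numeric(scale(s)), tolerance = 1e-8)
  expect_error(standardize_scores(2 * covs$age + 3, covs), "residual")
})

test_that("score test agrees with the Wald test away from separation", {
  set.seed(74)
  n <- 80
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.5 * x))
  fit0 <- fit_logistic(y, NULL)
  st <- score_test_logistic(fit0, NULL, y, x)
  wald <- fit_logistic(y, data.frame(x = x))$p["x"]
  expect_lt(abs(st$p - unname(wald)), 0.02)
})

test_that("mrs_association handles null predictors and reports nested R2", {
  set.seed(75)
  n <- 40
  y <- rep(c("case", "control"), each = n / 2)
  covs <- data.frame(age = rnorm(n, 50, 5))
  scores <- matrix(0, n, 2, dimnames = list(NULL, c("PT_0.5", "PT_1")))
  res <- mrs_association(y, scores, covs)
  expect_equal(res$table$delta_r2, c(0, 0), tolerance = 1e-8)
  expect_equal(res$table$p, c(1, 1))

  # informative score: full model must dominate the covariate-only model
  scores2 <- scores
  scores2[, 2] <- rnorm(n) + 2 * (y == "case")
  res2 <- mrs_association(y, scores2, covs)
  row <- res2$table[2, ]
  expect_gte(row$r2_full, row$r2_covariates)
  expect_equal(row$delta_r2, row$r2_full - row$r2_covariates)
  expect_lt(row$p, 0.01)
  expect_true(row$best)
  expect_equal(mean(res2$zscores[, 2]), 0, tolerance = 1e-8)

  # affine rescaling of the score leaves delta-R2 unchanged
  scores3 <- scores2; scores3[, 2] <- 10 * scores3[, 2] + 5
  res3 <- mrs_association(y, scores3, covs)
  expect_equal(res3$table$delta_r2[2], res2$table$delta_r2[2],
               tolerance = 1e-6)
})
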