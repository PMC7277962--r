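test_that("remission and response boundaries follow their definitions", {
  f <- classify_outcomes(c(26, 20, 26), c(7, 10, 8))
  expect_equal(f$remission, c(TRUE, FALSE, FALSE))
  expect_equal(f$response, c(TRUE, TRUE, TRUE))   # 19/26, 10/20, 18/26
  expect_false(classify_outcomes(20, 11)$response) # 45% drop
  expect_error(classify_outcomes(0, 3), "baseline")
  expect_error(classify_outcomes(20, -1), "nonnegative")
})

test_that("median split partitions with ties assigned to the low group", {
  s <- median_split(1:52)
  expect_equal(as.vector(table(s$group)), c(26, 26))

  s2 <- median_split(c(1, 2, 3, 4))
  expect_equal(as.character(s2$group), c("low", "low", "high", "high"))

  s3 <- median_split(c(1, 2, 2, 3))
  expect_equal(as.character(s3$group), c("low", "low", "low", "high"))

  expect_error(median_split(rep(3, 10)), "identical")
  expect_error(median_split(c(1, 2, NA, NA, NA)), "at least 4")
})

test_that("contingency tables count groups by outcome", {
  g <- factor(rep(c("low", "high"), c(26, 26)), levels = c("low", "high"))
  remit <- c(rep(TRUE, 20), rep(FALSE, 6), rep(TRUE, 12), rep(FALSE, 14))
  tab <- contingency(g, remit)
  expect_equal(unname(tab), matrix(c(20L, 12L, 6L, 14L), 2))
  expect_equal(sum(tab), 52)
})

test_that("pearson chi-square equals the closed form on 2x2 tables", {
  # brute-force oracle: X2 = n(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))
  brute <- function(tab) {
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
    n <- sum(tab)
    n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
  }
  set.seed(9)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 10) + 1, 2)
    expect_equal(pearson_chi2(tab)$statistic, brute(tab),
                 tolerance = 1e-12)
  }
  expect_equal(pearson_chi2(matrix(c(10, 10, 10, 10), 2))$statistic, 0)
  expect_error(pearson_chi2(matrix(c(0, 0, 5, 5), 2)), "margin")
  expect_error(pearson_chi2(matrix(1:6, 2)), "2x2")
})

test_that("chi-square reconstruction matches the cohort's printed values", {
  remission <- matrix(c(20, 12, 6, 14), 2)
  response <- matrix(c(23, 17, 3, 9), 2)
  expect_equal(round(pearson_chi2(remission)$statistic, 2), 5.20)
  expect_equal(pearson_chi2(remission)$df, 1)
  expect_equal(round(pearson_chi2(response)$statistic, 2), 3.90)
})

test_that("sphericity diagnostics react to the covariance structure", {
  k <- 4
  set.seed(21)
  # compound symmetry: sphericity holds, epsilon near 1
  n <- 200
  subj <- rnorm(n, sd = 2)
  Y_cs <- sapply(1:k, function(j) subj + rnorm(n))
  cs <- mauchly_and_epsilon(Y_cs)
  expect_gt(cs$epsilon, 0.9)
  expect_gt(cs$mauchly_p, 0.05)

  # strong AR(1): known violation direction
  Y_ar <- matrix(0, n, k)
  Y_ar[, 1] <- rnorm(n)
  for (j in 2:k) Y_ar[, j] <- 0.95 * Y_ar[, j - 1] + rnorm(n, sd = 0.15)
  ar <- mauchly_and_epsilon(Y_ar)
  expect_lt(ar$epsilon, 0.9)
  expect_lt(ar$mauchly_p, 0.05)
  expect_gte(ar$epsilon, 1 / (k - 1))
  expect_lte(cs$epsilon, 1)

  expect_error(mauchly_and_epsilon(Y_cs[, 1:2]), "at least 3")
  Y_sing <- Y_cs; Y_sing[, 2] <- Y_sing[, 1]
  expect_error(mauchly_and_epsilon(Y_sing[, c(1, 2, 1, 2)]), "singular")
})

test_that("greenhouse-geisser df adjustment follows the exact algebra", {
  eps <- 0.77
  dfs <- gg_adjust_df(eps, k = 4, df_error = 46)
  expect_equal(unname(dfs[1]), eps * 3)
  expect_equal(unname(dfs[2]), eps * 3 * 46)
})

test_that("rm_ancova matches car::Anova on simulated cohorts", {
  skip_if_not_installed("car")
  for (seed in c(5, 17)) {
    co <- gen_clinical_cohort(sim_config(seed = seed))
    cl <- co$clinical
    Y <- as.matrix(cl[, c("hamd_w0", "hamd_w2", "hamd_w4", "hamd_w8")])
    sp <- median_split(co$truth$faa_f5f6_true)
    covs <- cl[, c("age", "sex", "hamd_w0", "medication")]
    mine <- rm_ancova(Y, sp$group, covs)

    d <- data.frame(group = sp$group, age = cl$age,
                    sex = as.numeric(cl$sex == "male"),
                    bl = cl$hamd_w0,
                    med = as.numeric(cl$medication == "vortioxetine"))
    m <- stats::lm(Y ~ group + age + sex + bl + med, data = d)
    a <- car::Anova(m, idata = data.frame(week = factor(c(0, 2, 4, 8))),
                    idesign = ~week, type = 3)
    s <- summary(a, multivariate = FALSE)
    u <- s$univariate.tests["group:week", ]
    expect_equal(mine$F, unname(u["F value"]), tolerance = 1e-8)
    expect_equal(mine$df1_unadj, unname(u["num Df"]))
    expect_equal(mine$df2_unadj, unname(u["den Df"]))
    expect_equal(mine$epsilon,
                 unname(s$pval.adjustments["group:week", "GG eps"]),
                 tolerance = 1e-8)
    expect_equal(mine$mauchly_w,
                 unname(s$sphericity.tests["group:week", "Test statistic"]),
                 tolerance = 1e-8)
    if (mine$gg_applied)
      expect_equal(mine$p,
                   unname(s$pval.adjustments["group:week", "Pr(>F[GG])"]),
                   tolerance = 1e-8)
    # df identity: df1 = eps (k-1), df2 = eps (k-1) (n - g - c)
    expect_equal(mine$df1, mine$epsilon * 3, tolerance = 1e-12)
    expect_equal(mine$df2, mine$epsilon * mine$df2_unadj,
                 tolerance = 1e-12)
  }
  expect_error(rm_ancova(matrix(rnorm(40), 10), rep("low", 10)),
               "two levels")
})

test_that("per-week ancova responds to group separation and confounds", {
  set.seed(3)
  score <- rnorm(40, 10, 2)
  g <- factor(rep(c("low", "high"), 20), levels = c("low", "high"))
  same <- ancova_at_week(rep(score[1:20], 2), factor(rep(c("low", "high"),
                                                         each = 20),
                                                     levels = c("low", "high")))
  expect_lt(same$F, 1e-20)

  sep <- ancova_at_week(score + 8 * (g == "high"), g,
                        demo_covariates(40))
  expect_lt(sep$p, 0.05)
  expect_equal(unname(sep$means["high"] - sep$means["low"]), 8,
               tolerance = 1.5)

  # covariate explaining the group difference attenuates the effect
  conf <- rnorm(40)
  y <- 10 + 5 * conf + rnorm(40, sd = 0.5)
  g2 <- factor(ifelse(conf > 0, "high", "low"), levels = c("low", "high"))
  with_cov <- ancova_at_week(y, g2, data.frame(conf = conf))
  without <- ancova_at_week(y, g2)
  expect_lt(with_cov$F, without$F)
})

test_that("partial correlation reduces to closed forms", {
  set.seed(8)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  expect_equal(partial_corr(x, y)$r, cor(x, y), tolerance = 1e-12)
  expect_equal(partial_corr(x, y)$df, 28)

  # first-order partial correlation on a fixed 6-point dataset
  x6 <- c(2, 4, 6, 7, 9, 12)
  y6 <- c(1, 3, 2, 6, 8, 9)
  z6 <- c(5, 4, 8, 9, 11, 15)
  rxy <- cor(x6, y6); rxz <- cor(x6, z6); ryz <- cor(y6, z6)
  closed <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  got <- partial_corr(x6, y6, data.frame(z = z6))
  expect_equal(got$r, closed, tolerance = 1e-10)
  expect_equal(got$df, 6 - 2 - 1)

  # covariates orthogonal to both variables leave r unchanged
  n <- 64
  xo <- rnorm(n); yo <- 0.4 * xo + rnorm(n)
  zo <- rnorm(n)
  zo <- stats::lm.fit(cbind(1, xo, yo), zo)$residuals
  expect_equal(partial_corr(xo, yo, data.frame(z = zo))$r, cor(xo, yo),
               tolerance = 1e-10)

  expect_error(partial_corr(rep(1, 10), rnorm(10)), "constant")
  expect_error(partial_corr(rnorm(4), rnorm(4),
                            data.frame(a = rnorm(4), b = rnorm(4))),
               "observations")
})
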