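test_that("Shapiro-Wilk wrapper screens normality and rejects degenerate input", {
  set.seed(1)
  # strong right skew is detected essentially always at n = 100
  rejections <- mean(replicate(100, shapiro_wilk(rlnorm(100, 0, 1))$p < 0.01))
  expect_gte(rejections, 0.95)
  # null p-values are uniform (Kolmogorov-Smirnov on replicate p-values)
  pvals <- replicate(200, shapiro_wilk(rnorm(200))$p)
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
  expect_error(shapiro_wilk(rep(1, 10)), "zero variance")
  expect_error(shapiro_wilk(c(1, 2)), "between 3 and 5000")
})

test_that("Kruskal-Wallis H matches the rank-formula oracle and handles ties", {
  # exchangeable groups: no separation
  same <- list(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5),
               c = c(1, 2, 3, 4, 5))
  kw0 <- kruskal_wallis(same)
  expect_lt(kw0$H, 1e-10)
  expect_gt(kw0$p, 0.999)
  # 4 x 5 toy with ties against the independent rank formula
  toy <- list(CS = c(0.061, 0.064, 0.070, 0.070, 0.075),
              CR = c(0.077, 0.082, 0.070, 0.090, 0.074),
              BR = c(0.070, 0.069, 0.071, 0.064, 0.077),
              BS = c(0.068, 0.066, 0.073, 0.070, 0.072))
  kw <- kruskal_wallis(toy)
  expect_equal(kw$H, kw_oracle_H(toy))
  expect_equal(kw$df, 3L)
  expect_equal(kw$effect_size, (kw$H - 4 + 1) / (20 - 4))
  # H is invariant under strictly monotone transforms of the pooled data
  toy_t <- lapply(toy, function(v) exp(5 * v))
  expect_equal(kruskal_wallis(toy_t)$H, kw$H)
  expect_error(kruskal_wallis(list(a = 1:3, b = numeric(0))), "non-empty")
})

test_that("Dunn z matches a brute-force oracle and Bonferroni never shrinks p", {
  two <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  d2 <- dunn_bonferroni(two)
  expect_equal(d2$z, 0)
  expect_equal(d2$p_adjusted, 1)
  toy <- list(g1 = c(2.1, 3.5, 1.2, 4.4), g2 = c(5.1, 6.0, 4.9),
              g3 = c(0.5, 1.1, 0.9, 2.2, 1.4))
  d <- dunn_bonferroni(toy)
  for (i in seq_len(nrow(d)))
    expect_equal(d$z[i], dunn_oracle_z(d$group1[i], d$group2[i], toy))
  expect_true(all(d$p_adjusted >= d$p_raw))
  expect_true(all(d$p_adjusted <= 1))
  expect_equal(d$p_adjusted, pmin(1, 3 * d$p_raw))
})

test_that("inverse-Gaussian GLM fits exactly, matches the deviance oracle,
           and flags bad input", {
  set.seed(2)
  n <- 60L
  dat <- data.frame(WW_g = runif(n, 5, 25), Arch_deg = runif(n, 0, 20))
  # zero-dispersion response exactly on the log-link mean model
  dat$F3D_N <- exp(-2.6 + 0.01 * dat$WW_g + 0.02 * dat$Arch_deg)
  fit <- fit_invgauss_glm(dat, F3D_N ~ WW_g + Arch_deg)
  expect_lt(fit$residual_deviance, 1e-10)
  expect_equal(unname(coef(fit)), c(-2.6, 0.01, 0.02), tolerance = 1e-6)
  # null deviance equals the closed-form sum of unit deviances about mean(y)
  dat$F3D_N <- dat$F3D_N * rlnorm(n, 0, 0.2)
  fit2 <- fit_invgauss_glm(dat, F3D_N ~ WW_g + Arch_deg)
  expect_equal(fit2$null_deviance,
               sum(invgauss_unit_deviance(dat$F3D_N, mean(dat$F3D_N))))
  expect_lte(fit2$residual_deviance, fit2$null_deviance)
  # deviance decreases weakly as nested terms are added
  fit1 <- fit_invgauss_glm(dat, F3D_N ~ WW_g)
  expect_lte(fit2$residual_deviance, fit1$residual_deviance)
  # domain errors
  bad <- dat; bad$F3D_N[1] <- -0.1
  expect_error(fit_invgauss_glm(bad, F3D_N ~ WW_g), "positive response")
  alias <- dat; alias$WW2 <- 2 * alias$WW_g
  expect_error(fit_invgauss_glm(alias, F3D_N ~ WW_g + WW2), "rank-deficient")
})

test_that("planted morphometric coefficients are recovered at study scale", {
  scfg <- signal_config()
  planted <- c("factor(FinSpreadClass)2" = scfg$beta_fin[2],
               "factor(FinSpreadClass)3" = scfg$beta_fin[3],
               "factor(FinSpreadClass)4" = scfg$beta_fin[4],
               "Arch_deg" = scfg$beta_arch, "WW_g" = scfg$beta_ww)
  hits <- 0L; total <- 0L
  for (r in 1:10) {
    tab <- simulate_run_table(cohort_config(seed = 500 + r), scfg,
                              seed = 600 + r)
    cf <- fit_invgauss_glm(tab)$coefficients
    for (nm in names(planted)) {
      total <- total + 1L
      hits <- hits + (abs(cf[nm, "Estimate"] - planted[[nm]]) <=
                        3 * cf[nm, "Std. Error"])
    }
  }
  expect_gte(hits / total, 0.8)
})

test_that("treatment_stats assembles the full battery on preserved runs", {
  tab <- simulate_run_table(cohort_config(seed = 11), signal_config(seed = 12))
  st <- treatment_stats(tab)
  expect_s3_class(st, "treatment_stats")
  expect_equal(st$kruskal$n, 448L)
  expect_equal(nrow(st$pairwise), 6L)
  expect_true(st$shapiro$p >= 0 && st$shapiro$p <= 1)
  expect_output(print(st), "Kruskal-Wallis")
})
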