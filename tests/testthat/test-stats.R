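test_that("pearson matches exact linear relations and a direct-formula oracle", {
  x <- c(1.2, 2.5, 3.1, 4.8, 5.0, 6.3, 7.7, 8.1, 9.9, 10.4)
  r1 <- pearson(x, 2 * x + 1)
  expect_equal(r1$r, 1.0, tolerance = 1e-12)
  r2 <- pearson(x, -x)
  expect_equal(r2$r, -1.0, tolerance = 1e-12)
  y <- c(2.1, 1.9, 3.5, 4.2, 5.9, 5.1, 8.0, 7.2, 9.1, 11.3)
  res <- pearson(x, y)
  ## brute-force covariance / SD oracle
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_direct, tolerance = 1e-12)
  t_stat <- r_direct * sqrt((10 - 2) / (1 - r_direct^2))
  expect_equal(res$p, 2 * pt(-abs(t_stat), 8), tolerance = 1e-12)
  expect_identical(res$n, 10L)
  ## pairwise deletion
  y_na <- y; y_na[3] <- NA
  expect_identical(pearson(x, y_na)$n, 9L)
  expect_error(pearson(x, rep(1, 10)), "variance")
  expect_error(pearson(1:2, 1:3), "equal length")
})

test_that("ANCOVA partial F matches the brute-force nested-RSS formula", {
  set.seed(31)
  n <- 50
  group <- rep(c("tbi", "control"), c(37, 13))
  age <- round(runif(n, 20, 85))
  dep <- 1.4 - 0.004 * age - 0.05 * (group == "tbi") + rnorm(n, 0, 0.1)
  res <- ancova_group(dep, group, data.frame(age = age))
  ## independent oracle: explicit design matrices and RSS comparison
  Xf <- cbind(1, group == "tbi", age)
  rss <- function(X) {
    b <- solve(t(X) %*% X, t(X) %*% dep)
    sum((dep - X %*% b)^2)
  }
  rss_full <- rss(Xf)
  f_group <- ((rss(cbind(1, age)) - rss_full) / 1) / (rss_full / (n - 3))
  f_age <- ((rss(cbind(1, group == "tbi")) - rss_full) / 1) / (rss_full / (n - 3))
  expect_equal(res$f_group, f_group, tolerance = 1e-10)
  expect_equal(res$covariate_tests$age$f, f_age, tolerance = 1e-10)
  expect_equal(res$df, c(1, n - 3))
  expect_equal(res$p_group, pf(f_group, 1, n - 3, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("ANCOVA adjusted means agree with the emmeans oracle", {
  skip_if_not_installed("emmeans")
  set.seed(5)
  n <- 40
  group <- rep(c("tbi", "control"), each = 20)
  age <- round(runif(n, 20, 80))
  dep <- 2 - 0.01 * age - 0.2 * (group == "tbi") + rnorm(n, 0, 0.3)
  res <- ancova_group(dep, group, data.frame(age = age))
  dat <- data.frame(dep = dep, group = factor(group), age = age)
  emm <- as.data.frame(emmeans::emmeans(lm(dep ~ group + age, dat), "group"))
  expect_equal(unname(res$adjusted_means[as.character(emm$group)]),
               emm$emmean, tolerance = 1e-10)
})

test_that("a pure group shift is detected and identical groups give F = 0", {
  n <- 30
  age <- rep(seq(25, 75, length.out = n / 2), 2)   # age balanced across groups
  group <- rep(c("a", "b"), each = n / 2)
  base <- sin(seq_len(n / 2))                       # same values in both groups
  ## constructed shift, zero noise: dep is exactly linear in age plus the
  ## group offset, so the full-model residuals separate exactly
  dep <- 0.002 * age + 0.5 * (group == "b")
  res <- ancova_group(dep, group, data.frame(age = age))
  expect_identical(res$f_group, Inf)
  expect_equal(res$p_group, 0)
  ## tiny noise: p far below 0.001
  set.seed(8)
  dep2 <- dep + rnorm(n, 0, 1e-4)
  res2 <- ancova_group(dep2, group, data.frame(age = age))
  expect_lt(res2$p_group, 1e-6)
  ## identical group distributions: F exactly 0
  res3 <- ancova_group(c(base, base) + 0.002 * age, group, data.frame(age = age))
  expect_equal(res3$f_group, 0, tolerance = 1e-9)
})

test_that("ANCOVA rejects singular designs", {
  group <- rep(c("a", "b"), each = 10)
  age <- ifelse(group == "a", 30, 60)   # covariate collinear with group
  dep <- rnorm(20)
  expect_error(ancova_group(dep, group, data.frame(age = age)), "singular")
})

test_that("regression coefficients match the normal-equations oracle", {
  set.seed(12)
  n <- 20
  X <- data.frame(alps = rnorm(n, 1.35, 0.15),
                  pvs = rnorm(n, 1, 0.4),
                  age = runif(n, 20, 80))
  y <- 40 - 20 * X$alps + 2 * X$pvs + 0.3 * X$age + rnorm(n, 0, 3)
  res <- multiple_regression(y, X)
  Xd <- cbind(1, as.matrix(X))
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
  expect_equal(res$coefficients$b_raw, unname(beta[-1]), tolerance = 1e-10)
  ## standardized coefficients satisfy b_std = b_raw * SD(x) / SD(y)
  expect_equal(res$coefficients$b_std,
               unname(beta[-1]) * apply(X, 2, sd) / sd(y), tolerance = 1e-10,
               ignore_attr = TRUE)
  ## R^2 from the oracle residuals
  rss <- sum((y - Xd %*% beta)^2)
  tss <- sum((y - mean(y))^2)
  expect_equal(res$r_squared, 1 - rss / tss, tolerance = 1e-12)
})

test_that("single-predictor standardized coefficient equals Pearson r", {
  set.seed(3)
  x <- rnorm(25); y <- 1 + 0.6 * x + rnorm(25, 0, 0.8)
  res <- multiple_regression(y, data.frame(x = x))
  expect_equal(res$coefficients$b_std, pearson(x, y)$r, tolerance = 1e-12)
})

test_that("an exact linear combination gives R squared of 1", {
  set.seed(4)
  X <- data.frame(a = rnorm(15), b = rnorm(15))
  y <- 2 + 3 * X$a - 1.5 * X$b
  res <- suppressWarnings(multiple_regression(y, X))
  expect_equal(res$r_squared, 1.0, tolerance = 1e-12)
})

test_that("collinear predictors are rejected with the offending columns named", {
  set.seed(6)
  x <- rnorm(30)
  X <- data.frame(x1 = x, x2 = 2 * x + 1e-13 * rnorm(30), z = rnorm(30))
  expect_error(multiple_regression(rnorm(30), X), "collinear.*x[12].*x[12]")
})

test_that("partial-regression residuals reproduce the focal coefficient", {
  set.seed(9)
  n <- 30
  X <- data.frame(alps = rnorm(n), age = rnorm(n))
  y <- 5 - 2 * X$alps + 0.5 * X$age + rnorm(n)
  res <- multiple_regression(y, X)
  pr <- res$partial_residuals$alps
  ## slope of the added-variable plot equals the multiple-regression slope
  slope <- sum(pr$x * pr$y) / sum(pr$x^2)
  expect_equal(slope, res$coefficients$b_raw[res$coefficients$predictor == "alps"],
               tolerance = 1e-10)
})

test_that("listwise deletion reports the n actually used", {
  set.seed(10)
  X <- data.frame(a = rnorm(20), b = rnorm(20))
  y <- rnorm(20); y[c(2, 5)] <- NA; X$a[7] <- NA
  res <- multiple_regression(y, X)
  expect_identical(res$n, 17L)
})

test_that("the cohort report recovers generative structure deterministically", {
  spc <- cohort_spec(seed = 77)
  tab <- generate_cohort(spc)$table
  rep1 <- group_compare(tab)
  ## negative generative ALPS -> NfL coefficient is recovered with its sign
  expect_s3_class(rep1$nfl_regression, "regression_result")
  b_alps <- rep1$nfl_regression$coefficients$b_std[
    rep1$nfl_regression$coefficients$predictor == "alps"]
  expect_lt(b_alps, 0)
  ## volume/count correlation mirrors its generative coupling
  expect_gt(rep1$correlations$pvs_volume_vs_pvs_count$r, 0.7)
  ## bit-for-bit reproducible under the same cohort seed
  rep2 <- group_compare(generate_cohort(cohort_spec(seed = 77))$table)
  expect_identical(report_snapshot(rep1), report_snapshot(rep2))
})

test_that("an identical sex split across groups gives a chi-square of zero", {
  spc <- cohort_spec(n_tbi = 26, n_control = 14, seed = 2)
  tab <- generate_cohort(spc)$table
  ## equal male proportion (one half) in both groups
  tab$sex <- "F"
  tab$sex[tab$group == "tbi"][1:13] <- "M"
  tab$sex[tab$group == "control"][1:7] <- "M"
  rep3 <- group_compare(tab)
  expect_equal(unname(rep3$demographics$sex_chisq$statistic), 0, tolerance = 1e-12)
})

test_that("missing required columns are reported by name", {
  tab <- generate_cohort(cohort_spec(seed = 1))$table
  tab$pvs_score <- NULL
  expect_error(group_compare(tab), "pvs_score")
})

test_that("the adjusted group difference is recovered without bias and CIs cover", {
  ## 200 cohorts at the study's group sizes with a -0.05 generative ALPS
  ## difference; the ANCOVA estimate should be unbiased (mean within 10%)
  ## and 95% confidence intervals should cover the truth 90-99% of the time
  res <- vapply(1:200, function(s) {
    spc <- cohort_spec(n_tbi = 37, n_control = 13,
                       group_alps_means = c(tbi = 1.336, control = 1.386),
                       alps_sd = 0.16, age_slope_alps = -0.005, seed = s)
    tab <- generate_cohort(spc)$table
    dat <- data.frame(dep = tab$alps_mean,
                      group = factor(tab$group, c("control", "tbi")),
                      age = tab$age)
    fit <- lm(dep ~ group + age, dat)
    ci <- confint(fit)["grouptbi", ]
    c(est = coef(fit)[["grouptbi"]], cover = ci[1] <= -0.05 && -0.05 <= ci[2])
  }, numeric(2))
  expect_lt(abs(mean(res[1, ]) - (-0.05)) / 0.05, 0.10)
  cover <- mean(res[2, ])
  expect_gte(cover, 0.90)
  expect_lte(cover, 0.99)
})
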