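test_that("ICC(3,1) is exact for perfect agreement and matches an aov-based oracle", {
  set.seed(41)
  x <- rnorm(12)
  perfect <- cbind(x, x)
  expect_equal(icc31(perfect)$icc, 1)
  # hand-built 6 x 2 table against a variance-components oracle from aov()
  r <- matrix(c(9, 2, 5, 8, 6, 1,
                10, 4, 6, 7, 8, 2), ncol = 2)
  got <- icc31(r)
  long <- data.frame(y = as.vector(r),
                     subj = factor(rep(1:6, 2)), rater = factor(rep(1:2, each = 6)))
  ms <- summary(aov(y ~ subj + rater, data = long))[[1]][, "Mean Sq"]
  icc_oracle <- (ms[1] - ms[3]) / (ms[1] + (2 - 1) * ms[3])
  expect_equal(got$icc, icc_oracle, tolerance = 1e-12)
  expect_true(got$ci[1] < got$icc && got$icc < got$ci[2])
  expect_error(icc31(matrix(1, 6, 2)), "ICC undefined")
  expect_error(icc31(matrix(rnorm(8), 4, 2)), ">= 5 subjects")
})

test_that("ICC(3,1) is near zero for independent raters", {
  set.seed(42)
  r <- matrix(rnorm(400), 200, 2)
  expect_lt(abs(icc31(r)$icc), 0.15)
})

test_that("ICV residual correction removes the ICV slope and preserves the mean", {
  set.seed(43)
  icv <- rnorm(30, 1.5e6, 1e5)
  # volumes uncorrelated with ICV (slope exactly 0 by construction)
  v0 <- rnorm(30, 500, 20)
  v0 <- v0 - cov(v0, icv) / var(icv) * (icv - mean(icv))
  expect_equal(icvCorrect(v0, icv), v0, tolerance = 1e-9)
  # volumes = c * ICV -> all adjusted values equal c * mean(ICV)
  v1 <- 3e-4 * icv
  adj <- icvCorrect(v1, icv)
  expect_true(all(abs(adj - 3e-4 * mean(icv)) < 1e-9))
  v2 <- rnorm(30, 500, 30) + 2e-4 * icv
  expect_equal(mean(icvCorrect(v2, icv)), mean(v2), tolerance = 1e-9)
  expect_lt(abs(cov(icvCorrect(v2, icv), icv)), 1e-6 * var(icv))
  expect_error(icvCorrect(v2, rep(1e6, 30)), "zero ICV variance")
})

test_that("one-way ANOVA + Tukey matches a sums-of-squares oracle and the t^2 identity", {
  vals <- c(4.1, 5.2, 6.3, 3.9, 8.8, 7.6, 9.1, 10.2, 1.2, 2.4, 1.9)
  grp <- rep(c("a", "b", "c"), c(4, 4, 3))
  got <- anovaTukey(vals, grp)
  # brute-force F
  gm <- mean(vals)
  ssb <- sum(tapply(vals, grp, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(unlist(tapply(vals, grp, function(v) (v - mean(v))^2)))
  Fo <- (ssb / 2) / (ssw / (length(vals) - 3))
  expect_equal(got$F, Fo, tolerance = 1e-10)
  expect_equal(got$df, c(2, 8))
  expect_equal(nrow(got$tukey), 3)
  # identical groups -> F = 0
  expect_equal(anovaTukey(rep(c(1, 2, 3), 2), rep(c("x", "y"), each = 3))$F, 0)
  # two groups: F equals the squared pooled-variance t statistic
  set.seed(44)
  a <- rnorm(12); b <- rnorm(12, 0.8)
  t2 <- t.test(a, b, var.equal = TRUE)$statistic^2
  expect_equal(anovaTukey(c(a, b), rep(c("a", "b"), each = 12))$F,
               unname(t2), tolerance = 1e-9)
  expect_error(anovaTukey(c(1, 2, 3), c("a", "a", "b")), ">= 2 values")
})

test_that("ANOVA type-I error is near alpha under the null", {
  set.seed(45)
  p <- replicate(200, {
    v <- rnorm(40)
    anovaTukey(v, rep(letters[1:4], each = 10), alpha = 0.05)$p
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 0.05)
})

test_that("the BMI regression standardizes correctly and reports VIFs", {
  set.seed(46)
  n <- 120
  tab <- data.frame(
    md_anterior_superior = rnorm(n), md_anterior_inferior = rnorm(n),
    md_intermediate = rnorm(n), md_posterior = rnorm(n),
    fitness = rnorm(n, 100, 15), age = sample(22:36, n, TRUE),
    sex = sample(c("male", "female"), n, TRUE))
  tab$bmi <- 26 + 1.2 * tab$md_anterior_superior + rnorm(n)
  fit <- fitBmiModel(tab)
  expect_equal(fit$df[2], n - 7 - 1)
  expect_true(all(fit$coefficients$vif[-1] >= 1))
  # VIF oracle: 1 / (1 - R^2_j) from regressing each predictor on the others
  z <- function(v) (v - mean(v)) / sd(v)
  X <- data.frame(lapply(tab[, c("md_anterior_superior", "md_anterior_inferior",
                                 "md_intermediate", "md_posterior",
                                 "fitness", "age")], z))
  X$sex_male <- as.numeric(tab$sex == "male")
  for (j in seq_along(X)) {
    r2 <- summary(lm(X[[j]] ~ ., data = X[-j]))$r.squared
    expect_equal(fit$coefficients$vif[j + 1], 1 / (1 - r2), tolerance = 1e-8)
  }
  # duplicated predictor -> rank deficiency error, not silent output
  bad <- tab
  bad$md_posterior <- bad$md_anterior_superior
  expect_error(fitBmiModel(bad), "collinear")
  expect_error(fitBmiModel(tab[, -1]), "missing columns")
})

test_that("a single standardized predictor's beta equals the Pearson r", {
  set.seed(47)
  x <- rnorm(50); y <- 2 * x + rnorm(50)
  b <- unname(coef(lm(scale(y) ~ scale(x)))[2])
  expect_equal(b, cor(x, y), tolerance = 1e-10)
  # the same identity holds inside fitBmiModel with orthogonalized noise
  # predictors: near-orthogonal design keeps VIF ~ 1
  n <- 2000
  tab <- data.frame(
    md_anterior_superior = rnorm(n), md_anterior_inferior = rnorm(n),
    md_intermediate = rnorm(n), md_posterior = rnorm(n),
    fitness = rnorm(n), age = rnorm(n), sex = rep(c("male", "female"), n / 2))
  tab$bmi <- 0.5 * tab$md_anterior_superior + rnorm(n, 0, sqrt(0.75))
  fit <- fitBmiModel(tab)
  co <- fit$coefficients
  expect_lt(max(abs(co$vif[-1] - 1)), 0.05)
  expect_equal(co$beta[co$predictor == "md_anterior_superior"],
               cor(tab$bmi, tab$md_anterior_superior), tolerance = 0.01)
})

test_that("null-response regressions give adjusted R^2 around zero", {
  set.seed(48)
  r2 <- replicate(40, {
    n <- 100
    tab <- data.frame(
      md_anterior_superior = rnorm(n), md_anterior_inferior = rnorm(n),
      md_intermediate = rnorm(n), md_posterior = rnorm(n),
      fitness = rnorm(n), age = rnorm(n),
      sex = sample(c("male", "female"), n, TRUE), bmi = rnorm(n))
    fitBmiModel(tab)$adj_r2
  })
  expect_lt(abs(mean(r2)), 0.03)
})

test_that("Pearson correlation handles exact and null cases", {
  x <- c(1, 2, 3, 4.5)
  expect_equal(pearsonCorrelation(x, 2 * x + 1)$r, 1)
  expect_equal(pearsonCorrelation(x, -x)$r, -1)
  set.seed(49)
  inside <- replicate(100, abs(pearsonCorrelation(rnorm(500), rnorm(500))$r) < 0.12)
  expect_gte(mean(inside), 0.95)
  expect_error(pearsonCorrelation(x, rep(1, 4)), "zero variance")
  expect_error(pearsonCorrelation(1:2, 1:2), "n >= 3")
})
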