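#' Intraclass correlation ICC(3,1)
#'
#' Two-way mixed-model, single-measurement, consistency ICC for inter-rater
#' reliability: (MS_rows - MS_error) / (MS_rows + (k - 1) MS_error) from the
#' two-way (subjects x raters) ANOVA decomposition, with the exact F-based
#' 95% confidence interval of the classic single-score formulation.
#'
#' @param ratings numeric matrix, subjects x raters (>= 5 subjects, >= 2
#'   raters).
#' @param conf confidence level (default 0.95).
#' @return `list(icc, ci = c(lower, upper), ms_rows, ms_error, df)`.
#' @export
icc31 <- function(ratings, conf = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (k < 2) stop("need >= 2 raters")
  if (n < 5) stop("need >= 5 subjects")
  mu <- mean(ratings)
  ssr <- k * sum((rowMeans(ratings) - mu)^2)
  ssc <- n * sum((colMeans(ratings) - mu)^2)
  sst <- sum((ratings - mu)^2)
  sse <- sst - ssr - ssc
  if (ssr <= .Machine$double.eps * sst)
    stop("ICC undefined: zero between-subject variance (constant ratings)")
  msr <- ssr / (n - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse)
  alpha <- 1 - conf
  Fobs <- msr / mse
  fl <- Fobs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
  fu <- Fobs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
  ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  list(icc = icc, ci = ci, ms_rows = msr, ms_error = mse,
       df = c(n - 1, (n - 1) * (k - 1)))
}

#' Residual-approach ICV correction
#'
#' Adjusts regional volumes for head size by removing their linear dependence
#' on total intracranial volume: adjusted_i = volume_i - b (ICV_i - mean ICV),
#' with b the least-squares slope of volume on ICV. The cohort mean volume is
#' preserved.
#'
#' @param volumes,icvs numeric vectors (mm^3), one value per subject (>= 3).
#' @return Adjusted volumes (mm^3).
#' @export
icvCorrect <- function(volumes, icvs) {
  if (length(volumes) != length(icvs)) stop("volumes and icvs differ in length")
  if (length(volumes) < 3) stop("need >= 3 subjects")
  v <- stats::var(icvs)
  if (v <= 0) stop("zero ICV variance")
  b <- stats::cov(volumes, icvs) / v
  volumes - b * (icvs - mean(icvs))
}

#' One-way ANOVA with Tukey HSD post hoc test
#'
#' Compares a measurement between clusters: one-way ANOVA F and p via
#' `stats::aov()`, pairwise comparisons via `stats::TukeyHSD()` (studentized
#' range distribution). Significance flags use `alpha`, defaulting to the
#' Bonferroni-adjusted 0.017 used when three cluster ANOVAs (volume, FA, MD)
#' are run together.
#'
#' @param values numeric measurements.
#' @param group factor/character of group memberships (>= 2 groups, >= 2
#'   values each).
#' @param alpha significance level for flags (default 0.017).
#' @return `list(F, df = c(between, within), p, significant, tukey)` where
#'   `tukey` is a data.frame with columns `comparison`, `diff`, `lwr`, `upr`,
#'   `p_adj`, `significant`.
#' @export
anovaTukey <- function(values, group, alpha = 0.017) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need >= 2 groups")
  if (any(table(group) < 2)) stop("every group needs >= 2 values")
  fit <- stats::aov(values ~ group)
  tab <- summary(fit)[[1]]
  Fv <- tab["group", "F value"]
  p <- tab["group", "Pr(>F)"]
  df <- c(tab["group", "Df"], tab["Residuals", "Df"])
  tk <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"],
                      significant = tk[, "p adj"] < alpha,
                      row.names = NULL)
  list(F = Fv, df = df, p = p, significant = p < alpha, tukey = tukey,
       alpha = alpha)
}

#' Multiple regression of BMI on subunit mean diffusivity
#'
#' Ordinary least squares of BMI on the four subunit MDs, cardiovascular
#' fitness, age, and sex. Response and continuous predictors are z-scored
#' before fitting, so their coefficients are standardized; sex enters as a raw
#' 0/1 indicator (labelled `sex_male`), whose coefficient is therefore on a
#' different scale. Reports per-predictor beta, SE, t, p and VIF (via
#' [car::vif()]), the model F with (p, n - p - 1) df, and adjusted R^2.
#'
#' @param table `data.frame` with columns `bmi`, `md_anterior_superior`,
#'   `md_anterior_inferior`, `md_intermediate`, `md_posterior`, `fitness`,
#'   `age`, `sex` (factor/character with level "male", or 0/1 numeric).
#' @return `list(coefficients (data.frame: predictor, beta, se, t, p, vif),
#'   F, df, p, adj_r2, n)`.
#' @export
fitBmiModel <- function(table) {
  needed <- c("bmi", "md_anterior_superior", "md_anterior_inferior",
              "md_intermediate", "md_posterior", "fitness", "age", "sex")
  miss <- setdiff(needed, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  cont <- c("md_anterior_superior", "md_anterior_inferior", "md_intermediate",
            "md_posterior", "fitness", "age")
  d <- table[, needed]
  if (anyNA(d)) stop("missing values in modelled columns")
  if (nrow(d) <= length(cont) + 2) stop("too few subjects for the model")
  z <- function(v) (v - mean(v)) / stats::sd(v)
  df <- data.frame(bmi = z(d$bmi))
  for (v in cont) {
    if (stats::sd(d[[v]]) == 0) stop("constant predictor: ", v)
    df[[v]] <- z(d[[v]])
  }
  df$sex_male <- if (is.numeric(d$sex)) as.numeric(d$sex > 0)
  else as.numeric(d$sex == "male")
  X <- as.matrix(df[, -1])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    bad <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)] - 1L]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(bmi ~ ., data = df)
  sm <- summary(fit)
  co <- sm$coefficients
  vifs <- car::vif(fit)
  coef_tab <- data.frame(
    predictor = rownames(co),
    beta = co[, "Estimate"], se = co[, "Std. Error"],
    t = co[, "t value"], p = co[, "Pr(>|t|)"],
    vif = c(NA_real_, vifs[rownames(co)[-1]]),
    row.names = NULL)
  fstat <- sm$fstatistic
  list(coefficients = coef_tab,
       F = unname(fstat["value"]),
       df = unname(fstat[c("numdf", "dendf")]),
       p = unname(stats::pf(fstat["value"], fstat["numdf"], fstat["dendf"],
                            lower.tail = FALSE)),
       adj_r2 = sm$adj.r.squared, n = nrow(df))
}

#' Pearson correlation with two-sided test
#'
#' @param x,y numeric vectors (n >= 3, nonzero variance).
#' @return `list(r, p)`.
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
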