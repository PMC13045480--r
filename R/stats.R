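#' z-score standardization
#'
#' Centres to mean 0 and scales to sample SD 1 (n - 1 denominator), the
#' standardization applied to every variable before regression so that
#' coefficients are comparable across models.
#'
#' @param values Numeric vector, length >= 2, non-constant.
#' @return The z-scores.
#' @examples
#' standardize(c(1, 2, 3))
#' @export
standardize <- function(values) {
  if (!is.numeric(values) || length(values) < 2L || anyNA(values)) {
    stop("'values' must be a numeric vector of length >= 2 without NAs")
  }
  s <- stats::sd(values)
  if (s == 0) stop("cannot standardize a constant vector")
  (values - mean(values)) / s
}

#' Linear regression on z-scored variables with diagnostics
#'
#' Ordinary least squares of the standardized outcome on the standardized
#' predictor(s) plus optional covariates (also standardized), with 95%
#' confidence intervals from the t distribution, and the usual assumption
#' checks: variance inflation factors (multicollinearity; > 10 flags a
#' violation), the Durbin-Watson statistic (residual autocorrelation),
#' maximal Cook's distance (influential points), an Anderson-Darling test
#' on the residuals (normality; `ok` when p > 0.01), and the slope of the
#' spread-location regression (sqrt(|standardized residual|) on fitted
#' values; `ok` when |slope| < 0.1).
#'
#' @param data Data frame holding all variables.
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of predictor column names.
#' @param covariates Optional character vector of adjustment columns.
#' @return A list of class `regression_result`: `coefficients` (tibble:
#'   `term`, `beta_std`, `ci_lo`, `ci_hi`, `p`), `diagnostics` (list:
#'   `vif`, `durbin_watson`, `max_cooks_d`, `residual_normality_ok`,
#'   `homoscedasticity_ok`, `spread_location_slope`, `ad_p`), `n`,
#'   and the fitted `model`.
#' @export
fit_regression <- function(data, outcome, predictors, covariates = character()) {
  vars <- c(outcome, predictors, covariates)
  if (!all(vars %in% names(data))) {
    stop("missing columns: ", paste(setdiff(vars, names(data)), collapse = ", "))
  }
  df <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  k <- length(predictors) + length(covariates)
  if (nrow(df) < 10L * max(1L, k)) {
    stop("need at least 10 observations per predictor")
  }
  z <- as.data.frame(lapply(df, standardize))
  rhs <- c(predictors, covariates)
  fml <- stats::reformulate(rhs, response = outcome)
  fit <- stats::lm(fml, data = z)
  if (any(!is.finite(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[!is.finite(stats::coef(fit))]
    stop("singular design; collinear columns: ", paste(bad, collapse = ", "))
  }
  ci <- stats::confint(fit, level = 0.95)
  sm <- summary(fit)$coefficients
  terms_keep <- rhs
  coefs <- tibble::tibble(
    term = terms_keep,
    beta_std = stats::coef(fit)[terms_keep],
    ci_lo = ci[terms_keep, 1L],
    ci_hi = ci[terms_keep, 2L],
    p = sm[terms_keep, 4L])

  vif <- if (length(rhs) >= 2L) car::vif(fit) else
    stats::setNames(1, rhs)
  dw <- unname(lmtest::dwtest(fit)$statistic)
  cooks <- max(stats::cooks.distance(fit))
  res <- stats::rstandard(fit)
  ad <- tryCatch(nortest::ad.test(res)$p.value, error = function(e) NA_real_)
  sl <- stats::coef(stats::lm(sqrt(abs(res)) ~ stats::fitted(fit)))[[2L]]
  structure(list(
    coefficients = coefs,
    diagnostics = list(
      vif = vif, durbin_watson = dw, max_cooks_d = cooks,
      ad_p = ad,
      residual_normality_ok = is.na(ad) || ad > 0.01,
      spread_location_slope = sl,
      homoscedasticity_ok = abs(sl) < 0.1),
    n = nrow(df), model = fit),
    class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result: n = %d>\n", x$n))
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' @param x,y Numeric vectors of equal length (n > 3).
#' @param alpha Two-sided error rate (default 0.05 for a 95% CI).
#' @return A list with `r`, `ci` (length 2), `n`.  For |r| = 1 the CI
#'   degenerates to the point itself.
#' @examples
#' set.seed(1)
#' x <- rnorm(100); pearson_with_ci(x, x + rnorm(100))
#' @export
pearson_with_ci <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n <= 3L) stop("need more than 3 complete pairs")
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    ci <- c(r, r)
  } else {
    z <- atanh(r)
    hw <- stats::qnorm(1 - alpha / 2) / sqrt(n - 3)
    ci <- tanh(c(z - hw, z + hw))
  }
  list(r = r, ci = ci, n = n)
}

# Covariance term between two Fisher-transformed overlapping correlations.
# "pooled": the common form using rbar = (r1 + r2)/2; "dunn1969": the
# per-correlation form of the original derivation.
dependent_cor_cov <- function(r1, r2, r12, method) {
  if (method == "pooled") {
    rb2 <- ((r1 + r2) / 2)^2
    (r12 * (1 - 2 * rb2) - 0.5 * rb2 * (1 - 2 * rb2 - r12^2)) / (1 - rb2)^2
  } else {
    (r12 * (1 - r1^2 - r2^2) - 0.5 * r1 * r2 * (1 - r1^2 - r2^2 - r12^2)) /
      ((1 - r1^2) * (1 - r2^2))
  }
}

#' Compare two overlapping dependent correlations (Dunn-Clark z)
#'
#' Tests whether X correlates differently with Y1 than with Y2 when all
#' three variables are measured on the same subjects, which makes the two
#' correlations dependent.  Both correlations are Fisher-transformed and
#' the dependence enters through a covariance term built from the
#' inter-correlation `r12` of Y1 and Y2:
#' `Z = (z1 - z2) * sqrt((n - 3) / (2 - 2c))`, two-sided p from the
#' standard normal.
#'
#' @param r1,r2 Correlations of the shared variable with Y1 and Y2.
#' @param r12 Correlation between Y1 and Y2.
#' @param n Sample size (> 10).
#' @param method Covariance variant: `"pooled"` (default; uses the mean of
#'   r1 and r2) or `"dunn1969"` (the original per-correlation form).
#' @return A list of class `corr_comparison`: `r1`, `r2`, `r12`, `n`,
#'   `z_stat`, `p`, `method`.
#' @examples
#' dunn_clark_test(0.72, 0.46, 0.42, n = 3837)
#' @export
dunn_clark_test <- function(r1, r2, r12, n,
                            method = c("pooled", "dunn1969")) {
  method <- match.arg(method)
  if (!(n > 10)) stop("'n' must exceed 10")
  for (r in c(r1, r2, r12)) {
    if (!is.finite(r) || abs(r) > 1) stop("correlations must lie in [-1, 1]")
  }
  R <- matrix(c(1, r1, r2, r1, 1, r12, r2, r12, 1), 3L, 3L)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("correlation matrix (1, r1, r2 / r1, 1, r12 / r2, r12, 1) is not positive semi-definite")
  }
  cterm <- dependent_cor_cov(r1, r2, r12, method)
  z1 <- atanh(r1); z2 <- atanh(r2)
  z_stat <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * cterm))
  p <- 2 * stats::pnorm(-abs(z_stat))
  structure(list(r1 = r1, r2 = r2, r12 = r12, n = n,
                 z_stat = z_stat, p = p, method = method),
            class = "corr_comparison")
}

#' @export
print.corr_comparison <- function(x, ...) {
  cat(sprintf(
    "<corr_comparison (%s): r1 = %.3f vs r2 = %.3f (r12 = %.3f, n = %d): Z = %.2f, p = %.3g>\n",
    x$method, x$r1, x$r2, x$r12, x$n, x$z_stat, x$p))
  invisible(x)
}
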