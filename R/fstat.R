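# First-stage F statistics and one-sided confidence intervals for the F
# parameter via noncentral-F inversion.

#' First-stage F statistic from individual-level data
#'
#' Global F test and R-squared from the multivariable linear regression of
#' the risk factor on all instrument columns plus an intercept. An exact
#' linear fit (zero residual sum of squares) returns `Inf`.
#'
#' @param risk_factor Numeric vector of risk-factor measurements.
#' @param genotypes Numeric matrix with one column per instrument and one
#'   row per individual.
#' @return Object of class `fstat`: list with `value`, `df1` (number of
#'   instruments), `df2` (residual degrees of freedom) and `r_squared`.
#' @examples
#' d <- simulate_continuous(sim_continuous_config(alpha = 0.08,
#'        n_total = 2000, n_sample = 1000), seed = 1)
#' observed_f(d$risk_factor, d$genotypes)
#' @export
observed_f <- function(risk_factor, genotypes) {
  genotypes <- as.matrix(genotypes)
  x <- as.numeric(risk_factor)
  n <- length(x)
  k <- ncol(genotypes)
  if (nrow(genotypes) != n)
    stop_domain("`risk_factor` and `genotypes` have different numbers of rows")
  if (n <= k + 1)
    stop_domain("need more than k + 1 observations to compute the F statistic")
  X <- cbind(`(intercept)` = 1, genotypes)
  fit <- lm.fit(X, x)
  if (fit$rank < ncol(X)) {
    dropped <- colnames(X)[is.na(fit$coefficients)]
    stop_domain("genotype matrix is rank deficient; collinear column(s): ",
                paste(dropped, collapse = ", "))
  }
  rss <- sum(fit$residuals^2)
  tss <- sum((x - mean(x))^2)
  if (tss <= 0) stop_domain("risk factor has zero variance")
  df1 <- k
  df2 <- n - k - 1
  r2 <- 1 - rss / tss
  f <- if (rss <= tss * .Machine$double.eps * n) Inf
       else (tss - rss) / df1 / (rss / df2)
  structure(list(value = f, df1 = df1, df2 = df2, r_squared = r2),
            class = "fstat")
}

#' @export
print.fstat <- function(x, ...) {
  cat(sprintf("First-stage F statistic: %.4g on %d and %d df (R2 = %.4g)\n",
              x$value, x$df1, x$df2, x$r_squared))
  invisible(x)
}

# lower confidence limit for the noncentrality parameter of an observed F:
# the largest lambda at which f_obs sits at the `level` quantile of
# noncentral F(df1, df2, lambda). pf() is decreasing in ncp, so the root is
# unique; the bracket is expanded geometrically if needed.
ncp_lower_limit <- function(f_obs, df1, df2, level, tol = 1e-8) {
  g <- function(l) pf(f_obs, df1, df2, ncp = l) - level
  if (g(0) < 0) return(list(ncp = 0, truncated = TRUE))
  hi <- max(df1 * f_obs * 10, 1)
  tries <- 0
  while (g(hi) > 0 && tries < 50) { hi <- hi * 2; tries <- tries + 1 }
  if (g(hi) > 0)
    stop_domain(sprintf(paste0(
      "noncentrality root not bracketed for F = %g (df1 = %g, df2 = %g, ",
      "level = %g); last bracket upper end %g"), f_obs, df1, df2, level, hi))
  r <- uniroot(g, c(0, hi), tol = tol * max(1, df1 * f_obs))
  list(ncp = r$root, truncated = FALSE)
}

# noncentrality -> F parameter. Anchored to worked consortium examples: the
# mode-type approximation (lambda + df1 - 2)/df1 reproduces published lower
# limits across df1 from 5 to 97, where the noncentral-F mean does not.
ncp_to_fparam <- function(ncp, df1) {
  max(1, (ncp + df1 - 2) / df1)
}

#' One-sided lower confidence limit for the F parameter
#'
#' The observed first-stage F statistic can be far from the F parameter (its
#' expectation), so bias calculations are more cautious when repeated at the
#' lower limit of a one-sided confidence interval for the F parameter. The
#' limit is obtained by noncentral-F inversion: solve for the noncentrality
#' `lambda_L` at which the observed F sits at the `level` quantile of the
#' noncentral F(df1, df2, lambda_L) distribution, then convert the
#' noncentrality to an F-parameter scale. If even `lambda = 0` places the
#' observed F below that quantile, the limit is truncated at 1 (the
#' approximate expectation of a central F) and flagged.
#'
#' @param f Observed F statistic, or an [observed_f()] result (in which case
#'   `df1`/`df2` are taken from it).
#' @param df1 Numerator degrees of freedom (number of instruments).
#' @param df2 Denominator degrees of freedom (sample size minus `df1 + 1`).
#' @param level One-sided confidence level, in (0.5, 1); default 0.95.
#' @return Object of class `fparam_ci`: list with `lower`, `level`,
#'   `noncentrality_lower`, `truncated`, and the inputs.
#' @examples
#' f_param_ci_lower(f_from_r2(0.027, 339224, 97), df1 = 97, df2 = 339126)
#' @export
f_param_ci_lower <- function(f, df1 = NULL, df2 = NULL, level = 0.95) {
  if (inherits(f, "fstat")) {
    df1 <- df1 %||% f$df1
    df2 <- df2 %||% f$df2
    f <- f$value
  }
  check_scalar(f, "f", lower = 0)
  check_scalar(df1, "df1", lower = 1)
  check_scalar(df2, "df2", lower = 1)
  check_scalar(level, "level", lower = 0.5, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  sol <- ncp_lower_limit(f, df1, df2, level)
  structure(list(lower = ncp_to_fparam(sol$ncp, df1),
                 level = level,
                 noncentrality_lower = sol$ncp,
                 truncated = sol$truncated,
                 f = f, df1 = df1, df2 = df2),
            class = "fparam_ci")
}

#' @export
print.fparam_ci <- function(x, ...) {
  cat(sprintf("One-sided %.0f%% lower confidence limit for the F parameter\n",
              100 * x$level))
  cat(sprintf("  observed F: %.4g (df1 = %g, df2 = %g)\n", x$f, x$df1, x$df2))
  cat(sprintf("  lower limit: %.4g (noncentrality %.4g)%s\n", x$lower,
              x$noncentrality_lower,
              if (x$truncated) "  [truncated at the null value]" else ""))
  invisible(x)
}

#' Project an externally estimated R-squared to a new sample size
#'
#' R-squared is independent of sample size, so instrument strength measured
#' in an external dataset can be translated into the F statistic expected at
#' the sample size of the dataset under investigation.
#'
#' @param r2_external R-squared from the external dataset, in \[0, 1).
#' @param n_target Sample size of the dataset under investigation.
#' @param k Number of instruments.
#' @return The projected F statistic.
#' @examples
#' project_f(0.001, 25490, 5) # about 5.1
#' @export
project_f <- function(r2_external, n_target, k) {
  f_from_r2(r2_external, n_target, k)
}
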