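# Closed-form calculators for weak-instrument bias, IV-estimate variance and
# Type 1 error under sample overlap. All formulas operate in raw units when
# var_x / var_ry are supplied; with the defaults (var = 1) they assume the
# risk factor and outcome are in standard deviation units.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain(sprintf("`%s` must be a single finite number", name))
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_domain(sprintf("`%s` = %g is outside its valid range %s%g, %g%s",
                        name, x, if (open_lower) "(" else "[", lower, upper,
                        if (open_upper) ")" else "]"))
  invisible(x)
}

#' Relative bias of a one-sample IV analysis
#'
#' The bias of the one-sample 2SLS (or IVW) estimate divided by the bias of
#' the observational (OLS) estimate is approximately and asymptotically the
#' reciprocal of the F parameter, the expected value of the first-stage F
#' statistic. An F parameter of 10 corresponds to a 10% relative bias.
#'
#' This quantity describes expected bias; it should not be used to "correct"
#' an estimate, because the F statistic observed in any one dataset can
#' differ substantially from the F parameter.
#'
#' @param f_param F parameter (expected first-stage F statistic), positive.
#' @return Relative bias as a proportion (0.10 means 10%).
#' @examples
#' relative_bias_one_sample(10) # 0.1
#' @export
relative_bias_one_sample <- function(f_param) {
  check_scalar(f_param, "f_param", lower = 0, open_lower = TRUE)
  1 / f_param
}

#' Nagar-style bias of the one-sample 2SLS estimator
#'
#' Approximate finite-sample bias of the two-stage least squares estimator in
#' a one-sample analysis, `sigma_xy * (k - 2) / (sigma_x2 * mu)`, where `mu`
#' is the concentration parameter, `k` the number of instruments, `sigma_x2`
#' the first-stage error variance and `sigma_xy` the covariance between the
#' first- and second-stage error terms. The cruder large-sample form
#' `sigma_xy / (sigma_x2 * E(F))`, with `E(F) = mu / k + 1`, is returned
#' alongside.
#'
#' @param sigma_xy Covariance of first- and second-stage errors.
#' @param sigma_x2 Variance of the first-stage error, positive.
#' @param k Number of instruments, at least 1.
#' @param mu Concentration parameter, strictly positive.
#' @return List with elements `exact` (the (k-2)/mu form), `approx`
#'   (the 1/E(F) form) and `e_f` (the implied F parameter).
#' @export
bias_2sls_one_sample <- function(sigma_xy, sigma_x2, k, mu) {
  check_scalar(sigma_xy, "sigma_xy")
  check_scalar(sigma_x2, "sigma_x2", lower = 0, open_lower = TRUE)
  check_scalar(k, "k", lower = 1)
  check_scalar(mu, "mu", lower = 0, open_lower = TRUE)
  e_f <- mu / k + 1
  list(exact  = sigma_xy * (k - 2) / (sigma_x2 * mu),
       approx = sigma_xy / (sigma_x2 * e_f),
       e_f    = e_f)
}

#' Expected bias under the causal null with partial sample overlap
#'
#' Under the causal null the expected bias of the IV estimate is the
#' observational (OLS) estimate times the overlap proportion times the
#' one-sample relative bias `1/F`: bias is linear in the overlap, zero for a
#' strict two-sample analysis and maximal for a one-sample analysis. The
#' overlap proportion is defined with respect to the larger of the two
#' datasets, since only shared participants induce correlation between the
#' association estimates.
#'
#' @param ols_estimate Observational regression slope (confounded estimate).
#' @param overlap Proportion of the larger sample shared, in \[0, 1\].
#' @param f_param F parameter (expected first-stage F statistic), positive.
#' @return Expected bias of the IV estimate, in the units of `ols_estimate`.
#' @examples
#' bias_under_null(1, 0.5, 10) # 0.05: 5% relative bias at 50% overlap
#' @export
bias_under_null <- function(ols_estimate, overlap, f_param) {
  check_scalar(ols_estimate, "ols_estimate")
  check_scalar(overlap, "overlap", lower = 0, upper = 1)
  ols_estimate * overlap * relative_bias_one_sample(f_param)
}

#' Approximate variance of the IV estimate, continuous outcome
#'
#' `var(R_Y) / (N * var(X) * rho2)`, where `N` is the sample size for the
#' IV-outcome associations, `R_Y` the residual outcome after removing the
#' causal effect of the risk factor (equal to the outcome itself under the
#' null), and `rho2` the proportion of risk-factor variance explained by the
#' instruments (estimated by the first-stage R-squared).
#'
#' @param n Sample size for the IV-outcome associations.
#' @param var_x Variance of the risk factor, positive.
#' @param r_squared Proportion of risk-factor variance explained by the
#'   instruments, in (0, 1).
#' @param var_ry Variance of the residual outcome, positive.
#' @return Variance of the IV estimate.
#' @export
iv_variance_continuous <- function(n, var_x, r_squared, var_ry) {
  check_scalar(n, "n", lower = 1)
  check_scalar(var_x, "var_x", lower = 0, open_lower = TRUE)
  check_scalar(r_squared, "r_squared", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  check_scalar(var_ry, "var_ry", lower = 0, open_lower = TRUE)
  var_ry / (n * var_x * r_squared)
}

#' Approximate variance of the IV estimate, binary outcome
#'
#' Case-control analogue of [iv_variance_continuous()], on the log odds
#' ratio scale: `1 / (N * var(X) * rho2 * P(Y=1) * P(Y=0))` with
#' `N = n_cases + n_controls`.
#'
#' @param n_cases,n_controls Numbers of cases and controls, both positive.
#' @inheritParams iv_variance_continuous
#' @return Variance of the IV log odds ratio estimate.
#' @export
iv_variance_binary <- function(n_cases, n_controls, var_x, r_squared) {
  check_scalar(n_cases, "n_cases", lower = 0, open_lower = TRUE)
  check_scalar(n_controls, "n_controls", lower = 0, open_lower = TRUE)
  check_scalar(var_x, "var_x", lower = 0, open_lower = TRUE)
  check_scalar(r_squared, "r_squared", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  n <- n_cases + n_controls
  p1 <- n_cases / n
  1 / (n * var_x * r_squared * p1 * (1 - p1))
}

#' Type 1 error rate of a biased normal test statistic
#'
#' For a two-sided test of nominal size `alpha_level`, an estimator with
#' expectation `bias` and standard error `se` rejects the null with
#' probability `2 - pnorm(z - bias/se) - pnorm(z + bias/se)` where
#' `z = qnorm(1 - alpha_level/2)`. The expression is symmetric in the sign
#' of the bias, equals `alpha_level` at zero bias, and increases to 1 as
#' `|bias|/se` grows.
#'
#' @param bias Expected bias of the estimator.
#' @param se Standard error of the estimator, positive.
#' @param alpha_level Nominal two-sided test size, in (0, 1); default 0.05
#'   (critical value 1.96).
#' @return Rejection probability in \[0, 1\].
#' @export
type1_error <- function(bias, se, alpha_level = 0.05) {
  check_scalar(bias, "bias")
  check_scalar(se, "se", lower = 0, open_lower = TRUE)
  check_scalar(alpha_level, "alpha_level", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  z <- qnorm(1 - alpha_level / 2)
  2 - pnorm(z - bias / se) - pnorm(z + bias / se)
}

#' Convert between the F statistic and R-squared
#'
#' For a regression of the risk factor on `k` instruments in a sample of
#' size `n`, `F = (n - k - 1) / k * r_squared / (1 - r_squared)`. Because
#' R-squared is independent of sample size, `f_from_r2()` also serves to
#' project instrument strength measured in an external dataset onto the
#' sample size under investigation (see [project_f()]).
#'
#' @param r_squared Proportion of variance explained, in \[0, 1).
#' @param f F statistic, non-negative.
#' @param n Sample size; must exceed `k + 1`.
#' @param k Number of instruments.
#' @return The implied F statistic, or R-squared for the inverse map.
#' @examples
#' f_from_r2(0.027, 339224, 97) # about 97.0
#' @export
f_from_r2 <- function(r_squared, n, k) {
  check_scalar(r_squared, "r_squared", lower = 0, upper = 1, open_upper = TRUE)
  check_scalar(k, "k", lower = 1)
  check_scalar(n, "n", lower = k + 1, open_lower = TRUE)
  (n - k - 1) / k * r_squared / (1 - r_squared)
}

#' @rdname f_from_r2
#' @export
r2_from_f <- function(f, n, k) {
  check_scalar(f, "f", lower = 0)
  check_scalar(k, "k", lower = 1)
  check_scalar(n, "n", lower = k + 1, open_lower = TRUE)
  a <- k * f / (n - k - 1)
  a / (1 + a)
}

#' R-squared explained by a single biallelic variant
#'
#' Under Hardy-Weinberg equilibrium a variant with per-allele effect
#' `alpha_hat` (risk factor in standard deviation units) and minor allele
#' frequency `maf` explains `2 * alpha_hat^2 * maf * (1 - maf)` of the
#' risk-factor variance.
#'
#' @param alpha_hat Per-allele association with the risk factor, SD units.
#' @param maf Minor allele frequency, in (0, 1).
#' @return Proportion of variance explained.
#' @export
r2_single_snp <- function(alpha_hat, maf) {
  check_scalar(alpha_hat, "alpha_hat")
  check_scalar(maf, "maf", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  2 * alpha_hat^2 * maf * (1 - maf)
}

#' Convert between the F parameter and the concentration parameter
#'
#' For large samples the expected first-stage F statistic relates to the
#' concentration parameter by `E(F) = mu / k + 1`, so `mu = k * (E(F) - 1)`.
#'
#' @param f_param F parameter, at least 1.
#' @param mu Concentration parameter, non-negative.
#' @param k Number of instruments.
#' @return The concentration parameter, or the F parameter for the inverse.
#' @export
concentration_from_f <- function(f_param, k) {
  check_scalar(f_param, "f_param", lower = 1)
  check_scalar(k, "k", lower = 1)
  k * (f_param - 1)
}

#' @rdname concentration_from_f
#' @export
f_from_concentration <- function(mu, k) {
  check_scalar(mu, "mu", lower = 0)
  check_scalar(k, "k", lower = 1)
  mu / k + 1
}

resolve_strength <- function(f_param, r_squared, n, k, tol = 0.01) {
  if (is.null(f_param) && is.null(r_squared))
    stop_domain("supply instrument strength as `f_param` or `r_squared`")
  if (!is.null(f_param) && !is.null(r_squared)) {
    implied <- f_from_r2(r_squared, n, k)
    if (abs(implied - f_param) > tol * max(abs(f_param), 1))
      stop_domain(sprintf(paste0(
        "`f_param` (%.4g) and `r_squared` (%.4g) disagree: the F/R-squared ",
        "relation implies F = %.4g at n = %g, k = %g; supply consistent ",
        "values or only one of the two"), f_param, r_squared, implied, n, k))
  }
  if (is.null(f_param)) f_param <- f_from_r2(r_squared, n, k)
  if (is.null(r_squared)) r_squared <- r2_from_f(f_param, n, k)
  check_scalar(f_param, "f_param", lower = 0, open_lower = TRUE)
  list(f_param = f_param, r_squared = r_squared)
}

#' Expected bias and Type 1 error under sample overlap
#'
#' The package's headline calculator: given the observational (OLS)
#' estimate, the overlap proportion, the instrument strength (F parameter or
#' R-squared), the outcome sample size and the number of instruments, it
#' composes the bias-under-null, IV-variance and Type-1-error formulas into
#' the expected behaviour of the IV estimate under the causal null.
#'
#' Supplying `n_cases` and `n_controls` switches to the binary case-control
#' variance formula (log odds ratio scale); otherwise the continuous-outcome
#' formula is used. With the default `var_x = var_ry = 1` the risk factor
#' and outcome are assumed to be in standard deviation units; supply the
#' actual variances for raw units. When both `f_param` and `r_squared` are
#' given they are checked against each other through the F/R-squared
#' relation (1% relative tolerance) rather than silently preferring one.
#'
#' @param ols_estimate Observational (confounded) regression slope; log odds
#'   ratio for a binary outcome.
#' @param overlap Proportion of the larger sample shared, in \[0, 1\].
#' @param f_param F parameter; supply this or `r_squared` (or both,
#'   consistently).
#' @param r_squared Proportion of risk-factor variance explained by the
#'   instruments, in \[0, 1).
#' @param n Sample size for the IV-outcome associations (for a binary
#'   outcome it defaults to `n_cases + n_controls`).
#' @param k Number of instruments.
#' @param var_x Variance of the risk factor (default 1 = SD units).
#' @param var_ry Variance of the residual outcome, equal to the outcome
#'   variance under the null (default 1 = SD units). Ignored for binary
#'   outcomes.
#' @param n_cases,n_controls Case and control counts for a binary outcome.
#' @param alpha_level Nominal two-sided test size, default 0.05.
#' @return An object of class `overlap_bias`: a list with `bias`,
#'   `relative_bias`, `iv_se`, `type1_error`, the resolved `f_param` and
#'   `r_squared`, the `outcome` type, and the call inputs.
#' @examples
#' overlap_bias(ols_estimate = 0.6, overlap = 0.5, f_param = 10,
#'              n = 50000, k = 20)
#' @export
overlap_bias <- function(ols_estimate, overlap, f_param = NULL,
                         r_squared = NULL, n = NULL, k = NULL,
                         var_x = 1, var_ry = 1,
                         n_cases = NULL, n_controls = NULL,
                         alpha_level = 0.05) {
  binary <- !is.null(n_cases) || !is.null(n_controls)
  if (binary && (is.null(n_cases) || is.null(n_controls)))
    stop_domain("supply both `n_cases` and `n_controls` for a binary outcome")
  if (binary && is.null(n)) n <- n_cases + n_controls
  if (is.null(n) || is.null(k))
    stop_domain("`n` and `k` are required to relate F and R-squared")
  s <- resolve_strength(f_param, r_squared, n, k)
  bias <- bias_under_null(ols_estimate, overlap, s$f_param)
  iv_var <- if (binary) {
    iv_variance_binary(n_cases, n_controls, var_x, s$r_squared)
  } else {
    iv_variance_continuous(n, var_x, s$r_squared, var_ry)
  }
  se <- sqrt(iv_var)
  out <- list(bias = bias,
              relative_bias = if (ols_estimate != 0) bias / ols_estimate
                              else overlap * relative_bias_one_sample(s$f_param),
              iv_se = se,
              type1_error = type1_error(bias, se, alpha_level),
              f_param = s$f_param,
              r_squared = s$r_squared,
              outcome = if (binary) "binary" else "continuous",
              inputs = list(ols_estimate = ols_estimate, overlap = overlap,
                            n = n, k = k, var_x = var_x, var_ry = var_ry,
                            n_cases = n_cases, n_controls = n_controls,
                            alpha_level = alpha_level))
  class(out) <- "overlap_bias"
  out
}

#' @export
print.overlap_bias <- function(x, digits = 3, ...) {
  cat("Expected weak-instrument bias under the causal null\n")
  cat(sprintf("  outcome: %s;  overlap: %.0f%%;  F parameter: %.3g (R2 = %.3g)\n",
              x$outcome, 100 * x$inputs$overlap, x$f_param, x$r_squared))
  cat(sprintf("  bias:           %.*g\n", digits, x$bias))
  cat(sprintf("  relative bias:  %.*g (%.1f%%)\n", digits, x$relative_bias,
              100 * x$relative_bias))
  cat(sprintf("  IV SE:          %.*g\n", digits, x$iv_se))
  cat(sprintf("  Type 1 error:   %.1f%% (nominal %.1f%%)\n",
              100 * x$type1_error, 100 * x$inputs$alpha_level))
  invisible(x)
}
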