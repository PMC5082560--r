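# Observational and instrumental-variable estimators, individual-level and
# summarized-data paths.

new_mr_estimate <- function(estimate, se, method, n_variants = NA_integer_,
                            nobs = NA_integer_) {
  structure(list(estimate = as.numeric(estimate), se = as.numeric(se),
                 method = method, n_variants = n_variants, nobs = nobs),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("MR estimate (%s): %.*g (SE %.*g)\n", x$method, digits,
              x$estimate, digits, x$se))
  ci <- confint(x)
  cat(sprintf("  95%% CI: %.*g to %.*g;  z = %.3f\n", digits, ci[1], digits,
              ci[2], x$estimate / x$se))
  invisible(x)
}

#' @export
coef.mr_estimate <- function(object, ...) {
  c(estimate = object$estimate)
}

#' @export
confint.mr_estimate <- function(object, parm, level = 0.95, ...) {
  z <- qnorm(1 - (1 - level) / 2)
  c(object$estimate - z * object$se, object$estimate + z * object$se)
}

# univariable linear regression of v on each column of G (with intercept);
# vectorized across columns. Returns beta, se, and a usable flag (FALSE for
# zero-variance columns).
linear_assoc <- function(G, v) {
  n <- length(v)
  gbar <- colMeans(G)
  Gc <- sweep(G, 2, gbar)
  sgg <- colSums(Gc^2)
  vc <- v - mean(v)
  svv <- sum(vc^2)
  sgv <- as.numeric(crossprod(Gc, vc))
  usable <- sgg > 0
  beta <- ifelse(usable, sgv / sgg, NA_real_)
  rss <- pmax(svv - beta^2 * sgg, 0)
  se <- ifelse(usable, sqrt(rss / (n - 2) / sgg), NA_real_)
  list(beta = beta, se = se, usable = usable)
}

# univariable logistic regression of y on g (with intercept)
logistic_assoc_one <- function(g, y) {
  X <- cbind(1, g)
  fit <- glm.fit(X, y, family = binomial())
  p <- fit$rank
  covmat <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  c(beta = unname(fit$coefficients[2]), se = sqrt(covmat[2, 2]))
}

#' Observational (ordinary least squares or logistic) estimate
#'
#' Unadjusted univariable regression of the outcome on the risk factor: the
#' confounded "observational" estimate against which relative bias is
#' measured. For a binary outcome the slope is the log odds ratio from
#' logistic regression.
#'
#' @param x Risk-factor vector.
#' @param y Outcome vector (0/1 for `binary = TRUE`).
#' @param binary Use logistic regression? Default detects a 0/1 outcome.
#' @return An `mr_estimate` with method `"ols"` (or `"logistic"`).
#' @export
mr_ols <- function(x, y, binary = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop_domain("`x` and `y` lengths differ")
  if (length(x) < 3) stop_domain("need at least 3 observations")
  if (is.null(binary)) binary <- all(y %in% c(0, 1))
  if (var(x) == 0) stop_domain("risk factor has zero variance")
  if (binary) {
    est <- logistic_assoc_one(x, y)
    return(new_mr_estimate(est["beta"], est["se"], "logistic",
                           nobs = length(x)))
  }
  a <- linear_assoc(matrix(x, ncol = 1), y)
  new_mr_estimate(a$beta, a$se, "ols", nobs = length(x))
}

#' Ratio (Wald) estimate from one variant
#'
#' The per-variant causal estimate: the variant-outcome coefficient divided
#' by the variant-risk factor coefficient, with the first-order standard
#' error `se_by / |bx|` that treats the denominator as fixed.
#'
#' @param bx Variant-risk factor association.
#' @param by Variant-outcome association.
#' @param se_by Standard error of `by`, positive.
#' @return An `mr_estimate` with method `"ratio"`.
#' @export
mr_ratio <- function(bx, by, se_by) {
  check_scalar(bx, "bx"); check_scalar(by, "by")
  check_scalar(se_by, "se_by", lower = 0, open_lower = TRUE)
  if (bx == 0)
    stop_domain("variant-risk factor association is zero: the instrument ",
                "relevance assumption appears violated")
  new_mr_estimate(by / bx, se_by / abs(bx), "ratio", n_variants = 1L)
}

#' Split-sample two-stage least squares
#'
#' First-stage multivariable regression of the risk factor on the genotypes
#' in `first_sample`; fitted risk-factor values are then constructed in
#' `second_sample` from its genotypes and the first-sample coefficients, and
#' the second stage regresses the second-sample outcome on those fitted
#' values (logistic regression for a binary outcome). Risk-factor
#' measurements in the second sample are not used, so partial or complete
#' overlap is expressed purely through which individuals appear in both
#' samples. With `second_sample` identical to `first_sample` this is the
#' standard one-sample 2SLS.
#'
#' Two standard-error conventions are available. `"second_stage"` (the
#' default) uses the second-stage regression alone — the only residual
#' information available in a genuine split-sample or summarized-data
#' analysis. `"textbook"` is the conventional one-sample 2SLS standard
#' error, with residuals computed from the observed (not fitted) risk
#' factor in the second sample; it therefore requires second-sample
#' risk-factor measurements and a continuous outcome, and is the
#' convention standard IV software reports for a one-sample analysis.
#'
#' @param first_sample,second_sample [mr_data()] objects with the same
#'   number of variants.
#' @param binary Logistic second stage? Default detects a 0/1 outcome in
#'   `second_sample`.
#' @param se_type Standard-error convention, `"second_stage"` or
#'   `"textbook"` (see Details).
#' @return An `mr_estimate` with method `"tsls"`.
#' @export
mr_tsls <- function(first_sample, second_sample = first_sample,
                    binary = NULL,
                    se_type = c("second_stage", "textbook")) {
  se_type <- match.arg(se_type)
  stopifnot(inherits(first_sample, "mr_data"),
            inherits(second_sample, "mr_data"))
  if (ncol(first_sample$genotypes) != ncol(second_sample$genotypes))
    stop_domain("samples have different numbers of variants")
  if (is.null(binary)) binary <- all(second_sample$outcome %in% c(0, 1))
  X1 <- cbind(1, first_sample$genotypes)
  fs <- lm.fit(X1, first_sample$risk_factor)
  if (fs$rank < ncol(X1))
    stop_domain("first-stage genotype matrix is rank deficient")
  fitted2 <- as.numeric(cbind(1, second_sample$genotypes) %*% fs$coefficients)
  y2 <- second_sample$outcome
  if (binary) {
    if (se_type == "textbook")
      stop_domain("the textbook 2SLS standard error is defined for a ",
                  "continuous outcome")
    est <- logistic_assoc_one(fitted2, y2)
    return(new_mr_estimate(est["beta"], est["se"], "tsls",
                           n_variants = ncol(first_sample$genotypes),
                           nobs = length(y2)))
  }
  a <- linear_assoc(matrix(fitted2, ncol = 1), y2)
  if (!a$usable) stop_domain("fitted risk-factor values have zero variance")
  se <- a$se
  if (se_type == "textbook") {
    x2 <- second_sample$risk_factor
    n2 <- length(y2)
    b <- a$beta
    res <- y2 - (mean(y2) - b * mean(x2)) - b * x2
    se <- sqrt(sum(res^2) / (n2 - 2) / sum((fitted2 - mean(fitted2))^2))
  }
  new_mr_estimate(a$beta, se, "tsls",
                  n_variants = ncol(first_sample$genotypes),
                  nobs = length(y2))
}

#' Inverse-variance weighted estimate from summarized data
#'
#' Fixed-effect meta-analysis of the per-variant ratio estimates with
#' first-order weights (outcome-side standard errors only):
#' `estimate = sum(bx * by / se_by^2) / sum(bx^2 / se_by^2)`,
#' `se = sum(bx^2 / se_by^2)^{-1/2}`. Assumes the variants are mutually
#' uncorrelated. Equals the 2SLS estimate asymptotically, and in finite
#' samples when the sample correlations between variants are exactly zero.
#'
#' @param summary A [summary_data()] data frame.
#' @return An `mr_estimate` with method `"ivw"`.
#' @export
mr_ivw <- function(summary) {
  summary <- validate_summary_data(summary)
  bx <- summary$beta_exposure
  by <- summary$beta_outcome
  w <- 1 / summary$se_outcome^2
  denom <- sum(bx^2 * w)
  if (denom == 0)
    stop_domain("all variant-risk factor associations are zero")
  new_mr_estimate(sum(bx * by * w) / denom, 1 / sqrt(denom), "ivw",
                  n_variants = nrow(summary))
}

#' Equally weighted allele-score estimate from summarized data
#'
#' Summarized-data equivalent of an unweighted allele-score analysis:
#' variants are re-oriented so every risk-factor association is
#' non-negative (equal weights are sign-sensitive), and the estimate is
#' `sum(by) / sum(bx)` with the delta-method standard error
#' `sqrt(sum(se_by^2)) / sum(bx)` treating the weights as fixed. Because the
#' weights do not depend on the exposure associations in the data under
#' analysis, this estimator is robust to overlap-induced weak-instrument
#' bias, at some cost in power.
#'
#' @param summary A [summary_data()] data frame, variants oriented to (or
#'   re-orientable to) the exposure-increasing allele.
#' @return An `mr_estimate` with method `"equal_score"`.
#' @export
mr_allele_score <- function(summary) {
  summary <- validate_summary_data(summary)
  flip <- sign(summary$beta_exposure)
  flip[flip == 0] <- 1
  bx <- summary$beta_exposure * flip
  by <- summary$beta_outcome * flip
  sbx <- sum(bx)
  if (sbx == 0)
    stop_domain("summed variant-risk factor association is zero")
  new_mr_estimate(sum(by) / sbx, sqrt(sum(summary$se_outcome^2)) / sbx,
                  "equal_score", n_variants = nrow(summary))
}

#' Per-variant univariable associations from individual-level data
#'
#' Estimates the summarized data that consortia release: for each variant, a
#' univariable linear regression of the risk factor on the variant (exposure
#' side) and a univariable linear or logistic regression of the outcome on
#' the variant (outcome side). For case-control data the exposure side can
#' be restricted to controls, the convention that protects against
#' outcome-dependent-sampling bias and reverse causation.
#'
#' Monomorphic variants (zero genotype variance in any regression subset)
#' are excluded with a warning; the excluded ids are recorded in the
#' `"excluded"` attribute of the result.
#'
#' @param data An [mr_data()] object.
#' @param binary_outcome Logistic regression on the outcome side? Default
#'   detects a 0/1 outcome.
#' @param controls_only_exposure Restrict exposure-side regressions to
#'   individuals with outcome 0 (controls)? Requires a binary outcome.
#' @return A [summary_data()] data frame with one row per usable variant.
#' @export
per_variant_associations <- function(data, binary_outcome = NULL,
                                     controls_only_exposure = FALSE) {
  stopifnot(inherits(data, "mr_data"))
  G <- data$genotypes
  k <- ncol(G)
  ids <- colnames(G) %||% paste0("g", seq_len(k))
  if (is.null(binary_outcome)) binary_outcome <- all(data$outcome %in% c(0, 1))
  if (controls_only_exposure && !binary_outcome)
    stop_domain("`controls_only_exposure` requires a binary outcome")
  exp_rows <- if (controls_only_exposure) which(data$outcome == 0)
              else seq_len(nrow(G))
  if (controls_only_exposure && length(exp_rows) < 3)
    stop_domain("fewer than 3 controls available for exposure associations")
  ex <- linear_assoc(G[exp_rows, , drop = FALSE], data$risk_factor[exp_rows])
  if (binary_outcome) {
    out_beta <- out_se <- rep(NA_real_, k)
    out_usable <- apply(G, 2, var) > 0
    for (j in which(out_usable)) {
      est <- logistic_assoc_one(G[, j], data$outcome)
      out_beta[j] <- est["beta"]; out_se[j] <- est["se"]
    }
  } else {
    oa <- linear_assoc(G, data$outcome)
    out_beta <- oa$beta; out_se <- oa$se; out_usable <- oa$usable
  }
  usable <- ex$usable & out_usable
  if (!any(usable)) stop_domain("no polymorphic variants available")
  if (any(!usable))
    warning("excluding monomorphic variant(s): ",
            paste(ids[!usable], collapse = ", "), call. = FALSE)
  res <- summary_data(variant_id = ids[usable],
                      beta_exposure = ex$beta[usable],
                      se_exposure = ex$se[usable],
                      beta_outcome = out_beta[usable],
                      se_outcome = out_se[usable],
                      n_exposure = length(exp_rows),
                      n_outcome = nrow(G))
  attr(res, "excluded") <- ids[!usable]
  res
}

#' Wald test decision for an IV estimate
#'
#' Rejects the null of no causal effect when `|estimate / se|` exceeds the
#' two-sided normal critical value.
#'
#' @param est An `mr_estimate`, or any list with `estimate` and `se`.
#' @param alpha_level Two-sided test size, default 0.05.
#' @return `TRUE` if the null is rejected.
#' @export
wald_reject <- function(est, alpha_level = 0.05) {
  check_scalar(est$se, "se", lower = 0, open_lower = TRUE)
  abs(est$estimate / est$se) > qnorm(1 - alpha_level / 2)
}
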