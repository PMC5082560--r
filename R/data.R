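# Containers: individual-level data and per-variant summarized data.

#' Individual-level Mendelian randomization data
#'
#' Bundles a genotype matrix (allele counts 0/1/2), a risk-factor vector and
#' an outcome vector. The outcome may be continuous or binary 0/1; for
#' case-control data a logical `case` indicator can be carried alongside.
#'
#' @param genotypes N x K numeric matrix of allele counts in \{0, 1, 2\}.
#' @param risk_factor Length-N numeric vector.
#' @param outcome Length-N numeric vector; for a binary outcome all values
#'   must be 0 or 1.
#' @param case Optional logical length-N case indicator.
#' @return Object of class `mr_data`.
#' @export
mr_data <- function(genotypes, risk_factor, outcome, case = NULL) {
  genotypes <- as.matrix(genotypes)
  risk_factor <- as.numeric(risk_factor)
  outcome <- as.numeric(outcome)
  n <- nrow(genotypes)
  if (length(risk_factor) != n || length(outcome) != n)
    stop_domain("genotypes, risk_factor and outcome must have matching lengths")
  if (!all(genotypes %in% c(0, 1, 2)))
    stop_domain("genotype entries must be allele counts in {0, 1, 2}")
  if (!is.null(case)) {
    case <- as.logical(case)
    if (length(case) != n) stop_domain("`case` must have length N")
  }
  structure(list(genotypes = genotypes, risk_factor = risk_factor,
                 outcome = outcome, case = case),
            class = "mr_data")
}

#' @export
print.mr_data <- function(x, ...) {
  cat(sprintf("Individual-level MR data: %d individuals, %d variants%s\n",
              nrow(x$genotypes), ncol(x$genotypes),
              if (!is.null(x$case))
                sprintf(" (%d cases / %d controls)", sum(x$case), sum(!x$case))
              else ""))
  invisible(x)
}

# subset rows of an mr_data object
mr_data_subset <- function(data, idx) {
  mr_data(data$genotypes[idx, , drop = FALSE], data$risk_factor[idx],
          data$outcome[idx], if (!is.null(data$case)) data$case[idx])
}

summary_data_required <- c("variant_id", "beta_exposure", "se_exposure",
                           "beta_outcome", "se_outcome")

#' Per-variant summarized association data
#'
#' The summarized-data analysis unit: per-variant association estimates
#' (beta and standard error) with the risk factor and with the outcome, from
#' univariable regressions. Variants are assumed mutually uncorrelated (not
#' in linkage disequilibrium).
#'
#' @param variant_id Character vector of variant identifiers.
#' @param beta_exposure,se_exposure Per-variant association with the risk
#'   factor and its standard error (SEs strictly positive).
#' @param beta_outcome,se_outcome Per-variant association with the outcome
#'   and its standard error (SEs strictly positive).
#' @param eaf,n_exposure,n_outcome Optional effect allele frequency and
#'   per-side sample sizes.
#' @return A `data.frame` of class `summary_data`.
#' @export
summary_data <- function(variant_id, beta_exposure, se_exposure,
                         beta_outcome, se_outcome, eaf = NULL,
                         n_exposure = NULL, n_outcome = NULL) {
  df <- data.frame(variant_id = as.character(variant_id),
                   beta_exposure = as.numeric(beta_exposure),
                   se_exposure = as.numeric(se_exposure),
                   beta_outcome = as.numeric(beta_outcome),
                   se_outcome = as.numeric(se_outcome),
                   stringsAsFactors = FALSE)
  if (!is.null(eaf)) df$eaf <- as.numeric(eaf)
  if (!is.null(n_exposure)) df$n_exposure <- as.numeric(n_exposure)
  if (!is.null(n_outcome)) df$n_outcome <- as.numeric(n_outcome)
  validate_summary_data(df)
}

#' Validate a summarized-data frame
#'
#' Checks the required columns, missingness and standard-error positivity,
#' and stamps the `summary_data` class. Errors name the offending rows.
#'
#' @param df A data frame with at least the columns `variant_id`,
#'   `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`.
#' @return `df`, classed as `summary_data`.
#' @export
validate_summary_data <- function(df) {
  missing_cols <- setdiff(summary_data_required, names(df))
  if (length(missing_cols))
    stop_domain("missing required column(s): ",
                paste(missing_cols, collapse = ", "))
  if (nrow(df) < 1L) stop_domain("summarized data must contain >= 1 variant")
  num_cols <- setdiff(summary_data_required, "variant_id")
  for (col in num_cols) {
    if (!is.numeric(df[[col]]))
      stop_domain(sprintf("column `%s` is not numeric", col))
    bad <- which(!is.finite(df[[col]]))
    if (length(bad))
      stop_domain(sprintf("column `%s` has missing/non-finite values at row(s) %s",
                          col, paste(bad, collapse = ", ")))
  }
  for (col in c("se_exposure", "se_outcome")) {
    bad <- which(df[[col]] <= 0)
    if (length(bad))
      stop_domain(sprintf("column `%s` must be > 0; violated at row(s) %s",
                          col, paste(bad, collapse = ", ")))
  }
  class(df) <- unique(c("summary_data", class(df)))
  df
}
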