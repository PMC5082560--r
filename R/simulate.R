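# Data-generating models: continuous outcome with overlap slicing, and a
# binary outcome sampled case-control from a simulated population.

#' Configuration for the continuous-outcome data-generating model
#'
#' The model draws `k` independent biallelic variants `g ~ Binomial(2, maf)`
#' per individual, a standard normal confounder `u` and error terms, and
#' sets
#' `x = alpha * sum(g) + u + e_x`, `y = beta_x * x + beta_u * u + e_y`.
#' Defaults are the package's reference simulation conditions: 20 variants
#' of minor allele frequency 0.3 with a common per-allele effect, 20,000
#' simulated individuals of whom 10,000 contribute to each association.
#'
#' @param alpha Per-allele effect of each variant on the risk factor.
#' @param k Number of variants (default 20).
#' @param maf Minor allele frequency (default 0.3).
#' @param beta_x Causal effect of the risk factor on the outcome (default 0).
#' @param beta_u Confounder effect on the outcome (default 1).
#' @param n_total Total simulated individuals (default 20,000).
#' @param n_sample Individuals per association sample (default 10,000).
#' @param overlap Proportion of shared individuals between the two
#'   association samples, in \[0, 1\] (default 0).
#' @return A list of class `sim_continuous_config`.
#' @export
sim_continuous_config <- function(alpha, k = 20, maf = 0.3, beta_x = 0,
                                  beta_u = 1, n_total = 20000,
                                  n_sample = 10000, overlap = 0) {
  check_scalar(alpha, "alpha")
  check_scalar(k, "k", lower = 1)
  check_scalar(maf, "maf", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  check_scalar(beta_x, "beta_x")
  check_scalar(beta_u, "beta_u")
  check_scalar(overlap, "overlap", lower = 0, upper = 1)
  check_scalar(n_sample, "n_sample", lower = k + 2)
  check_scalar(n_total, "n_total", lower = 1)
  if (round(n_sample * (2 - overlap)) > n_total)
    stop_domain(sprintf(
      "n_total = %g cannot hold two samples of %g with overlap %g (needs %g)",
      n_total, n_sample, overlap, round(n_sample * (2 - overlap))))
  structure(list(alpha = alpha, k = k, maf = maf, beta_x = beta_x,
                 beta_u = beta_u, n_total = n_total, n_sample = n_sample,
                 overlap = overlap),
            class = "sim_continuous_config")
}

#' Simulate individual-level data with a continuous outcome
#'
#' @param config A [sim_continuous_config()].
#' @param seed Integer seed; the same seed reproduces the same dataset.
#' @return An [mr_data()] object with `n_total` individuals.
#' @examples
#' d <- simulate_continuous(sim_continuous_config(alpha = 0.06,
#'        n_total = 2000, n_sample = 900), seed = 7)
#' var(d$risk_factor) # close to 2 + 2 k alpha^2 maf (1 - maf)
#' @export
simulate_continuous <- function(config, seed) {
  stopifnot(inherits(config, "sim_continuous_config"))
  set.seed(seed)
  n <- config$n_total
  k <- config$k
  G <- matrix(rbinom(n * k, 2, config$maf), n, k,
              dimnames = list(NULL, paste0("g", seq_len(k))))
  u <- rnorm(n)
  x <- as.numeric(G %*% rep(config$alpha, k)) + u + rnorm(n)
  y <- config$beta_x * x + config$beta_u * u + rnorm(n)
  mr_data(G, x, y)
}

#' Deterministic overlap slicing
#'
#' Index sets for the two association samples given the per-sample size and
#' the overlap proportion. The first (exposure) sample is individuals
#' `1:n_sample`; the second (outcome) sample is shifted so that exactly
#' `round(overlap * n_sample)` individuals are shared: with `n_sample`
#' 10,000, 0% overlap uses individuals 10,001-20,000, 10% overlap uses
#' 9,001-19,000, and so on, up to 100% overlap re-using 1-10,000 (a
#' one-sample analysis). Indices are 1-based and independent of the data.
#'
#' @param n_sample Individuals per association sample.
#' @param overlap Overlap proportion in \[0, 1\].
#' @return List of class `overlap_slices` with integer vectors
#'   `first_stage`, `second_stage`, and `n_overlap`.
#' @export
overlap_slices <- function(n_sample, overlap) {
  check_scalar(n_sample, "n_sample", lower = 1)
  check_scalar(overlap, "overlap", lower = 0, upper = 1)
  n_ov <- round(overlap * n_sample)
  start <- n_sample - n_ov + 1L
  structure(list(first_stage = seq_len(n_sample),
                 second_stage = seq.int(start, start + n_sample - 1L),
                 n_overlap = n_ov),
            class = "overlap_slices")
}

#' Configuration for the binary-outcome case-control model
#'
#' As the continuous model for the genotypes, confounder and risk factor,
#' but the outcome is Bernoulli with
#' `logit P(y = 1) = intercept + beta_x * x + beta_u * u`. A case-control
#' study is formed by simulating `n_population` individuals and taking, in
#' generation order, the first `n_cases` with an event and the first
#' `n_controls` without. The default intercept -3 gives a population
#' prevalence near 4.7% under the null, so 100,000 individuals comfortably
#' yield 5,000 cases.
#'
#' @inheritParams sim_continuous_config
#' @param intercept Logistic intercept (default -3).
#' @param n_population Individuals simulated (default 100,000).
#' @param n_cases,n_controls Cases and controls retained (default 5,000 each).
#' @return A list of class `sim_binary_config`.
#' @export
sim_binary_config <- function(alpha, k = 20, maf = 0.3, beta_x = 0,
                              beta_u = 1, intercept = -3,
                              n_population = 100000, n_cases = 5000,
                              n_controls = 5000) {
  check_scalar(alpha, "alpha")
  check_scalar(k, "k", lower = 1)
  check_scalar(maf, "maf", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  check_scalar(beta_x, "beta_x")
  check_scalar(beta_u, "beta_u")
  check_scalar(intercept, "intercept")
  check_scalar(n_cases, "n_cases", lower = 1)
  check_scalar(n_controls, "n_controls", lower = 1)
  check_scalar(n_population, "n_population",
               lower = n_cases + n_controls)
  structure(list(alpha = alpha, k = k, maf = maf, beta_x = beta_x,
                 beta_u = beta_u, intercept = intercept,
                 n_population = n_population, n_cases = n_cases,
                 n_controls = n_controls),
            class = "sim_binary_config")
}

#' Simulate a case-control sample with a binary outcome
#'
#' Simulates the full population and keeps the first `n_cases` individuals
#' with an event and the first `n_controls` without, preserving generation
#' order. Errors (reporting the achieved counts) if the population yields
#' too few of either.
#'
#' @param config A [sim_binary_config()].
#' @param seed Integer seed.
#' @return An [mr_data()] object of `n_cases + n_controls` individuals
#'   (cases first) with the `case` indicator set.
#' @export
simulate_binary_cc <- function(config, seed) {
  stopifnot(inherits(config, "sim_binary_config"))
  set.seed(seed)
  n <- config$n_population
  k <- config$k
  G <- matrix(rbinom(n * k, 2, config$maf), n, k,
              dimnames = list(NULL, paste0("g", seq_len(k))))
  u <- rnorm(n)
  x <- as.numeric(G %*% rep(config$alpha, k)) + u + rnorm(n)
  p <- plogis(config$intercept + config$beta_x * x + config$beta_u * u)
  y <- rbinom(n, 1, p)
  cases <- which(y == 1)
  controls <- which(y == 0)
  if (length(cases) < config$n_cases || length(controls) < config$n_controls)
    stop_domain(sprintf(
      "population of %g produced %d cases and %d controls; %g + %g requested",
      n, length(cases), length(controls), config$n_cases, config$n_controls))
  idx <- c(cases[seq_len(config$n_cases)],
           controls[seq_len(config$n_controls)])
  out <- mr_data(G[idx, , drop = FALSE], x[idx], y[idx],
                 case = y[idx] == 1)
  attr(out, "population_cases") <- length(cases)
  attr(out, "population_size") <- n
  out
}
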