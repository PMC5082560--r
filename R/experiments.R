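# Monte Carlo harness: the three simulation studies (overlap grid with a
# continuous outcome, one-sample null validation of the analytic formulae,
# binary case-control validation) at configurable replication scale.

# deterministic per-cell seed below 2^31, reproducible for any subgrid
derive_seed <- function(base_seed, key) {
  h <- 0
  for (ch in utf8ToInt(paste(format(key, digits = 10), collapse = "|")))
    h <- (h * 31 + ch) %% 2147483563
  (abs(as.numeric(base_seed)) * 7919 + h) %% 2147483563
}

# one replicate of the continuous design: returns the per-replicate
# statistics the summaries are built from
replicate_continuous <- function(config, seed, alpha_level = 0.05) {
  d <- simulate_continuous(config, seed)
  sl <- overlap_slices(config$n_sample, config$overlap)
  s1 <- mr_data_subset(d, sl$first_stage)
  s2 <- mr_data_subset(d, sl$second_stage)
  # a fully overlapping analysis is a genuine one-sample 2SLS, for which the
  # conventional (textbook) standard error is the reference Wald test
  ts <- mr_tsls(s1, s2, binary = FALSE,
                se_type = if (config$overlap == 1) "textbook"
                          else "second_stage")
  ex <- linear_assoc(s1$genotypes, s1$risk_factor)
  oa <- linear_assoc(s2$genotypes, s2$outcome)
  iv <- mr_ivw(summary_data(colnames(s1$genotypes), ex$beta, ex$se,
                            oa$beta, oa$se))
  ols <- mr_ols(s2$risk_factor, s2$outcome, binary = FALSE)
  fs <- observed_f(s1$risk_factor, s1$genotypes)
  c(tsls = ts$estimate, tsls_se = ts$se, ivw = iv$estimate,
    ivw_se = iv$se, ols = ols$estimate, f = fs$value, r2 = fs$r_squared,
    var_x = var(s1$risk_factor), var_y = var(s2$outcome),
    reject = as.numeric(wald_reject(ts, alpha_level)))
}

#' Summarize one cell of the continuous simulation design
#'
#' Runs `n_replicates` seeded replicates of the continuous data-generating
#' model at one parameter setting, applying the deterministic overlap
#' slicing, the split-sample 2SLS estimator, the IVW estimator from
#' per-variant summarized associations, the observational OLS estimate and
#' the first-stage F statistic to each.
#'
#' @param config A [sim_continuous_config()].
#' @param n_replicates Number of replicates (at least 100 for any reported
#'   summary).
#' @param base_seed Base seed; replicate `r` uses a seed derived from the
#'   cell parameters plus `r`, so any cell is reproducible in isolation.
#' @param alpha_level Wald test size for the empirical rejection rate.
#' @param keep_replicates Keep the per-replicate statistics matrix?
#' @return A one-row data frame of cell summaries (means, the Monte Carlo
#'   standard error `mc_se` of the mean 2SLS estimate, the mean |IVW-2SLS|
#'   discrepancy, and the empirical rejection rate). With
#'   `keep_replicates = TRUE` the matrix is attached as attribute
#'   `"replicates"`.
#' @export
run_continuous_cell <- function(config, n_replicates, base_seed,
                                alpha_level = 0.05, keep_replicates = FALSE) {
  stopifnot(inherits(config, "sim_continuous_config"))
  cell_seed <- derive_seed(base_seed, c("cont", config$alpha, config$beta_x,
                                        config$beta_u, config$overlap,
                                        config$k, config$n_sample))
  reps <- vapply(seq_len(n_replicates), function(r) {
    replicate_continuous(config, (cell_seed + r) %% 2147483563, alpha_level)
  }, numeric(10))
  m <- rowMeans(reps)
  out <- data.frame(alpha = config$alpha, beta_x = config$beta_x,
                    beta_u = config$beta_u, overlap = config$overlap,
                    n_replicates = n_replicates,
                    mean_estimate = m["tsls"],
                    median_estimate = median(reps["tsls", ]),
                    mc_se = sd(reps["tsls", ]) / sqrt(n_replicates),
                    mean_ivw = m["ivw"],
                    mean_abs_ivw_tsls_diff =
                      mean(abs(reps["ivw", ] - reps["tsls", ])),
                    mean_f = m["f"], mean_r2 = m["r2"], mean_ols = m["ols"],
                    mean_var_x = m["var_x"], mean_var_y = m["var_y"],
                    empirical_type1 = m["reject"],
                    row.names = NULL)
  if (keep_replicates) attr(out, "replicates") <- reps
  out
}

#' Continuous-outcome simulation study across an overlap grid
#'
#' Reference conditions: per-allele effects 0.04/0.06/0.08, causal effect 0
#' or 0.2, confounder effects 0.6/1/2, overlap 0 to 100% in steps of 10%,
#' 10,000 individuals per association.
#'
#' @param alphas,beta_xs,beta_us,overlaps Parameter vectors defining the
#'   grid.
#' @param n_replicates Replicates per cell.
#' @param base_seed Base seed for the deterministic cell-seed ladder.
#' @param ... Further arguments to [sim_continuous_config()].
#' @return Data frame with one row per cell (see [run_continuous_cell()]).
#' @export
run_overlap_grid <- function(alphas = c(0.04, 0.06, 0.08),
                             beta_xs = c(0.2, 0),
                             beta_us = c(0.6, 1, 2),
                             overlaps = seq(0, 1, by = 0.1),
                             n_replicates = 1000, base_seed = 1, ...) {
  grid <- expand.grid(alpha = alphas, beta_x = beta_xs, beta_u = beta_us,
                      overlap = overlaps)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- sim_continuous_config(alpha = grid$alpha[i],
                                 beta_x = grid$beta_x[i],
                                 beta_u = grid$beta_u[i],
                                 overlap = grid$overlap[i], ...)
    run_continuous_cell(cfg, n_replicates, base_seed)
  })
  do.call(rbind, res)
}

#' One-sample null validation of the analytic formulae
#'
#' The continuous model under the causal null with 100% overlap and strong
#' confounding (`beta_u = 2` by default), across a range of instrument
#' strengths. For each strength the empirical relative bias (mean IV
#' estimate over mean OLS estimate) and rejection rate are compared with
#' the analytic predictions: relative bias close to the reciprocal of the
#' mean F statistic, and the expected Type 1 error computed from the mean
#' F, R-squared, risk-factor/outcome variances and OLS estimate across
#' replicates.
#'
#' @param alphas Per-allele effect sizes to sweep.
#' @param n_replicates Replicates per strength.
#' @param base_seed Base seed.
#' @param beta_u Confounder effect (default 2, the strongest reference
#'   level).
#' @param alpha_level Wald test size.
#' @param ... Further arguments to [sim_continuous_config()].
#' @return Data frame with one row per instrument strength: cell summaries
#'   plus `relative_bias`, `inv_mean_f` and `expected_type1`.
#' @export
run_null_validation <- function(alphas = c(0.04, 0.06, 0.08, 0.1, 0.15, 0.2),
                                n_replicates = 1000, base_seed = 1,
                                beta_u = 2, alpha_level = 0.05, ...) {
  res <- lapply(alphas, function(a) {
    cfg <- sim_continuous_config(alpha = a, beta_x = 0, beta_u = beta_u,
                                 overlap = 1, ...)
    cell <- run_continuous_cell(cfg, n_replicates, base_seed, alpha_level)
    bias <- bias_under_null(cell$mean_ols, 1, cell$mean_f)
    se <- sqrt(iv_variance_continuous(cfg$n_sample, cell$mean_var_x,
                                      cell$mean_r2, cell$mean_var_y))
    cell$relative_bias <- cell$mean_estimate / cell$mean_ols
    cell$inv_mean_f <- 1 / cell$mean_f
    cell$expected_type1 <- type1_error(bias, se, alpha_level)
    cell
  })
  do.call(rbind, res)
}

# one replicate of the binary case-control design; both exposure-side
# conventions (controls only, all participants) are analysed on the same
# dataset. Outcome-side logistic associations are computed once and shared.
replicate_binary <- function(config, seed, alpha_level = 0.05) {
  d <- simulate_binary_cc(config, seed)
  G <- d$genotypes
  controls <- which(d$outcome == 0)
  k <- ncol(G)
  out_beta <- out_se <- numeric(k)
  for (j in seq_len(k)) {
    est <- logistic_assoc_one(G[, j], d$outcome)
    out_beta[j] <- est["beta"]; out_se[j] <- est["se"]
  }
  res <- c()
  for (mode in c("controls", "all")) {
    rows <- if (mode == "controls") controls else seq_len(nrow(G))
    ex <- linear_assoc(G[rows, , drop = FALSE], d$risk_factor[rows])
    iv <- mr_ivw(summary_data(colnames(G), ex$beta, ex$se, out_beta, out_se))
    fs <- observed_f(d$risk_factor[rows], G[rows, , drop = FALSE])
    res <- c(res, stats::setNames(
      c(iv$estimate, fs$value, fs$r_squared,
        as.numeric(wald_reject(iv, alpha_level))),
      paste0(mode, c("_ivw", "_f", "_r2", "_reject"))))
  }
  obs <- mr_ols(d$risk_factor, d$outcome, binary = TRUE)
  c(res, obs = obs$estimate, var_x = var(d$risk_factor))
}

#' Binary case-control validation study
#'
#' The binary data-generating model under the causal null, analysed as a
#' one-sample (fully overlapping) summarized-data IVW analysis with the
#' exposure-side associations estimated either in controls only or in all
#' participants. Controls-only estimation is expected to show no bias and
#' nominal rejection rates at every instrument strength; all-participant
#' estimation reproduces the weak-instrument bias of the continuous design
#' on the log odds ratio scale.
#'
#' @param alphas Per-allele effect sizes to sweep (reference study:
#'   0.01-0.05, 0.08).
#' @param n_replicates Replicates per strength.
#' @param base_seed Base seed.
#' @param beta_u Confounder effect (default 1).
#' @param alpha_level Wald test size.
#' @param ... Further arguments to [sim_binary_config()].
#' @return Data frame with two rows per instrument strength (one per
#'   exposure-side convention): mean F and R-squared for that convention,
#'   mean observational log odds ratio, mean IVW estimate with `mc_se`,
#'   `relative_bias`, `inv_mean_f` and the empirical rejection rate.
#' @export
run_binary_validation <- function(alphas = c(0.01, 0.02, 0.03, 0.04, 0.05, 0.08),
                                  n_replicates = 500, base_seed = 1,
                                  beta_u = 1, alpha_level = 0.05, ...) {
  res <- lapply(alphas, function(a) {
    cfg <- sim_binary_config(alpha = a, beta_x = 0, beta_u = beta_u, ...)
    cell_seed <- derive_seed(base_seed, c("bin", a, beta_u, cfg$k,
                                          cfg$n_cases, cfg$n_controls))
    reps <- vapply(seq_len(n_replicates), function(r) {
      replicate_binary(cfg, (cell_seed + r) %% 2147483563, alpha_level)
    }, numeric(10))
    m <- rowMeans(reps)
    do.call(rbind, lapply(c("controls", "all"), function(mode) {
      est <- reps[paste0(mode, "_ivw"), ]
      data.frame(alpha = a, beta_u = beta_u, exposure_sample = mode,
                 n_replicates = n_replicates,
                 mean_f = m[paste0(mode, "_f")],
                 mean_r2 = m[paste0(mode, "_r2")],
                 mean_obs = m["obs"],
                 mean_estimate = mean(est),
                 mc_se = sd(est) / sqrt(n_replicates),
                 relative_bias = mean(est) / m["obs"],
                 inv_mean_f = 1 / m[paste0(mode, "_f")],
                 empirical_type1 = m[paste0(mode, "_reject")],
                 row.names = NULL)
    }))
  })
  do.call(rbind, res)
}

#' Overlap proportion at which the two bias directions cancel
#'
#' With a non-null causal effect, the split-sample estimate is attenuated
#' towards the null at 0% overlap and pulled towards the confounded
#' association at 100% overlap; in between the mean estimate crosses the
#' true effect. The crossing ("balance point") is located from a
#' least-squares line of the mean estimate on the overlap proportion.
#'
#' @param grid Output of [run_overlap_grid()].
#' @param alpha,beta_u Cell family to use.
#' @param beta_x True causal effect the means must cross (default 0.2).
#' @return The overlap proportion at the crossing, or `NA` (with a message)
#'   if the fitted line does not cross within \[0, 1\].
#' @export
balance_point <- function(grid, alpha, beta_u, beta_x = 0.2) {
  rows <- grid[grid$alpha == alpha & grid$beta_u == beta_u &
                 grid$beta_x == beta_x, ]
  if (nrow(rows) < 2)
    stop_domain("need at least two overlap levels for this cell family")
  fit <- stats::lm(mean_estimate ~ overlap, data = rows)
  b <- coef(fit)
  if (b[2] == 0) { message("mean estimate does not vary with overlap"); return(NA_real_) }
  cross <- (beta_x - b[1]) / b[2]
  if (cross < 0 || cross > 1) {
    message(sprintf("no crossing of %g within the overlap range", beta_x))
    return(NA_real_)
  }
  unname(cross)
}

#' Plot mean IV estimate against sample overlap
#'
#' Simple base-graphics visualisation of a [run_overlap_grid()] result:
#' one line per (alpha, beta_u) cell family at a fixed causal effect.
#'
#' @param grid Output of [run_overlap_grid()].
#' @param beta_x Causal effect whose cells to draw (default 0).
#' @return Invisibly, the subset drawn.
#' @export
plot_overlap_grid <- function(grid, beta_x = 0) {
  rows <- grid[grid$beta_x == beta_x, ]
  if (nrow(rows) == 0) stop_domain("no cells at beta_x = ", beta_x)
  fam <- interaction(rows$alpha, rows$beta_u, drop = TRUE)
  graphics::plot(range(rows$overlap), range(rows$mean_estimate), type = "n",
                 xlab = "sample overlap proportion",
                 ylab = "mean IV estimate",
                 main = sprintf("causal effect %g", beta_x))
  for (f in levels(fam)) {
    r <- rows[fam == f, ]
    r <- r[order(r$overlap), ]
    graphics::lines(r$overlap, r$mean_estimate, type = "b",
                    col = which(levels(fam) == f))
  }
  graphics::abline(h = beta_x, lty = 3)
  invisible(rows)
}
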