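# Observational and instrumental-variable estimators.

test_that("observational estimate is the univariable regression slope", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(mr_ols(x, 2 * x)$estimate, 2)
  expect_equal(mr_ols(x, 2 * x)$se, 0)
  set.seed(11)
  y <- 0.5 * x + rnorm(6)
  fit <- mr_ols(x, y)
  oracle <- summary(lm(y ~ x))$coefficients
  expect_equal(fit$estimate, oracle["x", "Estimate"])
  expect_equal(fit$se, oracle["x", "Std. Error"])
  expect_equal(mr_ols(x, y + 7)$estimate, fit$estimate)
  expect_error(mr_ols(rep(1, 6), y), "zero variance")
})

test_that("logistic observational estimate matches glm()", {
  set.seed(12)
  x <- rnorm(500)
  y <- rbinom(500, 1, plogis(-1 + 0.8 * x))
  fit <- mr_ols(x, y)
  oracle <- summary(glm(y ~ x, family = binomial()))$coefficients
  expect_equal(fit$method, "logistic")
  expect_equal(fit$estimate, oracle["x", "Estimate"], tolerance = 1e-6)
  expect_equal(fit$se, oracle["x", "Std. Error"], tolerance = 1e-6)
})

test_that("ratio estimate divides outcome by exposure associations", {
  r <- mr_ratio(bx = 0.08, by = 0.04, se_by = 0.012)
  expect_equal(r$estimate, 0.5)
  expect_equal(r$se, 0.012 / 0.08)
  expect_equal(mr_ratio(0.08, 0, 0.01)$estimate, 0)
  expect_equal(mr_ratio(-0.08, 0.04, 0.012)$se, 0.012 / 0.08)
  expect_error(mr_ratio(0, 0.04, 0.012), "relevance")
})

test_that("IVW reduces to the ratio for one variant and matches fixed-effect meta-analysis", {
  s <- toy_summary()
  expect_equal(mr_ivw(s[1, ])$estimate, mr_ratio(0.08, 0.04, 0.012)$estimate)
  expect_equal(mr_ivw(s[1, ])$se, mr_ratio(0.08, 0.04, 0.012)$se)
  est <- mr_ivw(s)
  # independent oracle: fixed-effect meta-analysis of the ratio estimates
  # with first-order standard errors
  fe <- metafor::rma(yi = s$beta_outcome / s$beta_exposure,
                     sei = s$se_outcome / abs(s$beta_exposure), method = "FE")
  expect_equal(est$estimate, as.numeric(fe$beta), tolerance = 1e-10)
  expect_equal(est$se, as.numeric(fe$se), tolerance = 1e-10)
})

test_that("IVW numerator cancels for mirrored variants", {
  s <- summary_data(c("a", "b"), beta_exposure = c(0.1, -0.1),
                    se_exposure = c(0.01, 0.01),
                    beta_outcome = c(0.05, 0.05), se_outcome = c(0.02, 0.02))
  expect_equal(mr_ivw(s)$estimate, 0)
  s_zero <- summary_data("a", 0, 0.01, 0.05, 0.02)
  expect_error(mr_ivw(s_zero), "zero")
})

test_that("equal-weight allele score: reductions and sign reorientation", {
  s1 <- toy_summary()[1, ]
  expect_equal(mr_allele_score(s1)$estimate, mr_ratio(0.08, 0.04, 0.012)$estimate)
  # identical variants collapse to the ratio estimate
  s3 <- toy_summary(); s3[2:3, -1] <- s3[rep(1, 2), -1]
  expect_equal(mr_allele_score(s3)$estimate, 0.04 / 0.08)
  # flipping a variant's reference allele must not change the estimate
  s <- toy_summary()
  s_flip <- s
  s_flip[2, c("beta_exposure", "beta_outcome")] <-
    -s_flip[2, c("beta_exposure", "beta_outcome")]
  expect_equal(mr_allele_score(s_flip)$estimate, mr_allele_score(s)$estimate)
})

test_that("one-sample 2SLS matches the two-stage lm() oracle", {
  set.seed(21)
  n <- 400; k <- 5
  G <- matrix(rbinom(n * k, 2, 0.3), n, k)
  u <- rnorm(n)
  x <- as.numeric(G %*% rep(0.15, k)) + u + rnorm(n)
  y <- 0.3 * x + u + rnorm(n)
  d <- mr_data(G, x, y)
  fit <- mr_tsls(d)
  xhat <- fitted(lm(x ~ G))
  oracle <- summary(lm(y ~ xhat))$coefficients
  expect_equal(fit$estimate, oracle["xhat", "Estimate"])
  expect_equal(fit$se, oracle["xhat", "Std. Error"])
})

test_that("split-sample 2SLS ignores second-sample risk factors", {
  set.seed(22)
  n <- 300; k <- 4
  mk <- function() {
    G <- matrix(rbinom(n * k, 2, 0.3), n, k)
    u <- rnorm(n)
    x <- as.numeric(G %*% rep(0.2, k)) + u + rnorm(n)
    mr_data(G, x, 0.5 * x + u + rnorm(n))
  }
  d1 <- mk(); d2 <- mk()
  fit <- mr_tsls(d1, d2)
  d2_scrambled <- mr_data(d2$genotypes, rev(d2$risk_factor), d2$outcome)
  expect_equal(mr_tsls(d1, d2_scrambled)$estimate, fit$estimate)
})

test_that("2SLS recovers the causal effect without confounding", {
  # without confounding there is no bias towards the observational
  # association; only the O(K/mu) split-sample attenuation remains, which
  # the strong instruments here make comparable to Monte Carlo error
  beta_x <- 0.2
  n_reps <- 100
  alpha <- 0.3; k <- 20; n <- 4000
  mu <- n * k * alpha^2 * 2 * 0.3 * 0.7 / 2
  ests <- vapply(seq_len(n_reps), function(r) {
    cfg <- sim_continuous_config(alpha = alpha, beta_x = beta_x, beta_u = 0,
                                 n_total = 2 * n, n_sample = n,
                                 overlap = 0.5)
    d <- simulate_continuous(cfg, seed = 500 + r)
    sl <- overlap_slices(n, 0.5)
    mr_tsls(mroverlap:::mr_data_subset(d, sl$first_stage),
            mroverlap:::mr_data_subset(d, sl$second_stage))$estimate
  }, 1)
  mc_se <- sd(ests) / sqrt(n_reps)
  expect_lt(abs(mean(ests) - beta_x), 3 * mc_se + beta_x * k / mu)
  # and never biased upwards (towards a confounded association)
  expect_lt(mean(ests), beta_x + 3 * mc_se)
})

test_that("per-variant associations reproduce univariable regressions", {
  set.seed(23)
  G <- toy_genotypes(n = 300, k = 4)
  x <- as.numeric(G %*% rep(0.3, 4)) + rnorm(300)
  y <- 0.4 * x + rnorm(300)
  s <- per_variant_associations(mr_data(G, x, y))
  expect_s3_class(s, "summary_data")
  expect_equal(nrow(s), 4)
  for (j in c(1, 3)) {
    ox <- summary(lm(x ~ G[, j]))$coefficients
    oy <- summary(lm(y ~ G[, j]))$coefficients
    expect_equal(s$beta_exposure[j], ox[2, "Estimate"])
    expect_equal(s$se_exposure[j], ox[2, "Std. Error"])
    expect_equal(s$beta_outcome[j], oy[2, "Estimate"])
    expect_equal(s$se_outcome[j], oy[2, "Std. Error"])
  }
})

test_that("monomorphic variants are excluded with a warning", {
  G <- toy_genotypes(n = 100, k = 3)
  G[, 2] <- 0
  set.seed(24)
  x <- rnorm(100); y <- rnorm(100)
  expect_warning(s <- per_variant_associations(mr_data(G, x, y)), "g2")
  expect_equal(nrow(s), 2)
  expect_equal(attr(s, "excluded"), "g2")
})

test_that("controls-only exposure associations use only controls", {
  set.seed(25)
  G <- toy_genotypes(n = 400, k = 3)
  x <- as.numeric(G %*% rep(0.2, 3)) + rnorm(400)
  y <- rbinom(400, 1, 0.4)
  s_ctl <- per_variant_associations(mr_data(G, x, y),
                                    controls_only_exposure = TRUE)
  ctl <- y == 0
  oracle <- summary(lm(x[ctl] ~ G[ctl, 1]))$coefficients
  expect_equal(s_ctl$beta_exposure[1], oracle[2, "Estimate"])
  expect_equal(unique(s_ctl$n_exposure), sum(ctl))
  # exposure side of the restricted analysis equals an unrestricted
  # analysis of the controls alone
  s_sub <- per_variant_associations(mr_data(G[ctl, ], x[ctl], x[ctl]),
                                    binary_outcome = FALSE)
  expect_equal(s_ctl$beta_exposure, s_sub$beta_exposure)
  expect_equal(s_ctl$se_exposure, s_sub$se_exposure)
})

test_that("Wald rejection uses the two-sided normal critical value", {
  expect_false(wald_reject(list(estimate = 0, se = 1)))
  expect_true(wald_reject(list(estimate = 1.97, se = 1), 0.05))
  expect_false(wald_reject(list(estimate = 1.95, se = 1), 0.05))
  expect_true(wald_reject(list(estimate = -2.0, se = 1), 0.05))
  expect_false(wald_reject(list(estimate = 2.5, se = 1), 0.01))
})

test_that("textbook one-sample SE matches the classical IV variance formula", {
  set.seed(27)
  n <- 500; k <- 6
  G <- matrix(rbinom(n * k, 2, 0.3), n, k)
  u <- rnorm(n)
  x <- as.numeric(G %*% rep(0.1, k)) + u + rnorm(n)
  y <- 2 * u + rnorm(n)
  d <- mr_data(G, x, y)
  fit <- mr_tsls(d, se_type = "textbook")
  # independent oracle: full instrumental-variable algebra
  X <- cbind(1, x); Z <- cbind(1, G)
  Xhat <- Z %*% qr.coef(qr(Z), X)
  theta <- solve(crossprod(Xhat), crossprod(Xhat, y))
  sigma2 <- sum((y - X %*% theta)^2) / (n - 2)
  se_oracle <- sqrt(sigma2 * solve(crossprod(Xhat))[2, 2])
  expect_equal(fit$estimate, theta[2], tolerance = 1e-10)
  expect_equal(fit$se, se_oracle, tolerance = 1e-10)
  # the split-sample convention gives a different (residual-only) SE
  expect_false(isTRUE(all.equal(fit$se, mr_tsls(d)$se)))
  # and the textbook convention is undefined for a binary outcome
  db <- mr_data(G, x, as.numeric(y > 0))
  expect_error(mr_tsls(db, se_type = "textbook"), "continuous")
})

test_that("IVW equals 2SLS exactly for orthogonal instruments with common weights", {
  # algebraic identity: with exactly uncorrelated instrument columns and
  # outcome-side weights proportional to the genotype sums of squares, the
  # fixed-effect combination of ratio estimates is the 2SLS estimate
  set.seed(26)
  n <- 200; k <- 3
  G <- matrix(rnorm(n * k), n, k)
  G <- qr.Q(qr(scale(G, scale = FALSE)))  # orthogonal, centred columns
  x <- as.numeric(G %*% c(2, 1, 3)) + rnorm(n)
  y <- 0.5 * x + rnorm(n)
  bx <- as.numeric(crossprod(G, x)) / colSums(G^2)
  by <- as.numeric(crossprod(G, y)) / colSums(G^2)
  se_by <- 1 / sqrt(colSums(G^2))  # common residual-variance factor drops out
  s <- summary_data(paste0("v", 1:k), bx, rep(1e-3, k), by, se_by)
  xhat <- fitted(lm(x ~ G))
  tsls <- unname(coef(lm(y ~ xhat))[2])
  expect_equal(mr_ivw(s)$estimate, tsls, tolerance = 1e-10)
})
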