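# Closed-form bias / variance / Type-1 calculators.

test_that("one-sample relative bias is the reciprocal of the F parameter", {
  expect_equal(relative_bias_one_sample(10), 0.10)
  expect_equal(relative_bias_one_sample(1), 1.0)
  expect_equal(relative_bias_one_sample(85), 1 / 85)
  expect_error(relative_bias_one_sample(0), "f_param")
  expect_error(relative_bias_one_sample(-3), "f_param")
})

test_that("Nagar-style one-sample 2SLS bias behaves at its edge cases", {
  b <- bias_2sls_one_sample(sigma_xy = 2, sigma_x2 = 2, k = 20,
                            mu = concentration_from_f(4.36, 20))
  expect_equal(b$approx, 2 / (2 * 4.36))
  expect_equal(b$e_f, 4.36)
  # no confounding, no bias
  expect_equal(bias_2sls_one_sample(0, 2, 20, 100)$exact, 0)
  expect_equal(bias_2sls_one_sample(0, 2, 20, 100)$approx, 0)
  # the (k - 2) factor zeroes the exact form at k = 2, not the approximation
  b2 <- bias_2sls_one_sample(2, 2, k = 2, mu = 10)
  expect_equal(b2$exact, 0)
  expect_gt(b2$approx, 0)
  expect_error(bias_2sls_one_sample(2, 2, 20, 0), "mu")
})

test_that("bias under the null is exactly linear in the overlap proportion", {
  expect_equal(bias_under_null(1, 0.5, 10), 0.05)  # 5% at 50% overlap
  expect_equal(bias_under_null(1, 0.3, 10), 0.03)  # 3% at 30% overlap
  expect_equal(bias_under_null(0.7, 0, 3), 0)
  b1 <- bias_under_null(0.993, 1, 4.4)
  for (ov in seq(0, 1, by = 0.125))
    expect_equal(bias_under_null(0.993, ov, 4.4), ov * b1,
                 tolerance = 1e-14)
  expect_error(bias_under_null(1, 1.2, 10), "overlap")
})

test_that("IV-estimate variance formulas: plug-ins, scaling, case balance", {
  expect_equal(iv_variance_continuous(100, 1, 1 - 1e-12, 1), 0.01,
               tolerance = 1e-9)
  v1 <- iv_variance_continuous(10000, 2, 0.01, 5)
  expect_equal(iv_variance_continuous(20000, 2, 0.01, 5), v1 / 2)
  expect_equal(iv_variance_binary(5000, 5000, 1, 1 - 1e-12), 4e-4,
               tolerance = 1e-9)
  vb <- function(p) iv_variance_binary(1e4 * p, 1e4 * (1 - p), 1, 0.01)
  expect_equal(vb(0.1) / vb(0.5), 25 / 9)
  expect_true(all(vb(0.5) <= sapply(c(0.05, 0.2, 0.35, 0.65, 0.9), vb)))
  expect_error(iv_variance_binary(0, 100, 1, 0.01), "n_cases")
})

test_that("Type 1 error: nominal at zero bias, symmetric, monotone, limits", {
  for (a in c(0.01, 0.05, 0.10, 0.32))
    expect_equal(type1_error(0, 2, a), a, tolerance = 1e-12)
  expect_equal(type1_error(0.3, 0.1, 0.05), type1_error(-0.3, 0.1, 0.05))
  t1 <- sapply(seq(0, 3, by = 0.25), type1_error, se = 1)
  expect_true(all(diff(t1) > 0))
  expect_equal(type1_error(10, 1, 0.05), 1, tolerance = 1e-6)
  expect_error(type1_error(0.1, 0, 0.05), "se")
})

test_that("F and R-squared conversions invert each other and match worked values", {
  expect_equal(f_from_r2(0.027, 339224, 97), 97.0, tolerance = 0.5 / 97)
  expect_equal(f_from_r2(0.001, 101069, 5), 20.2, tolerance = 0.5 / 20)
  for (r2 in c(0.0005, 0.01, 0.12, 0.5, 0.9))
    expect_equal(r2_from_f(f_from_r2(r2, 5000, 15), 5000, 15), r2,
                 tolerance = 1e-12)
  for (f in c(0, 1, 8.6, 97))
    expect_equal(f_from_r2(r2_from_f(f, 3.4e5, 97), 3.4e5, 97), f,
                 tolerance = 1e-9)
  expect_error(f_from_r2(0.01, 20, 20), "n")
})

test_that("single-variant R-squared formula and its maximum in MAF", {
  expect_equal(r2_single_snp(0.08, 0.3), 2 * 0.08^2 * 0.3 * 0.7)
  r2s <- sapply(c(0.1, 0.25, 0.5, 0.75, 0.9), r2_single_snp, alpha_hat = 0.05)
  expect_equal(which.max(r2s), 3L)
  expect_error(r2_single_snp(0.08, 0), "maf")
  expect_error(r2_single_snp(0.08, 1), "maf")
})

test_that("F parameter / concentration parameter conversions", {
  expect_equal(concentration_from_f(10, 20), 180)
  expect_equal(concentration_from_f(1, 7), 0)
  expect_equal(f_from_concentration(concentration_from_f(4.4, 20), 20), 4.4)
  expect_error(concentration_from_f(0.9, 20), "f_param")
})

test_that("composed calculator: nominal error at zero overlap, monotone in overlap", {
  r <- overlap_bias(0.985, 0, f_param = 8.6, n = 10000, k = 20,
                    var_x = 2.03, var_ry = 5)
  expect_equal(r$bias, 0)
  expect_equal(r$type1_error, 0.05, tolerance = 1e-12)
  t1s <- sapply(c(0, 0.25, 0.5, 0.75, 1), function(ov)
    overlap_bias(0.985, ov, f_param = 8.6, n = 10000, k = 20,
                 var_x = 2.03, var_ry = 5)$type1_error)
  expect_true(all(diff(t1s) > 0))
})

test_that("composed calculator reproduces the strong-instrument validation rows", {
  # one-sample null validation summaries (mean F, mean R2, mean OLS) and the
  # expected Type 1 error they imply; var(x) from the model moments, var(y)
  # = beta_u^2 + 1 = 5 under the null
  rows <- data.frame(alpha = c(0.08, 0.09, 0.10, 0.15, 0.20),
                     f     = c(14.4, 18.0, 22.0, 48.3, 85.0),
                     r2    = c(0.028, 0.035, 0.042, 0.088, 0.145),
                     ols   = c(0.974, 0.967, 0.960, 0.914, 0.856),
                     expected = c(0.115, 0.101, 0.090, 0.066, 0.058))
  for (i in seq_len(nrow(rows))) {
    r <- overlap_bias(rows$ols[i], 1, f_param = rows$f[i],
                      r_squared = rows$r2[i], n = 10000, k = 20,
                      var_x = pop_var_x(rows$alpha[i]), var_ry = 5)
    expect_equal(r$type1_error, rows$expected[i], tolerance = 0.005 / rows$expected[i])
    # and an independent recomposition of the same quantity
    manual <- type1_error(rows$ols[i] / rows$f[i],
                          sqrt(5 / (10000 * pop_var_x(rows$alpha[i]) * rows$r2[i])))
    expect_equal(r$type1_error, manual, tolerance = 1e-12)
  }
})

test_that("inconsistent joint F and R-squared inputs are an error, not a preference", {
  expect_error(overlap_bias(1, 0.5, f_param = 20, r_squared = 0.017,
                            n = 10000, k = 20), "disagree")
  # consistent values pass
  expect_silent(overlap_bias(1, 0.5, f_param = f_from_r2(0.017, 10000, 20),
                             r_squared = 0.017, n = 10000, k = 20))
  expect_error(overlap_bias(1, 0.5, n = 10000, k = 20), "instrument strength")
})

test_that("binary outcome path uses the case-control variance", {
  r <- overlap_bias(0.5, 1, f_param = 10, k = 20, var_x = 2,
                    n_cases = 5000, n_controls = 5000)
  se_manual <- sqrt(iv_variance_binary(5000, 5000, 2, r$r_squared))
  expect_equal(r$iv_se, se_manual)
  expect_equal(r$outcome, "binary")
  expect_error(overlap_bias(0.5, 1, f_param = 10, k = 20, n_cases = 5000),
               "n_controls")
})
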