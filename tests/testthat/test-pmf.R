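test_that("uncertainty matrix follows the error model and censoring rule", {
  # above MDL: sqrt((sigma c)^2 + (0.5 MDL)^2)
  expect_equal(uncertainty_matrix(matrix(10), sigma = 0.1, mdl = 1)[1, 1],
               sqrt(1.25))
  # at/below MDL: 5/6 MDL
  expect_equal(uncertainty_matrix(matrix(0.5), sigma = 0.1, mdl = 1)[1, 1],
               5 / 6)
  # MDL = 0 degenerates to sigma * conc
  expect_equal(uncertainty_matrix(matrix(50), sigma = 0.2, mdl = 0)[1, 1], 10)
  expect_error(uncertainty_matrix(matrix(-1), 0.1, 1), "non-negative")
  expect_error(uncertainty_matrix(matrix(1), -0.1, 1), "sigma")

  # literal dialect replaces wherever MDL <= mu
  X <- matrix(c(10, 0.5), 1)
  lit <- uncertainty_matrix(X, sigma = 0.2, mdl = 1, dialect = "literal")
  # cell 1: mu = sqrt(4 + 0.25) > 1 -> replaced by 5/6
  expect_equal(lit[1, 1], 5 / 6)
  # epa dialect keeps the propagated value there
  epa <- uncertainty_matrix(X, sigma = 0.2, mdl = 1, dialect = "epa")
  expect_equal(epa[1, 1], sqrt(4.25))
})

test_that("noiseless low-rank data is recovered essentially exactly", {
  set.seed(7)
  n <- 40; m <- 9; k <- 3
  # identifiable world: block-dominant profiles of comparable magnitude,
  # and a few near-pure samples per source
  F_ <- rbind(c(10, 8, 0.5, 0.2, 1, 0.1, 0.3, 0.2, 0.5),
              c(0.3, 0.5, 9, 7, 0.8, 0.2, 0.1, 0.4, 0.3),
              c(0.2, 0.1, 0.4, 0.5, 0.2, 8, 6, 5, 0.4))
  G <- rbind(3 * diag(k), matrix(rlnorm((n - k) * k, 0, 0.8), n - k, k))
  X <- G %*% F_
  u <- matrix(1, n, m)
  fit <- pmf_fit(X, u, n_factors = k, n_runs = 8, seed = 2)
  expect_lt(fit$Q, 1e-6 * n * m)
  mm <- match_factors(fit$F, F_)
  expect_true(all(mm$cosine > 0.99))

  # rank-1 special case: relative Frobenius reconstruction error < 1e-6
  X1 <- outer(rlnorm(20), rlnorm(5, 1, 1))
  f1 <- pmf_fit(X1, matrix(1, 20, 5), n_factors = 1, n_runs = 3, seed = 4)
  rel <- norm(X1 - f1$G %*% f1$F, "F") / norm(X1, "F")
  expect_lt(rel, 1e-6)
})

test_that("the objective is monotone within every run and scales as Q/4 when u doubles", {
  ds <- generate_dataset(synthetic_config(n_samples = 30, seed = 10))
  X <- as.matrix(ds$samples[pte_elements])
  u <- uncertainty_matrix(X, 0.08, default_mdl)
  fit <- pmf_fit(X, u, n_factors = 3, n_runs = 6, seed = 3, max_iter = 400)
  for (tr in fit$q_traces) {
    expect_true(all(diff(tr) <= 1e-9 * pmax(head(tr, -1), 1)))
  }
  # scaling identity at fixed G, F
  q1 <- pmf_objective(X, fit$G, fit$F, u)
  q2 <- pmf_objective(X, fit$G, fit$F, 2 * u)
  expect_equal(q2, q1 / 4, tolerance = 1e-12)
  expect_true(all(fit$G >= 0))
  expect_true(all(fit$F >= 0))
  expect_equal(fit$Q, sum(fit$scaled_residuals^2), tolerance = 1e-8)
})

test_that("diagnostics report residuals, S/N limits and profile percentages", {
  set.seed(11)
  G <- matrix(rlnorm(30 * 2), 30, 2)
  F_ <- matrix(rlnorm(2 * 6, 2, 0.5), 2, 6,
               dimnames = list(NULL, paste0("E", 1:6)))
  X <- G %*% F_
  u <- matrix(0.05 * X + 0.01, 30, 6)
  # perfect reconstruction: all residuals zero, R^2 = 1
  d <- pmf_diagnostics(X = X, u = u, G = G, F = F_)
  expect_true(all(d$pct_resid_in_3 == 100))
  expect_true(all(abs(d$r_squared - 1) < 1e-12))

  # profile percentages: columns sum to 100
  pct <- pmf_fit(X, u, n_factors = 2, n_runs = 4, seed = 9)$profile_pct
  expect_equal(unname(colSums(pct)), rep(100, 6), tolerance = 1e-9)

  # S/N limits: strong signal when conc >> MDL, ~0 when conc << MDL
  conc_hi <- matrix(rlnorm(50, 5, 0.3), 50, 1, dimnames = list(NULL, "E"))
  u_hi <- uncertainty_matrix(conc_hi, sigma = 0.1, mdl = 0.01)
  d_hi <- pmf_diagnostics(X = conc_hi, u = u_hi, G = matrix(1, 50, 1),
                          F = matrix(mean(conc_hi), 1, 1))
  expect_gt(d_hi$snr, 6)
  conc_lo <- matrix(rlnorm(50, -3, 0.3), 50, 1, dimnames = list(NULL, "E"))
  u_lo <- uncertainty_matrix(conc_lo, sigma = 0.1, mdl = 10)
  d_lo <- pmf_diagnostics(X = conc_lo, u = u_lo, G = matrix(1, 50, 1),
                          F = matrix(mean(conc_lo), 1, 1))
  expect_lt(d_lo$snr, 0.05)
})

test_that("fits are reproducible and invalid inputs rejected", {
  ds <- generate_dataset(synthetic_config(n_samples = 25, seed = 44))
  X <- as.matrix(ds$samples[pte_elements])
  u <- uncertainty_matrix(X, 0.1, default_mdl)
  f1 <- pmf_fit(X, u, n_factors = 2, n_runs = 3, seed = 5, max_iter = 300)
  f2 <- pmf_fit(X, u, n_factors = 2, n_runs = 3, seed = 5, max_iter = 300)
  expect_identical(f1$Q, f2$Q)
  expect_identical(f1$F, f2$F)
  expect_error(pmf_fit(X, u, n_factors = 12), "n_factors")
  expect_error(pmf_fit(X, u * 0, n_factors = 2), "strictly positive")
  expect_error(pmf_fit(-X, u, n_factors = 2), "non-negative")
})

test_that("factor scan reports Q per candidate factor count", {
  ds <- generate_dataset(synthetic_config(n_samples = 25, seed = 15))
  X <- as.matrix(ds$samples[pte_elements])
  u <- uncertainty_matrix(X, 0.1, default_mdl)
  scan <- pmf_factor_scan(X, u, k_range = 2:4, n_runs = 2, seed = 1,
                          max_iter = 200)
  expect_equal(scan$k, 2:4)
  expect_true(all(diff(scan$Q) <= 1e-6))  # more factors never fit worse
})
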