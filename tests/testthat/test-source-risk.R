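make_fit <- function(n = 40, seed = 19, k = 3) {
  ds <- generate_dataset(synthetic_config(n_samples = n, seed = seed))
  X <- as.matrix(ds$samples[pte_elements])
  u <- uncertainty_matrix(X, 0.1, default_mdl)
  list(ds = ds, X = X,
       fit = pmf_fit(X, u, n_factors = k, n_runs = 6, seed = 2,
                     max_iter = 500))
}

test_that("apportionment is exactly additive and non-negative", {
  w <- make_fit()
  app <- apportion(w$fit)
  expect_equal(length(app$factors), 3)
  total <- Reduce(`+`, app$factors)
  expect_lt(max(abs(total - app$reconstruction)), 1e-10)
  expect_true(all(vapply(app$factors, function(m) all(m >= 0), logical(1))))
  # single-factor model: the one factor is the whole reconstruction
  f1 <- pmf_fit(w$X, uncertainty_matrix(w$X, 0.1, default_mdl),
                n_factors = 1, n_runs = 2, seed = 1, max_iter = 300)
  a1 <- apportion(f1)
  expect_equal(a1$factors[[1]], a1$reconstruction, tolerance = 1e-12)
  expect_error(apportion(list()), "pmf_fit")
})

test_that("noiseless apportionment recovers the generating source totals", {
  set.seed(6)
  n <- 60
  # identifiable world: each source carries a marker element absent from
  # the others (Sb = smelter, Cr = geogenic bedrock, As = ore tailings),
  # plus a few source-dominated samples; this pins the noiseless
  # factorisation uniquely to the generating one
  F_true <- rbind(
    smelter  = c(As = 0, Pb = 300, Sb = 2.5, Cr = 0,  Fe = 1500,  Mn = 40,  Zn = 50),
    geogenic = c(As = 0, Pb = 18,  Sb = 0,   Cr = 55, Fe = 26000, Mn = 600, Zn = 55),
    tailings = c(As = 70, Pb = 40, Sb = 0,   Cr = 0,  Fe = 2500,  Mn = 100, Zn = 30))
  sdlog <- sqrt(log(2))
  G_true <- rbind(2 * diag(3),
                  matrix(rlnorm((n - 3) * 3, -sdlog^2 / 2, sdlog), n - 3, 3))
  X <- G_true %*% F_true
  # relative uncertainties so every element informs the fit despite the
  # orders-of-magnitude scale differences between Fe and the trace metals
  fit <- pmf_fit(X, 0.05 * X + 0.01, n_factors = 3, n_runs = 8, seed = 3,
                 max_iter = 4000)
  mm <- match_factors(fit$F, F_true)
  expect_true(all(mm$cosine > 0.99))
  app <- apportion(fit)
  # apportionment error measured against each element's total mass: a
  # factor's near-zero share of an element is not a meaningful denominator
  total_mass <- colSums(X)
  for (r in seq_len(3)) {
    est_tot <- colSums(app$factors[[mm$perm[r]]])
    true_tot <- colSums(outer(G_true[, r], F_true[r, ]))
    expect_lt(max(abs(est_tot - true_tot) / total_mass), 0.02)
  }
})

test_that("deterministic per-factor risks sum to the reconstruction's risk", {
  w <- make_fit()
  app <- apportion(w$fit)
  det <- source_health_risk(app, mode = "deterministic")
  recon_mean <- colMeans(app$reconstruction)
  full <- deterministic_risk(recon_mean[intersect(colnames(app$reconstruction),
                                                  default_toxicity$element)])
  for (pop in c("child", "adult")) {
    hi_sum <- sum(det$HI[det$population == pop])
    hi_full <- sum(full$HI[full$population == pop], na.rm = TRUE)
    expect_equal(hi_sum, hi_full, tolerance = 1e-10)
  }
  # restriction to a subset never increases risk
  sub <- source_health_risk(app, factors = app$factor_names[1:2],
                            mode = "deterministic")
  for (pop in c("child", "adult")) {
    expect_lte(sum(sub$HI[sub$population == pop]),
               sum(det$HI[det$population == pop]) + 1e-12)
  }
  expect_error(source_health_risk(app, factors = character(0)), "empty")
  expect_error(source_health_risk(app, factors = "nope"), "unknown")
})

test_that("a zero factor yields identically zero risk distributions", {
  w <- make_fit(k = 2)
  app <- apportion(w$fit)
  app$factors$null <- app$factors[[1]] * 0
  app$factor_names <- c(app$factor_names, "null")
  sr <- source_health_risk(app, factors = "null",
                           config = mc_config(n_iter = 200, seed = 4))
  expect_true(all(sr$null$hi$child == 0))
  expect_true(all(sr$null$tcr == 0))
  expect_equal(sr$null$no_risk[["child"]], 1)
})

test_that("a factor carrying all the As captures almost all As-driven cancer risk", {
  # constructed two-source world: source 1 owns As, source 2 owns Pb
  set.seed(31)
  n <- 80
  F_true <- rbind(asrc = c(As = 50, Pb = 0.5, Zn = 30),
                  pbsrc = c(As = 0.5, Pb = 400, Zn = 60))
  G_true <- rbind(2 * diag(2),
                  matrix(rlnorm((n - 2) * 2, 0, 0.6), n - 2, 2))
  X <- G_true %*% F_true
  fit <- pmf_fit(X, 0.05 * X, n_factors = 2, n_runs = 6, seed = 7,
                 max_iter = 4000)
  app <- apportion(fit)
  det <- source_health_risk(app, mode = "deterministic")
  # the factor whose profile is As-dominated
  as_factor <- rownames(fit$F)[which.max(fit$F[, "As"])]
  tcr <- det$TCR[det$population == "child"]
  names(tcr) <- det$factor[det$population == "child"]
  expect_gt(tcr[[as_factor]] / sum(tcr), 0.90)

  # the As factor's apportioned As column carries > 95% of total As
  as_share <- colSums(app$factors[[as_factor]])["As"] /
    colSums(app$reconstruction)["As"]
  expect_gt(as_share, 0.95)
})

test_that("MC source risk mirrors the total pipeline per factor", {
  w <- make_fit(n = 30, k = 2)
  app <- apportion(w$fit)
  sr <- source_health_risk(app, config = mc_config(n_iter = 300, seed = 8))
  expect_named(sr, app$factor_names)
  summ <- summarise_source_risk(sr)
  expect_true(all(c("factor", "population", "quantity", "mean", "p") %in%
                    names(summ)))
  expect_true(all(summ$mean >= 0))
  nr <- summ$no_risk_prob[summ$quantity == "HI" & summ$element == "total"]
  expect_true(all(nr >= 0 & nr <= 1))
  # reproducible
  sr2 <- source_health_risk(app, config = mc_config(n_iter = 300, seed = 8))
  expect_identical(summarise_source_risk(sr2), summ)
})
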