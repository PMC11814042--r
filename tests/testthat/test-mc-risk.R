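test_that("moment-matched lognormal fits reproduce the sample moments exactly", {
  set.seed(2)
  x <- rlnorm(500, 3, 0.8)
  d <- fit_concentration_distribution(x)
  expect_equal(exp(d$meanlog + d$sdlog^2 / 2), mean(x), tolerance = 1e-12)
  mom_sd <- sqrt((exp(d$sdlog^2) - 1) * exp(2 * d$meanlog + d$sdlog^2))
  expect_equal(mom_sd, sd(x), tolerance = 1e-12)

  # parameter recovery within 3 SE at large n
  y <- rlnorm(1e5, 1.5, 0.6)
  dm <- fit_concentration_distribution(y, method = "mle")
  expect_lt(abs(dm$meanlog - 1.5), 3 * 0.6 / sqrt(1e5))
  expect_lt(abs(dm$sdlog - 0.6), 3 * 0.6 / sqrt(2 * 1e5))

  # constant sample -> degenerate point mass
  dc <- fit_concentration_distribution(rep(4, 10))
  expect_equal(draw_concentrations(dc, 5), rep(4, 5))
  expect_error(fit_concentration_distribution(c(-1, 2, 3, 4, 5)),
               "non-negative")
  expect_error(fit_concentration_distribution(c(1, 2)), "at least 5")
})

test_that("zero-variance inputs collapse the MC to the deterministic result", {
  conc <- c(As = 85.11, Pb = 411.02, Sb = 3.07)
  dists <- lapply(conc, function(v) fit_concentration_distribution(rep(v, 6)))
  rd <- monte_carlo_risk(dists, config = mc_config(n_iter = 200, seed = 1))
  det <- deterministic_risk(conc)
  td <- tidy(rd)
  for (el in names(conc)) {
    mc_hi <- td$mean[td$population == "child" & td$element == el]
    det_hi <- det$HI[det$population == "child" & det$element == el]
    expect_equal(mc_hi, det_hi, tolerance = 1e-14)
    # degenerate draws: percentile equals mean
    expect_equal(td$p[td$population == "child" & td$element == el], mc_hi)
  }
  # all draws identical -> exceedance of any higher threshold is 0
  tot <- td[td$population == "adult" & td$element == "total", ]
  expect_equal(tot$prob_hi_gt_1, if (tot$mean > 1) 1 else 0)
})

test_that("exceedance probability matches the closed-form lognormal tail", {
  # single element, ingestion-only risk: HI is a linear map of a lognormal
  meanlog <- log(80); sdlog <- 0.9
  mu <- exp(meanlog + sdlog^2 / 2)
  s <- sqrt((exp(sdlog^2) - 1)) * mu
  x <- emulate_study_marginals(mu, s, 1e4, seed = 3) # exact lognormal draws
  d <- fit_concentration_distribution(x)             # recovers (meanlog, sdlog)
  tox <- dplyr::mutate(dplyr::filter(default_toxicity, element == "As"),
                       RfC = NA, ABSd = 0)           # ingestion only
  rd <- monte_carlo_risk(list(As = d), tox = tox,
                         config = mc_config(n_iter = 1e4, seed = 7),
                         populations = "child")
  # analytic tail: HI = a*C with a from the deterministic equation at C = 1
  a <- quiet_hq(1, exposure_params("child"),
                dplyr::slice(tox, 1))$HI
  p_true <- 1 - plnorm(1 / a, d$meanlog, d$sdlog)
  p_hat <- mean(rd$hi$child[, "total"] > 1)
  se <- sqrt(p_true * (1 - p_true) / 1e4)
  expect_lt(abs(p_hat - p_true), 3 * se)
})

test_that("the MC mean converges to the deterministic value for linear maps", {
  x <- emulate_study_marginals(85, 60, 2000, seed = 9)
  d <- fit_concentration_distribution(x)
  tox <- dplyr::filter(default_toxicity, element == "As")
  rd <- monte_carlo_risk(list(As = d), tox = tox,
                         config = mc_config(n_iter = 1e5, seed = 11),
                         populations = "child")
  det <- quiet_hq(exp(d$meanlog + d$sdlog^2 / 2), exposure_params("child"),
                  dplyr::slice(tox, 1))$HI
  expect_lt(abs(mean(rd$hi$child[, "total"]) - det) / det, 0.005)
})

test_that("draws are reproducible and exceedance is monotone in the threshold", {
  ds <- generate_dataset(synthetic_config(seed = 23))
  els <- c("As", "Pb", "Sb")
  dists <- lapply(setNames(els, els), function(el)
    fit_concentration_distribution(ds$samples[[el]]))
  cfg <- mc_config(n_iter = 500, seed = 13)
  r1 <- monte_carlo_risk(dists, config = cfg)
  r2 <- monte_carlo_risk(dists, config = cfg)
  expect_identical(r1$draws, r2$draws)
  expect_identical(tidy(r1), tidy(r2))
  tot <- r1$hi$child[, "total"]
  probs <- vapply(c(0.5, 1, 2, 5), function(t) mean(tot > t), numeric(1))
  expect_true(all(diff(probs) <= 0))
})

test_that("contribution shares are exact same-draw fractions of the total", {
  x <- emulate_study_marginals(50, 30, 1000, seed = 2)
  d <- fit_concentration_distribution(x)
  rd1 <- monte_carlo_risk(list(As = d),
                          config = mc_config(n_iter = 300, seed = 5),
                          populations = "child")
  expect_equal(contribution_shares(rd1, "HI", "child")$share_pct, 100)

  # two elements with identical distributions and identical toxicity
  tox2 <- dplyr::bind_rows(
    dplyr::mutate(dplyr::filter(default_toxicity, element == "As"),
                  element = "E1"),
    dplyr::mutate(dplyr::filter(default_toxicity, element == "As"),
                  element = "E2"))
  rd2 <- monte_carlo_risk(list(E1 = d, E2 = d), tox = tox2,
                          config = mc_config(n_iter = 4000, seed = 6),
                          populations = "child")
  sh <- contribution_shares(rd2, "HI", "child")
  expect_equal(sum(sh$share_pct), 100, tolerance = 1e-10)
  expect_equal(sh$share_pct[1], 50, tolerance = 3)  # symmetry within MC error
})
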