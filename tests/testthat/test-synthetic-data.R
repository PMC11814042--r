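test_that("generator reduces to G.F in the zero-noise limit and for rank-1 worlds", {
  F_true <- rbind(s1 = c(A = 2, B = 5, C = 1))
  cfg <- synthetic_config(n_samples = 10, elements = c("A", "B", "C"),
                          profile_matrix = F_true, contribution_cv = 0.5,
                          noise_cv = 1e-9, mdl = 0, seed = 3)
  ds <- generate_dataset(cfg)
  X <- as.matrix(ds$samples[, c("A", "B", "C")])
  expect_equal(X, ds$true_G %*% ds$true_F, tolerance = 1e-6,
               ignore_attr = TRUE)
  # rank-1: every row proportional to the single profile
  ratios <- sweep(X, 2, F_true[1, ], "/")
  expect_lt(max(apply(ratios, 1, sd) / apply(ratios, 1, mean)), 1e-6)
  expect_false(any(as.matrix(ds$censored[-1])))
})

test_that("same seed gives an identical dataset; different seed differs", {
  cfg <- synthetic_config(seed = 99)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$samples, d2$samples)
  expect_identical(d1$true_G, d2$true_G)
  d3 <- generate_dataset(synthetic_config(seed = 100))
  expect_false(identical(d1$samples, d3$samples))
})

test_that("per-element CVs match a brute-force re-simulation of the generating law", {
  cfg <- synthetic_config(n_samples = 200, noise_cv = 0.05, seed = 1)
  ds <- generate_dataset(cfg)
  got_cv <- summarize_elements(ds$samples, cfg$elements)$cv

  # independent oracle: 10 brute-force replicate surveys of the same law at
  # the same n, written from scratch (lognormal activities, profile mixing,
  # lognormal noise). The sample CV of heavy-tailed marginals has
  # substantial sampling spread at n = 200, so the generator's realisation
  # is compared against the envelope of the oracle replicates, widened by
  # the stated 20% band.
  set.seed(4242)
  n <- cfg$n_samples
  k <- cfg$n_sources; m <- length(cfg$elements)
  sdlog_g <- sqrt(log(1 + cfg$contribution_cv^2))
  sdl <- sqrt(log(1 + cfg$noise_cv^2))
  oracle_cv <- replicate(10, {
    G <- matrix(rlnorm(n * k, log(cfg$contribution_mean) - sdlog_g^2 / 2,
                       sdlog_g), n, k)
    X <- (G %*% cfg$profile_matrix) *
      matrix(rlnorm(n * m, -sdl^2 / 2, sdl), n, m)
    apply(X, 2, function(v) 100 * sd(v) / mean(v))
  })
  lo <- 0.8 * apply(oracle_cv, 1, min)
  hi <- 1.2 * apply(oracle_cv, 1, max)
  expect_true(all(got_cv >= lo & got_cv <= hi))
})

test_that("moment-matched marginals reproduce printed survey moments", {
  # degenerate case
  expect_equal(emulate_study_marginals(3, 0, 10), rep(3, 10))
  expect_error(emulate_study_marginals(-1, 1, 10), "positive")

  # mean/sd recovered within 3 standard errors at n = 1e5
  x <- emulate_study_marginals(85.11, 58.16, 1e5, seed = 8)
  se_mean <- 58.16 / sqrt(1e5)
  expect_lt(abs(mean(x) - 85.11), 3 * se_mean)
  cv <- sqrt(exp(log(1 + (58.16 / 85.11)^2)) - 1)
  se_sd <- 58.16 * sqrt((cv^2 + 2) / (4 * 1e5))  # lognormal sd sampling error (approx)
  expect_lt(abs(sd(x) - 58.16), 6 * se_sd)
})

test_that("censoring fraction matches the analytic lognormal CDF at the MDL", {
  # single source, single element: concentration is exactly lognormal
  F_true <- rbind(s = c(E = 1))
  cfg <- synthetic_config(n_samples = 4000, elements = "E",
                          profile_matrix = F_true, contribution_cv = 1,
                          noise_cv = 0.10, mdl = c(E = 0.4), seed = 12)
  ds <- generate_dataset(cfg)
  frac <- mean(ds$censored$E)
  # product of two lognormals: combined sdlog
  s2 <- log(1 + 1^2) + log(1 + 0.10^2)
  meanlog <- -log(1 + 1^2) / 2 - log(1 + 0.10^2) / 2
  p_true <- plnorm(0.4, meanlog, sqrt(s2))
  se <- sqrt(p_true * (1 - p_true) / 4000)
  expect_lt(abs(frac - p_true), 4 * se)
  # censored cells are reported at substitute * MDL
  expect_true(all(ds$samples$E[ds$censored$E] == 0.5 * 0.4))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_samples = 0), "positive integer")
  expect_error(synthetic_config(profile_matrix = matrix(1, 2, 3)),
               "one column per element")
  expect_error(synthetic_config(noise_cv = 0), "noise_cv")
  F_bad <- default_profiles; F_bad[1, ] <- 0
  expect_error(synthetic_config(profile_matrix = F_bad), "all-zero source")
})

test_that("sample tables round-trip through CSV with censoring sidecar", {
  cfg <- synthetic_config(n_samples = 25, seed = 31,
                          mdl = default_mdl * 40) # force some censoring
  ds <- generate_dataset(cfg)
  expect_gt(sum(as.matrix(ds$censored[-1])), 0)
  path <- file.path(withr::local_tempdir(), "samples.csv")
  write_sample_table(ds, path)
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  expect_true(any(raw == "<MDL", na.rm = TRUE))
  back <- read_sample_table(path, mdl = cfg$mdl, substitute = 0.5)
  for (el in cfg$elements) {
    expect_equal(back$samples[[el]], ds$samples[[el]], tolerance = 1e-12)
  }
  expect_equal(as.data.frame(back$censored), as.data.frame(ds$censored))
})
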