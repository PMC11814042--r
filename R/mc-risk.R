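#' Monte Carlo configuration
#'
#' Settings for the probabilistic risk simulation: 1000 iterations and a
#' 95% reporting percentile by default. Only concentrations are treated as
#' stochastic; exposure parameters stay at their point values.
#'
#' @param n_iter Iterations (>= 100; default 1000).
#' @param seed Integer seed; draws are a pure function of the config.
#' @param confidence Reporting percentile in (0, 100); default 95.
#' @param distribution Concentration distribution family:
#'   `"lognormal"` (moment-matched, default) or `"empirical"` (bootstrap).
#' @return Object of class `mc_config`.
#' @export
mc_config <- function(n_iter = 1000, seed = 1L, confidence = 95,
                      distribution = c("lognormal", "empirical")) {
  distribution <- match.arg(distribution)
  if (n_iter < 100) abort("n_iter must be at least 100")
  if (confidence <= 0 || confidence >= 100) abort("confidence must be in (0, 100)")
  structure(list(n_iter = as.integer(n_iter), seed = as.integer(seed),
                 confidence = confidence, distribution = distribution),
            class = "mc_config")
}

#' Fit a concentration distribution
#'
#' Fits the input distribution used to resample concentrations in the
#' Monte Carlo. The default is a lognormal matched in closed form to the
#' sample mean and SD (so the fitted distribution reproduces both
#' exactly); `method = "mle"` fits by maximum likelihood on the logs;
#' `family = "empirical"` resamples the observed values. A zero-variance
#' (or all-zero) sample yields the degenerate point mass.
#'
#' @param x Concentration values (>= 5 of them).
#' @param family `"lognormal"` or `"empirical"`.
#' @param method For the lognormal: `"moments"` (default) or `"mle"`.
#' @return Object of class `conc_dist` with the fitted parameters.
#' @export
fit_concentration_distribution <- function(x,
                                           family = c("lognormal", "empirical"),
                                           method = c("moments", "mle")) {
  family <- match.arg(family)
  method <- match.arg(method)
  if (length(x) < 5) abort("need at least 5 values to fit a distribution")
  if (any(x < 0)) abort("concentrations must be non-negative")
  if (family == "empirical") {
    return(structure(list(family = "empirical", values = x), class = "conc_dist"))
  }
  mu <- mean(x); s <- sd(x)
  if (mu == 0 || s == 0) {
    return(structure(list(family = "degenerate", value = mu), class = "conc_dist"))
  }
  if (method == "mle") {
    if (any(x <= 0)) abort("maximum-likelihood lognormal fit requires strictly positive values")
    meanlog <- mean(log(x)); sdlog <- sd(log(x))
  } else {
    cv <- s / mu
    sdlog <- sqrt(log(1 + cv^2))
    meanlog <- log(mu) - sdlog^2 / 2
  }
  structure(list(family = "lognormal", meanlog = meanlog, sdlog = sdlog,
                 mean = mu, sd = s, method = method),
            class = "conc_dist")
}

#' Draw from a fitted concentration distribution
#'
#' @param dist A [fit_concentration_distribution()] result.
#' @param n Number of draws.
#' @return Numeric vector of non-negative draws.
#' @export
draw_concentrations <- function(dist, n) {
  stopifnot(inherits(dist, "conc_dist"))
  switch(dist$family,
         lognormal = rlnorm(n, dist$meanlog, dist$sdlog),
         empirical = sample(dist$values, n, replace = TRUE),
         degenerate = rep(dist$value, n))
}

#' Monte Carlo simulation of HI and TCR distributions
#'
#' Per iteration, concentrations are drawn per element from their fitted
#' distributions and pushed through the deterministic risk equations; the
#' accumulated draws give per-element and total hazard-index (HI)
#' distributions for each population and total carcinogenic risk (TCR)
#' distributions for the carcinogenic elements under the age-adjusted
#' scenario. Concentration draws are shared across populations (the soil
#' does not change between receptors), and each element uses an
#' independent deterministic child stream of the config seed.
#'
#' @param dists Named list of `conc_dist` objects, one per element.
#' @param tox Toxicity table (default [default_toxicity]).
#' @param config An [mc_config()].
#' @param populations Populations for the hazard index.
#' @param exposure Optional named list of [exposure_params()] overriding
#'   the defaults per population (names among `populations` and
#'   `"age_adjusted"`).
#' @return Object of class `risk_distribution`: `hi` (per population, an
#'   `n_iter` x elements matrix of HI draws plus a `total` column), `tcr`
#'   (age-adjusted, same layout over carcinogens), `config`, `confidence`.
#' @export
monte_carlo_risk <- function(dists, tox = default_toxicity,
                             config = mc_config(),
                             populations = c("child", "adult"),
                             exposure = NULL) {
  stopifnot(inherits(config, "mc_config"))
  elements <- names(dists)
  if (length(elements) == 0) abort("no concentration distributions supplied")
  missing_tox <- setdiff(elements, tox$element)
  if (length(missing_tox) > 0) {
    abort(paste0("no toxicity entry for: ", paste(missing_tox, collapse = ", ")))
  }
  n_iter <- config$n_iter

  draws <- vapply(elements, function(el) {
    withr::with_seed(child_seed(config$seed, paste0("mc_", el)),
                     draw_concentrations(dists[[el]], n_iter))
  }, numeric(n_iter))
  draws <- matrix(draws, nrow = n_iter,
                  dimnames = list(NULL, elements))

  get_params <- function(pop) {
    if (!is.null(exposure) && pop %in% names(exposure)) exposure[[pop]]
    else exposure_params(pop)
  }

  hi <- list()
  for (pop in populations) {
    prm <- get_params(pop)
    m <- vapply(elements, function(el) {
      hq <- withCallingHandlers(
        hazard_quotients(draws[, el], prm, tox_entry(tox, el)),
        sourcerisk_missing_route = function(w) invokeRestart("muffleWarning"))
      hq$HI
    }, numeric(n_iter))
    m <- matrix(m, nrow = n_iter, dimnames = list(NULL, elements))
    hi[[pop]] <- cbind(m, total = rowSums(m, na.rm = TRUE))
  }

  carcinogens <- elements[vapply(elements, function(el) {
    te <- tox_entry(tox, el)
    !is.na(te$CSFo) || !is.na(te$IUR)
  }, logical(1))]
  tcr <- NULL
  if (length(carcinogens) > 0) {
    aa <- get_params("age_adjusted")
    m <- vapply(carcinogens, function(el) {
      cancer_risks(draws[, el], aa, tox_entry(tox, el))$TCR
    }, numeric(n_iter))
    m <- matrix(m, nrow = n_iter, dimnames = list(NULL, carcinogens))
    tcr <- cbind(m, total = rowSums(m))
  }

  structure(list(hi = hi, tcr = tcr, draws = draws, config = config,
                 confidence = config$confidence),
            class = "risk_distribution")
}

#' @export
print.risk_distribution <- function(x, ...) {
  cat(sprintf("<risk_distribution> %d iterations, populations: %s\n",
              x$config$n_iter, paste(names(x$hi), collapse = ", ")))
  print(tidy(x), n = 6)
  invisible(x)
}

#' Summarise a Monte Carlo risk distribution
#'
#' One row per population, quantity (HI or TCR) and element (plus
#' `"total"`): the mean, the configured reporting percentile (linear
#' interpolation between order statistics), and the exceedance
#' probabilities of the classification boundaries (HI > 1; CR above
#' 1e-6 and above 1e-4).
#'
#' @param x A `risk_distribution`.
#' @param ... Unused.
#' @return Tibble: `population`, `quantity`, `element`, `mean`,
#'   `p` (at the configured percentile), `exceed_1` (HI) or
#'   `exceed_1e6`/`exceed_1e4` (TCR) as `prob_*` columns.
#' @export
tidy.risk_distribution <- function(x, ...) {
  conf <- x$confidence / 100
  summarise_mat <- function(m, pop, quantity) {
    list_rbind(map(colnames(m), function(el) {
      v <- m[, el]
      tibble(population = pop, quantity = quantity, element = el,
             mean = mean(v),
             p = unname(quantile(v, conf, type = 7)),
             prob_hi_gt_1 = if (quantity == "HI") mean(v > 1) else NA_real_,
             prob_cr_gt_1e6 = if (quantity == "TCR") mean(v > 1e-6) else NA_real_,
             prob_cr_gt_1e4 = if (quantity == "TCR") mean(v > 1e-4) else NA_real_)
    }))
  }
  out <- list_rbind(imap(x$hi, function(m, pop) summarise_mat(m, pop, "HI")))
  if (!is.null(x$tcr)) {
    out <- dplyr::bind_rows(out, summarise_mat(x$tcr, "age_adjusted", "TCR"))
  }
  out
}

#' Per-element contribution to the mean total risk
#'
#' `share = 100 * mean(element risk) / mean(total risk)` over the same
#' draws, so the shares sum to exactly 100%.
#'
#' @param rd A `risk_distribution`.
#' @param quantity `"HI"` or `"TCR"`.
#' @param population Population whose HI draws to use (ignored for TCR).
#' @return Tibble `element`, `share_pct`.
#' @export
contribution_shares <- function(rd, quantity = c("HI", "TCR"),
                                population = NULL) {
  quantity <- match.arg(quantity)
  stopifnot(inherits(rd, "risk_distribution"))
  m <- if (quantity == "HI") {
    population <- population %||% names(rd$hi)[1]
    rd$hi[[population]]
  } else {
    if (is.null(rd$tcr)) abort("no carcinogenic draws in this distribution")
    rd$tcr
  }
  total <- mean(m[, "total"])
  if (total == 0) abort("total risk is zero; shares undefined")
  els <- setdiff(colnames(m), "total")
  tibble(element = els,
         share_pct = unname(100 * colMeans(m[, els, drop = FALSE],
                                           na.rm = TRUE) / total))
}

#' Cumulative probability curves of simulated risk
#'
#' Empirical CDF per population of the total HI (or TCR) draws with the
#' classification boundaries marked.
#'
#' @param object A `risk_distribution`.
#' @param quantity `"HI"` or `"TCR"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.risk_distribution <- function(object, quantity = c("HI", "TCR"), ...) {
  quantity <- match.arg(quantity)
  df <- if (quantity == "HI") {
    list_rbind(imap(object$hi, function(m, pop) {
      tibble(population = pop, value = m[, "total"])
    }))
  } else {
    if (is.null(object$tcr)) abort("no carcinogenic draws")
    tibble(population = "age_adjusted", value = object$tcr[, "total"])
  }
  vline <- if (quantity == "HI") 1 else c(1e-6, 1e-4)
  ggplot(df, aes(x = .data$value, colour = .data$population)) +
    stat_ecdf() +
    geom_vline(xintercept = vline, linetype = "dashed", colour = "grey40") +
    scale_x_log10() +
    labs(x = quantity, y = "Cumulative probability") +
    theme_minimal()
}
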