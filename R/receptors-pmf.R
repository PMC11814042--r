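#' Per-cell uncertainty matrix for weighted factorisation
#'
#' Builds the uncertainty `u_ij` that scales each residual in the PMF
#' objective. For a cell above the detection limit,
#' `u = sqrt((sigma * conc)^2 + (0.5 * MDL)^2)` with `sigma` the element's
#' relative standard deviation; a censored cell (concentration at or below
#' MDL) carries the fixed `u = 5/6 * MDL`. The `"literal"` dialect instead
#' evaluates the error-propagation formula everywhere and replaces `u`
#' with `5/6 * MDL` wherever `MDL <= u`.
#'
#' @param conc Samples x elements matrix (or sample tibble) of
#'   concentrations (mg/kg, non-negative).
#' @param sigma Relative standard deviation, scalar or named per element
#'   (fraction, > 0).
#' @param mdl Per-element detection limit (mg/kg, >= 0), scalar or named.
#' @param dialect `"epa"` (default, trigger on concentration <= MDL) or
#'   `"literal"`.
#' @param elements Element columns if `conc` is a tibble.
#' @return Matrix of strictly positive uncertainties, same shape as the
#'   concentration matrix.
#' @examples
#' uncertainty_matrix(matrix(10), sigma = 0.1, mdl = 1)
#' @export
uncertainty_matrix <- function(conc, sigma, mdl,
                               dialect = c("epa", "literal"),
                               elements = NULL) {
  dialect <- match.arg(dialect)
  m <- if (is.matrix(conc)) conc else sample_matrix(conc, elements)
  if (any(m < 0)) abort("concentrations must be non-negative")
  expand <- function(v) {
    if (length(v) == 1) return(rep(v, ncol(m)))
    v <- v[colnames(m)]
    if (anyNA(v)) abort("sigma/mdl must cover every element")
    v
  }
  sig <- expand(sigma); dl <- expand(mdl)
  if (any(sig <= 0)) abort("sigma must be positive")
  if (any(dl < 0)) abort("mdl must be non-negative")
  S <- matrix(sig, nrow(m), ncol(m), byrow = TRUE)
  D <- matrix(dl, nrow(m), ncol(m), byrow = TRUE)
  u <- sqrt((S * m)^2 + (0.5 * D)^2)
  repl <- if (dialect == "epa") m <= D else D <= u
  u[repl] <- (5 / 6) * D[repl]
  if (any(u <= 0)) {
    abort("uncertainty matrix contains non-positive cells (zero concentration with zero MDL?)")
  }
  dimnames(u) <- dimnames(m)
  u
}

#' Uncertainty-scaled PMF objective
#'
#' `Q = sum(((X - G F) / u)^2)`, the quantity the factorisation minimises.
#'
#' @param X Observed matrix; `G`, `F` factor matrices; `u` uncertainties.
#' @return Scalar Q.
#' @export
pmf_objective <- function(X, G, F, u) {
  sum(((X - G %*% F) / u)^2)
}

#' Positive matrix factorisation with per-cell uncertainties
#'
#' Fits the receptor model `X = G F + E` with non-negative sample
#' contributions `G` (samples x factors) and source profiles `F`
#' (factors x elements, mg/kg) by minimising the uncertainty-scaled
#' objective `Q = sum(((X - GF)/u)^2)`. The optimiser alternates exact
#' non-negative weighted least-squares solves of the rows of `G` and the
#' columns of `F` (Lawson-Hanson on the normal equations), so Q is
#' non-increasing at every iteration. Multiple seeded random restarts are
#' run (20 by default) and the best-Q solution kept; factors are ordered by
#' explained variance.
#'
#' @param X Samples x elements matrix (or sample tibble) of non-negative
#'   concentrations, censored cells at their substitute value.
#' @param u Uncertainty matrix from [uncertainty_matrix()] (same shape,
#'   strictly positive).
#' @param n_factors Number of factors, `< min(n_samples, n_elements)`.
#' @param n_runs Random restarts (default 20).
#' @param seed Integer seed; run `r` draws its start from a deterministic
#'   child seed, so the fit is reproducible and runs are independent.
#' @param max_iter Maximum alternating sweeps per run.
#' @param tol Relative change in Q declaring convergence.
#' @param elements Element columns if `X` is a tibble.
#' @return Object of class `pmf_fit`: `G`, `F`, `Q`, `q_trace` (best run),
#'   `q_traces` (objective trace of every run), `scaled_residuals`,
#'   `profile_pct` (factors x elements, columns sum to 100), `diagnostics`
#'   (per-element tibble), `explained_variance_pct` (per factor), `runs`
#'   (per-run tibble: seed, Q, iterations, converged), `converged`.
#' @references The alternating update keeps each subproblem's optimum
#'   exact, which guarantees monotone descent of Q.
#' @export
pmf_fit <- function(X, u, n_factors, n_runs = 20, seed = 1L,
                    max_iter = 2000, tol = 1e-8, elements = NULL) {
  Xm <- if (is.matrix(X)) X else sample_matrix(X, elements)
  if (any(Xm < 0)) abort("X must be non-negative")
  u <- as.matrix(u)
  if (!all(dim(u) == dim(Xm))) abort("u must match X in shape")
  if (any(u <= 0)) abort("u must be strictly positive")
  n <- nrow(Xm); m <- ncol(Xm); k <- as.integer(n_factors)
  if (k < 1 || k >= min(n, m)) abort("n_factors must be in [1, min(dim) - 1]")

  colmax <- apply(Xm, 2, max)
  runs <- vector("list", n_runs)
  q_traces <- vector("list", n_runs)
  best <- NULL
  for (r in seq_len(n_runs)) {
    rs <- child_seed(seed, paste0("pmf_run_", r))
    init <- withr::with_seed(rs, {
      list(G = matrix(runif(n * k), n, k),
           F = matrix(runif(k * m), k, m) * matrix(colmax, k, m, byrow = TRUE))
    })
    fit <- .pmf_als(Xm, u, init$G, init$F, as.integer(max_iter), tol)
    q_traces[[r]] <- fit$q_trace
    runs[[r]] <- tibble(run = r, seed = rs, Q = fit$Q,
                        iterations = length(fit$q_trace) - 1L,
                        converged = fit$converged)
    if (is.null(best) || fit$Q < best$Q) { best <- fit; best$run <- r }
  }
  if (!best$converged) {
    warn(sprintf("best PMF run (run %d) did not converge within %d iterations; returning best iterate",
                 best$run, max_iter))
  }

  G <- best$G; F_ <- best$F
  # order factors by explained variance (descending)
  ev <- pmf_explained_variance(G, F_)
  ord <- order(ev, decreasing = TRUE)
  G <- G[, ord, drop = FALSE]; F_ <- F_[ord, , drop = FALSE]; ev <- ev[ord]
  fac <- paste0("F", seq_len(k))
  dimnames(G) <- list(rownames(Xm), fac)
  dimnames(F_) <- list(fac, colnames(Xm))

  out <- structure(
    list(G = G, F = F_, Q = best$Q, q_trace = best$q_trace,
         q_traces = q_traces, X = Xm, u = u,
         scaled_residuals = (Xm - G %*% F_) / u,
         profile_pct = pmf_profile_pct(F_),
         explained_variance_pct = ev,
         runs = list_rbind(runs),
         converged = best$converged, n_factors = k,
         seed = seed),
    class = "pmf_fit")
  out$diagnostics <- pmf_diagnostics(out)
  out
}

# per-factor explained variance of the reconstruction:
# 100 * sum_ij (g_ik f_kj)^2 / sum_ij (sum_k g_ik f_kj)^2
pmf_explained_variance <- function(G, F) {
  recon2 <- sum((G %*% F)^2)
  vapply(seq_len(ncol(G)), function(kk) {
    100 * sum((G[, kk, drop = FALSE] %*% F[kk, , drop = FALSE])^2) / recon2
  }, numeric(1))
}

# column-normalised profile percentages: 100 * f_kj / sum_k f_kj
pmf_profile_pct <- function(F) {
  cs <- colSums(F)
  P <- sweep(F, 2, ifelse(cs > 0, cs, NA_real_), "/") * 100
  P
}

#' Diagnostics for a fitted PMF model
#'
#' Per-element fit diagnostics: percentage of scaled residuals within
#' \[-3, 3\]; signal-to-noise ratio
#' `S/N = sqrt(sum(max(x - u, 0)^2) / sum(u^2))` (cells whose signal does
#' not exceed its uncertainty contribute no signal); `R^2` as the squared
#' Pearson correlation between observed and reconstructed concentrations.
#'
#' @param fit A `pmf_fit` (or pass `X`, `u`, `G`, `F` explicitly).
#' @param X,u,G,F Optional explicit matrices overriding the fit's.
#' @return Tibble: `element`, `pct_resid_in_3`, `snr`, `r_squared`.
#' @export
pmf_diagnostics <- function(fit = NULL, X = NULL, u = NULL, G = NULL, F = NULL) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "pmf_fit"))
    X <- X %||% fit$X; u <- u %||% fit$u
    G <- G %||% fit$G; F <- F %||% fit$F
  }
  recon <- G %*% F
  sres <- (X - recon) / u
  per_el <- function(j) {
    obs <- X[, j]; pred <- recon[, j]
    r2 <- if (sd(obs) == 0 || sd(pred) == 0) {
      if (max(abs(obs - pred)) < 1e-12) 1 else NA_real_
    } else cor(obs, pred)^2
    tibble(element = colnames(X)[j] %||% as.character(j),
           pct_resid_in_3 = 100 * mean(abs(sres[, j]) <= 3),
           snr = sqrt(sum(pmax(X[, j] - u[, j], 0)^2) / sum(u[, j]^2)),
           r_squared = r2)
  }
  list_rbind(map(seq_len(ncol(X)), per_el))
}

#' Scan the PMF objective across factor counts
#'
#' Helper for choosing the number of factors: fits the model for each `k`
#' and reports Q alongside the theoretical expectation `Qexp ~ n*m` (the
#' number of cells) for a well-specified fit. No automatic choice is made.
#'
#' @param X,u As in [pmf_fit()].
#' @param k_range Integer vector of factor counts to try.
#' @param ... Passed to [pmf_fit()].
#' @return Tibble `k`, `Q`, `Q_over_Qexp`, `converged`.
#' @export
pmf_factor_scan <- function(X, u, k_range, ...) {
  Xm <- if (is.matrix(X)) X else sample_matrix(X)
  qexp <- prod(dim(Xm))
  list_rbind(map(k_range, function(kk) {
    f <- pmf_fit(Xm, u, n_factors = kk, ...)
    tibble(k = kk, Q = f$Q, Q_over_Qexp = f$Q / qexp, converged = f$converged)
  }))
}

#' @export
print.pmf_fit <- function(x, ...) {
  cat(sprintf("<pmf_fit> %d factors, Q = %.4g (%d runs, best run %s)\n",
              x$n_factors, x$Q,
              nrow(x$runs), x$runs$run[which.min(x$runs$Q)]))
  cat("  explained variance (%):",
      paste(sprintf("%.1f", x$explained_variance_pct), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy PMF source profiles
#'
#' @param x A `pmf_fit`.
#' @param ... Unused.
#' @return Long tibble `factor`, `element`, `profile` (mg/kg per unit
#'   contribution), `profile_pct` (% of the element's total across
#'   factors).
#' @export
tidy.pmf_fit <- function(x, ...) {
  long <- function(m, name) {
    as_tibble(m, rownames = "factor") |>
      tidyr::pivot_longer(-"factor", names_to = "element", values_to = name)
  }
  dplyr::left_join(long(x$F, "profile"), long(x$profile_pct, "profile_pct"),
                   by = c("factor", "element"))
}

#' One-row summary of a PMF fit
#'
#' @param x A `pmf_fit`.
#' @param ... Unused.
#' @return Tibble: `n_factors`, `Q`, `Q_over_cells`, `converged`,
#'   `min_pct_resid_in_3`, `min_r_squared`.
#' @export
glance.pmf_fit <- function(x, ...) {
  tibble(n_factors = x$n_factors, Q = x$Q,
         Q_over_cells = x$Q / prod(dim(x$X)),
         converged = x$converged,
         min_pct_resid_in_3 = min(x$diagnostics$pct_resid_in_3),
         min_r_squared = min(x$diagnostics$r_squared, na.rm = TRUE))
}

#' Plot PMF source composition percentages
#'
#' Bar panel per factor of the column-normalised profile percentages.
#'
#' @param object A `pmf_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pmf_fit <- function(object, ...) {
  td <- tidy(object)
  td$element <- factor(td$element, levels = colnames(object$F))
  ggplot(td, aes(x = .data$element, y = .data$profile_pct)) +
    geom_col(fill = "indianred") +
    facet_wrap(~factor, ncol = 1) +
    labs(x = NULL, y = "Source composition (%)") +
    theme_minimal()
}
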