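#' Coefficient of variation in percent
#'
#' `cv_percent()` is the single definition of the coefficient of variation
#' used throughout the package: `100 * sd / mean`, with `sd` understood as
#' the sample (n - 1) standard deviation when computed from data.
#'
#' @param mean Mean value (must be non-zero).
#' @param sd Standard deviation (non-negative).
#' @return CV as a percentage.
#' @examples
#' cv_percent(85.11, 58.16)
#' @export
cv_percent <- function(mean, sd) {
  stopifnot(is.numeric(mean), is.numeric(sd))
  if (any(mean == 0)) abort("cv_percent(): mean must be non-zero")
  if (any(sd < 0)) abort("cv_percent(): sd must be non-negative")
  100 * sd / mean
}

# Extract the elements-only numeric matrix from a sample tibble.
# `elements` defaults to every numeric column that is not metadata.
sample_matrix <- function(data, elements = NULL) {
  stopifnot(is.data.frame(data))
  meta <- c("sample_id", "x", "y", "clay_pct", "om_pct")
  if (is.null(elements)) {
    elements <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], meta)
  }
  missing <- setdiff(elements, names(data))
  if (length(missing) > 0) {
    abort(paste0("columns not found: ", paste(missing, collapse = ", ")))
  }
  m <- as.matrix(data[, elements, drop = FALSE])
  if (!is.numeric(m)) abort("element columns must be numeric")
  rownames(m) <- if ("sample_id" %in% names(data)) as.character(data$sample_id) else NULL
  m
}

# Deterministic child seed for stage `label` derived from a global seed.
# Keeps per-stage RNG streams independent of which other stages run.
child_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

# Match estimated factor rows to reference rows by maximising total cosine
# similarity over all permutations (k is small; exhaustive is exact).
# Returns the permutation p such that est[p[r], ] matches ref[r, ].
match_factors <- function(est, ref) {
  stopifnot(nrow(est) == nrow(ref), ncol(est) == ncol(ref))
  k <- nrow(ref)
  if (k > 8) abort("match_factors(): exhaustive matching supports k <= 8")
  cosim <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(0)
    sum(a * b) / (na * nb)
  }
  S <- outer(seq_len(k), seq_len(k),
             Vectorize(function(i, j) cosim(est[i, ], ref[j, ])))
  perms <- permutations_of(k)
  best <- NULL; best_val <- -Inf
  for (p in perms) {
    val <- sum(S[cbind(p, seq_len(k))])
    if (val > best_val) { best_val <- val; best <- p }
  }
  list(perm = best,
       cosine = S[cbind(best, seq_len(k))])
}

permutations_of <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in permutations_of(k - 1L)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}
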