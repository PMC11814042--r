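#' Varimax-rotated principal component analysis
#'
#' PCA on the correlation matrix (columns z-scored), component retention by
#' the Kaiser criterion (eigenvalue > 1) unless a count is given, followed
#' by varimax rotation with Kaiser row normalisation. Factor scores use the
#' regression (Thomson) method. Rotation is orthogonal, so per-element
#' communalities are invariant under it.
#'
#' @param data Sample tibble.
#' @param elements Element columns (default: all non-metadata numeric).
#' @param n_components `"auto"` (Kaiser criterion) or an integer.
#' @return Object of class `pca_varimax`: `loadings` (elements x
#'   components, rotated), `variance_pct` (per retained component, % of
#'   total variance), `scores`, `eigenvalues` (all), `communality`,
#'   `rotation` (the varimax rotation matrix), `n_components`.
#' @export
pca_varimax <- function(data, elements = NULL, n_components = "auto") {
  m <- sample_matrix(data, elements)
  if (nrow(m) < 3) abort("need at least 3 samples")
  const <- apply(m, 2, function(v) sd(v) == 0)
  if (any(const)) {
    abort(paste0("constant column(s): ", paste(colnames(m)[const], collapse = ", ")))
  }
  Z <- scale(m)
  R <- cor(m)
  eig <- eigen(R, symmetric = TRUE)
  p <- ncol(m)
  if (identical(n_components, "auto")) {
    k <- sum(eig$values > 1)
    if (k == 0) k <- 1
    near_unit <- sum(abs(eig$values - 1) < 0.1)
    if (near_unit > p / 2) {
      warn(paste0("eigenvalue spectrum is near-flat around 1 (", near_unit,
                  " of ", p, " eigenvalues in (0.9, 1.1)); ",
                  "Kaiser retention is unstable for this data"))
    }
  } else {
    k <- as.integer(n_components)
    if (k < 1 || k > qr(Z)$rank) abort("n_components out of range")
  }
  L <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(eig$values[seq_len(k)]), k)
  if (k > 1) {
    vm <- varimax(L, normalize = TRUE)
    Lr <- unclass(vm$loadings)
    rot <- vm$rotmat
  } else {
    Lr <- L
    rot <- diag(1)
  }
  # order rotated components by explained variance, flip signs so the
  # largest-magnitude loading of each component is positive
  ssl <- colSums(Lr^2)
  ord <- order(ssl, decreasing = TRUE)
  Lr <- Lr[, ord, drop = FALSE]
  ssl <- ssl[ord]
  for (j in seq_len(k)) {
    if (Lr[which.max(abs(Lr[, j])), j] < 0) Lr[, j] <- -Lr[, j]
  }
  scores <- Z %*% solve(R, Lr)   # regression method
  dimnames(Lr) <- list(colnames(m), paste0("PC", seq_len(k)))
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(loadings = Lr, variance_pct = 100 * ssl / p,
                 scores = scores, eigenvalues = eig$values,
                 communality = rowSums(Lr^2), rotation = rot,
                 n_components = k),
            class = "pca_varimax")
}

#' @export
print.pca_varimax <- function(x, ...) {
  cat(sprintf("<pca_varimax> %d components retained, %.1f%% of variance\n",
              x$n_components, sum(x$variance_pct)))
  print(round(x$loadings, 3))
  invisible(x)
}

#' Tidy rotated PCA loadings
#'
#' @param x A `pca_varimax`.
#' @param ... Unused.
#' @return Long tibble `element`, `component`, `loading`.
#' @export
tidy.pca_varimax <- function(x, ...) {
  as_tibble(x$loadings, rownames = "element") |>
    tidyr::pivot_longer(-"element", names_to = "component",
                        values_to = "loading")
}

#' One-row summary of a rotated PCA
#'
#' @param x A `pca_varimax`.
#' @param ... Unused.
#' @return Tibble with `n_components`, `total_variance_pct`.
#' @export
glance.pca_varimax <- function(x, ...) {
  tibble(n_components = x$n_components,
         total_variance_pct = sum(x$variance_pct))
}
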