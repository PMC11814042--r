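#' Close a composition to a constant sum
#'
#' Rescales strictly positive parts so they sum to the closure constant
#' `kappa` (default 1e6, interpretable as mg/kg of a unit soil mass).
#'
#' @param x Numeric vector (one composition) or matrix/data frame of
#'   compositions in rows; all parts strictly positive.
#' @param kappa Closure constant (> 0).
#' @return Same shape as `x`, rows summing to `kappa`.
#' @export
close_composition <- function(x, kappa = 1e6) {
  if (kappa <= 0) abort("kappa must be positive")
  if (is.vector(x)) {
    if (any(x <= 0)) abort("all parts must be strictly positive")
    return(kappa * x / sum(x))
  }
  m <- as.matrix(x)
  if (any(m <= 0)) abort("all parts must be strictly positive")
  sweep(m, 1, rowSums(m), "/") * kappa
}

#' Replace below-detection zeros before log-ratio analysis
#'
#' Multiplicative simple replacement: any cell at or below its element's
#' detection limit (or non-positive) is set to `frac * mdl` (default 0.65,
#' the usual compositional-data convention).
#'
#' @param m Samples x elements matrix.
#' @param mdl Named per-element detection limits.
#' @param frac Replacement fraction of MDL.
#' @return Matrix with strictly positive entries.
#' @export
replace_below_detection <- function(m, mdl, frac = 0.65) {
  m <- as.matrix(m)
  mdl <- mdl[colnames(m)]
  for (j in seq_len(ncol(m))) {
    bad <- m[, j] <= mdl[j] | m[, j] <= 0
    m[bad, j] <- frac * mdl[j]
  }
  m
}

#' Centred log-ratio (clr) transform
#'
#' Maps each strictly positive composition row to
#' `log(x_j / g(x))` with `g(x)` the row geometric mean. clr coordinates
#' sum to zero within each row and are invariant to rescaling a row by any
#' positive constant, which removes the closure artefacts of raw
#' concentration data.
#'
#' @param x Numeric vector or samples x elements matrix/data frame with
#'   strictly positive entries.
#' @return clr vector or matrix; rows sum to 0.
#' @examples
#' clr_transform(c(1, exp(1), exp(2)))
#' @export
clr_transform <- function(x) {
  if (is.vector(x)) {
    if (any(x <= 0)) abort("clr requires strictly positive parts")
    return(log(x) - mean(log(x)))
  }
  m <- as.matrix(x)
  if (any(m <= 0)) abort("clr requires strictly positive parts")
  lm_ <- log(m)
  sweep(lm_, 1, rowMeans(lm_), "-")
}

#' clr biplot of a composition matrix
#'
#' Singular value decomposition of the column-centred clr matrix. In the
#' default covariance (form) scaling the element rays absorb the singular
#' values, so each ray's squared length is proportional to that element's
#' clr variance; sample scores are left unit-scaled. `scaling = "form"`
#' puts the singular values on the scores instead.
#'
#' @param data Sample tibble (or matrix) of strictly positive
#'   concentrations.
#' @param elements Element columns (default: all non-metadata numeric).
#' @param scaling `"covariance"` (default) or `"form"`.
#' @return Object of class `clr_biplot`: `scores` (samples x axes), `rays`
#'   (elements x axes), `var_explained` (% per axis, non-increasing),
#'   `clr` (the centred clr matrix), `scaling`.
#' @export
clr_biplot <- function(data, elements = NULL,
                       scaling = c("covariance", "form")) {
  scaling <- match.arg(scaling)
  m <- if (is.matrix(data)) data else sample_matrix(data, elements)
  if (nrow(m) < 3 || ncol(m) < 3) abort("need >= 3 samples and >= 3 elements")
  Z <- clr_transform(m)
  Zc <- scale(Z, center = TRUE, scale = FALSE)
  sv <- svd(Zc)
  pos <- sv$d > max(sv$d) * 1e-12
  if (!any(pos)) abort("degenerate (rank-0) clr matrix")
  d <- sv$d[pos]; U <- sv$u[, pos, drop = FALSE]; V <- sv$v[, pos, drop = FALSE]
  n <- nrow(Zc)
  if (scaling == "covariance") {
    scores <- U * sqrt(n - 1)
    rays <- sweep(V, 2, d / sqrt(n - 1), "*")
  } else {
    scores <- sweep(U, 2, d, "*")
    rays <- V
  }
  rownames(scores) <- rownames(m)
  rownames(rays) <- colnames(m)
  colnames(scores) <- colnames(rays) <- paste0("A", seq_along(d))
  structure(list(scores = scores, rays = rays,
                 var_explained = 100 * d^2 / sum(d^2),
                 singular_values = d, clr = Zc, scaling = scaling),
            class = "clr_biplot")
}

#' @export
print.clr_biplot <- function(x, ...) {
  cat(sprintf("<clr_biplot> %d samples x %d elements (%s scaling)\n",
              nrow(x$scores), nrow(x$rays), x$scaling))
  cat("  variance explained (%):",
      paste(sprintf("%.1f", head(x$var_explained, 4)), collapse = ", "),
      if (length(x$var_explained) > 4) "..." else "", "\n")
  invisible(x)
}

#' k-means clustering of samples in clr space
#'
#' Clusters samples either in the full clr coordinate space (default, so
#' no variance is discarded) or on the first `axes` biplot axes for figure
#' parity. Uses multiple seeded random restarts and keeps the lowest
#' within-cluster sum of squares.
#'
#' @param biplot A [clr_biplot()] result.
#' @param k Number of clusters (default 3).
#' @param axes `"all"` (cluster on the full clr matrix) or an integer
#'   number of leading biplot axes.
#' @param seed Integer seed; results are deterministic given the seed.
#' @param n_init Random restarts.
#' @return Object of class `clr_kmeans`: `cluster` (integer labels, 1..k),
#'   `centers`, `tot_withinss`, `totss`, plus the space clustered.
#' @export
clr_kmeans <- function(biplot, k = 3, axes = "all", seed = 1L, n_init = 25) {
  stopifnot(inherits(biplot, "clr_biplot"))
  space <- if (identical(axes, "all")) biplot$clr else
    biplot$scores[, seq_len(axes), drop = FALSE]
  if (k > nrow(space)) abort("k cannot exceed the number of samples")
  if (k == nrow(space)) {
    # one sample per cluster: zero within-cluster sum of squares
    totss <- sum(scale(space, scale = FALSE)^2)
    return(structure(list(cluster = seq_len(k), centers = space,
                          tot_withinss = 0, totss = totss,
                          k = k, space = space),
                     class = "clr_kmeans"))
  }
  fit <- withr::with_seed(as.integer(seed),
                          kmeans(space, centers = k, nstart = n_init,
                                 iter.max = 100))
  structure(list(cluster = fit$cluster, centers = fit$centers,
                 tot_withinss = fit$tot.withinss, totss = fit$totss,
                 k = k, space = space),
            class = "clr_kmeans")
}

#' Tidy a clr biplot into a long tibble of scores and rays
#'
#' @param x A `clr_biplot`.
#' @param ... Unused.
#' @return Tibble with `id`, axis columns and a `type` column
#'   (`"sample"` or `"ray"`).
#' @export
tidy.clr_biplot <- function(x, ...) {
  dplyr::bind_rows(
    as_tibble(x$scores, rownames = "id") |> mutate(type = "sample"),
    as_tibble(x$rays, rownames = "id") |> mutate(type = "ray"))
}

#' Plot a clr biplot
#'
#' Samples as points, elements as rays from the origin, first two axes.
#'
#' @param object A `clr_biplot`.
#' @param clusters Optional [clr_kmeans()] result to colour samples.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.clr_biplot <- function(object, clusters = NULL, ...) {
  sc <- as_tibble(object$scores[, 1:2, drop = FALSE], rownames = "id")
  names(sc)[2:3] <- c("a1", "a2")
  if (!is.null(clusters)) sc$cluster <- factor(clusters$cluster)
  rays <- as_tibble(object$rays[, 1:2, drop = FALSE], rownames = "element")
  names(rays)[2:3] <- c("a1", "a2")
  p <- ggplot(sc, aes(x = .data$a1, y = .data$a2)) +
    geom_segment(data = rays, aes(x = 0, y = 0, xend = .data$a1, yend = .data$a2),
                 colour = "grey40",
                 arrow = grid::arrow(length = grid::unit(2, "mm"))) +
    geom_text(data = rays, aes(label = .data$element),
              colour = "grey20", vjust = -0.5, size = 3) +
    labs(x = sprintf("Axis 1 (%.1f%%)", object$var_explained[1]),
         y = sprintf("Axis 2 (%.1f%%)", object$var_explained[2])) +
    theme_minimal()
  if (is.null(clusters)) p + geom_point()
  else p + geom_point(aes(colour = .data$cluster))
}
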