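#' Build a signed element-association network
#'
#' Pairwise associations between element concentrations become the weighted
#' edges of an undirected network: positive edges for elements that rise
#' together, negative for antagonistic pairs. Edges whose association fails
#' the retention rule (default: Benjamini-Hochberg adjusted p < 0.05) are
#' set to zero. Spearman's rank correlation is the default estimator,
#' robust to the heavy-tailed marginals of polluted-soil surveys; Pearson
#' and a ridge-regularised partial correlation are available.
#'
#' @param data Sample tibble.
#' @param elements Element columns (default: all non-metadata numeric).
#' @param estimator `"spearman"` (default), `"pearson"`, or `"partial"`
#'   (ridge-regularised partial correlation, no p-value screening).
#' @param alpha Significance level for edge retention.
#' @param adjust Multiple-testing adjustment passed to [stats::p.adjust()]
#'   (default `"BH"`; `"none"` disables).
#' @param ridge Ridge penalty added to the correlation matrix diagonal for
#'   the partial estimator.
#' @return Object of class `element_network`: `nodes`, `adjacency`
#'   (symmetric, zero diagonal, entries in \[-1, 1\]), `pvalues`
#'   (adjusted; NA for `"partial"`), `method`.
#' @export
build_network <- function(data, elements = NULL,
                          estimator = c("spearman", "pearson", "partial"),
                          alpha = 0.05, adjust = "BH", ridge = 0.01) {
  estimator <- match.arg(estimator)
  m <- sample_matrix(data, elements)
  if (nrow(m) < 4) abort("need at least 4 samples")
  if (ncol(m) < 2) abort("need at least 2 elements")
  const <- apply(m, 2, function(v) sd(v) == 0)
  if (any(const)) {
    abort(paste0("constant column(s): ",
                 paste(colnames(m)[const], collapse = ", "),
                 " - correlation undefined"))
  }
  p <- ncol(m)
  if (estimator == "partial") {
    R <- cor(m, method = "pearson")
    P <- solve(R + diag(ridge, p))
    A <- -sweep(sweep(P, 1, sqrt(diag(P)), "/"), 2, sqrt(diag(P)), "/")
    diag(A) <- 0
    pv <- matrix(NA_real_, p, p)
  } else {
    A <- cor(m, method = estimator)
    pv <- matrix(NA_real_, p, p)
    for (i in seq_len(p - 1)) {
      for (j in (i + 1):p) {
        pv[i, j] <- pv[j, i] <- suppressWarnings(
          cor.test(m[, i], m[, j], method = estimator, exact = FALSE)$p.value)
      }
    }
    up <- upper.tri(pv)
    pv[up] <- p.adjust(pv[up], method = adjust)
    pv[lower.tri(pv)] <- t(pv)[lower.tri(pv)]
    A[!is.na(pv) & pv >= alpha] <- 0
    diag(A) <- 0
  }
  A <- pmin(pmax((A + t(A)) / 2, -1), 1)
  dimnames(A) <- dimnames(pv) <- list(colnames(m), colnames(m))
  structure(list(nodes = colnames(m), adjacency = A, pvalues = pv,
                 method = estimator, alpha = alpha, adjust = adjust),
            class = "element_network")
}

#' Construct an element network from a given adjacency matrix
#'
#' Low-level constructor for networks whose edge weights are already
#' known (e.g. literature-reported associations). The matrix must be
#' symmetric with zero diagonal and weights in \[-1, 1\].
#'
#' @param adjacency Named symmetric numeric matrix.
#' @param method Estimator tag to record.
#' @return An `element_network`.
#' @export
element_network <- function(adjacency, method = "given") {
  A <- as.matrix(adjacency)
  if (nrow(A) != ncol(A)) abort("adjacency must be square")
  if (max(abs(A - t(A))) > 1e-12) abort("adjacency must be symmetric")
  if (any(diag(A) != 0)) abort("adjacency must have zero diagonal")
  if (any(abs(A) > 1)) abort("weights must lie in [-1, 1]")
  nodes <- rownames(A) %||% paste0("V", seq_len(nrow(A)))
  dimnames(A) <- list(nodes, nodes)
  structure(list(nodes = nodes, adjacency = A,
                 pvalues = matrix(NA_real_, nrow(A), ncol(A)),
                 method = method, alpha = NA_real_, adjust = "none"),
            class = "element_network")
}

#' @export
print.element_network <- function(x, ...) {
  ne <- sum(x$adjacency[upper.tri(x$adjacency)] != 0)
  cat(sprintf("<element_network> %d nodes, %d retained edges (%s)\n",
              length(x$nodes), ne, x$method))
  invisible(x)
}

#' Expected-influence centrality
#'
#' One-step expected influence of each node: the sum of the signed weights
#' of its edges. Unlike strength centrality (which sums absolute weights)
#' the signed sum lets inhibitory (negative) associations pull a node's
#' influence down, so an element that anticorrelates with the rest of the
#' network can score negative. Both variants are available; z-scores across
#' nodes are reported for scale-free comparison.
#'
#' @param network An [build_network()] result.
#' @param mode `"signed"` (default, expected influence) or `"absolute"`
#'   (strength centrality).
#' @return Tibble with `element`, `ei`, `ei_z` (NA when all EI equal).
#' @export
expected_influence <- function(network, mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  stopifnot(inherits(network, "element_network"))
  A <- network$adjacency
  if (length(network$nodes) == 0) abort("empty network")
  ei <- if (mode == "signed") rowSums(A) else rowSums(abs(A))
  z <- if (sd(ei) > 0) as.numeric(scale(ei)) else rep(NA_real_, length(ei))
  tibble(element = network$nodes, ei = unname(ei), ei_z = z)
}

#' Tidy an element network into an edge list
#'
#' @param x An `element_network`.
#' @param keep_zero Keep non-retained (zero-weight) edges?
#' @param ... Unused.
#' @return Tibble `node_a`, `node_b`, `weight`, `p_adjusted`.
#' @export
tidy.element_network <- function(x, keep_zero = FALSE, ...) {
  A <- x$adjacency
  idx <- which(upper.tri(A), arr.ind = TRUE)
  out <- tibble(node_a = rownames(A)[idx[, 1]],
                node_b = colnames(A)[idx[, 2]],
                weight = A[idx],
                p_adjusted = x$pvalues[idx])
  if (!keep_zero) out <- dplyr::filter(out, .data$weight != 0)
  out
}

#' Plot expected influence per element
#'
#' Bar chart of (optionally standardised) expected influence, ordered.
#'
#' @param object An `element_network`.
#' @param standardized Plot z-scores instead of raw EI?
#' @param ... Passed to [expected_influence()].
#' @return A ggplot object.
#' @export
autoplot.element_network <- function(object, standardized = FALSE, ...) {
  ei <- expected_influence(object, ...)
  ei$value <- if (standardized) ei$ei_z else ei$ei
  ggplot(ei, aes(x = stats::reorder(.data$element, .data$value),
                 y = .data$value)) +
    geom_col(fill = "steelblue") +
    coord_flip() +
    labs(x = NULL, y = if (standardized) "Expected influence (z)" else
      "Expected influence") +
    theme_minimal()
}
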