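# Community ordination: Bray-Curtis dissimilarity, NMDS with Shepard
# diagnostics.

#' Bray-Curtis dissimilarity between two count vectors
#'
#' `sum(|x - y|) / sum(x + y)`: 0 for identical vectors, 1 for disjoint
#' support. A bounded semimetric (the triangle inequality is not
#' guaranteed).
#'
#' @param x,y Non-negative count vectors of equal length.
#' @return Dissimilarity in `[0, 1]`.
#' @export
#' @examples
#' bray_curtis(c(1, 1, 0), c(0, 1, 1))  # 0.5
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) abort("bray_curtis(): negative counts")
  tot <- sum(x + y)
  if (tot == 0) abort("bray_curtis(): both vectors are all-zero")
  sum(abs(x - y)) / tot
}

#' Bray-Curtis dissimilarity matrix of an OTU table
#'
#' Samples are columns of the OTU table; computed with
#' [vegan::vegdist()].
#'
#' @param otu_table Tibble with `otu_id` + per-sample count columns.
#' @return A `dist` object over samples.
#' @export
bray_curtis_matrix <- function(otu_table) {
  m <- t(otu_matrix(otu_table))
  vegan::vegdist(m, method = "bray")
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal stress-1 NMDS over multiple seeded random starts (via
#' [vegan::metaMDS()] on the supplied dissimilarities); the best-stress
#' solution is returned together with the Shepard correlation between
#' ordination distances and input dissimilarities.
#'
#' @param D A `dist` object or symmetric dissimilarity matrix.
#' @param k Target dimensionality (default 2).
#' @param n_starts Random starts (default 20).
#' @param max_iter Iterations per start (default 200).
#' @param seed Integer seed; fixes the solution.
#' @return An object of class `smdiv_nmds`: list with `coordinates`
#'   (tibble: sample, NMDS1..NMDSk), `stress`, `shepard_r`, `k`,
#'   `converged`.
#' @export
nmds <- function(D, k = 2, n_starts = 20, max_iter = 200, seed = 1) {
  D <- stats::as.dist(D)
  n <- attr(D, "Size")
  if (n < 3) abort("nmds(): need at least 3 samples")
  fit <- with_seed(seed, {
    vegan::metaMDS(D, k = k, trymax = n_starts, maxit = max_iter,
                   autotransform = FALSE, wascores = FALSE, trace = 0)
  })
  coords <- as_tibble(fit$points, .name_repair = "minimal")
  names(coords) <- paste0("NMDS", seq_len(k))
  coords <- dplyr::bind_cols(
    tibble(sample = labels(D) %||% as.character(seq_len(n))), coords)
  sr <- shepard_correlation(D, fit$points)
  structure(list(coordinates = coords, stress = fit$stress,
                 shepard_r = sr, k = k,
                 converged = isTRUE(fit$converged) || fit$converged > 0),
            class = "smdiv_nmds")
}

#' @export
print.smdiv_nmds <- function(x, ...) {
  cat(sprintf("NMDS (k = %d): stress = %.4f, Shepard r = %.3f\n",
              x$k, x$stress, x$shepard_r))
  print(x$coordinates)
  invisible(x)
}

#' Shepard correlation between input dissimilarities and ordination
#' distances
#'
#' Pearson correlation of the vectorized upper triangles of the input
#' dissimilarity matrix and the Euclidean distances among ordination
#' coordinates.
#'
#' @param D `dist` or symmetric matrix of input dissimilarities.
#' @param coordinates Numeric matrix (or tibble of numeric columns) of
#'   ordination coordinates, samples in rows.
#' @return Correlation in `[-1, 1]`.
#' @export
shepard_correlation <- function(D, coordinates) {
  D <- stats::as.dist(D)
  if (is.data.frame(coordinates)) {
    coordinates <- as.matrix(coordinates[vapply(coordinates, is.numeric,
                                                logical(1))])
  }
  dd <- stats::dist(coordinates)
  cor(as.vector(D), as.vector(dd))
}
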