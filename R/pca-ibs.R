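#' Identity-by-state similarity matrix
#'
#' For each pair of individuals the IBS similarity is
#' `(# loci sharing both alleles + 0.5 x # loci sharing one allele) /
#' (# jointly called loci)`: genotype pairs (0,0), (1,1), (2,2) share both
#' alleles, (0,1), (1,2) share one, (0,2) share none. Missing entries use
#' pairwise-complete loci; pairs with fewer than `min_joint` jointly called
#' loci are flagged.
#'
#' @param gm a [genotype_matrix()] with at least 2 samples.
#' @param min_joint minimum jointly called loci below which a pair is
#'   flagged (default 10).
#' @return An `N x N` symmetric matrix of class `ibs_matrix`, unit
#'   diagonal, with attribute `flagged` (2-column matrix of flagged sample
#'   pairs, possibly empty).
#' @export
ibs_matrix <- function(gm, min_joint = 10) {
  if (n_samples(gm) < 2) stop("need at least 2 samples", call. = FALSE)
  G <- gm$G
  called <- !is.na(G)
  M <- replace(G, !called, 0L)
  storage.mode(M) <- "double"
  called <- called * 1
  # distance contribution |g_i - g_j| summed over joint loci, via genotype
  # indicators: |a-b| = 1 for {0,1} and {1,2} pairs, 2 for {0,2}.
  I0 <- (M == 0) * called
  I1 <- (M == 1) * called
  I2 <- (M == 2) * called
  D <- tcrossprod(I0, I1) + tcrossprod(I1, I0) +
    tcrossprod(I1, I2) + tcrossprod(I2, I1) +
    2 * (tcrossprod(I0, I2) + tcrossprod(I2, I0))
  C <- tcrossprod(called)
  S <- 1 - D / (2 * pmax(C, 1))
  S[C == 0] <- NA_real_
  diag(S) <- 1
  dimnames(S) <- list(gm$samples, gm$samples)
  low <- which(C < min_joint & upper.tri(C), arr.ind = TRUE)
  flagged <- cbind(gm$samples[low[, 1]], gm$samples[low[, 2]])
  structure(S, class = c("ibs_matrix", "matrix"), flagged = flagged)
}

#' Principal-coordinate map from an IBS matrix
#'
#' Classical (metric) multidimensional scaling of the dissimilarity
#' `1 - S`: double-centring followed by eigendecomposition, keeping the top
#' `n_components` eigenvectors scaled by the square roots of their
#' eigenvalues — the "two-dimensional PCA on IBS values" of
#' population-structure practice. Each axis's sign is fixed so that its
#' largest-magnitude loading is positive, making coordinates reproducible
#' across platforms.
#'
#' @param sim an [ibs_matrix()] (or any symmetric similarity matrix in
#'   `[0, 1]` with unit diagonal).
#' @param n_components number of axes (default 2, `<=` number of samples).
#' @param pop_labels optional per-sample labels carried into the output.
#' @return A tibble with columns `sample`, `population` and `PC1..PCn`;
#'   eigenvalues are attached as attribute `eig`.
#' @export
pca_from_ibs <- function(sim, n_components = 2, pop_labels = NULL) {
  S <- unclass(sim)
  if (!isSymmetric(unname(S), tol = 1e-8)) {
    stop("similarity matrix must be symmetric", call. = FALSE)
  }
  n <- nrow(S)
  stopifnot(n_components >= 1, n_components <= n)
  D <- 1 - S
  cmd <- stats::cmdscale(stats::as.dist(D), k = n_components, eig = TRUE)
  X <- cmd$points
  if (ncol(X) < n_components) {   # degenerate geometry: pad with zeros
    X <- cbind(X, matrix(0, n, n_components - ncol(X)))
  }
  for (j in seq_len(ncol(X))) {
    if (X[which.max(abs(X[, j])), j] < 0) X[, j] <- -X[, j]
  }
  colnames(X) <- paste0("PC", seq_len(ncol(X)))
  out <- tibble::tibble(sample = rownames(S) %||% paste0("sample", seq_len(n)),
                        population = pop_labels %||% NA_character_)
  out <- dplyr::bind_cols(out, tibble::as_tibble(X))
  attr(out, "eig") <- cmd$eig
  out
}
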