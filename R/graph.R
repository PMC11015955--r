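#' Pairwise squared Euclidean row distances
#'
#' \eqn{D_{ij} = \lVert M_{i\cdot} - M_{j\cdot} \rVert_2^2}, computed by the
#' Gram-matrix identity with negative round-off clipped to zero and an exact
#' zero diagonal. Used for the graph couplings on both the latent cell
#' representation and the soft cluster indicator.
#'
#' @param M Numeric matrix, rows are points.
#' @return Symmetric `n x n` matrix of squared distances.
#' @export
pairwise_sq_dists <- function(M) {
  M <- as.matrix(M)
  if (!all(is.finite(M))) stop("pairwise_sq_dists: nonfinite entries",
                               call. = FALSE)
  r <- rowSums(M^2)
  D <- outer(r, r, "+") - 2 * tcrossprod(M)
  D <- (D + t(D)) / 2
  D[D < 0] <- 0
  diag(D) <- 0
  D
}

#' Graph Laplacian of a nonnegative affinity matrix
#'
#' Returns the degree vector \eqn{d_i = \sum_j A_{ij}} and the unnormalized
#' Laplacian \eqn{L = D - A}, whose quadratic form
#' \eqn{x^\top L x = \tfrac12 \sum_{ij} A_{ij}(x_i - x_j)^2} penalizes
#' disagreement across strongly connected pairs.
#'
#' @param A Symmetric nonnegative affinity matrix.
#' @param tol Symmetry tolerance (default `1e-8` relative).
#' @return List with `degree` (numeric vector) and `L` (matrix).
#' @export
graph_laplacian <- function(A, tol = 1e-8) {
  A <- as.matrix(A)
  scale <- max(abs(A), 1)
  if (max(abs(A - t(A))) > tol * scale)
    stop("graph_laplacian: affinity matrix is not symmetric", call. = FALSE)
  if (min(A) < 0)
    stop("graph_laplacian: affinity matrix has negative entries",
         call. = FALSE)
  d <- rowSums(A)
  L <- -A
  diag(L) <- d - diag(A)
  list(degree = d, L = L)
}
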