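#' Co-cluster indicator matrix of a labeling
#'
#' Turns one clustering result into the binary symmetric matrix \eqn{S} with
#' \eqn{S_{ij} = 1} iff cells \eqn{i} and \eqn{j} carry the same label (so
#' the diagonal is all ones). Equivalently \eqn{S = Z Z^\top} for the one-hot
#' membership matrix \eqn{Z}. These indicator matrices are what the consensus
#' step aggregates; they are invariant to any relabeling of the clusters.
#'
#' @param labels A [label_vector()] (or named vector coercible to one).
#' @return Binary symmetric `n x n` numeric matrix with cell ids as dimnames.
#' @export
cocluster_indicator <- function(labels) {
  if (!inherits(labels, "label_vector"))
    labels <- label_vector(labels, names(labels))
  code <- unclass(labels)
  S <- outer(code, code, "==") * 1
  dimnames(S) <- list(names(labels), names(labels))
  S
}

#' Bundle base clustering results
#'
#' A base clustering set is the `q x m` grid of labelings feeding the
#' ensemble: `q` methods applied to each of `m` omics views. All labelings
#' must cover the same cells in the same order. Labelings may use any number
#' of clusters — only co-membership matters downstream.
#'
#' @param labelings List of [label_vector()]s (length `q*m`, view-major or
#'   any order consistent with `methods`/`views`).
#' @param methods Character vector: method name per labeling.
#' @param views Character vector: view name per labeling.
#' @return Object of class `"base_clustering_set"` with elements
#'   `labelings`, `methods`, `views`, `cell_ids`, `q`, `m`.
#' @export
base_clustering_set <- function(labelings, methods = NULL, views = NULL) {
  stopifnot(is.list(labelings), length(labelings) >= 1)
  labelings <- lapply(labelings, function(l) {
    if (inherits(l, "label_vector")) l else label_vector(l, names(l))
  })
  ids <- names(labelings[[1]])
  for (i in seq_along(labelings)) {
    if (!identical(names(labelings[[i]]), ids))
      stop("base labeling ", i, " does not cover the same cells in the same ",
           "order as the first", call. = FALSE)
  }
  if (is.null(methods)) methods <- paste0("method", seq_along(labelings))
  if (is.null(views)) views <- rep("view1", length(labelings))
  stopifnot(length(methods) == length(labelings),
            length(views) == length(labelings))
  structure(list(labelings = labelings,
                 methods = as.character(methods),
                 views = as.character(views),
                 cell_ids = ids,
                 q = length(unique(methods)),
                 m = length(unique(views))),
            class = "base_clustering_set")
}

#' @export
print.base_clustering_set <- function(x, ...) {
  cat("Base clustering set: ", length(x$labelings), " labeling(s) (",
      x$q, " method(s) x ", x$m, " view(s)) over ",
      length(x$cell_ids), " cells\n", sep = "")
  for (i in seq_along(x$labelings))
    cat(sprintf("  [%d] %s on %s: %d clusters\n", i, x$methods[i], x$views[i],
                length(attr(x$labelings[[i]], "levels"))))
  invisible(x)
}

# q x m co-cluster indicator matrices of a base set, as a flat list
.cocluster_list <- function(base) {
  lapply(base$labelings, cocluster_indicator)
}

#' Run built-in base clusterers on every view
#'
#' Applies each requested method independently to each omics view, producing
#' the `q x m` grid of base clustering results the ensemble consumes. These
#' built-ins stand in for external single-cell clustering tools; externally
#' produced labelings can be supplied instead via
#' [ingest_external_labelings()].
#'
#' Methods:
#' \describe{
#'   \item{`kmeans-pca`}{k-means (10 restarts) on the leading principal
#'     components.}
#'   \item{`spectral-knn`}{Normalized-Laplacian spectral embedding of a
#'     symmetrized k-nearest-neighbour graph (built on the PCA scores),
#'     followed by k-means on the row-normalized eigenvectors.}
#'   \item{`agglomerative-ward`}{Ward linkage (`ward.D2`) on Euclidean
#'     distances in PCA space, cut at `C` clusters.}
#' }
#'
#' @param views A `"multiomics"` list (aligned, preprocessed).
#' @param methods Subset of `c("kmeans-pca", "spectral-knn",
#'   "agglomerative-ward")`.
#' @param C Target number of clusters (same for every base run).
#' @param seed Integer seed; the whole grid is reproducible from it.
#' @param pca_dim Number of principal components (default 30, capped at
#'   `min(n, p_v) - 1`).
#' @param knn Neighbourhood size for `spectral-knn` (default 15, capped at
#'   `n - 1`).
#' @return A [base_clustering_set()].
#' @export
run_base_clusterers <- function(views, methods = c("kmeans-pca", "spectral-knn",
                                                   "agglomerative-ward"),
                                C, seed = 1L, pca_dim = 30, knn = 15) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (!inherits(views, "multiomics")) views <- align_views(views)
  n <- nrow(views[[1]])
  if (C > n) stop("C (", C, ") exceeds the number of cells (", n, ")",
                  call. = FALSE)
  if (C < 2) stop("C must be at least 2", call. = FALSE)
  labelings <- list(); meth <- character(); vw <- character()
  for (v in names(views)) {
    X <- as.matrix(views[[v]])
    if (ncol(X) < 2)
      stop("view '", v, "' has fewer than 2 features; cannot cluster",
           call. = FALSE)
    d <- max(1, min(pca_dim, nrow(X) - 1, ncol(X) - 1))
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = d)$x
    for (mth in methods) {
      set.seed(.stream_seed(seed, paste0(mth, "/", v)))
      lab <- switch(mth,
        "kmeans-pca" = stats::kmeans(pc, centers = C, nstart = 10,
                                     iter.max = 100)$cluster,
        "agglomerative-ward" = stats::cutree(
          stats::hclust(stats::dist(pc), method = "ward.D2"), k = C),
        "spectral-knn" = .spectral_knn(pc, C = C, knn = min(knn, nrow(X) - 1))
      )
      labelings <- c(labelings, list(label_vector(lab, rownames(X))))
      meth <- c(meth, mth); vw <- c(vw, v)
    }
  }
  base_clustering_set(labelings, methods = meth, views = vw)
}

# Spectral clustering on a symmetrized kNN graph: bottom eigenvectors of the
# symmetric normalized Laplacian, rows normalized, then k-means.
.spectral_knn <- function(Y, C, knn) {
  n <- nrow(Y)
  D2 <- pairwise_sq_dists(Y)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(D2[i, ])[2:(knn + 1)]
    A[i, nb] <- 1
  }
  A <- pmax(A, t(A))                     # union kNN graph, symmetric
  deg <- pmax(rowSums(A), .Machine$double.eps)
  Dm <- 1 / sqrt(deg)
  Lsym <- diag(n) - (Dm * A) * rep(Dm, each = n)   # I - D^-1/2 A D^-1/2
  ev <- eigen((Lsym + t(Lsym)) / 2, symmetric = TRUE)
  U <- ev$vectors[, n - seq_len(C) + 1, drop = FALSE]  # C smallest eigenvalues
  rn <- sqrt(rowSums(U^2))
  U <- U / pmax(rn, .Machine$double.eps)
  stats::kmeans(U, centers = C, nstart = 10, iter.max = 100)$cluster
}

#' Ingest externally produced base labelings
#'
#' Reads a grid of label CSV files (one per method/view pair), checks each
#' covers every cell of the dataset, and reorders to the dataset's cell
#' order. This is the bridge for feeding results from external single-cell
#' clustering tools into the ensemble.
#'
#' @param paths Character vector of label CSV paths (see [load_labels()]).
#' @param views A `"multiomics"` list defining the canonical cell order, or a
#'   character vector of cell ids.
#' @param methods,view_names Optional provenance, recycled against `paths`.
#' @return A [base_clustering_set()].
#' @export
ingest_external_labelings <- function(paths, views, methods = NULL,
                                      view_names = NULL) {
  cell_ids <- if (is.character(views)) views else rownames(views[[1]])
  labelings <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    lv <- load_labels(paths[i])
    labelings[[i]] <- .align_labels(lv, cell_ids, what = paths[i])
  }
  if (is.null(methods)) methods <- paste0("external", seq_along(paths))
  if (is.null(view_names)) view_names <- rep("external", length(paths))
  base_clustering_set(labelings, methods = methods, views = view_names)
}
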