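#' Graph-regularized multi-view ensemble clustering
#'
#' Fits the joint model that clusters `n` cells from `m` omics views and
#' `q x m` base clustering results. Four coupled nonnegative factors are
#' learned by alternating multiplicative updates:
#' \describe{
#'   \item{`W` (`n x k`)}{consensus low-dimensional cell representation from
#'     the weighted joint factorization \eqn{\sum_v w_v \lVert X^v - W V^v
#'     \rVert_F^2};}
#'   \item{`V^v` (`k x p_v`)}{per-view basis matrices;}
#'   \item{`S` (`n x n`)}{consensus co-cluster affinity aggregating the base
#'     results' binary co-cluster indicators \eqn{S^{rv}} with self-tuned
#'     reliabilities \eqn{\alpha_{rv}};}
#'   \item{`H` (`n x C`)}{soft cluster-indicator matrix with unit row sums;
#'     hard labels are the row-wise argmax.}
#' }
#' Two graph-Laplacian couplings tie the blocks together:
#' \eqn{\lambda_1\,\mathrm{tr}(W^\top L_H W)} pulls cells that `H` considers
#' co-clustered toward nearby representations, and
#' \eqn{\lambda_2\,\mathrm{tr}(H^\top L_S H)} pulls cells with high consensus
#' affinity toward the same cluster. View weights \eqn{w_v =
#' 1/(2\lVert X^v - W V^v\rVert_F)} and base-result weights \eqn{\alpha_{rv}
#' = 1/(2\lVert S - S^{rv}\rVert_F)} are re-tuned every iteration, so noisy
#' views and unreliable base results are down-weighted automatically.
#'
#' Each sweep updates `W`, then the `V^v`, then `S`, then `H` (row-unitized),
#' then the weights, and finally records the objective; the loop stops when
#' the relative objective change drops below `tol` or after `max_iter`
#' sweeps. Every multiplicative denominator is floored at `denom_floor`,
#' which keeps all factors nonnegative.
#'
#' Two numerical safeguards are applied by default, both documented in the
#' methods vignette:
#' \itemize{
#'   \item `normalize_W`: after each sweep's `W`/`V` updates, the columns of
#'     `W` are rescaled to unit Euclidean norm with the inverse scaling
#'     applied to every `V^v`. The reconstructions `W V^v` are unchanged, but
#'     the rescaling removes the factorization's scale indeterminacy — without
#'     it the graph penalty drives the scale of `W` toward zero (the `V^v`
#'     absorb it), which silently switches off the representation-indicator
#'     coupling.
#'   \item `init = "spectral"`: `H` is initialized from a spectral clustering
#'     of the mean base co-cluster indicator (k-means on its top `C`
#'     eigenvectors, softened towards uniform). Multiplicative updates can
#'     only rescale entries of `H`, never re-mix its columns, so a
#'     structure-blind uniform random `H` can lock the fit into partitions
#'     that merge well-supported clusters; seeding `H` with the ensemble's
#'     own consensus signal removes those spurious basins. `init = "random"`
#'     gives the plain seeded uniform(0,1) initialization for all factors.
#' }
#'
#' @param views A `"multiomics"` list from [align_views()] /
#'   [preprocess_views()] (or a plain named list of cell-by-feature
#'   nonnegative matrices over the same cells).
#' @param base A [base_clustering_set()] (or a list of [label_vector()]s)
#'   covering the same cells.
#' @param C Number of clusters, `2 <= C <= n`.
#' @param lambda1 Weight of the representation-indicator coupling
#'   (default 0.1).
#' @param lambda2 Weight of the affinity-indicator coupling (default 0.01).
#' @param k Latent dimension of the consensus representation (default 50).
#' @param tol Relative-objective stopping tolerance (default `1e-6`).
#' @param max_iter Maximum number of sweeps (default 200).
#' @param seed Integer seed for the random initialization.
#' @param init `"spectral"` (default) seeds `H` from the base-consensus
#'   spectral clustering; `"random"` initializes all factors from seeded
#'   uniform(0,1) draws (`S` symmetrized, `H` row-unitized). See Details.
#' @param normalize_W Rescale `W` to unit-norm columns each sweep,
#'   compensating in the `V^v` (default `TRUE`). See Details.
#' @param update_weights Re-tune `w` and `alpha` every sweep (default
#'   `TRUE`). With `FALSE` they stay at their initial values `1/m` and
#'   `1/(qm)` (or at `w_init`/`alpha_init`).
#' @param w_init,alpha_init Optional initial weights (defaults `1/m`,
#'   `1/(qm)`).
#' @param warm_start_S Initialize `S` at the unweighted mean of the base
#'   co-cluster indicators instead of random (default `FALSE`).
#' @param denom_floor,residual_floor Numerical floors for multiplicative
#'   denominators and weight residuals (defaults `1e-10`).
#' @param verbose Print the objective every 10 sweeps.
#' @return An object of class `"grmec"`: a list with the factors `W`, `V`,
#'   `S`, `H`, the weights `w` and `alpha`, hard `labels` (a
#'   [label_vector()]), the `objective` trace (initial value followed by one
#'   value per sweep), `iterations`, `converged`, and the call/hyperparameter
#'   record. Methods: [print.grmec()], [summary.grmec()], [plot.grmec()],
#'   `coef` (returns `W`), `fitted` (per-view reconstructions `W V^v`).
#' @examples
#' sim <- simulate_multiomics(n = 60, C = 3, m = 2, p = c(40, 20),
#'                            separation = 3, seed = 1)
#' base <- simulate_base_set(sim$truth, q = 2, m = 2, error_rate = 0.1,
#'                           seed = 1)
#' fit <- grmec(sim$dataset, base, C = 3, k = 6, seed = 1, max_iter = 50)
#' adjusted_rand_index(fit$labels, sim$truth)
#' @export
grmec <- function(views, base, C,
                  lambda1 = 0.1, lambda2 = 0.01, k = 50,
                  tol = 1e-6, max_iter = 200, seed = 1L,
                  init = c("spectral", "random"), normalize_W = TRUE,
                  update_weights = TRUE, w_init = NULL, alpha_init = NULL,
                  warm_start_S = FALSE,
                  denom_floor = 1e-10, residual_floor = 1e-10,
                  verbose = FALSE) {
  init <- match.arg(init)
  if (!inherits(views, "multiomics")) views <- align_views(views)
  cell_ids <- rownames(views[[1]])
  n <- length(cell_ids)
  m <- length(views)
  stopifnot(lambda1 >= 0, lambda2 >= 0, k >= 1, tol >= 0, max_iter >= 1)
  if (C < 2 || C > n)
    stop("C must satisfy 2 <= C <= n (got C=", C, ", n=", n, ")",
         call. = FALSE)
  Xs <- lapply(views, as.matrix)
  if (k > min(n, vapply(Xs, ncol, integer(1))))
    warning("latent dimension k=", k, " exceeds min(n, p_v); the ",
            "factorization is overparameterized", call. = FALSE)

  if (!inherits(base, "base_clustering_set")) base <- base_clustering_set(base)
  if (!identical(base$cell_ids, cell_ids)) {
    base$labelings <- lapply(base$labelings, .align_labels, cell_ids = cell_ids)
    base$cell_ids <- cell_ids
  }
  Slist <- .cocluster_list(base)
  nb <- length(Slist)

  # seeded uniform(0,1) initialization; S symmetrized, H row-stochastic
  set.seed(.stream_seed(seed, "init"))
  W <- matrix(stats::runif(n * k), n, k)
  Vs <- lapply(Xs, function(X) matrix(stats::runif(k * ncol(X)), k, ncol(X)))
  S <- if (warm_start_S) {
    Reduce(`+`, Slist) / nb
  } else {
    S0 <- matrix(stats::runif(n * n), n, n)
    (S0 + t(S0)) / 2
  }
  H <- if (init == "spectral") {
    .spectral_H_init(Slist, C)
  } else {
    matrix(stats::runif(n * C), n, C)
  }
  H <- H / rowSums(H)
  w <- if (is.null(w_init)) rep(1 / m, m) else rep_len(w_init, m)
  alpha <- if (is.null(alpha_init)) rep(1 / nb, nb) else rep_len(alpha_init, nb)

  trace <- .objective(W, Xs, Vs, w, H, S, Slist, alpha, lambda1, lambda2)$total
  n_reset <- 0L
  increases <- integer(0)
  converged <- FALSE
  t <- 0L
  while (t < max_iter) {
    t <- t + 1L
    W <- .mu_update_W(W, Xs, Vs, w, H, lambda1, denom_floor)
    Vs <- .mu_update_V(W, Xs, Vs, denom_floor)
    if (normalize_W) {
      cn <- pmax(sqrt(colSums(W^2)), denom_floor)
      W <- sweep(W, 2, cn, "/")
      Vs <- lapply(Vs, function(V) V * cn)
    }
    Dh <- pairwise_sq_dists(H)
    S <- .mu_update_S(S, Slist, alpha, Dh, lambda2, denom_floor)
    up <- .mu_update_H(H, S, W, lambda1, lambda2, denom_floor, warn = FALSE)
    H <- up$H
    n_reset <- n_reset + up$n_reset
    if (update_weights) {
      w <- .update_weight_w(W, Xs, Vs, residual_floor)
      alpha <- .update_weight_alpha(S, Slist, residual_floor)
    }
    obj <- .objective(W, Xs, Vs, w, H, S, Slist, alpha, lambda1, lambda2)$total
    prev <- trace[length(trace)]
    trace <- c(trace, obj)
    if (obj > prev * (1 + 1e-8) + 1e-12) increases <- c(increases, t)
    if (verbose && t %% 10 == 0)
      cat(sprintf("sweep %4d  objective %.6e\n", t, obj))
    if (abs(prev - obj) <= tol * max(abs(obj), .Machine$double.xmin)) {
      converged <- TRUE
      break
    }
  }
  if (length(increases) > 0)
    warning("objective increased beyond tolerance at sweep(s) ",
            paste(utils::head(increases, 5), collapse = ", "), call. = FALSE)
  if (n_reset > 0)
    warning(n_reset, " H-row reset(s) to uniform during fitting",
            call. = FALSE)

  dimnames(W) <- list(cell_ids, paste0("k", seq_len(k)))
  dimnames(S) <- list(cell_ids, cell_ids)
  dimnames(H) <- list(cell_ids, paste0("cluster", seq_len(C) - 1L))
  names(Vs) <- names(views)
  for (v in names(views))
    dimnames(Vs[[v]]) <- list(paste0("k", seq_len(k)), colnames(views[[v]]))

  structure(list(
    W = W, V = Vs, S = S, H = H,
    w = stats::setNames(w, names(views)),
    alpha = stats::setNames(alpha, paste(base$methods, base$views, sep = "/")),
    labels = assign_labels(H),
    objective = trace,
    iterations = t, converged = converged,
    n_reset_rows = n_reset,
    C = C, k = k, lambda1 = lambda1, lambda2 = lambda2,
    tol = tol, max_iter = max_iter, seed = seed,
    n = n, view_names = names(views),
    base_methods = base$methods, base_views = base$views,
    call = match.call()
  ), class = "grmec")
}

# Seed H with the ensemble's own consensus: k-means on the top-C eigenvectors
# of the mean co-cluster indicator, softened toward uniform so no entry
# starts at an exact (multiplicatively locked) zero.
.spectral_H_init <- function(Slist, C, soften = 0.9) {
  Sbar <- Reduce(`+`, Slist) / length(Slist)
  U <- eigen(Sbar, symmetric = TRUE)$vectors[, seq_len(C), drop = FALSE]
  km <- suppressWarnings(stats::kmeans(U, centers = C, nstart = 10,
                                       iter.max = 100))
  diag(C)[km$cluster, , drop = FALSE] * soften + (1 - soften) / C
}

#' Hard cluster labels from a soft indicator matrix
#'
#' Each cell is assigned to the column holding the largest entry of its row
#' of `H`; ties are broken by the lowest column index. Labels are 0-based.
#'
#' @param H Nonnegative matrix, rows = cells (row names used as cell ids).
#' @return A [label_vector()] whose decoded values ([label_values()]) are the
#'   0-based argmax column indices.
#' @export
assign_labels <- function(H) {
  H <- as.matrix(H)
  idx <- max.col(H, ties.method = "first") - 1L
  ids <- rownames(H)
  if (is.null(ids)) ids <- paste0("cell", seq_len(nrow(H)))
  label_vector(idx, ids)
}

#' Decoded label values of a label vector
#'
#' @param x A [label_vector()].
#' @return Character vector of the original (pre-encoding) labels, named by
#'   cell id.
#' @export
label_values <- function(x) {
  stopifnot(inherits(x, "label_vector"))
  stats::setNames(attr(x, "levels")[unclass(x) + 1L], names(x))
}

#' @export
print.grmec <- function(x, ...) {
  cat("Graph-regularized multi-view ensemble clustering fit\n")
  cat(sprintf("  %d cells, %d view(s) [%s], %d base labeling(s)\n",
              x$n, length(x$view_names), paste(x$view_names, collapse = ", "),
              length(x$alpha)))
  cat(sprintf("  C = %d clusters, k = %d, lambda1 = %g, lambda2 = %g\n",
              x$C, x$k, x$lambda1, x$lambda2))
  cat(sprintf("  %d sweep(s), %sconverged (tol %g); objective %.6g -> %.6g\n",
              x$iterations, if (x$converged) "" else "NOT ", x$tol,
              x$objective[1], x$objective[length(x$objective)]))
  cat("  cluster sizes:",
      paste(tabulate(unclass(x$labels) + 1L, nbins = x$C), collapse = " "),
      "\n")
  invisible(x)
}

#' Summary of a fitted multi-view ensemble clustering model
#'
#' @param object A `"grmec"` fit.
#' @param ... Unused.
#' @return An object of class `"summary.grmec"` reporting cluster sizes,
#'   learned view weights, the range of base-result weights and convergence
#'   diagnostics.
#' @export
summary.grmec <- function(object, ...) {
  sizes <- table(label_values(object$labels))
  structure(list(
    n = object$n, C = object$C, k = object$k,
    lambda1 = object$lambda1, lambda2 = object$lambda2,
    sizes = sizes,
    w = object$w, alpha = object$alpha,
    iterations = object$iterations, converged = object$converged,
    objective_first = object$objective[1],
    objective_last = object$objective[length(object$objective)],
    n_reset_rows = object$n_reset_rows
  ), class = "summary.grmec")
}

#' @export
print.summary.grmec <- function(x, ...) {
  cat("Graph-regularized multi-view ensemble clustering\n")
  cat(sprintf("  n = %d, C = %d, k = %d, lambda1 = %g, lambda2 = %g\n",
              x$n, x$C, x$k, x$lambda1, x$lambda2))
  cat(sprintf("  %d sweep(s), %sconverged; objective %.6g -> %.6g\n",
              x$iterations, if (x$converged) "" else "NOT ",
              x$objective_first, x$objective_last))
  cat("\nCluster sizes:\n")
  print(x$sizes)
  cat("\nView weights w_v (higher = better reconstructed view):\n")
  print(round(x$w, 6))
  cat("\nBase-result weights alpha_rv (higher = closer to consensus):\n")
  print(round(x$alpha, 6))
  if (x$n_reset_rows > 0)
    cat("\nNote:", x$n_reset_rows, "H-row reset(s) to uniform during fitting\n")
  invisible(x)
}

#' Objective trace plot
#'
#' @param x A `"grmec"` fit.
#' @param log Plot the objective on a log scale (default `TRUE`).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.grmec <- function(x, log = TRUE, ...) {
  graphics::plot(seq_along(x$objective) - 1L, x$objective,
                 type = "b", pch = 16, cex = 0.6,
                 log = if (log && all(x$objective > 0)) "y" else "",
                 xlab = "sweep", ylab = "objective",
                 main = "Multiplicative-update objective trace", ...)
  invisible(x)
}

#' @export
coef.grmec <- function(object, ...) object$W

#' @export
fitted.grmec <- function(object, ...) {
  lapply(object$V, function(Vv) object$W %*% Vv)
}
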