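#' Simulate a multi-omics dataset with planted cluster structure
#'
#' Generates `m` nonnegative count views sharing one ground-truth partition
#' of `n` cells into `C` clusters, following the low-rank structure the
#' factorization model assumes: a shared nonnegative latent representation
#' `W_true` (cluster-specific latent means separated by `separation`) and
#' per-view nonnegative bases `V_true`, with counts drawn from a Poisson law
#' around the mean matrix `W_true %*% V_true` scaled to `count_scale`, then
#' thinned by independent dropout. Negative-binomial overdispersion is
#' available via `nb_size` (off by default).
#'
#' Every random component draws from its own named stream derived from
#' `seed`, so adding a view never perturbs the draws of earlier views.
#'
#' @param n Number of cells.
#' @param C Number of planted clusters.
#' @param m Number of views.
#' @param p Integer vector of feature counts per view (recycled to length
#'   `m`).
#' @param proportions Cluster mixing proportions (default uniform).
#' @param k_true Latent dimension of the generating factors (default
#'   `max(C, 2)`).
#' @param separation Scale of the between-cluster latent mean differences;
#'   larger values make clusters easier to recover (default 2).
#' @param noise_sd Standard deviation of per-view multiplicative log-normal
#'   noise on the mean matrix (default 0.1).
#' @param dropout Per-view dropout (independent zeroing) probabilities in
#'   `[0, 1)`, recycled to length `m` (default 0).
#' @param count_scale Target mean library size per cell (default 2000).
#' @param nb_size If finite, counts are negative binomial with this size
#'   (dispersion) parameter instead of Poisson (default `Inf` = Poisson).
#' @param seed Integer seed.
#' @return A list of class `"sim_multiomics"`: `dataset` (a `"multiomics"`
#'   list of count matrices named `view1..viewm`), `truth` (a
#'   [label_vector()]), and the generating factors `W_true`, `V_true`.
#' @export
simulate_multiomics <- function(n, C, m = 2, p = 500,
                                proportions = NULL, k_true = max(C, 2),
                                separation = 2, noise_sd = 0.1,
                                dropout = 0, count_scale = 2000,
                                nb_size = Inf, seed = 1L) {
  stopifnot(n >= 2, C >= 2, C <= n, m >= 1, separation > 0, noise_sd >= 0,
            count_scale > 0, k_true >= 1)
  p <- rep_len(as.integer(p), m)
  dropout <- rep_len(dropout, m)
  stopifnot(all(p >= 1), all(dropout >= 0), all(dropout < 1))
  if (is.null(proportions)) proportions <- rep(1 / C, C)
  stopifnot(length(proportions) == C, all(proportions > 0))
  proportions <- proportions / sum(proportions)

  # planted memberships
  set.seed(.stream_seed(seed, "membership"))
  z <- sample.int(C, n, replace = TRUE, prob = proportions)
  while (length(unique(z)) < C) {                 # guarantee no empty cluster
    z[sample.int(n, C)] <- seq_len(C)
  }

  # cluster-separated nonnegative latent means: baseline + an elevated block
  set.seed(.stream_seed(seed, "latent-means"))
  mu <- matrix(stats::runif(C * k_true, 0.05, 0.25), C, k_true)
  for (c in seq_len(C)) mu[c, 1 + (c - 1) %% k_true] <-
    mu[c, 1 + (c - 1) %% k_true] + separation
  set.seed(.stream_seed(seed, "latent-cells"))
  W_true <- mu[z, , drop = FALSE] *
    matrix(exp(stats::rnorm(n * k_true, 0, 0.1)), n, k_true)
  cell_ids <- sprintf("cell%0*d", nchar(n), seq_len(n))
  rownames(W_true) <- cell_ids

  views <- vector("list", m)
  V_true <- vector("list", m)
  for (v in seq_len(m)) {
    vn <- paste0("view", v)
    set.seed(.stream_seed(seed, paste0("basis/", vn)))
    Vv <- matrix(stats::runif(k_true * p[v]), k_true, p[v])
    feature_ids <- sprintf("%s_f%0*d", vn, nchar(p[v]), seq_len(p[v]))
    colnames(Vv) <- feature_ids
    M <- W_true %*% Vv
    set.seed(.stream_seed(seed, paste0("noise/", vn)))
    if (noise_sd > 0)
      M <- M * matrix(exp(stats::rnorm(n * p[v], 0, noise_sd)), n, p[v])
    M <- M * (count_scale / mean(rowSums(M)))     # mean library = count_scale
    set.seed(.stream_seed(seed, paste0("counts/", vn)))
    X <- if (is.finite(nb_size)) {
      matrix(stats::rnbinom(n * p[v], mu = as.vector(M), size = nb_size),
             n, p[v])
    } else {
      matrix(stats::rpois(n * p[v], as.vector(M)), n, p[v])
    }
    if (dropout[v] > 0) {
      set.seed(.stream_seed(seed, paste0("dropout/", vn)))
      X[matrix(stats::runif(n * p[v]) < dropout[v], n, p[v])] <- 0
    }
    X <- matrix(as.numeric(X), n, p[v],
                dimnames = list(cell_ids, feature_ids))
    attr(X, "view_name") <- vn
    views[[v]] <- X
    V_true[[v]] <- Vv
  }
  names(views) <- paste0("view", seq_len(m))
  names(V_true) <- names(views)
  structure(list(dataset = structure(views, class = "multiomics"),
                 truth = label_vector(z - 1L, cell_ids),
                 W_true = W_true, V_true = V_true),
            class = "sim_multiomics")
}

#' Corrupt a labeling at a given error rate
#'
#' Each cell's label is independently replaced, with probability
#' `error_rate`, by a label drawn uniformly from the other `C - 1` clusters.
#' Used to manufacture base clustering results of controlled quality.
#'
#' @param truth A [label_vector()].
#' @param error_rate Probability of corrupting each cell, in `[0, 1)`.
#' @param C Number of clusters to draw replacements from (default: number of
#'   levels of `truth`).
#' @param seed Integer seed.
#' @return A [label_vector()] over the same cells.
#' @export
corrupt_labeling <- function(truth, error_rate, C = NULL, seed = 1L) {
  stopifnot(error_rate >= 0, error_rate < 1)
  if (!inherits(truth, "label_vector"))
    truth <- label_vector(truth, names(truth))
  code <- unclass(truth)
  lev <- attr(truth, "levels")
  if (is.null(C)) C <- length(lev)
  stopifnot(C >= 2)
  if (C > length(lev)) lev <- c(lev, paste0("corrupt", seq_len(C - length(lev))))
  set.seed(.stream_seed(seed, "corrupt"))
  n <- length(code)
  flip <- stats::runif(n) < error_rate
  if (any(flip)) {
    # uniform over the C-1 labels different from the current one
    shift <- sample.int(C - 1, sum(flip), replace = TRUE)
    code[flip] <- (code[flip] + shift) %% C
  }
  # rebuild through the level strings so an uncorrupted labeling round-trips
  # to the identical canonical encoding
  label_vector(lev[code + 1L], names(truth))
}

#' Simulate a grid of corrupted base clusterings
#'
#' Produces the `q x m` base clustering results the ensemble consumes, each
#' an independently corrupted copy of the planted truth.
#'
#' @param truth A [label_vector()].
#' @param q Number of base methods.
#' @param m Number of views.
#' @param error_rate Scalar, or `q x m` matrix / length-`q*m` vector of
#'   per-labeling corruption rates (view-major order).
#' @param C Number of clusters for corruption draws (default: levels of
#'   `truth`).
#' @param seed Integer seed.
#' @return A [base_clustering_set()] with methods `sim1..simq` and views
#'   `view1..viewm`.
#' @export
simulate_base_set <- function(truth, q, m, error_rate = 0.1, C = NULL,
                              seed = 1L) {
  stopifnot(q >= 1, m >= 1)
  rates <- matrix(rep_len(as.numeric(error_rate), q * m), q, m)
  labelings <- list(); meth <- character(); vw <- character()
  for (v in seq_len(m)) {
    for (r in seq_len(q)) {
      labelings <- c(labelings, list(
        corrupt_labeling(truth, rates[r, v], C = C,
                         seed = .stream_seed(seed, sprintf("base/%d/%d", r, v)))))
      meth <- c(meth, paste0("sim", r)); vw <- c(vw, paste0("view", v))
    }
  }
  base_clustering_set(labelings, methods = meth, views = vw)
}
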