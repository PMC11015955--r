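.as_codes <- function(x) {
  if (inherits(x, "label_vector")) return(unclass(x))
  if (!is.null(names(x))) return(unclass(label_vector(x, names(x))))
  unclass(label_vector(x, seq_along(x)))
}

.check_pair <- function(a, b) {
  ca <- .as_codes(a); cb <- .as_codes(b)
  if (length(ca) != length(cb))
    stop("label vectors differ in length (", length(ca), " vs ", length(cb),
         ")", call. = FALSE)
  if (!is.null(names(ca)) && !is.null(names(cb))) {
    if (!setequal(names(ca), names(cb)))
      stop("label vectors cover different cells", call. = FALSE)
    cb <- cb[names(ca)]
  }
  list(a = ca, b = cb)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions under the permutation
#' model: \deqn{ARI = \frac{\sum_{ij}\binom{n_{ij}}{2} - E}{\tfrac12(\sum_i
#' \binom{a_i}{2} + \sum_j \binom{b_j}{2}) - E}, \quad E = \frac{\sum_i
#' \binom{a_i}{2}\sum_j \binom{b_j}{2}}{\binom{n}{2}},} computed from the
#' contingency table \eqn{n_{ij}} with margins \eqn{a_i, b_j}. Equals 1 iff
#' the partitions are identical up to relabeling; independent partitions
#' score around 0.
#'
#' @param a,b [label_vector()]s (or named/plain label vectors) over the same
#'   cells. If both are named, `b` is reordered onto `a`'s cells.
#' @return A number in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  p <- .check_pair(a, b)
  tab <- table(p$a, p$b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  expected <- sa * sb / choose(n, 2)
  denom <- (sa + sb) / 2 - expected
  if (denom == 0) return(1)  # both partitions trivial (all-singletons/all-one)
  (sij - expected) / denom
}

#' Normalized mutual information
#'
#' Mutual information between two partitions normalized by the arithmetic
#' mean of their entropies, \eqn{NMI = 2\,I(a,b)/(H(a) + H(b))} (natural
#' logs; the value is base-invariant). By convention the score is 0 when
#' either partition has a single cluster (zero entropy), and 1 for identical
#' partitions with at least two clusters.
#'
#' @inheritParams adjusted_rand_index
#' @return A number in `[0, 1]`.
#' @export
normalized_mutual_information <- function(a, b) {
  p <- .check_pair(a, b)
  tab <- table(p$a, p$b)
  n <- sum(tab)
  pa <- rowSums(tab) / n
  pb <- colSums(tab) / n
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha == 0 || hb == 0) return(0)
  pj <- tab / n
  nz <- pj > 0
  mi <- sum(pj[nz] * log(pj[nz] / (pa[row(pj)[nz]] * pb[col(pj)[nz]])))
  max(0, min(1, mi / ((ha + hb) / 2)))
}

#' Rank marker features per cluster by Wilcoxon rank-sum tests
#'
#' One-vs-rest differential expression: for each cluster and each feature,
#' cells in the cluster are compared against all other cells by a two-sided
#' Wilcoxon rank-sum test (normal approximation with tie and continuity
#' correction). Within each cluster, features are ranked by ascending
#' p-value, ties broken by descending in-cluster mean, and the `top_n` best
#' are returned. No multiple-testing correction is applied — the ranking is
#' by raw p-value.
#'
#' @param X Cell-by-feature omics matrix (typically normalized expression).
#' @param labels A [label_vector()] over the rows of `X`.
#' @param top_n Markers to report per cluster (default 4). Values larger
#'   than the number of features return all features, ranked.
#' @return A data frame with columns `cluster`, `rank`, `feature`,
#'   `statistic` (sum of ranks of the in-cluster cells), `p_value`,
#'   `mean_in`, `mean_out`. Clusters of fewer than 2 cells are skipped with
#'   a warning.
#' @export
rank_markers <- function(X, labels, top_n = 4) {
  stopifnot(top_n >= 1)
  X <- as.matrix(X)
  if (!inherits(labels, "label_vector"))
    labels <- label_vector(labels, names(labels))
  if (!is.null(rownames(X))) labels <- .align_labels(labels, rownames(X))
  if (length(labels) != nrow(X))
    stop("labels do not cover the rows of X", call. = FALSE)
  vals <- label_values(labels)
  clusters <- unique(vals)
  if (length(clusters) < 2)
    stop("rank_markers needs at least 2 clusters", call. = FALSE)

  n <- nrow(X)
  # rank each feature once across all cells; tie-corrected variance pieces
  R <- apply(X, 2, rank)
  tie_term <- apply(X, 2, function(x) {
    t <- table(x)
    sum(t^3 - t)
  })

  out <- list()
  for (cl in clusters) {
    in_cl <- vals == cl
    n1 <- sum(in_cl); n2 <- n - n1
    if (n1 < 2) {
      warning("cluster '", cl, "' has fewer than 2 cells; skipped",
              call. = FALSE)
      next
    }
    stat <- colSums(R[in_cl, , drop = FALSE])         # rank sum of in-group
    mu <- n1 * (n + 1) / 2
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
    z <- numeric(ncol(X))
    pos <- sigma2 > 0
    # continuity correction toward the null, as in the classical test
    z[pos] <- (stat[pos] - mu - sign(stat[pos] - mu) * 0.5) / sqrt(sigma2[pos])
    p <- ifelse(pos, 2 * stats::pnorm(-abs(z)), 1)
    p <- pmin(p, 1)
    mean_in <- colMeans(X[in_cl, , drop = FALSE])
    mean_out <- colMeans(X[!in_cl, , drop = FALSE])
    ord <- order(p, -mean_in, colnames(X), method = "radix")
    keep <- ord[seq_len(min(top_n, ncol(X)))]
    out[[length(out) + 1]] <- data.frame(
      cluster = cl, rank = seq_along(keep), feature = colnames(X)[keep],
      statistic = stat[keep], p_value = p[keep],
      mean_in = mean_in[keep], mean_out = mean_out[keep],
      row.names = NULL, stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    stop("no cluster with at least 2 cells", call. = FALSE)
  do.call(rbind, out)
}
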