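#' Select highly variable features
#'
#' Ranks features by a mean-binned standardized dispersion computed on
#' log1p-transformed values — the classic dispersion recipe used for
#' highly-variable-gene selection in single-cell toolkits, made fully
#' deterministic here. Per feature the mean \eqn{\mu_f} and dispersion
#' \eqn{d_f = \mathrm{var}_f/\mu_f} of `log1p(x)` are computed; dispersions
#' are then z-scored within `n_bins` equal-frequency bins of \eqn{\mu_f}, and
#' the `n_top` features with the highest standardized dispersion are kept.
#' Ties are broken by higher mean, then by feature-id lexical order.
#'
#' @param X Cell-by-feature omics matrix (nonnegative).
#' @param n_top Number of features to keep (default 1000, the usual HVG
#'   count for scRNA-seq). If `n_top >= ncol(X)` the input is returned
#'   unchanged.
#' @param n_bins Number of equal-frequency mean bins (default 20).
#' @return `X` restricted to the selected features, original cell order
#'   preserved; selected feature ids in the original column order.
#' @export
select_hvg <- function(X, n_top = 1000, n_bins = 20) {
  stopifnot(n_top >= 1)
  validate_omics_matrix(X, what = "select_hvg input")
  p <- ncol(X)
  if (n_top >= p) return(X)

  sc <- hvg_scores(X, n_bins = n_bins)
  if (all(sc$dispersion == 0))
    stop("select_hvg: all features are constant; no variability signal",
         call. = FALSE)
  ord <- order(-sc$score, -sc$mean, sc$feature, method = "radix")
  keep <- sort(match(sc$feature[ord[seq_len(n_top)]], colnames(X)))
  X[, keep, drop = FALSE]
}

#' @describeIn select_hvg Per-feature mean, raw dispersion and standardized
#'   dispersion score on the log1p scale, as a data frame (one row per
#'   feature).
#' @export
hvg_scores <- function(X, n_bins = 20) {
  Y <- log1p(as.matrix(X))
  mu <- colMeans(Y)
  v <- .colVars(Y, mu)
  disp <- ifelse(mu > 0, v / mu, 0)

  # equal-frequency mean bins; duplicate quantiles collapse gracefully
  br <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1),
                               names = FALSE, type = 7))
  bin <- if (length(br) > 2) {
    cut(mu, breaks = br, include.lowest = TRUE, labels = FALSE)
  } else rep(1L, length(mu))

  z <- numeric(length(disp))
  for (b in unique(bin)) {
    i <- which(bin == b)
    s <- stats::sd(disp[i])
    z[i] <- if (length(i) > 1 && is.finite(s) && s > 0)
      (disp[i] - mean(disp[i])) / s else 0
  }
  z[disp <= 0] <- -Inf   # constant features are never selected
  data.frame(feature = colnames(X), mean = mu, dispersion = disp,
             score = z, bin = bin, row.names = NULL,
             stringsAsFactors = FALSE)
}

.colVars <- function(Y, mu = colMeans(Y)) {
  n <- nrow(Y)
  (colSums(Y^2) - n * mu^2) / (n - 1)
}

#' Drop cells dominated by zero counts
#'
#' Removes every cell whose fraction of zero-valued features strictly
#' exceeds `cutoff`, the usual guard against near-empty droplets before
#' factorization. Surviving cells keep their order.
#'
#' @param X Cell-by-feature omics matrix.
#' @param cutoff Maximum tolerated zero fraction, in (0, 1]. Default 0.95:
#'   conservative, removes only near-empty cells.
#' @return List with `matrix` (filtered view) and `dropped` (character
#'   vector of removed cell ids).
#' @export
filter_cells_by_zero_count <- function(X, cutoff = 0.95) {
  stopifnot(cutoff > 0, cutoff <= 1)
  validate_omics_matrix(X, what = "filter_cells_by_zero_count input")
  nz <- if (inherits(X, "sparseMatrix")) {
    Matrix::rowSums(X != 0)
  } else {
    rowSums(X != 0)
  }
  zero_frac <- 1 - nz / ncol(X)
  drop <- zero_frac > cutoff
  if (all(drop))
    stop("filter_cells_by_zero_count: every cell exceeds the zero-fraction ",
         "cutoff (", cutoff, "); empty dataset", call. = FALSE)
  list(matrix = X[!drop, , drop = FALSE], dropped = rownames(X)[drop])
}

#' Normalize a count matrix for factorization
#'
#' `libsize-log1p` scales each cell to the median library size of the view
#' and applies `log(1 + x)`; output stays nonnegative, as the factorization
#' requires. `none` returns the input untouched. The recommended default is
#' `libsize-log1p` for RNA/ATAC count views and `none` for small ADT panels.
#'
#' @param X Cell-by-feature omics matrix (nonnegative).
#' @param mode `"none"` or `"libsize-log1p"`.
#' @return Normalized matrix, same dimnames and cell order.
#' @export
normalize_counts <- function(X, mode = c("libsize-log1p", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(X)
  validate_omics_matrix(X, what = "normalize_counts input")
  libsize <- if (inherits(X, "sparseMatrix")) Matrix::rowSums(X) else rowSums(X)
  if (any(libsize == 0))
    stop("normalize_counts: cell(s) with zero total count: ",
         paste(utils::head(rownames(X)[libsize == 0], 5), collapse = ", "),
         call. = FALSE)
  target <- stats::median(libsize)
  out <- log1p(as.matrix(X) * (target / libsize))
  dimnames(out) <- dimnames(X)
  attr(out, "view_name") <- attr(X, "view_name")
  out
}

#' Preprocess a multi-omics dataset
#'
#' Convenience wrapper applying, per view: zero-count cell filtering (on the
#' intersection of survivors across views), highly variable feature selection
#' on the counts (selection already works on the log1p scale internally), and
#' normalization of the selected submatrix. Per-view settings override the
#' defaults by view name.
#'
#' @param views A `"multiomics"` list from [align_views()] (or a plain named
#'   list of omics matrices).
#' @param n_hvg Features to keep per view (default 1000); `Inf` disables
#'   selection.
#' @param zero_cutoff Zero-fraction cutoff for cell filtering (default 0.95).
#' @param normalize Named character vector or single mode; per view
#'   `"libsize-log1p"` or `"none"`. Unnamed single value applies to all
#'   views.
#' @return A `"multiomics"` list of preprocessed, aligned views.
#' @export
preprocess_views <- function(views, n_hvg = 1000, zero_cutoff = 0.95,
                             normalize = "libsize-log1p") {
  if (!inherits(views, "multiomics")) views <- align_views(views)
  nms <- names(views)
  modes <- if (length(normalize) == 1 && is.null(names(normalize))) {
    stats::setNames(rep(normalize, length(nms)), nms)
  } else {
    stats::setNames(
      ifelse(nms %in% names(normalize), normalize[nms], "libsize-log1p"), nms)
  }
  # filter cells per view, keep the intersection of survivors
  keep <- rownames(views[[1]])
  for (nm in nms) {
    f <- filter_cells_by_zero_count(views[[nm]], cutoff = zero_cutoff)
    keep <- keep[keep %in% rownames(f$matrix)]
  }
  if (length(keep) < 2)
    stop("preprocess_views: fewer than 2 cells survive filtering",
         call. = FALSE)
  out <- vector("list", length(nms))
  names(out) <- nms
  for (nm in nms) {
    Xv <- views[[nm]][keep, , drop = FALSE]
    if (is.finite(n_hvg) && n_hvg < ncol(Xv)) Xv <- select_hvg(Xv, n_hvg)
    Xv <- normalize_counts(Xv, modes[[nm]])
    attr(Xv, "view_name") <- nm
    out[[nm]] <- Xv
  }
  structure(out, class = "multiomics")
}
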