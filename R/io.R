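#' Read a single-omics cell-by-feature matrix
#'
#' Loads one omics view (e.g. RNA counts, ADT counts, ATAC peak counts) into
#' the package's canonical orientation: cells in rows, features in columns,
#' all entries nonnegative. Sparse inputs stay sparse
#' (a [Matrix::sparseMatrix]).
#'
#' Three dialects are understood:
#' \describe{
#'   \item{`dense-csv`}{CSV/TSV with a header row of feature ids and first
#'     column of cell ids. Already cell-major; read as-is.}
#'   \item{`mtx-triplet`}{A Matrix Market `.mtx` file with `barcodes.tsv`
#'     and `features.tsv` sidecars (one id per line) in the same directory.
#'     Rows are barcodes (cells).}
#'   \item{`tenx-dir`}{A 10x-style directory containing `matrix.mtx`,
#'     `barcodes.tsv` and `features.tsv` (or `genes.tsv`). The 10x triplet is
#'     feature-major, so the matrix is transposed on read.}
#' }
#'
#' The loader validates, it never filters: all-zero rows/columns are kept
#' (cell/feature filtering belongs to the preprocessing step).
#'
#' @param path File (dense CSV / .mtx) or directory (10x) to read.
#' @param fmt One of `"dense-csv"`, `"mtx-triplet"`, `"tenx-dir"`.
#' @param view_name Label for the view, e.g. `"rna"`, `"adt"`, `"atac"`.
#' @param sep Field separator for `dense-csv` (default `","`).
#' @return A numeric matrix (dense) or `dgCMatrix` (sparse) with cell ids as
#'   row names, feature ids as column names, and the view name in
#'   `attr(, "view_name")`.
#' @seealso [align_views()], [write_omics_matrix()]
#' @export
load_omics_matrix <- function(path, fmt = c("dense-csv", "mtx-triplet", "tenx-dir"),
                              view_name = "view", sep = ",") {
  fmt <- match.arg(fmt)
  X <- switch(fmt,
    "dense-csv" = .read_dense_csv(path, sep),
    "mtx-triplet" = .read_mtx_triplet(path, transpose = FALSE),
    "tenx-dir" = .read_tenx_dir(path)
  )
  validate_omics_matrix(X, what = path)
  attr(X, "view_name") <- view_name
  X
}

.read_dense_csv <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("dense CSV needs a cell-id column plus >=1 feature: ", path,
                         call. = FALSE)
  cells <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    stop("non-numeric entries in column '", names(df)[-1][bad], "' of ", path,
         call. = FALSE)
  }
  rownames(vals) <- cells
  vals
}

.read_id_file <- function(path) {
  ids <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)[[1]]
  as.character(ids)
}

.find_sidecar <- function(dir, stems) {
  for (s in stems) {
    for (ext in c(".tsv", ".txt", "")) {
      f <- file.path(dir, paste0(s, ext))
      if (file.exists(f)) return(f)
    }
  }
  stop("missing sidecar file (tried: ", paste(stems, collapse = ", "),
       ") in ", dir, call. = FALSE)
}

.read_mtx_triplet <- function(path, transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  X <- as(Matrix::readMM(path), "CsparseMatrix")
  dir <- dirname(path)
  barcodes <- .read_id_file(.find_sidecar(dir, "barcodes"))
  features <- .read_id_file(.find_sidecar(dir, c("features", "genes")))
  if (transpose) X <- Matrix::t(X)
  if (nrow(X) != length(barcodes) || ncol(X) != length(features))
    stop("matrix is ", nrow(X), "x", ncol(X), " but sidecars list ",
         length(barcodes), " barcodes and ", length(features), " features: ",
         path, call. = FALSE)
  dimnames(X) <- list(barcodes, features)
  X
}

.read_tenx_dir <- function(path) {
  if (!dir.exists(path)) stop("directory not found: ", path, call. = FALSE)
  mtx <- file.path(path, "matrix.mtx")
  if (!file.exists(mtx)) stop("no matrix.mtx in ", path, call. = FALSE)
  # 10x writes features x barcodes; transpose into cells x features
  X <- as(Matrix::readMM(mtx), "CsparseMatrix")
  barcodes <- .read_id_file(.find_sidecar(path, "barcodes"))
  features <- .read_id_file(.find_sidecar(path, c("features", "genes")))
  if (nrow(X) != length(features) || ncol(X) != length(barcodes))
    stop("matrix.mtx is ", nrow(X), "x", ncol(X), " but sidecars list ",
         length(features), " features and ", length(barcodes), " barcodes: ",
         path, call. = FALSE)
  X <- Matrix::t(X)
  dimnames(X) <- list(barcodes, features)
  X
}

#' Validate an omics matrix
#'
#' Checks the invariants every view must satisfy before entering the model:
#' nonnegative entries, unique non-missing cell and feature ids, at least two
#' cells and one feature.
#'
#' @param X Matrix-like with cell row names and feature column names.
#' @param what Label used in error messages.
#' @return `X`, invisibly.
#' @export
validate_omics_matrix <- function(X, what = "omics matrix") {
  if (is.null(rownames(X)) || is.null(colnames(X)))
    stop(what, ": cell ids (rownames) and feature ids (colnames) are required",
         call. = FALSE)
  if (anyDuplicated(rownames(X)))
    stop(what, ": duplicate cell ids, e.g. '",
         rownames(X)[duplicated(rownames(X))][1], "'", call. = FALSE)
  if (anyDuplicated(colnames(X)))
    stop(what, ": duplicate feature ids, e.g. '",
         colnames(X)[duplicated(colnames(X))][1], "'", call. = FALSE)
  if (nrow(X) < 2) stop(what, ": need at least 2 cells", call. = FALSE)
  if (ncol(X) < 1) stop(what, ": need at least 1 feature", call. = FALSE)
  mn <- if (inherits(X, "sparseMatrix")) min(0, min(X@x, 0)) else min(X)
  if (is.na(mn) || mn < 0)
    stop(what, ": negative or missing entries are not allowed ",
         "(nonnegativity is required for the factorization)", call. = FALSE)
  invisible(X)
}

#' Write an omics matrix as dense CSV
#'
#' Inverse of [load_omics_matrix()] for the `dense-csv` dialect.
#'
#' @param X Cell-by-feature matrix with dimnames.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(X, path) {
  df <- data.frame(cell_id = rownames(X), as.matrix(X), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("cell_id", colnames(X))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align multiple omics views onto one shared set of cells
#'
#' All views of a multi-omics dataset must describe the same cells in the
#' same order. `align_views` restricts every view to the intersection of the
#' cell ids and reorders to the first view's order. Cells present in only
#' some views are dropped (counts reported via `message`); values are never
#' imputed.
#'
#' @param views List of omics matrices (see [load_omics_matrix()]); names are
#'   used as view names, falling back to each matrix's `view_name` attribute.
#' @return A named list of views with identical row names, of class
#'   `"multiomics"`.
#' @export
align_views <- function(views) {
  stopifnot(is.list(views), length(views) >= 1)
  nms <- names(views)
  if (is.null(nms)) nms <- rep("", length(views))
  for (i in seq_along(views)) {
    if (!nzchar(nms[i])) {
      vn <- attr(views[[i]], "view_name")
      nms[i] <- if (!is.null(vn)) vn else paste0("view", i)
    }
    validate_omics_matrix(views[[i]], what = paste0("view '", nms[i], "'"))
  }
  if (anyDuplicated(nms)) stop("duplicate view names: ",
                               paste(nms[duplicated(nms)], collapse = ", "),
                               call. = FALSE)
  names(views) <- nms

  shared <- rownames(views[[1]])
  for (v in views[-1]) shared <- shared[shared %in% rownames(v)]
  if (length(shared) == 0)
    stop("alignment error: the views share no cell ids", call. = FALSE)
  for (i in seq_along(views)) {
    dropped <- nrow(views[[i]]) - length(shared)
    if (dropped > 0)
      message("align_views: dropping ", dropped, " cell(s) from view '",
              nms[i], "'")
    views[[i]] <- views[[i]][shared, , drop = FALSE]
  }
  structure(views, class = "multiomics")
}

#' @export
print.multiomics <- function(x, ...) {
  cat("Multi-omics dataset: ", length(x), " view(s), ",
      nrow(x[[1]]), " shared cells\n", sep = "")
  for (nm in names(x))
    cat(sprintf("  %-8s %6d features  %s\n", nm, ncol(x[[nm]]),
                if (inherits(x[[nm]], "sparseMatrix")) "(sparse)" else ""))
  invisible(x)
}

#' Construct a label vector
#'
#' Canonical per-cell cluster assignment: 0-based contiguous integer codes,
#' named by cell id, with the original label strings kept in
#' `attr(, "levels")` (codes index `levels` in order of first appearance).
#'
#' @param labels Vector of cluster labels (integer, factor or character).
#' @param cell_ids Cell ids, same length as `labels`.
#' @return Named integer vector of class `"label_vector"`.
#' @export
label_vector <- function(labels, cell_ids) {
  if (length(labels) != length(cell_ids))
    stop("labels and cell_ids differ in length", call. = FALSE)
  if (anyDuplicated(cell_ids))
    stop("duplicate cell id in labels: '",
         cell_ids[duplicated(cell_ids)][1], "'", call. = FALSE)
  if (anyNA(labels) || anyNA(cell_ids))
    stop("missing values in labels or cell ids", call. = FALSE)
  lab <- as.character(labels)
  lev <- unique(lab)                       # order of first appearance
  code <- match(lab, lev) - 1L
  names(code) <- as.character(cell_ids)
  structure(code, levels = lev, class = "label_vector")
}

#' @export
print.label_vector <- function(x, ...) {
  cat("Label vector: ", length(x), " cells, ",
      length(attr(x, "levels")), " clusters\n", sep = "")
  print(stats::setNames(table(attr(x, "levels")[unclass(x) + 1L]), NULL))
  invisible(x)
}

#' Read / write per-cell cluster labels
#'
#' `load_labels` reads a two-column CSV with header `cell_id,label`;
#' `write_labels` is its exact inverse on the canonical form, so
#' `load_labels(write_labels(x))` reproduces `x` including the level
#' encoding.
#'
#' @param path CSV file.
#' @return `load_labels`: a [label_vector()].
#' @export
load_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("cell_id", "label") %in% colnames(df)))
    stop("label file must have header 'cell_id,label': ", path, call. = FALSE)
  label_vector(df$label, df$cell_id)
}

#' @param labels A [label_vector()] (or anything `label_vector()` accepts,
#'   with cell ids as names).
#' @rdname load_labels
#' @return `write_labels`: `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  if (!inherits(labels, "label_vector"))
    labels <- label_vector(labels, names(labels))
  lev <- attr(labels, "levels")
  df <- data.frame(cell_id = names(labels),
                   label = lev[unclass(labels) + 1L],
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Reorder a label vector onto `cell_ids`, failing loudly on missing cells.
.align_labels <- function(labels, cell_ids, what = "label vector") {
  missing <- setdiff(cell_ids, names(labels))
  if (length(missing) > 0)
    stop(what, ": missing cells: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ..." else "", call. = FALSE)
  out <- labels[cell_ids]
  structure(unclass(out), levels = attr(labels, "levels"),
            names = cell_ids, class = "label_vector")
}
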