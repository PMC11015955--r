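#' Write / read a model checkpoint
#'
#' A checkpoint is a directory of plain-text artifacts: `W.csv`, one
#' `V_<view>.csv` per view, `S.mtx` (Matrix Market), `H.csv`, `labels.csv`
#' and `metadata.json` (hyper-parameters, seed, weights, objective trace).
#' Everything a checkpoint writes can be re-loaded without loss by
#' `read_checkpoint` (values round-trip through full-precision text).
#'
#' @param fit A `"grmec"` fit.
#' @param dir Output directory (created if needed).
#' @return `write_checkpoint`: `dir`, invisibly. `read_checkpoint`: a list
#'   with elements `W`, `V`, `S`, `H`, `labels` and `meta`.
#' @export
write_checkpoint <- function(fit, dir) {
  stopifnot(inherits(fit, "grmec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_factor_csv(fit$W, file.path(dir, "W.csv"), "cell_id")
  for (v in names(fit$V))
    .write_factor_csv(t(fit$V[[v]]), file.path(dir, paste0("V_", v, ".csv")),
                      "feature_id")
  Matrix::writeMM(methods::as(methods::as(fit$S, "sparseMatrix"),
                              "generalMatrix"),
                  file.path(dir, "S.mtx"))
  writeLines(rownames(fit$S), file.path(dir, "S_cells.txt"))
  .write_factor_csv(fit$H, file.path(dir, "H.csv"), "cell_id")
  write_labels(fit$labels, file.path(dir, "labels.csv"))
  meta <- list(C = fit$C, k = fit$k, lambda1 = fit$lambda1,
               lambda2 = fit$lambda2, tol = fit$tol, max_iter = fit$max_iter,
               seed = fit$seed, n = fit$n, view_names = fit$view_names,
               iterations = fit$iterations, converged = fit$converged,
               w = as.list(fit$w), alpha = as.list(fit$alpha),
               objective_trace = fit$objective)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

.write_factor_csv <- function(M, path, id_col) {
  df <- data.frame(rownames(M), format(M, digits = 17, trim = TRUE,
                                       scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(M) %||% paste0("c", seq_len(ncol(M))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @param dir Checkpoint directory written by `write_checkpoint`.
#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(dir) {
  rd <- function(f, id_col) {
    df <- utils::read.csv(file.path(dir, f), check.names = FALSE)
    M <- as.matrix(df[, -1, drop = FALSE])
    rownames(M) <- df[[1]]
    M
  }
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  W <- rd("W.csv")
  H <- rd("H.csv")
  S <- as.matrix(Matrix::readMM(file.path(dir, "S.mtx")))
  cells <- readLines(file.path(dir, "S_cells.txt"))
  dimnames(S) <- list(cells, cells)
  Vfiles <- list.files(dir, pattern = "^V_.*\\.csv$")
  V <- lapply(Vfiles, function(f) t(rd(f)))
  names(V) <- sub("^V_(.*)\\.csv$", "\\1", Vfiles)
  list(W = W, V = V, S = S, H = H,
       labels = load_labels(file.path(dir, "labels.csv")), meta = meta)
}

#' Write a simulated dataset to disk in the package's file formats
#'
#' @param sim A `"sim_multiomics"` object from [simulate_multiomics()].
#' @param dir Output directory.
#' @return Paths of the written files (named list), invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (v in names(sim$dataset)) {
    p <- file.path(dir, paste0(v, ".csv"))
    write_omics_matrix(sim$dataset[[v]], p)
    paths[[v]] <- p
  }
  paths$truth <- file.path(dir, "truth.csv")
  write_labels(sim$truth, paths$truth)
  invisible(paths)
}

.log_line <- function(con, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ", ...)
  if (!is.null(con)) writeLines(line, con)
  message(line)
}

#' Run the full clustering pipeline from a manifest
#'
#' Orchestrates load -> align -> preprocess -> base clustering -> model fit
#' -> evaluation from a single YAML manifest, writing a checkpoint, the
#' predicted labels, metrics (if a truth labeling is given) and a timestamped
#' run log into the output directory.
#'
#' The manifest is a YAML file (or an equivalent R list) with keys:
#' \preformatted{
#' views:                  # one entry per omics view
#'   - {name: rna, path: rna.csv, format: dense-csv,
#'      normalize: libsize-log1p}      # normalize is optional
#' clusters: 4
#' base:
#'   methods: [kmeans-pca, agglomerative-ward]   # built-ins, and/or
#'   external:                                   # externally produced labels
#'     - {method: toolA, view: rna, path: toolA_rna.csv}
#' preprocess: {n_hvg: 1000, zero_cutoff: 0.95}  # optional
#' params: {lambda1: 0.1, lambda2: 0.01, k: 50,  # optional
#'          tol: 1e-6, max_iter: 200, seed: 1}
#' truth: truth.csv                              # optional
#' output: outdir
#' }
#'
#' @param manifest Path to a YAML manifest, or the equivalent named list.
#' @param output Output directory (overrides the manifest's `output`).
#' @return Invisibly, a list with the `"grmec"` `fit`, the `metrics` (or
#'   `NULL`) and the `output` directory.
#' @export
run_pipeline <- function(manifest, output = NULL) {
  mf <- if (is.character(manifest)) yaml::read_yaml(manifest) else manifest
  out <- output %||% mf$output
  if (is.null(out)) stop("no output directory given", call. = FALSE)
  if (is.null(mf$views) || length(mf$views) == 0)
    stop("manifest lists no views", call. = FALSE)
  if (is.null(mf$clusters)) stop("manifest must set 'clusters'", call. = FALSE)

  # fail fast on missing inputs before any computation
  for (vw in mf$views)
    if (!file.exists(vw$path) && !dir.exists(vw$path))
      stop("view '", vw$name, "': path not found: ", vw$path, call. = FALSE)
  for (ex in mf$base$external)
    if (!file.exists(ex$path))
      stop("external labeling not found: ", ex$path, call. = FALSE)
  if (!is.null(mf$truth) && !file.exists(mf$truth))
    stop("truth labeling not found: ", mf$truth, call. = FALSE)

  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log <- file(file.path(out, "run.log"), open = "wt")
  on.exit(close(log))

  .log_line(log, "stage=load views=", length(mf$views))
  views <- list()
  for (vw in mf$views) {
    views[[vw$name]] <- load_omics_matrix(vw$path, fmt = vw$format %||% "dense-csv",
                                          view_name = vw$name)
  }
  views <- align_views(views)
  .log_line(log, "stage=align cells=", nrow(views[[1]]))

  pp <- mf$preprocess %||% list()
  norm <- stats::setNames(
    vapply(mf$views, function(vw) vw$normalize %||% "libsize-log1p",
           character(1)),
    vapply(mf$views, `[[`, character(1), "name"))
  views <- preprocess_views(views,
                            n_hvg = pp$n_hvg %||% 1000,
                            zero_cutoff = pp$zero_cutoff %||% 0.95,
                            normalize = norm)
  .log_line(log, "stage=preprocess cells=", nrow(views[[1]]), " features=",
            paste(vapply(views, ncol, integer(1)), collapse = ","))

  hp <- mf$params %||% list()
  seed <- hp$seed %||% 1L
  C <- mf$clusters

  base_parts <- list()
  if (!is.null(mf$base$methods))
    base_parts <- c(base_parts, list(
      run_base_clusterers(views, methods = unlist(mf$base$methods), C = C,
                          seed = seed)))
  if (!is.null(mf$base$external) && length(mf$base$external) > 0)
    base_parts <- c(base_parts, list(ingest_external_labelings(
      vapply(mf$base$external, `[[`, character(1), "path"), views,
      methods = vapply(mf$base$external, `[[`, character(1), "method"),
      view_names = vapply(mf$base$external, `[[`, character(1), "view"))))
  if (length(base_parts) == 0)
    stop("manifest defines no base clusterings (base.methods or ",
         "base.external)", call. = FALSE)
  base <- if (length(base_parts) == 1) base_parts[[1]] else
    base_clustering_set(
      c(base_parts[[1]]$labelings, base_parts[[2]]$labelings),
      methods = c(base_parts[[1]]$methods, base_parts[[2]]$methods),
      views = c(base_parts[[1]]$views, base_parts[[2]]$views))
  .log_line(log, "stage=base labelings=", length(base$labelings))

  fit <- grmec(views, base, C = C,
               lambda1 = hp$lambda1 %||% 0.1, lambda2 = hp$lambda2 %||% 0.01,
               k = hp$k %||% 50, tol = hp$tol %||% 1e-6,
               max_iter = hp$max_iter %||% 200, seed = seed)
  .log_line(log, "stage=fit sweeps=", fit$iterations, " converged=",
            fit$converged, " objective=",
            format(fit$objective[length(fit$objective)], digits = 10))
  for (t in seq_along(fit$objective))
    writeLines(sprintf("objective sweep=%d value=%.10e", t - 1L,
                       fit$objective[t]), log)

  write_checkpoint(fit, file.path(out, "checkpoint"))
  write_labels(fit$labels, file.path(out, "labels.csv"))

  metrics <- NULL
  if (!is.null(mf$truth)) {
    truth <- .align_labels(load_labels(mf$truth), names(fit$labels),
                           what = mf$truth)
    metrics <- list(ari = adjusted_rand_index(fit$labels, truth),
                    nmi = normalized_mutual_information(fit$labels, truth))
    jsonlite::write_json(metrics, file.path(out, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    .log_line(log, "stage=evaluate ari=", format(metrics$ari, digits = 6),
              " nmi=", format(metrics$nmi, digits = 6))
  }
  .log_line(log, "stage=done output=", out)
  invisible(list(fit = fit, metrics = metrics, output = out))
}
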