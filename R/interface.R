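# File I/O for datasets and results.
#
# Two on-disk encodings are supported: comma-delimited text (no header by
# default, '.' decimal) with a YAML metadata sidecar, and an R-native RDS
# container holding named arrays. Both round-trip through the same
# in-memory Dataset structure.

#' In-memory dataset container
#'
#' @param design `n x D` design matrix.
#' @param response length-`n` response vector.
#' @param shape filter axis lengths (or an `ald_grid`).
#' @param metadata free-form named list (source, seed, units, ...).
#' @return An object of class `ald_dataset` with fields `design`,
#'   `response`, `grid`, `metadata`.
#' @export
ald_dataset <- function(design, response, shape, metadata = list()) {
  design <- as.matrix(design)
  response <- as.numeric(response)
  grid <- if (inherits(shape, "ald_grid")) shape else filter_grid(shape)
  if (nrow(design) != length(response)) {
    stop("design has ", nrow(design), " rows but response has ",
         length(response), " entries")
  }
  if (ncol(design) != grid$D) {
    stop("declared shape implies ", grid$D, " columns but design has ",
         ncol(design))
  }
  structure(list(design = design, response = response, grid = grid,
                 metadata = metadata),
            class = "ald_dataset")
}

#' Save a dataset
#'
#' `format = "csv"` writes `<prefix>.design.csv`, `<prefix>.response.csv`
#' (comma-separated, no header) and `<prefix>.meta.yaml`;
#' `format = "rds"` writes a single `<prefix>.rds` container with named
#' entries `design`, `response`, `shape`, `metadata`.
#'
#' @param dataset an [ald_dataset()] object.
#' @param prefix output path prefix.
#' @param format `"csv"` or `"rds"`.
#' @param header write a header row in the CSV encoding.
#' @return (invisibly) the vector of files written.
#' @export
save_dataset <- function(dataset, prefix, format = c("csv", "rds"),
                         header = FALSE) {
  stopifnot(inherits(dataset, "ald_dataset"))
  format <- match.arg(format)
  if (format == "rds") {
    path <- paste0(prefix, ".rds")
    saveRDS(list(design = dataset$design, response = dataset$response,
                 shape = dataset$grid$shape, metadata = dataset$metadata),
            path)
    return(invisible(path))
  }
  fd <- paste0(prefix, ".design.csv")
  fr <- paste0(prefix, ".response.csv")
  fm <- paste0(prefix, ".meta.yaml")
  utils::write.table(dataset$design, fd, sep = ",", row.names = FALSE,
                     col.names = header)
  utils::write.table(dataset$response, fr, sep = ",", row.names = FALSE,
                     col.names = header)
  yaml::write_yaml(c(list(shape = as.integer(dataset$grid$shape),
                          header = header), dataset$metadata), fm)
  invisible(c(fd, fr, fm))
}

#' Load a dataset
#'
#' Accepts either an RDS container (`*.rds`), or a delimited-text design
#' file with the response in a companion file or in the final column.
#' Declared filter geometry is validated against the design width.
#'
#' @param path RDS container path, CSV design path, or a prefix written by
#'   [save_dataset()].
#' @param shape axis lengths; for RDS containers the stored shape is used
#'   when `NULL`.
#' @param response_path companion CSV with the response (defaults to the
#'   `.response.csv` sibling when `path` is a `.design.csv` file).
#' @param response_in_last_col if `TRUE`, split the response off the final
#'   design column.
#' @param header does the CSV have a header row.
#' @return An [ald_dataset()].
#' @export
load_dataset <- function(path, shape = NULL, response_path = NULL,
                         response_in_last_col = FALSE, header = FALSE) {
  if (!grepl("\\.(rds|csv)$", path)) {
    # prefix form
    if (file.exists(paste0(path, ".rds"))) {
      path <- paste0(path, ".rds")
    } else {
      meta_file <- paste0(path, ".meta.yaml")
      if (file.exists(meta_file)) {
        meta <- yaml::read_yaml(meta_file)
        if (is.null(shape)) shape <- meta$shape
        header <- isTRUE(meta$header)
      }
      path <- paste0(path, ".design.csv")
    }
  }
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.rds$", path)) {
    obj <- readRDS(path)
    if (is.null(shape)) shape <- obj$shape
    return(ald_dataset(obj$design, obj$response, shape,
                       obj$metadata %||% list()))
  }
  design <- as.matrix(utils::read.table(path, sep = ",", header = header))
  dimnames(design) <- NULL
  if (response_in_last_col) {
    response <- design[, ncol(design)]
    design <- design[, -ncol(design), drop = FALSE]
  } else {
    if (is.null(response_path)) {
      response_path <- sub("\\.design\\.csv$", ".response.csv", path)
    }
    if (!file.exists(response_path)) {
      stop("response file not found: ", response_path)
    }
    response <- drop(as.matrix(utils::read.table(response_path, sep = ",",
                                                 header = header)))
  }
  if (is.null(shape)) stop("`shape` must be given for text datasets")
  ald_dataset(design, response, shape)
}

#' Save a fit or MCMC trace
#'
#' Persists the result in an RDS container together with a structured
#' YAML sidecar (`<path>.summary.yaml`) holding the scalar summary: final
#' log evidence, noise variance, iteration or acceptance counts, family,
#' and tool version. The full posterior covariance is not stored (the
#' fits keep only the diagonal); pass the fitted posterior through
#' [posterior_moments()] if the full matrix is needed.
#'
#' @param result an `ald_fit` or `ald_mcmc` object.
#' @param path output RDS path.
#' @return (invisibly) the sidecar path.
#' @export
save_result <- function(result, path) {
  if (!inherits(result, c("ald_fit", "ald_mcmc"))) {
    stop("result must be an ald_fit or ald_mcmc object")
  }
  ok <- tryCatch({ saveRDS(result, path); TRUE },
                 error = function(e) {
                   stop("failed to write '", path, "': ", conditionMessage(e))
                 })
  smry <- if (inherits(result, "ald_fit")) {
    list(type = "fit",
         family = if (is.null(result$hyperparams)) "ml"
                  else result$hyperparams$family,
         log_evidence = if (is.null(result$posterior)) NA_real_
                        else result$posterior$log_evidence,
         noise_var = if (is.null(result$hyperparams)) NA_real_
                     else result$hyperparams$noise_var,
         iterations = length(result$trace))
  } else {
    list(type = "mcmc", family = result$family,
         n_samples = nrow(result$states),
         acceptance = mean(result$accepted),
         proposal_scale = result$proposal_scale,
         seed = result$seed)
  }
  smry$version <- as.character(utils::packageVersion("aldrf"))
  side <- paste0(path, ".summary.yaml")
  yaml::write_yaml(smry, side, precision = 15)
  invisible(side)
}

#' @rdname save_result
#' @export
load_result <- function(path) readRDS(path)
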