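#' Read a delimited regression dataset
#'
#' Reads a delimited text file with a header row, splits off the target
#' column and returns the remaining columns as the numeric input matrix.
#' Row order is preserved.
#'
#' @param path Path to a CSV/TSV file with a header.
#' @param target_column Name (or 1-based index) of the target column.
#' @param delimiter Field delimiter, default comma.
#' @return List with `X` (`N x d` matrix), `y` (length-`N` vector) and
#'   `feature_names`.
#' @export
read_dataset <- function(path, target_column = "t", delimiter = ",") {
  if (!file.exists(path)) stop_contract(sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) {
    stop_contract(sprintf("empty dataset (header only): %s", path))
  }
  if (is.numeric(target_column)) {
    if (target_column < 1 || target_column > ncol(df)) {
      stop_contract(sprintf("target column index %d out of range",
                            target_column))
    }
    tgt <- names(df)[target_column]
  } else {
    tgt <- target_column
    if (!tgt %in% names(df)) {
      stop_contract(sprintf("target column '%s' not found (columns: %s)",
                            tgt, paste(names(df), collapse = ", ")))
    }
  }
  for (nm in names(df)) {
    col <- df[[nm]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      if (anyNA(num) && !anyNA(col)) {
        bad <- which(is.na(num))[1]
        stop_contract(sprintf("non-numeric cell in column '%s', row %d", nm, bad))
      }
      df[[nm]] <- num
    }
    if (anyNA(df[[nm]])) {
      stop_contract(sprintf("missing/non-numeric value in column '%s', row %d",
                            nm, which(is.na(df[[nm]]))[1]))
    }
  }
  y <- df[[tgt]]
  Xdf <- df[setdiff(names(df), tgt)]
  if (ncol(Xdf) == 0L) stop_contract("no feature columns besides the target")
  list(X = as.matrix(Xdf), y = y, feature_names = names(Xdf))
}

#' Write a regression dataset as delimited text
#'
#' Inverse of [read_dataset()]: features as columns `x1..xd` (or supplied
#' names) plus the target column `t`.
#'
#' @param path Output path.
#' @param X Input matrix.
#' @param y Target vector.
#' @param delimiter Field delimiter.
#' @param feature_names Optional column names for the features.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(path, X, y, delimiter = ",",
                          feature_names = NULL) {
  X <- as.matrix(X)
  if (is.null(feature_names)) feature_names <- paste0("x", seq_len(ncol(X)))
  df <- as.data.frame(X)
  names(df) <- feature_names
  df$t <- as.numeric(y)
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Serialize hyperparameters to JSON
#'
#' Fields are written with explicit names `eta`, `lambda`, `mu` and a
#' `schema_version` marker.
#'
#' @param hp A [hyperparameters()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hyperparameters <- function(hp, path) {
  stopifnot(inherits(hp, "hyperparameters"))
  jsonlite::write_json(
    list(schema_version = 1L, eta = hp$eta, lambda = hp$lambda, mu = hp$mu),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read hyperparameters from JSON
#'
#' @param path Path to a JSON file with fields `eta`, `lambda`, `mu`.
#' @return A [hyperparameters()] object.
#' @export
read_hyperparameters <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  hyperparameters(eta = obj$eta, lambda = obj$lambda, mu = obj$mu)
}

#' Read a basis configuration from JSON
#'
#' Accepts the flat schema
#' `{"family": ..., "include_bias": ..., "degree": ..., "width": ...,
#' "n_centers": ..., "centers": ...}` with absent fields defaulting as in
#' [basis_config()].
#'
#' @param path Path to a JSON file.
#' @return A [basis_config()].
#' @export
read_basis_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  basis_config(
    family = if (is.null(obj$family)) "gaussian_rbf" else obj$family,
    include_bias = if (is.null(obj$include_bias)) TRUE else obj$include_bias,
    degree = obj$degree,
    centers = obj$centers,
    width = obj$width,
    n_centers = obj$n_centers
  )
}

#' Write a fit result (JSON summary + trace CSV)
#'
#' Writes `<prefix>_result.json` (schema-versioned summary with the final
#' hyperparameters, posterior mean, status and restart count) and
#' `<prefix>_trace.csv` with one row per evidence evaluation
#' (`iteration`, `log_evidence`, `pinv_flag`).
#'
#' @param fit An `em_fit` from [fit_em()] or a `pso_result` from
#'   [pso_fit()].
#' @param prefix Output path prefix.
#' @return Character vector of the two paths written, invisibly.
#' @export
write_fit_result <- function(fit, prefix) {
  json_path <- paste0(prefix, "_result.json")
  trace_path <- paste0(prefix, "_trace.csv")
  if (inherits(fit, "em_fit")) {
    jsonlite::write_json(
      list(schema_version = 1L, method = "em",
           status = fit$status, n_restarts = fit$n_restarts,
           n_iterations = nrow(fit$trace),
           hyperparameters = list(eta = fit$hyperparameters$eta,
                                  lambda = fit$hyperparameters$lambda,
                                  mu = fit$hyperparameters$mu),
           posterior = list(m = fit$posterior$m,
                            C = fit$posterior$C,
                            used_pseudo_inverse =
                              fit$posterior$used_pseudo_inverse),
           final_log_evidence = fit$trace$log_evidence[nrow(fit$trace)]),
      json_path, auto_unbox = TRUE, digits = NA)
    tr <- data.frame(iteration = fit$trace$iteration,
                     log_evidence = fit$trace$log_evidence,
                     pinv_flag = as.integer(fit$trace$used_pseudo_inverse))
  } else if (inherits(fit, "pso_result")) {
    jsonlite::write_json(
      list(schema_version = 1L, method = "pso",
           best_log_evidence = fit$best_log_evidence,
           first_converged_iteration =
             if (is.na(fit$first_converged_iteration)) "never"
             else fit$first_converged_iteration,
           hyperparameters = list(eta = fit$best_hp$eta,
                                  lambda = fit$best_hp$lambda,
                                  mu = fit$best_hp$mu)),
      json_path, auto_unbox = TRUE, digits = NA)
    tr <- data.frame(iteration = seq_along(fit$trace),
                     log_evidence = fit$trace,
                     pinv_flag = 0L)
  } else {
    stop_contract("`fit` must be an em_fit or pso_result")
  }
  utils::write.table(tr, trace_path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(c(json_path, trace_path))
}

#' Run the EM fit on a diabetes-style table (optional demo)
#'
#' Demonstration path for the classic 442-patient diabetes regression
#' benchmark (10 baseline variables, quantitative disease-progression
#' target).  The table is an optional external input: when `path` does
#' not exist the demo is skipped with a message and `NULL` is returned.
#' Any table with numeric feature columns and a numeric target works, so
#' a synthetic stand-in of the same shape exercises the identical code
#' path.
#'
#' @param path Path to a delimited file with the baseline variables and
#'   the target column.
#' @param target_column Target column name or index.
#' @param basis A [basis_config()] applied to the feature columns
#'   (default: identity with bias).
#' @param config An [em_config()].
#' @param output_prefix Optional prefix for [write_fit_result()] outputs.
#' @param delimiter Field delimiter.
#' @return An `em_fit`, or `NULL` (invisibly) when the file is absent.
#' @export
run_demo_diabetes <- function(path, target_column = "t",
                              basis = basis_config("identity"),
                              config = em_config(seed = 1L),
                              output_prefix = NULL, delimiter = ",") {
  if (!file.exists(path)) {
    message("diabetes demo skipped: '", path, "' not found ",
            "(the dataset is an optional external input)")
    return(invisible(NULL))
  }
  ds <- read_dataset(path, target_column = target_column,
                     delimiter = delimiter)
  data <- regression_data(ds$X, ds$y, basis = basis)
  fit <- fit_em(data, config)
  if (!is.null(output_prefix)) write_fit_result(fit, output_prefix)
  fit
}
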