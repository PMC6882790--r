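#' Write a flat trial table
#'
#' One row per trial, tab-delimited: session, block_id, t, b, mu_true, N_B,
#' N_R, y. Simulation-truth columns (b, mu_true) and responses may be
#' missing for real data before responding.
#'
#' @param trials trial table data.frame.
#' @param path output file path.
#' @export
write_trials <- function(trials, path) {
  cols <- intersect(c("session", "block_id", "t", "b", "mu_true",
                      "N_B", "N_R", "y"), names(trials))
  utils::write.table(trials[cols], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a flat trial table
#'
#' Reads a table written by [write_trials()] (or hand-prepared real data
#' with at least block_id, t, N_B, N_R) and recomputes N and the exact
#' sample proportion q.
#'
#' @param path input file path.
#' @return Trial table data.frame.
#' @export
read_trials <- function(path) {
  df <- utils::read.delim(path)
  if (!all(c("N_B", "N_R") %in% names(df)))
    stop("trial table must carry N_B and N_R")
  finish_trials(df)
}

#' Read a generative configuration from a YAML file
#'
#' Key/value file mirroring the [generative_config()] arguments; unknown
#' keys are rejected.
#'
#' @param path YAML file path.
#' @return A [generative_config()].
#' @export
read_generative_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read config files")
  vals <- yaml::read_yaml(path)
  known <- names(formals(generative_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(generative_config, vals)
}

#' Serialize a fit result to a structured text file
#'
#' Flat named-parameter record plus per-fold held-out log-likelihoods,
#' written as tab-delimited key/value lines readable by [read_fit()].
#'
#' @param fit a \code{"hierconf_fit"}.
#' @param path output file path.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "hierconf_fit"))
  lines <- c(paste0("model\t", fit$model),
             paste0("experiment\t", fit$experiment),
             paste0("par.", names(fit$par), "\t",
                    formatC(fit$par, format = "g", digits = 17)),
             paste0("train_loglik\t",
                    formatC(fit$train_loglik, format = "g", digits = 17)),
             paste0("cvll\t", formatC(fit$cvll, format = "g", digits = 17)),
             paste0("fold_test_loglik\t",
                    paste(formatC(fit$fold_test_logliks, format = "g",
                                  digits = 17), collapse = ",")),
             paste0("converged\t", fit$converged))
  writeLines(lines, path)
  invisible(path)
}

#' Read a serialized fit result
#'
#' @param path file written by [write_fit()].
#' @return A \code{"hierconf_fit"} list.
#' @export
read_fit <- function(path) {
  kv <- utils::read.delim(path, header = FALSE,
                          col.names = c("key", "value"),
                          colClasses = "character")
  get1 <- function(k) kv$value[kv$key == k]
  num1 <- function(k) {
    v <- trimws(get1(k))
    if (identical(v, "NA")) NA_real_ else as.numeric(v)
  }
  pk <- grepl("^par\\.", kv$key)
  par <- stats::setNames(as.numeric(kv$value[pk]),
                         sub("^par\\.", "", kv$key[pk]))
  folds <- get1("fold_test_loglik")
  structure(list(model = get1("model"), experiment = get1("experiment"),
                 par = par,
                 train_loglik = num1("train_loglik"),
                 fold_test_logliks = if (nzchar(folds))
                   as.numeric(strsplit(folds, ",")[[1]]) else numeric(0),
                 cvll = num1("cvll"),
                 converged = as.logical(get1("converged"))),
            class = "hierconf_fit")
}
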