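#' Read and write Q-matrix CSV files
#'
#' The Q-matrix interchange format is a comma-separated UTF-8 file with
#' a header row: first column the item identifier, an optional `C`
#' column of per-item category counts, and one 0/1 column per attribute
#' (column names are the attribute names).
#'
#' @param path File path.
#' @return `read_qmatrix()`: a list with `Q` (binary integer matrix,
#'   item ids as rownames) and `category_counts` (integer vector, or
#'   `NULL` when the file has no `C` column).
#' @export
read_qmatrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2L) abort("Q-matrix file needs an item column plus attribute columns.",
                           class = "gpdm_parse_error")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate item id(s): %s.",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "gpdm_parse_error")
  }
  df <- df[-1L]
  category_counts <- NULL
  ccol <- which(tolower(names(df)) == "c")
  if (length(ccol) == 1L) {
    category_counts <- as.integer(df[[ccol]])
    if (anyNA(category_counts) || any(category_counts < 2L)) {
      abort("Category counts must be integers >= 2.", class = "gpdm_parse_error")
    }
    df <- df[-ccol]
  }
  Q <- as.matrix(df)
  bad <- which(!(Q %in% c(0, 1)) | is.na(Q), arr.ind = FALSE)
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(Q))
    abort(sprintf("Non-binary Q-matrix cell at row %d, column '%s'.",
                  rc[1L], colnames(Q)[rc[2L]]),
          class = "gpdm_parse_error")
  }
  storage.mode(Q) <- "integer"
  rownames(Q) <- ids
  Q <- validate_qmatrix(Q)
  list(Q = Q, category_counts = category_counts)
}

#' @rdname read_qmatrix
#' @param Q Binary Q-matrix with item ids as rownames.
#' @param category_counts Optional per-item category counts written as
#'   a `C` column.
#' @export
write_qmatrix <- function(Q, path, category_counts = NULL) {
  Q <- validate_qmatrix(Q)
  df <- tibble(item = rownames(Q))
  if (!is.null(category_counts)) df$C <- as.integer(category_counts)
  df <- dplyr::bind_cols(df, as_tibble(Q))
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Read and write response-matrix CSV files
#'
#' Responses are stored as a header-ed CSV of integer categories
#' (`0 ... C_j - 1`), one row per examinee, one column per item.
#'
#' @param path File path.
#' @param category_counts Optional per-item category counts used for
#'   range validation.
#' @return `read_responses()`: an N x J integer matrix.
#' @export
read_responses <- function(path, category_counts = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  X <- as.matrix(df)
  v <- validate_responses(X, category_counts)
  v$X
}

#' @rdname read_responses
#' @param X Integer response matrix.
#' @export
write_responses <- function(X, path) {
  readr::write_csv(as_tibble(as.matrix(X)), path, progress = FALSE)
  invisible(path)
}

#' Bundled Q-matrices
#'
#' `qmatrix_sim20()` is the balanced J = 20, K = 5 simulation Q-matrix
#' (one- to three-attribute items, every attribute measured 8 times);
#' `qmatrix_sim40()` stacks it twice for the J = 40 conditions.
#' `qmatrix_pisa_reading()` is the retrofitted Q-matrix for 20 released
#' PISA 2000 reading items (K = 5; five items have three score
#' categories) together with its category counts — the response data
#' themselves are not distributed.
#'
#' @return `qmatrix_sim20()`/`qmatrix_sim40()`: a binary matrix;
#'   `qmatrix_pisa_reading()`: a list with `Q` and `category_counts`.
#' @export
qmatrix_sim20 <- function() {
  read_qmatrix(system.file("extdata", "qmatrix_sim_j20.csv", package = "gpdm"))$Q
}

#' @rdname qmatrix_sim20
#' @export
qmatrix_sim40 <- function() {
  Q <- qmatrix_sim20()
  Q2 <- rbind(Q, Q)
  rownames(Q2) <- paste0("item", seq_len(nrow(Q2)))
  Q2
}

#' @rdname qmatrix_sim20
#' @export
qmatrix_pisa_reading <- function() {
  read_qmatrix(system.file("extdata", "qmatrix_pisa_reading.csv", package = "gpdm"))
}

#' Export a fitted model to JSON
#'
#' Serializes the probability tables, standard errors, structural
#' distribution, log-likelihood and settings to a JSON file.
#'
#' @param fit A [fit_gpdm()] result.
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path) {
  payload <- list(
    model = fit$model,
    loglik = fit$loglik,
    n_iter = fit$n_iter,
    converged = fit$converged,
    structural = as.list(fit$structural),
    items = lapply(seq_along(fit$item_probs), function(j) {
      list(item = fit$item_maps[[j]]$item,
           probs = fit$item_probs[[j]],
           se = if (!is.null(fit$se_tables)) fit$se_tables[[j]] else NULL,
           groups = group_labels(fit$item_maps[[j]]))
    }),
    settings = fit$settings
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
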