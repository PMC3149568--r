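#' Two-class labeled expression dataset
#'
#' Container for a samples-by-variables measurement matrix with binary class
#' labels coded -1/+1. Columns are mean-centered on construction and the
#' centering vector is retained, so that a model trained on this dataset can
#' center new samples with the *training* means (the only leakage-free
#' choice). Because the matrix is centered, fitted linear models need no
#' intercept: the offset is identically zero.
#'
#' @param X numeric matrix, samples in rows, variables in columns. Must be
#'   complete (no missing or non-finite values).
#' @param y numeric vector of class labels, one per row of `X`, each -1 or +1
#'   (+1 is the positive / diseased class).
#' @param variable_ids character vector of unique variable identifiers;
#'   defaults to `colnames(X)` or `V1..Vd`.
#' @param sample_ids character vector of sample identifiers; defaults to
#'   `rownames(X)` or `S1..Sn`.
#'
#' @return An object of class `labeled_dataset`: a list with elements `X`
#'   (the centered matrix), `y`, `variable_ids`, `sample_ids` and
#'   `column_means` (the training centering vector).
#' @examples
#' X <- matrix(rnorm(20), nrow = 5)
#' d <- labeled_dataset(X, c(1, 1, -1, -1, 1))
#' colMeans(d$X)  # ~0
#' @export
labeled_dataset <- function(X, y, variable_ids = NULL, sample_ids = NULL) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("X must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)[1, ]
    stop(sprintf("X contains missing or non-finite values (first at row %d, column %d)",
                 bad[1], bad[2]), call. = FALSE)
  }
  y <- as.numeric(y)
  if (length(y) != nrow(X)) {
    stop("length(y) must equal nrow(X)", call. = FALSE)
  }
  if (any(abs(y) != 1)) {
    stop("labels must be coded -1/+1; found: ",
         paste(unique(y[abs(y) != 1]), collapse = ", "), call. = FALSE)
  }
  if (is.null(variable_ids)) {
    variable_ids <- colnames(X)
    if (is.null(variable_ids)) variable_ids <- paste0("V", seq_len(ncol(X)))
  }
  if (length(variable_ids) != ncol(X)) {
    stop("variable_ids length must equal ncol(X)", call. = FALSE)
  }
  if (anyDuplicated(variable_ids)) {
    stop("duplicate variable ids: ",
         paste(unique(variable_ids[duplicated(variable_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(X)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(X)))
  }
  if (length(sample_ids) != nrow(X)) {
    stop("sample_ids length must equal nrow(X)", call. = FALSE)
  }
  column_means <- colMeans(X)
  Xc <- sweep(X, 2, column_means, "-")
  dimnames(Xc) <- list(sample_ids, variable_ids)
  names(column_means) <- variable_ids
  structure(
    list(X = Xc, y = y, variable_ids = variable_ids,
         sample_ids = sample_ids, column_means = column_means),
    class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d samples x %d variables (%d positive, %d negative)\n",
              nrow(x$X), ncol(x$X), sum(x$y == 1), sum(x$y == -1)))
  invisible(x)
}

# Uncentered measurement matrix (adds back the stored column means).
dataset_raw <- function(data) {
  stopifnot(inherits(data, "labeled_dataset"))
  sweep(data$X, 2, data$column_means, "+")
}

# Row subset as a fresh labeled_dataset, re-centered on the subset's own
# means. Used by the cross-validation loops so every training part gets its
# own centering vector.
dataset_subset <- function(data, idx) {
  raw <- dataset_raw(data)
  labeled_dataset(raw[idx, , drop = FALSE], data$y[idx],
                  variable_ids = data$variable_ids,
                  sample_ids = data$sample_ids[idx])
}
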