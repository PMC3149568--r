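#' Extract a frequency-thresholded signature from a cross-validation result
#'
#' Promotes as relevant the variables that are most *stable* across the
#' outer-fold selected lists: every variable whose frequency is at or above
#' `threshold` percent (the comparison is inclusive). Entries are ordered by
#' descending frequency, ties by variable id, so output is stable.
#'
#' @param cv a `cv_result` from [nested_cv()], or any named percentage
#'   vector of frequencies.
#' @param threshold frequency cut in percent, in (0, 100]; default 40.
#' @param source optional identifier of the dataset the signature came from.
#' @return An object of class `signature`: a data.frame with columns
#'   `variable_id` and `frequency`, plus attributes `mu_level`, `threshold`
#'   and `source`. An empty signature is allowed (and reported).
#' @examples
#' extract_signature(c(A = 100, B = 40, C = 30), threshold = 40)
#' @export
extract_signature <- function(cv, threshold = 40, source = NA_character_) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 100) {
    stop("threshold must be a percentage in (0, 100]", call. = FALSE)
  }
  if (inherits(cv, "cv_result")) {
    freq <- cv$frequency
    mu_level <- cv$mu
  } else {
    freq <- cv
    mu_level <- NA_real_
  }
  if (is.null(names(freq))) stop("frequencies must be named", call. = FALSE)
  keep <- freq >= threshold
  entries <- data.frame(variable_id = names(freq)[keep],
                        frequency = unname(freq[keep]),
                        stringsAsFactors = FALSE)
  entries <- entries[order(-entries$frequency, entries$variable_id), ,
                     drop = FALSE]
  rownames(entries) <- NULL
  structure(entries, class = c("signature", "data.frame"),
            mu_level = mu_level, threshold = threshold, source = source)
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf("signature: %d variables at frequency >= %s%% (mu = %s)\n",
              nrow(x), format(attr(x, "threshold")),
              format(attr(x, "mu_level"))))
  if (nrow(x) == 0) {
    cat("  [empty signature]\n")
  } else {
    print.data.frame(x, ...)
  }
  invisible(x)
}

#' Cross-validation along a path of the correlation parameter
#'
#' Runs [nested_cv()] once per value of `mu` (same master seed, hence the
#' same fold plans) and extracts a signature at each level. The *reported*
#' signature is the one at the largest value, mu = 1, which admits the full
#' set of correlated discriminative variables; the size of the *minimal-mu*
#' list is retained as the cluster count for [kmeans_correlation()], since
#' the minimal list approximates one representative per correlated group.
#'
#' @inheritParams nested_cv
#' @param mu_values ascending nonnegative values ending at 1
#'   (default `c(0.01, 0.1, 0.5, 1)`).
#' @param threshold frequency cut passed to [extract_signature()].
#' @return An object of class `mu_path`: list of per-level results
#'   (`mu`, `cv`, `signature`), plus `signature` (the mu = 1 entry) and
#'   `k_min` (size of the minimal-mu signature).
#' @export
mu_path <- function(data, mu_values = c(0.01, 0.1, 0.5, 1), K_outer = 10,
                    K_inner = 10, seed = 1, threshold = 40, grid = NULL,
                    tol = 1e-6, max_iter = 1e5) {
  if (length(mu_values) == 0 || any(mu_values < 0)) {
    stop("mu_values must be nonnegative", call. = FALSE)
  }
  if (is.unsorted(mu_values, strictly = TRUE)) {
    stop("mu_values must be sorted in strictly ascending order",
         call. = FALSE)
  }
  if (mu_values[length(mu_values)] != 1) {
    stop("mu_values must end at 1 (the reported signature level)",
         call. = FALSE)
  }
  levels <- lapply(mu_values, function(mu) {
    cv <- nested_cv(data, mu = mu, K_outer = K_outer, K_inner = K_inner,
                    seed = seed, grid = grid, tol = tol, max_iter = max_iter)
    list(mu = mu, cv = cv,
         signature = extract_signature(cv, threshold = threshold))
  })
  structure(
    list(levels = levels,
         mu_values = mu_values,
         signature = levels[[length(levels)]]$signature,
         k_min = nrow(levels[[1]]$signature)),
    class = "mu_path")
}

#' @export
print.mu_path <- function(x, ...) {
  sizes <- vapply(x$levels, function(l) nrow(l$signature), integer(1))
  errs <- vapply(x$levels, function(l) l$cv$mean_error, numeric(1))
  cat("mu_path:\n")
  for (i in seq_along(x$levels)) {
    cat(sprintf("  mu = %-5s  signature size = %-4d  CV error = %.4f\n",
                format(x$mu_values[i]), sizes[i], errs[i]))
  }
  invisible(x)
}

#' Fit the final classifier on a signature
#'
#' Regularized least squares on the full training set restricted to the
#' signature variables. The ridge weight defaults to the median of the
#' outer-fold `lambda*_k` values when a `cv_result` is supplied.
#'
#' @param data the training [labeled_dataset()].
#' @param sig a `signature` (nonempty; all variables present in `data`).
#' @param lambda ridge weight; alternatively pass `cv` to use the median of
#'   its per-fold chosen values.
#' @param cv optional `cv_result` from which to take
#'   `lambda = median(lambda*_k)`.
#' @return An `enet_model` over the signature variables.
#' @export
final_model <- function(data, sig, lambda = NULL, cv = NULL) {
  stopifnot(inherits(sig, "signature"))
  if (nrow(sig) == 0) {
    stop("empty signature: no variables to fit the final model on",
         call. = FALSE)
  }
  if (is.null(lambda)) {
    if (is.null(cv)) {
      stop("supply lambda or a cv_result to take the median lambda from",
           call. = FALSE)
    }
    lams <- vapply(cv$folds, `[[`, numeric(1), "lambda")
    lambda <- median(lams, na.rm = TRUE)
  }
  fit_rls(data, lambda, support = sig$variable_id)
}

#' Evaluate a fitted model on a held-out test set
#'
#' Extracts the sub-matrix of the model's (signature) variables from the
#' test set, centers it with the *training* column means stored in the
#' model, predicts by the sign rule, and decomposes the result into
#' TP/FN/FP/TN counts. Multi-class test sets must be binarized upstream
#' (positive class vs rest).
#'
#' @param model an `enet_model` (e.g. from [final_model()]).
#' @param test a [labeled_dataset()], or a raw matrix (then `truth` is
#'   required).
#' @param truth labels in -1/+1 when `test` is a raw matrix.
#' @return A `confusion_counts` object.
#' @export
evaluate_test <- function(model, test, truth = NULL) {
  if (inherits(test, "labeled_dataset")) {
    truth <- test$y
    test <- dataset_raw(test)
  }
  if (is.null(truth)) {
    stop("truth labels are required when test is a raw matrix",
         call. = FALSE)
  }
  confusion(predict(model, test), truth)
}
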