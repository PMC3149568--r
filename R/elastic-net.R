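#' Soft-thresholding operator
#'
#' Elementwise `sign(v) * pmax(|v| - gamma, 0)`, the proximal map of the l1
#' norm and the basic building block of the iterative soft-thresholding
#' solver.
#'
#' @param v numeric vector.
#' @param gamma nonnegative threshold.
#' @return Numeric vector of the same length as `v`.
#' @examples
#' soft_threshold(c(1.2, -0.3, 0.5), 0.5)
#' @export
soft_threshold <- function(v, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1 || is.na(gamma) || gamma < 0) {
    stop("gamma must be a single nonnegative number", call. = FALSE)
  }
  sign(v) * pmax(abs(v) - gamma, 0)
}

#' Naive elastic-net objective
#'
#' Evaluates `(1/n) ||y - X beta||^2 + tau ||beta||_1 + mu ||beta||_2^2`,
#' the functional minimized by [fit_elastic_net()]. The least-squares term
#' fits the labels; the l1 penalty enforces sparsity; the squared l2 penalty
#' (weight `mu`, the correlation parameter) lets correlated variables enter
#' the model together instead of arbitrarily picking one of them.
#'
#' @param beta coefficient vector.
#' @param X centered design matrix (samples x variables).
#' @param y label vector (-1/+1).
#' @param tau l1 penalty weight (> 0).
#' @param mu l2 penalty weight (>= 0).
#' @return The objective value (a single number).
#' @export
enet_objective <- function(beta, X, y, tau, mu) {
  r <- y - as.vector(X %*% beta)
  sum(r^2) / nrow(X) + tau * sum(abs(beta)) + mu * sum(beta^2)
}

#' Karush-Kuhn-Tucker residuals of an elastic-net solution
#'
#' For the functional of [enet_objective()], optimality at `beta` requires
#' the gradient of the smooth part, `g = (2/n) X'(X beta - y) + 2 mu beta`,
#' to satisfy `g_j = -tau * sign(beta_j)` on the support and `|g_j| <= tau`
#' off it. Returns the largest violation, used to verify solver output.
#'
#' @inheritParams enet_objective
#' @return Maximum KKT violation (0 at an exact optimum).
#' @export
kkt_residual <- function(beta, X, y, tau, mu) {
  n <- nrow(X)
  g <- (2 / n) * as.vector(crossprod(X, as.vector(X %*% beta) - y)) +
    2 * mu * beta
  on_support <- beta != 0
  viol_on <- if (any(on_support)) {
    max(abs(g[on_support] + tau * sign(beta[on_support])))
  } else 0
  viol_off <- if (any(!on_support)) {
    max(pmax(abs(g[!on_support]) - tau, 0))
  } else 0
  max(viol_on, viol_off)
}

#' Smallest l1 weight that zeroes the elastic-net solution
#'
#' `tau_max = max_j |(2/n) X_j' y|`: for any `tau` at or above this value
#' (and any `mu >= 0`) the all-zero vector is the elastic-net optimum, so
#' regularization paths are searched below it.
#'
#' @param data a [labeled_dataset()].
#' @return A single positive number.
#' @export
tau_max <- function(data) {
  stopifnot(inherits(data, "labeled_dataset"))
  max(abs((2 / nrow(data$X)) * as.vector(crossprod(data$X, data$y))))
}

new_enet_model <- function(beta, variable_ids, column_means, tau, mu, lambda,
                           converged = TRUE, iterations = NA_integer_) {
  names(beta) <- variable_ids
  structure(
    list(beta = beta,
         support = which(beta != 0),
         variable_ids = variable_ids,
         column_means = column_means,
         tau = tau, mu = mu, lambda = lambda,
         converged = converged, iterations = iterations),
    class = "enet_model")
}

#' @export
print.enet_model <- function(x, ...) {
  cat(sprintf(
    "enet_model: %d of %d variables in support (tau=%s, mu=%s, lambda=%s)%s\n",
    length(x$support), length(x$beta),
    format(x$tau), format(x$mu), format(x$lambda),
    if (isTRUE(x$converged)) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Fit the naive elastic net by iterative soft-thresholding
#'
#' Minimizes `(1/n) ||y - X beta||^2 + tau ||beta||_1 + mu ||beta||_2^2` by
#' the proximal-gradient (ISTA) iteration
#' `beta <- soft_threshold(beta - g/C, tau/C)` with
#' `g = (2/n) X'(X beta - y) + 2 mu beta` and step constant
#' `C = 2 (sigma_max(X'X)/n + mu)`, which guarantees monotone descent of the
#' objective without line search. This is the variable-*selection* stage of
#' the double optimization: its support is what matters, and a regularized
#' least squares refit ([fit_rls()]) produces the classifier.
#'
#' @param data a [labeled_dataset()] (centered on construction).
#' @param tau l1 penalty weight (> 0).
#' @param mu l2 penalty weight (>= 0); larger values admit more correlated
#'   variables into the selection.
#' @param tol convergence tolerance on the max-norm coefficient change.
#' @param max_iter iteration cap; if reached without meeting `tol` the
#'   returned model is flagged `converged = FALSE` (with a warning), never
#'   silently accepted.
#' @param beta0 optional warm-start coefficient vector.
#' @return An `enet_model`: coefficient vector `beta` (zeros off support),
#'   `support` indices, the penalty weights, and convergence information.
#' @examples
#' d <- labeled_dataset(matrix(rnorm(40), 10), rep(c(1, -1), 5))
#' fit <- fit_elastic_net(d, tau = 0.1, mu = 0.5)
#' @export
fit_elastic_net <- function(data, tau, mu = 0, tol = 1e-6, max_iter = 1e5,
                            beta0 = NULL) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0) {
    stop("tau must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(mu) || length(mu) != 1 || mu < 0) {
    stop("mu must be a single nonnegative number", call. = FALSE)
  }
  d <- ncol(data$X)
  if (is.null(beta0)) beta0 <- numeric(d)
  stopifnot(length(beta0) == d)
  res <- .enet_ista_cpp(data$X, data$y, tau, mu, beta0, tol,
                        as.integer(max_iter))
  if (!res$converged) {
    warning(sprintf("ISTA did not converge in %d iterations (tau=%g, mu=%g)",
                    as.integer(max_iter), tau, mu), call. = FALSE)
  }
  new_enet_model(as.vector(res$beta), data$variable_ids, data$column_means,
                 tau = tau, mu = mu, lambda = NA_real_,
                 converged = res$converged, iterations = res$iterations)
}

# Warm-started elastic-net path over a decreasing tau sequence at fixed mu.
# Returns a d x length(taus) coefficient matrix plus convergence flags.
enet_path <- function(data, taus, mu, tol = 1e-6, max_iter = 1e5) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (any(diff(taus) >= 0)) {
    stop("taus must be strictly decreasing", call. = FALSE)
  }
  res <- .enet_path_cpp(data$X, data$y, taus, mu, tol, as.integer(max_iter))
  list(betas = res$betas, taus = taus, mu = mu,
       converged = as.logical(res$converged),
       iterations = as.integer(res$iterations))
}

#' Regularized least squares on a selected support
#'
#' The second stage of the double optimization: given the support selected
#' by the elastic net, refit by ridge regression restricted to those
#' variables, `beta_S = (X_S' X_S + n lambda I)^-1 X_S' y`, the minimizer of
#' `(1/n) ||y - X_S beta||^2 + lambda ||beta||^2`. The refit removes the
#' downward bias of the l1 shrinkage and yields the classifier actually used
#' for prediction.
#'
#' @param data a [labeled_dataset()].
#' @param lambda ridge penalty weight (>= 0).
#' @param support variables to keep: integer column indices or variable ids.
#'   Defaults to all variables.
#' @return An `enet_model` whose `beta` has zeros outside `support`.
#' @examples
#' d <- labeled_dataset(matrix(c(2, 0), 2, 1), c(1, -1))
#' fit_rls(d, lambda = 1)$beta  # 1-D ridge closed form
#' @export
fit_rls <- function(data, lambda, support = NULL) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0) {
    stop("lambda must be a single nonnegative number", call. = FALSE)
  }
  d <- ncol(data$X)
  if (is.null(support)) support <- seq_len(d)
  if (is.character(support)) {
    idx <- match(support, data$variable_ids)
    if (anyNA(idx)) {
      stop("variables not in dataset: ",
           paste(support[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    support <- idx
  }
  support <- sort(unique(as.integer(support)))
  if (length(support) == 0) {
    stop("empty selection: cannot fit RLS on an empty support", call. = FALSE)
  }
  Xs <- data$X[, support, drop = FALSE]
  n <- nrow(Xs)
  G <- crossprod(Xs) + n * lambda * diag(length(support))
  bs <- solve(G, crossprod(Xs, data$y))
  beta <- numeric(d)
  beta[support] <- as.vector(bs)
  new_enet_model(beta, data$variable_ids, data$column_means,
                 tau = NA_real_, mu = NA_real_, lambda = lambda)
}

#' Predict class labels with a fitted linear model
#'
#' Centers the new samples with the *training* column means stored in the
#' model and classifies by the sign of the linear score `x . beta`. A score
#' of exactly zero is resolved to +1 (documented tie-break).
#'
#' @param object an `enet_model`.
#' @param newdata numeric matrix of raw (uncentered) measurements with named
#'   columns covering the model's variables, or a [labeled_dataset()].
#' @param type `"class"` for -1/+1 labels (default) or `"score"` for the
#'   linear scores.
#' @param ... unused.
#' @return Numeric vector of labels or scores, one per row of `newdata`.
#' @export
predict.enet_model <- function(object, newdata, type = c("class", "score"),
                               ...) {
  type <- match.arg(type)
  if (inherits(newdata, "labeled_dataset")) newdata <- dataset_raw(newdata)
  newdata <- as.matrix(newdata)
  vars <- object$variable_ids[object$support]
  if (length(vars) == 0) {
    # all-zero model: every score is 0, tie-break to +1
    score <- numeric(nrow(newdata))
  } else {
    if (is.null(colnames(newdata))) {
      if (ncol(newdata) != length(object$variable_ids)) {
        stop("unnamed newdata must have one column per model variable",
             call. = FALSE)
      }
      colnames(newdata) <- object$variable_ids
    }
    missing_vars <- setdiff(vars, colnames(newdata))
    if (length(missing_vars) > 0) {
      stop("newdata is missing model variables: ",
           paste(missing_vars, collapse = ", "), call. = FALSE)
    }
    Xs <- newdata[, vars, drop = FALSE]
    Xs <- sweep(Xs, 2, object$column_means[vars], "-")
    score <- as.vector(Xs %*% object$beta[object$support])
  }
  if (type == "score") return(score)
  ifelse(score >= 0, 1, -1)
}

#' Confusion counts for a two-class prediction
#'
#' Decomposes test predictions into true positives, false negatives, false
#' positives and true negatives, with +1 (diseased) as the positive class,
#' and reports the error rate `(FP + FN) / total`.
#'
#' @param pred predicted labels in -1/+1.
#' @param truth reference labels in -1/+1.
#' @return An object of class `confusion_counts`: list with `TP`, `FN`,
#'   `FP`, `TN`, `n` and `error`.
#' @examples
#' confusion(c(1, 1, -1, -1), c(1, -1, -1, -1))
#' @export
confusion <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("pred and truth must have equal length", call. = FALSE)
  }
  if (any(abs(pred) != 1) || any(abs(truth) != 1)) {
    stop("labels must be coded -1/+1", call. = FALSE)
  }
  out <- list(
    TP = sum(pred == 1 & truth == 1),
    FN = sum(pred == -1 & truth == 1),
    FP = sum(pred == 1 & truth == -1),
    TN = sum(pred == -1 & truth == -1),
    n = length(truth))
  out$error <- (out$FP + out$FN) / out$n
  structure(out, class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP=%d FN=%d FP=%d TN=%d  (n=%d, error=%.4f)\n",
              x$TP, x$FN, x$FP, x$TN, x$n, x$error))
  invisible(x)
}
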