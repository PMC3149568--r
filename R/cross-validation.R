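#' Stratified K-fold partition of a two-class sample
#'
#' Assigns samples to K folds so that each fold contains (up to rounding)
#' the same proportion of the two classes: within every class, per-fold
#' counts differ by at most one. This keeps the mean response approximately
#' equal across folds and balances Type I / Type II errors in the
#' cross-validated estimates.
#'
#' @param labels label vector in -1/+1.
#' @param K number of folds (>= 2); each class must have at least K members.
#' @param seed integer seed; the plan is deterministic given the seed.
#' @return An object of class `fold_plan`: list with `K`, `assignments`
#'   (fold index per sample) and `seed`.
#' @examples
#' plan <- stratified_kfold(rep(c(1, -1), each = 5), K = 5, seed = 1)
#' table(plan$assignments)
#' @export
stratified_kfold <- function(labels, K, seed) {
  if (any(abs(labels) != 1)) stop("labels must be coded -1/+1", call. = FALSE)
  K <- as.integer(K)
  if (K < 2) stop("K must be at least 2", call. = FALSE)
  counts <- table(factor(labels, levels = c(-1, 1)))
  small <- counts[counts < K]
  if (length(small) > 0) {
    stop(sprintf("class %s has %d sample(s), fewer than K = %d folds",
                 names(small)[1], small[1], K), call. = FALSE)
  }
  assignments <- integer(length(labels))
  with_seed(seed, {
    for (cls in c(-1, 1)) {
      idx <- which(labels == cls)
      # rep() balances counts across folds (difference <= 1 per class);
      # sample() randomizes both which sample lands where and which folds
      # receive the remainder.
      assignments[idx] <- sample(rep(seq_len(K), length.out = length(idx)))
    }
  })
  structure(list(K = K, assignments = assignments, seed = seed),
            class = "fold_plan")
}

#' Data-driven regularization grid
#'
#' Builds the search grid for the nested cross-validation: `n_tau`
#' log-spaced l1 weights descending from `tau_max(data)` (the smallest value
#' that zeroes the solution) down to `tau_max / tau_min_ratio`, and
#' log-spaced ridge weights for the second-stage refit.
#'
#' @param data a [labeled_dataset()]; the grid is computed on *this*
#'   training part, so every cross-validation split derives its own grid.
#' @param n_tau number of l1 weights (default 20).
#' @param tau_min_ratio ratio `tau_max / tau_min` (default 1000).
#' @param lambda_values ridge weights (default 7 log-spaced values in
#'   `[1e-4, 10]`).
#' @return An object of class `parameter_grid` with decreasing
#'   `tau_values` and `lambda_values`.
#' @export
parameter_grid <- function(data, n_tau = 20, tau_min_ratio = 1000,
                           lambda_values = 10^seq(-4, 1, length.out = 7)) {
  tmax <- tau_max(data)
  tau_values <- exp(seq(log(tmax), log(tmax / tau_min_ratio),
                        length.out = n_tau))
  new_parameter_grid(tau_values, lambda_values)
}

new_parameter_grid <- function(tau_values, lambda_values) {
  if (length(tau_values) == 0 || length(lambda_values) == 0) {
    stop("parameter grid must be nonempty", call. = FALSE)
  }
  if (any(tau_values <= 0) || any(diff(tau_values) >= 0)) {
    stop("tau_values must be positive and strictly decreasing", call. = FALSE)
  }
  if (any(lambda_values <= 0)) {
    stop("lambda_values must be positive", call. = FALSE)
  }
  structure(list(tau_values = tau_values,
                 lambda_values = sort(lambda_values)),
            class = "parameter_grid")
}

# Ridge coefficients over a whole lambda path from one thin SVD of the
# restricted design: beta(lambda) = V diag(s / (s^2 + n lambda)) U' y,
# identical to the fit_rls closed form for every lambda > 0. Used by the
# inner loop where the same support is scored at several lambdas.
rls_path_svd <- function(Xs, y, lambdas) {
  n <- nrow(Xs)
  sv <- svd(Xs, nu = min(dim(Xs)), nv = min(dim(Xs)))
  uty <- as.vector(crossprod(sv$u, y))
  vapply(lambdas, function(lam) {
    as.vector(sv$v %*% (uty * sv$d / (sv$d^2 + n * lam)))
  }, numeric(ncol(Xs)))
}

# Majority-class fallback label of a training set (ties to +1). Used when a
# (tau, lambda) cell selects no variables on some fold: that cell is scored
# with the majority-class error instead of being dropped, keeping the inner
# error surface defined without biasing the search toward dense models.
majority_label <- function(y) if (sum(y == 1) >= sum(y == -1)) 1 else -1

#' Inner cross-validation search for (tau*, lambda*)
#'
#' Scores every `(tau, lambda)` cell of the grid by the mean inner-fold
#' error of the full two-stage procedure (elastic-net selection at `tau`,
#' `mu`; RLS refit at `lambda`; prediction on the held-out inner fold) and
#' returns the minimizing pair. Ties are broken toward larger `tau`
#' (sparser model), then smaller `lambda`.
#'
#' @param train a [labeled_dataset()] (an outer-loop training part).
#' @param grid a [parameter_grid()].
#' @param mu l2 (correlation) penalty weight, fixed during the search.
#' @param K_inner number of inner folds.
#' @param seed integer seed for the inner fold plan.
#' @param tol,max_iter solver controls passed to the elastic-net stage.
#' @return List with `tau`, `lambda`, `error` (the winning mean inner error)
#'   and `error_grid` (tau x lambda matrix of mean errors).
#' @export
inner_select <- function(train, grid, mu, K_inner, seed,
                         tol = 1e-6, max_iter = 1e5) {
  stopifnot(inherits(train, "labeled_dataset"),
            inherits(grid, "parameter_grid"))
  taus <- grid$tau_values
  lambdas <- grid$lambda_values
  plan <- stratified_kfold(train$y, K_inner, seed)
  err <- array(0, dim = c(length(taus), length(lambdas), K_inner))
  for (k in seq_len(K_inner)) {
    hold <- plan$assignments == k
    tr <- dataset_subset(train, which(!hold))
    te_raw <- dataset_raw(train)[hold, , drop = FALSE]
    te_y <- train$y[hold]
    path <- enet_path(tr, taus, mu, tol = tol, max_iter = max_iter)
    fallback_err <- mean(majority_label(tr$y) != te_y)
    te_ctr <- sweep(te_raw, 2, tr$column_means, "-")
    seen <- new.env(parent = emptyenv())  # cache errors by support
    for (i in seq_along(taus)) {
      support <- which(path$betas[, i] != 0)
      if (length(support) == 0) {
        err[i, , k] <- fallback_err
        next
      }
      key <- paste(support, collapse = ",")
      if (is.null(seen[[key]])) {
        betas <- rls_path_svd(tr$X[, support, drop = FALSE], tr$y, lambdas)
        scores <- te_ctr[, support, drop = FALSE] %*% betas
        pred <- ifelse(scores >= 0, 1, -1)
        seen[[key]] <- colMeans(pred != te_y)
      }
      err[i, , k] <- seen[[key]]
    }
  }
  mean_err <- apply(err, c(1, 2), mean)
  dimnames(mean_err) <- list(tau = format(taus), lambda = format(lambdas))
  # taus are stored descending and lambdas ascending, so the first minimum
  # in row-major order is the sparsest (largest tau), least-ridged winner
  best <- which(mean_err == min(mean_err), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  list(tau = taus[best[1]], lambda = lambdas[best[2]],
       error = min(mean_err), error_grid = mean_err)
}

#' Nested stratified cross-validation of the double optimization
#'
#' The outer loop estimates prediction error and produces one selected
#' variable list per fold; the inner loop (on each outer training part)
#' chooses `(tau*, lambda*)` by [inner_select()]. For each outer fold the
#' elastic net is refit at `(tau*_k, mu)` on the whole outer training part,
#' the RLS classifier is fit at `lambda*_k` on the selected support, and the
#' held-out fold is scored. The per-variable *frequency* — the percentage of
#' outer folds whose selected list contains the variable — is the stability
#' score from which signatures are extracted.
#'
#' @param data a [labeled_dataset()].
#' @param mu l2 (correlation) penalty weight; reported signatures use the
#'   largest value of the path (mu = 1).
#' @param K_outer,K_inner fold counts for the two loops (default 10 and 10).
#' @param seed integer master seed; outer and inner fold plans are derived
#'   from it deterministically.
#' @param grid optional [parameter_grid()]; by default each outer training
#'   part derives its own grid via [parameter_grid()].
#' @param tol,max_iter solver controls.
#' @return An object of class `cv_result`: per-fold results (`selected`
#'   variable ids, `tau`, `lambda`, `confusion`, `error`), `mean_error`,
#'   `frequency` (named percentage vector over all variables), plus the
#'   settings used.
#' @examples
#' \donttest{
#' sim <- generate_dataset(synthetic_spec(n_samples = 40, n_variables = 30,
#'   n_informative = 4, effect_size = 2, seed = 7))
#' cv <- nested_cv(sim$data, mu = 1, K_outer = 4, K_inner = 3, seed = 7)
#' cv$mean_error
#' }
#' @export
nested_cv <- function(data, mu = 1, K_outer = 10, K_inner = 10, seed = 1,
                      grid = NULL, tol = 1e-6, max_iter = 1e5) {
  stopifnot(inherits(data, "labeled_dataset"))
  outer_plan <- stratified_kfold(data$y, K_outer, sub_seed(seed, 1))
  folds <- vector("list", K_outer)
  for (k in seq_len(K_outer)) {
    hold <- outer_plan$assignments == k
    train <- dataset_subset(data, which(!hold))
    te_raw <- dataset_raw(data)[hold, , drop = FALSE]
    te_y <- data$y[hold]
    grid_k <- if (is.null(grid)) parameter_grid(train) else grid
    sel <- inner_select(train, grid_k, mu, K_inner,
                        seed = sub_seed(seed, 100 + k),
                        tol = tol, max_iter = max_iter)
    fit <- fit_elastic_net(train, sel$tau, mu, tol = tol,
                           max_iter = max_iter)
    if (length(fit$support) == 0) {
      pred <- rep(majority_label(train$y), sum(hold))
      selected <- character(0)
      lambda_k <- NA_real_
    } else {
      model <- fit_rls(train, sel$lambda, fit$support)
      pred <- predict(model, te_raw)
      selected <- data$variable_ids[fit$support]
      lambda_k <- sel$lambda
    }
    folds[[k]] <- list(selected = selected, tau = sel$tau,
                       lambda = lambda_k, inner_error = sel$error,
                       confusion = confusion(pred, te_y))
    folds[[k]]$error <- folds[[k]]$confusion$error
  }
  counts <- table(factor(unlist(lapply(folds, `[[`, "selected")),
                         levels = data$variable_ids))
  frequency <- 100 * as.vector(counts) / K_outer
  names(frequency) <- data$variable_ids
  structure(
    list(folds = folds,
         mean_error = mean(vapply(folds, `[[`, numeric(1), "error")),
         frequency = frequency,
         K_outer = K_outer, K_inner = K_inner, mu = mu, seed = seed),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  sizes <- vapply(x$folds, function(f) length(f$selected), integer(1))
  cat(sprintf("cv_result: %d-fold outer / %d-fold inner CV at mu = %s\n",
              x$K_outer, x$K_inner, format(x$mu)))
  cat(sprintf("  mean CV error: %.4f\n", x$mean_error))
  cat(sprintf("  selected list sizes per fold: %s\n",
              paste(sizes, collapse = " ")))
  cat(sprintf("  variables at frequency >= 40%%: %d\n",
              sum(x$frequency >= 40)))
  invisible(x)
}
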