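#' Specification of a synthetic two-class omics dataset
#'
#' Describes a dataset with equicorrelated variable blocks and a small set
#' of class-discriminative variables, emulating the statistical structure of
#' two-class expression / abundance studies: tens-to-hundreds of samples,
#' hundreds-to-thousands of variables, correlated groups of variables, and a
#' sparse multivariate signal.
#'
#' Blocks tile a prefix of the variable index space (`n_blocks` blocks of
#' `block_size` variables each); the remaining variables are independent
#' noise. The informative variables are the first `n_informative`, so with
#' the defaults they sit inside the correlated blocks.
#'
#' @param n_samples number of samples.
#' @param n_variables number of variables.
#' @param block_size,n_blocks size and count of the equicorrelated blocks;
#'   `block_size * n_blocks <= n_variables`.
#' @param within_block_corr target pairwise correlation `rho` within a
#'   block, in `[0, 1)`.
#' @param n_informative number of class-discriminative variables
#'   (`<= n_variables`).
#' @param effect_size class mean shift `delta`, in units of the within-class
#'   standard deviation.
#' @param noise_sd within-class standard deviation `sigma` (> 0).
#' @param class_balance fraction of samples in the positive class, in (0, 1).
#' @param seed integer seed; generation is fully deterministic given it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 100, n_variables = 500,
                           block_size = 5, n_blocks = 10,
                           within_block_corr = 0.5, n_informative = 10,
                           effect_size = 1.5, noise_sd = 1,
                           class_balance = 0.5, seed = 1) {
  check_count <- function(x, name, min = 1) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
        x != round(x)) {
      stop(sprintf("invalid %s: must be an integer >= %d", name, min),
           call. = FALSE)
    }
  }
  check_count(n_samples, "n_samples", 2)
  check_count(n_variables, "n_variables")
  check_count(block_size, "block_size")
  check_count(n_blocks, "n_blocks", 0)
  check_count(n_informative, "n_informative", 0)
  check_count(seed, "seed", -2147483646)
  if (!is.numeric(within_block_corr) || within_block_corr < 0 ||
      within_block_corr >= 1) {
    stop("invalid within_block_corr: must be in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(effect_size) || length(effect_size) != 1 ||
      is.na(effect_size)) {
    stop("invalid effect_size: must be a number", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    stop("invalid noise_sd: must be positive", call. = FALSE)
  }
  if (!is.numeric(class_balance) || class_balance <= 0 ||
      class_balance >= 1) {
    stop("invalid class_balance: must be in (0, 1)", call. = FALSE)
  }
  if (n_informative > n_variables) {
    stop("invalid n_informative: exceeds n_variables", call. = FALSE)
  }
  if (block_size * n_blocks > n_variables) {
    stop("invalid n_blocks: blocks exceed n_variables", call. = FALSE)
  }
  structure(
    list(n_samples = as.integer(n_samples),
         n_variables = as.integer(n_variables),
         block_size = as.integer(block_size),
         n_blocks = as.integer(n_blocks),
         within_block_corr = within_block_corr,
         n_informative = as.integer(n_informative),
         effect_size = effect_size, noise_sd = noise_sd,
         class_balance = class_balance, seed = as.integer(seed)),
    class = "synthetic_spec")
}

#' Generate a synthetic two-class dataset with known ground truth
#'
#' Labels are assigned first (`round(n_samples * class_balance)` positives,
#' order shuffled), then expression is built as an equicorrelated-block
#' Gaussian: variables in block `b` are
#' `sigma * (sqrt(rho) * z_b + sqrt(1 - rho) * eps)` with a shared
#' per-sample latent factor `z_b`, giving every within-block pair population
#' correlation exactly `rho`; off-block variables are independent
#' `N(0, sigma^2)` noise. Each informative variable then receives a class
#' mean shift of `+/- delta * sigma / 2`, so its class-conditional mean
#' difference is `delta * sigma`.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `data` (a [labeled_dataset()]) and `truth` (class
#'   `ground_truth`: `informative_ids`, `true_weights`, `block_membership`).
#' @examples
#' sim <- generate_dataset(synthetic_spec(n_samples = 20, n_variables = 12,
#'   n_informative = 2, seed = 42))
#' sim$truth$informative_ids
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_samples
  d <- spec$n_variables
  rho <- spec$within_block_corr
  variable_ids <- sprintf("G%04d", seq_len(d))
  sample_ids <- sprintf("S%03d", seq_len(n))
  with_seed(spec$seed, {
    n_pos <- round(n * spec$class_balance)
    y <- sample(c(rep(1, n_pos), rep(-1, n - n_pos)))
    X <- matrix(rnorm(n * d), n, d)
    block_membership <- integer(d)
    if (spec$n_blocks > 0) {
      for (b in seq_len(spec$n_blocks)) {
        cols <- ((b - 1) * spec$block_size + 1):(b * spec$block_size)
        block_membership[cols] <- b
        z <- rnorm(n)
        X[, cols] <- sqrt(rho) * z + sqrt(1 - rho) * X[, cols]
      }
    }
    X <- spec$noise_sd * X
    true_weights <- numeric(d)
    if (spec$n_informative > 0) {
      inf <- seq_len(spec$n_informative)
      shift <- spec$effect_size * spec$noise_sd / 2
      true_weights[inf] <- shift
      X[, inf] <- X[, inf] + outer(y, rep(shift, spec$n_informative))
    }
  })
  names(true_weights) <- variable_ids
  names(block_membership) <- variable_ids
  dimnames(X) <- list(sample_ids, variable_ids)
  truth <- structure(
    list(informative_ids = variable_ids[true_weights != 0],
         true_weights = true_weights,
         block_membership = block_membership),
    class = "ground_truth")
  list(data = labeled_dataset(X, y), truth = truth)
}

#' Generate a gene-set collection with one planted causal set
#'
#' Builds `n_sets` sets over the generated variables: one "causal" set
#' containing every informative variable plus random non-informative
#' padding, and `n_sets - 1` sets drawn uniformly from the non-informative
#' variables. Enrichment of a recovered signature against this collection
#' should flag the causal set.
#'
#' @param truth a `ground_truth` from [generate_dataset()].
#' @param n_sets number of sets (>= 1; the first is the causal one).
#' @param set_size members per set; must be at least the number of
#'   informative variables (they all go into the causal set).
#' @param seed integer seed.
#' @return A [gene_set_collection()] whose universe is all generated
#'   variables; the causal set is named `"causal_set"`.
#' @export
generate_genesets <- function(truth, n_sets = 20, set_size = 10, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  universe <- names(truth$true_weights)
  informative <- truth$informative_ids
  if (n_sets < 1) stop("n_sets must be at least 1", call. = FALSE)
  if (set_size > length(universe)) {
    stop("set_size exceeds the number of variables", call. = FALSE)
  }
  if (set_size < length(informative)) {
    stop(sprintf(
      "set_size (%d) is smaller than the number of informative variables (%d): the causal set cannot hold them all",
      set_size, length(informative)), call. = FALSE)
  }
  noninf <- setdiff(universe, informative)
  sets <- with_seed(seed, {
    causal <- c(informative,
                sample(noninf, set_size - length(informative)))
    others <- lapply(seq_len(n_sets - 1), function(i) {
      sort(sample(noninf, min(set_size, length(noninf))))
    })
    c(list(sort(causal)), others)
  })
  names(sets) <- c("causal_set",
                   if (n_sets > 1) sprintf("random_set_%02d",
                                           seq_len(n_sets - 1)))
  gene_set_collection(sets,
                      categories = c("causal",
                                     rep("random", n_sets - 1)),
                      universe = universe)
}
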