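# Independent oracles used across the suite.

# Convex oracle for the naive elastic net: minimize
#   (1/n)||y - X b||^2 + tau ||b||_1 + mu ||b||_2^2
# over the positive/negative split b = w+ - w- (the l1 term becomes linear,
# the objective smooth), solved with box-constrained L-BFGS-B. Entirely
# independent of the proximal-gradient implementation under test.
enet_oracle <- function(X, y, tau, mu) {
  n <- nrow(X)
  d <- ncol(X)
  obj <- function(w) {
    b <- w[1:d] - w[(d + 1):(2 * d)]
    sum((y - X %*% b)^2) / n + tau * sum(w) + mu * sum(b^2)
  }
  gr <- function(w) {
    b <- w[1:d] - w[(d + 1):(2 * d)]
    g <- as.vector(-2 / n * crossprod(X, y - X %*% b)) + 2 * mu * b
    c(g + tau, -g + tau)
  }
  fit <- stats::optim(rep(0, 2 * d), obj, gr, method = "L-BFGS-B",
                      lower = 0, control = list(maxit = 5000, factr = 1e3))
  list(beta = fit$par[1:d] - fit$par[(d + 1):(2 * d)], value = fit$value)
}

# Exact combinatorial enumeration of the upper-tail hypergeometric
# probability, via binomial coefficients only.
hyper_enum <- function(N, K, n, k) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Small random two-class dataset.
toy_dataset <- function(n = 12, d = 5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  y <- rep(c(1, -1), length.out = n)
  labeled_dataset(X, y)
}

# Design with exactly orthonormal centered columns scaled so X'X = n I.
orthonormal_dataset <- function(n = 24, d = 6, seed = 1) {
  set.seed(seed)
  M <- matrix(rnorm(n * d), n, d)
  M <- sweep(M, 2, colMeans(M), "-")
  Q <- qr.Q(qr(M)) * sqrt(n)
  y <- rep(c(1, -1), length.out = n)
  labeled_dataset(Q, y)
}

extdata <- function(f) system.file("extdata", f, package = "sparsesig")

# Two planted groups of correlated profiles (rows), within-group latent
# correlation rho, between-group ~0.
make_grouped_profiles <- function(n_per = 5, n_samples = 30, rho = 0.95,
                                  seed = 1) {
  set.seed(seed)
  z1 <- rnorm(n_samples)
  z2 <- rnorm(n_samples)
  g1 <- t(replicate(n_per, sqrt(rho) * z1 + sqrt(1 - rho) * rnorm(n_samples)))
  g2 <- t(replicate(n_per, sqrt(rho) * z2 + sqrt(1 - rho) * rnorm(n_samples)))
  profiles <- rbind(g1, g2)
  rownames(profiles) <- sprintf("P%02d", seq_len(2 * n_per))
  profiles
}
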