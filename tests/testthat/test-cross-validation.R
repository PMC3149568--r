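test_that("stratified folds balance both classes to within one sample", {
  labels <- rep(c(1, -1), each = 5)
  plan <- stratified_kfold(labels, K = 5, seed = 1)
  for (k in 1:5) {
    expect_equal(sum(plan$assignments == k & labels == 1), 1)
    expect_equal(sum(plan$assignments == k & labels == -1), 1)
  }
  # training-set composition of a typical cohort: 43 positive, 40 negative
  labels <- c(rep(1, 43), rep(-1, 40))
  plan <- stratified_kfold(labels, K = 10, seed = 7)
  sizes <- table(plan$assignments)
  expect_true(all(sizes >= 8 & sizes <= 9))
  pos <- vapply(1:10, function(k) sum(plan$assignments == k & labels == 1),
                numeric(1))
  expect_true(all(pos %in% 4:5))
  expect_error(stratified_kfold(c(1, -1, -1, -1), K = 2, seed = 1),
               "class 1 has 1 sample")
})

test_that("fold plans are deterministic and stratification always holds", {
  labels <- rep(c(1, -1), each = 5)
  expect_identical(stratified_kfold(labels, 5, seed = 3)$assignments,
                   stratified_kfold(labels, 5, seed = 3)$assignments)
  # property: over random label vectors, per-class fold counts differ <= 1
  for (s in 1:25) {
    set.seed(s)
    n <- sample(20:80, 1)
    K <- sample(2:8, 1)
    labels <- sample(c(-1, 1), n, replace = TRUE)
    if (min(table(labels)) < K) next
    plan <- stratified_kfold(labels, K, seed = s)
    for (cls in c(-1, 1)) {
      cnt <- vapply(seq_len(K), function(k) {
        sum(plan$assignments == k & labels == cls)
      }, numeric(1))
      expect_lte(max(cnt) - min(cnt), 1)
    }
    expect_equal(sort(unique(plan$assignments)), seq_len(K))
  }
})

test_that("parameter grids are data-driven and validated", {
  dat <- toy_dataset(n = 20, d = 10, seed = 5)
  grid <- parameter_grid(dat)
  expect_length(grid$tau_values, 20)
  expect_equal(grid$tau_values[1], tau_max(dat))
  expect_equal(grid$tau_values[20], tau_max(dat) / 1000, tolerance = 1e-10)
  expect_true(all(diff(grid$tau_values) < 0))
  expect_length(grid$lambda_values, 7)
  expect_error(sparsesig:::new_parameter_grid(c(1, 2), 1), "decreasing")
  expect_error(sparsesig:::new_parameter_grid(numeric(0), 1), "nonempty")
})

test_that("inner_select returns the degenerate cell and breaks ties sparse-first", {
  sim <- generate_dataset(synthetic_spec(n_samples = 40, n_variables = 20,
                                         block_size = 2, n_blocks = 3,
                                         n_informative = 3, effect_size = 3,
                                         seed = 9))
  one <- sparsesig:::new_parameter_grid(0.5, 0.1)
  sel <- inner_select(sim$data, one, mu = 1, K_inner = 3, seed = 1)
  expect_equal(sel$tau, 0.5)
  expect_equal(sel$lambda, 0.1)
  # duplicated lambda column: identical errors, smaller lambda must win;
  # huge taus select nothing everywhere -> identical fallback errors, and
  # the larger tau must win
  tmax <- tau_max(sim$data)
  grid <- sparsesig:::new_parameter_grid(c(tmax * 3, tmax * 2),
                                         c(0.2, 0.4))
  sel <- inner_select(sim$data, grid, mu = 1, K_inner = 3, seed = 1)
  expect_equal(sel$tau, tmax * 3)
  expect_equal(sel$lambda, 0.2)
  # fallback scores equal the majority-class error, never NA
  expect_true(all(is.finite(sel$error_grid)))
})

test_that("strong signal beats null data in the inner search", {
  errs <- vapply(1:5, function(s) {
    sim <- generate_dataset(synthetic_spec(n_samples = 60, n_variables = 40,
                                           block_size = 2, n_blocks = 5,
                                           n_informative = 4,
                                           effect_size = 2.5, seed = s))
    null <- generate_dataset(synthetic_spec(n_samples = 60, n_variables = 40,
                                            block_size = 2, n_blocks = 5,
                                            n_informative = 0, seed = s))
    g1 <- parameter_grid(sim$data)
    g0 <- parameter_grid(null$data)
    c(inner_select(sim$data, g1, 1, 5, seed = s)$error,
      inner_select(null$data, g0, 1, 5, seed = s)$error)
  }, numeric(2))
  expect_lt(mean(errs[1, ]), mean(errs[2, ]))
  expect_lt(mean(errs[1, ]), 0.15)
})

test_that("nested_cv produces frequencies on the 100/K lattice and a fold log", {
  sim <- generate_dataset(synthetic_spec(n_samples = 40, n_variables = 30,
                                         block_size = 2, n_blocks = 4,
                                         n_informative = 3, effect_size = 2,
                                         seed = 15))
  cv <- nested_cv(sim$data, mu = 1, K_outer = 5, K_inner = 3, seed = 15)
  expect_length(cv$folds, 5)
  expect_true(all(cv$frequency %in% seq(0, 100, by = 20)))
  expect_equal(cv$mean_error,
               mean(vapply(cv$folds, `[[`, numeric(1), "error")))
  counted <- table(factor(unlist(lapply(cv$folds, `[[`, "selected")),
                          levels = sim$data$variable_ids))
  expect_equal(unname(cv$frequency), 100 * as.vector(counted) / 5)
  # per-fold confusion adds up to the fold size
  for (f in cv$folds) {
    cc <- f$confusion
    expect_equal(cc$TP + cc$FN + cc$FP + cc$TN, cc$n)
  }
  # reproducible under the same seed
  cv2 <- nested_cv(sim$data, mu = 1, K_outer = 5, K_inner = 3, seed = 15)
  expect_identical(cv$frequency, cv2$frequency)
  expect_identical(cv$mean_error, cv2$mean_error)
})

test_that("frequencies are invariant to sample-order permutation", {
  sim <- generate_dataset(synthetic_spec(n_samples = 30, n_variables = 20,
                                         block_size = 2, n_blocks = 3,
                                         n_informative = 2, effect_size = 2.5,
                                         seed = 23))
  cv <- nested_cv(sim$data, mu = 1, K_outer = 3, K_inner = 3, seed = 23)
  set.seed(1)
  perm <- sample(30)
  raw <- sparsesig:::dataset_raw(sim$data)[perm, ]
  permuted <- labeled_dataset(raw, sim$data$y[perm])
  # re-seeded identical fold plan: carry the permutation into the folds by
  # reusing the same fold memberships
  plan <- stratified_kfold(sim$data$y, 3, sparsesig:::sub_seed(23, 1))
  # variables selected on identical training *sets* must coincide, so check
  # via one outer fold refit on the same membership
  hold <- plan$assignments == 1
  tr1 <- sparsesig:::dataset_subset(sim$data, which(!hold))
  tr2 <- sparsesig:::dataset_subset(permuted, which(!hold[perm]))
  f1 <- fit_elastic_net(tr1, tau_max(tr1) / 10, 1, tol = 1e-10)
  f2 <- fit_elastic_net(tr2, tau_max(tr2) / 10, 1, tol = 1e-10)
  expect_equal(sort(names(f1$beta[f1$support])),
               sort(names(f2$beta[f2$support])))
})
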