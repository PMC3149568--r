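test_that("signature extraction is inclusive at the threshold and ordered", {
  sig <- extract_signature(c(A = 100, B = 40, C = 30), threshold = 40)
  expect_equal(sig$variable_id, c("A", "B"))
  expect_equal(sig$frequency, c(100, 40))
  # tie order is by variable id
  sig <- extract_signature(c(Z = 60, A = 60, M = 100), threshold = 40)
  expect_equal(sig$variable_id, c("M", "A", "Z"))
  only_always <- extract_signature(c(A = 100, B = 90), threshold = 100)
  expect_equal(only_always$variable_id, "A")
  empty <- extract_signature(c(A = 10), threshold = 40)
  expect_equal(nrow(empty), 0)
  expect_error(extract_signature(c(A = 1), threshold = 0), "percentage")
})

test_that("lowering the threshold never removes a variable", {
  set.seed(2)
  freq <- round(runif(50, 0, 10)) * 10
  names(freq) <- sprintf("V%02d", 1:50)
  prev <- character(0)
  for (thr in c(100, 80, 60, 40, 20, 10)) {
    cur <- extract_signature(freq, thr)$variable_id
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("the 40% cut retains every row of the published signature tables", {
  protein <- read_signature(extdata("protein_signature.tsv"))
  expect_equal(nrow(protein), 21)
  gse1297 <- read_signature(extdata("gse1297_signature.tsv"))
  expect_equal(nrow(gse1297), 12)
  expect_equal(length(unique(attr(gse1297, "annotation")$gene_symbol)), 11)
  gse5281 <- read_signature(extdata("gse5281_signature.tsv"))
  expect_equal(nrow(gse5281), 39)
  # the tables contain rows at exactly 40%, forcing the inclusive cut
  expect_true(any(protein$frequency == 40))
  expect_true(any(gse5281$frequency == 40))
})

test_that("mu_path validates its grid and reduces to nested_cv at mu = 1", {
  sim <- generate_dataset(synthetic_spec(n_samples = 30, n_variables = 20,
                                         block_size = 2, n_blocks = 3,
                                         n_informative = 2, effect_size = 2.5,
                                         seed = 33))
  expect_error(mu_path(sim$data, mu_values = c(1, 0.5)), "ascending")
  expect_error(mu_path(sim$data, mu_values = c(0.1, 0.5)), "end at 1")
  mp <- mu_path(sim$data, mu_values = 1, K_outer = 3, K_inner = 3,
                seed = 33)
  cv <- nested_cv(sim$data, mu = 1, K_outer = 3, K_inner = 3, seed = 33)
  expect_equal(mp$signature$variable_id,
               extract_signature(cv, 40)$variable_id)
  expect_equal(mp$k_min, nrow(mp$levels[[1]]$signature))
})

test_that("the l2 term pulls duplicated features in together at high mu", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 40
    X <- matrix(rnorm(n * 12), n, 12)
    y <- sample(rep(c(1, -1), each = n / 2))
    X[, 1] <- X[, 1] + y * 1.5
    X[, 2] <- X[, 1] + rnorm(n, sd = 0.05)  # near-duplicate of the signal
    dat <- labeled_dataset(X, y)
    cv_hi <- nested_cv(dat, mu = 1, K_outer = 5, K_inner = 3, seed = s)
    cv_lo <- nested_cv(dat, mu = 0.01, K_outer = 5, K_inner = 3, seed = s)
    hi <- extract_signature(cv_hi, 40)$variable_id
    lo <- extract_signature(cv_lo, 40)$variable_id
    pair_lo <- intersect(lo, c("V1", "V2"))
    c(both = all(c("V1", "V2") %in% hi), contain = all(pair_lo %in% hi))
  }, logical(2))
  # the high-mu list catches the whole duplicated pair in most replicates,
  # and always contains whatever part of the pair the minimal-mu list kept
  expect_gte(mean(hits[1, ]), 0.7)
  expect_gte(mean(hits[2, ]), 0.9)
})

test_that("final_model matches the RLS closed form and needs a signature", {
  sim <- generate_dataset(synthetic_spec(n_samples = 30, n_variables = 10,
                                         block_size = 2, n_blocks = 2,
                                         n_informative = 2, effect_size = 2,
                                         seed = 41))
  sig1 <- extract_signature(c(G0001 = 100), threshold = 40)
  m1 <- final_model(sim$data, sig1, lambda = 0.5)
  direct <- fit_rls(sim$data, 0.5, "G0001")
  expect_equal(m1$beta, direct$beta)
  # signature covering all variables equals plain RLS
  freq <- rep(100, 10)
  names(freq) <- sim$data$variable_ids
  sig_all <- extract_signature(freq, 40)
  expect_equal(final_model(sim$data, sig_all, lambda = 0.2)$beta,
               fit_rls(sim$data, 0.2)$beta)
  empty <- extract_signature(c(G0001 = 10), 40)
  expect_error(final_model(sim$data, empty, lambda = 1), "empty signature")
  # lambda defaults to the median of per-fold chosen values
  cv <- nested_cv(sim$data, mu = 1, K_outer = 3, K_inner = 3, seed = 41)
  m <- final_model(sim$data, extract_signature(cv, 40), cv = cv)
  lams <- vapply(cv$folds, `[[`, numeric(1), "lambda")
  expect_equal(m$lambda, median(lams, na.rm = TRUE))
})

test_that("test evaluation centers with training means and counts errors", {
  sim <- generate_dataset(synthetic_spec(n_samples = 40, n_variables = 8,
                                         block_size = 2, n_blocks = 2,
                                         n_informative = 2, effect_size = 6,
                                         seed = 43))
  freq <- rep(100, 8)
  names(freq) <- sim$data$variable_ids
  model <- final_model(sim$data, extract_signature(freq, 40), lambda = 1e-4)
  # training set as test set on (near) separable data: error 0
  cc <- evaluate_test(model, sim$data)
  expect_equal(cc$error, 0)
  # all-positive truth, all-positive prediction: only TP filled
  raw <- sparsesig:::dataset_raw(sim$data)
  pos_rows <- raw[sim$data$y == 1, , drop = FALSE]
  cc_pos <- evaluate_test(model, pos_rows, truth = rep(1, nrow(pos_rows)))
  expect_equal(cc_pos$TP, nrow(pos_rows))
  expect_equal(cc_pos$FN + cc_pos$FP + cc_pos$TN, 0)
  # permuting the test sample order leaves the counts unchanged
  set.seed(1)
  perm <- sample(nrow(raw))
  cc_perm <- evaluate_test(model, raw[perm, ], truth = sim$data$y[perm])
  expect_identical(unclass(cc)[c("TP", "FN", "FP", "TN")],
                   unclass(cc_perm)[c("TP", "FN", "FP", "TN")])
})

test_that("a test set with planted misclassifications scores exactly 7/92", {
  # mirror of the published train/test protocol: fit on a training cohort,
  # then flip the labels of 7 of 92 held-out samples whose margin is safe,
  # so the decomposed test error is 7/92 by construction
  spec <- synthetic_spec(n_samples = 83, n_variables = 120, block_size = 4,
                         n_blocks = 10, n_informative = 8, effect_size = 3,
                         class_balance = 43 / 83, seed = 47)
  sim <- generate_dataset(spec)
  cv <- nested_cv(sim$data, mu = 1, K_outer = 5, K_inner = 3, seed = 47)
  sig <- extract_signature(cv, 40)
  model <- final_model(sim$data, sig, cv = cv)
  test_spec <- synthetic_spec(n_samples = 92, n_variables = 120,
                              block_size = 4, n_blocks = 10,
                              n_informative = 8, effect_size = 3,
                              class_balance = 42 / 92, seed = 48)
  test_sim <- generate_dataset(test_spec)
  raw <- sparsesig:::dataset_raw(test_sim$data)
  pred <- predict(model, raw)
  truth <- pred
  flip <- seq_len(7)
  truth[flip] <- -truth[flip]
  cc <- evaluate_test(model, raw, truth = truth)
  expect_equal(cc$error, 7 / 92)
  expect_equal(cc$FP + cc$FN, 7)
  expect_equal(cc$n, 92)
})
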