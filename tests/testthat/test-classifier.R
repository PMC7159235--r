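test_that("stratified folds preserve the class ratio within one sample", {
  set.seed(1)
  y <- c(rep("tolerant", 50), rep("low", 49))
  fold <- stratified_folds(y, 10)
  for (f in 1:10) {
    expect_equal(sum(y[fold == f] == "tolerant"), 5)
    expect_true(sum(y[fold == f] == "low") %in% 4:5)
  }
  # agreement with an independent stratified-fold implementation on the
  # class-balance property
  skip_if_not_installed("caret")
  cf <- caret::createFolds(factor(y), k = 10)
  sizes_caret <- sort(unname(lengths(cf)))
  sizes_ours <- sort(tabulate(fold, 10))
  expect_equal(sizes_ours, sizes_caret)
})

test_that("separated classes are learned nearly perfectly", {
  fx <- separable_matrix()
  tr <- balanced_repeat_train(fx$matrix, fx$labels, repeats = 5,
                              pos_per_repeat = 50, folds = 10, seed = 42)
  expect_gte(tr$model$winning_repeat$mean_auroc, 0.92)
  expect_gte(tr$auroc_mean, 0.9)
  # held-out positives dominate: score the positives not used in training
  sc <- predict_scores(tr$model, fx$matrix)
  held_pos <- sc$p_lof_tol[sc$enhancer_id %in% fx$pos_ids]
  expect_gt(median(held_pos), 0.5)
})

test_that("permuted labels collapse performance to chance", {
  fx <- separable_matrix()
  set.seed(9)
  ids <- c(fx$pos_ids, fx$neg_ids)
  perm <- sample(ids)
  plab <- label_set(perm[seq_along(fx$pos_ids)],
                    perm[-seq_along(fx$pos_ids)])
  tr <- balanced_repeat_train(fx$matrix, plab, repeats = 5,
                              pos_per_repeat = 50, folds = 10, seed = 42)
  expect_gte(tr$auroc_mean, 0.35)
  expect_lte(tr$auroc_mean, 0.65)
})

test_that("a single repeat over the full positive pool has no sampling variance", {
  fx <- separable_matrix(n_pos = 60, n_noise = 20)
  tr <- balanced_repeat_train(fx$matrix, fx$labels, repeats = 1,
                              pos_per_repeat = 60, folds = 5, seed = 1)
  expect_equal(nrow(tr$runs), 1)
  expect_setequal(tr$runs$pos_ids[[1]], fx$pos_ids)
  expect_equal(tr$auroc_sd, NA_real_)
})

test_that("every positive appears in at least one repeat when possible", {
  fx <- separable_matrix(n_pos = 120, n_noise = 20)
  tr <- balanced_repeat_train(fx$matrix, fx$labels, repeats = 4,
                              pos_per_repeat = 50, folds = 5, seed = 5,
                              search_budget = list(n_random = 2,
                                                   refine = FALSE))
  used <- unique(unlist(tr$runs$pos_ids))
  expect_setequal(used, fx$pos_ids)   # 4 x 50 >= 120
})

test_that("training errors on inadequate inputs", {
  fx <- separable_matrix(n_pos = 30, n_noise = 10)
  expect_error(balanced_repeat_train(fx$matrix, fx$labels, repeats = 2,
                                     pos_per_repeat = 50),
               "fewer positives")
  m_na <- fx$matrix
  m_na$inform_1[1] <- NA
  expect_error(balanced_repeat_train(m_na, fx$labels, repeats = 1,
                                     pos_per_repeat = 30),
               "missing values")
})

test_that("the protocol is reproducible from the master seed", {
  fx <- separable_matrix(n_pos = 60, n_noise = 30)
  a <- balanced_repeat_train(fx$matrix, fx$labels, repeats = 3,
                             pos_per_repeat = 50, folds = 5, seed = 7)
  b <- balanced_repeat_train(fx$matrix, fx$labels, repeats = 3,
                             pos_per_repeat = 50, folds = 5, seed = 7)
  expect_identical(a$runs$pos_ids, b$runs$pos_ids)
  expect_identical(a$runs$mean_auroc, b$runs$mean_auroc)
  expect_identical(a$model$winning_repeat$repeat_index,
                   b$model$winning_repeat$repeat_index)
  expect_identical(predict_scores(a$model, fx$matrix)$p_lof_tol,
                   predict_scores(b$model, fx$matrix)$p_lof_tol)
})

test_that("scores carry threshold-consistent calls and exclude training ids", {
  fx <- separable_matrix()
  tr <- balanced_repeat_train(fx$matrix, fx$labels, repeats = 2,
                              pos_per_repeat = 50, folds = 5, seed = 3)
  sc <- predict_scores(tr$model, fx$matrix)
  expect_length(intersect(sc$enhancer_id, tr$model$training_ids), 0)
  expect_true(all(sc$p_lof_tol >= 0 & sc$p_lof_tol <= 1))
  expect_equal(sc$binary_call, ifelse(sc$p_lof_tol >= 0.5, "tolerant", "low"))
  expect_equal(sc$confident_call,
               ifelse(sc$p_lof_tol > 0.95, "tolerant",
                      ifelse(sc$p_lof_tol < 0.05, "low", "none")))
  # schema mismatch is a hard error naming the missing columns
  expect_error(predict_scores(tr$model, fx$matrix[, 1:4]), "missing model")
})

test_that("importances normalize, group-sum, and surface informative columns", {
  fx <- separable_matrix()
  tr <- balanced_repeat_train(fx$matrix, fx$labels, repeats = 2,
                              pos_per_repeat = 50, folds = 5, seed = 3)
  rep_ <- feature_importance_report(tr$model)
  expect_equal(sum(rep_$features$importance), 1, tolerance = 1e-9)
  for (g in rep_$groups$group) {
    expect_equal(rep_$groups$importance[rep_$groups$group == g],
                 sum(rep_$features$importance[rep_$features$group == g]),
                 tolerance = 1e-12)
  }
  top10 <- rep_$features$feature[1:10]
  expect_true(all(sprintf("inform_%d", 1:5) %in% top10))
})

test_that("feature groups map by schema", {
  expect_equal(enhtol:::feature_group(
    c("conservation", "EGTUa", "ETU", "Liver__EOD", "GISa", "Liver__GIDa")),
    c("conservation", "edge", "enhancer", "enhancer", "gene", "gene"))
})

test_that("null model on pure noise sits at chance", {
  set.seed(4)
  n <- 220
  ids <- sprintf("e%03d", 1:n)
  m <- tibble::as_tibble(matrix(rnorm(n * 30), n,
                                dimnames = list(NULL,
                                                sprintf("f%02d", 1:30))))
  m <- tibble::add_column(m, enhancer = ids, .before = 1)
  lab <- label_set(ids[1:60], ids[61:110])
  nm <- null_model_check(m, lab, repeats = 6, pos_per_repeat = 50,
                         n_pseudo = 50, folds = 5, seed = 2)
  expect_length(nm$mean_aurocs, 6)
  expect_gt(nm$mean, 0.35)
  expect_lt(nm$mean, 0.68)
  expect_error(null_model_check(m, label_set(ids[1:60], ids[61:219]),
                                n_pseudo = 50),
               "unlabeled pool")
})

test_that("dropping conservation degrades but does not break training", {
  u <- small_universe()
  tr <- balanced_repeat_train(small_features(), small_labels(), repeats = 3,
                              pos_per_repeat = 50, folds = 5, seed = 8,
                              with_conservation = FALSE)
  expect_false("conservation" %in% tr$model$schema)
  expect_gt(tr$auroc_mean, 0.5)
})
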