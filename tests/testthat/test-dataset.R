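test_that("pair enumeration matches the closed form and ordering", {
  expect_equal(nrow(enumerate_pairs(548)), 149878L)
  expect_equal(nrow(enumerate_pairs(707)), 249571L)
  expect_equal(nrow(enumerate_pairs(807)), 325221L)
  expect_equal(enumerate_pairs(4),
               cbind(i = c(1L, 1L, 1L, 2L, 2L, 3L),
                     j = c(2L, 3L, 4L, 3L, 4L, 4L)))
  for (n in c(2, 3, 17, 100, 1000)) {
    p <- enumerate_pairs(n)
    expect_equal(nrow(p), n * (n - 1) / 2)
    expect_true(all(p[, 1] < p[, 2]))
    expect_false(anyDuplicated(p) > 0)
  }
  expect_error(enumerate_pairs(1), ">= 2")
})

test_that("dataset assembly aligns modalities, labels and pair extraction", {
  n <- 10
  mods <- list(a = random_similarity(n, 1), b = random_similarity(n, 2),
               c = random_similarity(n, 3))
  L <- random_labels(n, 0.3, seed = 5)
  ds <- ddi_dataset(mods, L, use_gip = TRUE)
  expect_length(ds$modalities, 3)     # GIP appended at fit time, not here
  expect_true(ds$use_gip)
  # label vector equals direct matrix indexing for every pair
  for (k in sample(nrow(ds$pairs), 20))
    expect_equal(ds$y[k], L[ds$pairs[k, 1], ds$pairs[k, 2]])
  # per-pair input vectors equal the similarity-matrix rows
  rows <- pair_inputs(ds$modalities, c(3, 7))
  expect_equal(rows[[2]][1, ], mods$b[3, ])
  expect_equal(rows[[2]][2, ], mods$b[7, ])
})

test_that("dataset assembly rejects misaligned or malformed inputs", {
  n <- 6
  mods <- list(a = random_similarity(n, 1))
  L <- random_labels(n, 0.4, seed = 2)
  bad <- random_similarity(n, 2)
  rownames(bad) <- colnames(bad) <- paste0("x", 1:n)
  expect_error(ddi_dataset(c(mods, list(b = bad)), L), "do not match")
  La <- L; La[1, 2] <- 1; La[2, 1] <- 0
  expect_warning(ds <- ddi_dataset(mods, La), "asymmetric")
  expect_equal(ds$labels[1, 2], 1) # symmetrised by OR
  expect_error(ddi_dataset(mods, L + 0.5), "0/1")
})

test_that("fold plans partition pairs with stratified class balance", {
  # exact divisibility: 100 pairs, 20 positive, 10 folds => 2 per fold
  y <- rep(c(1, 0), c(20, 80))
  plan <- make_folds(y, n_folds = 10, seed = 4)
  expect_equal(sort(unique(plan$fold)), 1:10)
  expect_equal(unname(table(plan$fold)), rep(10L, 10), ignore_attr = TRUE)
  for (f in 1:10) expect_equal(sum(y[plan$fold == f]), 2)
  # determinism
  plan2 <- make_folds(y, n_folds = 10, seed = 4)
  expect_identical(plan$fold, plan2$fold)
  expect_identical(plan$val, plan2$val)
  # low prevalence: per-fold positive proportion within 1pp of global
  y2 <- withr::with_seed(9, sample(rep(c(1, 0), c(30, 1970))))
  plan3 <- make_folds(y2, n_folds = 10, seed = 7)
  for (f in 1:10) {
    prop <- mean(y2[plan3$fold == f])
    expect_lt(abs(prop - 0.015), 0.01)
    # validation set drawn from the training portion only, stratified
    expect_true(all(plan3$fold[plan3$val[[f]]] != f))
    expect_true(any(y2[plan3$val[[f]]] == 1))
  }
  expect_error(make_folds(rep(c(1, 0), c(5, 95)), n_folds = 10),
               "stratification")
})

test_that("class weights are inverse-frequency with unit mean", {
  expect_equal(unname(class_weights(rep(c(0, 1), 50))), c(1, 1))
  w <- class_weights(rep(c(0, 1), c(90, 10)))
  expect_equal(unname(w[["1"]] / w[["0"]]), 9)
  expect_equal(mean(w[rep(c(0, 1), c(90, 10)) + 1]), 1) # mean weight 1
  # DS3-CYP-like imbalance: ratio equals (K - npos)/npos
  yk <- rep(c(1L, 0L), c(5039L, 325221L - 5039L))
  wk <- class_weights(yk)
  expect_equal(unname(wk[["1"]] / wk[["0"]]), (325221 - 5039) / 5039,
               tolerance = 1e-12) # = 63.54
  expect_error(class_weights(rep(1, 10)), "both classes")
})
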