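test_that("training learns a separable planted-signal toy", {
  ds <- toy_dataset(n_drugs = 30, prevalence = 0.15, seed = 3)
  folds <- make_folds(ds, n_folds = 3, seed = 2)
  fit <- train_fold(ds, folds, 1, toy_config(n_epochs = 30))
  expect_s3_class(fit, "ddinet")
  expect_gte(fit$best_val_aupr, 0.5) # far above 15% prevalence
  # loss decreases over the first epochs (averaged, non-strict)
  expect_lt(mean(fit$log$loss_total[11:15]), mean(fit$log$loss_total[1:5]))
  # the best-epoch checkpoint reproduces its recorded validation AUPR
  vp <- predict_probs(fit$params, fit$config, fit$inputs,
                      enumerate_pairs(30)[fit$val_idx, ], symmetrize = FALSE)
  expect_equal(aupr(vp, ds$y[fit$val_idx]), fit$best_val_aupr,
               tolerance = 1e-9)
})

test_that("training is deterministic given the seed", {
  ds <- toy_dataset(n_drugs = 24, seed = 4)
  f1 <- ddinet(ds, toy_config(n_epochs = 4, dropout = 0.3))
  f2 <- ddinet(ds, toy_config(n_epochs = 4, dropout = 0.3))
  expect_identical(f1$final_params, f2$final_params)
  expect_identical(f1$log, f2$log)
  expect_equal(f1$n_params,
               sum(vapply(f1$final_params, length, integer(1))))
})

test_that("single-epoch runs select epoch one", {
  ds <- toy_dataset(n_drugs = 20, seed = 6)
  fit <- ddinet(ds, toy_config(n_epochs = 1))
  expect_equal(fit$best_epoch, 1L)
})

test_that("model variants build the stated architectures", {
  ds <- toy_dataset(n_drugs = 20, n_modalities = 2, seed = 7)
  fits <- lapply(c("full", "attention_only", "feedforward_only"),
                 function(v) ddinet(ds, toy_config(n_epochs = 2, variant = v)))
  names(fits) <- c("full", "attention_only", "feedforward_only")
  # feed-forward-only variant has no attention parameters at all
  expect_false(any(grepl("Wq|Wk|Wv|Wu|ctx", names(fits$feedforward_only$params))))
  # full and attention-only variants carry per-head attention projections
  expect_true(all(c("u1_h1_Wq", "u1_h1_Wk", "u1_h1_Wv", "ctx")
                  %in% names(fits$full$params)))
  expect_true("u1_h1_Wq" %in% names(fits$attention_only$params))
  # the Siamese classifier concatenates [z_a; z_b; dist]; the non-Siamese
  # head maps a single pooled z
  expect_equal(ncol(fits$full$params$W_out), 2L * 16L + 1L)
  expect_equal(ncol(fits$attention_only$params$W_out), 16L)
  # non-Siamese encoder consumes the pair's 2T vectors as one input set:
  # its predictions are order-invariant by pooling
  pm <- enumerate_pairs(20)[c(3, 50), ]
  ao <- fits$attention_only
  expect_equal(predict(ao, pairs = pm, symmetrize = FALSE),
               predict(ao, pairs = pm[, 2:1], symmetrize = FALSE),
               tolerance = 1e-10)
})

test_that("contrastive-heavy training widens the inter-class distance gap", {
  # cosine distance (the reference setting) is bounded, so the gap is
  # comparable across runs regardless of representation scale
  ds <- toy_dataset(n_drugs = 30, prevalence = 0.15, seed = 9)
  dist_gap <- function(gamma) {
    fit <- ddinet(ds, toy_config(n_epochs = 20, gamma = gamma))
    Z <- ddi_encode(fit, capture_trace = FALSE)$z
    za <- Z[ds$pairs[, 1], ]; zb <- Z[ds$pairs[, 2], ]
    d <- 1 - rowSums(za * zb) /
      pmax(sqrt(rowSums(za^2) * rowSums(zb^2)), 1e-12)
    mean(d[ds$y == 0]) - mean(d[ds$y == 1])
  }
  expect_gt(dist_gap(0.05), dist_gap(0.95))
})

test_that("random search logs trials and survives degenerate configurations", {
  ds <- toy_dataset(n_drugs = 24, seed = 12)
  base <- toy_config(n_epochs = 3)
  one <- random_search(ds, list(n_heads = c(1, 2)), n_trials = 1,
                       config = base, n_folds = 3, seed = 4)
  expect_s3_class(one$best_config, "ddinet_config")
  expect_equal(nrow(one$trials), 1L)
  expect_equal(one$best_config$n_heads, one$trials$n_heads[1])
  # same seed reproduces the identical trial sequence
  again <- random_search(ds, list(n_heads = c(1, 2)), n_trials = 1,
                         config = base, n_folds = 3, seed = 4)
  expect_identical(one$trials, again$trials)
  # a known-good and a divergent learning rate: the good one is selected
  res <- random_search(ds, list(learning_rate = c(2e-3, 10)), n_trials = 4,
                       config = base, n_folds = 3, seed = 6)
  expect_equal(res$best_config$learning_rate, 2e-3)
  expect_error(random_search(ds, list(), 2), "non-empty")
  expect_error(random_search(ds, list(bogus = 1), 2), "unknown")
})
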