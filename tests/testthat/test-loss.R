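test_that("pair distances match their closed forms", {
  z <- c(0.3, -0.2, 0.5)
  expect_equal(pair_distance(z, z, "euclidean"), 0)
  expect_equal(pair_distance(z, z, "cosine"), 0)
  expect_equal(pair_distance(c(1, 0), c(0, 1), "euclidean"), sqrt(2))
  expect_equal(pair_distance(c(1, 0), c(0, 1), "cosine"), 1)
  expect_equal(pair_distance(c(0, 0), c(1, 2), "cosine"), 0) # zero-norm rule
  za <- withr::with_seed(1, rnorm(5)); zb <- withr::with_seed(2, rnorm(5))
  expect_equal(pair_distance(za, zb, "euclidean"), sqrt(sum((za - zb)^2)))
  expect_equal(pair_distance(za, zb, "cosine"),
               1 - sum(za * zb) / sqrt(sum(za^2) * sum(zb^2)))
  expect_error(pair_distance(1:3, 1:4), "length")
})

test_that("the classifier head produces the stated softmax probabilities", {
  dp <- 2
  W0 <- matrix(0, 2, 2 * dp + 1)
  expect_equal(classify_pair(c(1, 2), c(3, 4), W0, c(0, 0)), c(0.5, 0.5))
  W <- matrix(c(0.2, -0.1, 0.05, 0.3, -0.2, 0.1, 0.4, -0.3, 0.15, 0.25),
              2, 5)
  b <- c(0.1, -0.1)
  za <- c(0.5, -1); zb <- c(0.2, 0.8)
  got <- classify_pair(za, zb, W, b, distance = "euclidean")
  feat <- c(za, zb, sqrt(sum((za - zb)^2)))
  logits <- drop(W %*% feat) + b
  expect_equal(got, exp(logits) / sum(exp(logits)))
  for (seed in 1:3) {
    zr <- withr::with_seed(seed, list(rnorm(2), rnorm(2)))
    expect_equal(sum(classify_pair(zr[[1]], zr[[2]], W, b)), 1)
  }
})

test_that("weighted NLL matches hand-summed cross-entropy", {
  expect_equal(nll_loss(1, 1), 0, tolerance = 1e-10)
  expect_equal(nll_loss(0.5, 1), log(2))
  # batch of three mixed cases, class weights (0.6, 3)
  yh <- c(0.9, 0.2, 0.7); y <- c(1, 0, 0); w <- c(0.6, 3)
  by_hand <- mean(c(-3 * log(0.9), -0.6 * log(0.8), -0.6 * log(0.3)))
  expect_equal(nll_loss(yh, y, w), by_hand)
  expect_true(is.finite(nll_loss(c(0, 1), c(1, 0), w))) # clamped logs
})

test_that("contrastive loss implements the hinged margin form", {
  expect_equal(contrastive_loss(0, 1), 0)
  expect_equal(contrastive_loss(c(1, 1.7), c(0, 0), margin = 1), 0)
  expect_equal(contrastive_loss(0, 0, margin = 1), 0.5) # mu^2 / 2
  expect_equal(contrastive_loss(c(0.5, 0.2), c(1, 0), margin = 1),
               mean(c(0.125, 0.32)))
  # literal printed form penalises beyond-margin distances too
  expect_equal(contrastive_loss(2, 0, margin = 1, literal = TRUE), 0.5)
  expect_equal(contrastive_loss(2, 0, margin = 1, literal = FALSE), 0)
  expect_error(contrastive_loss(-0.1, 1), "nonnegative")
  # monotone: nonincreasing in dist for y = 0, nondecreasing for y = 1
  d <- seq(0, 2, by = 0.05)
  l0 <- sapply(d, contrastive_loss, y = 0, margin = 1)
  l1 <- sapply(d, contrastive_loss, y = 1, margin = 1)
  expect_true(all(diff(l0) <= 1e-12))
  expect_true(all(diff(l1) >= -1e-12))
})

test_that("the total objective is the stated linear combination", {
  expect_equal(total_loss(1, 2, gamma = 0.05), 0.05 + 0.95 * 2)
  expect_equal(total_loss(1.3, 2, gamma = 0.999), 1.3, tolerance = 1e-2)
  par <- list(a = matrix(1:4, 2), b = c(1, -1))
  expect_equal(total_loss(0, 0, 0.5, par, weight_decay = 0.1),
               0.05 * (sum((1:4)^2) + 2))
  expect_error(total_loss(1, 1, gamma = 1), "gamma")
  expect_gte(total_loss(0.3, 0.7, 0.4, par, 0.01), 0)
})

test_that("symmetrized predictions are exactly pair-order invariant", {
  ds <- toy_dataset(n_drugs = 20, seed = 5)
  fit <- ddinet(ds, toy_config(n_epochs = 3))
  pm <- enumerate_pairs(20)[c(5, 40, 111), ]
  p_ab <- predict(fit, pairs = pm)
  p_ba <- predict(fit, pairs = pm[, 2:1])
  expect_identical(p_ab, p_ba)
  # without symmetrization the concat order generally matters
  q_ab <- predict(fit, pairs = pm, symmetrize = FALSE)
  q_ba <- predict(fit, pairs = pm[, 2:1], symmetrize = FALSE)
  expect_equal(p_ab, (q_ab + q_ba) / 2)
})
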