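test_that("jaccard similarity matches hand-enumerated counts and conventions", {
  expect_equal(jaccard_similarity(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  expect_equal(jaccard_similarity(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(jaccard_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(jaccard_similarity(c(0, 0), c(0, 0)), 0) # all-zero convention
  expect_error(jaccard_similarity(c(1, 0), c(1, 0, 1)), "length")
  expect_error(jaccard_similarity(c(1, 2), c(1, 0)), "0/1")
})

test_that("jaccard matrix equals the naive double-loop oracle", {
  for (seed in 1:3) {
    dims <- list(c(5, 8), c(12, 6), c(20, 20))[[seed]]
    feats <- withr::with_seed(seed, matrix(rbinom(prod(dims), 1, 0.4),
                                           dims[1], dims[2]))
    S <- build_jaccard_matrix(feats)
    oracle <- diag(dims[1])
    for (i in 1:(dims[1] - 1)) for (j in (i + 1):dims[1])
      oracle[i, j] <- oracle[j, i] <- jaccard_similarity(feats[i, ], feats[j, ])
    expect_equal(unname(S), oracle, ignore_attr = TRUE)
    expect_true(all(S >= 0 & S <= 1))
    expect_equal(S, t(S), ignore_attr = TRUE)
  }
})

test_that("jaccard matrix handles identical, disjoint and all-zero rows", {
  expect_equal(unname(build_jaccard_matrix(matrix(c(1, 1, 0, 0), 2, 2))),
               matrix(1, 2, 2), ignore_attr = TRUE)
  disjoint <- diag(3) # three drugs with pairwise-disjoint features
  expect_equal(unname(build_jaccard_matrix(disjoint)), diag(3),
               ignore_attr = TRUE)
  withzero <- rbind(c(1, 1, 0), c(0, 0, 0), c(0, 0, 0))
  S <- build_jaccard_matrix(withzero)
  expect_equal(diag(S), rep(1, 3), ignore_attr = TRUE) # unit diagonal kept
  expect_equal(S[2, 3], 0)                             # zero off-diagonal
  expect_error(build_jaccard_matrix(matrix(1, 1, 3)), "at least 2")
})

test_that("GIP matches the per-pair Gaussian kernel formula", {
  L <- random_labels(4, prevalence = 0.5, seed = 8)
  S <- build_gip_matrix(L, bandwidth_scale = 1.5)
  gamma_g <- 1.5 / mean(rowSums(L^2))
  for (i in 1:4) for (j in 1:4) {
    expected <- if (i == j) 1 else exp(-gamma_g * sum((L[i, ] - L[j, ])^2))
    expect_equal(S[i, j], expected, tolerance = 1e-12)
  }
})

test_that("GIP degenerate and structural properties hold", {
  # identical interaction profiles => similarity 1
  L <- matrix(0, 3, 3); L[1, 3] <- L[3, 1] <- 1; L[2, 3] <- L[3, 2] <- 1
  expect_equal(build_gip_matrix(L)[1, 2], 1)
  # no positive labels => identity matrix
  expect_equal(unname(build_gip_matrix(matrix(0, 4, 4))), diag(4),
               ignore_attr = TRUE)
  # symmetric, positive, unit diagonal; monotone in Hamming distance
  L <- random_labels(12, prevalence = 0.4, seed = 2)
  S <- build_gip_matrix(L)
  expect_equal(S, t(S), ignore_attr = TRUE)
  expect_true(all(S > 0))
  expect_equal(diag(S), rep(1, 12), ignore_attr = TRUE)
  h <- as.matrix(stats::dist(L, method = "manhattan"))
  off <- upper.tri(S)
  ord <- order(h[off])
  expect_true(all(diff(S[off][ord]) <= 1e-12))
  expect_error(build_gip_matrix(matrix(2, 3, 3)), "0/1")
})

test_that("similarity TSV round trip preserves ids and values", {
  S <- random_similarity(3, seed = 4)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_similarity_tsv(S, f)
  S2 <- read_similarity_tsv(f)
  expect_identical(rownames(S2), rownames(S))
  expect_equal(unname(S2), unname(S), tolerance = 1e-12)
})

test_that("malformed similarity files are rejected", {
  S <- random_similarity(3, seed = 4)
  f <- withr::local_tempfile(fileext = ".tsv")
  Sa <- S; Sa[1, 2] <- Sa[1, 2] + 0.5 # asymmetric
  write_similarity_tsv(Sa, f)
  expect_error(read_similarity_tsv(f), "symmetric")
  Sb <- S; Sb[1, 2] <- Sb[2, 1] <- 1.2 # out of range
  write_similarity_tsv(Sb, f)
  expect_error(read_similarity_tsv(f), "outside")
  Sc <- S; Sc[2, 3] <- Sc[3, 2] <- NaN
  write_similarity_tsv(Sc, f)
  expect_error(read_similarity_tsv(f), "NaN|missing")
})
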