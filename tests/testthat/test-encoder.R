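test_that("single-head self-attention matches a scalar brute-force oracle", {
  withr::local_seed(21)
  Tn <- 3; d <- 3; dp <- 2
  u <- matrix(runif(Tn * d), Tn, d)
  Wq <- matrix(rnorm(dp * d), dp, d)
  Wk <- matrix(rnorm(dp * d), dp, d)
  Wv <- matrix(rnorm(dp * d), dp, d)
  got <- self_attention_head(u, Wq, Wk, Wv)
  for (t in 1:Tn) {
    q <- Wq %*% u[t, ]
    sc <- sapply(1:Tn, function(l) sum(q * (Wk %*% u[l, ]))) / sqrt(dp)
    al <- exp(sc) / sum(exp(sc))
    r <- rep(0, dp)
    for (l in 1:Tn) r <- r + al[l] * (Wv %*% u[l, ])
    expect_equal(got$attn[t, ], al, tolerance = 1e-12)
    expect_equal(got$r[t, ], drop(r), tolerance = 1e-12)
  }
  expect_equal(rowSums(got$attn), rep(1, Tn), tolerance = 1e-9)
})

test_that("self-attention degenerate cases: singleton and uniform scores", {
  W <- diag(2)
  one <- self_attention_head(matrix(c(1, 2), 1, 2), W, W, 2 * W)
  expect_equal(one$attn, matrix(1, 1, 1))
  expect_equal(one$r[1, ], c(2, 4)) # r_1 = W_value u_1
  # zero keys make all scores equal => uniform attention
  unif <- self_attention_head(matrix(runif(8), 4, 2), W, 0 * W, W)
  expect_equal(unname(unif$attn), matrix(0.25, 4, 4), ignore_attr = TRUE)
  expect_error(self_attention_head(matrix(1, 2, 3), W, W, W), "dimension")
})

test_that("multi-head unification is the stated affine map", {
  r1 <- matrix(1:6, 3, 2)
  expect_equal(multi_head_unify(list(r1), diag(2), c(0, 0)), r1)
  expect_equal(multi_head_unify(list(r1), 0 * diag(2), c(3, 4)),
               matrix(c(3, 3, 3, 4, 4, 4), 3, 2))
  W <- matrix(c(1, 0, 0, 1, 1, 1, 0, -1), 2, 4) # 2 x 4, H = 2
  r2 <- matrix(c(1, 1, 1, 2, 2, 2), 3, 2)
  got <- multi_head_unify(list(r1, r2), W, c(0.5, -0.5))
  for (t in 1:3) # hand-computed affine map per position
    expect_equal(got[t, ], drop(W %*% c(r1[t, ], r2[t, ])) + c(0.5, -0.5))
})

test_that("layer normalisation standardises then scales and shifts", {
  expect_equal(layer_norm(c(5, 5, 5)), c(0, 0, 0))             # zero variance
  expect_equal(layer_norm(c(1, -1), eps = 1e-12), c(1, -1),
               tolerance = 1e-6)                                # standardized
  v <- c(2, 4, 6)
  expect_equal(layer_norm(v, gamma = rep(2, 3), beta = rep(1, 3), eps = 1e-8),
               2 * (v - 4) / sqrt(8 / 3 + 1e-8) + 1)
  M <- matrix(rnorm(12), 3, 4)
  out <- layer_norm(M, gamma = rep(1.5, 4), beta = rep(2, 4))
  expect_equal(rowMeans((out - 2) / 1.5), rep(0, 3), tolerance = 1e-9)
})

test_that("feed-forward transform follows affine-ReLU-affine", {
  dp <- 2; xi <- 2
  W1 <- matrix(1, xi * dp, dp); b1 <- rep(-100, xi * dp) # kills any signal
  W2 <- matrix(rnorm(dp * xi * dp), dp, xi * dp); b2 <- c(7, -3)
  r <- matrix(runif(6), 3, 2)
  dead <- feed_forward(r, W1, b1, W2, b2)
  expect_equal(dead, matrix(rep(b2, each = 3), 3, 2)) # g = b_MLP2
  b1 <- c(0, 0, 0, 0)
  got <- feed_forward(r, W1, b1, W2, b2)
  expect_equal(dim(got), c(3L, 2L)) # output width d' regardless of xi
  for (t in 1:3)
    expect_equal(got[t, ], drop(W2 %*% pmax(W1 %*% r[t, ], 0)) + b2)
})

test_that("feature-attention pooling matches its softmax definition", {
  g1 <- matrix(c(1, 2), 1, 2)
  one <- feature_attention_pool(g1, c(0.3, -0.2))
  expect_equal(one$psi, 1)
  expect_equal(one$z, c(1, 2))
  same <- feature_attention_pool(matrix(1:2, 3, 2, byrow = TRUE), c(1, 1))
  expect_equal(same$psi, rep(1 / 3, 3))
  expect_equal(same$z, c(1, 2))
  withr::local_seed(5)
  G <- matrix(runif(6), 3, 2); ctx <- rnorm(2)
  got <- feature_attention_pool(G, ctx)
  sc <- drop(G %*% ctx) / sqrt(2)
  psi <- exp(sc) / sum(exp(sc))
  expect_equal(got$psi, psi, tolerance = 1e-12)
  expect_equal(got$z, drop(psi %*% G), tolerance = 1e-12)
  expect_equal(sum(got$psi), 1, tolerance = 1e-9)
})

test_that("the full encoder equals the chained sub-operations", {
  cfg <- ddinet_config(n_heads = 1, n_units = 1, model_dim = 3, mlp_factor = 2,
                       dropout = 0, seed = 2)
  par <- withr::with_seed(2, init_ddinet_params(cfg, input_dim = 4, n_modalities = 3))
  u <- withr::with_seed(3, matrix(runif(12), 3, 4))
  got <- encode_drug(u, par, cfg, capture_trace = TRUE)
  # manual chain: project -> attention -> unify -> add+norm -> ff -> add+norm
  X <- t(apply(u, 1, function(x) drop(par$proj_W %*% x) + par$proj_b))
  sa <- self_attention_head(X, par$u1_h1_Wq, par$u1_h1_Wk, par$u1_h1_Wv)
  rt <- multi_head_unify(list(sa$r), par$u1_Wu, par$u1_bu)
  A <- layer_norm(X + rt, par$u1_ln1_g, par$u1_ln1_b, cfg$layernorm_eps)
  g <- feed_forward(A, par$u1_W1, par$u1_b1, par$u1_W2, par$u1_b2)
  Y <- layer_norm(A + g, par$u1_ln2_g, par$u1_ln2_b, cfg$layernorm_eps)
  pool <- feature_attention_pool(Y, par$ctx)
  expect_equal(got$z, pool$z, tolerance = 1e-12)
  expect_equal(got$trace$psi, pool$psi, tolerance = 1e-12)
  expect_equal(got$trace$attn$e1_h1, sa$attn, tolerance = 1e-12)
})

test_that("encoder is deterministic, Siamese and batch-consistent", {
  cfg <- ddinet_config(n_heads = 2, n_units = 2, model_dim = 4, dropout = 0,
                       seed = 6)
  par <- withr::with_seed(6, init_ddinet_params(cfg, input_dim = 5, n_modalities = 3))
  inputs <- lapply(1:3, function(t) random_similarity(5, seed = t))
  # batched forward over all 5 drugs vs encoding each drug alone
  fw <- enc_forward(pair_inputs(inputs, 1:5), par, cfg)
  for (dr in 1:5) {
    u <- t(sapply(inputs, function(S) S[dr, ]))
    alone <- encode_drug(u, par, cfg)
    expect_equal(fw$Z[dr, ], alone$z, tolerance = 1e-12)
  }
  # two passes agree exactly with dropout disabled
  fw2 <- enc_forward(pair_inputs(inputs, 1:5), par, cfg)
  expect_identical(fw$Z, fw2$Z)
  # the pair sides share one parameter set by construction: encoding drug a
  # is unaffected by which partner appears in the batch (rows independent)
  sub <- enc_forward(pair_inputs(inputs, c(1, 3)), par, cfg)
  expect_equal(sub$Z[1, ], fw$Z[1, ], tolerance = 1e-12)
  expect_equal(sub$Z[2, ], fw$Z[3, ], tolerance = 1e-12)
})

test_that("permuting the modality order permutes attention and preserves z", {
  cfg <- ddinet_config(n_heads = 1, n_units = 1, model_dim = 4, dropout = 0,
                       seed = 9)
  par <- withr::with_seed(9, init_ddinet_params(cfg, input_dim = 6, n_modalities = 4))
  u <- withr::with_seed(10, matrix(runif(24), 4, 6))
  perm <- c(3, 1, 4, 2)
  a <- encode_drug(u, par, cfg, capture_trace = TRUE)
  b <- encode_drug(u[perm, ], par, cfg, capture_trace = TRUE)
  expect_equal(b$z, a$z, tolerance = 1e-10)
  expect_equal(b$trace$psi, a$trace$psi[perm], tolerance = 1e-10)
  expect_equal(b$trace$attn$e1_h1, a$trace$attn$e1_h1[perm, perm],
               tolerance = 1e-10)
})
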