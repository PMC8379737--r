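# Shared fixture builders. All fixtures are generated in code under fixed
# seeds; nothing is read from disk.

# A random symmetric similarity matrix with unit diagonal.
random_similarity <- function(n, seed = 1) {
  withr::with_seed(seed, {
    S <- matrix(runif(n * n), n, n)
    S <- (S + t(S)) / 2
    diag(S) <- 1
    dimnames(S) <- list(sprintf("d%02d", 1:n), sprintf("d%02d", 1:n))
    S
  })
}

# A random symmetric 0/1 label matrix with zero diagonal.
random_labels <- function(n, prevalence = 0.3, seed = 1) {
  withr::with_seed(seed, {
    L <- matrix(0, n, n)
    up <- upper.tri(L)
    L[up] <- rbinom(sum(up), 1, prevalence)
    L <- L + t(L)
    dimnames(L) <- list(sprintf("d%02d", 1:n), sprintf("d%02d", 1:n))
    L
  })
}

# Small ready-to-fit planted-signal dataset used by the training tests.
toy_dataset <- function(n_drugs = 40, n_modalities = 2, prevalence = 0.15,
                        seed = 3, use_gip = TRUE) {
  synth_dataset(synth_config(n_drugs = n_drugs, n_modalities = n_modalities,
                             n_latent_groups = max(4, round(n_drugs / 8)),
                             n_features_per_modality = 120,
                             informative_modalities = 1,
                             prevalence = prevalence, seed = seed),
                use_gip = use_gip)
}

# Fast training configuration for toy problems.
toy_config <- function(...) {
  base <- list(model_dim = 16, n_epochs = 15, batch_size = 200,
               learning_rate = 2e-3, dropout = 0.1, seed = 11)
  do.call(ddinet_config, utils::modifyList(base, list(...)))
}

# Independent scalar reimplementation of the encoder math for oracle
# comparisons: plain loops, no shared code with the package internals
# beyond parameter shapes.
oracle_encoder <- function(u, par, cfg) {
  dp <- cfg$model_dim
  X <- matrix(0, nrow(u), dp)
  for (t in 1:nrow(u)) X[t, ] <- par$proj_W %*% u[t, ] + par$proj_b
  for (e in 1:cfg$n_units) {
    p <- function(s) par[[paste0("u", e, "_", s)]]
    concat <- matrix(0, nrow(u), 0)
    for (h in 1:cfg$n_heads) {
      ph <- function(s) par[[paste0("u", e, "_h", h, "_", s)]]
      q <- k <- v <- matrix(0, nrow(X), dp)
      for (t in 1:nrow(X)) {
        q[t, ] <- ph("Wq") %*% X[t, ]
        k[t, ] <- ph("Wk") %*% X[t, ]
        v[t, ] <- ph("Wv") %*% X[t, ]
      }
      r <- matrix(0, nrow(X), dp)
      for (t in 1:nrow(X)) {
        sc <- sapply(1:nrow(X), function(l) sum(q[t, ] * k[l, ]) / sqrt(dp))
        al <- exp(sc - max(sc)); al <- al / sum(al)
        for (l in 1:nrow(X)) r[t, ] <- r[t, ] + al[l] * v[l, ]
      }
      concat <- cbind(concat, r)
    }
    Rt <- matrix(0, nrow(X), dp)
    for (t in 1:nrow(X)) Rt[t, ] <- p("Wu") %*% concat[t, ] + p("bu")
    ln <- function(x, g, b) {
      mu <- mean(x); s2 <- mean((x - mu)^2)
      g * (x - mu) / sqrt(s2 + cfg$layernorm_eps) + b
    }
    A <- matrix(0, nrow(X), dp)
    for (t in 1:nrow(X))
      A[t, ] <- ln(X[t, ] + Rt[t, ], p("ln1_g"), p("ln1_b"))
    Y <- matrix(0, nrow(X), dp)
    for (t in 1:nrow(X)) {
      g1 <- p("W2") %*% pmax(p("W1") %*% A[t, ] + p("b1"), 0) + p("b2")
      pre <- if (cfg$ff_residual) A[t, ] + g1 else g1
      Y[t, ] <- ln(pre, p("ln2_g"), p("ln2_b"))
    }
    X <- Y
  }
  sc <- sapply(1:nrow(X), function(t) sum(par$ctx * X[t, ]) / sqrt(dp))
  psi <- exp(sc - max(sc)); psi <- psi / sum(psi)
  z <- rep(0, dp)
  for (t in 1:nrow(X)) z <- z + psi[t] * X[t, ]
  list(z = z, psi = psi)
}
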