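# Mini-batch training engine: parameter initialisation, vectorised
# forward/backward passes for the three model variants, and Adam updates.
# The math matches the per-drug operations in encoder.R / loss.R; analytic
# gradients are checked against finite differences in the test suite.

#' Initialise model parameters
#'
#' Weights are drawn uniformly in \eqn{\pm 1/\sqrt{fan\_in}} from the
#' current RNG stream; layer-norm scales start at 1, all biases at 0. The
#' first-unit projections act on the learned d -> d' input embedding, so
#' every attention map is d' x d'.
#'
#' @param config A \code{\link{ddinet_config}}.
#' @param input_dim Length d of each modality input vector (= N, the number
#'   of drugs, when inputs are similarity-matrix rows).
#' @param n_modalities Number of modality vectors per drug T (required for
#'   the \code{feedforward_only} variant, whose input is the concatenation
#'   of all 2T pair vectors).
#' @return Named list of parameter matrices/vectors.
#' @export
init_ddinet_params <- function(config, input_dim, n_modalities = NULL) {
  dp <- config$model_dim; H <- config$n_heads; E <- config$n_units
  xi <- config$mlp_factor
  runi <- function(nr, nc) matrix(stats::runif(nr * nc, -1, 1) / sqrt(nc), nr, nc)
  par <- list()
  if (config$variant == "feedforward_only") {
    if (is.null(n_modalities))
      stop("n_modalities is required for the feedforward_only variant",
           call. = FALSE)
    din <- 2L * n_modalities * input_dim
    hid <- xi * dp
    par$ff_W1 <- runi(hid, din); par$ff_b1 <- numeric(hid)
    par$ff_W2 <- runi(2L, hid); par$ff_b2 <- numeric(2L)
    return(par)
  }
  par$proj_W <- runi(dp, input_dim); par$proj_b <- numeric(dp)
  for (e in seq_len(E)) {
    for (h in seq_len(H)) {
      pre <- paste0("u", e, "_h", h, "_")
      par[[paste0(pre, "Wq")]] <- runi(dp, dp)
      par[[paste0(pre, "Wk")]] <- runi(dp, dp)
      par[[paste0(pre, "Wv")]] <- runi(dp, dp)
    }
    pre <- paste0("u", e, "_")
    par[[paste0(pre, "Wu")]] <- runi(dp, dp * H)
    par[[paste0(pre, "bu")]] <- numeric(dp)
    par[[paste0(pre, "ln1_g")]] <- rep(1, dp)
    par[[paste0(pre, "ln1_b")]] <- numeric(dp)
    par[[paste0(pre, "W1")]] <- runi(xi * dp, dp)
    par[[paste0(pre, "b1")]] <- numeric(xi * dp)
    par[[paste0(pre, "W2")]] <- runi(dp, xi * dp)
    par[[paste0(pre, "b2")]] <- numeric(dp)
    par[[paste0(pre, "ln2_g")]] <- rep(1, dp)
    par[[paste0(pre, "ln2_b")]] <- numeric(dp)
  }
  if (config$pooling_mode == "attn")
    par$ctx <- stats::runif(dp, -1, 1) / sqrt(dp)
  nout <- if (config$variant == "full") 2L * dp + 1L else dp
  par$W_out <- runi(2L, nout)
  par$b_out <- numeric(2L)
  par
}

ln_forward <- function(M, g, b, eps) {
  mu <- rowMeans(M)
  xc <- M - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  list(y = addrow(xhat * rep(g, each = nrow(M)), b), xhat = xhat, inv = inv)
}

ln_backward <- function(dY, cache, g) {
  dxhat <- dY * rep(g, each = nrow(dY))
  mdx <- rowMeans(dxhat)
  mdxx <- rowMeans(dxhat * cache$xhat)
  list(dX = (dxhat - mdx - cache$xhat * mdxx) * cache$inv,
       dg = colSums(dY * cache$xhat),
       db = colSums(dY))
}

# Batched encoder forward. X: list over T modalities of B x d matrices.
enc_forward <- function(X, par, cfg, training = FALSE, capture = FALSE) {
  Tn <- length(X); B <- nrow(X[[1]]); dp <- cfg$model_dim
  H <- cfg$n_heads; E <- cfg$n_units; sdp <- sqrt(dp)
  p_drop <- if (training) cfg$dropout else 0
  X0 <- lapply(X, function(M) addrow(M %*% t(par$proj_W), par$proj_b))
  Xc <- X0
  units <- vector("list", E)
  trace_attn <- if (capture) list() else NULL
  for (e in seq_len(E)) {
    pe <- function(s) par[[paste0("u", e, "_", s)]]
    heads <- vector("list", H)
    for (h in seq_len(H)) {
      ph <- function(s) par[[paste0("u", e, "_h", h, "_", s)]]
      tWq <- t(ph("Wq")); tWk <- t(ph("Wk")); tWv <- t(ph("Wv"))
      Q <- lapply(Xc, function(M) M %*% tWq)
      K <- lapply(Xc, function(M) M %*% tWk)
      V <- lapply(Xc, function(M) M %*% tWv)
      alpha <- array(0, c(B, Tn, Tn))
      for (t in seq_len(Tn)) {
        S <- matrix(0, B, Tn)
        for (l in seq_len(Tn)) S[, l] <- rowSums(Q[[t]] * K[[l]]) / sdp
        alpha[, t, ] <- softmax_rows(S)
      }
      r <- vector("list", Tn)
      for (t in seq_len(Tn)) {
        acc <- V[[1]] * alpha[, t, 1]
        for (l in seq_len(Tn)[-1]) acc <- acc + V[[l]] * alpha[, t, l]
        r[[t]] <- acc
      }
      heads[[h]] <- list(Q = Q, K = K, V = V, alpha = alpha, r = r)
      if (capture) trace_attn[[paste0("e", e, "_h", h)]] <- alpha
    }
    Rc <- lapply(seq_len(Tn), function(t)
      do.call(cbind, lapply(heads, function(hh) hh$r[[t]])))
    tWu <- t(pe("Wu")); bu <- pe("bu")
    Rt <- lapply(Rc, function(M) addrow(M %*% tWu, bu))
    D1 <- NULL
    if (p_drop > 0) {
      D1 <- lapply(seq_len(Tn), function(t)
        matrix(stats::rbinom(B * dp, 1, 1 - p_drop) / (1 - p_drop), B, dp))
      Rt <- Map(`*`, Rt, D1)
    }
    Res1 <- Map(`+`, Xc, Rt)
    ln1 <- lapply(Res1, ln_forward, g = pe("ln1_g"), b = pe("ln1_b"),
                  eps = cfg$layernorm_eps)
    A <- lapply(ln1, `[[`, "y")
    tW1 <- t(pe("W1")); b1 <- pe("b1")
    tW2 <- t(pe("W2")); b2 <- pe("b2")
    Pre <- lapply(A, function(M) addrow(M %*% tW1, b1))
    Rel <- lapply(Pre, pmax, 0)
    G <- lapply(Rel, function(M) addrow(M %*% tW2, b2))
    D2 <- NULL
    if (p_drop > 0) {
      D2 <- lapply(seq_len(Tn), function(t)
        matrix(stats::rbinom(B * dp, 1, 1 - p_drop) / (1 - p_drop), B, dp))
      G <- Map(`*`, G, D2)
    }
    Res2 <- if (cfg$ff_residual) Map(`+`, A, G) else G
    ln2 <- lapply(Res2, ln_forward, g = pe("ln2_g"), b = pe("ln2_b"),
                  eps = cfg$layernorm_eps)
    Y <- lapply(ln2, `[[`, "y")
    units[[e]] <- list(Xin = Xc, heads = heads, Rc = Rc, D1 = D1, ln1 = ln1,
                       A = A, Pre = Pre, Rel = Rel, D2 = D2, ln2 = ln2)
    Xc <- Y
  }
  pool <- list(Y = Xc)
  if (cfg$pooling_mode == "attn") {
    Smat <- vapply(Xc, function(M) drop(M %*% par$ctx) / sdp, numeric(B))
    if (is.null(dim(Smat))) Smat <- matrix(Smat, nrow = B)
    psi <- softmax_rows(Smat)
    Z <- Xc[[1]] * psi[, 1]
    for (t in seq_len(Tn)[-1]) Z <- Z + Xc[[t]] * psi[, t]
    pool$psi <- psi
  } else if (cfg$pooling_mode == "mean") {
    Z <- Reduce(`+`, Xc) / Tn
    pool$psi <- matrix(1 / Tn, B, Tn)
  } else {
    Z <- Xc[[1]]
    amax <- matrix(1L, B, dp)
    for (t in seq_len(Tn)[-1]) {
      upd <- Xc[[t]] > Z
      Z[upd] <- Xc[[t]][upd]
      amax[upd] <- t
    }
    pool$amax <- amax
  }
  list(Z = Z, cache = list(X_raw = X, X0 = X0, units = units, pool = pool),
       trace = if (capture) list(attn = trace_attn, psi = pool$psi) else NULL)
}

# Batched encoder backward: gradient of the loss w.r.t. every encoder
# parameter given dL/dZ. Returns a flat named list mirroring the parameters.
enc_backward <- function(dZ, fw, par, cfg) {
  cache <- fw$cache
  Tn <- length(cache$X0); B <- nrow(dZ); dp <- cfg$model_dim
  H <- cfg$n_heads; E <- cfg$n_units; sdp <- sqrt(dp)
  g <- new.env(parent = emptyenv())
  gadd <- function(nm, val) {
    prev <- if (exists(nm, envir = g, inherits = FALSE)) get(nm, envir = g) else 0
    assign(nm, prev + val, envir = g)
  }
  Y <- cache$pool$Y
  dY <- vector("list", Tn)
  if (cfg$pooling_mode == "attn") {
    psi <- cache$pool$psi
    dpsi <- vapply(seq_len(Tn), function(t) rowSums(dZ * Y[[t]]), numeric(B))
    if (is.null(dim(dpsi))) dpsi <- matrix(dpsi, nrow = B)
    for (t in seq_len(Tn)) dY[[t]] <- dZ * psi[, t]
    ds <- psi * (dpsi - rowSums(dpsi * psi))
    dctx <- 0
    for (t in seq_len(Tn)) {
      dctx <- dctx + colSums(Y[[t]] * ds[, t]) / sdp
      dY[[t]] <- dY[[t]] + outer(ds[, t], par$ctx) / sdp
    }
    gadd("ctx", dctx)
  } else if (cfg$pooling_mode == "mean") {
    for (t in seq_len(Tn)) dY[[t]] <- dZ / Tn
  } else {
    amax <- cache$pool$amax
    for (t in seq_len(Tn)) dY[[t]] <- dZ * (amax == t)
  }
  for (e in rev(seq_len(E))) {
    uc <- cache$units[[e]]
    nm <- function(s) paste0("u", e, "_", s)
    pe <- function(s) par[[nm(s)]]
    dRes2 <- vector("list", Tn); dg2 <- 0; db2ln <- 0
    for (t in seq_len(Tn)) {
      lb <- ln_backward(dY[[t]], uc$ln2[[t]], pe("ln2_g"))
      dRes2[[t]] <- lb$dX; dg2 <- dg2 + lb$dg; db2ln <- db2ln + lb$db
    }
    gadd(nm("ln2_g"), dg2); gadd(nm("ln2_b"), db2ln)
    W1 <- pe("W1"); W2 <- pe("W2")
    dA <- vector("list", Tn)
    dW1 <- 0; db1 <- 0; dW2 <- 0; db2 <- 0
    for (t in seq_len(Tn)) {
      dG <- if (is.null(uc$D2)) dRes2[[t]] else dRes2[[t]] * uc$D2[[t]]
      dW2 <- dW2 + crossprod(dG, uc$Rel[[t]])
      db2 <- db2 + colSums(dG)
      dPre <- (dG %*% W2) * (uc$Pre[[t]] > 0)
      dW1 <- dW1 + crossprod(dPre, uc$A[[t]])
      db1 <- db1 + colSums(dPre)
      dA[[t]] <- dPre %*% W1
      if (cfg$ff_residual) dA[[t]] <- dA[[t]] + dRes2[[t]]
    }
    gadd(nm("W1"), dW1); gadd(nm("b1"), db1)
    gadd(nm("W2"), dW2); gadd(nm("b2"), db2)
    dRes1 <- vector("list", Tn); dg1 <- 0; db1ln <- 0
    for (t in seq_len(Tn)) {
      lb <- ln_backward(dA[[t]], uc$ln1[[t]], pe("ln1_g"))
      dRes1[[t]] <- lb$dX; dg1 <- dg1 + lb$dg; db1ln <- db1ln + lb$db
    }
    gadd(nm("ln1_g"), dg1); gadd(nm("ln1_b"), db1ln)
    dXin <- dRes1
    Wu <- pe("Wu")
    dWu <- 0; dbu <- 0
    dRc <- vector("list", Tn)
    for (t in seq_len(Tn)) {
      dRt <- if (is.null(uc$D1)) dRes1[[t]] else dRes1[[t]] * uc$D1[[t]]
      dWu <- dWu + crossprod(dRt, uc$Rc[[t]])
      dbu <- dbu + colSums(dRt)
      dRc[[t]] <- dRt %*% Wu
    }
    gadd(nm("Wu"), dWu); gadd(nm("bu"), dbu)
    Xin <- uc$Xin
    for (h in seq_len(H)) {
      hc <- uc$heads[[h]]
      cols <- ((h - 1L) * dp + 1L):(h * dp)
      drh <- lapply(dRc, function(M) M[, cols, drop = FALSE])
      alpha <- hc$alpha
      dalpha <- array(0, c(B, Tn, Tn))
      dV <- rep(list(0), Tn)
      for (t in seq_len(Tn)) for (l in seq_len(Tn)) {
        dalpha[, t, l] <- rowSums(drh[[t]] * hc$V[[l]])
        dV[[l]] <- dV[[l]] + drh[[t]] * alpha[, t, l]
      }
      dQ <- rep(list(0), Tn); dK <- rep(list(0), Tn)
      for (t in seq_len(Tn)) {
        dal <- matrix(dalpha[, t, ], nrow = B)
        al <- matrix(alpha[, t, ], nrow = B)
        dS <- al * (dal - rowSums(dal * al))
        for (l in seq_len(Tn)) {
          dQ[[t]] <- dQ[[t]] + hc$K[[l]] * (dS[, l] / sdp)
          dK[[l]] <- dK[[l]] + hc$Q[[t]] * (dS[, l] / sdp)
        }
      }
      hn <- function(s) paste0("u", e, "_h", h, "_", s)
      Wq <- par[[hn("Wq")]]; Wk <- par[[hn("Wk")]]; Wv <- par[[hn("Wv")]]
      dWq <- 0; dWk <- 0; dWv <- 0
      for (t in seq_len(Tn)) {
        dWq <- dWq + crossprod(dQ[[t]], Xin[[t]])
        dWk <- dWk + crossprod(dK[[t]], Xin[[t]])
        dWv <- dWv + crossprod(dV[[t]], Xin[[t]])
        dXin[[t]] <- dXin[[t]] + dQ[[t]] %*% Wq + dK[[t]] %*% Wk + dV[[t]] %*% Wv
      }
      gadd(hn("Wq"), dWq); gadd(hn("Wk"), dWk); gadd(hn("Wv"), dWv)
    }
    dY <- dXin
  }
  dpW <- 0; dpb <- 0
  for (t in seq_len(Tn)) {
    dpW <- dpW + crossprod(dY[[t]], cache$X_raw[[t]])
    dpb <- dpb + colSums(dY[[t]])
  }
  gadd("proj_W", dpW); gadd("proj_b", dpb)
  as.list(g)
}

# Classifier head over pair indices into a drug representation matrix Z.
cls_forward <- function(Z, ia, ib, par, cfg) {
  za <- Z[ia, , drop = FALSE]; zb <- Z[ib, , drop = FALSE]
  if (cfg$distance == "euclidean") {
    diff <- za - zb
    dist <- sqrt(rowSums(diff^2))
    dcache <- list(diff = diff, dist = dist)
  } else {
    dot <- rowSums(za * zb)
    na <- sqrt(rowSums(za^2)); nb <- sqrt(rowSums(zb^2))
    zero <- na < 1e-12 | nb < 1e-12
    na <- pmax(na, 1e-12); nb <- pmax(nb, 1e-12)
    dist <- 1 - dot / (na * nb)
    dist[zero] <- 0
    dcache <- list(dot = dot, na = na, nb = nb, zero = zero)
  }
  feat <- unname(cbind(za, zb, dist))
  logits <- addrow(feat %*% t(par$W_out), par$b_out)
  m <- pmax(logits[, 1], logits[, 2])
  lse <- m + log(exp(logits[, 1] - m) + exp(logits[, 2] - m))
  lsm <- logits - lse
  list(feat = feat, lsm = lsm, p = exp(lsm), dist = unname(dist),
       dcache = dcache, za = za, zb = zb)
}

# Loss value and gradients for the full Siamese variant on one batch.
full_loss_grad <- function(cf, y, cw, par, cfg) {
  n <- length(y)
  dp <- (ncol(cf$feat) - 1L) / 2L
  w <- cw[y + 1L]
  lC <- mean(-w * cf$lsm[cbind(seq_len(n), y + 1L)])
  mu <- cfg$margin
  slack <- if (cfg$contrastive_literal) mu - cf$dist else pmax(mu - cf$dist, 0)
  wD <- if (cfg$weight_contrastive) w else rep(1, n)
  lD <- mean(wD * ifelse(y == 1, cf$dist^2 / 2, slack^2 / 2))
  l2 <- sum(vapply(par, function(p) sum(p^2), numeric(1)))
  loss <- cfg$gamma * lC + (1 - cfg$gamma) * lD + cfg$weight_decay / 2 * l2
  Y1 <- cbind(1 - y, y)
  dlog <- cfg$gamma * (cf$p - Y1) * (w / n)
  dW_out <- crossprod(dlog, cf$feat)
  db_out <- colSums(dlog)
  dfeat <- dlog %*% par$W_out
  dza <- dfeat[, seq_len(dp), drop = FALSE]
  dzb <- dfeat[, dp + seq_len(dp), drop = FALSE]
  ddist <- dfeat[, 2L * dp + 1L] +
    (1 - cfg$gamma) * (wD / n) * (y * cf$dist - (1 - y) * slack)
  dc <- cf$dcache
  if (cfg$distance == "euclidean") {
    inv <- ddist / pmax(dc$dist, 1e-12)
    dza <- dza + dc$diff * inv
    dzb <- dzb - dc$diff * inv
  } else {
    f1 <- ddist * !dc$zero
    nanb <- dc$na * dc$nb
    dza <- dza + (-cf$zb / nanb + cf$za * (dc$dot / (dc$na^2 * nanb))) * f1
    dzb <- dzb + (-cf$za / nanb + cf$zb * (dc$dot / (dc$nb^2 * nanb))) * f1
  }
  list(loss = loss, loss_C = lC, loss_D = lD,
       dW_out = dW_out, db_out = db_out, dza = dza, dzb = dzb)
}

scatter_dz <- function(dza, dzb, ia, ib, n_drugs) {
  dZ <- matrix(0, n_drugs, ncol(dza))
  agg <- rowsum(rbind(dza, dzb), c(ia, ib))
  dZ[as.integer(rownames(agg)), ] <- agg
  dZ
}

# Weighted softmax cross-entropy on logits (attention_only / feedforward
# variants); returns loss and dlogits.
softmax_nll_grad <- function(logits, y, cw) {
  n <- length(y)
  m <- pmax(logits[, 1], logits[, 2])
  lse <- m + log(exp(logits[, 1] - m) + exp(logits[, 2] - m))
  lsm <- logits - lse
  w <- cw[y + 1L]
  lC <- mean(-w * lsm[cbind(seq_len(n), y + 1L)])
  dlog <- (exp(lsm) - cbind(1 - y, y)) * (w / n)
  list(loss_C = lC, dlog = dlog, p = exp(lsm))
}

adam_init <- function(par)
  list(m = lapply(par, function(p) p * 0), v = lapply(par, function(p) p * 0),
       t = 0L)

adam_step <- function(par, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t; c2 <- 1 - beta2^st$t
  for (nm in names(par)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * gr
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * gr^2
    par[[nm]] <- par[[nm]] - lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
  }
  list(par = par, state = st)
}

# Assemble pair-level inputs for the non-Siamese variants.
pairset_inputs <- function(inputs, ia, ib)
  c(lapply(inputs, function(S) S[ia, , drop = FALSE]),
    lapply(inputs, function(S) S[ib, , drop = FALSE]))

ff_input <- function(inputs, ia, ib)
  do.call(cbind, pairset_inputs(inputs, ia, ib))

# Interaction probabilities for arbitrary pairs under fixed parameters.
# `inputs` is the list of T modality matrices (N x N rows = drug vectors).
predict_probs <- function(par, cfg, inputs, pairs, symmetrize = TRUE,
                          chunk = 4000L) {
  n <- nrow(pairs)
  out <- numeric(n)
  if (cfg$variant == "full") {
    drugs <- sort(unique(c(pairs[, 1], pairs[, 2])))
    pos <- match(seq_len(nrow(inputs[[1]])), drugs)
    Z <- enc_forward(pair_inputs(inputs, drugs), par, cfg)$Z
    ia <- pos[pairs[, 1]]; ib <- pos[pairs[, 2]]
    p1 <- unname(cls_forward(Z, ia, ib, par, cfg)$p[, 2])
    if (!symmetrize) return(p1)
    p2 <- unname(cls_forward(Z, ib, ia, par, cfg)$p[, 2])
    return((p1 + p2) / 2)
  }
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    ia <- pairs[idx, 1]; ib <- pairs[idx, 2]
    if (cfg$variant == "attention_only") {
      Z <- enc_forward(pairset_inputs(inputs, ia, ib), par, cfg)$Z
      logits <- addrow(Z %*% t(par$W_out), par$b_out)
      p <- unname(softmax_rows(logits)[, 2])
    } else {
      p <- ff_predict(par, ff_input(inputs, ia, ib))
      if (symmetrize)
        p <- (p + ff_predict(par, ff_input(inputs, ib, ia))) / 2
    }
    out[idx] <- p
  }
  out
}

ff_predict <- function(par, x) {
  h1 <- pmax(addrow(x %*% t(par$ff_W1), par$ff_b1), 0)
  unname(softmax_rows(addrow(h1 %*% t(par$ff_W2), par$ff_b2))[, 2])
}
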