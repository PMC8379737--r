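# Siamese Transformer-style encoder, expressed as its constituent
# operations on a single drug's set of T modality vectors. These functions
# define the model math one drug at a time; the mini-batch training engine
# in nn.R computes the same quantities vectorised over drugs and is tested
# against the composition of these operations.

#' Single-head scaled dot-product self-attention over modality vectors
#'
#' Projects every input vector \eqn{u_t} to query, key and value vectors
#' (\eqn{q_t = W_{query} u_t} etc.), forms attention weights
#' \eqn{\alpha_{tl} = softmax_l(q_t^\top k_l / \sqrt{d'})} and returns the
#' weighted value sums \eqn{r_t = \sum_l \alpha_{tl} v_l}.
#'
#' @param u T x d matrix; row t is the input vector of modality t.
#' @param W_query,W_key,W_value d' x d projection matrices.
#' @return List with \code{r} (T x d' matrix of outputs) and \code{attn}
#'   (T x T row-stochastic attention matrix).
#' @export
self_attention_head <- function(u, W_query, W_key, W_value) {
  u <- rbind(u)
  if (ncol(u) != ncol(W_query))
    stop("input dimension ", ncol(u), " does not match projection width ",
         ncol(W_query), call. = FALSE)
  dp <- nrow(W_query)
  Q <- u %*% t(W_query)
  K <- u %*% t(W_key)
  V <- u %*% t(W_value)
  S <- Q %*% t(K) / sqrt(dp)          # S[t, l] = q_t . k_l / sqrt(d')
  A <- softmax_rows(S)
  list(r = A %*% V, attn = A)
}

#' Unify multi-head attention outputs
#'
#' Concatenates the H per-head outputs position-wise and applies the affine
#' map \eqn{\tilde r_t = W_{unify} \, concat(r_t^1, ..., r_t^H) + b_{unify}}.
#'
#' @param heads List of H matrices, each T x d'.
#' @param W_unify d' x (d'H) matrix.
#' @param b_unify Length-d' vector.
#' @return T x d' matrix.
#' @export
multi_head_unify <- function(heads, W_unify, b_unify) {
  if (!is.list(heads)) heads <- list(heads)
  concat <- do.call(cbind, heads)
  if (ncol(concat) != ncol(W_unify))
    stop("expected ", ncol(W_unify) / ncol(heads[[1]]), " heads of width ",
         ncol(heads[[1]]), call. = FALSE)
  addrow(concat %*% t(W_unify), b_unify)
}

#' Layer normalisation
#'
#' Standardises each row across the feature dimension using its mean and
#' (biased) variance, then applies the learned scale \eqn{\gamma} and shift
#' \eqn{\beta}: \eqn{LayerNorm(v) = \gamma (v - \mu)/\sqrt{\sigma^2 +
#' \epsilon} + \beta}.
#'
#' @param v Vector, or matrix normalised row-wise.
#' @param gamma,beta Length-d' scale and shift parameters.
#' @param eps Variance floor.
#' @return Same shape as \code{v}.
#' @export
layer_norm <- function(v, gamma = rep(1, ncol(rbind(v))),
                       beta = rep(0, ncol(rbind(v))), eps = 1e-6) {
  M <- rbind(v)
  mu <- rowMeans(M)
  s2 <- rowMeans((M - mu)^2)
  out <- addrow((M - mu) / sqrt(s2 + eps) * rep(gamma, each = nrow(M)), beta)
  if (is.matrix(v)) out else drop(out)
}

#' Position-wise feed-forward transform
#'
#' Two affine maps with a ReLU in between:
#' \eqn{g_t = W_{MLP2}\,ReLU(W_{MLP1} \tilde r_t + b_{MLP1}) + b_{MLP2}}.
#' The surrounding residual connection and layer normalisation are applied
#' by the encoder, see \code{\link{encode_drug}}.
#'
#' @param r T x d' matrix (or a single d' vector).
#' @param W_mlp1 (\eqn{\xi d'}) x d' matrix; \code{b_mlp1} its bias.
#' @param W_mlp2 d' x (\eqn{\xi d'}) matrix; \code{b_mlp2} its bias.
#' @param b_mlp1,b_mlp2 Bias vectors.
#' @return Matrix/vector shaped like \code{r} with d' columns.
#' @export
feed_forward <- function(r, W_mlp1, b_mlp1, W_mlp2, b_mlp2) {
  M <- rbind(r)
  hidden <- pmax(addrow(M %*% t(W_mlp1), b_mlp1), 0)
  out <- addrow(hidden %*% t(W_mlp2), b_mlp2)
  if (is.matrix(r)) out else drop(out)
}

#' Feature-attention pooling into a single drug representation
#'
#' Scores each transformed modality vector against a learned global context
#' vector, \eqn{\psi_t = softmax_t(c^\top \tilde g_t / \sqrt{d'})}, and
#' returns the weighted sum \eqn{z = \sum_t \psi_t \tilde g_t}.
#'
#' @param g T x d' matrix of transformed modality vectors.
#' @param context Length-d' context vector c.
#' @return List with \code{z} (length-d' vector) and \code{psi} (length-T
#'   probability vector).
#' @export
feature_attention_pool <- function(g, context) {
  g <- rbind(g)
  s <- unname(drop(g %*% context)) / sqrt(ncol(g))
  psi <- unname(drop(softmax_rows(rbind(s))))
  list(z = unname(drop(crossprod(g, psi))), psi = psi)
}

#' Encode one drug's modality vectors into a representation z
#'
#' Applies the full encoder to a single drug: a learned input projection
#' d -> d' (so residual sums are dimension-consistent), then E stacked
#' units of [multi-head self-attention, residual add + layer norm,
#' feed-forward, residual add + layer norm], and finally a pooling step
#' (feature attention by default) that aggregates the T transformed vectors
#' into one d' vector. Deterministic (dropout is a training-time device and
#' is not applied here). The Siamese property holds by construction: the
#' output depends only on this drug's input set and the shared parameters.
#'
#' @param u T x d matrix of the drug's modality vectors.
#' @param params Parameter list as produced by
#'   \code{\link{init_ddinet_params}}.
#' @param config A \code{\link{ddinet_config}}.
#' @param capture_trace Return attention matrices and pooling weights.
#' @return List with \code{z} and, when \code{capture_trace}, \code{trace}
#'   containing \code{attn} (list over units/heads of T x T matrices) and
#'   \code{psi} (length-T pooling weights).
#' @export
encode_drug <- function(u, params, config, capture_trace = FALSE) {
  u <- rbind(u)
  Tn <- nrow(u)
  X <- addrow(u %*% t(params$proj_W), params$proj_b)
  trace <- list(attn = list(), psi = NULL)
  for (e in seq_len(config$n_units)) {
    pe <- function(nm) params[[paste0("u", e, "_", nm)]]
    heads <- vector("list", config$n_heads)
    for (h in seq_len(config$n_heads)) {
      ph <- function(nm) params[[paste0("u", e, "_h", h, "_", nm)]]
      sa <- self_attention_head(X, ph("Wq"), ph("Wk"), ph("Wv"))
      heads[[h]] <- sa$r
      if (capture_trace) trace$attn[[paste0("e", e, "_h", h)]] <- sa$attn
    }
    rt <- multi_head_unify(heads, pe("Wu"), pe("bu"))
    A <- layer_norm(X + rt, pe("ln1_g"), pe("ln1_b"), config$layernorm_eps)
    g <- feed_forward(A, pe("W1"), pe("b1"), pe("W2"), pe("b2"))
    pre <- if (config$ff_residual) A + g else g
    X <- layer_norm(pre, pe("ln2_g"), pe("ln2_b"), config$layernorm_eps)
  }
  pooled <- switch(config$pooling_mode,
    attn = feature_attention_pool(X, params$ctx),
    mean = list(z = colMeans(X), psi = rep(1 / Tn, Tn)),
    max  = list(z = apply(X, 2, max), psi = NULL))
  if (capture_trace) {
    trace$psi <- pooled$psi
    list(z = pooled$z, trace = trace)
  } else list(z = pooled$z)
}
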