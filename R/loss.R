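# Pair distance, classifier head and the joint objective:
# L_total = gamma * L_C + (1 - gamma) * L_Dist + lambda/2 * ||theta||^2.

#' Distance between two drug representations
#'
#' Euclidean: \eqn{\|z_a - z_b\|_2}. Cosine: \eqn{1 - z_a \cdot z_b /
#' (\|z_a\| \|z_b\|)}, defined as 0 when either norm is zero.
#'
#' @param z_a,z_b Equal-length numeric vectors.
#' @param kind \code{"euclidean"} or \code{"cosine"}.
#' @return Nonnegative scalar.
#' @export
pair_distance <- function(z_a, z_b, kind = c("euclidean", "cosine")) {
  kind <- match.arg(kind)
  if (length(z_a) != length(z_b))
    stop("representation vectors have different lengths", call. = FALSE)
  if (kind == "euclidean") return(sqrt(sum((z_a - z_b)^2)))
  na <- sqrt(sum(z_a^2)); nb <- sqrt(sum(z_b^2))
  if (na == 0 || nb == 0) return(0)
  1 - sum(z_a * z_b) / (na * nb)
}

#' Interaction probability for one drug pair
#'
#' Concatenates the two representations with their distance and maps the
#' result through an affine transform and softmax:
#' \eqn{\hat y = softmax(W_{out} [z_a; z_b; Dist] + b_{out})}.
#'
#' @param z_a,z_b Drug representations (length d').
#' @param W_out 2 x (2d' + 1) matrix; \code{b_out} length-2 vector.
#' @param b_out Output bias.
#' @param distance Distance kind fed into the concatenation.
#' @return Length-2 probability vector (no-interaction, interaction).
#' @export
classify_pair <- function(z_a, z_b, W_out, b_out,
                          distance = c("euclidean", "cosine")) {
  distance <- match.arg(distance)
  feat <- c(z_a, z_b, pair_distance(z_a, z_b, distance))
  if (length(feat) != ncol(W_out))
    stop("W_out must have ", length(feat), " columns", call. = FALSE)
  logits <- drop(W_out %*% feat) + b_out
  e <- exp(logits - max(logits))
  e / sum(e)
}

#' Class-weighted negative log-likelihood (binary cross-entropy)
#'
#' Per pair: \eqn{l^C = -w_{y} [y \log \hat y + (1 - y)\log(1 - \hat y)]};
#' the batch loss is the mean. Probabilities are clamped at 1e-12.
#'
#' @param y_hat Predicted interaction probabilities.
#' @param y 0/1 labels.
#' @param weights Length-2 class weights \code{c(w0, w1)}.
#' @return Nonnegative scalar.
#' @export
nll_loss <- function(y_hat, y, weights = c(1, 1)) {
  y <- as.integer(y)
  p <- pmin(pmax(y_hat, 1e-12), 1 - 1e-12)
  w <- weights[y + 1L]
  mean(-w * (y * log(p) + (1 - y) * log(1 - p)))
}

#' Contrastive (margin) loss on pair distances
#'
#' Interacting pairs (y = 1) are pulled together, \eqn{d^2/2}; non-
#' interacting pairs are pushed beyond the margin,
#' \eqn{\max(\mu - d, 0)^2 / 2}. The batch loss is the mean.
#' \code{literal = TRUE} uses \eqn{\max((\mu - d)^2, 0)/2} instead, which
#' coincides for \eqn{d \le \mu} but also penalises distances beyond the
#' margin.
#'
#' @param dist Nonnegative pair distances.
#' @param y 0/1 labels.
#' @param margin Margin \eqn{\mu > 0}.
#' @param literal Use the un-hinged squared form for dissimilar pairs.
#' @param weights Optional per-pair weights (mean-normalised externally).
#' @return Nonnegative scalar.
#' @export
contrastive_loss <- function(dist, y, margin = 1, literal = FALSE,
                             weights = NULL) {
  if (any(dist < 0)) stop("distances must be nonnegative", call. = FALSE)
  if (margin <= 0) stop("margin must be positive", call. = FALSE)
  y <- as.integer(y)
  slack <- if (literal) margin - dist else pmax(margin - dist, 0)
  l <- ifelse(y == 1, dist^2 / 2, slack^2 / 2)
  if (!is.null(weights)) l <- l * weights
  mean(l)
}

#' Joint training objective
#'
#' \eqn{L^{Total} = \gamma L^C + (1-\gamma) L^{Dist} +
#' \frac{\lambda}{2}\|\theta\|_2^2}.
#'
#' @param nll Classification loss \eqn{L^C}.
#' @param contrastive Distance loss \eqn{L^{Dist}}.
#' @param gamma Mixing weight in (0, 1).
#' @param params Optional parameter list entering the L2 penalty.
#' @param weight_decay Penalty coefficient \eqn{\lambda}.
#' @return Scalar total loss.
#' @export
total_loss <- function(nll, contrastive, gamma, params = NULL,
                       weight_decay = 0) {
  if (gamma <= 0 || gamma >= 1) stop("gamma must be in (0, 1)", call. = FALSE)
  l2 <- if (is.null(params) || weight_decay == 0) 0
        else sum(vapply(params, function(p) sum(p^2), numeric(1)))
  gamma * nll + (1 - gamma) * contrastive + weight_decay / 2 * l2
}
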