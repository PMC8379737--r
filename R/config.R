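# Model and training configuration, including the four benchmark
# hyperparameter presets and YAML/JSON round-tripping.

#' Model and training configuration
#'
#' All architecture and optimisation hyperparameters in one validated
#' object.
#'
#' @param n_heads Number of self-attention heads H.
#' @param n_units Number of stacked encoder units E.
#' @param model_dim Latent dimension d' of the query/key/value projections
#'   and of the drug representation z. Not fixed by the architecture
#'   definition; default 128.
#' @param mlp_factor Width multiplier \eqn{\xi} of the feed-forward hidden
#'   layer (\eqn{\xi d'}).
#' @param dropout Dropout rate in \code{[0, 1)}, applied after the unified
#'   attention output and after the feed-forward output (standard
#'   Transformer placement).
#' @param pooling_mode How the T per-modality encodings are pooled into one
#'   drug vector: \code{"attn"} (learned feature attention, the reference
#'   setting), \code{"mean"} or \code{"max"}.
#' @param distance Pair distance used by the classifier and contrastive
#'   loss: \code{"cosine"} or \code{"euclidean"}.
#' @param weight_decay L2 penalty coefficient \eqn{\lambda}, applied as an
#'   explicit term \eqn{\frac{\lambda}{2}\|\theta\|^2} in the objective.
#' @param batch_size Mini-batch size (pairs).
#' @param n_epochs Training epochs.
#' @param gamma Loss-mixing weight \eqn{\gamma \in (0,1)}: total loss is
#'   \eqn{\gamma L^C + (1-\gamma) L^{Dist} + \frac{\lambda}{2}\|\theta\|^2}.
#' @param margin Contrastive-loss margin \eqn{\mu > 0}.
#' @param learning_rate Adam step size.
#' @param seed Integer seed driving parameter initialisation, batch
#'   shuffling and dropout.
#' @param variant \code{"full"} (Siamese attention model),
#'   \code{"attention_only"} (single non-Siamese encoder over the pair's 2T
#'   vectors) or \code{"feedforward_only"} (concatenated pair features
#'   through an MLP head).
#' @param layernorm_eps Layer-norm variance floor \eqn{\epsilon}.
#' @param ff_residual Keep the residual connection around the feed-forward
#'   block (\code{TRUE}, the "Add + Normalize" reading); \code{FALSE}
#'   normalises the feed-forward output alone.
#' @param contrastive_literal Use the literal printed dissimilar-pair term
#'   \eqn{\max((\mu - d)^2, 0)/2} instead of the standard hinge
#'   \eqn{\max(\mu - d, 0)^2/2}; the two differ only when \eqn{d > \mu}.
#' @param weight_contrastive Apply the class weights to the contrastive
#'   term as well as the NLL term (default: NLL only).
#' @return Object of class \code{ddinet_config}.
#' @export
ddinet_config <- function(n_heads = 2, n_units = 1, model_dim = 128,
                          mlp_factor = 2, dropout = 0.3,
                          pooling_mode = c("attn", "mean", "max"),
                          distance = c("cosine", "euclidean"),
                          weight_decay = 1e-6, batch_size = 1000,
                          n_epochs = 100, gamma = 0.05, margin = 1,
                          learning_rate = 1e-3, seed = 1,
                          variant = c("full", "attention_only", "feedforward_only"),
                          layernorm_eps = 1e-6, ff_residual = TRUE,
                          contrastive_literal = FALSE,
                          weight_contrastive = FALSE) {
  pooling_mode <- match.arg(pooling_mode)
  distance <- match.arg(distance)
  variant <- match.arg(variant)
  stopifnot(n_heads >= 1, n_units >= 1, model_dim >= 1, mlp_factor >= 1,
            dropout >= 0, dropout < 1, weight_decay >= 0, batch_size >= 1,
            n_epochs >= 1, margin > 0, learning_rate > 0, layernorm_eps > 0)
  if (gamma <= 0 || gamma >= 1)
    stop("gamma must lie strictly in (0, 1)", call. = FALSE)
  structure(list(n_heads = as.integer(n_heads), n_units = as.integer(n_units),
                 model_dim = as.integer(model_dim),
                 mlp_factor = as.integer(mlp_factor), dropout = dropout,
                 pooling_mode = pooling_mode, distance = distance,
                 weight_decay = weight_decay, batch_size = as.integer(batch_size),
                 n_epochs = as.integer(n_epochs), gamma = gamma, margin = margin,
                 learning_rate = learning_rate, seed = as.integer(seed),
                 variant = variant, layernorm_eps = layernorm_eps,
                 ff_residual = isTRUE(ff_residual),
                 contrastive_literal = isTRUE(contrastive_literal),
                 weight_contrastive = isTRUE(weight_contrastive)),
            class = "ddinet_config")
}

#' @export
print.ddinet_config <- function(x, ...) {
  cat("ddinet config (", x$variant, "): H=", x$n_heads, " E=", x$n_units,
      " d'=", x$model_dim, " xi=", x$mlp_factor, " dropout=", x$dropout,
      " pool=", x$pooling_mode, " dist=", x$distance, "\n",
      "  lambda=", x$weight_decay, " batch=", x$batch_size,
      " epochs=", x$n_epochs, " gamma=", x$gamma, " mu=", x$margin,
      " lr=", x$learning_rate, " seed=", x$seed, "\n", sep = "")
  invisible(x)
}

#' Benchmark hyperparameter presets
#'
#' Returns the reference per-dataset training configuration for the four
#' benchmark datasets (548-drug multi-modal, 707-drug chemical-only, and
#' the 807-drug set with CYP or non-CYP labels).
#'
#' @param name One of \code{"ds1"}, \code{"ds2"}, \code{"ds3cyp"},
#'   \code{"ds3ncyp"}.
#' @param ... Overrides passed on to \code{\link{ddinet_config}} (for
#'   example \code{model_dim} or \code{seed}).
#' @return A \code{ddinet_config}.
#' @export
ddinet_preset <- function(name = c("ds1", "ds2", "ds3cyp", "ds3ncyp"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    ds1     = list(n_heads = 2, n_units = 1, dropout = 0.30, weight_decay = 1e-6,
                   batch_size = 1000, n_epochs = 100),
    ds2     = list(n_heads = 2, n_units = 1, dropout = 0.30, weight_decay = 1e-6,
                   batch_size = 1000, n_epochs = 100),
    ds3cyp  = list(n_heads = 4, n_units = 1, dropout = 0.45, weight_decay = 1e-8,
                   batch_size = 400, n_epochs = 200),
    ds3ncyp = list(n_heads = 2, n_units = 1, dropout = 0.30, weight_decay = 1e-6,
                   batch_size = 1000, n_epochs = 100))
  shared <- list(mlp_factor = 2, pooling_mode = "attn", distance = "cosine",
                 gamma = 0.05, margin = 1)
  do.call(ddinet_config, utils::modifyList(c(base, shared), list(...)))
}

#' Read / write a configuration file
#'
#' Configurations are stored as flat YAML or JSON with keys matching the
#' \code{\link{ddinet_config}} arguments. Unknown keys are an error.
#'
#' @param path File ending in \code{.yaml}/\code{.yml} or \code{.json}.
#' @param config A \code{ddinet_config} (for writing).
#' @return \code{read_ddinet_config} returns a \code{ddinet_config}.
#' @export
read_ddinet_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(ddinet_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(ddinet_config, vals)
}

#' @rdname read_ddinet_config
#' @export
write_ddinet_config <- function(config, path) {
  stopifnot(inherits(config, "ddinet_config"))
  vals <- unclass(config)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(vals, path)
  else jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}
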