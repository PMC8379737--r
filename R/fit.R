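# Model fitting: mini-batch Adam training with validation-AUPR model
# selection, and the S3 interface of the fitted model.

#' Fit a Siamese attention DDI model
#'
#' Trains the selected variant on the training pairs of a
#' \code{\link{ddi_dataset}} by mini-batch Adam under the joint objective
#' \eqn{\gamma L^C + (1-\gamma) L^{Dist} + \frac{\lambda}{2}\|\theta\|^2},
#' with examples weighted inversely proportional to class frequency. After
#' every epoch the model is scored on the validation pairs; the parameters
#' from the epoch with the best validation AUPR (earliest on ties) are
#' kept.
#'
#' When the dataset was assembled with \code{use_gip = TRUE} the GIP
#' modality is computed here from the training labels: by default label
#' entries of pairs outside the training+validation portion are zeroed
#' before the kernel is built (\code{gip = "train"}), which keeps held-out
#' labels out of the input features; \code{gip = "full"} reproduces the
#' label-matrix-wide construction.
#'
#' @param data A \code{\link{ddi_dataset}}.
#' @param config A \code{\link{ddinet_config}}.
#' @param train_idx,val_idx Integer indices into \code{data$pairs}. When
#'   missing, a stratified validation split of
#'   \code{val_fraction} is drawn from all pairs.
#' @param gip \code{"train"} or \code{"full"}, see Details.
#' @param val_fraction Fraction used for the automatic validation split.
#' @param verbose Print per-epoch progress.
#' @return Object of class \code{ddinet} with elements \code{params} (best
#'   epoch), \code{final_params}, \code{best_epoch}, \code{log} (per-epoch
#'   losses and validation metrics), \code{inputs} (the T modality input
#'   matrices used, GIP included), \code{config}, and the index sets.
#' @seealso \code{\link{ddinet_cv}}, \code{\link{predict.ddinet}}
#' @export
ddinet <- function(data, config = ddinet_config(), train_idx = NULL,
                   val_idx = NULL, gip = c("train", "full"),
                   val_fraction = 0.10, verbose = FALSE) {
  stopifnot(inherits(data, "ddi_dataset"), inherits(config, "ddinet_config"))
  gip <- match.arg(gip)
  K <- nrow(data$pairs)
  y_all <- data$y
  if (is.null(train_idx)) train_idx <- seq_len(K)
  if (is.null(val_idx)) {
    val_idx <- with_seed(config$seed + 97L, {
      unlist(lapply(c(1L, 0L), function(cls) {
        pool <- train_idx[y_all[train_idx] == cls]
        pool[sample.int(length(pool),
                        max(1L, round(val_fraction * length(pool))))]
      }))
    })
    train_idx <- setdiff(train_idx, val_idx)
  }
  if (length(intersect(train_idx, val_idx)))
    stop("train_idx and val_idx overlap", call. = FALSE)
  if (length(unique(y_all[train_idx])) < 2L ||
      length(unique(y_all[val_idx])) < 2L)
    stop("both classes must be present in the training and validation sets",
         call. = FALSE)

  inputs <- data$modalities
  if (data$use_gip) {
    lab <- data$labels
    if (gip == "train") {
      hid <- setdiff(seq_len(K), c(train_idx, val_idx))
      if (length(hid)) {
        ij <- data$pairs[hid, , drop = FALSE]
        lab[ij] <- 0
        lab[ij[, 2:1, drop = FALSE]] <- 0
      }
    }
    inputs <- c(inputs, list(GIP = build_gip_matrix(lab, data$gip_bandwidth)))
  }
  d <- ncol(inputs[[1]])
  Tn <- length(inputs)
  cw <- class_weights(y_all[train_idx])
  n_drugs <- length(data$drug_ids)

  with_seed(config$seed, {
    par <- init_ddinet_params(config, d, Tn)
    st <- adam_init(par)
    best <- list(aupr = -Inf, par = par, epoch = 0L)
    log <- vector("list", config$n_epochs)
    for (epoch in seq_len(config$n_epochs)) {
      ord <- sample(train_idx)
      nb <- ceiling(length(ord) / config$batch_size)
      eC <- 0; eD <- 0; eT <- 0; nseen <- 0
      for (b in seq_len(nb)) {
        idx <- ord[((b - 1L) * config$batch_size + 1L):
                     min(b * config$batch_size, length(ord))]
        pi <- data$pairs[idx, , drop = FALSE]
        yb <- y_all[idx]
        if (config$variant == "full") {
          drugs <- sort(unique(c(pi)))
          pos <- integer(n_drugs); pos[drugs] <- seq_along(drugs)
          ia <- pos[pi[, 1]]; ib <- pos[pi[, 2]]
          fw <- enc_forward(pair_inputs(inputs, drugs), par, config,
                            training = TRUE)
          cf <- cls_forward(fw$Z, ia, ib, par, config)
          lg <- full_loss_grad(cf, yb, cw, par, config)
          grads <- enc_backward(scatter_dz(lg$dza, lg$dzb, ia, ib,
                                           length(drugs)), fw, par, config)
          grads$W_out <- lg$dW_out
          grads$b_out <- lg$db_out
          lossC <- lg$loss_C; lossD <- lg$loss_D; lossT <- lg$loss
        } else if (config$variant == "attention_only") {
          fw <- enc_forward(pairset_inputs(inputs, pi[, 1], pi[, 2]), par,
                            config, training = TRUE)
          logits <- addrow(fw$Z %*% t(par$W_out), par$b_out)
          sg <- softmax_nll_grad(logits, yb, cw)
          grads <- enc_backward(sg$dlog %*% par$W_out, fw, par, config)
          grads$W_out <- crossprod(sg$dlog, fw$Z)
          grads$b_out <- colSums(sg$dlog)
          lossC <- sg$loss_C; lossD <- 0
          lossT <- lossC + config$weight_decay / 2 *
            sum(vapply(par, function(p) sum(p^2), numeric(1)))
        } else {
          x <- ff_input(inputs, pi[, 1], pi[, 2])
          h1 <- pmax(addrow(x %*% t(par$ff_W1), par$ff_b1), 0)
          logits <- addrow(h1 %*% t(par$ff_W2), par$ff_b2)
          sg <- softmax_nll_grad(logits, yb, cw)
          dh1 <- (sg$dlog %*% par$ff_W2) * (h1 > 0)
          grads <- list(ff_W2 = crossprod(sg$dlog, h1),
                        ff_b2 = colSums(sg$dlog),
                        ff_W1 = crossprod(dh1, x),
                        ff_b1 = colSums(dh1))
          lossC <- sg$loss_C; lossD <- 0
          lossT <- lossC + config$weight_decay / 2 *
            sum(vapply(par, function(p) sum(p^2), numeric(1)))
        }
        if (!is.finite(lossT))
          stop("training diverged (non-finite loss) at epoch ", epoch,
               ", batch ", b, "; consider lowering the learning rate",
               call. = FALSE)
        if (config$weight_decay > 0)
          for (nmp in names(par))
            grads[[nmp]] <- (grads[[nmp]] %||% 0) + config$weight_decay * par[[nmp]]
        upd <- adam_step(par, grads, st, config$learning_rate)
        par <- upd$par; st <- upd$state
        nidx <- length(idx)
        eC <- eC + lossC * nidx; eD <- eD + lossD * nidx
        eT <- eT + lossT * nidx; nseen <- nseen + nidx
      }
      vp <- predict_probs(par, config, inputs,
                          data$pairs[val_idx, , drop = FALSE],
                          symmetrize = FALSE)
      va <- auc_roc(vp, y_all[val_idx])
      vpr <- aupr(vp, y_all[val_idx])
      log[[epoch]] <- data.frame(epoch = epoch, loss_C = eC / nseen,
                                 loss_dist = eD / nseen,
                                 loss_total = eT / nseen,
                                 val_aupr = vpr, val_auc = va)
      if (vpr > best$aupr)
        best <- list(aupr = vpr, par = par, epoch = epoch)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val AUPR %.4f  val AUC %.4f",
                        epoch, eT / nseen, vpr, va))
    }
    structure(list(params = best$par, final_params = par,
                   best_epoch = best$epoch, best_val_aupr = best$aupr,
                   log = do.call(rbind, log), config = config,
                   inputs = inputs, drug_ids = data$drug_ids,
                   modality_names = names(inputs),
                   train_idx = sort(train_idx), val_idx = sort(val_idx),
                   class_weights = cw, gip = if (data$use_gip) gip else "none",
                   n_params = sum(vapply(par, length, integer(1)))),
              class = "ddinet")
  })
}

#' Train the model on one cross-validation fold
#'
#' Convenience wrapper selecting the training/validation pairs of fold
#' \code{fold_id} from a fold plan and fitting \code{\link{ddinet}}.
#'
#' @param data A \code{\link{ddi_dataset}}.
#' @param folds A \code{\link{make_folds}} plan.
#' @param fold_id Test fold index in \code{1..n_folds}.
#' @param config A \code{\link{ddinet_config}}.
#' @param ... Passed to \code{\link{ddinet}}.
#' @return A \code{ddinet} model with \code{fold_id} and \code{test_idx}
#'   recorded.
#' @export
train_fold <- function(data, folds, fold_id, config = ddinet_config(), ...) {
  stopifnot(inherits(folds, "ddi_folds"), fold_id >= 1,
            fold_id <= folds$n_folds)
  test_idx <- which(folds$fold == fold_id)
  val_idx <- folds$val[[fold_id]]
  train_idx <- setdiff(which(folds$fold != fold_id), val_idx)
  fit <- ddinet(data, config, train_idx = train_idx, val_idx = val_idx, ...)
  fit$fold_id <- as.integer(fold_id)
  fit$test_idx <- test_idx
  fit
}

#' Predict interaction probabilities
#'
#' @param object A fitted \code{ddinet} model.
#' @param pairs Pairs to score: an n x 2 integer matrix of drug indices, a
#'   character matrix of drug ids, or an integer vector of row indices into
#'   the dataset's pair enumeration. Defaults to the model's test pairs
#'   when it was trained on a fold, otherwise to its validation pairs.
#' @param dataset Optional \code{ddi_dataset} supplying the pair
#'   enumeration for vector-form \code{pairs}.
#' @param type \code{"prob"} for interaction probabilities,
#'   \code{"class"} for 0/1 at threshold 0.5.
#' @param symmetrize Average the class probabilities over both
#'   concatenation orders so that score(a, b) = score(b, a) exactly.
#' @param ... Unused.
#' @return Numeric (or integer) vector of length \code{nrow(pairs)}.
#' @export
predict.ddinet <- function(object, pairs = NULL, dataset = NULL,
                           type = c("prob", "class"), symmetrize = TRUE, ...) {
  type <- match.arg(type)
  pm <- resolve_pairs(object, pairs, dataset)
  p <- predict_probs(object$params, object$config, object$inputs, pm,
                     symmetrize = symmetrize)
  if (type == "class") as.integer(p >= 0.5) else p
}

resolve_pairs <- function(object, pairs, dataset = NULL) {
  n <- length(object$drug_ids)
  if (is.null(pairs)) {
    idx <- object$test_idx %||% object$val_idx
    return(enumerate_pairs(n)[idx, , drop = FALSE])
  }
  if (is.matrix(pairs) && ncol(pairs) == 2L) {
    if (is.character(pairs)) {
      m <- matrix(match(pairs, object$drug_ids), ncol = 2L)
      if (anyNA(m)) stop("unknown drug ids in `pairs`", call. = FALSE)
      return(m)
    }
    return(pairs)
  }
  pe <- if (!is.null(dataset)) dataset$pairs else enumerate_pairs(n)
  pe[as.integer(pairs), , drop = FALSE]
}

#' @export
print.ddinet <- function(x, ...) {
  cat("ddinet model (", x$config$variant, "), ", length(x$drug_ids),
      " drugs, ", length(x$modality_names), " modalities [",
      paste(x$modality_names, collapse = ", "), "]\n", sep = "")
  cat(sprintf("  %d parameters; best epoch %d/%d (val AUPR %.4f)\n",
              x$n_params, x$best_epoch, x$config$n_epochs, x$best_val_aupr))
  invisible(x)
}

#' @export
summary.ddinet <- function(object, ...) {
  print(object)
  print(object$config)
  n <- nrow(object$log)
  cat("final epoch losses: total", sprintf("%.4f", object$log$loss_total[n]),
      "(NLL", sprintf("%.4f", object$log$loss_C[n]),
      "| contrastive", sprintf("%.4f", object$log$loss_dist[n]), ")\n")
  invisible(object)
}

#' @export
coef.ddinet <- function(object, ...) object$params

#' @export
plot.ddinet <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(x$log$epoch, x$log$loss_total, type = "l", xlab = "epoch",
       ylab = "training loss", main = "objective", ...)
  plot(x$log$epoch, x$log$val_aupr, type = "l", xlab = "epoch",
       ylab = "validation AUPR", main = "model selection", ...)
  graphics::abline(v = x$best_epoch, lty = 2)
  invisible(x)
}

#' Encode drugs with a fitted model
#'
#' Runs the encoder of a fitted full-variant model over the stored modality
#' inputs and returns the drug representations, optionally with the
#' attention traces needed for modality attribution.
#'
#' @param object A fitted \code{ddinet} model (\code{variant = "full"}).
#' @param drugs Integer indices of drugs to encode (default all).
#' @param capture_trace Also return self-attention matrices and pooling
#'   weights.
#' @return List with \code{z} (n x d' matrix) and, when requested,
#'   \code{psi} (n x T pooling weights) and \code{attn} (list over
#'   unit/head of n x T x T self-attention arrays).
#' @export
ddi_encode <- function(object, drugs = NULL, capture_trace = TRUE) {
  stopifnot(inherits(object, "ddinet"))
  if (object$config$variant != "full")
    stop("per-drug encoding requires the full Siamese variant", call. = FALSE)
  drugs <- drugs %||% seq_along(object$drug_ids)
  fw <- enc_forward(pair_inputs(object$inputs, drugs), object$params,
                    object$config, capture = capture_trace)
  if (!capture_trace) return(list(z = fw$Z))
  list(z = fw$Z, psi = fw$trace$psi, attn = fw$trace$attn)
}
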