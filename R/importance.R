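# Modality importance attribution: aggregation of captured attention
# scores, and the masking-ablation experiment that retrains the model with
# one modality removed at a time.

#' Modality importance from one drug's attention trace
#'
#' Combines a drug's feature-attention weights with its self-attention
#' matrices: the T x T attention matrices are averaged over all heads and
#' encoder units and premultiplied by the (row-vector) pooling weights,
#' \eqn{ModalityImp^{Attn} = featAttn \cdot (\frac{1}{E}\sum_e
#' \frac{1}{H}\sum_h Attn^{[h,e]})}. With row-stochastic attention and a
#' simplex featAttn the result is itself a probability vector over the T
#' modalities.
#'
#' @param featAttn Length-T pooling weight vector \eqn{\psi}.
#' @param attn_mats List (over unit/head) of T x T row-stochastic attention
#'   matrices.
#' @return Length-T importance vector.
#' @export
modality_importance_from_trace <- function(featAttn, attn_mats) {
  if (!is.list(attn_mats)) attn_mats <- list(attn_mats)
  Tn <- length(featAttn)
  if (!all(vapply(attn_mats, function(A) all(dim(A) == Tn), logical(1))))
    stop("attention matrices must be T x T with T = length(featAttn)",
         call. = FALSE)
  avg <- Reduce(`+`, attn_mats) / length(attn_mats)
  drop(rbind(featAttn) %*% avg)
}

#' Attention-based modality importance
#'
#' Aggregates the attention traces of a fitted model over drug pairs: each
#' drug's importance vector is \code{\link{modality_importance_from_trace}}
#' applied to its trace, each pair's vector is the mean of its two drugs'
#' vectors, and the report is the mean over all scored pairs. For a
#' \code{ddinet_cv} object the average runs over the test pairs of all
#' folds, each scored by its fold's model.
#'
#' @param object A fitted \code{ddinet} (full variant, attention pooling)
#'   or a \code{ddinet_cv} whose models were kept.
#' @param pairs Pairs over which to average (defaults to the model's test
#'   or validation pairs; ignored for \code{ddinet_cv}).
#' @param ... Unused.
#' @return Named length-T numeric vector summing to 1.
#' @export
attention_importance <- function(object, ...) UseMethod("attention_importance")

#' @rdname attention_importance
#' @export
attention_importance.ddinet <- function(object, pairs = NULL, ...) {
  if (object$config$variant != "full" || object$config$pooling_mode != "attn")
    stop("attention importance requires the full variant with attention pooling",
         call. = FALSE)
  pm <- resolve_pairs(object, pairs)
  drugs <- sort(unique(c(pm)))
  tr <- ddi_encode(object, drugs, capture_trace = TRUE)
  # per-drug importance: psi_i %*% mean_over_{e,h}(Attn_i)
  avg <- Reduce(`+`, tr$attn) / length(tr$attn)       # n x T x T
  Tn <- ncol(tr$psi)
  imp <- matrix(0, nrow(tr$psi), Tn)
  for (l in seq_len(Tn))
    imp[, l] <- rowSums(tr$psi * avg[, , l])          # sum_t psi_t Attn[t, l]
  pos <- match(seq_along(object$drug_ids), drugs)
  v <- (imp[pos[pm[, 1]], , drop = FALSE] +
        imp[pos[pm[, 2]], , drop = FALSE]) / 2
  out <- colMeans(v)
  names(out) <- object$modality_names
  out
}

#' @rdname attention_importance
#' @export
attention_importance.ddinet_cv <- function(object, ...) {
  if (is.null(object$models))
    stop("cross-validation was run with keep_models = FALSE", call. = FALSE)
  tot <- 0; n <- 0
  for (fit in object$models) {
    pm <- enumerate_pairs(length(fit$drug_ids))[fit$test_idx, , drop = FALSE]
    tot <- tot + attention_importance(fit, pairs = pm) * nrow(pm)
    n <- n + nrow(pm)
  }
  tot / n
}

#' Masking-ablation modality importance
#'
#' For each modality, retrains the cross-validated model with that modality
#' removed from the input set (sharing the fold plan and seeds with the
#' base run) and reports the relative change in performance per fold,
#' \eqn{(metric_{base} - metric_{masked}) / metric_{base}}, averaged over
#' folds, for AUC and AUPR, together with their average. The higher the
#' relative change, the more the model depended on the masked modality.
#' \code{method = "zero"} is a cheap alternative that keeps the base
#' models and zeroes the masked modality's input vectors at test time.
#'
#' @param data A \code{\link{ddi_dataset}}.
#' @param config A \code{\link{ddinet_config}}.
#' @param n_folds,val_fraction,seed,gip As in \code{\link{ddinet_cv}}.
#' @param method \code{"retrain"} (reference procedure) or \code{"zero"}.
#' @param base A precomputed base \code{ddinet_cv} to compare against
#'   (must have been run with the same fold plan); computed when missing.
#' @param verbose Print progress.
#' @return Object of class \code{ddi_importance}: data frame with columns
#'   \code{modality}, \code{rel_change_auc}, \code{rel_change_aupr},
#'   \code{avg_rel_change}, plus the base run in \code{attr(, "base")}.
#' @export
masking_importance <- function(data, config = ddinet_config(), n_folds = 10,
                               val_fraction = 0.10, seed = NULL,
                               gip = c("train", "full"),
                               method = c("retrain", "zero"), base = NULL,
                               verbose = FALSE) {
  stopifnot(inherits(data, "ddi_dataset"))
  method <- match.arg(method)
  gip <- match.arg(gip)
  n_mod <- length(data$modalities) + data$use_gip
  if (n_mod < 2L)
    stop("masking requires at least two modalities", call. = FALSE)
  if (is.null(base))
    base <- ddinet_cv(data, config, n_folds = n_folds,
                      val_fraction = val_fraction, seed = seed, gip = gip,
                      keep_models = (method == "zero"), verbose = verbose)
  mod_names <- c(names(data$modalities), if (data$use_gip) "GIP")
  rows <- vector("list", n_mod)
  for (m in seq_len(n_mod)) {
    if (verbose) message("masking modality: ", mod_names[m])
    if (method == "retrain") {
      data_m <- data
      if (m > length(data$modalities)) data_m$use_gip <- FALSE
      else data_m$modalities <- data$modalities[-m]
      cv_m <- ddinet_cv(data_m, config, n_folds = n_folds,
                        val_fraction = val_fraction, seed = seed, gip = gip,
                        keep_models = FALSE)
      auc_m <- cv_m$per_fold$auc
      aupr_m <- cv_m$per_fold$aupr
    } else {
      auc_m <- aupr_m <- numeric(base$folds$n_folds)
      for (f in seq_len(base$folds$n_folds)) {
        fit <- base$models[[f]]
        inp <- fit$inputs
        inp[[m]][] <- 0
        test_idx <- fit$test_idx
        pm <- enumerate_pairs(length(fit$drug_ids))[test_idx, , drop = FALSE]
        sc <- predict_probs(fit$params, fit$config, inp, pm)
        yb <- data$y[test_idx]
        auc_m[f] <- auc_roc(sc, yb)
        aupr_m[f] <- aupr(sc, yb)
      }
    }
    rel_auc <- mean((base$per_fold$auc - auc_m) / base$per_fold$auc)
    rel_aupr <- mean((base$per_fold$aupr - aupr_m) / base$per_fold$aupr)
    rows[[m]] <- data.frame(modality = mod_names[m],
                            rel_change_auc = rel_auc,
                            rel_change_aupr = rel_aupr,
                            avg_rel_change = (rel_auc + rel_aupr) / 2)
  }
  out <- do.call(rbind, rows)
  attr(out, "base") <- base
  attr(out, "method") <- method
  class(out) <- c("ddi_importance", class(out))
  out
}

#' Top-k agreement between two importance rankings
#'
#' @param a,b Equal-length importance vectors (higher = more important).
#' @param k Size of the compared top sets.
#' @return Integer size of the intersection of the two top-k index sets.
#' @export
ranking_agreement <- function(a, b, k = 3) {
  if (length(a) != length(b))
    stop("importance vectors have different lengths", call. = FALSE)
  if (k > length(a))
    stop("k exceeds the number of modalities", call. = FALSE)
  top <- function(v) order(v, decreasing = TRUE)[seq_len(k)]
  length(intersect(top(a), top(b)))
}
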