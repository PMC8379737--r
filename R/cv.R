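# Stratified 10-fold cross-validation workflow and random hyperparameter
# search with validation-AUPR selection.

#' Cross-validated training and evaluation
#'
#' Builds a stratified fold plan, trains one model per fold (each with its
#' own stratified validation subset for epoch selection), scores every
#' pair exactly once as a member of its test fold, and summarises AUC and
#' AUPR per fold. Mean-over-folds metrics are the primary summary; pooled
#' metrics over all test predictions are also reported.
#'
#' @param data A \code{\link{ddi_dataset}}.
#' @param config A \code{\link{ddinet_config}}; fold f is trained with seed
#'   \code{config$seed + f} so folds are independent but reproducible.
#' @param n_folds Number of folds (default 10).
#' @param val_fraction Validation fraction within each training portion.
#' @param seed Seed for the fold plan (defaults to \code{config$seed}).
#' @param gip GIP construction mode, see \code{\link{ddinet}}.
#' @param keep_models Keep the per-fold fitted models in the result.
#' @param verbose Print per-fold progress.
#' @return Object of class \code{ddinet_cv}: \code{predictions} (data frame
#'   with drug indices, label, fold, score), \code{per_fold} metrics,
#'   \code{mean_auc}, \code{mean_aupr}, \code{pooled} metric report,
#'   \code{folds}, and (optionally) \code{models}.
#' @export
ddinet_cv <- function(data, config = ddinet_config(), n_folds = 10,
                      val_fraction = 0.10, seed = NULL,
                      gip = c("train", "full"), keep_models = TRUE,
                      verbose = FALSE) {
  stopifnot(inherits(data, "ddi_dataset"))
  gip <- match.arg(gip)
  seed <- seed %||% config$seed
  folds <- make_folds(data, n_folds = n_folds, val_fraction = val_fraction,
                      seed = seed)
  models <- vector("list", n_folds)
  preds <- vector("list", n_folds)
  per_fold <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    cfg_f <- config
    cfg_f$seed <- config$seed + f
    fit <- train_fold(data, folds, f, cfg_f, gip = gip, verbose = verbose)
    test_idx <- fit$test_idx
    sc <- predict_probs(fit$params, cfg_f, fit$inputs,
                        data$pairs[test_idx, , drop = FALSE])
    preds[[f]] <- data.frame(i = data$pairs[test_idx, 1],
                             j = data$pairs[test_idx, 2],
                             label = data$y[test_idx], fold = f, score = sc)
    per_fold[[f]] <- data.frame(fold = f,
                                auc = auc_roc(sc, data$y[test_idx]),
                                aupr = aupr(sc, data$y[test_idx]),
                                best_epoch = fit$best_epoch,
                                val_aupr = fit$best_val_aupr)
    if (verbose)
      message(sprintf("fold %2d: test AUC %.4f AUPR %.4f (best epoch %d)",
                      f, per_fold[[f]]$auc, per_fold[[f]]$aupr,
                      fit$best_epoch))
    models[[f]] <- if (keep_models) fit else NULL
  }
  predictions <- do.call(rbind, preds)
  per_fold <- do.call(rbind, per_fold)
  structure(list(predictions = predictions, per_fold = per_fold,
                 mean_auc = mean(per_fold$auc),
                 mean_aupr = mean(per_fold$aupr),
                 pooled = metric_report(predictions$score, predictions$label),
                 folds = folds, config = config,
                 models = if (keep_models) models else NULL,
                 modality_names = if (keep_models) models[[1]]$modality_names
                                  else names(data$modalities)),
            class = "ddinet_cv")
}

#' @export
print.ddinet_cv <- function(x, ...) {
  cat("ddinet cross-validation (", x$folds$n_folds, " folds, variant ",
      x$config$variant, ")\n", sep = "")
  cat(sprintf("  mean over folds: AUC %.4f  AUPR %.4f\n",
              x$mean_auc, x$mean_aupr))
  cat(sprintf("  pooled:          AUC %.4f  AUPR %.4f\n",
              x$pooled$auc, x$pooled$aupr))
  invisible(x)
}

#' @export
summary.ddinet_cv <- function(object, ...) {
  print(object)
  print(object$per_fold, row.names = FALSE)
  invisible(object)
}

#' Random hyperparameter search on one fold
#'
#' Samples \code{n_trials} configurations uniformly from a discrete search
#' space, trains each on one randomly chosen fold of the plan, and returns
#' the configuration with the best validation AUPR.
#'
#' @param data A \code{\link{ddi_dataset}}.
#' @param space Named list of candidate values, e.g.
#'   \code{list(n_heads = c(1, 2, 4), dropout = c(0.3, 0.45))}; names must
#'   be \code{\link{ddinet_config}} arguments.
#' @param n_trials Number of sampled configurations.
#' @param config Base configuration supplying unsearched values.
#' @param n_folds Folds in the plan from which the single training fold is
#'   drawn.
#' @param seed Seed controlling the fold choice and the trial sequence.
#' @param ... Passed to \code{\link{train_fold}}.
#' @return List with \code{best_config}, \code{fold_id} and a \code{trials}
#'   data frame (sampled values and validation AUPR per trial).
#' @export
random_search <- function(data, space, n_trials, config = ddinet_config(),
                          n_folds = 10, seed = 1, ...) {
  if (!length(space) || !all(lengths(space) >= 1L))
    stop("`space` must be a non-empty named list of candidate values",
         call. = FALSE)
  bad <- setdiff(names(space), names(formals(ddinet_config)))
  if (length(bad))
    stop("unknown hyperparameters in space: ", paste(bad, collapse = ", "),
         call. = FALSE)
  folds <- make_folds(data, n_folds = n_folds, seed = seed)
  draws <- with_seed(seed, {
    fold_id <- sample.int(n_folds, 1L)
    trials <- lapply(seq_len(n_trials), function(i)
      lapply(space, function(v) v[[sample.int(length(v), 1L)]]))
    list(fold_id = fold_id, trials = trials)
  })
  rows <- vector("list", n_trials)
  best <- list(aupr = -Inf, config = NULL)
  for (i in seq_len(n_trials)) {
    cfg <- do.call(ddinet_config,
                   utils::modifyList(unclass(config), draws$trials[[i]]))
    # a degenerate draw (e.g. an absurd learning rate) may diverge; record
    # the trial as failed instead of aborting the search
    fit <- tryCatch(train_fold(data, folds, draws$fold_id, cfg, ...),
                    error = function(e) NULL)
    va <- if (is.null(fit)) NA_real_ else fit$best_val_aupr
    rows[[i]] <- data.frame(trial = i, as.data.frame(draws$trials[[i]]),
                            val_aupr = va)
    if (!is.na(va) && va > best$aupr)
      best <- list(aupr = va, config = cfg)
  }
  list(best_config = best$config, fold_id = draws$fold_id,
       trials = do.call(rbind, rows))
}
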