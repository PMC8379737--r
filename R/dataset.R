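# Pair-level dataset assembly: enumerate unordered drug pairs, attach
# per-modality input vectors and labels, build stratified CV folds and
# inverse-frequency class weights.

#' Enumerate all unordered drug pairs
#'
#' @param n_drugs Number of drugs N (>= 2).
#' @return An integer matrix with \eqn{K = N(N-1)/2} rows and columns
#'   \code{i}, \code{j}, lexicographically ordered with \code{i < j}
#'   (1-based indices).
#' @examples
#' nrow(enumerate_pairs(548)) # 149878
#' @export
enumerate_pairs <- function(n_drugs) {
  if (length(n_drugs) != 1L || n_drugs != as.integer(n_drugs) || n_drugs < 2)
    stop("n_drugs must be a single integer >= 2", call. = FALSE)
  n <- as.integer(n_drugs)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  cbind(i = i, j = j)
}

#' Assemble a pair-level DDI dataset from similarity matrices and labels
#'
#' Binds T modality similarity matrices and the binary label matrix into one
#' object holding the \eqn{K = \binom{N}{2}} unordered drug pairs and their
#' labels (the upper triangle of the symmetrised label matrix). The GIP
#' modality is not precomputed here: because it is derived from the labels
#' themselves, it is built at fit time from training labels only (or from
#' the full matrix when explicitly requested), see \code{\link{ddinet}}.
#'
#' @param modalities Named list of N x N similarity matrices sharing
#'   identical drug ids and order.
#' @param labels N x N binary label matrix (symmetrised by OR, diagonal
#'   ignored).
#' @param use_gip Logical; append the GIP kernel of the label matrix as an
#'   extra modality at fit time.
#' @param gip_bandwidth Bandwidth scale passed to
#'   \code{\link{build_gip_matrix}}.
#' @return An object of class \code{ddi_dataset} with elements
#'   \code{drug_ids}, \code{modalities}, \code{labels}, \code{pairs},
#'   \code{y}, \code{use_gip}.
#' @export
ddi_dataset <- function(modalities, labels, use_gip = TRUE, gip_bandwidth = 1) {
  if (is.matrix(modalities)) modalities <- list(modalities)
  if (length(modalities) < 1L) stop("need at least one modality", call. = FALSE)
  labels <- validate_label_matrix(labels)
  ids <- rownames(labels)
  if (is.null(names(modalities)) || any(names(modalities) == ""))
    names(modalities) <- vapply(seq_along(modalities), function(t)
      attr(modalities[[t]], "modality") %||% paste0("modality", t), character(1))
  if (anyDuplicated(names(modalities)))
    names(modalities) <- make.unique(names(modalities))
  for (t in seq_along(modalities)) {
    m <- as.matrix(modalities[[t]])
    assert_similarity_matrix(m, name = paste0("modality '", names(modalities)[t], "'"))
    mids <- rownames(m) %||% ids
    if (nrow(m) != nrow(labels) || !identical(mids, ids))
      stop("drug ids of modality '", names(modalities)[t],
           "' do not match the label matrix", call. = FALSE)
    dimnames(m) <- list(ids, ids)
    modalities[[t]] <- m
  }
  pairs <- enumerate_pairs(nrow(labels))
  y <- labels[pairs]
  structure(list(drug_ids = ids, modalities = modalities, labels = labels,
                 pairs = pairs, y = as.integer(y), use_gip = isTRUE(use_gip),
                 gip_bandwidth = gip_bandwidth),
            class = "ddi_dataset")
}

#' @export
print.ddi_dataset <- function(x, ...) {
  cat("DDI pair dataset:", length(x$drug_ids), "drugs,",
      nrow(x$pairs), "pairs,", length(x$modalities), "modalities",
      if (x$use_gip) "(+ GIP at fit time)" else "", "\n")
  cat("  modalities:", paste(names(x$modalities), collapse = ", "), "\n")
  cat(sprintf("  known DDIs: %d (%.2f%%)\n", sum(x$y), 100 * mean(x$y)))
  invisible(x)
}

#' Stratified cross-validation folds over drug pairs
#'
#' Pairs are partitioned into \code{n_folds} test folds preserving the
#' positive-label proportion; within each fold's training portion a
#' stratified validation subset of \code{val_fraction} is reserved for
#' model selection. Splits are at the pair level (drugs are not held out),
#' so both drugs of a test pair may occur in training pairs.
#'
#' @param dataset A \code{ddi_dataset}, or a 0/1 label vector.
#' @param n_folds Number of folds (default 10).
#' @param val_fraction Fraction of each training portion used for
#'   validation (default 0.10).
#' @param seed Integer seed; the plan is deterministic given the seed.
#' @return Object of class \code{ddi_folds}: \code{fold} (per-pair test-fold
#'   index) and \code{val} (per-fold validation index vectors).
#' @export
make_folds <- function(dataset, n_folds = 10, val_fraction = 0.10, seed = 1) {
  y <- if (inherits(dataset, "ddi_dataset")) dataset$y else as.integer(dataset)
  K <- length(y)
  npos <- sum(y == 1); nneg <- sum(y == 0)
  if (npos < n_folds || nneg < n_folds)
    stop("need at least n_folds pairs of each class for stratification",
         call. = FALSE)
  fold <- integer(K)
  with_seed(seed, {
    for (cls in c(1L, 0L)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    val <- lapply(seq_len(n_folds), function(f) {
      tr <- which(fold != f)
      v <- unlist(lapply(c(1L, 0L), function(cls) {
        pool <- tr[y[tr] == cls]
        pool[sample.int(length(pool),
                        max(1L, round(val_fraction * length(pool))))]
      }))
      sort(v)
    })
    structure(list(n_folds = as.integer(n_folds), fold = fold, val = val,
                   val_fraction = val_fraction, seed = seed),
              class = "ddi_folds")
  })
}

#' @export
print.ddi_folds <- function(x, ...) {
  cat("Stratified fold plan:", x$n_folds, "folds over", length(x$fold),
      "pairs (val fraction", x$val_fraction, ", seed", x$seed, ")\n")
  invisible(x)
}

#' Inverse-frequency class weights
#'
#' Training examples are weighted inversely proportional to class frequency,
#' normalised so the mean per-example weight is 1:
#' \eqn{w_c = K / (2 n_c)}.
#'
#' @param labels 0/1 vector.
#' @return Named numeric vector \code{c("0" = w0, "1" = w1)}.
#' @export
class_weights <- function(labels) {
  labels <- as.integer(labels)
  counts <- c(sum(labels == 0), sum(labels == 1))
  if (any(counts == 0))
    stop("both classes must be present to compute class weights", call. = FALSE)
  w <- length(labels) / (2 * counts)
  names(w) <- c("0", "1")
  w
}

# Per-modality input vectors for given drug indices: list over modalities of
# length(drugs) x N matrices (each drug's row of each similarity matrix).
pair_inputs <- function(mats, drugs) lapply(mats, function(S) S[drugs, , drop = FALSE])
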