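# Synthetic benchmark generator: binary drug-feature matrices with planted
# co-feature structure, interaction labels correlated with that structure
# at a configurable prevalence, and shape presets mirroring the four
# benchmark datasets.

#' Configuration for the synthetic DDI generator
#'
#' Drugs are assigned to latent groups. Interactions are planted as
#' within-group pair blocks plus greedily designated cross-group blocks
#' until the requested prevalence is met within 0.5 percentage points.
#' In each informative modality every interaction unit (each group, and
#' each designated cross-group pair) owns a dedicated block of features
#' that its member drugs carry with probability \code{signal_strength}
#' (background rate \code{(1 - signal_strength)/4}), so interacting drugs
#' share features and are Jaccard-similar; non-informative modalities are
#' pure noise (features on with probability 0.15 regardless of group).
#'
#' @param n_drugs Number of drugs N.
#' @param n_modalities Number of feature modalities T (before GIP).
#' @param n_features_per_modality Features M per modality.
#' @param n_latent_groups Latent groups G; finer groups allow the planted
#'   prevalence to match the target more precisely.
#' @param signal_strength Within-block feature probability in [0, 1].
#' @param informative_modalities Indices of modalities carrying the planted
#'   structure; the rest are noise.
#' @param prevalence Target fraction of interacting pairs in (0, 1).
#' @param noise_flip_rate Fraction of pair labels flipped at random after
#'   planting (label noise).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return Object of class \code{synth_config}.
#' @export
synth_config <- function(n_drugs = 200, n_modalities = 3,
                         n_features_per_modality = 250,
                         n_latent_groups = 20, signal_strength = 0.9,
                         informative_modalities = c(1, 2),
                         prevalence = 0.07, noise_flip_rate = 0, seed = 1) {
  stopifnot(n_drugs >= 4, n_modalities >= 1, n_features_per_modality >= 1,
            n_latent_groups >= 2, n_latent_groups <= n_drugs,
            signal_strength >= 0, signal_strength <= 1,
            prevalence > 0, prevalence < 1,
            noise_flip_rate >= 0, noise_flip_rate < 1)
  informative_modalities <- sort(unique(as.integer(informative_modalities)))
  if (length(informative_modalities) &&
      (min(informative_modalities) < 1 ||
       max(informative_modalities) > n_modalities))
    stop("informative_modalities must index the modalities", call. = FALSE)
  structure(list(n_drugs = as.integer(n_drugs),
                 n_modalities = as.integer(n_modalities),
                 n_features_per_modality = as.integer(n_features_per_modality),
                 n_latent_groups = as.integer(n_latent_groups),
                 signal_strength = signal_strength,
                 informative_modalities = informative_modalities,
                 prevalence = prevalence, noise_flip_rate = noise_flip_rate,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic multi-modal DDI benchmark
#'
#' @param config A \code{\link{synth_config}}.
#' @return List with \code{features} (list of N x M binary matrices, one
#'   per modality), \code{labels} (N x N binary matrix) and \code{truth}
#'   (group assignments, designated interaction blocks, informative
#'   modality set, realised prevalence).
#' @export
synth_ddi <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    N <- config$n_drugs; G <- config$n_latent_groups
    ids <- sprintf("D%03d", seq_len(N))
    groups <- sample(rep_len(seq_len(G), N))
    K <- N * (N - 1) / 2
    target <- round(config$prevalence * K)
    tol <- max(1, round(0.005 * K))

    # Candidate interaction blocks: every within-group block first, then
    # cross-group blocks in random order; accept greedily while staying
    # under target + tol, stop once target is reached.
    sizes <- tabulate(groups, G)
    cross <- enumerate_pairs(G)[sample(G * (G - 1) / 2), , drop = FALSE]
    blocks <- c(lapply(seq_len(G), function(g) c(g, g)),
                lapply(seq_len(nrow(cross)), function(r) cross[r, ]))
    bsize <- vapply(blocks, function(b)
      if (b[1] == b[2]) sizes[b[1]] * (sizes[b[1]] - 1) / 2
      else sizes[b[1]] * sizes[b[2]], numeric(1))
    sel <- logical(length(blocks))
    cum <- 0
    for (bi in seq_along(blocks)) {
      if (cum >= target) break
      if (bsize[bi] > 0 && cum + bsize[bi] <= target + tol) {
        sel[bi] <- TRUE
        cum <- cum + bsize[bi]
      }
    }
    selected <- blocks[sel]

    # Labels from the selected blocks.
    interacts <- matrix(FALSE, G, G)
    for (b in selected) {
      interacts[b[1], b[2]] <- TRUE
      interacts[b[2], b[1]] <- TRUE
    }
    lab <- matrix(0, N, N, dimnames = list(ids, ids))
    pairs <- enumerate_pairs(N)
    pos <- interacts[cbind(groups[pairs[, 1]], groups[pairs[, 2]])]
    ylab <- as.integer(pos)
    if (config$noise_flip_rate > 0) {
      flip <- stats::runif(K) < config$noise_flip_rate
      ylab[flip] <- 1L - ylab[flip]
    }
    # Thin/boost to land within +/- 0.5pp of the target prevalence.
    excess <- sum(ylab) - target
    if (excess > tol) {
      drop_idx <- sample(which(ylab == 1L), excess)
      ylab[drop_idx] <- 0L
    } else if (excess < -tol) {
      zeros <- which(ylab == 0L)
      if (length(zeros) < -excess)
        stop("requested prevalence is unreachable for this configuration",
             call. = FALSE)
      ylab[sample(zeros, -excess)] <- 1L
    }
    lab[pairs] <- ylab
    lab[pairs[, 2:1]] <- ylab

    # Feature matrices. Interaction units: each group, plus each selected
    # cross-group block (whose members span both groups).
    units <- c(lapply(seq_len(G), function(g) g),
               lapply(selected[vapply(selected, function(b) b[1] != b[2],
                                      logical(1))], identity))
    n_units <- length(units)
    M <- config$n_features_per_modality
    bg <- (1 - config$signal_strength) / 4
    feats <- vector("list", config$n_modalities)
    for (m in seq_len(config$n_modalities)) {
      if (m %in% config$informative_modalities) {
        # one feature block per interaction unit; if there are more units
        # than features, the leading units (all groups first) get one each
        n_eff <- min(n_units, M)
        per <- max(1L, M %/% n_units)
        Fm <- matrix(0L, N, M, dimnames = list(ids, NULL))
        prob <- matrix(bg, N, per * n_eff)
        for (u in seq_len(n_eff)) {
          memb <- groups %in% units[[u]]
          prob[memb, ((u - 1) * per + 1):(u * per)] <- config$signal_strength
        }
        Fm[, seq_len(per * n_eff)] <-
          matrix(as.integer(stats::runif(N * per * n_eff) < prob), N,
                 per * n_eff)
        extra <- M - per * n_eff
        if (extra > 0 && bg > 0)
          Fm[, (M - extra + 1):M] <-
            matrix(stats::rbinom(N * extra, 1, bg), N, extra)
      } else {
        Fm <- matrix(stats::rbinom(N * M, 1, 0.15), N, M,
                     dimnames = list(ids, NULL))
      }
      feats[[m]] <- Fm
    }
    names(feats) <- paste0("mod", seq_len(config$n_modalities))

    list(features = feats, labels = lab,
         truth = list(groups = stats::setNames(groups, ids),
                      blocks = selected,
                      informative_modalities = config$informative_modalities,
                      realized_prevalence = mean(ylab)))
  })
}

#' Assemble a ready-to-fit dataset from a synthetic benchmark
#'
#' Builds the Jaccard similarity matrix of each generated feature modality
#' and wraps them with the labels into a \code{\link{ddi_dataset}}; the
#' ground truth is attached as \code{attr(, "truth")}.
#'
#' @param config A \code{\link{synth_config}}.
#' @param use_gip Append the GIP modality at fit time.
#' @return A \code{ddi_dataset}.
#' @export
synth_dataset <- function(config = synth_config(), use_gip = TRUE) {
  gen <- synth_ddi(config)
  mods <- lapply(names(gen$features), function(nm)
    build_jaccard_matrix(gen$features[[nm]], modality = nm))
  names(mods) <- names(gen$features)
  ds <- ddi_dataset(mods, gen$labels, use_gip = use_gip)
  attr(ds, "truth") <- gen$truth
  ds
}

#' Benchmark-shaped synthetic fixtures
#'
#' Generates a fixture with the drug count, modality count and interaction
#' prevalence of one of the four benchmark datasets (multi-modal 548-drug
#' at ~32% prevalence; chemical-only 707-drug at ~7%; 807-drug with seven
#' modalities at ~1.5% CYP or ~6% non-CYP prevalence), optionally scaled
#' down in drug count.
#'
#' @param name One of \code{"ds1"}, \code{"ds2"}, \code{"ds3cyp"},
#'   \code{"ds3ncyp"}.
#' @param scale_factor Multiplier in (0, 1] on the drug count.
#' @param seed Generator seed.
#' @return A \code{\link{synth_config}}.
#' @export
synth_benchmark_config <- function(name = c("ds1", "ds2", "ds3cyp", "ds3ncyp"),
                                   scale_factor = 1, seed = 1) {
  name <- match.arg(name)
  stopifnot(scale_factor > 0, scale_factor <= 1)
  shape <- switch(name,
    ds1     = list(n = 548, t = 8, prev = 0.32),
    ds2     = list(n = 707, t = 1, prev = 0.07),
    ds3cyp  = list(n = 807, t = 7, prev = 0.015),
    ds3ncyp = list(n = 807, t = 7, prev = 0.06))
  n <- round(scale_factor * shape$n)
  if (n < 10) stop("scaled drug count below 10", call. = FALSE)
  synth_config(n_drugs = n, n_modalities = shape$t,
               n_latent_groups = max(10L, round(n / 10)),
               informative_modalities = seq_len(ceiling(shape$t / 2)),
               prevalence = shape$prev, seed = seed)
}
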