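#' Configuration of the bagging ensemble
#'
#' The ensemble diversifies the basic DWKNN predictor along two axes: the
#' amino acid index used to build each wordbook (one wordbook per index,
#' shared by that index's engines) and, per engine, a random neighbor count
#' K and a random feature mask in which each of the concatenated feature
#' positions is discarded independently with probability `discard_prob`.
#' The final score is the plain average of all base-learner outputs.
#' Training pairs are not resampled by default; set `bootstrap = TRUE` to
#' also bag over pairs.
#'
#' @param indices Accessions of the amino acid indices to use; defaults to
#'   the five bundled scales (see [default_aaindex_accessions()]).
#' @param Ne Engines per index (default 4).
#' @param K_range Inclusive range random K is drawn from (default 1 to 15).
#' @param discard_prob Per-feature discard probability (default 0.05).
#' @param bootstrap Resample training pairs with replacement per learner.
#' @return A list of class `ensemble_config`.
#' @export
ensemble_config <- function(indices = default_aaindex_accessions(),
                            Ne = 4L, K_range = c(1L, 15L),
                            discard_prob = 0.05, bootstrap = FALSE) {
  stopifnot(Ne >= 1, length(K_range) == 2, K_range[1] >= 1,
            K_range[1] <= K_range[2],
            discard_prob >= 0, discard_prob < 1)
  structure(
    list(indices = indices, Ne = as.integer(Ne),
         K_range = as.integer(K_range), discard_prob = discard_prob,
         bootstrap = bootstrap),
    class = "ensemble_config"
  )
}

# Resolve an accession (or an aa_index passed through) to an aa_index.
resolve_index <- function(x) {
  if (inherits(x, "aa_index")) x else default_aaindex(x)
}

# Draw every learner's randomized parameters in one seeded block, in a
# fixed order, so the ensemble is fully reproducible from the master seed.
draw_learner_params <- function(config, n_features, seed) {
  withr::with_seed(seed, {
    purrr::map(seq_along(config$indices), function(i) {
      purrr::map(seq_len(config$Ne), function(e) {
        # sample.int keeps a single-value K range fixed (sample(x, 1) on a
        # scalar x would draw from 1:x instead)
        K <- config$K_range[1] - 1L +
          sample.int(config$K_range[2] - config$K_range[1] + 1L, 1)
        mask <- stats::runif(n_features) >= config$discard_prob
        while (!any(mask)) { # empty mask is redrawn
          message("Redrawing an all-discard feature mask.")
          mask <- stats::runif(n_features) >= config$discard_prob
        }
        list(index_pos = i, engine = e, K = K, mask = mask)
      })
    }) %>% purrr::flatten()
  })
}

#' Fit the bagging ensemble of DWKNN engines
#'
#' Builds one wordbook per amino acid index from `sequences`, featurizes
#' the training pairs under each index, and instantiates
#' `length(indices) * Ne` base learners, each with its own feature mask and
#' neighbor count. All randomness derives from `seed`.
#'
#' @param pairs Labeled training pair tibble.
#' @param sequences Sequences the wordbooks are learned from (the training
#'   split). Must cover every receptor referenced by `pairs` unless
#'   `all_sequences` is supplied.
#' @param fingerprints Drug fingerprint tibble.
#' @param config An [ensemble_config()].
#' @param wb_config A [wordbook_config()].
#' @param threshold Discrimination threshold stored with the model.
#' @param seed Master seed.
#' @param all_sequences Optional larger sequence table used for
#'   featurization (the wordbooks still come from `sequences` only).
#' @param drug_feats Optional precomputed [drug_features()] table.
#' @return An object of class `dwknn_ensemble`.
#' @export
ensemble_fit <- function(pairs, sequences, fingerprints,
                         config = ensemble_config(),
                         wb_config = wordbook_config(), threshold = 0.5,
                         seed = 1L, all_sequences = NULL,
                         drug_feats = NULL) {
  feat_seq <- if (is.null(all_sequences)) sequences else all_sequences
  if (is.null(drug_feats)) {
    drug_feats <- drug_features(fingerprints)
  }
  indices <- lapply(config$indices, resolve_index)
  wordbooks <- lapply(seq_along(indices), function(i) {
    build_wordbook(sequences, indices[[i]], wb_config, seed = seed + i)
  })
  per_index_feats <- lapply(seq_along(indices), function(i) {
    gf <- gpcr_features(feat_seq, wordbooks[[i]], indices[[i]])
    pair_features(pairs, gf, drug_feats)
  })
  n_features <- ncol(per_index_feats[[1]]) -
    sum(c("gpcr_id", "drug_id", "label") %in% names(per_index_feats[[1]]))
  params <- draw_learner_params(config, n_features, seed)
  learners <- purrr::map(seq_along(params), function(j) {
    p <- params[[j]]
    pf <- per_index_feats[[p$index_pos]]
    if (config$bootstrap) {
      pf <- withr::with_seed(seed + 100003L + j,
                             pf[sample.int(nrow(pf), replace = TRUE), ])
    }
    model <- dwknn_fit(mask_pair_features(pf, p$mask), K = p$K,
                       threshold = threshold)
    list(index_accession = config$indices[[p$index_pos]],
         index_pos = p$index_pos, engine = p$engine, K = p$K,
         mask = p$mask, model = model)
  })
  structure(
    list(learners = learners, wordbooks = wordbooks, indices = indices,
         config = config, wb_config = wb_config, threshold = threshold,
         seed = seed),
    class = "dwknn_ensemble"
  )
}

# Keep id/label columns, subset feature columns by a logical mask.
mask_pair_features <- function(pair_feats, mask) {
  meta_cols <- intersect(c("gpcr_id", "drug_id", "label"), names(pair_feats))
  feat_cols <- setdiff(names(pair_feats), meta_cols)
  pair_feats[, c(meta_cols, feat_cols[mask])]
}

#' @export
print.dwknn_ensemble <- function(x, ...) {
  cat("<dwknn_ensemble> ", length(x$learners), " base learners (",
      length(x$indices), " indices x Ne = ", x$config$Ne,
      "), threshold = ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Score receptor-drug pairs with a fitted ensemble
#'
#' Each base learner featurizes the query with its own wordbook and feature
#' mask and scores it; the ensemble score is the arithmetic mean of the
#' base-learner outputs.
#'
#' @param object A [ensemble_fit()] model.
#' @param pairs Query pair tibble (`gpcr_id`, `drug_id`, optional `label`).
#' @param sequences Sequence table covering the query receptors.
#' @param fingerprints Fingerprint table covering the query drugs.
#' @param ... Ignored.
#' @return Tibble with ids, optional `label`, `score`, `predicted`.
#' @export
predict.dwknn_ensemble <- function(object, pairs, sequences, fingerprints,
                                   ...) {
  drug_feats <- drug_features(fingerprints)
  per_index_feats <- lapply(seq_along(object$indices), function(i) {
    gf <- gpcr_features(sequences, object$wordbooks[[i]],
                        object$indices[[i]])
    pair_features(pairs, gf, drug_feats)
  })
  score_mat <- vapply(object$learners, function(lr) {
    pf <- mask_pair_features(per_index_feats[[lr$index_pos]], lr$mask)
    predict(lr$model, pf)$score
  }, numeric(nrow(pairs)))
  score_mat <- matrix(score_mat, nrow = nrow(pairs))
  scores <- rowMeans(score_mat)
  meta_cols <- intersect(c("gpcr_id", "drug_id", "label"), names(pairs))
  dplyr::bind_cols(
    pairs[, meta_cols],
    tibble::tibble(score = scores,
                   predicted = predict_label(scores, object$threshold))
  )
}

#' Manifest of an ensemble's base learners
#' @param x A `dwknn_ensemble`.
#' @param ... Ignored.
#' @return Tibble with one row per learner: index accession, engine number,
#'   K, number of retained features.
#' @export
tidy.dwknn_ensemble <- function(x, ...) {
  purrr::map_dfr(x$learners, function(lr) {
    tibble::tibble(
      index_accession = lr$index_accession, engine = lr$engine, K = lr$K,
      n_features_kept = sum(lr$mask)
    )
  })
}

#' One-row summary of an ensemble
#' @param x A `dwknn_ensemble`.
#' @param ... Ignored.
#' @return One-row tibble.
#' @export
glance.dwknn_ensemble <- function(x, ...) {
  tibble::tibble(
    n_learners = length(x$learners),
    n_indices = length(x$indices),
    Ne = x$config$Ne,
    discard_prob = x$config$discard_prob,
    threshold = x$threshold,
    seed = x$seed
  )
}

# Ensemble LOOCV: wordbooks and per-index feature matrices are built once
# from the full pair set, learner parameters are drawn exactly as in
# ensemble_fit, and each learner scores every pair with itself excluded.
# Pair bootstrap is not applied here (self-exclusion over resampled copies
# is ill-defined); the default configuration does not use it.
loocv_scores_ensemble <- function(pairs, sequences, fingerprints, config,
                                  wb_config, seed) {
  drug_feats <- drug_features(fingerprints)
  indices <- lapply(config$indices, resolve_index)
  per_index <- lapply(seq_along(indices), function(i) {
    wb <- build_wordbook(sequences, indices[[i]], wb_config, seed = seed + i)
    gf <- gpcr_features(sequences, wb, indices[[i]])
    pair_matrix(pair_features(pairs, gf, drug_feats))
  })
  n <- nrow(pairs)
  n_features <- ncol(per_index[[1]]$features)
  params <- draw_learner_params(config, n_features, seed)
  score_mat <- vapply(params, function(p) {
    pm <- per_index[[p$index_pos]]
    feats <- pm$features[, p$mask, drop = FALSE]
    dwknn_score_matrix(feats, feats, as.integer(pm$meta$label),
                       min(p$K, n - 1), exclude = seq_len(n))
  }, numeric(n))
  rowMeans(matrix(score_mat, nrow = n))
}

#' Persist an ensemble model as a plain-text directory
#'
#' Writes one wordbook file per index, each base learner's training table,
#' and a JSON manifest (configuration, masks, K values, seed).
#'
#' @param fit A `dwknn_ensemble`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(fit$wordbooks)) {
    write_wordbook(fit$wordbooks[[i]],
                   file.path(dir, sprintf("wordbook_%02d.txt", i)))
  }
  for (j in seq_along(fit$learners)) {
    write_dwknn(fit$learners[[j]]$model,
                file.path(dir, sprintf("learner_%03d.tsv", j)))
  }
  manifest <- list(
    indices = fit$config$indices,
    Ne = fit$config$Ne,
    K_range = fit$config$K_range,
    discard_prob = fit$config$discard_prob,
    bootstrap = fit$config$bootstrap,
    threshold = fit$threshold,
    seed = fit$seed,
    learners = lapply(fit$learners, function(lr) {
      list(index_pos = lr$index_pos, engine = lr$engine, K = lr$K,
           mask = as.integer(lr$mask))
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read an ensemble model written by [write_ensemble()]
#' @param dir Model directory.
#' @return A `dwknn_ensemble`.
#' @export
read_ensemble <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  config <- ensemble_config(
    indices = unlist(manifest$indices),
    Ne = manifest$Ne,
    K_range = unlist(manifest$K_range),
    discard_prob = manifest$discard_prob,
    bootstrap = isTRUE(manifest$bootstrap)
  )
  wordbooks <- lapply(seq_along(config$indices), function(i) {
    read_wordbook(file.path(dir, sprintf("wordbook_%02d.txt", i)))
  })
  learners <- lapply(seq_along(manifest$learners), function(j) {
    m <- manifest$learners[[j]]
    model <- read_dwknn(file.path(dir, sprintf("learner_%03d.tsv", j)))
    list(index_accession = config$indices[[m$index_pos]],
         index_pos = m$index_pos, engine = m$engine, K = m$K,
         mask = as.logical(unlist(m$mask)), model = model)
  })
  structure(
    list(learners = learners, wordbooks = wordbooks,
         indices = lapply(config$indices, resolve_index),
         config = config, wb_config = wordbook_config(),
         threshold = manifest$threshold, seed = manifest$seed),
    class = "dwknn_ensemble"
  )
}
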