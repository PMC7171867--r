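#' Confusion counts under a strict score threshold
#'
#' Applies the strict `score > t` positive rule and tallies true/false
#' positives and negatives.
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param labels Binary observed labels (same length).
#' @param t Threshold.
#' @return Named list with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(scores, labels, t = 0.5) {
  if (length(scores) == 0 || length(scores) != length(labels)) {
    abort("`scores` and `labels` must be non-empty and the same length.",
          class = "bowdti_validation_error")
  }
  if (!all(labels %in% c(0, 1))) {
    abort("`labels` must be binary.", class = "bowdti_validation_error")
  }
  pred <- predict_label(scores, t)
  list(
    TP = sum(pred == 1 & labels == 1),
    FP = sum(pred == 1 & labels == 0),
    TN = sum(pred == 0 & labels == 0),
    FN = sum(pred == 0 & labels == 1)
  )
}

#' Classification metrics from confusion counts
#'
#' Sensitivity, specificity, accuracy and strength are reported in percent;
#' strength is the arithmetic mean of sensitivity and specificity, a
#' balance-aware summary for imbalanced pair sets. MCC is the Matthews
#' correlation coefficient, with 0 substituted when its denominator is 0.
#'
#' @param counts A [confusion_counts()] result.
#' @return One-row tibble: `Sn`, `Sp`, `Acc`, `Str` (percent), `MCC`.
#' @export
#' @examples
#' classification_metrics(list(TP = 130, FP = 0, TN = 260, FN = 0))
classification_metrics <- function(counts) {
  tp <- as.numeric(counts$TP); fp <- as.numeric(counts$FP)
  tn <- as.numeric(counts$TN); fn <- as.numeric(counts$FN)
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / (tp + fp + tn + fn)
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  tibble::tibble(
    Sn = 100 * sn, Sp = 100 * sp, Acc = 100 * acc,
    Str = 100 * (sn + sp) / 2, MCC = mcc
  )
}

#' ROC curve and area under it
#'
#' Sweeps every distinct score as a threshold (strict `>` rule), returning
#' the (FPR, TPR) points from (0, 0) to (1, 1) and the trapezoidal area,
#' which for this construction equals the rank statistic: the probability
#' that a random interactive pair outscores a random non-interactive one,
#' ties counted one half.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels; both classes must be present.
#' @return List with `points` (tibble `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  if (length(unique(labels)) < 2) {
    abort("Both classes must be present to build a ROC curve.",
          class = "bowdti_validation_error")
  }
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # group tied scores: each distinct threshold admits its whole tie group
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  last <- which(!duplicated(grp, fromLast = TRUE))
  pts <- tibble::tibble(
    threshold = c(Inf, s[last]),
    fpr = c(0, fp[last] / n_neg),
    tpr = c(0, tp[last] / n_pos)
  )
  auc <- sum(diff(pts$fpr) *
               (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Area under the ROC curve
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  roc_curve(scores, labels)$auc
}

#' Threshold maximizing the Matthews correlation coefficient
#'
#' Scans thresholds at the midpoints between adjacent distinct sorted
#' scores, plus one extreme below the minimum (everything called positive)
#' and the maximum score itself (strict rule: everything negative), and
#' returns the lowest maximizing threshold with its MCC.
#'
#' @inheritParams roc_curve
#' @return List with `threshold` and `mcc`.
#' @export
max_mcc_threshold <- function(scores, labels) {
  u <- sort(unique(scores))
  cands <- c(u[1] - 1,
             if (length(u) > 1) (u[-length(u)] + u[-1]) / 2,
             u[length(u)])
  cands <- sort(unique(cands))
  mccs <- vapply(cands, function(t) {
    pred <- as.integer(scores > t)
    tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
    tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
    den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
    if (den == 0) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) / den
  }, numeric(1))
  best <- which(mccs >= max(mccs) - 1e-12)[1]
  list(threshold = cands[best], mcc = mccs[best])
}

#' Dipeptide composition (DPC)
#'
#' 400-D frequencies of ordered standard-residue pairs; the classical
#' 2-gram baseline. Dipeptides containing a non-standard residue are
#' excluded from numerator and denominator. Sequences shorter than 2 give
#' an all-zero block.
#'
#' @param seq Amino acid string.
#' @return Named numeric 400-vector (names like `"AC"`), summing to 1 for
#'   sequences with at least one standard dipeptide.
#' @export
dpc_composition <- function(seq) {
  chars <- strsplit(gsub("\\s", "", toupper(seq)), "")[[1]]
  lv <- as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0)))
  out <- stats::setNames(numeric(400), lv)
  if (length(chars) < 2) {
    return(out)
  }
  di <- paste0(chars[-length(chars)], chars[-1])
  di <- di[di %in% lv]
  if (length(di) == 0) {
    return(out)
  }
  counts <- table(factor(di, levels = lv))
  stats::setNames(as.numeric(counts) / length(di), lv)
}

#' Classical composition baselines for receptor sequences
#'
#' AAC (20-D), DPC (400-D) or their concatenation (420-D), for comparison
#' against the learned bag-of-words representation.
#'
#' @param sequences Tibble with `gpcr_id` and `sequence` columns.
#' @param type One of `"aac"`, `"dpc"`, `"aac_dpc"`.
#' @return Tibble: `gpcr_id` plus feature columns.
#' @export
baseline_features <- function(sequences, type = c("aac", "dpc", "aac_dpc")) {
  type <- match.arg(type)
  featurize <- switch(
    type,
    aac = function(s) aac_composition(s),
    dpc = function(s) dpc_composition(s),
    aac_dpc = function(s) c(aac_composition(s), dpc_composition(s))
  )
  proto <- featurize(sequences$sequence[1])
  mat <- t(vapply(sequences$sequence, featurize, proto, USE.NAMES = FALSE))
  colnames(mat) <- paste0("b_", names(proto))
  dplyr::bind_cols(
    tibble::tibble(gpcr_id = sequences$gpcr_id),
    tibble::as_tibble(mat)
  )
}

# Stratified fold assignment: labels are split per class so each fold
# respects the positive/negative imbalance.
stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Cross-validated evaluation of the interaction predictor
#'
#' Splits the labeled pair table at the pair level (a held-out pair's
#' receptor or drug may still appear in training through other pairs),
#' trains the chosen engine on each training split, pools the held-out
#' scores and reports metrics at the given threshold plus ROC/AUC and the
#' MCC-maximizing threshold.
#'
#' Ten-fold splits are stratified by label. For k-fold protocols the
#' wordbook is rebuilt from the training split of every fold by default
#' (no information leaks from held-out sequences into the vocabulary);
#' for leave-one-out it is built once from all sequences, since removing a
#' single pair essentially never removes a sequence from the training
#' split and per-fold reclustering would dominate the runtime.
#'
#' @param pairs Labeled pair tibble (`gpcr_id`, `drug_id`, `label`).
#' @param sequences Receptor tibble (`gpcr_id`, `sequence`).
#' @param fingerprints Drug tibble (`drug_id`, `fingerprint`).
#' @param protocol `"kfold"` or `"loocv"`.
#' @param k Number of folds for `"kfold"` (default 10).
#' @param engine `"dwknn"` (single learner) or `"ensemble"`.
#' @param index An [aa_index()] for the single learner (default hydropathy).
#' @param K Neighbor count for the single learner.
#' @param threshold Discrimination threshold for the reported metrics.
#' @param config [wordbook_config()] controlling vocabulary learning.
#' @param ensemble An [ensemble_config()] when `engine = "ensemble"`.
#' @param rebuild_wordbook `"fold"` or `"once"`; defaults to `"fold"` for
#'   k-fold and `"once"` for LOOCV.
#' @param seed Integer seed for fold assignment and all learner randomness.
#' @return An object of class `bowdti_eval`: pooled `scores` tibble,
#'   `metrics`, `roc` points, `auc`, `max_mcc`, `threshold`, `protocol`.
#' @export
cross_validate <- function(pairs, sequences, fingerprints,
                           protocol = c("kfold", "loocv"), k = 10,
                           engine = c("dwknn", "ensemble"),
                           index = default_aaindex(), K = 13L,
                           threshold = 0.5, config = wordbook_config(),
                           ensemble = ensemble_config(),
                           rebuild_wordbook = NULL, seed = 1L) {
  protocol <- match.arg(protocol)
  engine <- match.arg(engine)
  if (sum(pairs$label == 1) < 2 || sum(pairs$label == 0) < 2) {
    abort("Need at least two pairs per class.",
          class = "bowdti_validation_error")
  }
  if (is.null(rebuild_wordbook)) {
    rebuild_wordbook <- if (protocol == "kfold") "fold" else "once"
  }
  rebuild_wordbook <- match.arg(rebuild_wordbook, c("fold", "once"))

  n <- nrow(pairs)
  if (protocol == "loocv") {
    scores <- if (engine == "dwknn") {
      loocv_scores_dwknn(pairs, sequences, fingerprints, index, K, config,
                         seed)
    } else {
      loocv_scores_ensemble(pairs, sequences, fingerprints, ensemble, config,
                            seed)
    }
  } else {
    folds <- stratified_folds(pairs$label, k, seed)
    scores <- rep(NA_real_, n)
    drug_feats <- drug_features(fingerprints)
    for (f in seq_len(k)) {
      test_idx <- which(folds == f)
      train_pairs <- pairs[-test_idx, ]
      test_pairs <- pairs[test_idx, ]
      wb_seq <- if (rebuild_wordbook == "fold") {
        sequences[sequences$gpcr_id %in% unique(train_pairs$gpcr_id), ]
      } else {
        sequences
      }
      if (engine == "dwknn") {
        wb <- build_wordbook(wb_seq, index, config, seed = seed)
        gf <- gpcr_features(sequences, wb, index)
        model <- dwknn_fit(pair_features(train_pairs, gf, drug_feats),
                           K = K, threshold = threshold)
        scores[test_idx] <-
          predict(model, pair_features(test_pairs, gf, drug_feats))$score
      } else {
        fit <- ensemble_fit(train_pairs, wb_seq, fingerprints,
                            config = ensemble, wb_config = config,
                            threshold = threshold, seed = seed,
                            all_sequences = sequences,
                            drug_feats = drug_feats)
        scores[test_idx] <- predict(fit, test_pairs, sequences,
                                    fingerprints)$score
      }
    }
  }

  score_tbl <- dplyr::bind_cols(
    pairs[, c("gpcr_id", "drug_id", "label")],
    tibble::tibble(score = scores)
  )
  new_bowdti_eval(score_tbl, threshold,
                  protocol = if (protocol == "kfold") paste0(k, "-fold")
                  else "LOOCV")
}

# Single-learner LOOCV: one wordbook, one feature matrix, self excluded
# per query by masking the diagonal of the distance matrix.
loocv_scores_dwknn <- function(pairs, sequences, fingerprints, index, K,
                               config, seed) {
  wb <- build_wordbook(sequences, index, config, seed = seed)
  gf <- gpcr_features(sequences, wb, index)
  df <- drug_features(fingerprints)
  pm <- pair_matrix(pair_features(pairs, gf, df))
  if (K > nrow(pm$features) - 1) {
    abort("K exceeds the LOOCV training size.",
          class = "bowdti_validation_error")
  }
  dwknn_score_matrix(pm$features, pm$features,
                     as.integer(pm$meta$label), K,
                     exclude = seq_len(nrow(pm$features)))
}

#' Summarize pooled scores into an evaluation report
#'
#' @param scores Tibble with `label` and `score` columns (plus ids).
#' @param threshold Reporting threshold.
#' @param protocol Free-text protocol tag.
#' @return A `bowdti_eval` object.
#' @export
new_bowdti_eval <- function(scores, threshold = 0.5,
                            protocol = "independent") {
  roc <- roc_curve(scores$score, scores$label)
  structure(
    list(
      scores = scores,
      threshold = threshold,
      protocol = protocol,
      metrics = classification_metrics(
        confusion_counts(scores$score, scores$label, threshold)
      ),
      roc = roc$points,
      auc = roc$auc,
      max_mcc = max_mcc_threshold(scores$score, scores$label)
    ),
    class = "bowdti_eval"
  )
}

#' @export
print.bowdti_eval <- function(x, ...) {
  cat("<bowdti_eval> ", x$protocol, ", ", nrow(x$scores), " pairs, t = ",
      x$threshold, "\n", sep = "")
  m <- x$metrics
  cat(sprintf(
    "  Acc %.2f%%  Sn %.2f%%  Sp %.2f%%  Str %.2f%%  MCC %.3f  AUC %.3f\n",
    m$Acc, m$Sn, m$Sp, m$Str, m$MCC, x$auc
  ))
  cat(sprintf("  max MCC %.3f at t = %.4f\n",
              x$max_mcc$mcc, x$max_mcc$threshold))
  invisible(x)
}

#' Metric table of an evaluation
#' @param x A `bowdti_eval`.
#' @param ... Ignored.
#' @return Long tibble of metric names and values.
#' @export
tidy.bowdti_eval <- function(x, ...) {
  wide <- dplyr::bind_cols(
    x$metrics,
    tibble::tibble(AUC = x$auc, max_MCC = x$max_mcc$mcc)
  )
  tidyr::pivot_longer(wide, dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' One-row summary of an evaluation
#' @param x A `bowdti_eval`.
#' @param ... Ignored.
#' @return One-row tibble with protocol, n, threshold, metrics, AUC.
#' @export
glance.bowdti_eval <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(protocol = x$protocol, n = nrow(x$scores),
                   threshold = x$threshold),
    x$metrics,
    tibble::tibble(AUC = x$auc, max_MCC = x$max_mcc$mcc,
                   max_MCC_threshold = x$max_mcc$threshold)
  )
}

#' ROC curve plot of an evaluation
#' @param object A `bowdti_eval`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.bowdti_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("%s ROC (AUC = %.3f)", object$protocol, object$auc)
    )
}

#' Write an evaluation report to disk
#'
#' Emits `<stem>_metrics.tsv` (one row), `<stem>_roc.tsv` (threshold, fpr,
#' tpr) and `<stem>_scores.tsv` (per-pair scores).
#'
#' @param eval A `bowdti_eval`.
#' @param stem Output path stem.
#' @return `stem`, invisibly.
#' @export
write_eval <- function(eval, stem) {
  readr::write_tsv(glance(eval), paste0(stem, "_metrics.tsv"))
  readr::write_tsv(eval$roc, paste0(stem, "_roc.tsv"))
  readr::write_tsv(eval$scores, paste0(stem, "_scores.tsv"))
  invisible(stem)
}
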