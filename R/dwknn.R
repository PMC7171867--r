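#' Concatenated feature vectors for receptor-drug pairs
#'
#' Joins a pair table against receptor and drug feature tables, laying out
#' each pair as the receptor block (128 values under the default wordbook)
#' followed by the drug block (128 DFT amplitudes), i.e. a 256-D vector.
#'
#' @param pairs Tibble with `gpcr_id`, `drug_id` and optional `label`.
#' @param gpcr_feats Output of [gpcr_features()].
#' @param drug_feats Output of [drug_features()].
#' @return Tibble: `gpcr_id`, `drug_id`, `label` (if present), then the
#'   receptor feature columns followed by the drug feature columns.
#' @export
pair_features <- function(pairs, gpcr_feats, drug_feats) {
  missing_g <- setdiff(pairs$gpcr_id, gpcr_feats$gpcr_id)
  missing_d <- setdiff(pairs$drug_id, drug_feats$drug_id)
  if (length(missing_g) || length(missing_d)) {
    abort(
      paste0(
        "Pair table references unknown ids: ",
        paste(c(missing_g, missing_d), collapse = ", ")
      ),
      class = "bowdti_validation_error"
    )
  }
  pairs %>%
    dplyr::left_join(gpcr_feats, by = "gpcr_id") %>%
    dplyr::left_join(drug_feats, by = "drug_id")
}

# Split a pair-feature tibble into an id/label part and a numeric matrix.
pair_matrix <- function(pair_feats) {
  meta_cols <- intersect(c("gpcr_id", "drug_id", "label"), names(pair_feats))
  mat <- as.matrix(pair_feats[, setdiff(names(pair_feats), meta_cols)])
  storage.mode(mat) <- "double"
  list(meta = pair_feats[, meta_cols], features = mat)
}

#' Distance weights of the K nearest neighbors
#'
#' Given the ascending distances `d_1 <= ... <= d_K` of a query's nearest
#' neighbors, the k-th neighbor's weight is
#' `(d_K - d_k) / (d_K - d_1)` when `d_K != d_1`, and 1 for every neighbor
#' otherwise (which also covers `K = 1`). The nearest neighbor always has
#' weight 1; the farthest has weight 0 unless all distances are equal.
#'
#' @param distances Non-negative numeric vector sorted ascending.
#' @return Numeric weights in `[0, 1]`, same length.
#' @export
#' @examples
#' dwknn_weights(c(1, 2, 3))
dwknn_weights <- function(distances) {
  if (is.unsorted(distances)) {
    abort("`distances` must be sorted ascending.",
          class = "bowdti_validation_error")
  }
  dK <- distances[length(distances)]
  d1 <- distances[1]
  if (dK == d1) {
    return(rep(1, length(distances)))
  }
  (dK - distances) / (dK - d1)
}

#' Fit a distance-weighted K-nearest-neighbor interaction model
#'
#' DWKNN is a lazy learner: fitting stores the training pair vectors and
#' labels. A query is scored as the weight fraction of interactive
#' neighbors among its K Euclidean-nearest training pairs (see
#' [dwknn_weights()]); the score lies in `[0, 1]` and is read as the
#' probability of interaction. Training rows are sorted by
#' `(gpcr_id, drug_id)` so that equal-distance ties resolve identically
#' regardless of input row order.
#'
#' @param pair_feats Labeled pair-feature tibble from [pair_features()]
#'   (must contain `label`).
#' @param K Neighbor count, `1 <= K <=` number of training pairs
#'   (default 13).
#' @param threshold Discrimination threshold `t`; a pair is called
#'   interactive when its score strictly exceeds `t` (default 0.5).
#' @return An object of class `dwknn`.
#' @export
dwknn_fit <- function(pair_feats, K = 13L, threshold = 0.5) {
  if (!"label" %in% names(pair_feats)) {
    abort("Training pairs must carry a `label` column.",
          class = "bowdti_validation_error")
  }
  ord <- order(pair_feats$gpcr_id, pair_feats$drug_id)
  pair_feats <- pair_feats[ord, ]
  pm <- pair_matrix(pair_feats)
  if (K < 1 || K > nrow(pm$features)) {
    abort(paste0("K = ", K, " must lie in [1, ", nrow(pm$features), "]."),
          class = "bowdti_validation_error")
  }
  structure(
    list(features = pm$features, labels = as.integer(pm$meta$label),
         meta = pm$meta[, c("gpcr_id", "drug_id")],
         K = as.integer(K), threshold = threshold),
    class = "dwknn"
  )
}

#' @export
print.dwknn <- function(x, ...) {
  cat("<dwknn> ", nrow(x$features), " training pairs (",
      sum(x$labels == 1), " interactive), K = ", x$K,
      ", threshold = ", x$threshold, "\n", sep = "")
  invisible(x)
}

# Squared Euclidean distances between query rows and training rows.
cross_dist2 <- function(query, train) {
  d2 <- outer(rowSums(query^2), rowSums(train^2), `+`) -
    2 * tcrossprod(query, train)
  d2[d2 < 0] <- 0 # numerical noise on (near-)duplicate rows
  d2
}

# Score query rows against explicit training data. `exclude` optionally
# gives, per query row, one training row index to leave out (LOOCV).
dwknn_score_matrix <- function(query, train, labels, K, exclude = NULL) {
  d2 <- cross_dist2(query, train)
  if (!is.null(exclude)) {
    d2[cbind(seq_len(nrow(query)), exclude)] <- Inf
  }
  vapply(seq_len(nrow(d2)), function(i) {
    row <- d2[i, ]
    nn <- order(row)[seq_len(K)] # stable order: ties to lowest training index
    d <- sqrt(row[nn])
    w <- dwknn_weights(d)
    sum(w[labels[nn] == 1]) / sum(w)
  }, numeric(1))
}

#' Score receptor-drug pairs with a fitted DWKNN model
#'
#' @param object A [dwknn_fit()] model.
#' @param pair_feats Pair-feature tibble for the query pairs (same feature
#'   columns as the training data; a `label` column, if present, is carried
#'   through untouched).
#' @param ... Ignored.
#' @return Tibble with `gpcr_id`, `drug_id`, optional observed `label`,
#'   `score` in `[0, 1]` and `predicted` (1 when `score > threshold`).
#' @export
predict.dwknn <- function(object, pair_feats, ...) {
  pm <- pair_matrix(pair_feats)
  if (ncol(pm$features) != ncol(object$features)) {
    abort("Query feature dimension does not match the training data.",
          class = "bowdti_validation_error")
  }
  scores <- dwknn_score_matrix(pm$features, object$features, object$labels,
                               object$K)
  dplyr::bind_cols(
    pm$meta,
    tibble::tibble(
      score = scores,
      predicted = predict_label(scores, object$threshold)
    )
  )
}

#' Convert interaction scores to labels with a strict threshold
#'
#' A pair is called interactive only when its score strictly exceeds `t`;
#' a score exactly equal to the threshold is non-interactive.
#'
#' @param score Numeric scores in `[0, 1]`.
#' @param t Threshold in `[0, 1]`.
#' @return Integer labels (0/1).
#' @export
#' @examples
#' predict_label(c(0.6, 0.5), 0.5)
predict_label <- function(score, t) {
  stopifnot(all(score >= 0 & score <= 1), t >= 0, t <= 1)
  as.integer(score > t)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the training table of a DWKNN model
#' @param x A `dwknn` model.
#' @param ... Ignored.
#' @return Tibble of training pairs with their labels.
#' @export
tidy.dwknn <- function(x, ...) {
  dplyr::bind_cols(x$meta, tibble::tibble(label = x$labels))
}

#' One-row summary of a DWKNN model
#' @param x A `dwknn` model.
#' @param ... Ignored.
#' @return One-row tibble: training size, positives, K, threshold,
#'   feature dimension.
#' @export
glance.dwknn <- function(x, ...) {
  tibble::tibble(
    n_train = nrow(x$features),
    n_positive = sum(x$labels == 1),
    K = x$K,
    threshold = x$threshold,
    n_features = ncol(x$features)
  )
}

#' Persist a DWKNN model as plain text
#'
#' Writes the training feature table as TSV and the hyperparameters as a
#' JSON sidecar (`<path>.json`).
#'
#' @param model A `dwknn` model.
#' @param path Path of the TSV file to write.
#' @return `path`, invisibly.
#' @export
write_dwknn <- function(model, path) {
  df <- dplyr::bind_cols(
    model$meta, tibble::tibble(label = model$labels),
    tibble::as_tibble(model$features)
  )
  # doubles are serialized at full precision so reloaded models score
  # bit-identically even where neighbor distances nearly tie
  df[] <- lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  })
  readr::write_tsv(df, path)
  jsonlite::write_json(
    list(K = model$K, threshold = model$threshold),
    paste0(path, ".json"),
    auto_unbox = TRUE
  )
  invisible(path)
}

#' Read a DWKNN model written by [write_dwknn()]
#' @param path Path of the TSV file.
#' @return A `dwknn` model.
#' @export
read_dwknn <- function(path) {
  # parsed with base R: its strtod-backed numeric conversion is correctly
  # rounded, so the %.17g columns written by write_dwknn reload exactly
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  df <- tibble::as_tibble(raw)
  num_cols <- setdiff(names(df), c("gpcr_id", "drug_id"))
  df[num_cols] <- lapply(df[num_cols], as.numeric)
  df$label <- as.integer(df$label)
  hp <- jsonlite::read_json(paste0(path, ".json"))
  dwknn_fit(df, K = hp$K, threshold = hp$threshold)
}
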