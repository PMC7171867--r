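test_that("confusion counts apply the strict threshold rule", {
  cc <- confusion_counts(c(0.9, 0.1), c(1, 0), 0.5)
  expect_equal(cc, list(TP = 1L, FP = 0L, TN = 1L, FN = 0L))
  # a score exactly at the threshold is negative
  expect_equal(confusion_counts(0.5, 1, 0.5)$FN, 1L)
  expect_error(confusion_counts(numeric(0), numeric(0)),
               class = "bowdti_validation_error")
  expect_error(confusion_counts(c(0.2, 0.4), c(1)),
               class = "bowdti_validation_error")
})

test_that("metrics follow their definitions, including strength", {
  perfect <- classification_metrics(list(TP = 130, FP = 0, TN = 260, FN = 0))
  expect_equal(perfect$Sn, 100)
  expect_equal(perfect$Sp, 100)
  expect_equal(perfect$Acc, 100)
  expect_equal(perfect$Str, 100)
  expect_equal(perfect$MCC, 1)
  # Str is exactly the mean of Sn and Sp: Sn 83.1%, Sp 82.7% -> Str 82.9%
  m <- classification_metrics(list(TP = 831, FN = 169, TN = 827, FP = 173))
  expect_equal(m$Sn, 83.1)
  expect_equal(m$Sp, 82.7)
  expect_equal(m$Str, 82.9)
  # degenerate all-positive prediction on balanced labels has MCC 0
  deg <- classification_metrics(list(TP = 10, FP = 10, TN = 0, FN = 0))
  expect_equal(deg$MCC, 0)
})

test_that("metrics match hand-computed values on a random confusion table", {
  withr::with_seed(41, {
    for (i in 1:10) {
      cc <- as.list(stats::setNames(sample(0:50, 4, TRUE),
                                    c("TP", "FP", "TN", "FN")))
      if (cc$TP + cc$FN == 0 || cc$TN + cc$FP == 0) next
      m <- classification_metrics(cc)
      expect_equal(m$Str, (m$Sn + m$Sp) / 2, tolerance = 1e-12)
      expect_equal(m$Acc,
                   100 * (cc$TP + cc$TN) / (cc$TP + cc$FP + cc$TN + cc$FN))
    }
  })
})

test_that("trapezoidal ROC AUC equals the rank statistic on random data", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  withr::with_seed(42, {
    for (i in 1:200) {
      n <- sample(10:60, 1)
      labels <- sample(0:1, n, replace = TRUE)
      if (length(unique(labels)) < 2) next
      # discretized scores force ties
      scores <- round(stats::runif(n), 1)
      expect_equal(roc_auc(scores, labels), rank_auc(scores, labels),
                   tolerance = 1e-12)
    }
    # labels independent of scores at large n give AUC near 1/2
    n <- 4000
    labels <- sample(0:1, n, replace = TRUE)
    scores <- stats::runif(n)
    expect_lt(abs(roc_auc(scores, labels) - 0.5), 0.05)
  })
  expect_error(roc_curve(c(0.3, 0.4), c(1, 1)),
               class = "bowdti_validation_error")
})

test_that("ROC AUC agrees with an independent library implementation", {
  withr::with_seed(43, {
    labels <- sample(0:1, 100, replace = TRUE)
    scores <- stats::runif(100) + 0.3 * labels
    ours <- roc_auc(scores, labels)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE)))
    expect_equal(ours, ref, tolerance = 1e-12)
  })
})

test_that("max-MCC threshold search matches a fine-grid scan", {
  grid_max_mcc <- function(scores, labels) {
    ts <- seq(-0.0001, 1.0001, by = 1e-4)
    mccs <- vapply(ts, function(t) {
      classification_metrics(confusion_counts(
        pmin(pmax(scores, 0), 1), labels, max(min(t, 1), 0)
      ))$MCC
    }, numeric(1))
    max(mccs)
  }
  # separable scores: MCC* = 1 at the lowest midpoint
  res <- max_mcc_threshold(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(res$mcc, 1)
  expect_equal(res$threshold, 0.5)
  # a single distinct score cannot discriminate
  expect_equal(max_mcc_threshold(rep(0.4, 6), c(1, 1, 1, 0, 0, 0))$mcc, 0)
  withr::with_seed(44, {
    for (i in 1:20) {
      n <- sample(15:40, 1)
      labels <- sample(0:1, n, replace = TRUE)
      if (length(unique(labels)) < 2) next
      scores <- round(stats::runif(n), 2)
      res <- max_mcc_threshold(scores, labels)
      expect_equal(res$mcc, grid_max_mcc(scores, labels), tolerance = 1e-9)
    }
  })
})

test_that("composition baselines have the right layout and normalization", {
  dpc <- dpc_composition("AC")
  expect_length(dpc, 400)
  expect_equal(unname(dpc[["AC"]]), 1)
  aaaa <- dpc_composition("AAAA")
  expect_equal(unname(aaaa[["AA"]]), 1)
  withr::with_seed(45, {
    s <- paste(sample(aa_letters, 30, TRUE), collapse = "")
    expect_equal(sum(dpc_composition(s)), 1, tolerance = 1e-12)
  })
  expect_equal(sum(dpc_composition("A")), 0)
  bf <- baseline_features(toy_sequences, "aac_dpc")
  expect_equal(ncol(bf), 421)
  expect_equal(unname(rowSums(as.matrix(bf[, -1]))), rep(2, 3),
               tolerance = 1e-12)
})

test_that("cross-validation folds are stratified, deterministic, pair-level", {
  ds <- generate_dataset(generator_config(n_gpcrs = 12, n_drugs = 20,
                                          n_pairs = 80, seed = 8,
                                          length_range = c(50, 150)))
  p <- ds$pairs[, c("gpcr_id", "drug_id", "label")]
  f1 <- bowdti:::stratified_folds(p$label, 5, seed = 2)
  f2 <- bowdti:::stratified_folds(p$label, 5, seed = 2)
  expect_identical(f1, f2)
  per_fold_pos <- tapply(p$label, f1, sum)
  expect_lte(diff(range(per_fold_pos)), 1)
  ev <- cross_validate(p, ds$sequences, ds$fingerprints, protocol = "kfold",
                       k = 5, K = 5, seed = 2)
  expect_s3_class(ev, "bowdti_eval")
  expect_equal(nrow(ev$scores), nrow(p))
  expect_true(all(!is.na(ev$scores$score)))
  ev2 <- cross_validate(p, ds$sequences, ds$fingerprints, protocol = "kfold",
                        k = 5, K = 5, seed = 2)
  expect_equal(ev$scores, ev2$scores)
  g <- glance(ev)
  expect_true(all(c("Sn", "Sp", "Acc", "Str", "MCC", "AUC") %in% names(g)))
  expect_equal(g$Str, (g$Sn + g$Sp) / 2, tolerance = 1e-12)
})

test_that("LOOCV on duplicated consistent pairs is perfect", {
  # two copies of every feature vector: each held-out pair finds its twin
  base <- separable_pair_features(6, 8, seed = 46)
  twin <- dplyr::mutate(base, gpcr_id = paste0(gpcr_id, "b"))
  pf <- dplyr::bind_rows(base, twin)
  pm <- bowdti:::pair_matrix(pf)
  scores <- bowdti:::dwknn_score_matrix(pm$features, pm$features,
                                        as.integer(pm$meta$label), 1,
                                        exclude = seq_len(nrow(pf)))
  m <- classification_metrics(confusion_counts(scores, pf$label, 0.5))
  expect_equal(m$Sn, 100)
  expect_equal(m$Sp, 100)
})

test_that("LOOCV leaves each pair out exactly once", {
  ds <- generate_dataset(generator_config(n_gpcrs = 8, n_drugs = 12,
                                          n_pairs = 40, seed = 9,
                                          length_range = c(50, 120)))
  p <- ds$pairs[, c("gpcr_id", "drug_id", "label")]
  ev <- cross_validate(p, ds$sequences, ds$fingerprints, protocol = "loocv",
                       K = 5, seed = 3)
  expect_equal(nrow(ev$scores), 40)
  expect_equal(ev$protocol, "LOOCV")
  expect_error(
    cross_validate(p, ds$sequences, ds$fingerprints, protocol = "loocv",
                   K = 40, seed = 3),
    class = "bowdti_validation_error"
  )
})

test_that("evaluation reports serialize and plot", {
  withr::with_seed(47, {
    scores <- tibble::tibble(
      gpcr_id = sprintf("g%d", 1:30), drug_id = sprintf("d%d", 1:30),
      label = sample(0:1, 30, TRUE), score = stats::runif(30)
    )
  })
  ev <- new_bowdti_eval(scores, 0.5, "independent")
  stem <- tempfile()
  write_eval(ev, stem)
  expect_true(file.exists(paste0(stem, "_metrics.tsv")))
  roc_back <- readr::read_tsv(paste0(stem, "_roc.tsv"),
                              col_types = "ddd", progress = FALSE)
  expect_equal(nrow(roc_back), nrow(ev$roc))
  p <- autoplot(ev)
  expect_s3_class(p, "ggplot")
  td <- tidy(ev)
  expect_true(all(c("AUC", "MCC", "Str") %in% td$metric))
})
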