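test_that("pair vectors are the receptor block followed by the drug block", {
  ds <- worked_example()
  wb <- build_wordbook(ds$sequences, hydropathy,
                       wordbook_config(c(`2` = 2L, `3` = 2L, `4` = 2L)),
                       seed = 1)
  gf <- gpcr_features(ds$sequences, wb, hydropathy)
  df <- drug_features(ds$fingerprints)
  pf <- pair_features(ds$pairs[, c("gpcr_id", "drug_id", "label")], gf, df)
  pm <- bowdti:::pair_matrix(pf)
  n_g <- ncol(gf) - 1
  expect_equal(ncol(pm$features), n_g + 128)
  i <- 3
  g_row <- as.numeric(gf[match(pf$gpcr_id[i], gf$gpcr_id), -1])
  d_row <- as.numeric(df[match(pf$drug_id[i], df$drug_id), -1])
  expect_equal(unname(pm$features[i, seq_len(n_g)]), g_row)
  expect_equal(unname(pm$features[i, (n_g + 1):(n_g + 128)]), d_row)
  # unknown ids are reported
  bad <- tibble::tibble(gpcr_id = "nope", drug_id = "D1", label = 1L)
  expect_error(pair_features(bad, gf, df), "nope",
               class = "bowdti_validation_error")
})

test_that("default wordbook makes pairs 256-dimensional", {
  ds <- generate_dataset(generator_config(n_gpcrs = 6, n_drugs = 6,
                                          n_pairs = 12, seed = 9))
  wb <- build_wordbook(ds$sequences, hydropathy, seed = 1)
  pf <- pair_features(ds$pairs[, c("gpcr_id", "drug_id", "label")],
                      gpcr_features(ds$sequences, wb, hydropathy),
                      drug_features(ds$fingerprints))
  expect_equal(ncol(bowdti:::pair_matrix(pf)$features), 256)
})

test_that("neighbor weights follow the linear distance rule", {
  expect_equal(dwknn_weights(c(1, 2, 3)), c(1, 0.5, 0))
  expect_equal(dwknn_weights(c(2, 2, 2)), c(1, 1, 1))
  expect_equal(dwknn_weights(5), 1)
  expect_equal(dwknn_weights(c(0, 1, 4)), c(1, 0.75, 0))
  expect_error(dwknn_weights(c(3, 1, 2)), class = "bowdti_validation_error")
})

test_that("scores are weighted positive fractions with hand-checked cases", {
  # three training points at distances 1, 2, 3 from the query
  train <- tibble::tibble(
    gpcr_id = c("a", "b", "c"), drug_id = c("x", "y", "z"),
    label = c(1L, 0L, 0L), f1 = c(1, 2, 3)
  )
  model <- dwknn_fit(train, K = 3)
  q <- tibble::tibble(gpcr_id = "q", drug_id = "q", f1 = 0)
  # weights [1, 0.5, 0], labels [1, 0, 0] -> 1 / 1.5
  expect_equal(predict(model, q)$score, 1 / 1.5)
  # all-positive and all-negative neighborhoods hit the bounds
  all_pos <- dwknn_fit(dplyr::mutate(train, label = 1L), K = 3)
  expect_equal(predict(all_pos, q)$score, 1)
  all_neg <- dwknn_fit(dplyr::mutate(train, label = 0L), K = 3)
  expect_equal(predict(all_neg, q)$score, 0)
  # K larger than the training set is rejected
  expect_error(dwknn_fit(train, K = 4), class = "bowdti_validation_error")
})

test_that("thresholding is strict and at the boundaries", {
  expect_equal(predict_label(c(0.6, 0.5, 0.0), 0.5), c(1L, 0L, 0L))
  expect_equal(predict_label(0, 0), 0L)
  expect_equal(predict_label(1, 0), 1L)
})

test_that("label complement maps score o to 1 - o", {
  pf <- separable_pair_features(seed = 31)
  q <- pf[1:5, setdiff(names(pf), "label")]
  m1 <- dwknn_fit(pf, K = 7)
  m2 <- dwknn_fit(dplyr::mutate(pf, label = 1L - label), K = 7)
  expect_equal(predict(m2, q)$score, 1 - predict(m1, q)$score)
})

test_that("with K = n the farthest point carries zero weight", {
  withr::with_seed(32, {
    pf <- separable_pair_features(6, 6, seed = 32)
    q <- tibble::tibble(gpcr_id = "q", drug_id = "q",
                        f1 = 0.5, f2 = 2, f3 = 0, f4 = 0)
    full <- dwknn_fit(pf, K = 12)
    s_full <- predict(full, q)$score
    d <- sqrt(bowdti:::cross_dist2(
      bowdti:::pair_matrix(q)$features, full$features
    ))[1, ]
    # hand-recompute the score: the farthest neighbor's weight is exactly 0
    w <- dwknn_weights(sort(d))
    expect_equal(w[12], 0)
    lab <- full$labels[order(d)]
    expect_equal(s_full, sum(w[lab == 1]) / sum(w), tolerance = 1e-12)
    # a duplicate of the farthest point (with the opposite label) also gets
    # weight 0 and cannot move the score
    far <- which.max(d)
    dup <- dplyr::bind_cols(full$meta, tibble::tibble(label = full$labels),
                            tibble::as_tibble(full$features))
    dup <- dplyr::bind_rows(dup, dplyr::mutate(
      dup[far, ], gpcr_id = "dup", label = 1L - label
    ))
    augmented <- dwknn_fit(dup, K = 13)
    expect_equal(predict(augmented, q)$score, s_full, tolerance = 1e-12)
  })
})

test_that("neighbor retrieval matches a brute-force full sort", {
  withr::with_seed(33, {
    train <- matrix(stats::runif(200 * 6), ncol = 6)
    labels <- sample(0:1, 200, replace = TRUE)
    queries <- matrix(stats::runif(500 * 6), ncol = 6)
    K <- 9
    fast <- bowdti:::dwknn_score_matrix(queries, train, labels, K)
    slow <- apply(queries, 1, function(q) {
      d <- sqrt(colSums((t(train) - q)^2))
      nn <- order(d)[1:K]
      w <- dwknn_weights(d[nn])
      sum(w[labels[nn] == 1]) / sum(w)
    })
    expect_equal(fast, slow, tolerance = 1e-12)
    expect_true(all(fast >= 0 & fast <= 1))
  })
})

test_that("scores are invariant to permutations of the training table", {
  withr::with_seed(34, {
    pf <- separable_pair_features(10, 10, seed = 34)
    q <- pf[c(2, 15), setdiff(names(pf), "label")]
    m <- dwknn_fit(pf, K = 5)
    perm <- pf[sample.int(nrow(pf)), ]
    mp <- dwknn_fit(perm, K = 5)
    expect_equal(predict(mp, q)$score, predict(m, q)$score)
  })
})

test_that("a zero-distance query is legal and model IO round-trips", {
  pf <- separable_pair_features(5, 5, seed = 35)
  m <- dwknn_fit(pf, K = 4)
  self_q <- pf[1, setdiff(names(pf), "label")]
  s <- predict(m, self_q)$score
  expect_true(s >= 0 && s <= 1)
  path <- tempfile(fileext = ".tsv")
  write_dwknn(m, path)
  m2 <- read_dwknn(path)
  expect_equal(m2$K, m$K)
  expect_equal(m2$labels, m$labels)
  expect_equal(predict(m2, self_q)$score, s)
  # broom-style accessors
  expect_equal(nrow(tidy(m)), 10)
  expect_equal(glance(m)$n_features, 4)
})
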