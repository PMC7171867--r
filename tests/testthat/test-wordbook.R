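test_that("sliding-window sampling yields L - l + 1 ordered fragments", {
  expect_equal(fragment_sliding(c(1, 2, 3), 2),
               matrix(c(1, 2, 2, 3), nrow = 2, byrow = TRUE))
  expect_equal(nrow(fragment_sliding(1:5, 2)), 4)
  expect_equal(nrow(fragment_sliding(1:3, 4)), 0)
  # left-to-right order
  fr <- fragment_sliding(10:1, 3)
  expect_equal(fr[1, ], c(10, 9, 8))
  expect_equal(fr[nrow(fr), ], c(3, 2, 1))
})

test_that("random sampling is reproducible, unique, and falls back", {
  enc <- withr::with_seed(1, stats::runif(1000))
  a <- fragment_random(enc, 2, 500, seed = 99)
  b <- fragment_random(enc, 2, 500, seed = 99)
  expect_equal(nrow(a), 500)
  expect_identical(a, b)
  # different seeds give generally different subsets of equal size
  c2 <- fragment_random(enc, 2, 500, seed = 100)
  expect_equal(nrow(c2), 500)
  expect_false(identical(a, c2))
  # short sequence: all sliding fragments returned (mode-1 fallback)
  short <- 1:10
  expect_equal(fragment_random(short, 2, 500, seed = 1),
               fragment_sliding(short, 2))
})

test_that("clustering recovers the brute-force optimal toy partition", {
  pts <- matrix(c(0, 0, 0, 0.1, 10, 10, 10, 10.1), ncol = 2, byrow = TRUE)
  centers <- cluster_fragments(pts, 2, seed = 5)
  # brute-force enumeration of all 2-partitions puts {1,2} and {3,4}
  # together; their means are the optimal centers
  expected <- matrix(c(0, 0.05, 10, 10.05), ncol = 2, byrow = TRUE)
  expect_equal(centers, expected, tolerance = 1e-12)
  # C = 1 is the coordinatewise mean
  expect_equal(cluster_fragments(pts, 1, seed = 1),
               matrix(colMeans(pts), nrow = 1))
  # fewer distinct points than clusters errors
  dup <- matrix(c(1, 1, 1, 1, 2, 2), ncol = 2, byrow = TRUE)
  expect_error(cluster_fragments(dup, 5),
               class = "bowdti_validation_error")
})

test_that("cluster centers stay in the bounding box and beat random centers", {
  withr::with_seed(7, {
    frags <- matrix(stats::rnorm(300 * 3), ncol = 3)
    centers <- cluster_fragments(frags, 8, seed = 2)
    expect_true(all(centers >= matrix(apply(frags, 2, min), 8, 3,
                                      byrow = TRUE)))
    expect_true(all(centers <= matrix(apply(frags, 2, max), 8, 3,
                                      byrow = TRUE)))
    wcss <- function(x, ctr) {
      d2 <- outer(rowSums(x^2), rowSums(ctr^2), `+`) - 2 * x %*% t(ctr)
      sum(apply(d2, 1, min))
    }
    rand_ctr <- frags[sample.int(nrow(frags), 8), ]
    expect_lte(wcss(frags, centers), wcss(frags, rand_ctr))
  })
})

test_that("wordbook building gives configured word counts, deterministically", {
  seqs <- generate_dataset(generator_config(n_gpcrs = 8, n_drugs = 5,
                                            n_pairs = 10, seed = 2))$sequences
  wb <- build_wordbook(seqs, hydropathy, seed = 3)
  expect_equal(vapply(wb$entries, nrow, 1L), c(`2` = 20L, `3` = 30L, `4` = 58L))
  expect_equal(vapply(wb$entries, ncol, 1L), c(`2` = 2L, `3` = 3L, `4` = 4L))
  expect_equal(wb$index_accession, "KYTJ820101")
  # no duplicated words within a length
  for (l in names(wb$entries)) {
    expect_equal(nrow(unique(wb$entries[[l]])), nrow(wb$entries[[l]]))
  }
  wb2 <- build_wordbook(seqs, hydropathy, seed = 3)
  expect_identical(wb, wb2)
  # the 10*l rule with a raised length-4 count
  cfg <- wordbook_config(cluster_counts = c(`2` = 20L, `3` = 30L, `4` = 58L))
  expect_equal(unname(cfg$cluster_counts), c(20L, 30L, 58L))
  # too few distinct fragments errors, naming the length
  expect_error(
    build_wordbook(tibble::tibble(gpcr_id = "g", sequence = "ACDEF"),
                   hydropathy, seed = 1),
    "length 2", class = "bowdti_validation_error"
  )
})

test_that("random-mode wordbooks pool 500 fragments per long sequence", {
  seqs <- generate_dataset(generator_config(n_gpcrs = 6, n_drugs = 5,
                                            n_pairs = 10,
                                            length_range = c(600, 900),
                                            seed = 4))$sequences
  cfg <- wordbook_config(cluster_counts = c(`2` = 10L), sampling = "random",
                         n_random = 500L)
  wb <- build_wordbook(seqs, hydropathy, cfg, seed = 5)
  expect_equal(nrow(wb$entries[["2"]]), 10)
  expect_identical(wb, build_wordbook(seqs, hydropathy, cfg, seed = 5))
})

test_that("wordbook serialization round-trips losslessly", {
  wb <- toy_wordbook()
  path <- tempfile(fileext = ".txt")
  write_wordbook(wb, path)
  back <- read_wordbook(path)
  expect_equal(back$index_accession, wb$index_accession)
  expect_equal(back$entries, wb$entries)
  # byte-stable across rewrites
  path2 <- tempfile()
  write_wordbook(back, path2)
  expect_identical(readLines(path), readLines(path2))
})
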