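# Shared fixtures and independent oracles used across the suite.

aa_letters <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Identity scale: A -> 1 ... Y -> 20. Makes encoded values readable.
identity_index <- aa_index("IDENT00001",
                           stats::setNames(1:20, aa_letters),
                           name = "identity fixture")

# A small two-column index file on disk.
write_two_column_index <- function(path = tempfile(fileext = ".txt")) {
  writeLines(paste(aa_letters, 1:20), path)
  path
}

# Kyte-Doolittle-style values for quick spot lookups.
hydropathy <- default_aaindex()

# Toy sequences long enough to populate every fragment length.
toy_sequences <- tibble::tibble(
  gpcr_id = c("g1", "g2", "g3"),
  sequence = c(
    strrep("ACDEFGHIKL", 8),
    strrep("MNPQRSTVWY", 8),
    strrep("AVAVLILIKR", 8)
  )
)

toy_wordbook <- function(counts = c(`2` = 4L, `3` = 5L, `4` = 6L),
                         seed = 1) {
  build_wordbook(toy_sequences, identity_index,
                 wordbook_config(cluster_counts = counts), seed = seed)
}

# Direct O(N^2) discrete Fourier transform, the oracle for stats::fft.
naive_dft_magnitudes <- function(x) {
  N <- length(x)
  k <- 0:(N - 1)
  vapply(k, function(kk) {
    ang <- -2 * pi * kk * (0:(N - 1)) / N
    Mod(sum(x * complex(real = cos(ang), imaginary = sin(ang))))
  }, numeric(1))
}

# Rank-statistic AUC: P(random positive outscores random negative),
# ties counted one half. O(n_pos * n_neg) pairwise oracle.
rank_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

random_hex_string <- function(n = 256) {
  paste(sample(c(as.character(0:9), LETTERS[1:6]), n, replace = TRUE),
        collapse = "")
}

# Small labeled pair set with features planted directly in feature space:
# positives cluster near 1, negatives near 0 in the first coordinate.
separable_pair_features <- function(n_pos = 8, n_neg = 12, seed = 1) {
  withr::with_seed(seed, {
    n <- n_pos + n_neg
    feats <- matrix(stats::runif(n * 4, 0, 0.1), ncol = 4)
    feats[seq_len(n_pos), 1] <- feats[seq_len(n_pos), 1] + 1
    colnames(feats) <- paste0("f", 1:4)
    dplyr::bind_cols(
      tibble::tibble(
        gpcr_id = sprintf("g%02d", seq_len(n)),
        drug_id = sprintf("d%02d", seq_len(n)),
        label = rep(c(1L, 0L), c(n_pos, n_neg))
      ),
      tibble::as_tibble(feats)
    )
  })
}
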