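#' Assign a fragment to its nearest word
#'
#' Nearest by Euclidean distance; ties broken toward the lowest word index.
#'
#' @param frag Numeric fragment of length `l`.
#' @param words Matrix of same-length words (rows).
#' @return 1-based index of the nearest word.
#' @export
assign_word <- function(frag, words) {
  if (length(frag) != ncol(words)) {
    abort("Fragment length does not match word length.",
          class = "bowdti_validation_error")
  }
  d2 <- rowSums(sweep(words, 2, frag)^2)
  which.min(d2) # which.min returns the first minimum: lowest-index tie rule
}

# Vectorized nearest-word assignment for a fragment matrix.
assign_words <- function(frags, words) {
  if (nrow(frags) == 0) {
    return(integer(0))
  }
  # squared distances via ||f||^2 - 2 f.w + ||w||^2
  cross <- frags %*% t(words)
  d2 <- sweep(-2 * cross, 2, rowSums(words^2), `+`)
  max.col(-d2, ties.method = "first")
}

#' Word-frequency block for one fragment length
#'
#' Slides the length-`l` window over the encoded sequence (sampling mode 1),
#' assigns every fragment to its nearest word, and returns word counts
#' divided by the number of fragments. A sequence shorter than `l` yields an
#' all-zero block rather than an error, so degenerate inputs still flow
#' through prediction.
#'
#' @param enc Encoded sequence (numeric vector).
#' @param l Fragment length (`l >= 2`; length 1 uses [aac_composition()]).
#' @param words Word matrix for this length.
#' @return Numeric frequency vector of length `nrow(words)`.
#' @export
word_frequencies <- function(enc, l, words) {
  stopifnot(l >= 2, ncol(words) == l)
  frags <- fragment_sliding(enc, l)
  out <- numeric(nrow(words))
  if (nrow(frags) == 0) {
    return(out)
  }
  hits <- tabulate(assign_words(frags, words), nbins = nrow(words))
  hits / nrow(frags)
}

#' Amino acid composition (AAC)
#'
#' Per-residue frequencies over the 20 standard residues in the fixed order
#' ACDEFGHIKLMNPQRSTVWY. Non-standard residues are excluded from both
#' numerator and denominator. This is the length-1 block of the receptor
#' feature vector (length-1 fragments cannot be clustered meaningfully, so
#' plain composition is used).
#'
#' @param seq Amino acid string.
#' @return Named numeric 20-vector summing to 1 (or all zeros if the
#'   sequence has no standard residues).
#' @export
#' @examples
#' aac_composition("ACDE")
aac_composition <- function(seq) {
  if (!is.character(seq) || length(seq) != 1 || nchar(trimws(seq)) == 0) {
    abort("`seq` must be a single non-empty string.",
          class = "bowdti_validation_error")
  }
  chars <- strsplit(gsub("\\s", "", toupper(seq)), "")[[1]]
  counts <- table(factor(chars, levels = AA_ALPHABET))
  counts <- as.numeric(counts)
  total <- sum(counts)
  out <- if (total > 0) counts / total else counts
  stats::setNames(out, AA_ALPHABET)
}

#' 128-D bag-of-words feature vector of a receptor sequence
#'
#' Concatenates the 20-D amino acid composition with the word-frequency
#' blocks for fragment lengths 2, 3 and 4 (20 + 30 + 58 words under the
#' default wordbook), giving 128 values. Each block sums to 1 when the
#' sequence yielded at least one fragment at that length and is all zeros
#' otherwise.
#'
#' @param seq Amino acid string.
#' @param wordbook A [build_wordbook()] result.
#' @param index The [aa_index()] used to build the wordbook; its accession
#'   must match `wordbook$index_accession`.
#' @param unknown_policy Passed to [encode_sequence()].
#' @return Numeric vector; 128 values under the default configuration.
#' @export
gpcr_feature_vector <- function(seq, wordbook, index,
                                unknown_policy = "mean") {
  if (!identical(attr(index, "accession"), wordbook$index_accession)) {
    abort(
      paste0("Wordbook was built with index ", wordbook$index_accession,
             " but got ", attr(index, "accession"), "."),
      class = "bowdti_validation_error"
    )
  }
  enc <- encode_sequence(seq, index, unknown_policy)
  blocks <- lapply(names(wordbook$entries), function(l) {
    word_frequencies(enc, as.integer(l), wordbook$entries[[l]])
  })
  c(unname(aac_composition(seq)), unlist(blocks, use.names = FALSE))
}

#' Featurize a table of receptor sequences
#'
#' @param sequences Tibble with `gpcr_id` and `sequence` columns.
#' @inheritParams gpcr_feature_vector
#' @return A tibble: `gpcr_id` plus one column per feature (`aac_*`, then
#'   `w<l>_<i>` for each word).
#' @export
gpcr_features <- function(sequences, wordbook, index,
                          unknown_policy = "mean") {
  mat <- t(vapply(
    sequences$sequence,
    gpcr_feature_vector,
    numeric(gpcr_feature_length(wordbook)),
    wordbook = wordbook, index = index, unknown_policy = unknown_policy,
    USE.NAMES = FALSE
  ))
  colnames(mat) <- gpcr_feature_names(wordbook)
  dplyr::bind_cols(
    tibble::tibble(gpcr_id = sequences$gpcr_id),
    tibble::as_tibble(mat)
  )
}

gpcr_feature_length <- function(wordbook) {
  20L + sum(vapply(wordbook$entries, nrow, 1L))
}

gpcr_feature_names <- function(wordbook) {
  c(
    paste0("aac_", AA_ALPHABET),
    unlist(lapply(names(wordbook$entries), function(l) {
      sprintf("w%s_%02d", l, seq_len(nrow(wordbook$entries[[l]])))
    }), use.names = FALSE)
  )
}
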