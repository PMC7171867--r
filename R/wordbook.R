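#' Sliding-window fragments of an encoded sequence
#'
#' Sampling mode 1: the window of length `l` moves left to right with
#' stride 1, yielding every fragment. A sequence shorter than `l` yields
#' zero fragments.
#'
#' @param enc Numeric vector, an encoded sequence (see [encode_sequence()]).
#' @param l Fragment length, `l >= 1`.
#' @return A matrix with `max(0, length(enc) - l + 1)` rows and `l` columns,
#'   fragments in order of their left endpoint.
#' @export
#' @examples
#' fragment_sliding(c(1, 2, 3), 2)
fragment_sliding <- function(enc, l) {
  stopifnot(l >= 1)
  n <- length(enc) - l + 1
  if (n <= 0) {
    return(matrix(numeric(0), nrow = 0, ncol = l))
  }
  idx <- outer(seq_len(n), 0:(l - 1), `+`)
  matrix(enc[idx], nrow = n, ncol = l)
}

#' Randomly sampled fragments of an encoded sequence
#'
#' Sampling mode 2: draws `n` fragments uniformly without replacement from
#' the sliding-window set. When the sequence is too short to supply `n`
#' fragments, all sliding-window fragments are returned instead (the
#' mode-1 fallback).
#'
#' @inheritParams fragment_sliding
#' @param n Number of fragments to draw.
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return A matrix of fragments (rows).
#' @export
fragment_random <- function(enc, l, n, seed) {
  stopifnot(l >= 1, n >= 1)
  all_frags <- fragment_sliding(enc, l)
  if (nrow(all_frags) < n) {
    return(all_frags)
  }
  keep <- withr::with_seed(seed, sample.int(nrow(all_frags), n))
  all_frags[keep, , drop = FALSE]
}

#' Cluster fragments into wordbook words
#'
#' Hard C-means (k-means) clustering of same-length fragments; the `C`
#' cluster centers become candidate words. Uses multiple random restarts
#' and returns the solution with the lowest within-cluster sum of squares;
#' deterministic under `seed`.
#'
#' @param fragments Matrix of fragments (rows), all the same length.
#' @param C Number of clusters; must not exceed the number of distinct
#'   fragments.
#' @param seed Integer seed.
#' @param nstart Number of random restarts.
#' @param max_iter Maximum Lloyd/Hartigan-Wong iterations.
#' @return A `C`-row matrix of cluster centers, sorted lexicographically
#'   by their coordinates so that word order is canonical.
#' @export
cluster_fragments <- function(fragments, C, seed = 1L, nstart = 10L,
                              max_iter = 300L) {
  fragments <- as.matrix(fragments)
  distinct <- unique(fragments)
  if (nrow(distinct) < C) {
    abort(
      paste0("Cannot form ", C, " clusters from ", nrow(distinct),
             " distinct fragments."),
      class = "bowdti_validation_error"
    )
  }
  if (nrow(distinct) == C) {
    centers <- distinct
  } else {
    fit <- withr::with_seed(
      seed,
      stats::kmeans(fragments, centers = C, nstart = nstart,
                    iter.max = max_iter)
    )
    centers <- fit$centers
  }
  ord <- do.call(order, lapply(seq_len(ncol(centers)), function(j) centers[, j]))
  unname(centers[ord, , drop = FALSE])
}

#' Default wordbook configuration
#'
#' Word counts per fragment length follow the 10*l rule for l = 2, 3 with
#' the l = 4 count raised to 58 so the receptor vector (20-D amino acid
#' composition + 20 + 30 + 58 word frequencies) matches the 128-D drug
#' vector.
#'
#' @param cluster_counts Named integer vector, words per fragment length.
#' @param sampling `"sliding"` (mode 1, every fragment) or `"random"`
#'   (mode 2, `n_random` fragments per sequence with mode-1 fallback for
#'   short sequences).
#' @param n_random Fragments per sequence under random sampling.
#' @param nstart,max_iter Clustering controls, see [cluster_fragments()].
#' @return A list of class `wordbook_config`.
#' @export
wordbook_config <- function(cluster_counts = c(`2` = 20L, `3` = 30L, `4` = 58L),
                            sampling = c("sliding", "random"),
                            n_random = 500L, nstart = 10L, max_iter = 300L) {
  sampling <- match.arg(sampling)
  stopifnot(all(cluster_counts >= 1), !is.null(names(cluster_counts)))
  structure(
    list(cluster_counts = cluster_counts, sampling = sampling,
         n_random = as.integer(n_random), nstart = as.integer(nstart),
         max_iter = as.integer(max_iter)),
    class = "wordbook_config"
  )
}

#' Learn a wordbook from training sequences
#'
#' Encodes every sequence with `index`, pools fragments of each configured
#' length across sequences (sliding or random sampling), clusters each pool
#' into its configured number of words, and stores the cluster centers as
#' the wordbook. Words are stored in canonical (lexicographic) order so a
#' wordbook built twice from the same inputs and seed is identical.
#'
#' @param sequences Tibble with `gpcr_id` and `sequence` columns, or a
#'   character vector of sequences.
#' @param index An [aa_index()]; its accession is recorded so that feature
#'   extraction can verify it uses the same scale.
#' @param config A [wordbook_config()].
#' @param seed Integer seed driving fragment sampling and clustering.
#' @param unknown_policy Passed to [encode_sequence()].
#' @return An object of class `wordbook`: list with `index_accession`,
#'   `entries` (named list of center matrices keyed by fragment length)
#'   and `config`.
#' @export
#' @examples
#' seqs <- tibble::tibble(
#'   gpcr_id = c("g1", "g2"),
#'   sequence = c(strrep("ACDEFGHIKL", 10), strrep("MNPQRSTVWY", 10))
#' )
#' wb <- build_wordbook(seqs, default_aaindex(),
#'                      wordbook_config(c(`2` = 3L)), seed = 1)
#' dim(wb$entries[["2"]])
build_wordbook <- function(sequences, index, config = wordbook_config(),
                           seed = 1L, unknown_policy = "mean") {
  if (is.character(sequences)) {
    sequences <- tibble::tibble(
      gpcr_id = paste0("seq", seq_along(sequences)), sequence = sequences
    )
  }
  encoded <- lapply(sequences$sequence, encode_sequence,
                    index = index, unknown_policy = unknown_policy)
  entries <- list()
  lengths <- as.integer(names(config$cluster_counts))
  for (i in seq_along(lengths)) {
    l <- lengths[i]
    C <- config$cluster_counts[[i]]
    pool <- lapply(seq_along(encoded), function(j) {
      if (config$sampling == "sliding") {
        fragment_sliding(encoded[[j]], l)
      } else {
        fragment_random(encoded[[j]], l, config$n_random,
                        seed = seed + 7919L * l + j)
      }
    })
    pool <- do.call(rbind, pool)
    if (nrow(unique(pool)) < C) {
      abort(
        paste0("Fragment length ", l, ": only ", nrow(unique(pool)),
               " distinct fragments pooled, need at least ", C, "."),
        class = "bowdti_validation_error"
      )
    }
    entries[[as.character(l)]] <- cluster_fragments(
      pool, C, seed = seed + l, nstart = config$nstart,
      max_iter = config$max_iter
    )
  }
  structure(
    list(index_accession = attr(index, "accession"), entries = entries,
         config = config),
    class = "wordbook"
  )
}

#' @export
print.wordbook <- function(x, ...) {
  sizes <- vapply(x$entries, nrow, 1L)
  cat("<wordbook> index ", x$index_accession, "; words per length: ",
      paste(names(sizes), sizes, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Serialize a wordbook to a plain-text file
#'
#' The format is line-oriented: a header with the index accession, then one
#' block per fragment length listing each center as tab-separated
#' full-precision decimals. [read_wordbook()] restores it losslessly.
#'
#' @param wordbook A [build_wordbook()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wordbook <- function(wordbook, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#wordbook\tindex=", wordbook$index_accession), con)
  for (l in names(wordbook$entries)) {
    m <- wordbook$entries[[l]]
    writeLines(paste0("#length\t", l, "\t", nrow(m)), con)
    writeLines(apply(m, 1, function(r) {
      paste(sprintf("%.17g", r), collapse = "\t")
    }), con)
  }
  invisible(path)
}

#' Read a wordbook written by [write_wordbook()]
#'
#' @param path Path to a wordbook text file.
#' @return A `wordbook` object.
#' @export
read_wordbook <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#wordbook")) {
    abort("Not a wordbook file.", class = "bowdti_format_error")
  }
  accession <- sub(".*index=", "", lines[1])
  entries <- list()
  i <- 2
  while (i <= length(lines)) {
    stopifnot(startsWith(lines[i], "#length"))
    hdr <- strsplit(lines[i], "\t")[[1]]
    l <- hdr[2]
    n <- as.integer(hdr[3])
    rows <- lines[(i + 1):(i + n)]
    entries[[l]] <- do.call(rbind, lapply(strsplit(rows, "\t"), as.numeric))
    i <- i + n + 1
  }
  counts <- stats::setNames(vapply(entries, nrow, 1L), names(entries))
  structure(
    list(index_accession = accession, entries = entries,
         config = wordbook_config(cluster_counts = counts)),
    class = "wordbook"
  )
}

#' Scatter plot of a wordbook's length-2 words over their fragments
#'
#' @param object A `wordbook`.
#' @param fragments Optional 2-column matrix of the training fragments to
#'   draw behind the words.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.wordbook <- function(object, fragments = NULL, ...) {
  words <- object$entries[["2"]]
  if (is.null(words)) {
    abort("Wordbook has no length-2 entry to plot.",
          class = "bowdti_validation_error")
  }
  p <- ggplot2::ggplot()
  if (!is.null(fragments)) {
    fd <- tibble::tibble(x = fragments[, 1], y = fragments[, 2])
    p <- p + ggplot2::geom_point(
      data = fd, ggplot2::aes(x = .data$x, y = .data$y),
      alpha = 0.2, size = 0.6
    )
  }
  wd <- tibble::tibble(x = words[, 1], y = words[, 2])
  p +
    ggplot2::geom_point(
      data = wd, ggplot2::aes(x = .data$x, y = .data$y),
      shape = 8, size = 3, colour = "black"
    ) +
    ggplot2::labs(
      x = "first residue property value", y = "second residue property value",
      title = paste0("Length-2 words (", object$index_accession, ")")
    )
}
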