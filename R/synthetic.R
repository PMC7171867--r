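#' Configuration of the synthetic benchmark generator
#'
#' The generator emulates the statistical shape of curated GPCR-drug
#' benchmarks: dozens of receptors (sequences 50-1000 residues), a larger
#' drug panel (256-hex-character fingerprints) and an imbalanced labeled
#' pair list with roughly one interactive pair per 1.9 non-interactive
#' ones. Interactions follow latent classes: each class owns a tripeptide
#' sequence motif and a reserved 32-character fingerprint block, both
#' planted with probability `motif_strength`, and a pair is interactive
#' when receptor and drug share a class. Labels are then flipped with
#' probability `noise`. At `motif_strength = 0` neither modality carries
#' the signal, which calibrates the null.
#'
#' @param n_gpcrs,n_drugs,n_pairs Dataset sizes (defaults 30/60/400).
#' @param length_range Sequence length bounds in residues.
#' @param positive_fraction Fraction of interactive pairs before noise
#'   (default 635/1860, the imbalance of the published training benchmark).
#' @param n_classes Latent interaction classes.
#' @param motif_strength Probability a molecule carries its class signal.
#' @param noise Label-flip probability.
#' @param seed Integer seed.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_gpcrs = 30L, n_drugs = 60L, n_pairs = 400L,
                             length_range = c(50L, 1000L),
                             positive_fraction = 635 / 1860,
                             n_classes = 3L, motif_strength = 0.9,
                             noise = 0.05, seed = 7L) {
  stopifnot(n_gpcrs >= 1, n_drugs >= 1, n_pairs >= 1, n_classes >= 1,
            length_range[1] >= 10, length_range[1] <= length_range[2],
            positive_fraction >= 0, positive_fraction <= 1,
            motif_strength >= 0, motif_strength <= 1,
            noise >= 0, noise <= 1)
  structure(
    list(n_gpcrs = as.integer(n_gpcrs), n_drugs = as.integer(n_drugs),
         n_pairs = as.integer(n_pairs),
         length_range = as.integer(length_range),
         positive_fraction = positive_fraction,
         n_classes = as.integer(n_classes),
         motif_strength = motif_strength, noise = noise,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# Class signatures: tripeptide motifs spread across the hydropathy scale
# and composition space, and per-class hex digits for the fingerprint
# block. Classes beyond the predefined ones recycle with an offset.
class_motif <- function(class) {
  motifs <- c("IVI", "DED", "KGK", "WFW", "STS", "PNP")
  motifs[(class - 1) %% length(motifs) + 1]
}

# Square-wave blocks of class-specific period: each class puts a distinct
# spectral line (and harmonics) into the fingerprint's DFT amplitudes.
class_fp_block <- function(class) {
  patterns <- c(
    strrep("FF00", 8),                # period 4
    strrep("FFFF0000", 4),            # period 8
    strrep("FFFFFFFF00000000", 2),    # period 16
    paste0(strrep("F", 16), strrep("0", 16)), # period 32
    strrep("FF000000", 4),            # period 8, quarter duty
    strrep("FFFF000000000000", 2)     # period 16, quarter duty
  )
  patterns[(class - 1) %% length(patterns) + 1]
}

class_fp_offset <- function(class, n_classes) {
  # non-overlapping 32-char windows, wrapped into the 256-char string
  (32 * ((class - 1) %% 8)) + 1
}

random_sequence <- function(len, motif = NULL) {
  if (is.null(motif)) {
    return(paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = ""))
  }
  # tile the motif through the sequence: one copy per ~10 residues, about
  # the motif density of a conserved repeat family
  n_blocks <- max(1, floor(len / 10))
  filler_len <- len - 3 * n_blocks
  filler <- sample(AA_ALPHABET, max(filler_len, 0), replace = TRUE)
  per_block <- ceiling(length(filler) / n_blocks)
  out <- character(0)
  for (b in seq_len(n_blocks)) {
    lo <- (b - 1) * per_block + 1
    hi <- min(b * per_block, length(filler))
    out <- c(out, if (lo <= hi) filler[lo:hi] else character(0),
             strsplit(motif, "")[[1]])
  }
  substr(paste(out, collapse = ""), 1, len)
}

# Background fingerprints are sparse, like real path-based fingerprints:
# each of the 1024 bits is set independently with probability `bit_density`
# (~150 bits set), then packed into 256 hex characters.
random_fingerprint <- function(block = NULL, offset = 1L,
                               bit_density = 0.10) {
  hex <- c(as.character(0:9), LETTERS[1:6])
  bits <- matrix(stats::runif(1024) < bit_density, nrow = 4)
  fp <- paste(hex[colSums(bits * c(8, 4, 2, 1)) + 1], collapse = "")
  if (!is.null(block)) {
    substr(fp, offset, offset + nchar(block) - 1) <- block
  }
  fp
}

#' Generate a synthetic receptor-drug interaction dataset
#'
#' @param config A [generator_config()].
#' @return A list of class `bowdti_dataset` with tibbles `sequences`
#'   (`gpcr_id`, `sequence`, `class`, `has_motif`), `fingerprints`
#'   (`drug_id`, `fingerprint`, `class`, `has_block`) and `pairs`
#'   (`gpcr_id`, `drug_id`, `label`, `true_label`), plus the `config`.
#' @export
#' @examples
#' ds <- generate_dataset(generator_config(n_gpcrs = 6, n_drugs = 8,
#'                                         n_pairs = 20, seed = 1))
#' table(ds$pairs$label)
generate_dataset <- function(config = generator_config()) {
  if (config$n_pairs > config$n_gpcrs * config$n_drugs) {
    abort("Requested more pairs than distinct receptor-drug combinations.",
          class = "bowdti_validation_error")
  }
  withr::with_seed(config$seed, {
    g_class <- sample(seq_len(config$n_classes), config$n_gpcrs,
                      replace = TRUE)
    d_class <- sample(seq_len(config$n_classes), config$n_drugs,
                      replace = TRUE)
    g_motif <- stats::runif(config$n_gpcrs) < config$motif_strength
    d_block <- stats::runif(config$n_drugs) < config$motif_strength

    lens <- sample(seq(config$length_range[1], config$length_range[2]),
                   config$n_gpcrs, replace = TRUE)
    sequences <- tibble::tibble(
      gpcr_id = sprintf("G%03d", seq_len(config$n_gpcrs)),
      sequence = vapply(seq_len(config$n_gpcrs), function(i) {
        random_sequence(lens[i],
                        if (g_motif[i]) class_motif(g_class[i]) else NULL)
      }, character(1)),
      class = g_class,
      has_motif = g_motif
    )
    fingerprints <- tibble::tibble(
      drug_id = sprintf("D%03d", seq_len(config$n_drugs)),
      fingerprint = vapply(seq_len(config$n_drugs), function(i) {
        if (d_block[i]) {
          random_fingerprint(class_fp_block(d_class[i]),
                             class_fp_offset(d_class[i], config$n_classes))
        } else {
          random_fingerprint()
        }
      }, character(1)),
      class = d_class,
      has_block = d_block
    )

    combos <- tidyr::expand_grid(
      g = seq_len(config$n_gpcrs), d = seq_len(config$n_drugs)
    )
    combos$match <- g_class[combos$g] == d_class[combos$d]
    n_pos <- round(config$positive_fraction * config$n_pairs)
    n_pos <- min(n_pos, sum(combos$match))
    n_neg <- min(config$n_pairs - n_pos, sum(!combos$match))
    pos_rows <- combos[combos$match, ][
      sample.int(sum(combos$match), n_pos), ]
    neg_rows <- combos[!combos$match, ][
      sample.int(sum(!combos$match), n_neg), ]
    chosen <- dplyr::bind_rows(pos_rows, neg_rows)
    true_label <- as.integer(chosen$match)
    flip <- stats::runif(nrow(chosen)) < config$noise
    pairs <- tibble::tibble(
      gpcr_id = sequences$gpcr_id[chosen$g],
      drug_id = fingerprints$drug_id[chosen$d],
      label = as.integer(xor(true_label == 1L, flip)),
      true_label = true_label
    )
    pairs <- pairs[order(pairs$gpcr_id, pairs$drug_id), ]
  })
  structure(
    list(sequences = sequences, fingerprints = fingerprints, pairs = pairs,
         config = config),
    class = "bowdti_dataset"
  )
}

#' @export
print.bowdti_dataset <- function(x, ...) {
  cat("<bowdti_dataset> ", nrow(x$sequences), " receptors, ",
      nrow(x$fingerprints), " drugs, ", nrow(x$pairs), " pairs (",
      sum(x$pairs$label == 1), " interactive)\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to standard files
#'
#' Emits `sequences.fasta`, `fingerprints.tsv`, `pairs.tsv` (without the
#' generator's hidden columns) and `manifest.json` recording the
#' configuration, into `dir`.
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sequences(dataset$sequences, file.path(dir, "sequences.fasta"))
  write_fingerprints(dataset$fingerprints, file.path(dir, "fingerprints.tsv"))
  write_pairs(dataset$pairs[, c("gpcr_id", "drug_id", "label")],
              file.path(dir, "pairs.tsv"))
  jsonlite::write_json(unclass(dataset$config),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Fixed hand-checkable micro-dataset
#'
#' Six short sequences, six patterned fingerprints and twelve labeled
#' pairs, small enough that fragment-to-word assignments under a tiny
#' wordbook can be verified by eye. Identical on every call.
#'
#' @return A `bowdti_dataset`.
#' @export
worked_example <- function() {
  sequences <- tibble::tibble(
    gpcr_id = sprintf("G%d", 1:6),
    sequence = c(
      strrep("IVIVIVIVIV", 2),  # strongly hydrophobic
      strrep("DEDEDEDEDE", 2),  # strongly hydrophilic
      strrep("IVDEIVDEIV", 2),  # alternating blocks
      strrep("KGKGKGKGKG", 2),
      strrep("IVKGIVKGIV", 2),
      strrep("DEKGDEKGDE", 2)
    ),
    class = c(1L, 2L, 1L, 3L, 1L, 2L),
    has_motif = TRUE
  )
  fingerprints <- tibble::tibble(
    drug_id = sprintf("D%d", 1:6),
    # six periodic fingerprints with pairwise distinct normalized
    # amplitude spectra (different periods and duty cycles; note that
    # cyclic shifts or rescalings of one another would collide)
    fingerprint = c(
      strrep("F000", 64), strrep("FF00", 64), strrep("F0", 128),
      strrep("FF000000", 32), strrep("FFFF0000", 32),
      strrep("FFFFFFFF00000000", 16)
    ),
    class = c(1L, 1L, 1L, 2L, 2L, 3L),
    has_block = TRUE
  )
  pairs <- tibble::tibble(
    gpcr_id = sequences$gpcr_id[c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 6, 6)],
    drug_id = fingerprints$drug_id[c(1, 4, 2, 6, 3, 5, 4, 1, 2, 6, 5, 3)]
  )
  g_cl <- sequences$class[match(pairs$gpcr_id, sequences$gpcr_id)]
  d_cl <- fingerprints$class[match(pairs$drug_id, fingerprints$drug_id)]
  pairs$label <- as.integer(g_cl == d_cl)
  pairs$true_label <- pairs$label
  structure(
    list(sequences = sequences, fingerprints = fingerprints, pairs = pairs,
         config = NULL),
    class = "bowdti_dataset"
  )
}
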