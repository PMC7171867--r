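#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort
#' @importFrom dplyr %>%
NULL

# Fixed residue order used everywhere a 20-vector over the standard amino
# acids is laid out.
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# AAindex1 "I" records list values in this order (two rows of ten).
AAINDEX_I_ORDER <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

#' Construct an amino acid property index
#'
#' An amino acid index maps each of the 20 standard one-letter residue
#' codes to a real property value (hydropathy, molecular weight, ...).
#'
#' @param accession Identifier string, e.g. `"KYTJ820101"`.
#' @param values Named numeric vector with exactly the 20 standard residue
#'   codes as names; all values must be finite.
#' @param name Free-text description of the scale.
#' @param standardize If `TRUE`, rescale the 20 values to zero mean and
#'   unit variance. Off by default: downstream clustering operates on the
#'   raw scale.
#'
#' @return An object of class `aa_index`: the named 20-vector with
#'   attributes `accession` and `name`.
#' @export
#' @examples
#' idx <- aa_index("TOY0000001", setNames(1:20, strsplit(
#'   "ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
#' idx[["A"]]
aa_index <- function(accession, values, name = "", standardize = FALSE) {
  if (!is.numeric(values) || is.null(names(values))) {
    abort("`values` must be a named numeric vector.", class = "bowdti_format_error")
  }
  missing_aa <- setdiff(AA_ALPHABET, names(values))
  if (length(missing_aa) > 0) {
    abort(
      paste0("Index `", accession, "` is missing residues: ",
             paste(missing_aa, collapse = ", ")),
      class = "bowdti_format_error"
    )
  }
  values <- values[AA_ALPHABET]
  if (any(!is.finite(values))) {
    abort(paste0("Index `", accession, "` contains non-finite values."),
          class = "bowdti_format_error")
  }
  if (standardize) {
    values <- (values - mean(values)) / stats::sd(values)
  }
  structure(values, accession = accession, name = name, class = "aa_index")
}

#' @export
print.aa_index <- function(x, ...) {
  cat("<aa_index> ", attr(x, "accession"), ": ", attr(x, "name"), "\n", sep = "")
  print(unclass(x))
  invisible(x)
}

#' Read amino acid indices from an AAindex1 flat file or a two-column table
#'
#' Supports two plain-text formats: the AAindex1 flat-file layout (records
#' delimited by `//`, with `H` accession lines, `D` description lines and an
#' `I` line followed by two rows of ten values in the database's standard
#' residue order) and a simple two-column whitespace- or tab-separated
#' `residue value` table (20 rows, any order).
#'
#' @param path Path to the file.
#' @param accession Accession to extract. For the two-column format any
#'   value is accepted and recorded as the accession of the result.
#' @param standardize Passed to [aa_index()].
#'
#' @return An [aa_index()] object.
#' @export
#' @examples
#' path <- system.file("extdata", "aaindex_default.txt", package = "bowdti")
#' hyd <- read_aaindex(path, "KYTJ820101")
#' hyd[["I"]] > hyd[["R"]]  # hydrophobic residues score high
read_aaindex <- function(path, accession, standardize = FALSE) {
  lines <- readLines(path, warn = FALSE)
  # AAindex1 flat files carry both H accession lines and // terminators; a
  # bare "H <value>" row in a two-column table must not trigger this branch
  if (any(grepl("^H ", lines)) && any(grepl("^//", lines))) {
    return(parse_aaindex1(lines, accession, standardize))
  }
  parse_two_column_index(lines, accession, standardize)
}

parse_aaindex1 <- function(lines, accession, standardize) {
  starts <- grep("^H ", lines)
  accs <- sub("^H\\s+", "", lines[starts])
  hit <- which(trimws(accs) == accession)
  if (length(hit) == 0) {
    abort(paste0("Accession `", accession, "` not found."),
          class = "bowdti_not_found_error")
  }
  start <- starts[hit[1]]
  ends <- grep("^//", lines)
  end <- min(ends[ends > start], length(lines))
  block <- lines[start:end]
  d_line <- grep("^D ", block, value = TRUE)
  name <- if (length(d_line)) trimws(sub("^D\\s+", "", d_line[1])) else ""
  i_at <- grep("^I ", block)
  if (length(i_at) == 0 || i_at[1] + 2 > length(block)) {
    abort(paste0("Malformed record for `", accession, "`: no I block."),
          class = "bowdti_format_error")
  }
  vals <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(block[i_at[1] + 1:2]), "\\s+")
  )))
  if (length(vals) != 20 || any(is.na(vals))) {
    abort(paste0("Record `", accession, "` does not contain 20 numeric values."),
          class = "bowdti_format_error")
  }
  aa_index(accession, stats::setNames(vals, AAINDEX_I_ORDER), name, standardize)
}

parse_two_column_index <- function(lines, accession, standardize) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\\s+")
  ok <- vapply(parts, length, 1L) >= 2
  parts <- parts[ok]
  res <- toupper(vapply(parts, `[[`, "", 1))
  val <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  keep <- res %in% AA_ALPHABET & !is.na(val)
  if (sum(keep) < 20) {
    abort("Two-column index table must provide values for all 20 residues.",
          class = "bowdti_format_error")
  }
  aa_index(accession, stats::setNames(val[keep], res[keep]), "", standardize)
}

#' The package's bundled amino acid indices
#'
#' Five AAindex scales commonly used for receptor encoding are shipped as a
#' plain-text data asset: hydropathy (KYTJ820101), molecular weight
#' (FASG760101), isoelectric point (ZIMJ680104), pK of the alpha-amino group
#' (FASG760104) and pK of the alpha-carboxyl group (FASG760105).
#'
#' @param accession One of the bundled accessions; defaults to hydropathy.
#' @return An [aa_index()] object.
#' @export
default_aaindex <- function(accession = "KYTJ820101") {
  read_aaindex(
    system.file("extdata", "aaindex_default.txt", package = "bowdti"),
    accession
  )
}

#' Accessions of the bundled amino acid indices
#' @return Character vector of five accessions.
#' @export
default_aaindex_accessions <- function() {
  c("KYTJ820101", "FASG760101", "ZIMJ680104", "FASG760104", "FASG760105")
}

#' Encode an amino acid sequence as a numeric property series
#'
#' Replaces each residue of the primary sequence by its property value
#' under `index`, giving the numeric series the wordbook fragments are
#' sampled from. Input is uppercased first. Non-standard codes (B, J, O,
#' U, X, Z and anything else outside the 20-letter alphabet) are either
#' assigned the mean of the 20 index values (`"mean"`, the default, which
#' preserves sequence length and therefore fragment counts) or removed
#' (`"drop"`).
#'
#' @param seq Amino acid string (one sequence).
#' @param index An [aa_index()].
#' @param unknown_policy `"mean"` or `"drop"`.
#'
#' @return Numeric vector of encoded values.
#' @export
#' @examples
#' encode_sequence("AR", default_aaindex())
encode_sequence <- function(seq, index,
                            unknown_policy = c("mean", "drop")) {
  unknown_policy <- match.arg(unknown_policy)
  stopifnot(inherits(index, "aa_index"))
  seq <- gsub("\\s", "", toupper(seq))
  if (!is.character(seq) || length(seq) != 1 || nchar(seq) == 0) {
    abort("`seq` must be a single non-empty string.",
          class = "bowdti_validation_error")
  }
  chars <- strsplit(seq, "")[[1]]
  vals <- unclass(index)[chars]
  if (unknown_policy == "mean") {
    vals[is.na(vals)] <- mean(unclass(index))
  } else {
    vals <- vals[!is.na(vals)]
  }
  if (length(vals) == 0) {
    abort("Sequence has no standard residues after applying `drop`.",
          class = "bowdti_validation_error")
  }
  unname(vals)
}

#' Read protein sequences from a FASTA file
#'
#' Identifiers are the first whitespace-delimited token of each header.
#'
#' @param path FASTA file (multi-record, wrapped lines allowed).
#' @return A tibble with columns `gpcr_id` and `sequence`.
#' @export
read_sequences <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1)
  tibble::tibble(gpcr_id = ids, sequence = unname(as.character(set)))
}

#' Write protein sequences to a FASTA file
#'
#' @param sequences Tibble with `gpcr_id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(sequences, path) {
  set <- Biostrings::AAStringSet(sequences$sequence)
  names(set) <- sequences$gpcr_id
  Biostrings::writeXStringSet(set, path, width = 70)
  invisible(path)
}
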