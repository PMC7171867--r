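#' Parse an FP2-style hexadecimal fingerprint
#'
#' An FP2 fingerprint is a 1024-bit path-based fingerprint emitted as a
#' 256-character hexadecimal string. Each character is read as its integer
#' value 0-15, giving a 256-point digital signal. Whitespace (including the
#' line breaks of multi-line fingerprint dumps) is stripped first and
#' parsing is case-insensitive.
#'
#' @param hex_string Fingerprint text.
#' @param drug_id Identifier carried along for error messages and output.
#' @return Integer vector of 256 digits in `[0, 15]`.
#' @export
#' @examples
#' parse_fingerprint(strrep("0F", 128))[1:4]
parse_fingerprint <- function(hex_string, drug_id = "?") {
  s <- toupper(gsub("\\s", "", hex_string))
  if (nchar(s) != 256) {
    abort(
      paste0("Fingerprint for `", drug_id, "` has ", nchar(s),
             " hex characters; expected 256."),
      class = "bowdti_format_error"
    )
  }
  chars <- strsplit(s, "")[[1]]
  digits <- match(chars, c(as.character(0:9), LETTERS[1:6])) - 1L
  if (anyNA(digits)) {
    bad <- which(is.na(digits))[1]
    abort(
      paste0("Fingerprint for `", drug_id, "`: non-hex character '",
             chars[bad], "' at position ", bad, "."),
      class = "bowdti_format_error"
    )
  }
  digits
}

#' Normalized DFT amplitude features of a fingerprint signal
#'
#' Computes the 256-point discrete Fourier transform of the digit signal
#' and keeps the magnitudes of coefficients k = 0..127 — the non-redundant
#' half for a real signal, whose spectrum is conjugate-symmetric. Each
#' magnitude is divided by the sum of the 128 kept magnitudes so the vector
#' sums to 1. An all-zero signal (sum of magnitudes 0) maps to the uniform
#' vector 1/128 so degenerate drugs remain classifiable.
#'
#' @param digits Integer vector of 256 fingerprint digits.
#' @param include_dc If `TRUE` (default) the kept coefficients are
#'   k = 0..127, including the DC term; if `FALSE`, k = 1..128.
#' @return Numeric vector of 128 non-negative amplitudes.
#' @export
#' @examples
#' dft_amplitudes(rep(3L, 256))[1:3]  # constant signal: all energy at DC
dft_amplitudes <- function(digits, include_dc = TRUE) {
  stopifnot(length(digits) == 256)
  mags <- Mod(stats::fft(as.numeric(digits)))
  kept <- if (include_dc) mags[1:128] else mags[2:129]
  s <- sum(kept)
  if (s == 0) {
    return(rep(1 / 128, 128))
  }
  kept / s
}

#' Featurize a table of drug fingerprints
#'
#' @param fingerprints Tibble with `drug_id` and `fingerprint` (256-hex-char
#'   string) columns.
#' @inheritParams dft_amplitudes
#' @return A tibble: `drug_id` plus amplitude columns `amp_001`..`amp_128`.
#' @export
drug_features <- function(fingerprints, include_dc = TRUE) {
  mat <- t(mapply(function(fp, id) {
    dft_amplitudes(parse_fingerprint(fp, id), include_dc = include_dc)
  }, fingerprints$fingerprint, fingerprints$drug_id, USE.NAMES = FALSE))
  colnames(mat) <- sprintf("amp_%03d", 1:128)
  dplyr::bind_cols(
    tibble::tibble(drug_id = fingerprints$drug_id),
    tibble::as_tibble(mat)
  )
}

#' Read drug fingerprints from a TSV file
#'
#' Expects two tab-separated columns, `drug_id` and `fingerprint`. A header
#' row is detected by the literal column names. Fingerprints may contain
#' internal whitespace (multi-line dump style); it is removed.
#'
#' @param path Input TSV.
#' @return Tibble with `drug_id` and `fingerprint` columns.
#' @export
read_fingerprints <- function(path) {
  df <- readr::read_tsv(
    path,
    col_names = c("drug_id", "fingerprint"),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(df) > 0 && identical(tolower(df$drug_id[1]), "drug_id")) {
    df <- df[-1, ]
  }
  df$fingerprint <- gsub("\\s", "", df$fingerprint)
  df
}

#' Write drug fingerprints to TSV
#' @param fingerprints Tibble with `drug_id` and `fingerprint` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fingerprints, path) {
  readr::write_tsv(fingerprints[, c("drug_id", "fingerprint")], path)
  invisible(path)
}

#' Read a labeled (or unlabeled) receptor-drug pair table from TSV
#'
#' Columns: `gpcr_id`, `drug_id` and optionally `label` (0/1, 1 =
#' interactive pair).
#'
#' @param path Input TSV.
#' @return Tibble with `gpcr_id`, `drug_id` and, when present, integer
#'   `label`.
#' @export
read_pairs <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    gpcr_id = readr::col_character(),
    drug_id = readr::col_character(),
    .default = readr::col_integer()
  ), progress = FALSE)
  if ("label" %in% names(df) && !all(df$label %in% c(0L, 1L))) {
    abort("`label` must be 0 or 1.", class = "bowdti_format_error")
  }
  df
}

#' Write a pair table to TSV
#' @param pairs Tibble with `gpcr_id`, `drug_id` and optional further
#'   columns (`label`, `score`, ...).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  readr::write_tsv(pairs, path)
  invisible(path)
}
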