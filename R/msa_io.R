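#' Encode aligned sequences as a 21-state integer matrix
#'
#' Maps each symbol of each row to an integer code: the 20 canonical amino
#' acids map to 0..19 in alphabetical one-letter order (`A = 0`, `C = 1`, ...,
#' `Y = 19`); `-`, `.` and every other symbol -- ambiguity codes (B, J, O, U,
#' X, Z), lowercase letters, anything non-canonical -- are pooled into the gap
#' state, code 20. Encoding is a pure per-character function; no case folding
#' is performed.
#'
#' @param rows Character vector of equal-length aligned sequences.
#' @return Integer matrix with one row per sequence, values in `0:20`.
#' @seealso [decode_symbols()] for the inverse (non-canonical symbols come
#'   back as `-`).
#' @export
#' @examples
#' encode_symbols(c("AC-E", "ACDE"))
encode_symbols <- function(rows) {
  stopifnot(is.character(rows), length(rows) >= 1L)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    stop_coev("rows have unequal lengths; encode_symbols requires an alignment",
              "coev_format_error")
  }
  chars <- strsplit(rows, "", fixed = TRUE)
  codes <- match(unlist(chars), AA_ALPHABET)
  codes[is.na(codes)] <- Q_STATES  # gap class, becomes 20 after the -1 below
  matrix(as.integer(codes) - 1L, nrow = length(rows), ncol = widths[1L],
         byrow = TRUE)
}

#' Decode an integer-encoded alignment back to character rows
#'
#' Codes 0..19 decode to the canonical amino acids; code 20 decodes to `-`.
#' `decode_symbols(encode_symbols(x))` reproduces `x` with every
#' non-canonical symbol replaced by `-`.
#'
#' @param encoded Integer matrix with values in `0:20`.
#' @return Character vector of sequences.
#' @export
decode_symbols <- function(encoded) {
  stopifnot(is.matrix(encoded))
  lut <- c(AA_ALPHABET, "-")
  apply(encoded, 1L, function(r) paste(lut[r + 1L], collapse = ""))
}

new_alignment <- function(rows) {
  if (length(rows) < 1L || any(!nzchar(rows))) {
    stop_coev("alignment must contain at least one non-empty sequence",
              "coev_empty_input")
  }
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop_coev(sprintf(
      "ragged alignment: row %d has length %d, expected %d",
      bad, widths[bad], widths[1L]), "coev_format_error")
  }
  encoded <- encode_symbols(rows)
  structure(list(
    rows = rows,
    encoded = encoded,
    M = length(rows),
    L = widths[1L],
    target_residues = strsplit(rows[1L], "", fixed = TRUE)[[1L]]
  ), class = "coev_alignment")
}

alignment_from_encoded <- function(encoded) {
  new_alignment(decode_symbols(encoded))
}

#' Read a multiple sequence alignment
#'
#' Reads an aligned FASTA file or a flat alignment (one aligned sequence per
#' line, no headers, first line the target). Row 0 (the first record) is the
#' target sequence; residue positions are 1-based on it throughout the
#' package. Gap columns of the target are deliberately *not* removed: the
#' alignment is assumed to be target-matched by the upstream aligner.
#'
#' @param file Path to the alignment file, or `NULL` when `text` is given.
#' @param text Optional character scalar/vector holding the alignment content
#'   directly (vector elements are treated as lines).
#' @param format `"auto"` (detect FASTA by a leading `>`), `"fasta"` or
#'   `"flat"`.
#' @return A `coev_alignment`: list with `rows`, integer `encoded` (M x L,
#'   codes 0..20 with 20 = gap/non-canonical), `M`, `L`, `target_residues`.
#' @export
#' @examples
#' aln <- read_alignment(text = "ACDE\nACDG", format = "flat")
#' aln$M; aln$L
read_alignment <- function(file = NULL, text = NULL,
                           format = c("auto", "fasta", "flat")) {
  format <- match.arg(format)
  if (is.null(file) == is.null(text)) {
    stop("exactly one of 'file' and 'text' must be given")
  }
  if (!is.null(text)) {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  } else {
    if (!identical(file, "stdin") && !file.exists(file)) {
      stop_coev(sprintf("alignment file '%s' not found", file),
                "coev_format_error")
    }
    lines <- readLines(file, warn = FALSE)
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop_coev("empty alignment input", "coev_empty_input")
  }
  if (format == "auto") {
    format <- if (startsWith(trimws(lines[1L]), ">")) "fasta" else "flat"
  }
  rows <- switch(format,
    fasta = read_fasta_rows(file, lines),
    flat  = trimws(lines)
  )
  aln <- new_alignment(rows)
  aln
}

## FASTA parsing goes through Biostrings when we have a real file; for
## in-memory text a temp file keeps a single code path.
read_fasta_rows <- function(file, lines) {
  if (is.null(file)) {
    file <- tempfile(fileext = ".fasta")
    on.exit(unlink(file), add = TRUE)
    writeLines(lines, file)
  }
  set <- Biostrings::readBStringSet(file)
  if (length(set) == 0L) {
    stop_coev("empty alignment input", "coev_empty_input")
  }
  rows <- as.character(set)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    nm <- names(rows)[bad]
    stop_coev(sprintf(
      "ragged alignment: record %d ('%s') has length %d, expected %d",
      bad, if (is.null(nm)) "" else nm, widths[bad], widths[1L]),
      "coev_format_error")
  }
  unname(rows)
}

#' Write an alignment to FASTA or flat format
#'
#' @param aln A `coev_alignment`.
#' @param file Output path.
#' @param format `"fasta"` or `"flat"`.
#' @export
write_alignment <- function(aln, file, format = c("fasta", "flat")) {
  format <- match.arg(format)
  stopifnot(inherits(aln, "coev_alignment"))
  if (format == "flat") {
    writeLines(aln$rows, file)
  } else {
    set <- Biostrings::BStringSet(aln$rows)
    names(set) <- c("target", sprintf("seq%d", seq_len(aln$M - 1L) + 1L))[seq_len(aln$M)]
    Biostrings::writeXStringSet(set, file)
  }
  invisible(file)
}

#' @export
print.coev_alignment <- function(x, ...) {
  cat(sprintf("<coev_alignment> %d sequences x %d columns; target: %s%s\n",
              x$M, x$L, substr(x$rows[1L], 1L, 40L),
              if (x$L > 40L) "..." else ""))
  invisible(x)
}

#' Write a ranked contact list as TSV
#'
#' One line per pair with the six columns
#' `i`, `res_i`, `j`, `res_j`, `raw_score`, `corrected_score`
#' (`i < j`, 1-based target positions, scores printed with 6 significant
#' digits), sorted by descending corrected score. An empty contact list
#' produces empty output.
#'
#' @param contacts A `coev_contacts` data frame from [rank_contacts()].
#' @param file Output path or connection; `""` writes to stdout.
#' @export
write_contacts <- function(contacts, file = "") {
  stopifnot(is.data.frame(contacts))
  if (nrow(contacts) == 0L) {
    cat("", file = file)
    return(invisible(NULL))
  }
  fmt6 <- function(x) vapply(x, function(v) as.character(signif(v, 6L)), "")
  lines <- paste(contacts$i, contacts$res_i, contacts$j, contacts$res_j,
                 fmt6(contacts$raw), fmt6(contacts$corrected), sep = "\t")
  writeLines(lines, con = file)
  invisible(NULL)
}
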