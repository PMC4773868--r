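#' The 20-letter amino-acid alphabet
#'
#' Standard one-letter codes, in the conventional alphabetical order used
#' throughout the feature registry.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Create a validated sequence record
#'
#' A `SequenceRecord` is an identifier plus an amino-acid string (a signal
#' peptide fused N-terminally to the mature protein). The sequence is
#' uppercased and validated: every character must be one of the 20 standard
#' residues and the length must be at least 2 (dipeptide features require
#' two residues). Non-standard letters (B, J, O, U, X, Z) are rejected, not
#' silently remapped.
#'
#' @param id Character scalar identifier.
#' @param sequence Character scalar amino-acid sequence.
#' @return An object of class `SequenceRecord` with fields `id` and
#'   `sequence`.
#' @examples
#' rec <- sequence_record("mbp", "MKIKTGARILALSALTTMMFSASALA")
#' nchar(rec$sequence)
#' @export
sequence_record <- function(id, sequence) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("invalid input: 'id' must be a non-empty character scalar",
         call. = FALSE)
  }
  if (!is.character(sequence) || length(sequence) != 1L) {
    stop("invalid input: 'sequence' must be a character scalar",
         call. = FALSE)
  }
  seq <- toupper(gsub("[[:space:]]", "", sequence))
  if (nchar(seq) < 2L) {
    stop(sprintf("invalid input: sequence '%s' has length %d (minimum 2)",
                 id, nchar(seq)), call. = FALSE)
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% AA_ALPHABET))
  if (length(bad) > 0L) {
    stop(sprintf(
      "invalid input: sequence '%s' contains illegal residue '%s' at position %d",
      id, chars[bad[1L]], bad[1L]), call. = FALSE)
  }
  structure(list(id = id, sequence = seq), class = "SequenceRecord")
}

#' @export
print.SequenceRecord <- function(x, ...) {
  cat(sprintf("SequenceRecord %s (%d aa)\n", x$id, nchar(x$sequence)))
  invisible(x)
}

as_sequence_record <- function(x) {
  if (inherits(x, "SequenceRecord")) return(x)
  if (is.character(x) && length(x) == 1L) {
    return(sequence_record("seq", x))
  }
  stop("invalid input: expected a SequenceRecord or a character scalar",
       call. = FALSE)
}

seq_chars <- function(record) {
  strsplit(record$sequence, "", fixed = TRUE)[[1L]]
}

#' Read amino-acid sequences from a FASTA file
#'
#' Parses a (possibly line-wrapped, multi-record) FASTA file and returns a
#' list of validated [sequence_record()] objects in file order. Identifiers
#' are the first whitespace-delimited token of each header. Records failing
#' residue validation abort with an error naming the record and position.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return List of `SequenceRecord` objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read FASTA: no such file '%s'", path), call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) {
      stop(sprintf("malformed FASTA '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    })
  if (length(set) == 0L) {
    stop(sprintf("malformed FASTA '%s': no records found", path),
         call. = FALSE)
  }
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop(sprintf("malformed FASTA '%s': empty record header", path),
         call. = FALSE)
  }
  mapply(sequence_record, ids, as.character(set),
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}
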