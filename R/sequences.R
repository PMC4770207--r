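#' Normalize a nucleotide string to the RNA alphabet
#'
#' Accepts DNA or RNA input in either case; `T` is converted to `U`.
#' Characters outside `A`, `C`, `G`, `U`, `T` (including IUPAC ambiguity
#' codes and gaps) are rejected with an error.
#'
#' @param x single character string.
#' @return uppercase RNA string over `{A,C,G,U}`.
#' @export
as_rna <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  s <- chartr("t", "u", toupper(x))
  s <- chartr("T", "U", s)
  bad <- gsub("[ACGU]", "", s)
  if (nzchar(bad)) {
    stop("sequence contains characters outside the DNA/RNA alphabet: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  }
  s
}

#' Reverse complement of an RNA string
#'
#' @param x RNA string (character scalar or vector).
#' @return reverse complement, same length as `x`.
#' @export
rna_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::RNAStringSet(x)))
}

#' Convert RNA to its DNA (coding-strand) form
#'
#' @param x RNA string.
#' @return DNA string with `U` replaced by `T`.
#' @export
rna_to_dna <- function(x) chartr("U", "T", x)

#' Construct a target transcript
#'
#' The central input object: the RNA to be cleaved. DNA input is converted
#' to RNA; the original alphabet is recorded.
#'
#' @param sequence nucleotide string (DNA or RNA, any case).
#' @param id identifier used in reports and FASTA output.
#' @return object of class `target_transcript` with fields `id`, `sequence`
#'   (RNA) and `source_alphabet`.
#' @examples
#' tgt <- target_transcript("GACTGTCAAGT", id = "toy")
#' tgt$sequence
#' @export
target_transcript <- function(sequence, id = "target") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  raw <- toupper(sequence)
  if (!nzchar(raw)) stop("target sequence must be non-empty")
  alpha <- if (grepl("T", raw, fixed = TRUE)) "DNA" else "RNA"
  structure(
    list(id = id, sequence = as_rna(sequence), source_alphabet = alpha),
    class = "target_transcript"
  )
}

#' @export
print.target_transcript <- function(x, ...) {
  n <- nchar(x$sequence)
  head <- substr(x$sequence, 1, min(60, n))
  cat(sprintf("<target_transcript> %s: %d nt (%s input)\n  %s%s\n",
              x$id, n, x$source_alphabet, head, if (n > 60) "..." else ""))
  invisible(x)
}

#' Read a target transcript from FASTA or plain text
#'
#' Multi-record FASTA is accepted; the first record is used unless
#' `record_id` names another. A file without a `>` header is read as a bare
#' sequence.
#'
#' @param path file path.
#' @param record_id optional FASTA record identifier (first whitespace-
#'   delimited header token).
#' @return a [target_transcript()].
#' @export
read_target_fasta <- function(path, record_id = NULL) {
  if (!file.exists(path)) stop("target file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!length(first) || !startsWith(first, ">")) {
    seq <- paste(gsub("\\s", "", readLines(path, warn = FALSE)), collapse = "")
    return(target_transcript(seq, id = sub("\\.[^.]*$", "", basename(path))))
  }
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  k <- if (is.null(record_id)) 1L else match(record_id, ids)
  if (is.na(k)) stop("record '", record_id, "' not found in ", path)
  target_transcript(as.character(set[[k]]), id = ids[k])
}

#' Write named sequences as FASTA
#'
#' @param seqs named character vector of RNA/DNA sequences.
#' @param path output file.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
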