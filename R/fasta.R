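## FASTA reading/writing. Sequences travel through the package as named
## character vectors (uppercase for generated genomes); seqinr does the actual
## parsing/serialisation so that record names and letter case round-trip.

#' Read a FASTA file
#'
#' Parses a (possibly multi-record, arbitrarily wrapped) FASTA file into a
#' named character vector, preserving record names and letter case.
#' Malformed input is rejected with an error naming the offending line.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences, in file order.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop(sprintf("malformed FASTA at line %d of %s: expected a '>' header, got %s",
                 nonblank[1], path, shQuote(substr(lines[nonblank[1]], 1, 30))))
  }
  bad <- grep("^[^>]", lines)
  bad <- bad[grepl("[^A-Za-z.*-]", gsub("\\s", "", lines[bad]))]
  if (length(bad)) {
    stop(sprintf("malformed FASTA at line %d of %s: non-sequence characters in %s",
                 bad[1], path, shQuote(substr(lines[bad[1]], 1, 30))))
  }
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             seqonly = FALSE)
  out <- vapply(recs, function(r) as.character(r)[1], character(1))
  names(out) <- vapply(recs, function(r) attr(r, "name"), character(1))
  out
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector or `Biostrings::DNAStringSet`.
#' @param path Output path.
#' @param width Line-wrap width in bases (default 80).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 80) {
  if (methods::is(sequences, "XStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  stopifnot(is.character(sequences), length(sequences) > 0)
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("all sequences must be named")
  }
  seqinr::write.fasta(as.list(unname(sequences)), names = names(sequences),
                      file.out = path, nbchar = width, as.string = TRUE)
  invisible(path)
}
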