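## Internal helpers shared across modules. All public coordinates are 1-based
## inclusive; conversions to other conventions (PAF, BED) happen at the I/O
## boundary only.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## fast i.i.d. nucleotide sequence at a given GC fraction
random_sequence <- function(length, gc = 0.5) {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  idx <- sample.int(4L, length, replace = TRUE, prob = p)
  rawToChar(charToRaw("ACGT")[idx])
}

## 1-based inclusive substring
seq_slice <- function(x, start, end) substr(x, start, end)

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' GC fraction of a nucleotide string
#'
#' @param x A nucleotide string (character scalar or vector).
#' @return Numeric vector of GC fractions in \[0, 1\].
#' @examples
#' gc_fraction("ACGT")
#' @export
gc_fraction <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    n <- nchar(s)
    if (n == 0L) return(NA_real_)
    b <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    sum(b %in% c("G", "C")) / n
  }, numeric(1), USE.NAMES = FALSE)
}

## coerce a window/interval argument to list(contig, start, end)
as_interval <- function(x) {
  if (is.list(x) && !is.data.frame(x) && all(c("start", "end") %in% names(x))) {
    return(list(contig = x$contig %||% NA_character_,
                start = as.numeric(x$start), end = as.numeric(x$end)))
  }
  if (is.data.frame(x) && nrow(x) == 1L && all(c("start", "end") %in% names(x))) {
    return(list(contig = if ("contig" %in% names(x)) x$contig else NA_character_,
                start = as.numeric(x$start), end = as.numeric(x$end)))
  }
  if (is.numeric(x) && length(x) == 2L) {
    return(list(contig = NA_character_, start = x[1], end = x[2]))
  }
  stop("cannot interpret interval; supply c(start, end) or list(contig=, start=, end=)")
}

## windows argument for QC: data.frame(contig, start, end); single interval ok
as_windows <- function(x) {
  if (is.data.frame(x) && all(c("contig", "start", "end") %in% names(x))) {
    return(x[, c("contig", "start", "end")])
  }
  iv <- as_interval(x)
  data.frame(contig = iv$contig, start = iv$start, end = iv$end,
             stringsAsFactors = FALSE)
}

stop_bad_fraction <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("%s must be a single value in [0, 1], got %s",
                 what, paste(format(x), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}
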