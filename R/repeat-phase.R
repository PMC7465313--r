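## Read-level minisatellite copy-number estimation and allele phasing.
## Instead of assembling haplotigs, each on-target read is scanned for the
## longest tandem run of approximate motif matches; the per-read copy
## estimates are then clustered into structural alleles (the R1-vs-R6
## situation: a 1-copy and a 6-copy promoter allele in a heterozygote).

#' Estimate tandem repeat copies in one read
#'
#' Finds approximate occurrences of the motif (edit distance at most
#' `max_edit_fraction * nchar(motif)` per unit), collapses near-duplicate
#' matches, and chains consecutive occurrences into tandem runs; the longest
#' run is reported. A motif absent under the threshold yields 0 copies, not
#' an error.
#'
#' @param read Read sequence (character scalar).
#' @param motif Repeat unit (>= 10 nt).
#' @param max_edit_fraction Maximum per-unit edit distance as a fraction of
#'   the motif length (default 0.2, reflecting nanopore error rates).
#' @return One-row `data.frame`: `copies`, `edit_fraction` (mean edits per
#'   matched unit / motif length), `offset` (1-based start of the run in the
#'   read; `NA` when `copies` is 0).
#' @export
count_repeat_units <- function(read, motif, max_edit_fraction = 0.2) {
  motif <- toupper(motif)
  u <- nchar(motif)
  if (u < 10L) stop("motif must be at least 10 nt")
  stop_bad_fraction(max_edit_fraction, "max_edit_fraction")
  max_edits <- floor(max_edit_fraction * u)
  empty <- data.frame(copies = 0L, edit_fraction = NA_real_, offset = NA_integer_)
  if (nchar(read) < u - max_edits) return(empty)
  m <- Biostrings::matchPattern(Biostrings::DNAString(motif),
                                Biostrings::DNAString(toupper(read)),
                                max.mismatch = max_edits, with.indels = TRUE)
  if (length(m) == 0L) return(empty)
  st <- IRanges::start(m); en <- IRanges::end(m)
  ed <- as.integer(utils::adist(as.character(m), motif))
  o <- order(st, ed)
  st <- st[o]; en <- en[o]; ed <- ed[o]

  ## collapse near-duplicate matches (< 0.6 unit apart): keep the best
  keep <- integer(0)
  for (i in seq_along(st)) {
    if (length(keep) && st[i] - st[keep[length(keep)]] < 0.6 * u) {
      j <- keep[length(keep)]
      if (ed[i] < ed[j]) keep[length(keep)] <- i
    } else keep <- c(keep, i)
  }
  st <- st[keep]; en <- en[keep]; ed <- ed[keep]

  ## chain tandem runs: next unit starts within half a unit of the previous end
  run_id <- cumsum(c(1L, as.integer(st[-1] - en[-length(en)] - 1L > 0.5 * u)))
  best <- which.max(tabulate(run_id))
  in_run <- run_id == best
  data.frame(copies = sum(in_run),
             edit_fraction = mean(ed[in_run]) / u,
             offset = min(st[in_run]))
}

#' Copy-number calls for a set of reads
#'
#' @param reads Character vector of read sequences (names used as read ids)
#'   or a `sim_run`.
#' @inheritParams count_repeat_units
#' @return `data.frame(read_id, motif, copies, edit_fraction, offset)`.
#' @export
count_repeat_calls <- function(reads, motif, max_edit_fraction = 0.2) {
  if (inherits(reads, "sim_run")) {
    reads <- stats::setNames(reads$sequences, reads$reads$id)
  }
  ids <- names(reads) %||% sprintf("read%06d", seq_along(reads))
  calls <- do.call(rbind, lapply(reads, count_repeat_units, motif = motif,
                                 max_edit_fraction = max_edit_fraction))
  cbind(data.frame(read_id = ids, motif = motif, stringsAsFactors = FALSE),
        calls, row.names = NULL)
}

#' Phase per-read copy estimates into structural alleles
#'
#' Reads with zero copies are uninformative and excluded. Copy values
#' supported by at least `min_support` reads are allele candidates; values
#' below support are merged into an adjacent (+/- 1 copy) candidate, toward
#' the better-supported neighbour (ties toward the smaller copy number).
#' Zygosity is `heterozygous` with two or more alleles, `homozygous` with
#' one, `ambiguous` with none.
#'
#' @param reads Read sequences (character vector or `sim_run`), or a
#'   precomputed call table from [count_repeat_calls()].
#' @param motif Repeat unit (ignored when `reads` is a call table).
#' @param min_support Minimum supporting reads per allele (default 5).
#' @param max_edit_fraction See [count_repeat_units()].
#' @return Object of class `allele_set`: `alleles`
#'   (`data.frame(copies, support)`), `zygosity`, `n_reads`, `calls`.
#' @export
phase_alleles <- function(reads, motif = NULL, min_support = 5,
                          max_edit_fraction = 0.2) {
  calls <- if (is.data.frame(reads) && "copies" %in% names(reads)) reads
           else {
             stopifnot(!is.null(motif))
             count_repeat_calls(reads, motif, max_edit_fraction)
           }
  if (nrow(calls) < min_support) {
    stop("fewer reads (", nrow(calls), ") than min_support (", min_support, ")")
  }
  cp <- calls$copies[calls$copies > 0L]
  alleles <- data.frame(copies = integer(0), support = integer(0))
  if (length(cp)) {
    tab <- table(cp)
    vals <- as.integer(names(tab))
    supp <- as.integer(tab)
    centers <- vals[supp >= min_support]
    agg <- stats::setNames(supp[match(centers, vals)], centers)
    for (i in seq_along(vals)) {
      v <- vals[i]
      if (v %in% centers) next
      nb <- intersect(c(v - 1L, v + 1L), centers)
      if (!length(nb)) next
      ## better-supported neighbour wins; ties toward the smaller copy number
      nb <- nb[order(-agg[as.character(nb)], nb)][1]
      agg[as.character(nb)] <- agg[as.character(nb)] + supp[i]
    }
    if (length(centers)) {
      alleles <- data.frame(copies = sort(centers),
                            support = as.integer(agg[as.character(sort(centers))]))
    }
  }
  zyg <- if (nrow(alleles) >= 2L) "heterozygous"
         else if (nrow(alleles) == 1L) "homozygous" else "ambiguous"
  structure(list(alleles = alleles, zygosity = zyg, n_reads = nrow(calls),
                 calls = calls),
            class = "allele_set")
}

#' @export
print.allele_set <- function(x, ...) {
  cat("allele_set (", x$zygosity, ", ", x$n_reads, " reads):\n", sep = "")
  print(x$alleles, row.names = FALSE)
  invisible(x)
}
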