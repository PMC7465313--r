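## Run-level and enrichment statistics from reads + alignments: read stats
## with the Q7 pass partition, on/off-target enrichment reporting against the
## cut-defined window, per-base depth, binned coverage and coverage-cluster
## off-target detection under a mapping-quality filter.

#' Read-set N50
#'
#' Largest length L such that reads of length >= L contain at least half of
#' all sequenced bases.
#'
#' @param lengths Numeric vector of read lengths.
#' @return N50 in bp.
#' @examples
#' n50(1000 * (1:5))  # 4000
#' @export
n50 <- function(lengths) {
  stopifnot(length(lengths) >= 1L, all(lengths > 0))
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

## vectorized probability-space mean quality over Phred+33 strings
mean_read_qualities <- function(qual_strings) {
  lens <- nchar(qual_strings)
  q <- as.integer(charToRaw(paste(qual_strings, collapse = ""))) - 33L
  p <- 10^(-q / 10)
  stops <- cumsum(lens)
  sums <- diff(c(0, cumsum(p)[stops]))
  -10 * log10(sums / lens)
}

#' Run-level read statistics with a pass partition
#'
#' Reports counts, bases, median length, N50 and median mean-quality for all
#' reads and for the pass subset (mean read quality at or above
#' `pass_threshold`; the threshold is inclusive, "Q7 or more").
#'
#' @param lengths Read lengths (bp).
#' @param mean_qualities Per-read mean qualities (see [mean_read_quality()]).
#' @param pass_threshold Pass threshold (default Q7).
#' @return One-row `data.frame` with `reads`, `bases`, `median_length`,
#'   `n50`, `median_quality` and the corresponding `pass_*` columns.
#' @export
read_stats <- function(lengths, mean_qualities, pass_threshold = 7) {
  stopifnot(length(lengths) >= 1L, length(lengths) == length(mean_qualities))
  pass <- mean_qualities >= pass_threshold
  stat <- function(l, q) {
    if (length(l) == 0L) {
      return(list(reads = 0L, bases = 0, median_length = NA_real_,
                  n50 = NA_real_, median_quality = NA_real_))
    }
    list(reads = length(l), bases = sum(l), median_length = stats::median(l),
         n50 = n50(l), median_quality = stats::median(q))
  }
  a <- stat(lengths, mean_qualities)
  p <- stat(lengths[pass], mean_qualities[pass])
  data.frame(reads = a$reads, bases = a$bases, median_length = a$median_length,
             n50 = a$n50, median_quality = a$median_quality,
             pass_reads = p$reads, pass_bases = p$bases,
             pass_median_length = p$median_length, pass_n50 = p$n50,
             pass_median_quality = p$median_quality)
}

#' Read statistics of a simulated run or FASTQ file
#'
#' @param x A `sim_run` or a FASTQ path.
#' @param pass_threshold Pass threshold (default Q7).
#' @return See [read_stats()].
#' @export
run_read_stats <- function(x, pass_threshold = 7) {
  if (inherits(x, "sim_run")) {
    quals <- x$qualities; lens <- nchar(x$sequences)
  } else {
    fq <- read_fastq(x)
    quals <- fq$qualities; lens <- nchar(fq$sequences)
  }
  read_stats(lens, mean_read_qualities(quals), pass_threshold)
}

## best (primary) alignment per read: highest mapq, deterministic tie-break
## by target coordinate
best_alignments <- function(paf) {
  o <- order(paf$qname, -paf$mapq, paf$tname, paf$tstart)
  paf <- paf[o, , drop = FALSE]
  paf[!duplicated(paf$qname), , drop = FALSE]
}

overlaps_windows <- function(contig, start, end, windows) {
  hit <- rep(FALSE, length(contig))
  for (i in seq_len(nrow(windows))) {
    hit <- hit | (contig == windows$contig[i] &
                    start <= windows$end[i] & end >= windows$start[i])
  }
  hit
}

#' On-target enrichment report
#'
#' A read is on-target when its best (highest mapping quality) alignment
#' overlaps the on-target window by at least 1 bp. Following the published
#' table semantics, "on-target coverage" is the on-target read count
#' (forward + reverse); the mean per-base depth over the window is reported
#' separately as `mean_depth`.
#'
#' @param alignments PAF `data.frame` (see [read_paf()]; `tstart`/`tend`
#'   0-based half-open).
#' @param windows On-target window(s): `data.frame(contig, start, end)`
#'   (1-based inclusive), e.g. one row per haplotype sequence.
#' @return One-row `data.frame`: `aligned_reads`, `on_target_forward`,
#'   `on_target_reverse`, `on_target_coverage`, `on_target_percentage`,
#'   `mean_depth`, `warning`.
#' @export
enrichment_report <- function(alignments, windows) {
  windows <- as_windows(windows)
  if (is.null(alignments) || nrow(alignments) == 0L) {
    warning("no alignments; returning zero report")
    return(data.frame(aligned_reads = 0L, on_target_forward = 0L,
                      on_target_reverse = 0L, on_target_coverage = 0L,
                      on_target_percentage = NA_real_, mean_depth = 0,
                      warning = TRUE))
  }
  best <- best_alignments(alignments)
  on <- overlaps_windows(best$tname, best$tstart + 1L, best$tend, windows)
  fwd <- sum(on & best$strand == "+")
  rev <- sum(on & best$strand == "-")
  depth <- per_base_depth(best)
  tot <- 0; nbp <- 0
  for (i in seq_len(nrow(windows))) {
    ctg <- windows$contig[i]
    if (!ctg %in% names(depth)) next
    d <- depth[[ctg]]
    idx <- windows$start[i]:min(windows$end[i], length(d))
    tot <- tot + sum(as.numeric(d[idx]))
    nbp <- nbp + length(idx)
  }
  data.frame(aligned_reads = nrow(best),
             on_target_forward = fwd, on_target_reverse = rev,
             on_target_coverage = fwd + rev,
             on_target_percentage = 100 * (fwd + rev) / nrow(best),
             mean_depth = if (nbp > 0) tot / nbp else 0,
             warning = FALSE)
}

#' Per-base alignment depth
#'
#' Depth at a position is the number of alignments with mapping quality at or
#' above `min_mapq` whose target interval covers it.
#'
#' @param alignments PAF `data.frame`.
#' @param min_mapq Mapping-quality filter (inclusive).
#' @return Named list of `S4Vectors::Rle` depth vectors, one per target
#'   contig (full contig length).
#' @export
per_base_depth <- function(alignments, min_mapq = 0) {
  keep <- alignments[alignments$mapq >= min_mapq, , drop = FALSE]
  out <- list()
  for (ctg in unique(alignments$tname)) {
    len <- max(alignments$tlen[alignments$tname == ctg])
    a <- keep[keep$tname == ctg, , drop = FALSE]
    out[[ctg]] <- if (nrow(a)) {
      IRanges::coverage(IRanges::IRanges(a$tstart + 1L, a$tend), width = len)
    } else S4Vectors::Rle(0L, len)
  }
  out
}

#' Binned mean coverage
#'
#' Tiles each target contig with fixed-width bins and reports the mean and
#' maximum per-base depth per bin under the mapping-quality filter.
#'
#' @param alignments PAF `data.frame`.
#' @param bin_size Bin width in bp (>= 1; default 1000).
#' @param min_mapq Mapping-quality filter.
#' @return `data.frame(contig, start, end, mean_depth, max_depth)`.
#' @export
bin_coverage <- function(alignments, bin_size = 1000, min_mapq = 0) {
  stopifnot(bin_size >= 1)
  depth <- per_base_depth(alignments, min_mapq)
  out <- lapply(names(depth), function(ctg) {
    d <- depth[[ctg]]
    len <- length(d)
    starts <- seq(1L, len, by = bin_size)
    ends <- pmin(starts + bin_size - 1L, len)
    v <- IRanges::Views(d, start = starts, end = ends)
    data.frame(contig = ctg, start = starts, end = ends,
               mean_depth = IRanges::viewMeans(v),
               max_depth = IRanges::viewMaxs(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Coverage-cluster off-target detection
#'
#' Bins qualifying under the depth threshold (mean bin depth >=
#' `min_coverage`, alignments filtered at `min_mapq`) are merged when
#' adjacent into candidate regions; regions overlapping the on-target window
#' are excluded. Raising `min_coverage` can only shrink the result set.
#'
#' @param alignments PAF `data.frame`.
#' @param windows On-target window(s) to exclude
#'   (`data.frame(contig, start, end)`).
#' @param min_coverage Depth threshold (default 25).
#' @param min_mapq Mapping-quality threshold (default 40).
#' @param bin_size Bin width in bp (default 1000).
#' @param annotation Optional `data.frame(contig, start, end, name)`; region
#'   annotations list overlapping names.
#' @return `data.frame(contig, start, end, size, max_coverage, annotation)`.
#' @export
detect_offtargets <- function(alignments, windows, min_coverage = 25,
                              min_mapq = 40, bin_size = 1000,
                              annotation = NULL) {
  stopifnot(min_coverage > 0, min_mapq >= 0)
  windows <- as_windows(windows)
  bins <- bin_coverage(alignments, bin_size = bin_size, min_mapq = min_mapq)
  depth <- per_base_depth(alignments, min_mapq)
  hot <- bins[bins$mean_depth >= min_coverage, , drop = FALSE]
  out <- list()
  for (ctg in unique(hot$contig)) {
    h <- hot[hot$contig == ctg, , drop = FALSE]
    merged <- IRanges::reduce(IRanges::IRanges(h$start, h$end))
    for (i in seq_along(merged)) {
      s <- IRanges::start(merged)[i]; e <- IRanges::end(merged)[i]
      if (any(ctg == windows$contig & s <= windows$end & e >= windows$start)) next
      mx <- max(as.integer(IRanges::Views(depth[[ctg]], start = s, end = e)[[1]]))
      ann <- ""
      if (!is.null(annotation)) {
        a <- annotation[annotation$contig == ctg & annotation$start <= e &
                          annotation$end >= s, , drop = FALSE]
        ann <- paste(a$name, collapse = ",")
      }
      out[[length(out) + 1L]] <- data.frame(
        contig = ctg, start = s, end = e, size = e - s + 1L,
        max_coverage = mx, annotation = ann, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), size = integer(0),
                      max_coverage = numeric(0), annotation = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$contig, res$start), , drop = FALSE]
}

#' Per-haplotype on-target windows of a guide panel
#'
#' Locates each guide in every haplotype sequence that contains it (SNPs and
#' repeat-length differences shift coordinates between haplotypes) and
#' computes the cut-defined window per sequence.
#'
#' @param genome Named character vector of haplotype sequences.
#' @param guides Guide `data.frame`.
#' @param mode Window basis, see [on_target_window()].
#' @param max_mismatches Substitution budget when locating a guide in a
#'   haplotype (default 2: tight enough that chance protospacer look-alikes
#'   elsewhere in the genome do not spawn spurious windows, loose enough for
#'   planted/real site SNPs).
#' @return `data.frame(contig, start, end, length)`, one row per haplotype
#'   sequence carrying all guides.
#' @export
target_windows <- function(genome, guides, mode = "cut_span",
                           max_mismatches = 2) {
  out <- list()
  for (ctg in names(genome)) {
    located <- guides
    ok <- TRUE
    for (i in seq_len(nrow(guides))) {
      loc <- locate_guide(guides[i, ], genome[[ctg]],
                          max_mismatches = max_mismatches)
      if (is.null(loc)) { ok <- FALSE; break }
      located$start[i] <- loc$start; located$end[i] <- loc$end
      located$strand[i] <- loc$strand; located$contig[i] <- ctg
    }
    if (!ok) next
    w <- on_target_window(located, mode = mode)
    out[[length(out) + 1L]] <- data.frame(
      contig = ctg, start = w$start, end = w$end, length = w$length,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no haplotype sequence contains all guides")
  do.call(rbind, out)
}
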