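## Synthetic diploid genome fixtures: decoy chromosomes at configured GC, a
## minisatellite target locus with different tandem copy numbers on the two
## haplotypes (the R1-vs-R6 situation: a short allele in one haplotype, a
## six-unit allele in the other), a high-identity paralog of the target locus,
## planted guide-site SNPs and planted ligatable-end hotspots. Everything is
## deterministic given the config seed.

#' Configuration for a synthetic diploid test genome
#'
#' @param seed Integer seed; the same config and seed reproduce byte-identical
#'   FASTA output and truth annotations.
#' @param chromosomes `data.frame(name, length, gc)` describing the background
#'   chromosomes (i.i.d. nucleotides at the given GC fraction). The target
#'   locus and paralog are spliced into these.
#' @param target_locus List with `chromosome`, `position` (1-based insertion
#'   point), `flank` (bp of flanking sequence included in the truth window),
#'   `repeat_unit` (nucleotide string, or `NULL` to draw a random 23-mer from
#'   the seed), `copies_hapA`, `copies_hapB` (tandem copies per haplotype,
#'   both >= 1).
#' @param paralog Optional list with `chromosome`, `position`, `identity`
#'   (fraction in \[0,1\]): a copy of the haplotype-A target window degraded by
#'   random substitutions at rate `1 - identity` is inserted there.
#' @param planted_snps Optional `data.frame(haplotype, position, alt)`:
#'   single-base substitutions applied to the target chromosome of haplotype
#'   `"A"` or `"B"` at the given final (post-insertion) coordinate.
#' @param planted_offtargets Optional `data.frame(chromosome, position,
#'   density)`: recurrent ligatable-end hotspots consumed by the read
#'   simulator; `density` is the hotspot's end weight relative to one free
#'   Cas9 cut end.
#' @return An object of class `synthetic_genome_config`.
#' @seealso [make_genome()]
#' @export
synthetic_genome_config <- function(seed,
                                    chromosomes,
                                    target_locus,
                                    paralog = NULL,
                                    planted_snps = NULL,
                                    planted_offtargets = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length", "gc") %in% names(chromosomes)),
            nrow(chromosomes) >= 1L,
            !anyDuplicated(chromosomes$name),
            all(chromosomes$length >= 1),
            all(chromosomes$gc >= 0 & chromosomes$gc <= 1))
  tl <- target_locus
  stopifnot(is.list(tl),
            all(c("chromosome", "position", "flank",
                  "copies_hapA", "copies_hapB") %in% names(tl)))
  if (!tl$chromosome %in% chromosomes$name) {
    stop("target_locus$chromosome not among configured chromosomes")
  }
  if (tl$copies_hapA < 1 || tl$copies_hapB < 1) {
    stop("repeat copies must be >= 1 on both haplotypes")
  }
  clen <- chromosomes$length[match(tl$chromosome, chromosomes$name)]
  if (tl$position <= tl$flank || tl$position + tl$flank > clen) {
    stop("target locus window (position +/- flank) extends outside its chromosome")
  }
  if (!is.null(tl$repeat_unit)) {
    stopifnot(is.character(tl$repeat_unit), nchar(tl$repeat_unit) >= 1,
              grepl("^[ACGTacgt]+$", tl$repeat_unit))
  }
  if (!is.null(paralog)) {
    stopifnot(all(c("chromosome", "position", "identity") %in% names(paralog)))
    stop_bad_fraction(paralog$identity, "paralog identity")
    if (!paralog$chromosome %in% chromosomes$name) {
      stop("paralog chromosome not among configured chromosomes")
    }
    pclen <- chromosomes$length[match(paralog$chromosome, chromosomes$name)]
    if (paralog$position < 1 || paralog$position > pclen) {
      stop("paralog position outside its chromosome")
    }
    if (identical(paralog$chromosome, tl$chromosome) &&
        abs(paralog$position - tl$position) <= tl$flank) {
      stop("paralog overlaps the target locus window on the same chromosome; ",
           "move it or place it on another chromosome")
    }
  }
  if (!is.null(planted_snps)) {
    stopifnot(is.data.frame(planted_snps),
              all(c("haplotype", "position", "alt") %in% names(planted_snps)),
              all(planted_snps$haplotype %in% c("A", "B")),
              all(planted_snps$alt %in% c("A", "C", "G", "T")))
  }
  if (!is.null(planted_offtargets)) {
    stopifnot(is.data.frame(planted_offtargets),
              all(c("chromosome", "position", "density") %in%
                    names(planted_offtargets)),
              all(planted_offtargets$chromosome %in% chromosomes$name),
              all(planted_offtargets$density > 0))
  }
  ## integer coordinates throughout so serialized truth round-trips exactly
  chromosomes$length <- as.integer(chromosomes$length)
  for (f in c("position", "flank", "copies_hapA", "copies_hapB")) {
    tl[[f]] <- as.integer(tl[[f]])
  }
  if (!is.null(paralog)) paralog$position <- as.integer(paralog$position)
  if (!is.null(planted_snps)) {
    planted_snps$position <- as.integer(planted_snps$position)
    rownames(planted_snps) <- NULL
  }
  if (!is.null(planted_offtargets)) {
    planted_offtargets$position <- as.integer(planted_offtargets$position)
    rownames(planted_offtargets) <- NULL
  }
  structure(list(seed = as.integer(seed),
                 chromosomes = chromosomes,
                 target_locus = tl,
                 paralog = paralog,
                 planted_snps = planted_snps,
                 planted_offtargets = planted_offtargets),
            class = "synthetic_genome_config")
}

## final coordinate of base-frame position q after insertions (pos, len),
## where an insertion at pos shifts everything at >= pos rightwards
shift_position <- function(q, ins_pos, ins_len) {
  q + sum(ins_len[ins_pos <= q])
}

apply_insertions <- function(seq, pos, pieces) {
  o <- order(pos, decreasing = TRUE)
  for (i in o) {
    seq <- paste0(substr(seq, 1L, pos[i] - 1L), pieces[i],
                  substr(seq, pos[i], nchar(seq)))
  }
  seq
}

mutate_to_identity <- function(seq, identity) {
  n <- nchar(seq)
  hit <- which(stats::runif(n) < (1 - identity))
  if (length(hit)) {
    b <- strsplit(seq, "", fixed = TRUE)[[1]]
    alpha <- c("A", "C", "G", "T")
    cur <- match(b[hit], alpha)
    b[hit] <- alpha[((cur - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L]
    seq <- paste(b, collapse = "")
  }
  seq
}

#' Generate a synthetic diploid genome with truth annotations
#'
#' Builds two haplotype sequence sets that differ only by the tandem repeat
#' copy number at the target locus and by any planted SNPs. The paralog is a
#' degraded copy of the haplotype-A target window sharing the configured
#' identity (1 - substitutions/length).
#'
#' @param config A [synthetic_genome_config()].
#' @return List with `sequences` (named character vector, names
#'   `<chromosome>_hapA` / `<chromosome>_hapB`) and `truth` (a `genome_truth`
#'   object: per-haplotype target windows, repeat copies, paralog interval,
#'   SNPs and planted hotspots, plus a config echo).
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "synthetic_genome_config"))
  tl <- config$target_locus
  chroms <- config$chromosomes

  gen <- with_seed(config$seed, {
    base <- stats::setNames(
      mapply(function(len, gc) random_sequence(len, gc),
             chroms$length, chroms$gc, SIMPLIFY = TRUE),
      chroms$name)
    unit <- tl$repeat_unit %||% random_sequence(23L, 0.5)
    unit <- toupper(unit)
    ## paralog substitutions are drawn later against the assembled window;
    ## pre-draw nothing else so RNG use is independent of planted SNPs
    list(base = base, unit = unit)
  })
  base <- gen$base
  unit <- gen$unit
  ulen <- nchar(unit)

  arrays <- list(A = strrep(unit, tl$copies_hapA),
                 B = strrep(unit, tl$copies_hapB))

  ## haplotype-A target chromosome with only the repeat inserted, to source
  ## the paralog window before any paralog insertion shifts coordinates
  tchrom <- tl$chromosome
  alenA <- nchar(arrays$A)
  hapA_target_only <- apply_insertions(base[[tchrom]], tl$position, arrays$A)
  winA0 <- c(tl$position - tl$flank, tl$position + alenA - 1L + tl$flank)
  window_seq <- seq_slice(hapA_target_only, winA0[1], winA0[2])

  para_seq <- NULL
  if (!is.null(config$paralog)) {
    para_seq <- with_seed(config$seed + 101L,
                          mutate_to_identity(window_seq, config$paralog$identity))
  }

  haps <- list()
  truth_target <- NULL
  truth_paralog <- NULL
  for (hap in c("A", "B")) {
    seqs <- base
    array <- arrays[[hap]]
    alen <- nchar(array)
    ## collect insertions per chromosome (base-frame positions)
    for (ch in names(seqs)) {
      pos <- integer(0); pieces <- character(0)
      if (ch == tchrom) { pos <- c(pos, tl$position); pieces <- c(pieces, array) }
      if (!is.null(para_seq) && ch == config$paralog$chromosome) {
        pos <- c(pos, config$paralog$position); pieces <- c(pieces, para_seq)
      }
      if (length(pos)) seqs[[ch]] <- apply_insertions(seqs[[ch]], pos, pieces)
    }
    ## final coordinates of the array and window on this haplotype
    ins_pos <- tl$position; ins_len <- alen
    if (!is.null(para_seq) && identical(config$paralog$chromosome, tchrom)) {
      ins_pos <- c(ins_pos, config$paralog$position)
      ins_len <- c(ins_len, nchar(para_seq))
    }
    array_start <- shift_position(tl$position, ins_pos[-1], ins_len[-1])
    truth_target <- rbind(truth_target, data.frame(
      haplotype = hap,
      contig = paste0(tchrom, "_hap", hap),
      window_start = array_start - tl$flank,
      window_end = array_start + alen - 1L + tl$flank,
      array_start = array_start,
      array_end = array_start + alen - 1L,
      copies = if (hap == "A") tl$copies_hapA else tl$copies_hapB,
      stringsAsFactors = FALSE))
    if (!is.null(para_seq)) {
      pch <- config$paralog$chromosome
      p_ins_pos <- config$paralog$position
      shift_by_target <- if (identical(pch, tchrom) && tl$position <= p_ins_pos) alen else 0L
      pstart <- p_ins_pos + shift_by_target
      truth_paralog <- rbind(truth_paralog, data.frame(
        haplotype = hap,
        contig = paste0(pch, "_hap", hap),
        start = pstart,
        end = pstart + nchar(para_seq) - 1L,
        identity = config$paralog$identity,
        stringsAsFactors = FALSE))
    }
    ## planted SNPs for this haplotype (final coordinates, target chromosome)
    if (!is.null(config$planted_snps)) {
      sn <- config$planted_snps[config$planted_snps$haplotype == hap, , drop = FALSE]
      for (i in seq_len(nrow(sn))) {
        p <- sn$position[i]
        if (p < 1 || p > nchar(seqs[[tchrom]])) {
          stop("planted SNP position outside target chromosome (haplotype ", hap, ")")
        }
        substr(seqs[[tchrom]], p, p) <- sn$alt[i]
      }
    }
    names(seqs) <- paste0(names(seqs), "_hap", hap)
    haps[[hap]] <- seqs
  }

  ## interleave so each chromosome's two haplotypes are adjacent
  sequences <- character(0)
  for (ch in chroms$name) {
    sequences <- c(sequences, haps$A[paste0(ch, "_hapA")], haps$B[paste0(ch, "_hapB")])
  }

  offt <- NULL
  if (!is.null(config$planted_offtargets)) {
    po <- config$planted_offtargets
    offt <- do.call(rbind, lapply(c("A", "B"), function(hap) {
      pos <- po$position
      if (any(po$chromosome == tchrom)) {
        i <- which(po$chromosome == tchrom)
        alen <- nchar(arrays[[hap]])
        pos[i] <- ifelse(po$position[i] >= tl$position, po$position[i] + alen,
                         po$position[i])
      }
      data.frame(haplotype = hap, contig = paste0(po$chromosome, "_hap", hap),
                 position = pos, density = po$density, stringsAsFactors = FALSE)
    }))
  }

  truth <- structure(list(
    seed = config$seed,
    repeat_unit = unit,
    sequence_names = names(sequences),
    sequence_lengths = stats::setNames(nchar(sequences), names(sequences)),
    target = truth_target,
    paralog = truth_paralog,
    snps = config$planted_snps,
    offtargets = offt,
    config = config
  ), class = "genome_truth")

  list(sequences = sequences, truth = truth)
}

#' @export
print.genome_truth <- function(x, ...) {
  cat("genome_truth:", length(x$sequence_names), "haplotype sequences, ",
      "repeat unit", nchar(x$repeat_unit), "bp\n")
  cat("target windows:\n")
  print(x$target, row.names = FALSE)
  invisible(x)
}

#' Serialize genome truth to JSON and BED
#'
#' Writes `<prefix>.truth.json` (full config echo plus derived truth, losslessly
#' re-readable with [read_genome_truth()]) and `<prefix>.truth.bed` (target
#' windows, repeat arrays, paralog intervals and planted hotspots, 0-based
#' half-open as BED requires).
#'
#' @param truth A `genome_truth` object.
#' @param prefix Output path prefix.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_genome_truth <- function(truth, prefix) {
  stopifnot(inherits(truth, "genome_truth"))
  json_path <- paste0(prefix, ".truth.json")
  bed_path <- paste0(prefix, ".truth.bed")
  payload <- unclass(truth)
  payload$config <- unclass(payload$config)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  bed <- rbind(
    data.frame(contig = truth$target$contig,
               start = truth$target$window_start - 1L,
               end = truth$target$window_end,
               name = paste0("target_window_hap", truth$target$haplotype)),
    data.frame(contig = truth$target$contig,
               start = truth$target$array_start - 1L,
               end = truth$target$array_end,
               name = paste0("repeat_array_hap", truth$target$haplotype)))
  if (!is.null(truth$paralog)) {
    bed <- rbind(bed, data.frame(contig = truth$paralog$contig,
                                 start = truth$paralog$start - 1L,
                                 end = truth$paralog$end,
                                 name = paste0("paralog_hap", truth$paralog$haplotype)))
  }
  if (!is.null(truth$offtargets)) {
    bed <- rbind(bed, data.frame(contig = truth$offtargets$contig,
                                 start = truth$offtargets$position - 1L,
                                 end = truth$offtargets$position,
                                 name = "planted_hotspot"))
  }
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(json = json_path, bed = bed_path))
}

truth_normalize_df <- function(df, int_cols) {
  if (is.null(df)) return(NULL)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (cl in intersect(int_cols, names(df))) df[[cl]] <- as.integer(df[[cl]])
  rownames(df) <- NULL
  df
}

#' Read genome truth back from JSON
#'
#' @param path Path to a `.truth.json` written by [write_genome_truth()].
#' @return A `genome_truth` object equal to the one serialized.
#' @export
read_genome_truth <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  ## absent/empty JSON members come back as NULL via [[ on a rebuilt list
  drop_empty <- function(v) if (length(v) == 0L) NULL else v
  for (f in c("paralog", "snps", "offtargets")) x[[f]] <- drop_empty(x[[f]])
  ints <- c("window_start", "window_end", "array_start", "array_end", "copies",
            "start", "end", "position", "length")
  x$target <- truth_normalize_df(x$target, ints)
  x$paralog <- truth_normalize_df(x$paralog, ints)
  x$snps <- truth_normalize_df(x$snps, ints)
  x$offtargets <- truth_normalize_df(x$offtargets, ints)
  x$seed <- as.integer(x$seed)
  x$sequence_lengths <- stats::setNames(as.integer(x$sequence_lengths),
                                        x$sequence_names)
  cfg <- x$config
  for (f in c("paralog", "planted_snps", "planted_offtargets")) {
    cfg[[f]] <- drop_empty(cfg[[f]])
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg$chromosomes <- truth_normalize_df(cfg$chromosomes, "length")
  cfg$planted_snps <- truth_normalize_df(cfg$planted_snps, ints)
  cfg$planted_offtargets <- truth_normalize_df(cfg$planted_offtargets, ints)
  if (!is.null(cfg$target_locus)) {
    for (f in c("position", "flank", "copies_hapA", "copies_hapB")) {
      cfg$target_locus[[f]] <- as.integer(cfg$target_locus[[f]])
    }
  }
  if (!is.null(cfg$paralog)) cfg$paralog$position <- as.integer(cfg$paralog$position)
  cfg <- structure(list(seed = cfg$seed, chromosomes = cfg$chromosomes,
                        target_locus = cfg$target_locus, paralog = cfg$paralog,
                        planted_snps = cfg$planted_snps,
                        planted_offtargets = cfg$planted_offtargets),
                   class = "synthetic_genome_config")
  structure(list(seed = x$seed, repeat_unit = x$repeat_unit,
                 sequence_names = x$sequence_names,
                 sequence_lengths = x$sequence_lengths,
                 target = x$target, paralog = x$paralog, snps = x$snps,
                 offtargets = x$offtargets, config = cfg),
            class = "genome_truth")
}
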