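## Enrichment library + nanopore run simulator with full truth tracking.
## Reads start at adapter-bearing fragment ends (Cas9 cut ends, leaked
## blocked ends, residual phosphorylated natural ends) or at diffuse
## background breaks, extend into their fragment, get a log-normal length
## model, per-base qualities around a profile median, and substitution /
## insertion / deletion errors. Truth alignments are emitted in PAF
## convention against the haplotype sequences.

#' Bundled per-read quality profiles
#'
#' Two profiles named after the run's two base callers: `caller_a`
#' (median read quality ~9.11) and `caller_b` (~11.22). The spread values are
#' calibrated so that the fraction of reads passing the Q7 threshold matches
#' the corresponding published pass fractions (86% and 90%).
#'
#' @return Named list of profiles (`median_q`, `spread`, `jitter`).
#' @export
quality_profiles <- function() {
  list(caller_a = list(name = "caller_a", median_q = 9.11, spread = 1.94, jitter = 3),
       caller_b = list(name = "caller_b", median_q = 11.22, spread = 3.24, jitter = 3))
}

#' Simulation configuration
#'
#' The default `"calibrated_run"` profile reproduces the enrichment regime of
#' the study run: ~3% of reads on-target at 7000 reads, read-length median
#' ~10 kb with N50 ~31 kb, and `caller_b` qualities. Its background-break and
#' leak parameters are calibrated (declared, not measured); the derivation
#' lives in the methods vignette.
#'
#' @param profile `"calibrated_run"` or `"custom"` (custom starts from the
#'   same defaults; override fields via `...`).
#' @param ... Field overrides: `n_reads`, `dephosphorylation_efficiency`,
#'   `background_break_rate` (breaks per bp), `blocked_end_leak`,
#'   `read_length_model` (list: `meanlog`, `sdlog`, `truncation_per_kb`,
#'   `max_read_length`), `quality_profile` (name or list), `error_model`
#'   (list: `substitution`, `insertion`, `deletion`), `seed`.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(profile = c("calibrated_run", "custom"), ...) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile,
    n_reads = 7000L,
    dephosphorylation_efficiency = 0.95,
    background_break_rate = 8.66e-5,
    blocked_end_leak = 0.02,
    read_length_model = list(meanlog = log(1e4), sdlog = 1.06,
                             truncation_per_kb = 0, max_read_length = 1e5),
    quality_profile = quality_profiles()$caller_b,
    error_model = list(substitution = 0.05, insertion = 0.03, deletion = 0.04),
    seed = 1L)
  over <- list(...)
  if (!is.null(over$quality_profile) && is.character(over$quality_profile)) {
    over$quality_profile <- quality_profiles()[[over$quality_profile]]
  }
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
    } else cfg[[nm]] <- over[[nm]]
  }
  stopifnot(cfg$n_reads > 0)
  stop_bad_fraction(cfg$dephosphorylation_efficiency, "dephosphorylation_efficiency")
  stop_bad_fraction(cfg$blocked_end_leak, "blocked_end_leak")
  for (f in c("substitution", "insertion", "deletion")) {
    stop_bad_fraction(cfg$error_model[[f]], paste0("error_model$", f))
  }
  stopifnot(cfg$background_break_rate >= 0)
  structure(cfg, class = "sim_config")
}

#' Ligate sequencing adapters to eligible fragment ends
#'
#' Adapters attach to ends that are phosphorylated, dA-tailed and not
#' Cas9-blocked. With probability `blocked_end_leak` a blocked (PAM-distal)
#' end escapes Cas9's grip: it becomes unblocked, is flagged `leaked` for
#' truth tracking, and ligates an adapter.
#'
#' @param fragments Fragment `data.frame` (after [dephosphorylate()] and
#'   [da_tail()]).
#' @param config A [sim_config()].
#' @return Updated fragment `data.frame` with adapter (and leak) flags set.
#' @export
ligate_adapters <- function(fragments, config) {
  leak <- config$blocked_end_leak
  for (side in c("left", "right")) {
    ph <- fragments[[paste0(side, "_phos")]]
    da <- fragments[[paste0(side, "_da")]]
    bl <- fragments[[paste0(side, "_blocked")]]
    blocked_ok <- which(ph & da & bl)
    if (length(blocked_ok) && leak > 0) {
      escaped <- blocked_ok[stats::runif(length(blocked_ok)) < leak]
      bl[escaped] <- FALSE
      fragments[[paste0(side, "_blocked")]] <- bl
      fragments[[paste0(side, "_leaked")]][escaped] <- TRUE
    }
    fragments[[paste0(side, "_adapter")]] <- ph & da & !bl
  }
  fragments
}

## classify a read source from an end's class/leak flags
end_source_class <- function(class, leaked) {
  ifelse(class == "cut" & leaked, "leak",
         ifelse(class == "cut", "cut", "background"))
}

phred_from_string <- function(s) as.integer(charToRaw(s)) - 33L

#' Mean read quality (probability-space mean Phred)
#'
#' The Phred score of the arithmetic mean per-base error probability:
#' `-10 * log10(mean(10^(-q/10)))`. This is the quantity thresholded by the
#' Q7 pass filter.
#'
#' @param qualities Integer/numeric vector of per-base Phred scores, or a
#'   single Phred+33 encoded quality string.
#' @return Mean quality (Phred, not rounded).
#' @examples
#' mean_read_quality(c(10, 20))  # 12.60
#' @export
mean_read_quality <- function(qualities) {
  if (is.character(qualities)) {
    stopifnot(length(qualities) == 1L)
    qualities <- phred_from_string(qualities)
  }
  if (length(qualities) == 0L) stop("empty quality vector")
  -10 * log10(mean(10^(-qualities / 10)))
}

## vectorized error injection over a set of read sequences
inject_errors <- function(seqs, sub_rate, ins_rate, del_rate) {
  if (sub_rate <= 0 && ins_rate <= 0 && del_rate <= 0) return(seqs)
  lens <- nchar(seqs)
  ends <- cumsum(lens)
  r <- charToRaw(paste(seqs, collapse = ""))
  n <- length(r)
  alpha <- charToRaw("ACGT")
  if (sub_rate > 0) {
    ns <- stats::rbinom(1L, n, sub_rate)
    if (ns > 0) {
      pos <- sample.int(n, ns)
      cur <- match(as.integer(r[pos]), as.integer(alpha))
      ok <- which(!is.na(cur))
      if (length(ok)) {
        shift <- sample.int(3L, length(ok), replace = TRUE)
        r[pos[ok]] <- alpha[((cur[ok] - 1L + shift) %% 4L) + 1L]
      }
    }
  }
  times <- rep.int(1L, n)
  nd <- if (del_rate > 0) stats::rbinom(1L, n, del_rate) else 0L
  if (nd > 0) times[sample.int(n, nd)] <- 0L
  ni <- if (ins_rate > 0) stats::rbinom(1L, n, ins_rate) else 0L
  if (ni > 0) {
    ip <- sample.int(n, ni)
    times[ip] <- times[ip] + 1L
  }
  if (nd > 0 || ni > 0) {
    idx <- rep.int(seq_len(n), times)
    out <- r[idx]
    dup <- which(c(FALSE, diff(idx) == 0L))
    if (length(dup)) out[dup] <- alpha[sample.int(4L, length(dup), replace = TRUE)]
    ct <- cumsum(times)
    newlens <- diff(c(0L, ct[ends]))
    rm(idx, times, ct)
  } else {
    out <- r
    newlens <- lens
  }
  s <- rawToChar(out)
  stops <- cumsum(newlens)
  substring(s, stops - newlens + 1L, stops)
}

## per-base quality strings whose probability-space mean equals the per-read
## draw from the profile
draw_qualities <- function(lens, profile) {
  nreads <- length(lens)
  qr <- stats::rnorm(nreads, profile$median_q, profile$spread)
  qr <- pmax(qr, 2)
  total <- sum(lens)
  qb <- rep.int(qr, lens) + stats::rnorm(total, 0, profile$jitter)
  p <- 10^(-qb / 10)
  cp <- cumsum(p)
  rm(p)
  stops <- cumsum(lens)
  sums <- diff(c(0, cp[stops]))
  rm(cp)
  corr <- qr - (-10 * log10(sums / lens))
  qb <- qb + rep.int(corr, lens)
  qb <- pmin(pmax(round(qb), 1L), 50L)
  qs <- rawToChar(as.raw(as.integer(qb) + 33L))
  rm(qb)
  substring(qs, stops - lens + 1L, stops)
}

#' Simulate an enrichment library sequencing run
#'
#' Read starts are sampled from three source pools, with weights proportional
#' to their expected ligatable-end abundance: adapter-bearing fragment ends
#' (weight 1 each; class `cut`, `leak` or `background` by end type), planted
#' ligatable-end hotspots from the genome truth (their configured density),
#' and a diffuse background of residual phosphorylated breaks with total
#' weight `2 * genome_length * background_break_rate *
#' (1 - dephosphorylation_efficiency)`. Each read extends from its start into
#' its fragment (or to the chromosome bound for background sources), with
#' length `min(extent, log-normal draw, max_read_length)`.
#'
#' @param genome Named character vector of haplotype sequences.
#' @param fragments Fragment `data.frame` with adapter flags
#'   (see [ligate_adapters()]).
#' @param config A [sim_config()]; `config$seed` seeds the run.
#' @param truth Optional `genome_truth` (source of planted hotspots).
#' @return Object of class `sim_run`: `reads` (truth table: `id`, `source`,
#'   `contig`, `haplotype`, `start`, `end`, `strand`, `length`), `sequences`,
#'   `qualities` (Phred+33 strings), `target_lengths`, `config`.
#' @export
simulate_run <- function(genome, fragments, config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  glens <- stats::setNames(nchar(genome), names(genome))

  ## source pool ------------------------------------------------------------
  src <- list()
  for (side in c("left", "right")) {
    sel <- which(fragments[[paste0(side, "_adapter")]])
    if (length(sel)) {
      f <- fragments[sel, ]
      src[[side]] <- data.frame(
        contig = f$template,
        haplotype = f$haplotype,
        position = if (side == "left") f$start else f$end,
        dir = if (side == "left") "right" else "left",
        extent = f$end - f$start + 1L,
        class = end_source_class(f[[paste0(side, "_class")]],
                                 f[[paste0(side, "_leaked")]]),
        weight = 1,
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(truth) && !is.null(truth$offtargets)) {
    ot <- truth$offtargets
    src$hotspot <- data.frame(
      contig = ot$contig, haplotype = ot$haplotype, position = ot$position,
      dir = NA_character_, extent = NA_integer_, class = "background",
      weight = ot$density, stringsAsFactors = FALSE)
  }
  sources <- do.call(rbind, src)
  w_bg <- 2 * sum(glens) * config$background_break_rate *
    (1 - config$dephosphorylation_efficiency)
  if ((is.null(sources) || nrow(sources) == 0L) && w_bg <= 0) {
    stop("no possible read sources: no adapter-bearing ends and no background")
  }
  k_end <- if (is.null(sources)) 0L else nrow(sources)
  weights <- c(if (k_end) sources$weight, w_bg)

  run <- with_seed(config$seed, {
    n <- config$n_reads
    pick <- sample.int(length(weights), n, replace = TRUE, prob = weights)
    is_diffuse <- pick > k_end

    contig <- character(n); pos <- integer(n); dir <- character(n)
    extent <- integer(n); class <- character(n); hap <- character(n)

    if (any(!is_diffuse)) {
      i <- which(!is_diffuse); si <- pick[i]
      contig[i] <- sources$contig[si]
      hap[i] <- sources$haplotype[si]
      pos[i] <- sources$position[si]
      dir[i] <- sources$dir[si]
      extent[i] <- sources$extent[si]
      class[i] <- sources$class[si]
      miss <- i[is.na(dir[i])]   # hotspots: direction uniform, extent to bound
      if (length(miss)) dir[miss] <- sample(c("left", "right"), length(miss),
                                            replace = TRUE)
    }
    if (any(is_diffuse)) {
      i <- which(is_diffuse)
      ctg <- sample.int(length(glens), length(i), replace = TRUE, prob = glens)
      contig[i] <- names(glens)[ctg]
      hap[i] <- ifelse(grepl("_hapA$", contig[i]), "A",
                       ifelse(grepl("_hapB$", contig[i]), "B", NA))
      pos[i] <- floor(stats::runif(length(i)) * glens[ctg]) + 1L
      dir[i] <- sample(c("left", "right"), length(i), replace = TRUE)
      class[i] <- "background"
    }
    na_ext <- which(is.na(extent) | extent == 0L)
    if (length(na_ext)) {
      extent[na_ext] <- ifelse(dir[na_ext] == "right",
                               glens[contig[na_ext]] - pos[na_ext] + 1L,
                               pos[na_ext])
    }

    ## lengths ---------------------------------------------------------------
    rl <- config$read_length_model
    ldraw <- stats::rlnorm(n, rl$meanlog, rl$sdlog)
    if (rl$truncation_per_kb > 0) {
      ldraw <- pmin(ldraw, stats::rexp(n, rate = rl$truncation_per_kb / 1000))
    }
    len <- pmax(pmin(ceiling(ldraw), rl$max_read_length, extent), 1L)
    start <- ifelse(dir == "right", pos, pos - len + 1L)
    end <- ifelse(dir == "right", pos + len - 1L, pos)
    strand <- ifelse(dir == "right", "+", "-")

    ## sequences -------------------------------------------------------------
    seqs <- character(n)
    for (ctg in unique(contig)) {
      i <- which(contig == ctg)
      subj <- Biostrings::DNAString(genome[[ctg]])
      pieces <- Biostrings::extractAt(subj, IRanges::IRanges(start[i], end[i]))
      neg <- strand[i] == "-"
      if (any(neg)) pieces[neg] <- Biostrings::reverseComplement(pieces[neg])
      seqs[i] <- as.character(pieces)
    }
    ## process errors and qualities in blocks of ~15 Mb to bound peak memory
    em <- config$error_model
    quals <- character(n)
    blocks <- split(seq_len(n),
                    cumsum(c(0, cumsum(as.numeric(nchar(seqs)))[-n]) %/% 15e6))
    for (b in blocks) {
      seqs[b] <- inject_errors(seqs[b], em$substitution, em$insertion,
                               em$deletion)
      quals[b] <- draw_qualities(nchar(seqs[b]), config$quality_profile)
    }

    list(reads = data.frame(
           id = sprintf("read%06d", seq_len(n)),
           source = class, contig = contig, haplotype = hap,
           start = as.integer(start), end = as.integer(end), strand = strand,
           length = as.integer(end - start + 1L), stringsAsFactors = FALSE),
         sequences = seqs, qualities = quals)
  })

  structure(list(reads = run$reads, sequences = run$sequences,
                 qualities = run$qualities, target_lengths = glens,
                 config = config),
            class = "sim_run")
}

#' @export
print.sim_run <- function(x, ...) {
  cat("sim_run:", nrow(x$reads), "reads;", sum(nchar(x$sequences)), "bases\n")
  print(table(x$reads$source))
  invisible(x)
}

#' Write simulated reads as FASTQ (Phred+33)
#'
#' @param run A `sim_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(run, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  block <- rbind(paste0("@", run$reads$id), run$sequences, "+", run$qualities)
  writeLines(as.vector(block), con)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path Path to an (uncompressed) FASTQ file.
#' @return List with `id`, `sequences`, `qualities` (Phred+33 strings).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L) stop("truncated FASTQ: ", path)
  ids <- sub("^@", "", sub("\\s.*$", "", lines[seq(1, length(lines), 4)]))
  list(id = ids,
       sequences = lines[seq(2, length(lines), 4)],
       qualities = lines[seq(4, length(lines), 4)])
}

#' Truth alignments of a simulated run in PAF convention
#'
#' One record per read against its haplotype sequence of origin; PAF uses
#' 0-based half-open target coordinates. Mapping quality is set to 60
#' (truth is unambiguous).
#'
#' @param run A `sim_run`.
#' @return PAF `data.frame` (12 standard columns).
#' @export
truth_paf <- function(run) {
  qlen <- nchar(run$sequences)
  span <- run$reads$length
  data.frame(
    qname = run$reads$id, qlen = qlen, qstart = 0L, qend = qlen,
    strand = run$reads$strand,
    tname = run$reads$contig,
    tlen = as.integer(run$target_lengths[run$reads$contig]),
    tstart = run$reads$start - 1L, tend = run$reads$end,
    nmatch = as.integer(pmin(qlen, span)),
    alnlen = as.integer(pmax(qlen, span)),
    mapq = 60L, stringsAsFactors = FALSE)
}

#' Write / read alignments in PAF format
#'
#' @param paf PAF `data.frame` (12 standard columns).
#' @param path File path.
#' @return `path` (write) or a PAF `data.frame` (read; extra tag columns are
#'   ignored).
#' @export
write_paf <- function(paf, path) {
  utils::write.table(paf, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_paf
#' @export
read_paf <- function(path) {
  cols <- c("qname", "qlen", "qstart", "qend", "strand", "tname", "tlen",
            "tstart", "tend", "nmatch", "alnlen", "mapq")
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           fill = TRUE, comment.char = "", quote = "")[, 1:12]
  names(tab) <- cols
  tab
}

#' Truth read origins as BED
#'
#' @param run A `sim_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(run, path) {
  bed <- data.frame(run$reads$contig, run$reads$start - 1L, run$reads$end,
                    run$reads$id, 0L, run$reads$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
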