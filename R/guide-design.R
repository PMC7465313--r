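## Guide discovery and scoring: exhaustive NGG scanning, genome-wide
## mismatch-tolerant specificity search, aggregate specificity score from a
## vendored per-position penalty table, cut-directionality relative to an ROI,
## SNP effect classification, and panel assembly for the three design
## strategies (targeted excision, single-cut walking, tiling).

#' Construct a guide record
#'
#' A guide is a 20-nt protospacer plus 3-nt NGG PAM with a genomic placement:
#' 1-based inclusive `start`/`end` spanning the full 23-bp site, and the
#' strand carrying the protospacer.
#'
#' @param name Guide name.
#' @param protospacer 20-nt string (5'-3' on the guide strand).
#' @param pam 3-nt string matching NGG.
#' @param contig,start,end Genomic placement of the 23-bp site.
#' @param strand `"+"` or `"-"`.
#' @return One-row guide `data.frame`.
#' @export
guide <- function(name, protospacer, pam, contig, start, end, strand) {
  protospacer <- toupper(protospacer); pam <- toupper(pam)
  stopifnot(nchar(protospacer) == 20L, nchar(pam) == 3L,
            strand %in% c("+", "-"))
  if (!grepl("^[ACGT]GG$", pam)) stop("PAM must match NGG, got ", pam)
  if (end - start + 1L != 23L) stop("guide site must span 23 bp (end - start + 1)")
  data.frame(name = name, protospacer = protospacer, pam = pam,
             contig = contig, start = as.integer(start), end = as.integer(end),
             strand = strand, stringsAsFactors = FALSE)
}

#' Genomic 23-bp slice of a guide site, reported on the guide strand
#' @param g One-row guide data.frame.
#' @param genome Named character vector of sequences.
#' @return Character scalar (protospacer + PAM as it reads on the guide strand).
#' @export
guide_site_seq <- function(g, genome) {
  s <- genome[[g$contig]]
  slice <- seq_slice(s, g$start, g$end)
  if (g$strand == "-") slice <- revcomp(slice)
  slice
}

#' Validate guide records against a genome
#'
#' Checks the type invariants (20-nt protospacer, NGG PAM, 23-bp span) and,
#' when a genome is supplied, that protospacer+PAM reconstructs the genomic
#' slice on the stated strand.
#'
#' @param guides Guide `data.frame`.
#' @param genome Optional named character vector of sequences.
#' @return `guides`, invisibly; errors describe the first violation.
#' @export
validate_guides <- function(guides, genome = NULL) {
  req <- c("name", "protospacer", "pam", "contig", "start", "end", "strand")
  if (!all(req %in% names(guides))) {
    stop("guides must have columns ", paste(req, collapse = ", "))
  }
  for (i in seq_len(nrow(guides))) {
    g <- guides[i, ]
    if (nchar(g$protospacer) != 20L) stop(g$name, ": protospacer must be 20 nt")
    if (!grepl("^[ACGT]GG$", g$pam)) stop(g$name, ": PAM must match NGG")
    if (g$end - g$start + 1L != 23L) stop(g$name, ": site must span 23 bp")
    if (!is.null(genome)) {
      if (!g$contig %in% names(genome)) stop(g$name, ": contig not in genome")
      got <- guide_site_seq(g, genome)
      want <- paste0(g$protospacer, g$pam)
      if (!identical(got, want)) {
        stop(sprintf("%s: genomic slice %s does not reconstruct protospacer+PAM %s",
                     g$name, got, want))
      }
    }
  }
  invisible(guides)
}

#' Scan a sequence for candidate NGG guides
#'
#' Exhaustive scan of both strands: every 20-mer followed by an NGG PAM is
#' returned as a candidate guide. Candidates containing ambiguity codes are
#' dropped (an N never matches).
#'
#' @param sequence Nucleotide string (>= 23 bases).
#' @param roi Optional interval (`c(start, end)` or list); only candidates
#'   whose full 23-bp site lies inside it are returned.
#' @param contig Contig name recorded in the candidates (default `"seq1"`).
#' @return Guide `data.frame`, ordered by start then strand.
#' @export
scan_pams <- function(sequence, roi = NULL, contig = "seq1") {
  sequence <- toupper(as.character(sequence))
  n <- nchar(sequence)
  if (n < 23L) stop("sequence must be at least 23 bases")
  if (!is.null(roi)) {
    roi <- as_interval(roi)
    if (roi$start < 1 || roi$end > n) stop("ROI outside sequence")
  }
  cand <- list()
  gg <- gregexpr("(?=GG)", sequence, perl = TRUE)[[1]]
  gg <- gg[gg >= 22L & gg + 1L <= n]
  if (length(gg) && gg[1] != -1L) {
    s <- gg - 21L
    cand$fwd <- data.frame(
      name = sprintf("%s_%d_fwd", contig, s),
      protospacer = substring(sequence, s, s + 19L),
      pam = substring(sequence, gg - 1L, gg + 1L),
      contig = contig, start = s, end = gg + 1L, strand = "+",
      stringsAsFactors = FALSE)
  }
  cc <- gregexpr("(?=CC)", sequence, perl = TRUE)[[1]]
  cc <- cc[cc >= 1L & cc + 22L <= n]
  if (length(cc) && cc[1] != -1L) {
    cand$rev <- data.frame(
      name = sprintf("%s_%d_rev", contig, cc),
      protospacer = vapply(cc, function(q)
        revcomp(substring(sequence, q + 3L, q + 22L)), character(1)),
      pam = vapply(cc, function(q)
        revcomp(substring(sequence, q, q + 2L)), character(1)),
      contig = contig, start = cc, end = cc + 22L, strand = "-",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, cand)
  if (is.null(out) || nrow(out) == 0L) {
    return(guide("none", strrep("A", 20), "AGG", contig, 1, 23, "+")[0, ])
  }
  keep <- !grepl("[^ACGT]", paste0(out$protospacer, out$pam))
  out <- out[keep, , drop = FALSE]
  if (!is.null(roi)) {
    out <- out[out$start >= roi$start & out$end <= roi$end, , drop = FALSE]
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## mismatch positions (protospacer coordinates, 1 = PAM-distal) between a
## genomic slice already oriented like the protospacer and the protospacer
proto_mismatches <- function(slice, protospacer) {
  a <- strsplit(slice, "", fixed = TRUE)[[1]]
  b <- strsplit(protospacer, "", fixed = TRUE)[[1]]
  which(a != b)
}

#' Genome-wide specificity search for a guide
#'
#' Finds every genomic site matching the guide's 20-nt protospacer with at
#' most `max_mismatches` substitutions and an adjacent NGG PAM, on both
#' strands, including the intended site. Mismatch positions use protospacer
#' coordinates 1..20 with 1 = PAM-distal.
#'
#' @param g One-row guide `data.frame`.
#' @param genome Named character vector of sequences.
#' @param max_mismatches Maximum substitutions (<= 6).
#' @return `data.frame` with `contig`, `start`, `end` (23-bp site), `strand`,
#'   `mismatches`, `mismatch_positions` (comma-separated), `has_pam`,
#'   `intended`. If no 0-mismatch site exists anywhere a warning is raised.
#' @export
specificity_search <- function(g, genome, max_mismatches = 4) {
  stopifnot(max_mismatches <= 6)
  proto <- Biostrings::DNAString(g$protospacer)
  rproto <- Biostrings::reverseComplement(proto)
  hits <- list()
  for (ctg in names(genome)) {
    subj <- Biostrings::DNAString(genome[[ctg]])
    n <- length(subj)
    m <- Biostrings::matchPattern(proto, subj, max.mismatch = max_mismatches)
    for (i in seq_along(m)) {
      s <- IRanges::start(m)[i]
      if (s + 22L > n) next
      pam <- as.character(subj[(s + 20L):(s + 22L)])
      if (!grepl("^[ACGT]GG$", pam)) next
      mm <- proto_mismatches(as.character(subj[s:(s + 19L)]), g$protospacer)
      hits[[length(hits) + 1L]] <- data.frame(
        contig = ctg, start = s, end = s + 22L, strand = "+",
        mismatches = length(mm),
        mismatch_positions = paste(mm, collapse = ","),
        has_pam = TRUE, stringsAsFactors = FALSE)
    }
    m <- Biostrings::matchPattern(rproto, subj, max.mismatch = max_mismatches)
    for (i in seq_along(m)) {
      s <- IRanges::start(m)[i]
      if (s < 4L) next
      pam_fwd <- as.character(subj[(s - 3L):(s - 1L)])
      if (!grepl("^CC[ACGT]$", pam_fwd)) next
      slice <- revcomp(as.character(subj[s:(s + 19L)]))
      mm <- proto_mismatches(slice, g$protospacer)
      hits[[length(hits) + 1L]] <- data.frame(
        contig = ctg, start = s - 3L, end = s + 19L, strand = "-",
        mismatches = length(mm),
        mismatch_positions = paste(mm, collapse = ","),
        has_pam = TRUE, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               strand = character(0), mismatches = integer(0),
               mismatch_positions = character(0), has_pam = logical(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out$intended <- out$mismatches == 0L & out$contig == g$contig &
    out$start == g$start & out$strand == g$strand
  if (!any(out$mismatches == 0L)) {
    warning("guide ", g$name, " not locatable anywhere with 0 mismatches")
  }
  out
}

#' Per-position mismatch penalty table
#'
#' The vendored 20-entry penalty vector used by [specificity_score()]
#' (positions in protospacer coordinates, 1 = PAM-distal; PAM-proximal
#' mismatches carry larger penalties, i.e. such off-target sites weigh less).
#' Swappable: any numeric vector of 20 penalties in \[0,1\] can be passed to
#' [specificity_score()] instead.
#'
#' @param path Optional path to a two-column TSV (`position`, `penalty`);
#'   defaults to the packaged table.
#' @return Numeric vector of length 20.
#' @export
mismatch_weights <- function(path = NULL) {
  path <- path %||% system.file("extdata", "mismatch_weights.tsv",
                                package = "capxcise", mustWork = TRUE)
  tab <- utils::read.delim(path)
  stopifnot(nrow(tab) == 20L, all(tab$position == 1:20),
            all(tab$penalty >= 0 & tab$penalty <= 1))
  tab$penalty
}

#' Aggregate specificity score of a guide from its off-target hits
#'
#' Each hit is weighted `w = prod(1 - penalty[p])` over its mismatch
#' positions; the score is `100 * w(intended) / sum(w)`. 100 exactly when the
#' intended site is the only hit; any secondary hit strictly lowers it, and
#' secondary hits with fewer or more PAM-distal mismatches lower it more.
#'
#' @param hits Hit `data.frame` from [specificity_search()]; must contain the
#'   intended (0-mismatch) site.
#' @param weights Penalty vector as from [mismatch_weights()].
#' @return Percentage in (0, 100].
#' @export
specificity_score <- function(hits, weights = mismatch_weights()) {
  if (is.null(hits) || nrow(hits) == 0L) stop("empty hit list")
  if (!any(hits$mismatches == 0L)) stop("hits must include the intended (0-mismatch) site")
  w <- vapply(seq_len(nrow(hits)), function(i) {
    if (hits$mismatches[i] == 0L) return(1)
    pos <- as.integer(strsplit(hits$mismatch_positions[i], ",", fixed = TRUE)[[1]])
    prod(1 - weights[pos])
  }, numeric(1))
  100 * 1 / sum(w)
}

#' Cut directionality of a guide relative to a region of interest
#'
#' After cleavage Cas9 stays bound to the PAM-distal side, so sequencing
#' adapters can only ligate to the freed PAM-proximal end. A guide reads
#' `"toward"` when that free end faces the ROI (its reads run into the ROI)
#' and `"away"` otherwise.
#'
#' @param g One-row guide `data.frame`.
#' @param roi Interval (`c(start, end)` or list) on the guide's contig.
#' @return `"toward"` or `"away"`.
#' @export
orientation <- function(g, roi) {
  roi <- as_interval(roi)
  if (g$start <= roi$end && g$end >= roi$start) {
    stop("guide ", g$name, " overlaps/lies inside the ROI; orientation undefined")
  }
  free_dir <- if (g$strand == "+") "right" else "left"
  roi_dir <- if (roi$start > g$end) "right" else "left"
  if (free_dir == roi_dir) "toward" else "away"
}

#' Default cleavage efficiency multipliers
#'
#' `full` sites always cut; a protospacer mismatch in the PAM-distal half
#' (positions 1-10) reduces efficiency moderately, one in the seed region
#' (positions 11-20, PAM-proximal) strongly; a disrupted PAM leaves a small
#' nonzero residual (`none`), reconciling detectable amplicon digestion with
#' the absence of genomic reads from such guides.
#'
#' @return Named list of multipliers in \[0,1\].
#' @export
cleavage_multipliers <- function() {
  list(full = 1.0, reduced_distal = 0.5, reduced_seed = 0.1, none = 0.05)
}

## best placement of a guide's protospacer in a template, substitutions only
locate_guide <- function(g, template_seq, max_mismatches = 4) {
  subj <- Biostrings::DNAString(toupper(template_seq))
  n <- length(subj)
  best <- NULL
  consider <- function(site_start, site_end, strand, slice, pam) {
    mm <- proto_mismatches(slice, g$protospacer)
    cand <- list(start = site_start, end = site_end, strand = strand,
                 mismatch_positions = mm, pam = pam,
                 pam_ok = grepl("^[ACGT]GG$", pam))
    if (is.null(best) || length(mm) < length(best$mismatch_positions) ||
        (length(mm) == length(best$mismatch_positions) && site_start < best$start)) {
      best <<- cand
    }
  }
  m <- Biostrings::matchPattern(Biostrings::DNAString(g$protospacer), subj,
                                max.mismatch = max_mismatches)
  for (i in seq_along(m)) {
    s <- IRanges::start(m)[i]
    if (s + 22L > n) next
    consider(s, s + 22L, "+", as.character(subj[s:(s + 19L)]),
             as.character(subj[(s + 20L):(s + 22L)]))
  }
  m <- Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString(g$protospacer)), subj,
    max.mismatch = max_mismatches)
  for (i in seq_along(m)) {
    s <- IRanges::start(m)[i]
    if (s < 4L) next
    consider(s - 3L, s + 19L, "-", revcomp(as.character(subj[s:(s + 19L)])),
             revcomp(as.character(subj[(s - 3L):(s - 1L)])))
  }
  best
}

#' Predicted effect of haplotype SNPs on a guide's cleavage
#'
#' Locates the guide site in a haplotype sequence (within 4 substitutions)
#' and classifies cleavage: a disrupted PAM gives class `"none"` (small
#' residual multiplier), a protospacer mismatch gives `"reduced"` (seed
#' mismatches, protospacer positions 11-20, are penalized harder than distal
#' ones), an identical site gives `"full"`.
#'
#' @param g One-row guide `data.frame`.
#' @param haplotype_seq Nucleotide string of the haplotype (or the slice
#'   containing the site).
#' @param multipliers Efficiency multipliers, see [cleavage_multipliers()].
#' @param seed_region Protospacer positions counted as seed (default 11:20).
#' @return List with `class` (`full`/`reduced`/`none`), `subclass`,
#'   `multiplier`, `mismatch_positions`, `pam`, and the located `site`.
#' @export
snp_effect <- function(g, haplotype_seq, multipliers = cleavage_multipliers(),
                       seed_region = 11:20) {
  loc <- locate_guide(g, haplotype_seq)
  if (is.null(loc)) {
    stop("guide ", g$name, " site not found in haplotype within 4 mismatches")
  }
  mm <- loc$mismatch_positions
  if (!loc$pam_ok) {
    cls <- "none"; sub <- "pam_disrupted"; mult <- multipliers$none
  } else if (length(mm) == 0L) {
    cls <- "full"; sub <- "full"; mult <- multipliers$full
  } else if (any(mm %in% seed_region)) {
    cls <- "reduced"; sub <- "seed"; mult <- multipliers$reduced_seed
  } else {
    cls <- "reduced"; sub <- "distal"; mult <- multipliers$reduced_distal
  }
  list(class = cls, subclass = sub, multiplier = mult,
       mismatch_positions = mm, pam = loc$pam,
       site = loc[c("start", "end", "strand")])
}

#' Assemble a guide panel for an ROI under a design strategy
#'
#' * `excision`: guides on both sides of the ROI, all oriented toward it
#'   (their freed ends read into the ROI), the excised piece spanning the ROI.
#' * `single_cut`: one guide at the stated known end, oriented toward the
#'   unknown side (genome walking).
#' * `tiling`: successive guides whose predicted cut sites are spaced 5-10 kb
#'   apart across the ROI, for even coverage of regions longer than one
#'   excisable piece.
#'
#' @param roi Interval list with `contig`, `start`, `end`.
#' @param genome Named character vector of sequences.
#' @param strategy `"excision"`, `"single_cut"` or `"tiling"`.
#' @param params List: `search_window` (bp scanned beside the ROI, default
#'   2000), `n_per_side` (excision guides per side, default 1), `known_end`
#'   (`"left"`/`"right"`, single_cut), `tile_min`/`tile_max` (cut spacing
#'   bounds, default 5000/10000).
#' @return Guide `data.frame`; errors name the failed constraint.
#' @export
plan_panel <- function(roi, genome,
                       strategy = c("excision", "single_cut", "tiling"),
                       params = list()) {
  strategy <- match.arg(strategy)
  roi <- as_interval(roi)
  if (is.na(roi$contig) || !roi$contig %in% names(genome)) {
    stop("ROI must name a contig present in the genome")
  }
  seq <- genome[[roi$contig]]
  n <- nchar(seq)
  if (roi$start < 1 || roi$end > n) stop("ROI outside contig bounds")
  p <- utils::modifyList(list(search_window = 2000L, n_per_side = 1L,
                              known_end = "left", tile_min = 5000L,
                              tile_max = 10000L), params)
  cands <- scan_pams(seq, contig = roi$contig)

  pick_side <- function(side, n_guides) {
    if (side == "left") {
      ok <- cands$end < roi$start & cands$start >= roi$start - p$search_window &
        cands$strand == "+"
      sel <- cands[ok, , drop = FALSE]
      sel <- sel[order(-sel$start), , drop = FALSE]
    } else {
      ok <- cands$start > roi$end & cands$end <= roi$end + p$search_window &
        cands$strand == "-"
      sel <- cands[ok, , drop = FALSE]
      sel <- sel[order(sel$start), , drop = FALSE]
    }
    if (nrow(sel) < n_guides) {
      stop("no panel: fewer than ", n_guides, " NGG candidate(s) oriented ",
           "toward the ROI within ", p$search_window, " bp on the ", side,
           " side")
    }
    utils::head(sel, n_guides)
  }

  out <- switch(strategy,
    excision = rbind(pick_side("left", p$n_per_side),
                     pick_side("right", p$n_per_side)),
    single_cut = pick_side(p$known_end, 1L),
    tiling = {
      cuts <- vapply(seq_len(nrow(cands)), function(i)
        cut_site(cands[i, ])$position, numeric(1))
      ## anchor: cut nearest the ROI start (at or just before it)
      anchor_ok <- cuts <= roi$start + p$tile_min
      if (!any(anchor_ok)) stop("no panel: no cut site at or near the ROI start")
      first <- which(anchor_ok)[which.max(cuts[anchor_ok])]
      chosen <- first
      repeat {
        cur <- cuts[chosen[length(chosen)]]
        if (cur >= roi$end) break
        win <- which(cuts >= cur + p$tile_min & cuts <= cur + p$tile_max)
        if (!length(win)) {
          stop("no panel: no NGG cut site within [", p$tile_min, ", ",
               p$tile_max, "] bp after position ", cur)
        }
        chosen <- c(chosen, win[which.max(cuts[win])])
      }
      cands[chosen, , drop = FALSE]
    })
  out$name <- sprintf("panel_%s_%02d", strategy, seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Write / read guides as TSV
#'
#' Tab-separated with the published table layout (`Name`, `Sequence 5'-3'`
#' as protospacer+PAM, `Chr`, `Start`, `End`) plus `Strand`.
#'
#' @param guides Guide `data.frame`.
#' @param path File path.
#' @return `path` (write) or a guide `data.frame` (read).
#' @export
write_guides <- function(guides, path) {
  out <- data.frame(Name = guides$name,
                    Sequence = paste0(guides$protospacer, guides$pam),
                    Chr = guides$contig, Start = guides$start,
                    End = guides$end, Strand = guides$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_guides
#' @export
read_guides <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    guide(tab$Name[i], substr(tab$Sequence[i], 1, 20),
          substr(tab$Sequence[i], 21, 23), tab$Chr[i], tab$Start[i],
          tab$End[i], tab$Strand[i])
  }))
}
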