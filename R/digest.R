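## In-silico Cas9 digestion. The blunt cut falls three bases upstream of the
## PAM; Cas9 stays bound to the PAM-distal side of the cut, blocking adapter
## ligation there, while the PAM-proximal side is freed with a ligatable
## 5' phosphate. Fragments carry a four-flag end state
## (phosphorylated / blocked / dA-tailed / adapter) on each end.

#' Predicted blunt cut site of a guide
#'
#' The cut falls between protospacer positions 17 and 18 (three bases
#' upstream of the PAM): for a forward guide occupying `[start, end]` the cut
#' lies between `end - 6` and `end - 5`; for a reverse guide between
#' `start + 5` and `start + 6`. `position` names the base immediately left of
#' the cut. The blocked side is the PAM-distal side.
#'
#' @param g One-row guide `data.frame`.
#' @return List with `contig`, `position`, `guide`, `blocked_side`,
#'   `free_side`.
#' @export
cut_site <- function(g) {
  stopifnot(g$strand %in% c("+", "-"))
  if (g$strand == "+") {
    list(contig = g$contig, position = as.integer(g$end - 6L), guide = g$name,
         blocked_side = "left", free_side = "right")
  } else {
    list(contig = g$contig, position = as.integer(g$start + 5L), guide = g$name,
         blocked_side = "right", free_side = "left")
  }
}

empty_end <- function(class = "natural", guide = NA_character_,
                      phosphorylated = TRUE, blocked = FALSE) {
  list(class = class, guide = guide, phosphorylated = phosphorylated,
       blocked = blocked, da_tailed = FALSE, adapter = FALSE, leaked = FALSE)
}

end_cols <- function(side, e) {
  stats::setNames(
    list(e$class, e$guide, e$phosphorylated, e$blocked, e$da_tailed,
         e$adapter, e$leaked),
    paste0(side, "_",
           c("class", "guide", "phos", "blocked", "da", "adapter", "leaked")))
}

#' Digest one template with a set of guides
#'
#' Each guide is located in the template (tolerating up to 4 substitutions so
#' haplotype SNPs shift or silence it per [snp_effect()]); cleavage is then
#' decided against the class multiplier: `full` always cuts, other classes
#' cut with probability equal to their multiplier (a seeded draw from the
#' caller's RNG). Fragments tile the template exactly; cut ends are
#' phosphorylated and blocked on the PAM-distal side, pre-existing template
#' ends are phosphorylated and unblocked.
#'
#' @param template_seq Nucleotide string.
#' @param guides Guide `data.frame`.
#' @param template_id Name recorded in the fragment table.
#' @param haplotype Haplotype tag carried through (`"A"`, `"B"` or `NA`).
#' @param multipliers See [cleavage_multipliers()].
#' @return Fragment `data.frame`: `template`, `haplotype`, `start`, `end`,
#'   and `left_*` / `right_*` end-state columns
#'   (`class`, `guide`, `phos`, `blocked`, `da`, `adapter`).
#' @export
digest_template <- function(template_seq, guides, template_id = "template",
                            haplotype = NA_character_,
                            multipliers = cleavage_multipliers()) {
  n <- nchar(template_seq)
  cuts <- list()
  for (i in seq_len(nrow(guides))) {
    g <- guides[i, ]
    eff <- tryCatch(snp_effect(g, template_seq, multipliers = multipliers),
                    error = function(e) NULL)
    if (is.null(eff)) next   # site absent from this template: no cut
    does_cut <- eff$multiplier >= 1 ||
      (eff$multiplier > 0 && stats::runif(1) < eff$multiplier)
    if (!does_cut) next
    gg <- g
    gg$start <- eff$site$start; gg$end <- eff$site$end; gg$strand <- eff$site$strand
    cs <- cut_site(gg)
    if (cs$position < 1L || cs$position >= n) next
    cuts[[length(cuts) + 1L]] <- cs
  }
  pos <- vapply(cuts, `[[`, numeric(1), "position")
  if (anyDuplicated(pos)) {
    stop("two cuts at the same position (", pos[duplicated(pos)][1],
         ") in template ", template_id)
  }
  o <- order(pos)
  cuts <- cuts[o]; pos <- pos[o]
  bounds <- c(0L, as.integer(pos), n)
  frags <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    left <- if (k == 1L) empty_end("natural") else {
      cs <- cuts[[k - 1L]]
      empty_end("cut", cs$guide, TRUE, cs$blocked_side == "right")
    }
    right <- if (k == length(bounds) - 1L) empty_end("natural") else {
      cs <- cuts[[k]]
      empty_end("cut", cs$guide, TRUE, cs$blocked_side == "left")
    }
    frags[[k]] <- data.frame(
      template = template_id, haplotype = haplotype,
      start = bounds[k] + 1L, end = bounds[k + 1L],
      end_cols("left", left), end_cols("right", right),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, frags)
  rownames(out) <- NULL
  out
}

#' Digest a whole (haplotype-resolved) genome
#'
#' Applies [digest_template()] to every sequence; sequences not containing
#' any guide site come back as a single uncut fragment. Haplotype tags are
#' parsed from `_hapA` / `_hapB` name suffixes when present.
#'
#' @param genome Named character vector of sequences.
#' @param guides Guide `data.frame`.
#' @inheritParams digest_template
#' @return Combined fragment `data.frame`.
#' @export
digest_genome <- function(genome, guides,
                          multipliers = cleavage_multipliers()) {
  do.call(rbind, lapply(names(genome), function(nm) {
    hap <- if (grepl("_hapA$", nm)) "A" else if (grepl("_hapB$", nm)) "B"
           else NA_character_
    digest_template(genome[[nm]], guides, template_id = nm, haplotype = hap,
                    multipliers = multipliers)
  }))
}

#' Dephosphorylate pre-existing DNA ends
#'
#' Models the alkaline-phosphatase step that removes 5' phosphates from
#' pre-existing (non-Cas9) ends so that adapters later ligate preferentially
#' to fresh cut ends. Only ends of class `"natural"` are affected; each loses
#' its phosphate independently with probability `efficiency`. Cut ends are
#' never touched.
#'
#' @param fragments Fragment `data.frame`.
#' @param efficiency Fraction in \[0,1\].
#' @return Updated fragment `data.frame`.
#' @export
dephosphorylate <- function(fragments, efficiency) {
  stop_bad_fraction(efficiency, "dephosphorylation efficiency")
  for (side in c("left", "right")) {
    cls <- fragments[[paste0(side, "_class")]]
    ph <- fragments[[paste0(side, "_phos")]]
    nat <- which(cls == "natural" & ph)
    if (length(nat)) {
      lose <- stats::runif(length(nat)) < efficiency
      ph[nat[lose]] <- FALSE
      fragments[[paste0(side, "_phos")]] <- ph
    }
  }
  fragments
}

#' dA-tail all fragment ends
#'
#' Every blunt end receives a single 3' adenine, making it ligation-ready.
#'
#' @param fragments Fragment `data.frame`.
#' @return Updated fragment `data.frame`.
#' @export
da_tail <- function(fragments) {
  fragments$left_da <- TRUE
  fragments$right_da <- TRUE
  fragments
}

#' Check fragment-set invariants
#'
#' Asserts that fragments from each template tile it exactly (no gaps or
#' overlaps, lengths summing to the template length when known) and that any
#' adapter-bearing end is phosphorylated, dA-tailed and unblocked.
#'
#' @param fragments Fragment `data.frame`.
#' @param template_lengths Optional named vector of template lengths.
#' @return `TRUE` invisibly; errors on the first violation.
#' @export
validate_fragments <- function(fragments, template_lengths = NULL) {
  for (tid in unique(fragments$template)) {
    f <- fragments[fragments$template == tid, ]
    f <- f[order(f$start), ]
    if (f$start[1] != 1L) stop("template ", tid, ": first fragment must start at 1")
    if (nrow(f) > 1L && any(f$start[-1] != f$end[-nrow(f)] + 1L)) {
      stop("template ", tid, ": fragments do not tile (gap or overlap)")
    }
    if (!is.null(template_lengths) && tid %in% names(template_lengths)) {
      if (f$end[nrow(f)] != template_lengths[[tid]]) {
        stop("template ", tid, ": fragment lengths do not sum to template length")
      }
    }
  }
  for (side in c("left", "right")) {
    ad <- fragments[[paste0(side, "_adapter")]]
    ok <- !ad | (fragments[[paste0(side, "_phos")]] &
                   fragments[[paste0(side, "_da")]] &
                   !fragments[[paste0(side, "_blocked")]])
    if (!all(ok)) {
      stop("adapter on an end that is not (phosphorylated & dA-tailed & unblocked)")
    }
  }
  invisible(TRUE)
}

#' Predicted digestion fragment sizes of a PCR amplicon
#'
#' @param forward_primer,reverse_primer One-row data.frames with `start`/`end`
#'   (as from [myb10_primers()]) or bare numeric coordinates (forward start /
#'   reverse end).
#' @param g One-row guide `data.frame` (reference coordinates).
#' @return Integer vector of fragment lengths: two lengths when the cut falls
#'   inside the amplicon, otherwise the intact amplicon length.
#' @examples
#' pr <- myb10_primers()
#' predict_amplicon_fragments(pr[1, ], pr[2, ], myb10_guides()[1, ])  # 131 249
#' @export
predict_amplicon_fragments <- function(forward_primer, reverse_primer, g) {
  fstart <- if (is.data.frame(forward_primer)) forward_primer$start
            else as.numeric(forward_primer)
  rend <- if (is.data.frame(reverse_primer)) reverse_primer$end
          else as.numeric(reverse_primer)
  if (rend < fstart) stop("reverse primer end precedes forward primer start")
  pos <- cut_site(g)$position
  if (pos >= fstart && pos + 1 <= rend) {
    as.integer(c(pos - fstart + 1, rend - pos))
  } else {
    as.integer(rend - fstart + 1)
  }
}

#' On-target window spanned by a guide panel
#'
#' Two bases are implemented explicitly because both appear in practice:
#' `cut_span` is the inclusive interval between the outermost predicted blunt
#' cut positions (the excised molecule as the library sees it); `site_span`
#' is the distance between the start coordinates of the innermost flanking
#' guide pair (the pair adjacent across the largest inter-guide gap, i.e.
#' across the ROI).
#'
#' @param guides Guide `data.frame` (>= 2 guides on one contig).
#' @param mode `"cut_span"` or `"site_span"`.
#' @return List with `contig`, `start`, `end`, `length` (bp), `mode`.
#' @examples
#' on_target_window(myb10_guides(), "cut_span")$length   # 9177
#' on_target_window(myb10_guides(), "site_span")$length  # 7841
#' @export
on_target_window <- function(guides, mode = c("cut_span", "site_span")) {
  mode <- match.arg(mode)
  if (nrow(guides) < 2L) {
    stop("on_target_window needs >= 2 guides; with a single guide use the ",
         "single_cut strategy (no excised window is defined)")
  }
  if (length(unique(guides$contig)) != 1L) {
    stop("all guides must lie on one contig")
  }
  if (mode == "cut_span") {
    pos <- vapply(seq_len(nrow(guides)), function(i)
      cut_site(guides[i, ])$position, numeric(1))
    start <- min(pos) + 1L; end <- max(pos)
    list(contig = guides$contig[1], start = as.integer(start),
         end = as.integer(end), length = as.integer(end - start + 1L),
         mode = mode)
  } else {
    o <- order(guides$start)
    starts <- guides$start[o]
    gaps <- diff(starts)
    i <- which.max(gaps)
    list(contig = guides$contig[1], start = as.integer(starts[i]),
         end = as.integer(starts[i + 1L]),
         length = as.integer(starts[i + 1L] - starts[i]), mode = mode,
         guides = guides$name[o][c(i, i + 1L)])
  }
}
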