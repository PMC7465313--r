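## Packaged end-to-end demonstration: a synthetic diploid genome emulating
## the study locus (a 1-copy vs 6-copy minisatellite heterozygote flanked by
## an excision guide panel, one upstream guide silenced by a PAM SNP and the
## downstream away-oriented guide weakened by a protospacer SNP), digested,
## library-prepped and sequenced under the calibrated simulation profile.

#' Genome configuration of the packaged demonstration locus
#'
#' Four 2-Mb chromosomes at plant-like GC: the target chromosome carries a
#' 23-bp repeat unit in 1 copy (haplotype A) vs 6 copies (haplotype B) with
#' 4.5-kb flanks; a second chromosome carries a 90%-identity paralog of the
#' target window; two decoys carry planted ligatable-end hotspots that the
#' off-target detector should recover.
#'
#' @param seed Integer seed.
#' @return A [synthetic_genome_config()] (without guide-site SNPs; the demo
#'   plants those after guide selection, see [enrichment_demo()]).
#' @export
demo_genome_config <- function(seed = 1) {
  synthetic_genome_config(
    seed = seed,
    chromosomes = data.frame(
      name = c("chrT", "chrP", "chrD1", "chrD2"),
      length = c(2e6, 2e6, 2e6, 2e6),
      gc = c(0.38, 0.38, 0.40, 0.36)),
    target_locus = list(chromosome = "chrT", position = 1e6, flank = 4500,
                        repeat_unit = NULL, copies_hapA = 1, copies_hapB = 6),
    paralog = list(chromosome = "chrP", position = 1e6, identity = 0.90),
    planted_offtargets = data.frame(
      chromosome = c("chrD1", "chrD2"),
      position = c(5e5, 1.2e6),
      density = c(0.8, 0.5)))
}

## pick the demo guide panel on the haplotype-A reference: two forward guides
## upstream (toward), one reverse guide just downstream (toward), one forward
## guide further downstream (away)
demo_pick_guides <- function(hapA_seq, roi) {
  n <- nchar(hapA_seq)
  up_from <- max(1L, roi$start - 600L)
  up <- scan_pams(substr(hapA_seq, up_from, roi$start + 22L), contig = "chrT")
  up$start <- up$start + up_from - 1L; up$end <- up$end + up_from - 1L
  fwd_up <- up[up$strand == "+" & up$end < roi$start, , drop = FALSE]
  fwd_up <- fwd_up[order(-fwd_up$start), , drop = FALSE]
  if (nrow(fwd_up) < 1L) stop("demo genome: no upstream forward guide found")
  g2 <- fwd_up[1, ]
  far <- fwd_up[fwd_up$start <= g2$start - 100L, , drop = FALSE]
  if (nrow(far) < 1L) stop("demo genome: no second upstream guide found")
  g1 <- far[1, ]

  dn_to <- min(n, roi$end + 600L)
  dn <- scan_pams(substr(hapA_seq, roi$end - 22L, dn_to), contig = "chrT")
  off <- roi$end - 22L - 1L
  dn$start <- dn$start + off; dn$end <- dn$end + off
  rev_dn <- dn[dn$strand == "-" & dn$start > roi$end, , drop = FALSE]
  rev_dn <- rev_dn[order(rev_dn$start), , drop = FALSE]
  if (nrow(rev_dn) < 1L) stop("demo genome: no downstream reverse guide found")
  g3 <- rev_dn[1, ]
  fwd_dn <- dn[dn$strand == "+" & dn$start >= g3$end + 50L, , drop = FALSE]
  fwd_dn <- fwd_dn[order(fwd_dn$start), , drop = FALSE]
  if (nrow(fwd_dn) < 1L) stop("demo genome: no downstream forward guide found")
  g4 <- fwd_dn[1, ]

  out <- rbind(g1, g2, g3, g4)
  out$name <- c("demo_up_1", "demo_up_2", "demo_dn_3", "demo_dn_4")
  rownames(out) <- NULL
  out
}

#' Run the packaged calibrated enrichment demonstration
#'
#' Builds the demo genome, selects the four-guide excision panel, plants the
#' two study-like SNPs (a PAM-disrupting SNP on the proximal upstream guide
#' and a distal protospacer SNP on the away-oriented downstream guide, on
#' both haplotypes), digests, library-preps and simulates a run under the
#' `"calibrated_run"` profile, then scores the truth alignments against the
#' cut-defined on-target windows.
#'
#' @param seed Integer seed driving every stage.
#' @param n_reads Number of simulated reads (default 7000).
#' @param sim_overrides Optional list of [sim_config()] overrides.
#' @return List: `genome` (sequences + truth), `guides`, `fragments`,
#'   `windows` (per-haplotype cut windows), `run` (`sim_run`), `report`
#'   (enrichment report) and `on_target_percent`.
#' @export
enrichment_demo <- function(seed = 1, n_reads = 7000, sim_overrides = list()) {
  seed <- as.integer(seed)
  cfg0 <- demo_genome_config(seed)
  g0 <- make_genome(cfg0)
  roiA <- as.list(g0$truth$target[g0$truth$target$haplotype == "A",
                                  c("window_start", "window_end")])
  roi <- list(start = roiA$window_start, end = roiA$window_end)
  hapA <- g0$sequences[["chrT_hapA"]]
  guides <- demo_pick_guides(hapA, roi)
  guides$contig <- "chrT"

  ## plant the study-like SNPs: g2 loses its PAM, g4 gains a distal
  ## protospacer mismatch; positions downstream of the repeat shift by the
  ## haplotype-B extra array length
  tl <- cfg0$target_locus
  delta <- (tl$copies_hapB - tl$copies_hapA) * nchar(g0$truth$repeat_unit)
  alt_base <- function(ref) setdiff(c("A", "C", "G", "T"), ref)[1]
  g2 <- guides[2, ]; g4 <- guides[4, ]
  pam_pos <- g2$end - 1L                       # first G of the NGG
  proto_pos <- g4$start + 2L                   # protospacer position 3 (distal)
  shiftB <- function(p) if (p > tl$position) p + delta else p
  snps <- data.frame(
    haplotype = c("A", "B", "A", "B"),
    position = c(pam_pos, shiftB(pam_pos), proto_pos, shiftB(proto_pos)),
    alt = c("A", "A",
            alt_base(substr(hapA, proto_pos, proto_pos)),
            alt_base(substr(hapA, proto_pos, proto_pos))),
    stringsAsFactors = FALSE)
  cfg <- synthetic_genome_config(
    seed = seed, chromosomes = cfg0$chromosomes, target_locus = tl,
    paralog = cfg0$paralog, planted_snps = snps,
    planted_offtargets = cfg0$planted_offtargets)
  g <- make_genome(cfg)

  config <- do.call(sim_config, c(list(profile = "calibrated_run",
                                       n_reads = n_reads, seed = seed + 2L),
                                  sim_overrides))
  frags <- with_seed(seed + 1L, {
    f <- digest_genome(g$sequences, guides)
    f <- dephosphorylate(f, config$dephosphorylation_efficiency)
    f <- da_tail(f)
    ligate_adapters(f, config)
  })
  windows <- target_windows(g$sequences, guides, mode = "cut_span")
  run <- simulate_run(g$sequences, frags, config, truth = g$truth)
  report <- enrichment_report(truth_paf(run), windows)
  list(genome = g, guides = guides, fragments = frags, windows = windows,
       run = run, report = report,
       on_target_percent = report$on_target_percentage)
}
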