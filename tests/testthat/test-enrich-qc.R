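# hand-built PAF rows (tstart 0-based half-open, as mappers emit)
make_paf <- function(tstart, tend, strand = "+", mapq = 60, tname = "chr1",
                     tlen = 30000, qname = NULL) {
  n <- length(tstart)
  data.frame(qname = qname %||% sprintf("r%04d", seq_len(n)),
             qlen = tend - tstart, qstart = rep(0L, n),
             qend = tend - tstart,
             strand = rep_len(strand, n), tname = rep_len(tname, n),
             tlen = rep_len(tlen, n),
             tstart = as.integer(tstart), tend = as.integer(tend),
             nmatch = tend - tstart, alnlen = tend - tstart,
             mapq = rep_len(as.integer(mapq), n), stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("N50 satisfies its defining property (oracle equivalence)", {
  expect_equal(n50(7000), 7000)
  expect_equal(n50(1000 * (1:5)), 4000)    # 5+4 = 9 >= 7.5
  set.seed(2)
  for (i in 1:20) {
    lens <- sample(100:50000, sample(1:100, 1), replace = TRUE)
    expect_equal(n50(lens), oracle_n50(lens))
  }
})

test_that("read stats partition pass reads inclusively at the threshold", {
  rs <- read_stats(c(8000, 9000, 10000), c(6.9, 7.0, 7.1), pass_threshold = 7)
  expect_equal(rs$reads, 3L)
  expect_equal(rs$pass_reads, 2L)          # "7 or more" includes 7.0
  expect_equal(rs$pass_bases, 19000)
  expect_equal(rs$median_length, 9000)
  one <- read_stats(7000, 9.5)
  expect_equal(one$n50, 7000)
  expect_equal(one$median_length, 7000)
  expect_error(read_stats(numeric(0), numeric(0)), "length")
})

test_that("enrichment report counts window-overlapping best alignments", {
  win <- data.frame(contig = "chr1", start = 10001, end = 19177)
  # all reads inside the window
  paf_all <- make_paf(rep(12000, 5), rep(13000, 5))
  r <- enrichment_report(paf_all, win)
  expect_equal(r$on_target_percentage, 100)
  # constructed truth: 30 of 1000 overlap
  on <- make_paf(seq(10500, by = 10, length.out = 30),
                 seq(11500, by = 10, length.out = 30),
                 qname = sprintf("on%03d", 1:30))
  off <- make_paf(seq(20001, by = 5, length.out = 970),
                  seq(20501, by = 5, length.out = 970),
                  qname = sprintf("off%03d", 1:970))
  r2 <- enrichment_report(rbind(on, off), win)
  expect_equal(r2$aligned_reads, 1000L)
  expect_equal(r2$on_target_coverage, 30L)
  expect_equal(r2$on_target_percentage, 3.0)
  # coverage is additive over strands: forward 3 + reverse 2 -> 5
  mix <- rbind(make_paf(rep(12000, 3), rep(12500, 3), strand = "+",
                        qname = paste0("f", 1:3)),
               make_paf(rep(12000, 2), rep(12500, 2), strand = "-",
                        qname = paste0("r", 1:2)))
  r3 <- enrichment_report(mix, win)
  expect_equal(c(r3$on_target_forward, r3$on_target_reverse), c(3L, 2L))
  expect_equal(r3$on_target_coverage, 5L)
  # boundary: 1 bp overlap counts
  edge <- make_paf(19176, 19600)           # covers 19177 only
  expect_equal(enrichment_report(edge, win)$on_target_coverage, 1L)
  expect_warning(r0 <- enrichment_report(make_paf(integer(0), integer(0)), win),
                 "no alignments")
  expect_true(r0$warning)
})

test_that("per-base depth equals brute-force counting", {
  paf <- make_paf(9, 20, tlen = 100)       # 1-based [10, 20]
  d <- per_base_depth(paf)[["chr1"]]
  expect_equal(as.integer(d[10:20]), rep(1L, 11))
  expect_equal(sum(as.integer(d)), 11L)
  two <- make_paf(c(9, 14), c(20, 30), tlen = 100)
  d2 <- per_base_depth(two)[["chr1"]]
  expect_equal(max(as.integer(d2)), 2L)
  expect_equal(as.integer(d2[15:20]), rep(2L, 6))
  set.seed(2)
  st <- sample(0:900, 50, replace = TRUE)
  en <- st + sample(10:100, 50, replace = TRUE)
  paf50 <- make_paf(st, en, tlen = 1000)
  got <- as.integer(per_base_depth(paf50)[["chr1"]])
  expect_equal(got, oracle_depth(st + 1L, en, 1000L))
  # total depth equals the summed alignment block lengths (no mapq filter)
  expect_equal(sum(got), sum(en - st))
})

test_that("binned coverage composes from per-base depth", {
  # uniform depth d: every bin reports d
  unif <- make_paf(rep(0, 4), rep(10000, 4), tlen = 10000)
  b <- bin_coverage(unif, bin_size = 1000)
  expect_equal(b$mean_depth, rep(4, 10))
  # one pileup confined to a single bin
  pile <- make_paf(rep(2100, 7), rep(2900, 7), tlen = 10000)
  b2 <- bin_coverage(pile, bin_size = 1000)
  expect_equal(sum(b2$mean_depth > 0), 1L)
  expect_equal(b2$contig[b2$mean_depth > 0], "chr1")
  # random alignments: bins equal naive recomputation from per-base depth
  set.seed(3)
  st <- sample(0:9000, 40, replace = TRUE)
  paf <- make_paf(st, st + sample(50:900, 40, replace = TRUE), tlen = 10000)
  b3 <- bin_coverage(paf, bin_size = 500)
  d <- as.integer(per_base_depth(paf)[["chr1"]])
  naive <- vapply(seq_len(nrow(b3)), function(i)
    mean(d[b3$start[i]:b3$end[i]]), numeric(1))
  expect_equal(b3$mean_depth, naive)
})

test_that("off-target detection applies depth and mapq gates and merges bins", {
  win <- data.frame(contig = "chr1", start = 100, end = 1000)
  # uniform background depth 5: nothing detected
  bg <- make_paf(rep(0, 5), rep(30000, 5))
  expect_equal(nrow(detect_offtargets(bg, win)), 0L)
  # planted pileup depth 40 spanning three bins outside the window
  pile <- make_paf(rep(5000, 40), rep(8000, 40))
  got <- detect_offtargets(pile, win)
  expect_equal(nrow(got), 1L)
  expect_equal(got$max_coverage, 40)
  expect_lte(abs(got$start - 5001), 1000)
  expect_lte(abs(got$end - 8000), 1000)
  expect_equal(got$size, got$end - got$start + 1L)
  # pileup overlapping the window is excluded
  onwin <- make_paf(rep(99, 40), rep(3000, 40))
  expect_equal(nrow(detect_offtargets(onwin, win)), 0L)
  # mapq gate: depth 30 at mapq 20 is invisible
  lowq <- make_paf(rep(5000, 30), rep(8000, 30), mapq = 20)
  expect_equal(nrow(detect_offtargets(lowq, win)), 0L)
  # annotation overlap labels
  ann <- data.frame(contig = "chr1", start = 6000, end = 6500, name = "geneX")
  expect_equal(detect_offtargets(pile, win, annotation = ann)$annotation,
               "geneX")
})

test_that("raising the coverage threshold never adds off-target regions", {
  set.seed(4)
  st <- sample(0:25000, 300, replace = TRUE)
  paf <- rbind(make_paf(st, st + 1500),
               make_paf(rep(12000, 35), rep(14500, 35)))
  win <- data.frame(contig = "chr1", start = 1, end = 100)
  lo <- detect_offtargets(paf, win, min_coverage = 20)
  hi <- detect_offtargets(paf, win, min_coverage = 30)
  expect_lte(nrow(hi), nrow(lo))
  if (nrow(hi)) {
    for (i in seq_len(nrow(hi))) {
      expect_true(any(lo$contig == hi$contig[i] & lo$start <= hi$start[i] &
                        lo$end >= hi$end[i]))
    }
  }
})

test_that("simulator truth and QC agree in a closed loop", {
  pg <- planted_guide_genome(seed = 55, at = 12001, n = 40000)
  f <- digest_template(pg$genome[["chr1"]], pg$guide, "chr1")
  f <- ligate_adapters(da_tail(dephosphorylate(f, 1.0)),
                       sim_config(blocked_end_leak = 0))
  cfg <- sim_config(n_reads = 300, background_break_rate = 2e-4,
                    dephosphorylation_efficiency = 0.5, blocked_end_leak = 0,
                    read_length_model = list(max_read_length = 5000),
                    seed = 8)
  run <- simulate_run(pg$genome, f, cfg)
  cut <- f$end[1]
  win <- data.frame(contig = "chr1", start = cut + 1L, end = cut + 5000L)
  rep_qc <- enrichment_report(truth_paf(run), win)
  truth_on <- run$reads$start <= win$end & run$reads$end >= win$start
  expect_equal(rep_qc$on_target_coverage, sum(truth_on))
  expect_equal(rep_qc$aligned_reads, nrow(run$reads))
  expect_equal(rep_qc$on_target_forward, sum(truth_on & run$reads$strand == "+"))
  expect_equal(rep_qc$on_target_percentage,
               100 * sum(truth_on) / nrow(run$reads))
  # run-level stats agree with direct recomputation from the emitted FASTQ
  fq <- tempfile(fileext = ".fastq")
  write_fastq(run, fq)
  rs_run <- run_read_stats(run)
  rs_fq <- run_read_stats(fq)
  expect_equal(rs_run, rs_fq)
  expect_equal(rs_run$n50, oracle_n50(nchar(run$sequences)))
})
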