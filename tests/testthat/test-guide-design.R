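test_that("scan_pams is exhaustive and exact on canonical cases", {
  # no GG or CC dinucleotide anywhere: no candidate can exist
  expect_equal(nrow(scan_pams(strrep("AT", 20))), 0L)
  # a published 23-mer as whole input: exactly one forward candidate,
  # PAM TGG occupying positions 21-23
  hit <- scan_pams("GTCATATCTAAGGACCCGCGTGG")
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$strand, "+")
  expect_equal(hit$pam, "TGG")
  expect_equal(c(hit$start, hit$end), c(1L, 23L))
  expect_equal(hit$protospacer, "GTCATATCTAAGGACCCGCG")
})

test_that("scan_pams agrees with the brute-force sliding-window oracle", {
  for (seed in c(3, 8, 21)) {
    seqs <- rand_seq(500, seed)
    got <- scan_pams(seqs)
    want <- brute_scan_pams(seqs)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
    # every candidate reconstructs its genomic slice
    validate_guides(got, c(seq1 = seqs))
  }
})

test_that("scan_pams respects the ROI restriction and rejects bad ROIs", {
  seqs <- rand_seq(1000, 4)
  all <- scan_pams(seqs)
  roi <- c(301, 600)
  inside <- scan_pams(seqs, roi = roi)
  expect_true(all(inside$start >= 301 & inside$end <= 600))
  expect_equal(nrow(inside), sum(all$start >= 301 & all$end <= 600))
  expect_error(scan_pams(seqs, roi = c(900, 1200)), "ROI")
})

test_that("specificity_search recovers planted sites with mismatch maps", {
  pg <- planted_guide_genome(seed = 42)
  hits <- specificity_search(pg$guide, pg$genome, 4)
  expect_equal(sum(hits$mismatches == 0L), 1L)
  expect_true(hits$intended[hits$mismatches == 0L])

  # plant a second site with substitutions at protospacer positions 4 and 9
  p2 <- pg$protospacer
  substr(p2, 4, 4) <- chartr("ACGT", "CGTA", substr(p2, 4, 4))
  substr(p2, 9, 9) <- chartr("ACGT", "CGTA", substr(p2, 9, 9))
  genome2 <- c(chr1 = paste0(pg$genome[["chr1"]], p2, "AGG",
                             substr(pg$genome[["chr1"]], 1, 500)))
  hits2 <- specificity_search(pg$guide, genome2, 4)
  sec <- hits2[hits2$mismatches == 2L, ]
  expect_equal(nrow(sec), 1L)
  expect_equal(sec$mismatch_positions, "4,9")
})

test_that("specificity_search is strand-symmetric", {
  pg <- planted_guide_genome(seed = 9)
  hits_f <- specificity_search(pg$guide, pg$genome, 3)
  n <- nchar(pg$genome[["chr1"]])
  flipped <- c(chr1 = rc(pg$genome[["chr1"]]))
  hits_r <- specificity_search(pg$guide, flipped, 3)
  expect_equal(nrow(hits_f), nrow(hits_r))
  # mirrored coordinates and flipped strands
  mirrored <- sort(n - hits_f$end + 1L)
  expect_equal(sort(hits_r$start), mirrored)
  expect_equal(sort(hits_f$mismatches), sort(hits_r$mismatches))
})

test_that("specificity_score matches the documented weight aggregation", {
  base <- data.frame(contig = "c", start = 1L, end = 23L, strand = "+",
                     mismatches = 0L, mismatch_positions = "", has_pam = TRUE,
                     intended = TRUE)
  expect_equal(specificity_score(base), 100)
  dup <- rbind(base, transform(base, intended = FALSE))
  expect_equal(specificity_score(dup), 50)
  # one 4-mismatch secondary site, hand-evaluated from the weight table
  m <- mismatch_weights()
  pos <- c(3, 9, 14, 20)
  sec <- transform(base, mismatches = 4L,
                   mismatch_positions = paste(pos, collapse = ","),
                   intended = FALSE)
  w_sec <- prod(1 - m[pos])
  expect_equal(specificity_score(rbind(base, sec)), 100 / (1 + w_sec))
  # any secondary hit strictly lowers the score
  for (k in 1:5) {
    pos_k <- sort(sample(1:20, k))
    sec_k <- transform(base, mismatches = k,
                       mismatch_positions = paste(pos_k, collapse = ","),
                       intended = FALSE)
    expect_lt(specificity_score(rbind(base, sec_k)), 100)
  }
  expect_error(specificity_score(base[0, ]), "empty")
})

test_that("orientation follows the PAM-proximal-free-end rule and flips", {
  proto <- paste0(strrep("A", 19), "C")
  g_up_fwd <- guide("u", proto, "AGG", "c", 100, 122, "+")
  g_dn_fwd <- guide("d", proto, "AGG", "c", 5000, 5022, "+")
  g_dn_rev <- guide("r", proto, "AGG", "c", 5000, 5022, "-")
  g_up_rev <- guide("s", proto, "AGG", "c", 100, 122, "-")
  roi <- c(1000, 4000)
  expect_equal(orientation(g_up_fwd, roi), "toward")
  expect_equal(orientation(g_dn_fwd, roi), "away")
  expect_equal(orientation(g_dn_rev, roi), "toward")
  expect_equal(orientation(g_up_rev, roi), "away")
  # flipping strand with ROI fixed flips orientation; moving the ROI to the
  # other side with strand fixed flips it too
  expect_false(orientation(g_up_fwd, roi) == orientation(g_up_rev, roi))
  expect_false(orientation(g_up_fwd, roi) ==
                 orientation(g_up_fwd, c(10, 50)))
  expect_error(orientation(g_up_fwd, c(50, 150)), "overlap")
})

test_that("snp_effect classifies PAM and protospacer SNPs like the study cases", {
  # embed the second upstream guide's site; a G>A in the final triplet
  # destroys the NGG and silences cleavage
  site2 <- "TCTGTACTCCGTCTGTCGGTCGG"
  hap <- paste0(rand_seq(200, 31), site2, rand_seq(200, 32))
  g2 <- guide("crRNA_RF_2_F", substr(site2, 1, 20), substr(site2, 21, 23),
              "c", 201, 223, "+")
  expect_equal(snp_effect(g2, hap)$class, "full")
  expect_equal(snp_effect(g2, hap)$multiplier, 1.0)
  hap_pam <- hap
  substr(hap_pam, 222, 222) <- "A"       # penultimate G of ...TCGG
  e <- snp_effect(g2, hap_pam)
  expect_equal(e$class, "none")
  expect_lte(e$multiplier, cleavage_multipliers()$none)
  # the downstream guide's protospacer position-3 T>A is a distal mismatch:
  # reduced, but milder than a seed mismatch
  site4 <- "TGTCTGGAAAGTTTCTAACGCGG"
  hap4 <- paste0(rand_seq(150, 33), site4, rand_seq(150, 34))
  g4 <- guide("crRNA_RF_4_F", substr(site4, 1, 20), substr(site4, 21, 23),
              "c", 151, 173, "+")
  hap4_snp <- hap4
  substr(hap4_snp, 153, 153) <- "A"      # protospacer position 3
  e4 <- snp_effect(g4, hap4_snp)
  expect_equal(e4$class, "reduced")
  expect_equal(e4$subclass, "distal")
  expect_equal(e4$mismatch_positions, 3L)
  hap4_seed <- hap4
  substr(hap4_seed, 166, 166) <- "C"     # protospacer position 16 (seed)
  e4s <- snp_effect(g4, hap4_seed)
  expect_equal(e4s$subclass, "seed")
  expect_lt(e4s$multiplier, e4$multiplier)
  expect_error(snp_effect(g4, rand_seq(500, 35)), "not found")
})

test_that("plan_panel satisfies each strategy's postconditions", {
  withr_seed(100)
  genome <- c(chr = paste(sample(c("A", "C", "G", "T"), 40000, replace = TRUE),
                          collapse = ""))
  roi <- list(contig = "chr", start = 16000, end = 24000)   # 8 kb ROI
  panel <- plan_panel(roi, genome, "excision", params = list(n_per_side = 1))
  expect_gte(nrow(panel), 2L)
  for (i in seq_len(nrow(panel))) {
    expect_equal(orientation(panel[i, ], roi), "toward")
  }
  cuts <- vapply(seq_len(nrow(panel)), function(i)
    cut_site(panel[i, ])$position, numeric(1))
  expect_true(any(cuts < roi$start) && any(cuts >= roi$end))

  single <- plan_panel(roi, genome, "single_cut",
                       params = list(known_end = "left"))
  expect_equal(nrow(single), 1L)
  expect_equal(orientation(single[1, ], roi), "toward")
  expect_equal(cut_site(single[1, ])$free_side, "right")

  expect_error(plan_panel(list(contig = "chr", start = 100, end = 8000),
                          c(chr = strrep("AT", 5000)), "excision"),
               "no panel")
})

test_that("tiling panels space successive cuts 5-10 kb apart across the ROI", {
  withr_seed(101)
  genome <- c(chr = paste(sample(c("A", "C", "G", "T"), 40000, replace = TRUE),
                          collapse = ""))
  roi <- list(contig = "chr", start = 6000, end = 31000)    # 25 kb ROI
  panel <- plan_panel(roi, genome, "tiling")
  cuts <- sort(vapply(seq_len(nrow(panel)), function(i)
    cut_site(panel[i, ])$position, numeric(1)))
  expect_gte(length(cuts), 3L)
  gaps <- diff(cuts)
  expect_true(all(gaps >= 5000 & gaps <= 10000))
  expect_gte(max(cuts), roi$end)
})

test_that("guides round-trip through the TSV interchange layout", {
  g <- myb10_guides()
  f <- tempfile(fileext = ".tsv")
  write_guides(g, f)
  back <- read_guides(f)
  expect_equal(back$protospacer, g$protospacer)
  expect_equal(back$pam, g$pam)
  expect_equal(back$start, g$start)
  expect_equal(back$strand, g$strand)
})
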