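# a one-cut library on a single template: exactly one free (adapter) end
one_end_library <- function(seed = 42, n = 30000, at = 10001) {
  pg <- planted_guide_genome(seed = seed, at = at, n = n)
  f <- digest_template(pg$genome[["chr1"]], pg$guide, "chr1")
  f <- dephosphorylate(f, 1.0)
  f <- da_tail(f)
  list(genome = pg$genome, guide = pg$guide, fragments = f)
}

test_that("mean read quality is the probability-space mean", {
  expect_equal(mean_read_quality(rep(10, 50)), 10)
  expect_equal(mean_read_quality(c(10, 20)),
               -10 * log10((0.1 + 0.01) / 2), tolerance = 1e-12)
  expect_equal(round(mean_read_quality(c(10, 20)), 2), 12.60)
  set.seed(1)
  q <- sample(2:40, 30, replace = TRUE)
  expect_equal(mean_read_quality(q), mean_read_quality(rev(q)))
  expect_equal(mean_read_quality(q), mean_read_quality(sample(q)))
  expect_error(mean_read_quality(numeric(0)), "empty")
})

test_that("adapters ligate only to eligible ends, with configured leak", {
  lib <- one_end_library()
  f <- ligate_adapters(lib$fragments, sim_config(blocked_end_leak = 0))
  # fully dephosphorylated genome, one cut: adapter exactly at the free cut end
  expect_equal(sum(f$left_adapter) + sum(f$right_adapter), 1L)
  expect_true(f$left_adapter[f$left_class == "cut" & !f$left_blocked])
  # zero leak: no adapter on any blocked (PAM-distal) end
  expect_false(any(f$left_adapter & f$left_blocked) ||
                 any(f$right_adapter & f$right_blocked))
  # leak 0.1 over 1000 blocked ends: binomial 100 +/- 30
  blocked <- lib$fragments[rep(1, 500), ]   # each row: one blocked right end
  blocked <- da_tail(blocked)
  blocked2 <- blocked
  blocked2$left_blocked <- TRUE             # make both ends blocked cut ends
  blocked2$left_phos <- TRUE
  blocked2$left_class <- "cut"
  set.seed(5)
  out <- ligate_adapters(blocked2, sim_config(blocked_end_leak = 0.1))
  n_leak <- sum(out$left_leaked) + sum(out$right_leaked)
  expect_gte(n_leak, 70)
  expect_lte(n_leak, 130)
  expect_true(all(out$left_adapter[out$left_leaked]))
  expect_false(any(out$left_blocked & out$left_adapter))
})

test_that("error-free reads are exact substrings anchored at the cut", {
  lib <- one_end_library(seed = 6)
  f <- ligate_adapters(lib$fragments, sim_config(blocked_end_leak = 0))
  cfg <- sim_config(n_reads = 40, background_break_rate = 0,
                    blocked_end_leak = 0,
                    error_model = list(substitution = 0, insertion = 0,
                                       deletion = 0),
                    read_length_model = list(max_read_length = 3000),
                    seed = 99)
  run <- simulate_run(lib$genome, f, cfg)
  cutpos <- f$end[1]
  # single free end: every read anchored there on one strand
  expect_true(all(run$reads$start == cutpos + 1L))
  expect_true(all(run$reads$strand == "+"))
  expect_true(all(run$reads$source == "cut"))
  # exact substring oracle
  for (i in seq_len(10)) {
    want <- substr(lib$genome[["chr1"]], run$reads$start[i], run$reads$end[i])
    expect_identical(run$sequences[i], want)
  }
  # truth and FASTQ agree: ids bijective, qlen equals sequence length
  paf <- truth_paf(run)
  expect_equal(sort(paf$qname), sort(run$reads$id))
  expect_false(anyDuplicated(paf$qname) > 0)
  expect_equal(paf$qlen, nchar(run$sequences))
  expect_equal(nchar(run$qualities), nchar(run$sequences))
})

test_that("substitution errors land at the configured per-base rate", {
  lib <- one_end_library(seed = 10)
  f <- ligate_adapters(lib$fragments, sim_config(blocked_end_leak = 0))
  s_rate <- 0.08
  cfg <- sim_config(n_reads = 60, background_break_rate = 0,
                    blocked_end_leak = 0,
                    error_model = list(substitution = s_rate, insertion = 0,
                                       deletion = 0),
                    read_length_model = list(max_read_length = 4000),
                    seed = 7)
  run <- simulate_run(lib$genome, f, cfg)
  n_mm <- 0; n_bases <- 0
  for (i in seq_len(nrow(run$reads))) {
    want <- substr(lib$genome[["chr1"]], run$reads$start[i], run$reads$end[i])
    a <- strsplit(run$sequences[i], "")[[1]]
    b <- strsplit(want, "")[[1]]
    expect_equal(length(a), length(b))   # no indels configured
    n_mm <- n_mm + sum(a != b)
    n_bases <- n_bases + length(a)
  }
  p_hat <- n_mm / n_bases
  tol <- 3 * sqrt(s_rate * (1 - s_rate) / n_bases)
  expect_lt(abs(p_hat - s_rate), tol)
})

test_that("FASTQ and PAF artifacts round-trip", {
  lib <- one_end_library(seed = 20)
  f <- ligate_adapters(lib$fragments, sim_config())
  cfg <- sim_config(n_reads = 25, read_length_model = list(max_read_length = 2000),
                    seed = 3)
  run <- simulate_run(lib$genome, f, cfg)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(run, fq)
  back <- read_fastq(fq)
  expect_equal(back$id, run$reads$id)
  expect_equal(back$sequences, run$sequences)
  expect_equal(back$qualities, run$qualities)
  pp <- tempfile(fileext = ".paf")
  write_paf(truth_paf(run), pp)
  expect_equal(read_paf(pp), truth_paf(run))
})

test_that("raising the background break rate dilutes on-target reads", {
  lib <- one_end_library(seed = 30)
  f <- ligate_adapters(lib$fragments, sim_config(blocked_end_leak = 0))
  frac_cut <- vapply(c(0, 2e-4, 4e-3), function(rate) {
    cfg <- sim_config(n_reads = 400, background_break_rate = rate,
                      blocked_end_leak = 0,
                      dephosphorylation_efficiency = 0.5,
                      read_length_model = list(max_read_length = 3000),
                      seed = 77)
    run <- simulate_run(lib$genome, f, cfg)
    mean(run$reads$source == "cut")
  }, numeric(1))
  expect_equal(frac_cut[1], 1)            # no background: all reads cut-anchored
  expect_true(all(diff(frac_cut) < 0))
})

test_that("simulation is reproducible and refuses an empty source pool", {
  lib <- one_end_library(seed = 40)
  f <- ligate_adapters(lib$fragments, sim_config())
  cfg <- sim_config(n_reads = 20, seed = 5,
                    read_length_model = list(max_read_length = 1000))
  r1 <- simulate_run(lib$genome, f, cfg)
  r2 <- simulate_run(lib$genome, f, cfg)
  expect_identical(r1$sequences, r2$sequences)
  expect_identical(r1$qualities, r2$qualities)
  no_ad <- lib$fragments            # never ligated
  cfg0 <- sim_config(background_break_rate = 0)
  expect_error(simulate_run(lib$genome, no_ad, cfg0), "no possible read sources")
})
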