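# Independent brute-force oracles and tiny fixture builders. These stay
# deliberately naive (loops, direct definitions) so they cannot share bugs
# with the implementation paths they check.

rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

rand_seq <- function(n, seed, letters = c("A", "C", "G", "T")) {
  withr_seed(seed)
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# minimal local seed helper (avoid depending on package internals)
withr_seed <- function(seed) set.seed(seed)

# -- FASTA ------------------------------------------------------------------
naive_read_fasta <- function(path) {
  lines <- readLines(path)
  out <- character(0)
  cur <- NULL
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      cur <- sub("^>\\s*", "", strsplit(ln, "\\s+")[[1]][1])
      cur <- sub("^>", "", cur)
      out[cur] <- ""
    } else if (nzchar(trimws(ln))) {
      out[cur] <- paste0(out[cur], trimws(ln))
    }
  }
  out
}

# -- PAM scanning -----------------------------------------------------------
brute_scan_pams <- function(seq) {
  n <- nchar(seq)
  res <- list()
  for (s in seq_len(max(0, n - 22L))) {
    site <- substr(seq, s, s + 22L)
    if (grepl("[^ACGT]", site)) next
    if (substr(site, 22, 22) == "G" && substr(site, 23, 23) == "G") {
      res[[length(res) + 1L]] <- data.frame(start = s, strand = "+")
    }
    rsite <- rc(site)
    if (substr(rsite, 22, 22) == "G" && substr(rsite, 23, 23) == "G") {
      res[[length(res) + 1L]] <- data.frame(start = s, strand = "-")
    }
  }
  if (!length(res)) return(data.frame(start = integer(0), strand = character(0)))
  out <- do.call(rbind, res)
  out[order(out$start, out$strand), ]
}

# -- N50 / depth ------------------------------------------------------------
oracle_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  half <- sum(s) / 2
  acc <- 0
  for (l in s) {
    acc <- acc + l
    if (acc >= half) return(l)
  }
}

oracle_depth <- function(starts, ends, len) {
  d <- integer(len)
  for (i in seq_along(starts)) {
    for (p in starts[i]:ends[i]) d[p] <- d[p] + 1L
  }
  d
}

# -- repeat counting --------------------------------------------------------
# exact-match oracle for error-free reads: longest run of exact tandem
# occurrences, found by direct string matching
oracle_exact_copies <- function(read, motif) {
  hits <- gregexpr(motif, read, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(0L)
  runs <- cumsum(c(1L, as.integer(diff(hits) != nchar(motif))))
  max(tabulate(runs))
}

# -- modal clustering -------------------------------------------------------
oracle_alleles <- function(copies, min_support) {
  cp <- copies[copies > 0]
  if (!length(cp)) return(data.frame(copies = integer(0), support = integer(0)))
  tab <- table(cp)
  vals <- as.integer(names(tab)); supp <- as.integer(tab)
  centers <- vals[supp >= min_support]
  agg <- setNames(supp[match(centers, vals)], centers)
  for (i in seq_along(vals)) {
    v <- vals[i]
    if (v %in% centers) next
    nb <- intersect(c(v - 1L, v + 1L), centers)
    if (!length(nb)) next
    nb <- nb[order(-agg[as.character(nb)], nb)][1]
    agg[as.character(nb)] <- agg[as.character(nb)] + supp[i]
  }
  if (!length(centers)) return(data.frame(copies = integer(0), support = integer(0)))
  data.frame(copies = sort(centers),
             support = as.integer(agg[as.character(sort(centers))]))
}

# -- simple independent sequence mutator ------------------------------------
mutate_read <- function(seq, sub = 0, ins = 0, del = 0) {
  b <- strsplit(seq, "")[[1]]
  out <- character(0)
  alpha <- c("A", "C", "G", "T")
  for (x in b) {
    r <- runif(1)
    if (r < del) next
    if (r < del + sub) x <- sample(setdiff(alpha, x), 1)
    out <- c(out, x)
    if (runif(1) < ins) out <- c(out, sample(alpha, 1))
  }
  paste(out, collapse = "")
}

# read from a heterozygote haplotype: flanked tandem array at ~8% total error
make_het_read <- function(motif, copies, seed, flank = 150) {
  set.seed(seed)
  read <- paste0(rand_seq(flank, seed + 101), strrep(motif, copies),
                 rand_seq(flank, seed + 202))
  mutate_read(read, sub = 0.04, ins = 0.02, del = 0.02)
}

# -- small genome fixture ----------------------------------------------------
small_genome_config <- function(seed = 7, copies_b = 6, flank = 989,
                                identity = 0.9) {
  synthetic_genome_config(
    seed = seed,
    chromosomes = data.frame(name = c("c1", "c2"),
                             length = c(30000, 20000), gc = c(0.4, 0.5)),
    target_locus = list(chromosome = "c1", position = 15000, flank = flank,
                        repeat_unit = NULL, copies_hapA = 1,
                        copies_hapB = copies_b),
    paralog = list(chromosome = "c2", position = 10000, identity = identity))
}

# plant a 23-bp guide site into a background and return genome + guide
planted_guide_genome <- function(seed = 42, at = 10001, n = 30000) {
  withr_seed(seed)
  bg <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  proto <- "GTCATATCTAAGGACCCGCG"
  g <- paste0(substr(bg, 1, at - 1), proto, "TGG", substr(bg, at, n))
  list(genome = c(chr1 = g),
       guide = guide("g", proto, "TGG", "chr1", at, at + 22L, "+"),
       protospacer = proto)
}
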